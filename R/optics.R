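#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, scattering coefficient, single-scattering
#' anisotropy and refractive index of a homogeneous medium, validating the
#' physical constraints each must satisfy.
#'
#' @param mua Absorption coefficient (mm^-1), `>= 0`.
#' @param mus Scattering coefficient (mm^-1), `>= 0`. `mua + mus` must be
#'   positive: a medium with neither absorption nor scattering has no defined
#'   interaction free path.
#' @param g Single-scattering anisotropy (mean cosine of the scattering
#'   angle), strictly inside `(-1, 1)`.
#' @param n Refractive index, `>= 1`.
#'
#' @return An object of class `"optical_properties"`.
#' @seealso [transport_parameters()], [optics_from_ratio()], [tissue_optics()]
#' @examples
#' op <- optical_properties(mua = 0.00990099, mus = 4.95049505, g = 0.8)
#' transport_parameters(op)
#' @export
optical_properties <- function(mua, mus, g, n = 1.4) {
  stopifnot(is.numeric(mua), is.numeric(mus), is.numeric(g), is.numeric(n),
            length(mua) == 1L, length(mus) == 1L, length(g) == 1L,
            length(n) == 1L)
  if (!is.finite(mua) || mua < 0)
    stop("invalid optical properties: mua must be finite and >= 0")
  if (!is.finite(mus) || mus < 0)
    stop("invalid optical properties: mus must be finite and >= 0")
  if (mua + mus <= 0)
    stop("invalid optical properties: mua + mus must be > 0")
  if (!is.finite(g) || g <= -1 || g >= 1)
    stop("invalid optical properties: g must lie strictly in (-1, 1)")
  if (!is.finite(n) || n < 1)
    stop("invalid optical properties: n must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  d <- transport_parameters(x)
  cat("Optical properties (mm^-1 where dimensional):\n")
  cat(sprintf("  mua = %g  mus = %g  g = %g  n = %g\n", x$mua, x$mus, x$g, x$n))
  cat(sprintf("  derived: musp = %g  l* = %g mm  albedo = %g  musp/mua = %g\n",
              d$musp, d$lstar, d$albedo, d$ratio))
  invisible(x)
}

#' Derived transport quantities
#'
#' Computes the reduced scattering coefficient `musp = mus * (1 - g)`, the
#' transport mean free path `lstar = 1 / (mua + musp)`, the single-scattering
#' albedo `mus / (mua + mus)` and the dimensionless ratio `musp / mua` that,
#' together with `lstar`, indexes the sampling-depth lookup table.
#'
#' @param props An [optical_properties()] object.
#' @return A list with components `musp`, `lstar`, `albedo` and `ratio`.
#'   `ratio` is `Inf` when `mua = 0` (allowed, e.g. for energy-conservation
#'   checks).
#' @export
transport_parameters <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  musp <- props$mus * (1 - props$g)
  lstar <- 1 / (props$mua + musp)
  albedo <- props$mus / (props$mus + props$mua)
  ratio <- if (props$mua == 0) Inf else musp / props$mua
  list(musp = musp, lstar = lstar, albedo = albedo, ratio = ratio)
}

#' Optical properties from dimensionless transport coordinates
#'
#' Inverts [transport_parameters()]: given the ratio `musp/mua` and the
#' transport mean free path `lstar`, returns the unique
#' `(mua, mus)` pair with the requested anisotropy, so that
#' `mua = 1 / (lstar * (1 + ratio))` and `musp = ratio * mua`.
#' This is the parameterization used for the lookup-table grid
#' (`lstar = 1` mm, `g = 0.8`, `n = 1.4`).
#'
#' @param ratio Target `musp/mua` (> 0).
#' @param lstar Target transport mean free path (mm, > 0).
#' @param g,n Anisotropy and refractive index of the constructed medium.
#' @return An [optical_properties()] object; `transport_parameters()` of the
#'   result round-trips `ratio` and `lstar` to machine precision.
#' @examples
#' optics_from_ratio(100, lstar = 1)   # mua = 0.00990099, musp = 0.99009901
#' @export
optics_from_ratio <- function(ratio, lstar = 1, g = 0.8, n = 1.4) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, is.finite(ratio),
            is.numeric(lstar), length(lstar) == 1L, is.finite(lstar))
  if (ratio <= 0) stop("ratio must be > 0")
  if (lstar <= 0) stop("lstar must be > 0")
  if (g >= 1) stop("g = 1 leaves mus undefined (musp / (1 - g) diverges)")
  mua <- 1 / (lstar * (1 + ratio))
  musp <- ratio * mua
  mus <- musp / (1 - g)
  optical_properties(mua = mua, mus = mus, g = g, n = n)
}

# -- embedded presets --------------------------------------------------------

# Literature tissue optical properties used for the sampling-depth analysis,
# stored exactly as printed (derived columns are always recomputed).
.tissue_table <- data.frame(
  tissue     = rep(c("human breast", "human brain", "mouse skin", "human skin"),
                   each = 2),
  wavelength = rep(c(731, 851), times = 4),
  mua = c(0.0044, 0.0066, 0.0090, 0.0124, 0.0937, 0.1070, 0.2437, 0.1563),
  mus = c(37.51, 31.95, 16.41, 12.84, 7.73, 6.17, 16.32, 16.71),
  g   = c(0.97, 0.97, 0.92, 0.92, 0.9, 0.9, 0.8357, 0.8707),
  n   = c(1.4728, 1.4728, 1.4026, 1.4026, 1.4, 1.4, 1.4637, 1.4637),
  stringsAsFactors = FALSE
)

#' Embedded tissue optical-property presets
#'
#' Eight literature tissue/wavelength pairs (human breast, human brain, mouse
#' skin and human skin at 731 and 851 nm) used for the real-tissue
#' sampling-depth sweeps. Values are stored at full printed precision;
#' derived columns (`musp`, `lstar`, `ratio`) are recomputed on the fly.
#'
#' @param derived If `TRUE` (default) append the derived transport columns.
#' @return A data frame with one row per (tissue, wavelength) pair.
#' @export
tissue_presets <- function(derived = TRUE) {
  tab <- .tissue_table
  if (derived) {
    d <- t(vapply(seq_len(nrow(tab)), function(i) {
      p <- transport_parameters(
        optical_properties(tab$mua[i], tab$mus[i], tab$g[i], tab$n[i]))
      c(p$musp, p$lstar, p$ratio)
    }, numeric(3)))
    tab$musp <- d[, 1]; tab$lstar <- d[, 2]; tab$ratio <- d[, 3]
  }
  tab
}

#' Look up a single tissue preset
#'
#' @param tissue Tissue name (case-insensitive), one of the names in
#'   [tissue_presets()].
#' @param wavelength Wavelength in nm (731 or 851).
#' @return An [optical_properties()] object.
#' @examples
#' tissue_optics("human breast", 731)
#' @export
tissue_optics <- function(tissue, wavelength) {
  tab <- .tissue_table
  hit <- tolower(tissue) == tab$tissue & wavelength == tab$wavelength
  if (sum(hit) != 1L) {
    keys <- paste(sprintf("'%s' @ %d nm", tab$tissue, tab$wavelength),
                  collapse = ", ")
    stop(sprintf("unknown tissue preset '%s' @ %s nm; valid keys: %s",
                 tissue, format(wavelength), keys))
  }
  i <- which(hit)
  optical_properties(tab$mua[i], tab$mus[i], tab$g[i], tab$n[i])
}

#' Ratio axis of the dimensionless lookup grid
#'
#' The 18 `musp/mua` values (1 to 1000) of the general optical-property grid
#' used to build the sampling-depth lookup table at fixed `lstar = 1` mm,
#' `g = 0.8`, `n = 1.4`.
#'
#' @return A strictly increasing numeric vector of length 18.
#' @export
lookup_ratios <- function() {
  c(1, 1.6, 2, 3, 4, 5, 8, 10, 16, 20, 30, 50, 80, 100, 160, 250, 300, 1000)
}

#' Export the embedded preset tables as CSV
#'
#' Writes either the tissue presets (with derived columns) or the
#' lookup-grid general properties with their conventional column headers.
#'
#' @param path Output CSV path.
#' @param which `"tissues"` or `"lookup_grid"`.
#' @return The path, invisibly.
#' @export
write_presets_csv <- function(path, which = c("tissues", "lookup_grid")) {
  which <- match.arg(which)
  if (which == "tissues") {
    tab <- tissue_presets(derived = TRUE)
    out <- data.frame(
      `Tissue type` = tab$tissue, `lambda (nm)` = tab$wavelength,
      `mua (mm-1)` = tab$mua, `mus (mm-1)` = tab$mus, g = tab$g,
      `l*` = round(tab$lstar, 2), n = tab$n,
      `musp/mua` = round(tab$ratio, 2), `musp (mm-1)` = round(tab$musp, 2),
      check.names = FALSE)
  } else {
    r <- lookup_ratios()
    props <- lapply(r, optics_from_ratio)
    out <- data.frame(
      `musp/mua` = r,
      `mua (mm-1)` = vapply(props, `[[`, numeric(1), "mua"),
      `musp (mm-1)` = vapply(props, function(p)
        transport_parameters(p)$musp, numeric(1)),
      check.names = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
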