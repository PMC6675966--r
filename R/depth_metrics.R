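#' Depth-resolved reflectance summaries
#'
#' These functions convert a maximum-depth distribution `Pzmax(z)` into
#' measurable summaries:
#' * `total_reflectance()` — the diffuse reflectance `Rd`, the integral of
#'   `Pzmax` over all depths (for the discrete tally, the sum of all bins
#'   including the overflow bin);
#' * `restricted_reflectance()` — `Pzmax(z <= d)`, the reflectance carried by
#'   packets whose whole trajectory stayed at or above depth `d`, with linear
#'   pro-rating of the partially covered bin;
#' * `sampling_fraction()` — `X(d) = Pzmax(z <= d) / Rd`, the fraction of the
#'   detected light restricted to depths `<= d`;
#' * `percentile_depth()` — the inverse: the smallest depth `dX` at which
#'   `X(dX) >= X`, linearly interpolated inside the crossing bin.
#'
#' Methods exist for raw numeric bin-mass vectors (all bins regular, bin
#' height `dz`) and for `"sfd_tally"` objects (real part of the tallied
#' `Pzmax` row at a chosen frequency; the overflow bin counts toward `Rd`
#' and toward `d = Inf` only).
#'
#' @param x A numeric vector of per-bin `Pzmax` mass, or an `"sfd_tally"`.
#' @param d Depth (mm, `>= 0`; may be `Inf`).
#' @param X Detected-light fraction in `(0, 1]`.
#' @param fx For tally input: which tallied spatial frequency to use
#'   (must match one entry of `x$fx`).
#' @param dz Bin height for raw-vector input (mm).
#' @return A scalar: reflectance, fraction, or depth in mm.
#' @examples
#' pz <- c(0.3, 0.2, 0.1)                 # toy distribution, dz = 1 mm
#' total_reflectance(pz)                  # 0.6
#' sampling_fraction(pz, 1, dz = 1)       # 0.5
#' percentile_depth(pz, 0.5, dz = 1)      # 1.0
#' @name depth-metrics
NULL

# internal: real Pzmax row for one frequency (includes overflow bin)
tally_row <- function(x, fx) {
  if (is.null(fx)) {
    if (length(x$fx) > 1L)
      stop("tally holds several frequencies; supply fx =")
    i <- 1L
  } else {
    i <- which(abs(x$fx - fx) <= 1e-12)
    if (length(i) != 1L)
      stop(sprintf("fx = %g not tallied (available: %s)", fx,
                   paste(x$fx, collapse = ", ")))
  }
  Re(x$pzmax[i, ])
}

#' @rdname depth-metrics
#' @export
total_reflectance <- function(x, ...) UseMethod("total_reflectance")

#' @rdname depth-metrics
#' @export
total_reflectance.default <- function(x, ...) sum(x)

#' @rdname depth-metrics
#' @param ... Passed between methods.
#' @export
total_reflectance.sfd_tally <- function(x, fx = NULL, ...)
  sum(tally_row(x, fx))

# core cumulative-with-pro-rating on regular bins
restricted_core <- function(mass, dz, d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single depth >= 0")
  nb <- length(mass)
  if (d >= nb * dz) return(sum(mass))
  k <- floor(d / dz)
  out <- if (k > 0) sum(mass[seq_len(k)]) else 0
  frac <- d / dz - k
  if (frac > 0) out <- out + frac * mass[k + 1]
  out
}

#' @rdname depth-metrics
#' @export
restricted_reflectance <- function(x, d, ...)
  UseMethod("restricted_reflectance")

#' @rdname depth-metrics
#' @export
restricted_reflectance.default <- function(x, d, dz = NULL, ...) {
  if (is.null(dz)) stop("supply dz for raw bin-mass input")
  if (is.infinite(d)) return(sum(x))
  restricted_core(x, dz, d)
}

#' @rdname depth-metrics
#' @export
restricted_reflectance.sfd_tally <- function(x, d, fx = NULL, ...) {
  row <- tally_row(x, fx)
  if (is.infinite(d)) return(sum(row))           # overflow included
  nb <- x$grid$n_bins
  restricted_core(row[seq_len(nb)], x$grid$dz, min(d, x$grid$z_cap))
}

#' @rdname depth-metrics
#' @export
sampling_fraction <- function(x, d, ...) UseMethod("sampling_fraction")

#' @rdname depth-metrics
#' @export
sampling_fraction.default <- function(x, d, dz = NULL, ...) {
  rd <- total_reflectance(x)
  if (rd <= 0) stop("sampling fraction undefined: Rd = 0")
  restricted_reflectance(x, d, dz = dz) / rd
}

#' @rdname depth-metrics
#' @export
sampling_fraction.sfd_tally <- function(x, d, fx = NULL, ...) {
  rd <- total_reflectance(x, fx = fx)
  if (rd <= 0) stop("sampling fraction undefined: Rd = 0")
  restricted_reflectance(x, d, fx = fx) / rd
}

# inverse of the cumulative fraction on regular bins; overflow_mass counts
# toward Rd but is unattainable by any finite depth
percentile_core <- function(mass, dz, X, overflow_mass = 0, z_cap = NULL) {
  if (!is.numeric(X) || length(X) != 1L || is.na(X) || X <= 0 || X > 1)
    stop("X must lie in (0, 1]")
  rd <- sum(mass) + overflow_mass
  if (rd <= 0) stop("percentile depth undefined: Rd = 0")
  target <- X * rd
  cum <- cumsum(mass)
  tot <- cum[length(cum)]
  if (target > tot) {
    cap <- if (is.null(z_cap)) length(mass) * dz else z_cap
    stop(sprintf(
      "X = %g exceeds the fraction attainable within z_cap = %g mm (%.4g); raise z_cap",
      X, cap, tot / rd))
  }
  i <- which(cum >= target)[1]
  before <- if (i > 1) cum[i - 1] else 0
  (i - 1) * dz + dz * (target - before) / mass[i]
}

#' @rdname depth-metrics
#' @export
percentile_depth <- function(x, X, ...) UseMethod("percentile_depth")

#' @rdname depth-metrics
#' @export
percentile_depth.default <- function(x, X, dz = NULL, ...) {
  if (is.null(dz)) stop("supply dz for raw bin-mass input")
  percentile_core(x, dz, X)
}

#' @rdname depth-metrics
#' @export
percentile_depth.sfd_tally <- function(x, X, fx = NULL, ...) {
  row <- tally_row(x, fx)
  nb <- x$grid$n_bins
  percentile_core(row[seq_len(nb)], x$grid$dz, X,
                  overflow_mass = row[nb + 1L], z_cap = x$grid$z_cap)
}

#' Percentile sampling-depth table
#'
#' Computes, for every tallied spatial frequency, the diffuse reflectance
#' `Rd` and the percentile sampling depths `dX` for each requested fraction
#' `X` — the machine-readable form of the usual median-depth-with-intervals
#' figure.
#'
#' @param x An `"sfd_tally"`.
#' @param X Fractions in `(0, 1]`, default `c(0.1, 0.25, 0.5, 0.75, 0.9)`.
#' @return A data frame with columns `fx`, `Rd` and one `d<percent>` column
#'   per fraction (e.g. `d50`), depths in mm.
#' @export
depth_summary <- function(x, X = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(x, "sfd_tally"))
  if (any(X <= 0 | X > 1)) stop("X must lie in (0, 1]")
  out <- data.frame(fx = x$fx,
                    Rd = vapply(x$fx, function(f)
                      total_reflectance(x, fx = f), numeric(1)))
  for (xx in X) {
    col <- paste0("d", formatC(100 * xx, format = "fg"))
    out[[col]] <- vapply(x$fx, function(f)
      percentile_depth(x, xx, fx = f), numeric(1))
  }
  out
}
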