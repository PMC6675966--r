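#' Absorbing base layer for two-layer phantom simulations
#'
#' Default optical properties of the extinguishing base: `mua = 100` mm^-1
#' with no scattering, so any packet crossing the interface is terminated at
#' its first collision (within ~0.01 mm). The refractive index defaults to
#' the top layer's so the internal interface is index-matched, as in a
#' water-based liquid-over-gel phantom.
#'
#' @param n Refractive index of the base layer.
#' @param mua,mus Absorption and scattering coefficients (mm^-1).
#' @return An [optical_properties()] object.
#' @export
absorbing_base <- function(n = 1.4, mua = 100, mus = 0) {
  optical_properties(mua = mua, mus = mus, g = 0, n = n)
}

#' Two-layer phantom sweep: extinction depth vs. restricted reflectance
#'
#' For each top-layer thickness `d`, runs a two-layer simulation whose base
#' extinguishes every packet reaching depth `d`, and compares its diffuse
#' reflectance `Rd(fx)` with the depth-restricted reflectance
#' `Pzmax(z <= d)` of a single homogeneous simulation of the top medium.
#' The two columns estimate the same quantity: a packet survives the
#' two-layer medium iff its maximum depth stays above the base, which is
#' exactly the event selected by restricting the homogeneous maximum-depth
#' distribution to `z <= d`. This is the in-silico twin of the layered
#' phantom measurement in which an absorbing gel is submerged at increasing
#' depths below a scattering liquid.
#'
#' @param top [optical_properties()] of the scattering top medium.
#' @param depths Top-layer thicknesses in mm (default `[0, 7.5] * lstar` in
#'   steps of `0.25 * lstar`). `d = 0` is the bare absorber (zero
#'   reflectance).
#' @param fx Spatial frequencies (mm^-1).
#' @param n_packets Packets per simulation.
#' @param seed Base seed; the homogeneous run uses `seed` and the sweep run
#'   for the i-th depth uses `seed + i`.
#' @param grid [depth_grid()] for the homogeneous tally; `z_cap` must cover
#'   `max(depths)`.
#' @param base Base-layer properties, default [absorbing_base()] matched to
#'   the top layer's index.
#' @param n_ambient Ambient refractive index.
#' @param ... Further transport options passed to [sfd_simulate()].
#' @return A data frame with columns `d`, `fx`, `rd_two_layer`,
#'   `sigma_two_layer`, `restricted` (homogeneous `Pzmax(z<=d)`),
#'   `sigma_restricted` and `diff`, plus the homogeneous tally as attribute
#'   `"homogeneous"`.
#' @export
phantom_sweep <- function(top, depths = NULL, fx = default_fx(),
                          n_packets = 1e5, seed = 1, grid = NULL,
                          base = absorbing_base(n = top$n),
                          n_ambient = 1.0, ...) {
  stopifnot(inherits(top, "optical_properties"))
  lstar <- transport_parameters(top)$lstar
  if (is.null(depths)) depths <- seq(0, 7.5, by = 0.25) * lstar
  if (any(depths < 0)) stop("depths must be >= 0")
  if (is.null(grid)) {
    cap <- max(40, ceiling(max(depths) / 10) * 10)
    grid <- depth_grid(dz = 0.01, z_cap = cap)
  }
  if (max(depths) > grid$z_cap)
    stop("grid z_cap must cover max(depths)")

  hom <- sfd_simulate(semi_infinite_stack(top, n_ambient = n_ambient),
                      fx = fx, n_packets = n_packets, seed = seed,
                      grid = grid, ...)
  rows <- list()
  for (i in seq_along(depths)) {
    d <- depths[i]
    stack_i <- if (d == 0)
      semi_infinite_stack(base, n_ambient = n_ambient)
    else
      two_layer_stack(top, d, base, n_ambient = n_ambient)
    two <- sfd_simulate(stack_i, fx = fx, n_packets = n_packets,
                        seed = seed + i, grid = grid, ...)
    rd2 <- Re(two$pvd[, 1])
    restr <- vapply(fx, function(f)
      restricted_reflectance(hom, d, fx = f), numeric(1))
    # 1-sigma of the restricted estimate from the per-bin second moments
    # (full bins at or above d; sub-bin pro-rating is negligible at dz)
    k <- min(floor(d / grid$dz), grid$n_bins)
    s2b <- if (k > 0) rowSums(hom$second_moment[, seq_len(k), drop = FALSE])
           else rep(0, length(fx))
    sig_restr <- sqrt(pmax((s2b / n_packets - restr^2) / n_packets, 0))
    rows[[i]] <- data.frame(
      d = d, fx = fx, rd_two_layer = rd2, sigma_two_layer = two$sigma[, 1],
      restricted = restr, sigma_restricted = sig_restr,
      diff = rd2 - restr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "homogeneous") <- hom
  out
}
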