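#' Depth grid for maximum-depth tallies
#'
#' Uniform depth bins `[i*dz, (i+1)*dz)` from the surface down to `z_cap`,
#' plus one overflow bin collecting packets whose maximum depth exceeds
#' `z_cap`. The default bin height of 0.01 mm gives sub-millimetre resolution
#' of the depth distributions.
#'
#' @param dz Bin height (mm, > 0). Default 0.01.
#' @param z_cap Deepest tallied depth (mm); must be a positive multiple of
#'   `dz`. Default 40.
#' @return A list with `dz`, `z_cap`, `n_bins` and `z_lower` (lower bin
#'   edges, the last entry being the overflow bin at `z_cap`).
#' @export
depth_grid <- function(dz = 0.01, z_cap = 40) {
  stopifnot(is.numeric(dz), is.numeric(z_cap), length(dz) == 1L,
            length(z_cap) == 1L)
  if (dz <= 0) stop("dz must be > 0")
  n_bins <- round(z_cap / dz)
  if (n_bins < 1 || abs(n_bins * dz - z_cap) > 1e-9 * z_cap)
    stop("z_cap must be a positive multiple of dz")
  structure(list(dz = dz, z_cap = z_cap, n_bins = as.integer(n_bins),
                 z_lower = c(seq_len(n_bins) - 1, n_bins) * dz),
            class = "depth_grid")
}

#' Default spatial-frequency list (mm^-1)
#'
#' The frequency set used by typical SFD instruments: 0 to 0.1 in steps of
#' 0.0125, then 0.125 to 0.2 in steps of 0.025, then 0.25 and 0.3.
#'
#' @param extended If `TRUE`, append 0.4 and 0.5 mm^-1 (subdiffusive range).
#' @return Numeric vector of spatial frequencies.
#' @export
default_fx <- function(extended = FALSE) {
  fx <- c(0, 0.0125, 0.025, 0.0375, 0.05, 0.0625, 0.075, 0.0875, 0.1,
          0.125, 0.15, 0.175, 0.2, 0.25, 0.3)
  if (extended) fx <- c(fx, 0.4, 0.5)
  fx
}

#' Complex SFD tally weight of a detected packet
#'
#' The per-packet random variable accumulated by the spatial-frequency-domain
#' tally: `xi = W * exp(-2i * pi * fx * dx)`, where `dx` is the displacement
#' along the modulation axis between the entry and exit points. Its modulus
#' is the detected weight; its expectation over packets is the SFD
#' reflectance.
#'
#' @param W Detected packet weight(s), > 0.
#' @param fx Spatial frequency (mm^-1, >= 0).
#' @param dx Lateral displacement(s) `xf - x0` (mm).
#' @return Complex tally value(s).
#' @export
sfd_weight <- function(W, fx, dx) {
  if (any(W <= 0)) stop("W must be > 0")
  if (any(fx < 0)) stop("fx must be >= 0")
  W * exp(-2i * pi * fx * dx)
}

#' Interconvert maximum-depth and visitation probability profiles
#'
#' `pvd_from_pzmax()` forms the reverse cumulative sum: the probability of a
#' detected packet having visited depth `z` or deeper is the total
#' maximum-depth mass at or below that bin. `pzmax_from_pvd()` is its exact
#' inverse (successive differences, last bin kept as is). Both accept a
#' vector or a matrix with one row per spatial frequency, real or complex.
#'
#' @param pzmax,pvd Numeric or complex vector/matrix of per-bin mass.
#' @return Object of the same shape.
#' @export
pvd_from_pzmax <- function(pzmax) {
  f <- function(v) rev(cumsum(rev(v)))
  if (is.matrix(pzmax)) t(apply(pzmax, 1, f)) else f(pzmax)
}

#' @rdname pvd_from_pzmax
#' @export
pzmax_from_pvd <- function(pvd) {
  f <- function(v) v - c(v[-1], if (is.complex(v)) 0 + 0i else 0)
  if (is.matrix(pvd)) t(apply(pvd, 1, f)) else f(pvd)
}

# assemble an sfd_tally object from raw per-bin complex sums
finalize_tally <- function(sum_re, sum_im, sum_re2, sum_im2, fx, grid,
                           n_packets, n_detected, n_truncated, seed,
                           packet_offset, stack, options,
                           runtime = NA_real_) {
  if (n_packets < 1) stop("n_packets must be >= 1")
  N <- n_packets
  pzmax <- (sum_re + 1i * sum_im) / N
  pvd <- pvd_from_pzmax(pzmax)
  cum_sigma <- function(s1, s2) {
    v <- (pvd_from_pzmax(s2) / N - (pvd_from_pzmax(s1) / N)^2) / N
    sqrt(pmax(v, 0))
  }
  sigma <- cum_sigma(sum_re, sum_re2)
  sigma_im <- cum_sigma(sum_im, sum_im2)
  structure(list(
    fx = fx, grid = grid, pzmax = pzmax, pvd = pvd, sigma = sigma,
    sigma_im = sigma_im, second_moment = sum_re2,
    n_packets = N, n_detected = n_detected, n_truncated = n_truncated,
    seed = seed, packet_offset = packet_offset, stack = stack,
    options = options, runtime = runtime), class = "sfd_tally")
}

#' Monte Carlo SFD depth-sampling simulation
#'
#' Runs the photon-packet random walk of [sfd_events()] with a streaming
#' complex tally: each detected packet deposits
#' `xi = W * exp(-2i*pi*fx*dx)` into the depth bin containing the maximum
#' depth `zmax` of its trajectory, once per spatial frequency. Dividing the
#' binned sums by the number of *launched* packets gives the maximum-depth
#' distribution `Pzmax(z)`; its reverse cumulative sum is the
#' visitation-and-detection probability `PV&D(z)`, whose surface value is the
#' diffuse reflectance `Rd(fx)`. Tallying once at `zmax` and cumulating is
#' mathematically identical to scoring every midway surface shallower than
#' `zmax`, at O(1) cost per packet.
#'
#' Reported distributions are the real parts of the complex estimates; the
#' imaginary parts are retained in the object and vanish in expectation for
#' this laterally symmetric geometry.
#'
#' @inheritParams sfd_events
#' @param fx Spatial frequencies to tally (mm^-1), default [default_fx()].
#' @param grid A [depth_grid()].
#' @param verbose Print a progress line every 1e5 packets and a final
#'   summary.
#' @return An object of class `"sfd_tally"` with components `fx`, `grid`,
#'   complex matrices `pzmax` and `pvd` (rows = frequencies, columns = depth
#'   bins including the final overflow bin), `sigma` (1-sigma error of
#'   `Re(pvd)`), `n_packets`, `n_detected`, `n_truncated`, `seed`, `stack`,
#'   `options`, `runtime` (seconds).
#' @seealso [depth_summary()], [percentile_depth()], [plot.sfd_tally()]
#' @examples
#' ref <- semi_infinite_stack(optics_from_ratio(100, lstar = 1))
#' tal <- sfd_simulate(ref, fx = c(0, 0.1), n_packets = 2000, seed = 7)
#' summary(tal)
#' @export
sfd_simulate <- function(stack, fx = default_fx(), n_packets = 1e6,
                         seed = 1, grid = depth_grid(), packet_offset = 0,
                         roulette_threshold = 1e-4, roulette_survival = 0.1,
                         specular = c("exclude", "fresnel"),
                         max_steps = 1e7, verbose = FALSE) {
  stopifnot(inherits(stack, "layer_stack"), inherits(grid, "depth_grid"))
  specular <- match.arg(specular)
  if (!is.numeric(n_packets) || n_packets < 1)
    stop("config error: n_packets must be >= 1")
  if (any(fx < 0) || anyDuplicated(fx))
    stop("config error: fx must be distinct nonnegative frequencies")
  check_transport_opts(roulette_threshold, roulette_survival, max_steps)
  t0 <- proc.time()[["elapsed"]]
  res <- .cpp_mc_tally(as_layer_matrix(stack), stack$n_ambient,
                       as.numeric(fx), grid$dz, grid$n_bins,
                       as.numeric(n_packets), as.integer(seed),
                       as.numeric(packet_offset),
                       roulette_threshold, roulette_survival,
                       specular == "fresnel", max_steps,
                       if (verbose) 1e5 else 0)
  runtime <- proc.time()[["elapsed"]] - t0
  opts <- list(roulette_threshold = roulette_threshold,
               roulette_survival = roulette_survival,
               specular = specular, max_steps = max_steps)
  out <- finalize_tally(res$sum_re, res$sum_im, res$sum_re2, res$sum_im2,
                        fx, grid, n_packets, res$n_detected,
                        res$n_truncated, seed, packet_offset, stack, opts,
                        runtime)
  if (verbose) {
    cat(sprintf("launched %g packets in %.1f s; detected weight/packet:\n",
                n_packets, runtime))
    print(stats::setNames(round(Re(out$pvd[, 1]), 5), paste0("fx=", fx)))
  }
  out
}

#' Tally a stored stream of detection events
#'
#' Builds an `"sfd_tally"` from an event table (e.g. from [sfd_events()] or a
#' synthetic fixture), accumulating the complex SFD weight of each event into
#' the depth bin of its maximum depth, in event order. With events produced
#' by [sfd_events()] under the same seed this reproduces the streaming tally
#' of [sfd_simulate()].
#'
#' @param events Data frame with columns `W`, `dx`, `zmax`.
#' @param fx Spatial frequencies (mm^-1).
#' @param grid A [depth_grid()].
#' @param n_packets Number of packets *launched* to produce the events
#'   (the tally normalizer); defaults to `attr(events, "n_packets")`.
#' @return An `"sfd_tally"`.
#' @export
tally_events <- function(events, fx, grid = depth_grid(),
                         n_packets = attr(events, "n_packets")) {
  stopifnot(is.data.frame(events),
            all(c("W", "dx", "zmax") %in% names(events)),
            inherits(grid, "depth_grid"))
  if (is.null(n_packets)) stop("n_packets missing and not an attribute")
  if (any(events$zmax < 0)) stop("internal error: negative zmax in events")
  K <- length(fx); B <- grid$n_bins + 1L
  sum_re <- matrix(0, K, B); sum_im <- matrix(0, K, B)
  sum_re2 <- matrix(0, K, B); sum_im2 <- matrix(0, K, B)
  bins <- pmin(floor(events$zmax / grid$dz), grid$n_bins) + 1L
  twopif <- -2 * pi * fx
  for (j in seq_len(nrow(events))) {        # event order, scalar adds, to
    b <- bins[j]; W <- events$W[j]          # mirror the streaming kernel
    ph <- twopif * events$dx[j]
    re <- W * cos(ph); im <- W * sin(ph)
    for (k in seq_len(K)) {
      sum_re[k, b] <- sum_re[k, b] + re[k]
      sum_im[k, b] <- sum_im[k, b] + im[k]
      sum_re2[k, b] <- sum_re2[k, b] + re[k]^2
      sum_im2[k, b] <- sum_im2[k, b] + im[k]^2
    }
  }
  finalize_tally(sum_re, sum_im, sum_re2, sum_im2, fx, grid, n_packets,
                 nrow(events), attr(events, "n_truncated"),
                 attr(events, "seed"), attr(events, "packet_offset"),
                 NULL, list())
}

# -- methods ----------------------------------------------------------------

#' @export
print.sfd_tally <- function(x, ...) {
  cat("SFD maximum-depth Monte Carlo tally\n")
  cat(sprintf("  packets launched: %g  detected: %g  truncated: %g\n",
              x$n_packets, x$n_detected, x$n_truncated))
  cat(sprintf("  depth grid: dz = %g mm, z_cap = %g mm (+ overflow bin)\n",
              x$grid$dz, x$grid$z_cap))
  cat(sprintf("  seed: %s   runtime: %s s\n", format(x$seed),
              format(round(x$runtime, 2))))
  rd <- Re(x$pvd[, 1])
  cat("  diffuse reflectance Rd(fx):\n")
  print(stats::setNames(signif(rd, 4), paste0("fx=", x$fx)))
  invisible(x)
}

#' @export
summary.sfd_tally <- function(object, X = c(0.1, 0.25, 0.5, 0.75, 0.9), ...) {
  structure(list(tally = object,
                 depths = depth_summary(object, X = X)),
            class = "summary.sfd_tally")
}

#' @export
print.summary.sfd_tally <- function(x, ...) {
  print(x$tally)
  cat("\nPercentile sampling depths (mm):\n")
  print(x$depths, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.sfd_tally <- function(x, ...) {
  K <- length(x$fx); B <- x$grid$n_bins + 1L
  data.frame(
    fx = rep(x$fx, each = B),
    z_bin_lower = rep(x$grid$z_lower, times = K),
    pvd_re = as.vector(t(Re(x$pvd))),
    pvd_im = as.vector(t(Im(x$pvd))),
    pvd_sigma = as.vector(t(x$sigma)),
    pzmax_re = as.vector(t(Re(x$pzmax))),
    pzmax_im = as.vector(t(Im(x$pzmax))))
}

#' Plot SFD depth distributions
#'
#' Plots `Re(PV&D)(z)` (default) or `Re(Pzmax)(z)` against depth, one curve
#' per spatial frequency, on a logarithmic ordinate.
#'
#' @param x An `"sfd_tally"`.
#' @param what `"pvd"` or `"pzmax"`.
#' @param zmax_plot Right edge of the depth axis (mm); default `z_cap`.
#' @param log Axis log specification passed to [graphics::matplot()].
#' @param ... Further arguments to [graphics::matplot()].
#' @return The tally, invisibly.
#' @export
plot.sfd_tally <- function(x, what = c("pvd", "pzmax"), zmax_plot = NULL,
                           log = "y", ...) {
  what <- match.arg(what)
  m <- Re(if (what == "pvd") x$pvd else x$pzmax)
  z <- x$grid$z_lower
  keep <- seq_len(x$grid$n_bins)           # drop the overflow bin
  if (!is.null(zmax_plot)) keep <- keep[z[keep] <= zmax_plot]
  y <- t(m[, keep, drop = FALSE])
  y[y <= 0] <- NA                          # log axis
  graphics::matplot(z[keep], y, type = "l", lty = 1, log = log,
                    xlab = "depth z (mm)",
                    ylab = if (what == "pvd") "PV&D(z)" else "Pzmax(z)", ...)
  graphics::legend("topright", legend = paste0("fx=", x$fx), lty = 1,
                   col = seq_along(x$fx), cex = 0.7, bty = "n")
  invisible(x)
}

#' Re-run a tally's configuration with fresh seeds
#'
#' `simulate()` on an `"sfd_tally"` repeats the identical simulation
#' configuration (stack, frequencies, grid, packet count, transport options)
#' under new seeds, returning independent replicate tallies.
#'
#' @param object An `"sfd_tally"` produced by [sfd_simulate()].
#' @param nsim Number of replicates.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`. Defaults to the
#'   original seed + 1.
#' @param ... Unused.
#' @return A list of `"sfd_tally"` objects (length `nsim`), or a single
#'   tally if `nsim = 1`.
#' @export
simulate.sfd_tally <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$stack))
    stop("cannot simulate: tally was built from events, not a stack")
  if (is.null(seed)) seed <- object$seed + 1
  reps <- lapply(seq_len(nsim), function(i)
    sfd_simulate(object$stack, fx = object$fx, n_packets = object$n_packets,
                 seed = seed + i - 1, grid = object$grid,
                 roulette_threshold = object$options$roulette_threshold,
                 roulette_survival = object$options$roulette_survival,
                 specular = object$options$specular,
                 max_steps = object$options$max_steps))
  if (nsim == 1) reps[[1]] else reps
}
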