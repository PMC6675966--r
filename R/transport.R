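#' Elementary transport sampling kernels
#'
#' Thin, validated wrappers over the compiled kernels used inside the photon
#' random walk; exposed so their statistical properties can be tested in
#' isolation.
#'
#' `sample_step()` converts a uniform variate into an exponential free path
#' `-log(u)/mut`. `sample_hg()` inverts the Henyey-Greenstein CDF to draw the
#' cosine of the polar scattering angle; its first moment equals the
#' anisotropy `g`. `fresnel_reflectance()` is the unpolarized Fresnel
#' reflectance (average of s and p polarizations with Snell refraction),
#' returning 1 beyond the critical angle.
#'
#' @param u Uniform variate(s); in `(0, 1]` for `sample_step`, `[0, 1)` for
#'   `sample_hg`.
#' @param mut Total interaction coefficient `mua + mus` (mm^-1, > 0).
#' @param g Anisotropy, strictly in `(-1, 1)`.
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_incident Cosine(s) of the incidence angle, in `[0, 1]`.
#' @return Numeric vector: step lengths (mm), scattering cosines in
#'   `[-1, 1]`, or reflectance probabilities in `[0, 1]`.
#' @examples
#' sample_step(exp(-1), mut = 1)          # unit free path
#' sample_hg(0.5, g = 0.8)                # 0.9440
#' fresnel_reflectance(1.4, 1.0, 1)       # ((0.4)/(2.4))^2
#' @name transport-kernels
NULL

#' @rdname transport-kernels
#' @export
sample_step <- function(u, mut) {
  stopifnot(is.numeric(u), is.numeric(mut), length(mut) == 1L)
  if (!is.finite(mut) || mut <= 0) stop("mut must be finite and > 0")
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  -log(u) / mut
}

#' @rdname transport-kernels
#' @export
sample_hg <- function(u, g) {
  stopifnot(is.numeric(u), is.numeric(g), length(g) == 1L)
  if (g <= -1 || g >= 1) stop("g must lie strictly in (-1, 1)")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  .cpp_sample_hg(as.numeric(u), g)
}

#' @rdname transport-kernels
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(is.numeric(n1), is.numeric(n2),
            length(n1) == 1L, length(n2) == 1L)
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1")
  if (any(cos_incident < 0 | cos_incident > 1))
    stop("cos_incident must lie in [0, 1]")
  .cpp_fresnel(n1, n2, as.numeric(cos_incident))
}

# shared validation of transport options
check_transport_opts <- function(roulette_threshold, roulette_survival,
                                 max_steps) {
  if (!is.numeric(roulette_threshold) || roulette_threshold <= 0 ||
      roulette_threshold >= 1)
    stop("config error: roulette_threshold must lie in (0, 1)")
  if (!is.numeric(roulette_survival) || roulette_survival <= 0 ||
      roulette_survival >= 1)
    stop("config error: roulette_survival must lie in (0, 1)")
  if (!is.numeric(max_steps) || max_steps < 1e3)
    stop("config error: max_steps must be at least 1e3")
  invisible(TRUE)
}

#' Simulate detection events packet by packet
#'
#' Propagates `n_packets` photon packets through a layered medium (pencil
#' beam at the origin, normal incidence) and returns one record per
#' *detected* packet: its residual weight `W` after discrete absorption
#' weighting, the lateral displacement `dx` between entry and exit along the
#' modulation axis, the maximum depth `zmax` its trajectory visited, and the
#' exit direction. Packets use independent random substreams indexed by
#' `packet_offset + 0:(n_packets-1)`, so a run may be partitioned across
#' calls without changing any trajectory.
#'
#' This event-level interface exists for validation and for custom tallies;
#' [sfd_simulate()] performs the same transport with a streaming tally and is
#' the ordinary entry point.
#'
#' @param stack A [layer_stack()].
#' @param n_packets Number of packets to launch.
#' @param seed Integer seed of the random stream family.
#' @param packet_offset Index of the first packet's substream.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability (defaults 1e-4 and 0.1). Roulette is
#'   unbiased: survivors carry weight `W / roulette_survival`.
#' @param specular `"exclude"` (default) launches packets just inside the
#'   medium with weight 1, excluding the specular reflection from the tally
#'   (crossed-polarizer convention); `"fresnel"` instead launches with weight
#'   `1 - ((n - n_ambient)/(n + n_ambient))^2`.
#' @param max_steps Per-packet cap on collision count; packets exceeding it
#'   are terminated and counted in `attr(, "n_truncated")`. Guards against
#'   the heavy-tailed return times of (nearly) conservative media.
#' @return A data frame with columns `packet`, `W`, `dx`, `zmax`,
#'   `exit_ux`, `exit_uy`, `exit_uz`, with attributes `n_packets`, `seed`,
#'   `packet_offset`, `n_truncated`.
#' @export
sfd_events <- function(stack, n_packets, seed, packet_offset = 0,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       specular = c("exclude", "fresnel"),
                       max_steps = 1e7) {
  stopifnot(inherits(stack, "layer_stack"), n_packets >= 1)
  specular <- match.arg(specular)
  check_transport_opts(roulette_threshold, roulette_survival, max_steps)
  res <- .cpp_mc_events(as_layer_matrix(stack), stack$n_ambient,
                        as.numeric(n_packets), as.integer(seed),
                        as.numeric(packet_offset),
                        roulette_threshold, roulette_survival,
                        specular == "fresnel", max_steps)
  out <- data.frame(packet = res$packet, W = res$W, dx = res$dx,
                    zmax = res$zmax, exit_ux = res$exit_ux,
                    exit_uy = res$exit_uy, exit_uz = res$exit_uz)
  attr(out, "n_packets") <- n_packets
  attr(out, "seed") <- seed
  attr(out, "packet_offset") <- packet_offset
  attr(out, "n_truncated") <- res$n_truncated
  out
}
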