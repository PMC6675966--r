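# Shared fixtures: media and small simulations reused across test files.

# reference highly scattering medium: musp/mua = 100, l* = 1 mm, g = 0.8,
# n = 1.4
ref_props <- function() optics_from_ratio(100, lstar = 1, g = 0.8, n = 1.4)
ref_stack <- function() semi_infinite_stack(ref_props())

# small cached reference tally shared by several test files
ref_tally_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sfd_simulate(ref_stack(), fx = c(0, 0.1, 0.5),
                             n_packets = 2e4, seed = 424242)
    cache
  }
})

# deterministic synthetic event stream with known percentiles: weights and
# zmax laid out by hand so depth metrics are testable without transport
toy_events <- function() {
  ev <- data.frame(
    packet = 0:3,
    W = c(0.3, 0.2, 0.1, 0.6),
    dx = c(0, 2.5, -1, 0.5),
    zmax = c(0.5, 1.5, 2.5, 0.035),
    exit_ux = 0, exit_uy = 0, exit_uz = -1)
  attr(ev, "n_packets") <- 4
  attr(ev, "seed") <- 0
  attr(ev, "packet_offset") <- 0
  attr(ev, "n_truncated") <- 0
  ev
}
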