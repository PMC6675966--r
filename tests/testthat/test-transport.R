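test_that("exponential step sampling has the right values and mean", {
  expect_identical(sample_step(1, mut = 5), 0)
  expect_equal(sample_step(exp(-1), mut = 1), 1.0)
  expect_error(sample_step(0.5, mut = 0), "mut")
  expect_error(sample_step(0, mut = 1), "\\(0, 1\\]")

  mut <- 4.95049505 + 0.00990099
  set.seed(1)
  n <- 1e5
  s <- sample_step(runif(n), mut)
  se <- sd(s) / sqrt(n)
  expect_lt(abs(mean(s) - 1 / mut), 3 * se)
})

test_that("Henyey-Greenstein inverse CDF: identities, spot value, first moment", {
  u <- c(0, 0.25, 0.5, 0.9, 1)
  expect_equal(sample_hg(u, g = 0), 2 * u - 1)
  expect_equal(sample_hg(0.5, g = 0.8), 0.9440, tolerance = 1e-4)
  # closed-form check at another node
  g <- 0.8; uu <- 0.1
  f <- (1 - g^2) / (1 - g + 2 * g * uu)
  expect_equal(sample_hg(uu, g), (1 + g^2 - f^2) / (2 * g))
  expect_true(all(abs(sample_hg(seq(0, 1, 1e-3), 0.99)) <= 1))

  set.seed(2)
  n <- 1e6
  ct <- sample_hg(runif(n), g = 0.8)
  se <- sd(ct) / sqrt(n)
  expect_lt(abs(mean(ct) - 0.8), 3 * se)
})

test_that("unpolarized Fresnel reflectance: matched, normal, critical", {
  expect_identical(fresnel_reflectance(1.4, 1.4, c(0, 0.5, 1)), c(0, 0, 0))
  expect_equal(fresnel_reflectance(1.4, 1.0, 1), (0.4 / 2.4)^2,
               tolerance = 1e-9)
  # beyond the critical angle sin(theta) > 1/1.4: total internal reflection
  ci_beyond <- sqrt(1 - (1 / 1.4)^2) * 0.99
  expect_identical(fresnel_reflectance(1.4, 1.0, ci_beyond), 1)
  expect_error(fresnel_reflectance(1.4, 1.0, 1.1), "cos_incident")
  # reflectance grows towards grazing incidence
  r <- fresnel_reflectance(1.0, 1.4, seq(1, 0.05, by = -0.05))
  expect_true(all(diff(r) >= 0))
})

test_that("ballistic absorber detects nothing; absorbing base kills on entry", {
  # pure absorber: first collision sets W = 0, packet never turns around
  ev <- sfd_events(semi_infinite_stack(optical_properties(10, 0, 0)),
                   n_packets = 1000, seed = 5)
  expect_identical(nrow(ev), 0L)
})

test_that("energy is conserved in a matched-boundary conservative medium", {
  # mua = 0, n matched everywhere, roulette never triggers (W stays 1).
  # Return to the surface is certain but heavy-tailed; the per-packet
  # collision cap truncates ~2.5e-4 of packets at the default 1e7, which
  # bounds |Rd - 1| well below 1e-3.
  st <- semi_infinite_stack(optical_properties(0, 5, 0, n = 1.0),
                            n_ambient = 1.0)
  tal <- sfd_simulate(st, fx = 0, n_packets = 1e5, seed = 7,
                      grid = depth_grid(dz = 0.1, z_cap = 100))
  rd <- Re(tal$pvd[1, 1])
  expect_true(all(Re(tal$pzmax[1, ]) >= 0))
  expect_lt(abs(rd - 1), 1e-3)
  # detected weights are exactly 1, so Rd = detected fraction
  expect_equal(rd, tal$n_detected / tal$n_packets)
})

test_that("exit directions are unit vectors and zmax bounds are respected", {
  ev <- sfd_events(ref_stack(), n_packets = 2000, seed = 9)
  norms <- sqrt(ev$exit_ux^2 + ev$exit_uy^2 + ev$exit_uz^2)
  expect_lt(max(abs(norms - 1)), 1e-9)
  expect_true(all(ev$exit_uz < 0))           # upward through the surface
  expect_true(all(ev$zmax > 0))
  expect_true(all(ev$W > 0 & ev$W <= 1))
})

test_that("direction norm drift stays within 1e-9 over long trajectories", {
  expect_lt(.cpp_direction_norm_drift(3, 0.8, 1e5), 1e-9)
  expect_lt(.cpp_direction_norm_drift(4, 0.97, 1e5), 1e-9)
})

test_that("similarity scaling: k*(mua,mus) with the same seed scales lengths by 1/k", {
  k <- 2 # power of two => the scaling is exact in floating point
  p1 <- ref_props()
  p2 <- optical_properties(k * p1$mua, k * p1$mus, p1$g, p1$n)
  e1 <- sfd_events(semi_infinite_stack(p1), n_packets = 3000, seed = 21)
  e2 <- sfd_events(semi_infinite_stack(p2), n_packets = 3000, seed = 21)
  expect_identical(e1$packet, e2$packet)
  expect_identical(e1$W, e2$W)                    # weights are unchanged
  expect_identical(e1$dx / k, e2$dx)              # lengths contract exactly
  expect_identical(e1$zmax / k, e2$zmax)
  expect_identical(e1$exit_uz, e2$exit_uz)        # directions congruent
})

test_that("packet substreams partition a run without changing trajectories", {
  full <- sfd_events(ref_stack(), n_packets = 2000, seed = 31)
  a <- sfd_events(ref_stack(), n_packets = 1000, seed = 31)
  b <- sfd_events(ref_stack(), n_packets = 1000, seed = 31,
                  packet_offset = 1000)
  both <- rbind(a, b)
  rownames(both) <- NULL
  expect_identical(full$W, both$W)
  expect_identical(full$dx, both$dx)
  expect_identical(full$zmax, both$zmax)
  # and distinct substreams produce distinct uniforms
  expect_false(any(.cpp_rng_uniforms(31, 0, 5) == .cpp_rng_uniforms(31, 1, 5)))
})

test_that("roulette settings outside (0,1) are config errors", {
  expect_error(sfd_events(ref_stack(), 10, 1, roulette_threshold = 0),
               "config error")
  expect_error(sfd_events(ref_stack(), 10, 1, roulette_survival = 1.5),
               "config error")
  expect_error(sfd_simulate(ref_stack(), fx = 0, n_packets = 0, seed = 1),
               "n_packets")
})
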