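test_that("toy distribution: Rd, restricted, fraction and percentile depths", {
  pz <- c(0.3, 0.2, 0.1)   # dz = 1 mm
  expect_equal(total_reflectance(pz), 0.6)
  expect_equal(total_reflectance(numeric(5)), 0)

  expect_equal(restricted_reflectance(pz, 0, dz = 1), 0)
  expect_equal(restricted_reflectance(pz, 1.5, dz = 1), 0.4) # pro-rated bin
  expect_equal(restricted_reflectance(pz, Inf, dz = 1), 0.6)
  expect_error(restricted_reflectance(pz, -1, dz = 1), "d must")

  expect_equal(sampling_fraction(pz, 0, dz = 1), 0)
  expect_equal(sampling_fraction(pz, 1, dz = 1), 0.5)
  expect_equal(sampling_fraction(pz, Inf, dz = 1), 1)
  expect_error(sampling_fraction(numeric(3), 1, dz = 1), "Rd = 0")

  expect_equal(percentile_depth(pz, 0.5, dz = 1), 1.0)
  expect_equal(percentile_depth(pz, 1.0, dz = 1), 3.0)  # end of support
  expect_equal(percentile_depth(pz, 0.25, dz = 1), 0.5) # inside first bin
  expect_error(percentile_depth(pz, 0, dz = 1), "X must")
  expect_error(percentile_depth(pz, 1.1, dz = 1), "X must")
})

test_that("restricted reflectance is nondecreasing and inverts percentile_depth", {
  tal <- ref_tally_small()
  d <- seq(0, 10, by = 0.37)
  r <- vapply(d, function(di) restricted_reflectance(tal, di, fx = 0),
              numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_equal(restricted_reflectance(tal, Inf, fx = 0),
               total_reflectance(tal, fx = 0))
  # fraction o percentile = identity (within one interpolation step)
  for (X in c(0.1, 0.35, 0.5, 0.8)) {
    dX <- percentile_depth(tal, X, fx = 0)
    expect_equal(sampling_fraction(tal, dX, fx = 0), X, tolerance = 1e-9)
  }
})

test_that("percentile depths from a tally are ordered across X and fx-selected", {
  tal <- ref_tally_small()
  ds <- depth_summary(tal)
  expect_equal(names(ds), c("fx", "Rd", "d10", "d25", "d50", "d75", "d90"))
  for (i in seq_len(nrow(ds)))
    expect_true(all(diff(unlist(ds[i, c("d10", "d25", "d50", "d75", "d90")]))
                    >= 0))
  # median depth shrinks with spatial frequency in the reference medium
  expect_true(all(diff(ds$d50) < 0))
  expect_error(percentile_depth(tal, 0.5, fx = 0.123), "not tallied")
})

test_that("unattainable fractions point at z_cap instead of extrapolating", {
  ev <- data.frame(W = c(0.5, 0.5), dx = 0, zmax = c(0.5, 9))
  attr(ev, "n_packets") <- 2
  tal <- tally_events(ev, fx = 0, grid = depth_grid(dz = 0.1, z_cap = 2))
  expect_equal(percentile_depth(tal, 0.25, fx = 0), 0.55) # half the bin
  expect_equal(percentile_depth(tal, 0.5, fx = 0), 0.6)   # whole bin
  expect_error(percentile_depth(tal, 0.9, fx = 0), "z_cap")
})

test_that("synthetic events give exact hand-computable depth statistics", {
  tal <- tally_events(toy_events(), fx = 0,
                      grid = depth_grid(dz = 0.01, z_cap = 5))
  # masses: 0.6 @ 0.035, 0.3 @ 0.5, 0.2 @ 1.5, 0.1 @ 2.5; Rd = 1.2 / 4
  expect_equal(total_reflectance(tal, fx = 0), 0.3)
  expect_equal(sampling_fraction(tal, 0.04, fx = 0), 0.5)
  expect_equal(percentile_depth(tal, 0.75, fx = 0), 0.5 + 0.01)
  expect_equal(percentile_depth(tal, 1, fx = 0), 2.5 + 0.01)
})

test_that("depth scaling law: (k mua, k mus, k fx) contracts depths by 1/k", {
  k <- 2
  p1 <- ref_props()
  p2 <- optical_properties(k * p1$mua, k * p1$mus, p1$g, p1$n)
  g1 <- depth_grid(dz = 0.02, z_cap = 40)
  g2 <- depth_grid(dz = 0.01, z_cap = 20)
  t1 <- sfd_simulate(semi_infinite_stack(p1), fx = c(0, 0.1),
                     n_packets = 5000, seed = 13, grid = g1)
  t2 <- sfd_simulate(semi_infinite_stack(p2), fx = c(0, 0.2),
                     n_packets = 5000, seed = 13, grid = g2)
  for (X in c(0.25, 0.5, 0.9)) {
    expect_equal(percentile_depth(t1, X, fx = 0) / k,
                 percentile_depth(t2, X, fx = 0))
    expect_equal(percentile_depth(t1, X, fx = 0.1) / k,
                 percentile_depth(t2, X, fx = 0.2))
  }
})

test_that("two-layer extinction equals restricted homogeneous reflectance within 3 sigma", {
  sweep <- phantom_sweep(ref_props(), depths = c(0, 0.5, 1, 2, 4, 7.5),
                         fx = c(0, 0.3), n_packets = 3e4, seed = 101,
                         grid = depth_grid(dz = 0.01, z_cap = 40))
  # bare absorber: nothing comes back
  expect_true(all(sweep$rd_two_layer[sweep$d == 0] == 0))
  nz <- sweep$d > 0
  sig <- sqrt(sweep$sigma_two_layer^2 + sweep$sigma_restricted^2)
  expect_true(all(abs(sweep$diff[nz]) <= 3 * sig[nz]))
  # reflectance recovers towards the homogeneous value as the base deepens
  s0 <- sweep[sweep$fx == 0, ]
  expect_true(all(diff(s0$rd_two_layer) > 0))
})
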