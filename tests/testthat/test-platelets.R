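test_that("margination redistribution conserves columns and hits the peak ratio", {
  m <- small_mesh()
  mm <- margination_model(m)
  C <- matrix(rep(2.5e5, m$nx * m$ny), m$nx, m$ny)
  C2 <- margination_redistribution(C, mm)
  expect_lt(max(abs(rowSums(C2) - rowSums(C)) / rowSums(C)), 1e-12)
  near <- mean(C2[, m$yc < 5]); bulk <- mean(C2[, m$yc >= 5 & m$yc <= 55])
  expect_equal(near / bulk, 3, tolerance = 0.05)
  # flat profile is the identity
  flat <- margination_model(m, peak = 1)
  expect_equal(margination_redistribution(C, flat), C)
  # non-uniform field: still conservative per column
  C3 <- matrix(runif(m$nx * m$ny), m$nx, m$ny)
  expect_lt(max(abs(rowSums(margination_redistribution(C3, mm)) -
                      rowSums(C3))), 1e-12)
  # discrete profile normalisation
  expect_equal(sum(mm$E), m$ny)
})

test_that("capture is first order at low occupancy and saturates at phi_max", {
  m <- small_mesh()
  pp0 <- platelet_params(adhesion_rate = 0, aggregation_rate = 0,
                         adhesion_multiplier = 0)
  st <- platelet_state(m, pp0)
  st2 <- adhesion_aggregation_step(st, m, 1, pp0)
  expect_identical(st2$bound_resting, st$bound_resting)
  expect_identical(st2$bound_activated, st$bound_activated)

  # doubling the rate doubles the initial deposition rate (small dt limit)
  cap <- function(rate) {
    pp <- platelet_params(adhesion_rate = rate, aggregation_rate = 0)
    s <- adhesion_aggregation_step(platelet_state(m, pp), m, 0.05, pp)
    sum(s$bound_resting + s$bound_activated)
  }
  expect_equal(cap(0.1) / cap(0.05), 2, tolerance = 0.02)

  # full cells capture nothing more
  pp <- platelet_params()
  st <- platelet_state(m, pp)
  st$bound_activated[m$thromb, 1] <- pp$phi_max
  st3 <- adhesion_aggregation_step(st, m, 1, pp)
  expect_equal(st3$bound_activated[m$thromb, 1],
               st$bound_activated[m$thromb, 1])
  expect_true(all(st3$bound_resting + st3$bound_activated <= pp$phi_max + 1e-12))
})

test_that("capture conserves total platelet count through the volume conversion", {
  m <- small_mesh()
  pp <- platelet_params()
  st <- platelet_state(m, pp)
  st$bound_activated[150, 1] <- 0.1      # a seeded clot cell
  st2 <- adhesion_aggregation_step(st, m, 5, pp)
  cap_vol <- pp$volume * 1e9
  d_mobile <- sum(st$mobile_resting + st$mobile_activated) -
    sum(st2$mobile_resting + st2$mobile_activated)
  d_bound <- sum(st2$bound_resting + st2$bound_activated) -
    sum(st$bound_resting + st$bound_activated)
  expect_equal(d_mobile, d_bound / cap_vol, tolerance = 1e-9)
  expect_gt(d_bound, 0)
})

test_that("activation follows the thrombin Hill law and conserves count", {
  m <- small_mesh()
  pp <- platelet_params()
  st <- platelet_state(m, pp)
  # no thrombin, no collagen-bound platelets: nothing converts
  st0 <- activation_step(st, matrix(0, m$nx, m$ny), m, 10, pp)
  expect_equal(st0$mobile_activated, st$mobile_activated)
  # saturating thrombin: exponential decay of the resting pool
  Tf <- matrix(1e4, m$nx, m$ny)
  st1 <- st
  for (i in 1:10) st1 <- activation_step(st1, Tf, m, 1, pp)
  frac <- st1$mobile_resting[1, 15] / st$mobile_resting[1, 15]
  expect_equal(frac, exp(-pp$k_act * 1e4 / (1 + 1e4) * 10), tolerance = 0.01)
  tot0 <- sum(st$mobile_resting + st$mobile_activated)
  expect_equal(sum(st1$mobile_resting + st1$mobile_activated), tot0,
               tolerance = 1e-12)
  expect_error(activation_step(st, matrix(-1, m$nx, m$ny), m, 1, pp))
})

test_that("Kozeny-Carman resistance matches the closed form and is monotone", {
  m <- small_mesh()
  pp <- platelet_params()
  st <- platelet_state(m, pp)
  expect_equal(max(resistance_from_composition(st, NULL, pp)), 0)
  st$bound_activated[1, 1] <- 0.3
  k <- resistance_from_composition(st, NULL, pp)
  expect_equal(k[1, 1], 180 * 0.09 / (0.343 * (2e-6)^2), tolerance = 1e-12)
  expect_equal(k[1, 1], 1.18e13, tolerance = 0.01)
  # strictly increasing in both volume fractions
  phis <- seq(0.05, 0.5, 0.05)
  kb <- vapply(phis, function(p) {
    s <- platelet_state(m, pp); s$bound_activated[1, 1] <- p
    resistance_from_composition(s, NULL, pp)[1, 1]
  }, 0)
  expect_true(all(diff(kb) > 0))
  fib <- matrix(0, m$nx, m$ny); fib[1, 1] <- 5000
  expect_gt(resistance_from_composition(st, fib, pp)[1, 1], k[1, 1])
  st$bound_activated[1, 1] <- 1
  expect_error(resistance_from_composition(st, NULL, pp), "upstream")
})
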