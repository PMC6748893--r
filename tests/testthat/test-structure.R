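test_that("core extraction matches indicator sets and level-set closed forms", {
  m <- small_mesh()
  # below threshold everywhere: empty contour, not an error
  expect_true(extract_core(matrix(0.5, m$nx, m$ny), m)$empty)
  expect_equal(occlusivity(extract_core(matrix(0, m$nx, m$ny), m), 60), 0)

  # indicator rectangle [290, 310] x [0, 10]
  f <- matrix(0, m$nx, m$ny)
  f[m$xc >= 290 & m$xc <= 310, m$yc <= 10] <- 2
  co <- extract_core(f, m)
  expect_lt(abs(co$height - 10), m$dy + 1e-9)
  expect_lt(abs(co$length - 20), 2 * m$dx + 1e-9)

  # half-Gaussian bump: 1-nM contour half-width = sigma * sqrt(2 ln 10)
  gx <- 10 * exp(-(m$xc - 300)^2 / (2 * 20^2))
  f2 <- outer(gx, as.numeric(m$yc <= 10))
  co2 <- extract_core(f2, m)
  half <- co2$length / 2
  expect_lt(abs(half - 20 * sqrt(2 * log(10))), m$dx + 1e-9)
})

test_that("shell thresholds nest and match plateau regions", {
  m <- small_mesh()
  expect_true(extract_shell(matrix(0, m$nx, m$ny), m)$empty)
  b <- matrix(0, m$nx, m$ny)
  b[m$xc >= 280 & m$xc <= 320, m$yc <= 16] <- 0.6
  sh <- extract_shell(b, m)
  expect_lt(abs(sh$height - 16), m$dy + 1e-9)
  expect_lt(abs(sh$length - 40), 2 * m$dx + 1e-9)
  # smooth bump: the 0.05 contour contains the 0.10 contour
  bump <- outer(0.6 * exp(-(m$xc - 300)^2 / (2 * 30^2)),
                exp(-m$yc^2 / (2 * 8^2)))
  s05 <- extract_shell(bump, m, threshold = 0.05)
  s10 <- extract_shell(bump, m, threshold = 0.10)
  expect_true(all(s10$h <= s05$h + 1e-9))
  expect_lte(s10$length, s05$length)
})

test_that("satellite deposits are ignored by the largest-component rule", {
  m <- small_mesh()
  f <- matrix(0, m$nx, m$ny)
  f[m$xc >= 280 & m$xc <= 320, m$yc <= 10] <- 2
  f[m$xc >= 500 & m$xc <= 504, m$yc <= 4] <- 2   # small satellite
  co <- extract_core(f, m)
  expect_lt(abs(co$length - 40), 2 * m$dx + 1e-9)
  expect_lt(max(co$h[m$xc > 400]), 1e-9)
})

test_that("core embedding reproduces the rescaling arithmetic", {
  x <- seq(0, 600, 2)
  # simulated pair: shell 20 um x 100 um, core 10 um x 60 um (ratios 0.5, 0.6);
  # half-open intervals so the column count times dx is the exact length
  shell_sim <- region_from_profile(x, ifelse(x >= 250 & x < 350, 20, 0))
  core_sim <- region_from_profile(x, ifelse(x >= 270 & x < 330, 10, 0))
  pair <- core_shell_pair(core_sim, shell_sim, k_core = 2e12, k_shell = 1e12)

  meas <- region_from_profile(x, ifelse(x >= 240 & x < 360, 15, 0))
  emb <- embed_core_in_shell(pair, meas)
  expect_equal(emb$core$height, 7.5)
  expect_equal(emb$core$length, 72, tolerance = 0.05)

  # identical shell: core comes back (up to contour resampling)
  emb2 <- embed_core_in_shell(pair, shell_sim)
  expect_equal(emb2$core$height, core_sim$height, tolerance = 1e-9)
  expect_equal(emb2$core$length, core_sim$length, tolerance = 0.05)

  # a downstream-shifted simulated core keeps its relative offset
  core_off <- region_from_profile(x, ifelse(x >= 280 & x < 340, 10, 0))
  pair_off <- core_shell_pair(core_off, shell_sim, 2e12, 1e12)
  emb3 <- embed_core_in_shell(pair_off, meas)
  off_sim <- 10 / shell_sim$length
  c_meas <- 300 + off_sim * meas$length
  nz <- which(emb3$core$h > 0)
  center_emb <- (emb3$core$x[min(nz)] + emb3$core$x[max(nz)]) / 2
  expect_equal(center_emb, c_meas, tolerance = 2 * 2)

  # empty simulated core gives an empty embedded core
  pair_e <- core_shell_pair(region_from_profile(x, rep(0, length(x))),
                            shell_sim, 2e12, 1e12)
  expect_true(embed_core_in_shell(pair_e, meas)$core$empty)
})

test_that("embedding preserves nesting on randomised shapes", {
  set.seed(42)
  x <- seq(0, 600, 2)
  for (i in 1:100) {
    Ls <- runif(1, 40, 200); Hs <- runif(1, 8, 40)
    Lc <- Ls * runif(1, 0.2, 0.95); Hc <- Hs * runif(1, 0.2, 0.95)
    off <- runif(1, -0.2, 0.2) * Ls
    shell_sim <- region_from_profile(x, Hs * pmax(1 - ((x - 300) / (Ls / 2))^2, 0))
    core_sim <- region_from_profile(
      x, Hc * pmax(1 - ((x - 300 - off) / (Lc / 2))^2, 0))
    pair <- core_shell_pair(core_sim, shell_sim, 2e12, 1e12, clip = TRUE)
    Lm <- runif(1, 40, 250); Hm <- runif(1, 5, 30)
    cm <- runif(1, 200, 400)
    meas <- region_from_profile(x, Hm * pmax(1 - ((x - cm) / (Lm / 2))^2, 0))
    emb <- embed_core_in_shell(pair, meas)
    hs <- approx(meas$x, meas$h, xout = emb$core$x, yleft = 0, yright = 0)$y
    expect_true(all(emb$core$h <= hs + 1e-9))
  }
})

test_that("region means average resistance over member cells", {
  m <- small_mesh()
  k <- matrix(5e11, m$nx, m$ny)
  reg <- region_from_profile(m$xc, ifelse(abs(m$xc - 300) <= 40, 12, 0))
  expect_equal(region_mean_resistance(k, reg, m), 5e11)
  # two-cell region with different k values averages arithmetically
  m2 <- build_mesh(channel_geometry(surface_length = 300), 300, 60)   # 2 x 1 cells
  k2 <- matrix(c(1e12, 3e12), 2, 1)
  reg2 <- region_from_profile(c(75, 225, 375, 525), c(40, 40, 40, 40))
  expect_equal(region_mean_resistance(k2, reg2, m2), 2e12)
  expect_error(region_mean_resistance(k, region_from_profile(m$xc,
                                                             rep(0, m$nx)), m))
})

test_that("occlusivity is height over channel height", {
  r <- region_from_profile(seq(0, 600, 2),
                           ifelse(abs(seq(0, 600, 2) - 300) < 30, 18, 0))
  expect_equal(occlusivity(r, 60), 0.3)
  r2 <- region_from_profile(seq(0, 600, 2),
                            ifelse(abs(seq(0, 600, 2) - 300) < 30, 60, 0))
  expect_equal(occlusivity(r2, 60), 1)
  expect_error(occlusivity(r2, 30), "exceeds")
})

test_that("flow through a measured shape has the expected velocity structure", {
  m <- small_mesh()
  fl <- fluid_properties()
  x <- seq(0, 600, 2)
  shell_sim <- region_from_profile(x, ifelse(abs(x - 300) <= 60,
                                             16 * cos(pi * (x - 300) / 240)^2, 0))
  core_sim <- region_from_profile(x, ifelse(abs(x - 300) <= 36,
                                            8 * cos(pi * (x - 300) / 144)^2, 0))
  pair <- core_shell_pair(core_sim, shell_sim, k_core = 5e13, k_shell = 1e13)
  meas <- region_from_profile(x, ifelse(abs(x - 300) <= 70,
                                        14 * cos(pi * (x - 300) / 280)^2, 0))
  res <- flow_through_measured_shape(meas, pair, m, fl)

  # zero-resistance control is indistinguishable from clot-free Poiseuille
  pair0 <- core_shell_pair(core_sim, shell_sim, 0, 0)
  res0 <- flow_through_measured_shape(meas, pair0, m, fl)
  prof <- inlet_profile(fl, 60)
  ue <- outer(rep(1, m$nx), prof$u(m$yc))
  expect_lt(max(abs(res0$flow$uc - ue)) / max(ue), 0.01)

  # intraclot flow stalls; fastest at the clot top, slowest at its base
  expect_lt(res$metrics$intraclot_mean / res$metrics$lumen_mean, 0.05)
  ic <- which.min(abs(m$xc - 300))
  jj <- which(m$yc < 14)
  ucol <- res$flow$uc[ic, jj]
  expect_equal(which.max(ucol), length(jj))
  expect_equal(which.min(ucol), 1L)
  # horizontal intraclot variation below the vertical variation
  expect_lt(res$metrics$sd_horizontal, res$metrics$sd_vertical)
  # the low-velocity region extends beyond the shell footprint
  expect_gt(res$metrics$low_velocity_extent, res$metrics$shell_fwhm)
})
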