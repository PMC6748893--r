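test_that("shear-enhanced diffusivity follows the augmentation law", {
  expect_equal(effective_diffusivity(5e-11, 0), 5e-11)
  expect_equal(effective_diffusivity(5e-11, 1000, hematocrit = 0), 5e-11)
  D <- effective_diffusivity(5e-11, 1000, 0.4)
  expect_equal(D, 5e-11 + 0.15 * (2.75e-6)^2 * 1000 * 0.4 * 0.6^0.8,
               tolerance = 1e-12)
  expect_equal(D, 3.5e-10, tolerance = 0.02)
})

test_that("a diffusing Gaussian pulse grows its variance at 2*D*t", {
  m <- small_mesh()
  C <- outer(exp(-(m$xc - 300)^2 / (2 * 15^2)), rep(1, m$ny))
  D <- 1e-10; dt <- 0.5; nstep <- 40
  res <- advance_transport(list(c = C), flow = NULL, dt = dt, mesh = m,
                           diffusivity = D, closed = TRUE)
  for (i in 2:nstep)
    res <- advance_transport(res$fields, flow = NULL, dt = dt, mesh = m,
                             diffusivity = D, closed = TRUE)
  varx <- function(M) {
    w <- rowSums(M); mu <- sum(w * m$xc) / sum(w)
    sum(w * (m$xc - mu)^2) / sum(w) * 1e-12          # um^2 -> m^2
  }
  growth <- varx(res$fields$c) - varx(C)
  expect_lt(abs(growth - 2 * D * nstep * dt) / (2 * D * nstep * dt), 0.02)
  # closed domain: mass conserved to round-off
  expect_lt(abs(sum(res$fields$c) - sum(C)) / sum(C), 1e-6)
})

test_that("a pulse advects at the flow speed within one cell per 100 steps", {
  m <- small_mesh()
  u0 <- 1e-5                      # CFL 0.5 at dt = 0.1 s
  u <- matrix(u0, m$nx + 1, m$ny); v <- matrix(0, m$nx, m$ny + 1)
  flow <- structure(list(u = u, v = v, mesh = m), class = "flow_state")
  C <- outer(exp(-(m$xc - 100)^2 / (2 * 10^2)), rep(1, m$ny))
  f <- list(c = C)
  for (i in 1:100)
    f <- advance_transport(f, flow, dt = 0.1, mesh = m, diffusivity = 0)$fields
  peak <- m$xc[which.max(f$c[, 1])]
  expected <- 100 + u0 * 100 * 0.1 * 1e6   # um
  expect_lt(abs(peak - expected), m$dx + 1e-9)
  expect_true(all(f$c >= 0))
})

test_that("no trigger means no reaction anywhere", {
  net <- coagulation_network()
  r <- reaction_rates(net, net$baselines)
  expect_equal(max(abs(r)), 0)
  # fibrinogen exhausted: no fibrin production regardless of thrombin
  x <- net$baselines; x["fibrinogen"] <- 0; x["FIIa"] <- 500
  expect_equal(reaction_rates(net, x)[["fibrin"]], 0)
  expect_error(reaction_rates(net, net$baselines[-1]), "every network species")
})

test_that("well-mixed reaction trajectories match a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  net <- coagulation_network()
  x0 <- net$baselines; x0["FXa"] <- 1
  times <- seq(0, 100, 5)
  oracle <- deSolve::ode(x0, times,
                         function(t, y, p) list(reaction_rates(net, pmax(y, 0))),
                         NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  m1 <- build_mesh(channel_geometry(surface_length = 200), 200, 20)  # 3 x 3 cells, closed box
  f <- init_species_fields(m1, net); f$FXa[] <- 1
  worst <- 0
  for (i in 2:length(times)) {
    f <- advance_transport(f, flow = NULL, dt = 5, mesh = m1, diffusivity = 0,
                           closed = TRUE, network = net)$fields
    ref <- oracle[i, -1]
    got <- vapply(net$species, function(s) f[[s]][1, 1], 0)
    worst <- max(worst, max(abs(got - ref) / (abs(ref) + 1e-3)))
  }
  expect_lt(worst, 0.005)
  # thrombin moiety: FII + FIIa (complexed thrombin does not exist here)
  expect_equal(f$FII[1, 1] + f$FIIa[1, 1], 1400, tolerance = 1e-6)
})

test_that("thrombin and fibrin totals are non-decreasing in a closed reactor", {
  net <- coagulation_network()
  m1 <- build_mesh(channel_geometry(surface_length = 200), 200, 20)
  f <- init_species_fields(m1, net); f$FXa[] <- 2
  iia <- fib <- numeric(0)
  for (i in 1:20) {
    f <- advance_transport(f, flow = NULL, dt = 5, mesh = m1, diffusivity = 0,
                           closed = TRUE, network = net)$fields
    iia <- c(iia, sum(f$FIIa)); fib <- c(fib, sum(f$fibrin))
  }
  expect_true(all(diff(iia) >= -1e-9 * max(iia)))
  expect_true(all(diff(fib) >= -1e-9 * max(fib)))
})

test_that("surface fluxes do site bookkeeping", {
  # no TF -> no flux, thrombin stays zero over any horizon
  g0 <- channel_geometry(tf_density = 0)
  m0 <- build_mesh(g0, 2, 2)
  s0 <- surface_state(m0)
  fx <- surface_reaction_flux(s0, list(FVII = rep(10, 10), FVIIa = rep(0.1, 10),
                                       FIX = rep(90, 10), FX = rep(170, 10),
                                       TFPI_FXa = rep(0, 10)))
  expect_true(all(unlist(fx) == 0))

  # total sites: 20x between densities at equal length, 5x between lengths
  tot <- function(g) {
    m <- build_mesh(g, 2, 2)
    sum(surface_state(m)$TF) * m$dx
  }
  expect_equal(tot(channel_geometry(tf_density = 2)) /
                 tot(channel_geometry(tf_density = 0.1)), 20)
  expect_equal(tot(channel_geometry(surface_length = 100)) /
                 tot(channel_geometry(surface_length = 20)), 5)
})

test_that("quiescent baseline plasma stays at baseline under transport", {
  net <- coagulation_network()
  m <- build_mesh(channel_geometry(), 4, 4)
  flow <- solve_flow(m, fluid_properties())
  f <- init_species_fields(m, net)
  out <- advance_transport(f, flow, dt = 0.5, diffusivity = 3e-10,
                           inlet = net$baselines, network = net)$fields
  for (sp in net$species)
    expect_equal(max(abs(out[[sp]] - net$baselines[[sp]])), 0,
                 tolerance = 1e-8, label = sp)
})
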