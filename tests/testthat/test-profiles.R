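grid <- seq(0, 600, 2)

tri <- function(center, half = 40, peak = 10, x = grid)
  pmax(peak * (1 - abs(x - center) / half), 0)

test_that("edge detection finds level crossings and centres", {
  p <- deposition_profile(grid, tri(250))
  ed <- detect_edges(p)
  expect_equal(ed$center, 250, tolerance = 1e-6)

  box <- deposition_profile(grid, ifelse(grid >= 280 & grid <= 320, 5, 0))
  eb <- detect_edges(box)
  expect_lt(abs(eb$x_up - 280), 2 + 1e-9)
  expect_lt(abs(eb$x_down - 320), 2 + 1e-9)

  # interval nesting across levels
  e1 <- detect_edges(p, level = 0.1); e2 <- detect_edges(p, level = 0.2)
  expect_lte(e1$x_up, e2$x_up); expect_gte(e1$x_down, e2$x_down)

  expect_error(detect_edges(deposition_profile(grid, rep(0, length(grid)))),
               "no accumulation")
})

test_that("alignment recovers known shifts and is idempotent", {
  shifts <- c(-20, 0, 30)
  profs <- lapply(shifts, function(s) deposition_profile(grid, tri(300 + s)))
  ens <- align_profiles(profs)
  expect_equal(ens$meta$shift, -shifts, tolerance = 1e-6)
  # aligned copies agree pairwise within interpolation tolerance (1% of peak)
  for (i in 2:3)
    expect_lt(sqrt(mean((ens$values[1, ] - ens$values[i, ])^2)), 0.01 * 10)
  # single already-centred profile is unchanged
  p0 <- deposition_profile(seq(0, 600, 1), tri(300, x = seq(0, 600, 1)))
  e0 <- align_profiles(list(p0))
  expect_equal(as.numeric(e0$values[1, ]), p0$value, tolerance = 1e-9)
  # idempotence: aligning an aligned ensemble changes nothing
  profs2 <- lapply(seq_len(nrow(ens$values)), function(i)
    deposition_profile(ens$x, ens$values[i, ]))
  ens2 <- align_profiles(profs2)
  expect_equal(ens2$values, ens$values, tolerance = 1e-9)
})

test_that("alignment recovers random shifts with r > 0.99", {
  set.seed(7)
  true_shift <- runif(20, -40, 40)
  profs <- lapply(true_shift, function(s)
    deposition_profile(grid, pmax(tri(300 + s) +
                                    rnorm(length(grid), 0, 0.05), 0)))
  ens <- align_profiles(profs)
  expect_gt(cor(-ens$meta$shift, true_shift), 0.99)
})

test_that("spurious profiles are filtered by the outside and twin-peak rules", {
  clean <- lapply(c(280, 300, 320), function(c0)
    deposition_profile(grid, tri(c0)))
  res <- filter_spurious(clean)
  expect_length(res$kept, 3); expect_length(res$rejected, 0)

  twin <- deposition_profile(grid, tri(250) + tri(450))
  res2 <- filter_spurious(c(clean, list(twin)))
  expect_length(res2$rejected, 1)
  expect_match(res2$reasons, "peak|fraction")

  empty <- filter_spurious(list())
  expect_length(empty$kept, 0)

  # rules are translation invariant: filtering before/after alignment agrees
  shifted <- lapply(c(-30, 0, 25), function(s)
    deposition_profile(grid, tri(300 + s) + tri(300 + s + 160) * 0.8))
  keep_pre <- length(filter_spurious(shifted)$kept)
  al <- align_profiles(shifted)
  realigned <- lapply(seq_len(nrow(al$values)), function(i)
    deposition_profile(al$x, al$values[i, ]))
  expect_equal(length(filter_spurious(realigned)$kept), keep_pre)
})

test_that("ensemble statistics are pointwise mean and sample SD", {
  p1 <- deposition_profile(grid, rep(0, length(grid)) + tri(300))
  ens <- align_profiles(list(p1, p1, p1))
  st <- ensemble_stats(ens)
  expect_equal(max(st$sd), 0)
  expect_equal(st$n, 3)

  # {0-line, 2-line}: mean 1, SD sqrt(2)
  flatish <- function(v) deposition_profile(grid, tri(300) * 0 + v + tri(300))
  e2 <- align_profiles(list(flatish(0), flatish(2)))
  mid <- which(abs(e2$x - 300) < 20)
  expect_equal(unname(st$mean[1]), 0)
  expect_equal(mean(e2$values[2, mid] - e2$values[1, mid]), 2, tolerance = 1e-6)
  st2 <- ensemble_stats(e2)
  expect_equal(unique(round(st2$sd[mid], 6)), round(sqrt(2), 6))
  # n = 1: SD undefined and flagged
  e1 <- align_profiles(list(p1))
  expect_false(ensemble_stats(e1)$sd_defined)
})
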