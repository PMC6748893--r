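test_that("generation is reproducible and noise-free profiles are templates", {
  spec <- default_condition_specs()$short_lo
  d1 <- generate_profiles(spec, seed = 4)
  d2 <- generate_profiles(spec, seed = 4)
  expect_identical(d1$profiles, d2$profiles)
  expect_identical(d1$ground_truth, d2$ground_truth)

  spec0 <- condition_spec("x", 20, 0.1, peak_height_mean = 10,
                          peak_height_sd = 0, center_jitter_sd = 0,
                          noise_sd = 0, spurious_prob = 0, donor_cv = 0)
  d0 <- generate_profiles(spec0, times = 400, seed = 1)
  vals <- do.call(rbind, lapply(d0$profiles, `[[`, "value"))
  expect_equal(max(apply(vals, 2, sd)), 0)
  ens <- align_profiles(d0$profiles)
  expect_equal(max(ensemble_stats(ens)$sd), 0)
  # ground truth covers every generated profile
  expect_equal(nrow(d0$ground_truth), length(d0$profiles))
})

test_that("the pipeline recovers the configured peak height", {
  spec <- default_condition_specs()$short_lo   # 7.5 um mean final peak
  d <- generate_profiles(spec, times = 400, seed = 8)
  keep <- filter_spurious(d$profiles)$kept
  ens <- align_profiles(keep)
  st <- ensemble_stats(ens)
  peak <- max(st$mean)
  n <- st$n
  sd_at_peak <- st$sd[which.max(st$mean)]
  expect_lt(abs(peak - 7.5), 2 * sd_at_peak / sqrt(n) + 0.5)
})

test_that("spurious events are injected at the configured rate and caught", {
  spec <- condition_spec("x", 20, 0.1, peak_height_mean = 10,
                         spurious_prob = 0.2, center_jitter_sd = 5,
                         noise_sd = 0.2)
  d <- generate_profiles(spec, n_donors = 25, n_reps = 4, times = 400,
                         seed = 12)     # 100 events
  n_spur <- sum(d$ground_truth$spurious)
  expect_gte(n_spur / 100, 0.12); expect_lte(n_spur / 100, 0.28)

  res <- filter_spurious(d$profiles)
  lab <- d$ground_truth$spurious
  pred <- vapply(d$profiles, function(p) FALSE, TRUE)
  rejected_keys <- vapply(res$rejected, function(p)
    paste(p$donor, p$repetition), "")
  keys <- paste(d$ground_truth$donor, d$ground_truth$repetition)
  pred <- keys %in% rejected_keys
  recall <- sum(pred & lab) / sum(lab)
  precision <- sum(pred & lab) / max(sum(pred), 1)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("synthetic kinetics encode the plateau ordering and synergy", {
  specs <- default_condition_specs()
  k0 <- generate_kinetics(specs, seed = 2, noise_cv = 0)
  at450 <- subset(k0$data, time_s == 450 & analyte == "thrombin")
  mn <- tapply(at450$value, at450$condition, mean)
  # noise-free donor-free ratio equals the configured 20x
  specs0 <- lapply(specs, function(s) { s$donor_cv <- 0; s })
  k00 <- generate_kinetics(specs0, seed = 2, noise_cv = 0, n_donors = 1,
                           n_reps = 1)
  a <- subset(k00$data, time_s == 450 & analyte == "thrombin")
  expect_equal(a$value[a$condition == "long_hi"] /
                 a$value[a$condition == "short_lo"], 20)
  expect_gt(mn[["long_hi"]], mn[["short_hi"]])
  expect_gt(mn[["long_hi"]], mn[["long_lo"]])
  expect_gt(mn[["short_hi"]], mn[["short_lo"]])
})

test_that("the measured significance pattern reproduces on default data", {
  k <- generate_kinetics(default_condition_specs(), seed = 31)
  for (an in c("platelet", "thrombin", "fibrin")) {
    at450 <- subset(k$data, time_s == 450 & analyte == an)
    samples <- split(at450$value, at450$condition)
    res <- compare_conditions(samples)
    vs_ref <- res[res$a == "long_hi" | res$b == "long_hi", ]
    expect_true(all(vs_ref$significant),
                label = paste("long_hi comparisons significant for", an))
  }
})

test_that("identical condition specs produce no spurious significance calls", {
  # donor effect off: pooled observations are then independent, so the
  # family-wise false-positive rate is near its nominal (Bonferroni) level
  base <- default_condition_specs()$short_lo
  base$donor_cv <- 0
  specs <- lapply(default_condition_specs(), function(s) base)
  names(specs) <- names(default_condition_specs())
  set.seed(9)
  hits <- replicate(40, {
    k <- generate_kinetics(specs, seed = sample.int(1e6, 1))
    at450 <- subset(k$data, time_s == 450 & analyte == "thrombin")
    res <- compare_conditions(split(at450$value, at450$condition))
    sum(res$significant)
  })
  # 6 comparisons x 40 replicates at adjusted alpha 0.05
  expect_lte(mean(hits > 0), 0.2)
})
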