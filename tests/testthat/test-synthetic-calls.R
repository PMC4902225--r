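test_that("population sampling honours exact counts and determinism", {
  cfg <- population_config(seed = 3)
  pop1 <- sample_population(cfg)
  pop2 <- sample_population(cfg)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 36)
  expect_equal(sum(pop1$sex == "M"), 14)
  expect_equal(sum(pop1$sex == "F"), 22)
  expect_equal(sum(pop1$age == "HY"), 25)
  expect_equal(sum(pop1$age == "AHY"), 11)
  prop <- attr(pop1, "variant_propensity")
  expect_equal(unname(rowSums(prop)), rep(1, 36))
})

test_that("sex assignment matches the configured ratio at large n", {
  pop <- sample_population(population_config(n_birds = 10000, sex_ratio = 0.4,
                                             seed = 9))
  # rounding is exact here: 4000 males of 10000
  expect_equal(sum(pop$sex == "M"), 4000)
  # and a binomially sampled ratio stays in the 99% interval around 0.4
  set.seed(1)
  draws <- rbinom(1, 10000, 0.4) / 10000
  expect_lt(abs(draws - 0.4), 2.576 * sqrt(0.4 * 0.6 / 10000))
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(sex_ratio = 1.2), "ratio")
  expect_error(population_config(freq_low_bound = 0), "freq_low_bound")
  expect_error(population_config(freq_high_bound = 30000), "freq_low_bound")
  expect_error(sample_population(population_config(n_birds = 0)), "n_birds")
})

test_that("variant templates satisfy their shape invariants", {
  tm <- default_variant_templates()
  expect_setequal(names(tm), c("A", "G", "M", "S", "V"))
  for (t in tm) {
    bp <- t$contour_breakpoints
    expect_true(all(diff(bp[, "time"]) > 0))
    expect_equal(bp[1, "time"], 0, ignore_attr = TRUE)
    expect_equal(bp[nrow(bp), "time"], 1, ignore_attr = TRUE)
    expect_true(all(bp[, "freq"] >= 3500 & bp[, "freq"] <= 10300))
  }
  # V: minimum-frequency breakpoint at relative time 0.5
  bpv <- tm$V$contour_breakpoints
  expect_equal(bpv[which.min(bpv[, "freq"]), "time"], 0.5, tolerance = 0.05,
               ignore_attr = TRUE)
  # S: tail lower in frequency than the start
  bps <- tm$S$contour_breakpoints
  expect_lt(bps[nrow(bps), "freq"], bps[1, "freq"])
  expect_error(variant_template("X", c(0, 0.5, 0.4, 1), rep(8000, 4)),
               "increasing")
  expect_error(variant_template("X", c(0, 1), c(8000, 20000)), "Hz")
})

test_that("V-type calls place their frequency minimum near the midpoint", {
  cfg <- clean_config(seed = 1)
  set.seed(1)
  clip <- synthesize_call(null_profile(), default_variant_templates()$V, cfg)
  sp <- compute_spectrogram(clip)
  e <- rowSums(sp$power)
  cum <- cumsum(e) / sum(e)
  sel <- which(cum >= 0.05 & cum <= 0.95)
  pk <- sp$freqs[apply(sp$power[sel, ], 1, which.max)]
  rel <- (which.min(pk) - 1) / (length(pk) - 1)
  expect_gt(rel, 0.4)
  expect_lt(rel, 0.6)
})

test_that("noiseless synthesis tracks the analytic contour", {
  cfg <- clean_config(seed = 1)
  set.seed(1)
  clip <- synthesize_call(null_profile(), default_variant_templates()$A, cfg)
  sp <- compute_spectrogram(clip)
  e <- rowSums(sp$power)
  cum <- cumsum(e) / sum(e)
  sel <- which(cum >= 0.05 & cum <= 0.95)
  pk <- sp$freqs[apply(sp$power[sel, ], 1, which.max)]
  contour <- clip$meta$contour_hz
  centers <- pmin(pmax(round((sel - 1) * 38 + 128) - clip$meta$n_pad, 1),
                  length(contour))
  dev_bins <- abs(pk - contour[centers]) / (44100 / 256)
  # within one bin except where the window straddles the sharp inflection
  expect_lt(stats::quantile(dev_bins, 0.9), 1)
  expect_lt(max(dev_bins), 1.5)
})

test_that("a flat noiseless template produces a pure windowed tone", {
  cfg <- clean_config(seed = 1)
  flat <- variant_template("F", c(0, 1), c(8000, 8000), tail_mod_depth = 0,
                           inflection_sharpness = 0.01)
  set.seed(1)
  clip <- synthesize_call(null_profile(), flat, cfg)
  expect_lte(max(abs(clip$samples)), 1)
  sp <- compute_spectrogram(clip)
  peak_bin <- which.max(colSums(sp$power))
  expect_equal(peak_bin, round(8000 * 256 / 44100) + 1, tolerance = 1)
})

test_that("contour exceeding Nyquist raises a generation error", {
  cfg <- clean_config(sample_rate = 8000, freq_low_bound = 200,
                      freq_high_bound = 3900, seed = 1)
  tm <- variant_template("X", c(0, 1), c(3900, 3900), freq_bounds = c(0, 4000))
  set.seed(1)
  expect_error(synthesize_call(null_profile(), tm, cfg), "Nyquist")
})

test_that("generated datasets have the configured structure", {
  cfg <- population_config(n_birds = 36, calls_per_bird = 5, seed = 5)
  gen <- generate_calls(cfg)
  expect_equal(nrow(gen$manifest), 180)
  expect_equal(length(gen$clips), 180)
  expect_true(all(table(gen$manifest$bird_id) == 5))
  # ranged call counts stay within the range
  cfg2 <- population_config(n_birds = 10, calls_per_bird = c(1, 8), seed = 5)
  gen2 <- generate_calls(cfg2)
  counts <- table(gen2$manifest$bird_id)
  expect_true(all(counts >= 1 & counts <= 8))
  # zero calls: empty manifest, no error
  gen0 <- generate_calls(population_config(n_birds = 3, calls_per_bird = 0,
                                           seed = 5))
  expect_equal(nrow(gen0$manifest), 0)
  expect_length(gen0$clips, 0)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- population_config(n_birds = 3, calls_per_bird = 2, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_identical(m1, m2)
  for (f in m1$file) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  # manifest matches files on disk
  expect_true(all(file.exists(file.path(d1, m1$file))))
})

test_that("realised contours stay within the configured frequency bounds", {
  cfg <- population_config(n_birds = 10, calls_per_bird = 3, seed = 21)
  gen <- generate_calls(cfg)
  for (clip in gen$clips) {
    expect_true(all(clip$meta$contour_hz >= cfg$freq_low_bound - 1e-9))
    expect_true(all(clip$meta$contour_hz <= cfg$freq_high_bound + 1e-9))
    expect_lte(max(abs(clip$samples)), 1)
  }
})

test_that("duration variance decomposes into bird and call components", {
  cfg <- population_config(n_birds = 40, calls_per_bird = 10, seed = 31)
  gen <- generate_calls(cfg)
  m <- gen$manifest
  # residualise the sex effect, then compare between- vs within-bird variance
  d <- m$duration_ms - ave(m$duration_ms, m$sex)
  between <- var(tapply(d, m$bird_id, mean))
  within <- mean(tapply(d, m$bird_id, var))
  expect_gt(between, within)
})

test_that("sex shifts duration by the configured 6 ms and age shifts nothing", {
  cfg <- population_config(n_birds = 200, calls_per_bird = 5, seed = 13)
  gen <- generate_calls(cfg)
  m <- gen$manifest
  diff_sex <- mean(m$duration_ms[m$sex == "M"]) -
    mean(m$duration_ms[m$sex == "F"])
  expect_equal(diff_sex, 6, tolerance = 1.5) # Monte-Carlo error at n = 1000
  p_age <- t.test(duration_ms ~ age, data = m)$p.value
  expect_gt(p_age, 0.01)
})
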