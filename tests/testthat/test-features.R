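# build a spectrogram object directly for closed-form checks
make_spec <- function(power, fs = 44100, nfft = 256L, hop = 38L) {
  structure(list(power = power,
                 times = ((seq_len(nrow(power)) - 1) * hop + nfft / 2) / fs,
                 freqs = (seq_len(ncol(power)) - 1) * fs / nfft,
                 params = list(nfft = nfft, window = "hann", hop = hop,
                               sample_rate = fs)),
            class = "spectrogram")
}

test_that("the default registry defines 95 uniquely named measurements", {
  spec <- default_feature_spec()
  expect_equal(nrow(spec), 95)
  expect_false(any(duplicated(spec$name)))
  expect_true(all(c("bw90_hz", "contour_median_hz", "time_corr_median_ms",
                    "freq_concentration_hz", "mag_modewidth_hz") %in%
                    spec$name))
})

test_that("every synthetic call yields 95 finite measurements", {
  ds <- small_dataset()
  fv <- compute_features(compute_spectrogram(ds$clips[[1]]))
  expect_length(fv, 95)
  expect_true(all(is.finite(fv)))
  expect_named(fv, default_feature_spec()$name)
  # non-negative where units demand it
  expect_gte(fv[["dur90_ms"]], 0)
  expect_gte(fv[["bw90_hz"]], 0)
  expect_gte(fv[["time_entropy_bits"]], 0)
})

test_that("percentile durations and bandwidths match closed forms", {
  # rectangular time envelope, all energy in one tone bin
  n_frames <- 100
  power <- matrix(0, n_frames, 129)
  power[, 47] <- 1 # single bin
  fv <- compute_features(make_spec(power))
  hop_ms <- 38 / 44100 * 1000
  T_ms <- n_frames * hop_ms
  expect_equal(fv[["dur90_ms"]], 0.9 * T_ms, tolerance = hop_ms / (0.9 * T_ms),
               ignore_attr = TRUE)
  expect_lte(fv[["bw90_hz"]], 2 * 44100 / 256)
  expect_equal(fv[["peak_freq_hz"]], 46 * 44100 / 256, ignore_attr = TRUE)
  # uniform envelope entropy = log2(n_frames)
  expect_equal(fv[["time_entropy_bits"]], log2(n_frames), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fv[["freq_entropy_bits"]], 0, ignore_attr = TRUE)
})

test_that("zero-energy spectrograms raise the empty-clip error", {
  expect_error(compute_features(make_spec(matrix(0, 10, 129))), "empty clip")
})

test_that("measurements are invariant to amplitude scaling", {
  ds <- small_dataset()
  clip <- ds$clips[[1]]
  scaled <- waveform(clip$samples * 3.7, clip$sample_rate)
  f1 <- compute_features(compute_spectrogram(clip))
  f2 <- compute_features(compute_spectrogram(scaled))
  absolute <- c("mean_cell_power", "peak_frame_energy")
  rel <- abs(f2 - f1) / pmax(abs(f1), 1e-12)
  expect_lt(max(rel[setdiff(names(f1), absolute)]), 1e-9)
  # absolute-power features scale as amplitude^2, as documented
  expect_equal(unname(f2[absolute] / f1[absolute]), rep(3.7^2, 2),
               tolerance = 1e-9)
})

test_that("silent padding and time shifts barely move energy measurements", {
  cfg <- clean_config(seed = 2)
  set.seed(2)
  clip <- synthesize_call(null_profile(), default_variant_templates()$A, cfg)
  fs <- clip$sample_rate
  pad <- rep(0, round(0.005 * fs))
  padded <- waveform(c(pad, clip$samples, pad), fs)
  shifted <- waveform(c(rep(0, 15 * 38), clip$samples, rep(0, 5 * 38)), fs)
  f0 <- compute_features(compute_spectrogram(clip))
  fp <- compute_features(compute_spectrogram(padded))
  fsft <- compute_features(compute_spectrogram(shifted))
  hop_ms <- 38 / fs * 1000
  bin_hz <- fs / 256
  span_feats <- c(dur90_ms = hop_ms, dur50_ms = hop_ms,
                  bw90_hz = bin_hz, bw50_hz = bin_hz,
                  time_concentration_ms = hop_ms,
                  freq_concentration_hz = bin_hz,
                  freq_modewidth_hz = bin_hz)
  for (f in names(span_feats)) {
    expect_lte(abs(fp[[f]] - f0[[f]]), span_feats[[f]] + 1e-9)
    expect_lte(abs(fsft[[f]] - f0[[f]]), span_feats[[f]] + 1e-9)
  }
  expect_lt(abs(fsft[["time_entropy_bits"]] - f0[["time_entropy_bits"]]), 0.1)
  expect_lt(abs(fsft[["total_entropy_bits"]] - f0[["total_entropy_bits"]]), 0.1)
})

test_that("batch measurement skips failing clips and reports them", {
  ds <- small_dataset()
  clips <- c(ds$clips[1:4], list(waveform(rep(0, 2000), 44100)))
  manifest <- rbind(ds$manifest[1:4, ],
                    data.frame(file = "silent.wav", bird_id = "bX", sex = "M",
                               age = "HY", variant = "A", duration_ms = 0))
  tab <- batch_features(clips, manifest)
  expect_equal(nrow(tab), 4)
  fails <- attr(tab, "failures")
  expect_equal(nrow(fails), 1)
  expect_match(fails$message, "empty clip")
  # empty input keeps the full header
  empty <- batch_features(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(default_feature_spec()$name %in% names(empty)))
})

test_that("correlation pruning removes duplicates and constants, keeps independents", {
  set.seed(8)
  n <- 180
  tab <- data.frame(call_id = sprintf("c%03d", 1:n), bird_id = "b",
                    matrix(rnorm(n * 20), n,
                           dimnames = list(NULL, sprintf("f%02d", 1:20))))
  # 20 iid normal columns: no removals at |r| >= 0.95
  res <- prune_correlated(tab)
  expect_length(feature_columns(res$table), 20)
  expect_equal(nrow(res$report), 0)
  # duplicate column: exactly one of the pair removed
  tab$dup <- tab$f01
  res2 <- prune_correlated(tab)
  expect_length(feature_columns(res2$table), 20)
  expect_equal(sum(c("f01", "dup") %in% feature_columns(res2$table)), 1)
  expect_equal(res2$report$reason, "correlated")
  expect_equal(res2$report$abs_r, 1, tolerance = 1e-12)
  # constant column removed first with its own reason
  tab$flat <- 5
  res3 <- prune_correlated(tab)
  expect_false("flat" %in% feature_columns(res3$table))
  expect_true("constant" %in% res3$report$reason)
  # surviving features all correlate below the threshold
  R <- abs(cor(res3$table[, feature_columns(res3$table)]))
  diag(R) <- 0
  expect_lt(max(R), 0.95)
  expect_error(prune_correlated(tab, threshold = 1.5), "threshold")
})

test_that("subsampling drops sparse birds and is seed-reproducible", {
  tab <- gaussian_table(6, 7, 3, seed = 2)
  tab <- tab[-(1:3), ] # first bird now has 4 calls
  s1 <- subsample_calls(tab, n_per_bird = 5, min_calls = 5, seed = 10)
  s2 <- subsample_calls(tab, n_per_bird = 5, min_calls = 5, seed = 10)
  expect_identical(s1, s2)
  expect_false("b01" %in% s1$bird_id)
  expect_true(all(table(s1$bird_id) == 5))
  expect_equal(nrow(s1), 25)
  expect_error(subsample_calls(tab, n_per_bird = 6, min_calls = 5), "exceed")
})

test_that("subset consistency passes on identity and flags injected shifts", {
  tab <- gaussian_table(8, 6, 10, seed = 4)
  res_id <- subset_consistency(tab, tab)
  expect_true(res_id$pass)
  expect_true(all(res_id$per_feature$mean_diff == 0))
  sub <- subsample_calls(tab, n_per_bird = 3, min_calls = 3, seed = 1)
  shifted <- sub
  shifted$f01 <- shifted$f01 + 5 # + 5 SD shift
  full_shifted <- tab
  full_shifted[full_shifted$call_id %in% shifted$call_id, "f01"] <-
    shifted$f01
  res_sh <- subset_consistency(full_shifted, shifted, seed = 3)
  flagged <- res_sh$per_feature$feature[res_sh$per_feature$flagged]
  expect_true("f01" %in% flagged)
  expect_false(res_sh$pass)
  bad <- sub[, setdiff(names(sub), "f02")]
  expect_error(subset_consistency(tab, bad), "f02")
})

test_that("subset-consistency per-feature tests hold their nominal level", {
  set.seed(99)
  n_rep <- 300
  rej <- 0
  for (i in seq_len(n_rep)) {
    tab <- gaussian_table(10, 4, 1, seed = 9000 + i)
    sub <- subsample_calls(tab, n_per_bird = 2, min_calls = 2, seed = i)
    res <- subset_consistency(tab, sub, n_perm = 19, seed = i)
    if (res$per_feature$p[1] < 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  expect_gt(rate, 0.05 - 2.576 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("feature tables round-trip through CSV with metadata first", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(path, ds$features)
  r <- read_feature_table(path)
  expect_equal(names(r)[1:5], c("call_id", "file", "bird_id", "sex", "age"))
  expect_equal(r$bird_id, ds$features$bird_id)
  expect_equal(r[["dur90_ms"]], ds$features[["dur90_ms"]], tolerance = 1e-9)
  # external column naming handled by the map
  ext <- utils::read.csv(path)
  names(ext)[names(ext) == "bird_id"] <- "Band.ID"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ext, path2, row.names = FALSE)
  r2 <- read_feature_table(path2, column_map = c(bird_id = "Band.ID"))
  expect_equal(r2$bird_id, ds$features$bird_id)
  expect_error(read_feature_table(path2, column_map = c(bird_id = "nope")),
               "nope")
})
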