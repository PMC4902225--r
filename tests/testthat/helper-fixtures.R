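# shared fixtures, all built in code at test time

tone_wave <- function(freq_hz, n, fs = 44100, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq_hz * (0:(n - 1)) / fs), fs)
}

# a bird profile with no individual offsets
null_profile <- function(sex = "M", age = "HY", bird_id = "b1") {
  data.frame(bird_id = bird_id, sex = sex, age = age,
             offset_duration_ms = 0, offset_freq_hz = 0,
             offset_tail_depth_hz = 0, offset_tail_rate_hz = 0,
             stringsAsFactors = FALSE)
}

# deterministic synthesis config: no noise, no within-bird variation
clean_config <- function(...) {
  population_config(snr_db = Inf,
                    within_bird_sd = c(duration_ms = 0, freq_hz = 0,
                                       tail_depth_hz = 0, tail_rate_hz = 0),
                    ...)
}

zero_sd <- c(duration_ms = 0, freq_hz = 0, tail_depth_hz = 0, tail_rate_hz = 0)

# population config with every bird-level effect removed (exchangeable calls)
exchangeable_config <- function(...) {
  svt <- default_sex_variant_table()
  svt["M", ] <- svt["F", ]
  population_config(between_bird_sd = zero_sd,
                    duration_mean_male = 69, duration_mean_female = 69,
                    freq_offset_female = 0, sex_variant_table = svt, ...)
}

# small feature table of iid gaussian columns with bird metadata
gaussian_table <- function(n_birds, calls_per_bird, p, seed = 1,
                           bird_shift = NULL) {
  set.seed(seed)
  n <- n_birds * calls_per_bird
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  bird <- rep(sprintf("b%02d", seq_len(n_birds)), each = calls_per_bird)
  if (!is.null(bird_shift)) {
    X <- X + bird_shift[match(bird, unique(bird))]
  }
  data.frame(call_id = sprintf("c%03d", seq_len(n)), bird_id = bird,
             sex = rep(rep(c("M", "F"), length.out = n_birds),
                       each = calls_per_bird),
             # period-4 cycle so age never aliases the period-2 sex labels
             age = rep(rep(rep(c("HY", "AHY"), each = 2),
                           length.out = n_birds), each = calls_per_bird),
             variant = sample(c("A", "V"), n, replace = TRUE),
             X, stringsAsFactors = FALSE)
}

# independent oracle: multivariate one-way sums of squares from coordinates
coord_f <- function(X, groups) {
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- 0
  for (g in unique(groups)) {
    sub <- X[groups == g, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  a <- length(unique(groups))
  n <- nrow(X)
  list(F = ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a)),
       ss_total = ss_total, ss_within = ss_within)
}

# a small cached synthetic dataset with features, shared across tests
local({
  cache <- new.env(parent = emptyenv())
  small_dataset <<- function() {
    if (is.null(cache$ds)) {
      cfg <- population_config(n_birds = 8, calls_per_bird = 5, seed = 42)
      gen <- generate_calls(cfg)
      feats <- batch_features(gen$clips, gen$manifest)
      cache$ds <- list(config = cfg, clips = gen$clips,
                       manifest = gen$manifest, features = feats)
    }
    cache$ds
  }
})
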