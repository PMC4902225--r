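#' Default flight-call variant templates
#'
#' Five stylised contour templates (codes A, G, M, S, V) covering the
#' qualitative shape classes of American Redstart flight calls: a typical
#' 'tick-mark' with a concave inflection and modulated tail (A), an acute
#' convex inflection followed by a shallow obtuse one (G), two convex
#' inflections flanking a central concave one (M), an obtuse central
#' concave inflection with the tail lower in frequency than the start (S),
#' and a symmetric, acute V-shape (V). Each template is a piecewise-linear
#' frequency contour over relative time \[0, 1\], smoothed at synthesis
#' time by a raised-cosine kernel, plus a sinusoidally frequency-modulated
#' tail. The breakpoint tables are fixed calibration constants of this
#' package, not field measurements.
#'
#' @return Named list of `variant_template` objects.
#' @export
default_variant_templates <- function() {
  tmpl <- function(code, t, f, sharp, depth, rate, tail) {
    variant_template(code, t, f, inflection_sharpness = sharp,
                     tail_mod_depth = depth, tail_mod_rate = rate,
                     tail_fraction = tail)
  }
  list(
    A = tmpl("A", c(0, 0.35, 0.75, 1), c(8800, 5200, 8200, 7800),
             sharp = 0.10, depth = 300, rate = 1000, tail = 0.30),
    G = tmpl("G", c(0, 0.25, 0.55, 1), c(5800, 8800, 6800, 7200),
             sharp = 0.12, depth = 300, rate = 1000, tail = 0.35),
    M = tmpl("M", c(0, 0.20, 0.50, 0.80, 1), c(6500, 9000, 5600, 9000, 7500),
             sharp = 0.08, depth = 250, rate = 1000, tail = 0.15),
    S = tmpl("S", c(0, 0.50, 1), c(8600, 6000, 6900),
             sharp = 0.18, depth = 300, rate = 900, tail = 0.30),
    V = tmpl("V", c(0, 0.50, 1), c(9300, 4800, 9300),
             sharp = 0.05, depth = 150, rate = 800, tail = 0.10)
  )
}

#' Construct a call-variant contour template
#'
#' @param variant_code Single-letter variant label.
#' @param times Breakpoint times as fractions of call duration; strictly
#'   increasing, first 0, last 1.
#' @param freqs Breakpoint frequencies in Hz.
#' @param inflection_sharpness Half-width of the raised-cosine smoothing
#'   kernel applied to the piecewise-linear contour, as a fraction of call
#'   duration (smaller = more acute inflections).
#' @param tail_mod_depth,tail_mod_rate Sinusoidal frequency modulation of
#'   the call tail: depth in Hz, rate in Hz.
#' @param tail_fraction Fraction of the call occupied by the modulated
#'   tail.
#' @param freq_bounds Global frequency bounds every breakpoint must obey.
#' @return A `variant_template`.
#' @export
variant_template <- function(variant_code, times, freqs,
                             inflection_sharpness = 0.1,
                             tail_mod_depth = 300, tail_mod_rate = 1000,
                             tail_fraction = 0.3,
                             freq_bounds = c(3500, 10300)) {
  if (length(times) != length(freqs)) {
    stop("'times' and 'freqs' must have equal length", call. = FALSE)
  }
  if (times[1] != 0 || times[length(times)] != 1 || any(diff(times) <= 0)) {
    stop("breakpoint times must be strictly increasing from 0 to 1",
         call. = FALSE)
  }
  if (any(freqs < freq_bounds[1] | freqs > freq_bounds[2])) {
    stop(sprintf("breakpoint frequencies must lie in [%g, %g] Hz",
                 freq_bounds[1], freq_bounds[2]), call. = FALSE)
  }
  structure(list(variant_code = variant_code,
                 contour_breakpoints = cbind(time = times, freq = freqs),
                 inflection_sharpness = inflection_sharpness,
                 tail_mod_depth = tail_mod_depth,
                 tail_mod_rate = tail_mod_rate,
                 tail_fraction = tail_fraction),
            class = "variant_template")
}

#' Configuration for a synthetic flight-call population
#'
#' Collects every tunable of the generator with defaults matching the
#' study population the package emulates: 36 birds (14 males, 22 females;
#' 25 hatch-year), male mean call duration 72 ms versus 66 ms for females,
#' call energy confined to 3.5--10.3 kHz at a 44.1 kHz sample rate, and
#' per-sex call-variant propensities taken from the observed sex-by-variant
#' call counts. Between-bird parameter scatter exceeds within-bird scatter
#' so calls carry an individual signature; age affects nothing.
#'
#' @param n_birds Number of birds.
#' @param calls_per_bird Calls per bird: a single count or a `c(min, max)`
#'   range sampled uniformly per bird.
#' @param sex_ratio Fraction of males (exact counts via `round`).
#' @param age_ratio Fraction of hatch-year (HY) birds.
#' @param duration_mean_male,duration_mean_female Mean call duration (ms).
#' @param duration_sd_within Within-bird duration SD (ms).
#' @param duration_range Hard clip on realised duration (ms).
#' @param freq_low_bound,freq_high_bound Frequency band of call energy (Hz).
#' @param freq_offset_female Additive shift of the whole contour for
#'   females (Hz); emulates the narrower, higher female frequency range.
#' @param between_bird_sd,within_bird_sd Named numeric vectors of SDs for
#'   the latent call parameters `duration_ms`, `freq_hz`, `tail_depth_hz`
#'   and `tail_rate_hz`; between-bird values are drawn once per bird,
#'   within-bird values once per call.
#' @param sex_variant_table 2 x 5 matrix of per-sex variant probabilities
#'   (rows `M`, `F`; columns `A G M S V`), each row summing to 1.
#' @param snr_db Signal-to-noise ratio of additive white Gaussian noise in
#'   dB (`Inf` for noiseless).
#' @param sample_rate Output sample rate (Hz).
#' @param pad_ms Near-silent padding on each side of every call (ms).
#' @param seed Integer seed; fixes profiles, call parameters and noise.
#' @return A list of class `"population_config"`.
#' @export
population_config <- function(n_birds = 36L,
                              calls_per_bird = 5L,
                              sex_ratio = 14 / 36,
                              age_ratio = 25 / 36,
                              duration_mean_male = 72,
                              duration_mean_female = 66,
                              duration_sd_within = 3,
                              duration_range = c(38, 95),
                              freq_low_bound = 3500,
                              freq_high_bound = 10300,
                              freq_offset_female = 300,
                              between_bird_sd = c(duration_ms = 6, freq_hz = 350,
                                                  tail_depth_hz = 100, tail_rate_hz = 250),
                              within_bird_sd = c(duration_ms = 3, freq_hz = 80,
                                                 tail_depth_hz = 30, tail_rate_hz = 50),
                              sex_variant_table = default_sex_variant_table(),
                              snr_db = 20,
                              sample_rate = 44100,
                              pad_ms = 5,
                              seed = 1L) {
  if (n_birds < 0) stop("'n_birds' must be non-negative", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1 || age_ratio < 0 || age_ratio > 1) {
    stop("sex_ratio and age_ratio must lie in [0, 1]", call. = FALSE)
  }
  if (!(freq_low_bound > 0 && freq_low_bound < freq_high_bound &&
        freq_high_bound < sample_rate / 2)) {
    stop("need 0 < freq_low_bound < freq_high_bound < sample_rate/2",
         call. = FALSE)
  }
  par_names <- c("duration_ms", "freq_hz", "tail_depth_hz", "tail_rate_hz")
  if (!all(par_names %in% names(between_bird_sd)) ||
      !all(par_names %in% names(within_bird_sd))) {
    stop("between_bird_sd and within_bird_sd must name: ",
         paste(par_names, collapse = ", "), call. = FALSE)
  }
  if (any(abs(rowSums(sex_variant_table) - 1) > 1e-8)) {
    stop("each row of sex_variant_table must sum to 1", call. = FALSE)
  }
  structure(list(
    n_birds = as.integer(n_birds), calls_per_bird = calls_per_bird,
    sex_ratio = sex_ratio, age_ratio = age_ratio,
    duration_mean_male = duration_mean_male,
    duration_mean_female = duration_mean_female,
    duration_sd_within = duration_sd_within,
    duration_range = duration_range,
    freq_low_bound = freq_low_bound, freq_high_bound = freq_high_bound,
    freq_offset_female = freq_offset_female,
    between_bird_sd = between_bird_sd[par_names],
    within_bird_sd = within_bird_sd[par_names],
    sex_variant_table = sex_variant_table,
    snr_db = snr_db, sample_rate = sample_rate, pad_ms = pad_ms,
    seed = as.integer(seed)
  ), class = "population_config")
}

#' Default per-sex variant propensities
#'
#' Probabilities of each call variant (A, G, M, S, V) by sex, derived from
#' observed call counts in which males produced no G calls, only males
#' produced M calls, and S calls came almost exclusively from females
#' (male counts 40/0/6/1/23 of 70; female counts 35/7/0/28/40 of 110).
#'
#' @return A 2 x 5 numeric matrix with rows `M`, `F`.
#' @export
default_sex_variant_table <- function() {
  m <- rbind(M = c(40, 0, 6, 1, 23) / 70,
             F = c(35, 7, 0, 28, 40) / 110)
  colnames(m) <- c("A", "G", "M", "S", "V")
  m
}

#' Sample a population of bird profiles
#'
#' Draws one latent profile per bird: sex and age labels (exact marginal
#' counts via rounding of the configured ratios, order randomised),
#' per-bird additive offsets for duration, contour frequency and tail
#' modulation (the individual signature), and the bird's sex-specific
#' variant propensities.
#'
#' @param config A [population_config].
#' @return A data-frame-like list of class `"bird_population"`: one row per
#'   bird with columns `bird_id`, `sex`, `age`, the four `offset_*`
#'   columns, and a `variant_propensity` matrix attribute.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  if (config$n_birds < 1) stop("'n_birds' must be >= 1", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_birds
  n_male <- round(n * config$sex_ratio)
  n_hy <- round(n * config$age_ratio)
  sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
  age <- sample(c(rep("HY", n_hy), rep("AHY", n - n_hy)))
  bsd <- config$between_bird_sd
  prof <- data.frame(
    bird_id = sprintf("bird%02d", seq_len(n)),
    sex = sex, age = age,
    offset_duration_ms = stats::rnorm(n, 0, bsd[["duration_ms"]]),
    offset_freq_hz = stats::rnorm(n, 0, bsd[["freq_hz"]]),
    offset_tail_depth_hz = stats::rnorm(n, 0, bsd[["tail_depth_hz"]]),
    offset_tail_rate_hz = stats::rnorm(n, 0, bsd[["tail_rate_hz"]]),
    stringsAsFactors = FALSE
  )
  attr(prof, "variant_propensity") <- config$sex_variant_table[prof$sex, , drop = FALSE]
  class(prof) <- c("bird_population", "data.frame")
  prof
}

# raised-cosine smoothing of a contour; half-width in samples
.smooth_contour <- function(f, half_width) {
  h <- max(1L, round(half_width))
  k <- seq(-h, h)
  w <- 1 + cos(pi * k / (h + 1))
  w <- w / sum(w)
  n <- length(f)
  fp <- c(rep(f[1], h), f, rep(f[n], h))
  stats::filter(fp, w, sides = 2)[(h + 1):(h + n)]
}

#' Synthesise one flight call
#'
#' Renders a call as `sin(phase)` where the phase is the cumulative
#' integral of a smoothed piecewise-linear frequency contour (the variant
#' template shifted by the bird's and the call's frequency offsets), with
#' a sinusoidally frequency-modulated tail, a Tukey (tapered-cosine)
#' amplitude envelope, near-silent padding on both ends and additive white
#' Gaussian noise at the configured SNR. The realised duration is the sex
#' mean plus the bird's offset plus within-bird noise, clipped to the
#' configured range.
#'
#' @param profile One row of a `bird_population` (data frame with the
#'   `offset_*` columns plus `sex`, `age`, `bird_id`).
#' @param template A `variant_template`.
#' @param config A [population_config].
#' @return A `call_clip`: a [waveform] with a `meta` element recording
#'   bird, sex, age, variant and the realised parameters.
#' @export
synthesize_call <- function(profile, template, config) {
  fs <- config$sample_rate
  wsd <- config$within_bird_sd
  sex_mean <- if (profile$sex == "M") config$duration_mean_male else config$duration_mean_female
  dur_ms <- sex_mean + profile$offset_duration_ms +
    stats::rnorm(1, 0, wsd[["duration_ms"]])
  dur_ms <- min(max(dur_ms, config$duration_range[1]), config$duration_range[2])
  n_call <- max(2L, round(dur_ms / 1000 * fs))

  freq_off <- profile$offset_freq_hz + stats::rnorm(1, 0, wsd[["freq_hz"]]) +
    if (profile$sex == "F") config$freq_offset_female else 0
  bp <- template$contour_breakpoints
  rel <- seq(0, 1, length.out = n_call)
  f <- stats::approx(bp[, "time"], bp[, "freq"], xout = rel)$y + freq_off
  f <- .smooth_contour(f, template$inflection_sharpness * n_call)

  depth <- max(0, template$tail_mod_depth + profile$offset_tail_depth_hz +
                 stats::rnorm(1, 0, wsd[["tail_depth_hz"]]))
  rate <- max(50, template$tail_mod_rate + profile$offset_tail_rate_hz +
                stats::rnorm(1, 0, wsd[["tail_rate_hz"]]))
  tail_n <- round(template$tail_fraction * n_call)
  if (tail_n > 1) {
    idx <- (n_call - tail_n + 1):n_call
    tt <- (seq_len(tail_n) - 1) / fs
    ramp <- seq(0, 1, length.out = tail_n) # fade modulation in
    f[idx] <- f[idx] + depth * ramp * sin(2 * pi * rate * tt)
  }
  if (max(f) >= fs / 2) {
    stop("contour exceeds the Nyquist frequency; lower freq_high_bound or raise sample_rate",
         call. = FALSE)
  }
  f <- pmin(pmax(f, config$freq_low_bound), config$freq_high_bound)

  phase <- 2 * pi * cumsum(f) / fs
  sig <- sin(phase)
  # Tukey envelope, 10% taper each side
  taper <- max(2L, round(0.1 * n_call))
  env <- rep(1, n_call)
  ramp_in <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper)))
  env[seq_len(taper)] <- ramp_in
  env[(n_call - taper + 1):n_call] <- rev(ramp_in)
  sig <- sig * env * 0.9

  n_pad <- .ms_to_samples(config$pad_ms, fs)
  x <- c(rep(0, n_pad), sig, rep(0, n_pad))
  if (is.finite(config$snr_db)) {
    rms_sig <- sqrt(mean(sig^2))
    sigma <- rms_sig * 10^(-config$snr_db / 20)
    x <- x + stats::rnorm(length(x), 0, sigma)
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x * (0.99 / peak)

  clip <- waveform(x, fs)
  clip$meta <- list(bird_id = profile$bird_id, sex = profile$sex,
                    age = profile$age, variant = template$variant_code,
                    duration_ms = dur_ms, freq_offset_hz = freq_off,
                    tail_depth_hz = depth, tail_rate_hz = rate,
                    n_pad = n_pad, contour_hz = as.numeric(f))
  class(clip) <- c("call_clip", "waveform")
  clip
}

#' Generate a synthetic call dataset in memory
#'
#' Samples a population, draws each bird's call count and per-call variant
#' (from the bird's sex-specific propensities), and synthesises every
#' call. Fully determined by `config$seed`.
#'
#' @param config A [population_config].
#' @return A list with `clips` (list of `call_clip`) and `manifest` (data
#'   frame with columns `file`, `bird_id`, `sex`, `age`, `variant`,
#'   `duration_ms`).
#' @export
generate_calls <- function(config) {
  stopifnot(inherits(config, "population_config"))
  if (config$n_birds < 1 || .total_calls_zero(config)) {
    return(list(clips = list(), manifest = .empty_manifest()))
  }
  pop <- sample_population(config) # seeds the stream
  templates <- default_variant_templates()
  prop <- attr(pop, "variant_propensity")
  cpb <- config$calls_per_bird
  clips <- list()
  rows <- list()
  k <- 0L
  for (b in seq_len(nrow(pop))) {
    n_calls <- if (length(cpb) == 2L) sample(cpb[1]:cpb[2], 1L) else cpb
    if (n_calls < 1) next
    variants <- sample(colnames(prop), n_calls, replace = TRUE, prob = prop[b, ])
    for (v in variants) {
      k <- k + 1L
      clip <- synthesize_call(pop[b, ], templates[[v]], config)
      clips[[k]] <- clip
      rows[[k]] <- data.frame(file = sprintf("call_%04d.wav", k),
                              bird_id = clip$meta$bird_id, sex = clip$meta$sex,
                              age = clip$meta$age, variant = v,
                              duration_ms = clip$meta$duration_ms,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- if (k > 0L) do.call(rbind, rows) else .empty_manifest()
  list(clips = clips, manifest = manifest)
}

.empty_manifest <- function() {
  data.frame(file = character(), bird_id = character(), sex = character(),
             age = character(), variant = character(), duration_ms = numeric(),
             stringsAsFactors = FALSE)
}

.total_calls_zero <- function(config) {
  cpb <- config$calls_per_bird
  if (length(cpb) == 2L) cpb[2] < 1 else cpb < 1
}

#' Write a synthetic call dataset to disk
#'
#' Like [generate_calls] but writes one mono WAV per call plus a
#' `manifest.csv` (columns `file,bird_id,sex,age,variant,duration_ms`)
#' into `out_dir`.
#'
#' @param config A [population_config].
#' @param out_dir Output directory (created if needed).
#' @param bit_depth WAV encoding, see [write_wav].
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(config, out_dir, bit_depth = "float32") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  res <- generate_calls(config)
  for (i in seq_along(res$clips)) {
    write_wav(file.path(out_dir, res$manifest$file[i]), res$clips[[i]],
              bit_depth = bit_depth)
  }
  utils::write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(res$manifest)
}
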