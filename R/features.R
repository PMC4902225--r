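## Acoustat-style energy-distribution measurements.
##
## Every measurement is computed from the spectrogram's marginal
## distributions: the time envelope e(t) = sum_f P(t,f), the aggregate
## power spectrum s(f) = sum_t P(t,f) and the aggregate magnitude spectrum
## m(f) = sum_t sqrt(P(t,f)). The registry below is the normative
## definition of each measurement for this package; names are stable and
## versioned with the package.

.meta_cols <- c("call_id", "file", "bird_id", "sex", "age", "variant",
                "duration_ms")

#' Names of the metadata (non-feature) columns of a feature table
#' @return Character vector of reserved metadata column names.
#' @export
metadata_columns <- function() .meta_cols

#' Feature columns of a feature table
#' @param table A feature table (data frame).
#' @return Character vector of feature column names (everything that is
#'   not a reserved metadata column).
#' @export
feature_columns <- function(table) setdiff(names(table), .meta_cols)

.feature_registry <- local({
  row <- function(name, family, units) data.frame(name = name, family = family,
                                                  units = units,
                                                  stringsAsFactors = FALSE)
  qs_lab <- c("2.5", "5", "25", "50", "75", "95", "97.5")
  rbind(
    row(paste0("time_pct", qs_lab, "_ms"), "time-percentile", "ms"),
    row(c("dur90_ms", "dur50_ms", "dur95_ms"), "time-percentile", "ms"),
    row("time_concentration_ms", "concentration", "ms"),
    row("time_modewidth_ms", "modewidth", "ms"),
    row("time_mode_ms", "modewidth", "ms"),
    row("time_entropy_bits", "entropy", "bits"),
    row(c("time_skewness", "time_kurtosis"), "time-percentile", "1"),
    row(c("time_corr_median_ms", "time_corr_spread_ms", "time_corr_halfwidth_ms"),
        "correlation-envelope", "ms"),
    row(paste0("freq_pct", qs_lab, "_hz"), "freq-percentile", "Hz"),
    row(c("bw90_hz", "bw50_hz", "bw95_hz"), "freq-percentile", "Hz"),
    row("freq_concentration_hz", "concentration", "Hz"),
    row("freq_modewidth_hz", "modewidth", "Hz"),
    row("freq_mode_hz", "modewidth", "Hz"),
    row("freq_entropy_bits", "entropy", "bits"),
    row(c("freq_skewness", "freq_kurtosis"), "freq-percentile", "1"),
    row("peak_freq_hz", "freq-percentile", "Hz"),
    row(c("freq_corr_median_hz", "freq_corr_spread_hz", "freq_corr_halfwidth_hz"),
        "correlation-envelope", "Hz"),
    row(paste0("mag_pct", qs_lab, "_hz"), "freq-percentile", "Hz"),
    row(c("mag_bw90_hz", "mag_bw50_hz"), "freq-percentile", "Hz"),
    row("mag_concentration_hz", "concentration", "Hz"),
    row("mag_modewidth_hz", "modewidth", "Hz"),
    row("mag_mode_hz", "modewidth", "Hz"),
    row("mag_entropy_bits", "entropy", "bits"),
    row("total_entropy_bits", "entropy", "bits"),
    row("peak_power_rel", "amplitude", "1"),
    row("peak_time_ms", "time-percentile", "ms"),
    row(c("contour_median_hz", "contour_mean_hz", "contour_spread_hz",
          "contour_min_hz", "contour_max_hz", "contour_range_hz",
          "contour_start_hz", "contour_end_hz"), "contour", "Hz"),
    row("contour_slope_hz_ms", "contour", "Hz/ms"),
    row(c("contour_upsweep_frac", "contour_inflections"), "contour", "1"),
    row("contour_sd_hz", "contour", "Hz"),
    row(c("contour_min_pos_rel", "contour_max_pos_rel"), "contour", "1"),
    row(c("contour_slope_first_hz_ms", "contour_slope_second_hz_ms"),
        "contour", "Hz/ms"),
    row("mean_cell_power", "amplitude", "power"),      # absolute scale
    row("peak_frame_energy", "amplitude", "power"),    # absolute scale
    row("crest_factor", "amplitude", "1"),
    row("spectral_flatness", "amplitude", "1"),
    row(c("frame_entropy_mean_bits", "frame_entropy_max_bits",
          "frame_entropy_min_bits"), "entropy", "bits"),
    row(c("attack_ms", "decay_ms"), "time-percentile", "ms"),
    row("temporal_asymmetry", "time-percentile", "1"),
    row(c("spectral_centroid_hz", "spectral_sd_hz", "spectral_rolloff85_hz"),
        "freq-percentile", "Hz"),
    row("spectral_asymmetry", "freq-percentile", "1"),
    row(c("temporal_centroid_ms", "temporal_sd_ms"), "time-percentile", "ms"),
    row(paste0("band_energy_q", 1:4), "amplitude", "1"),
    row(paste0("time_energy_q", 1:4), "amplitude", "1")
  )
})

#' The default acoustic-feature specification
#'
#' An ordered registry of 95 named energy-distribution measurements:
#' cumulative-energy percentile locations and derived durations and
#' bandwidths on the time envelope and the aggregate power and magnitude
#' spectra; concentrations (smallest total bin width holding half of the
#' energy) and modewidths (contiguous half-maximum width around the mode);
#' Shannon entropies; peak-frequency-contour statistics over the
#' 90-percent-energy time span; correlation-envelope statistics; and
#' amplitude/shape summaries. Columns: `name`, `family`, `units`.
#'
#' The two `amplitude`-family measurements `mean_cell_power` and
#' `peak_frame_energy` are on the absolute power scale and scale with the
#' square of the waveform amplitude; every other measurement is invariant
#' to amplitude scaling.
#'
#' @return A 95-row data frame of class `"feature_spec"`.
#' @export
default_feature_spec <- function() {
  spec <- .feature_registry
  class(spec) <- c("feature_spec", "data.frame")
  spec
}

# location of quantile q of a discrete mass w over ordered axis x
.wpctl <- function(x, w, q) {
  cum <- cumsum(w) / sum(w)
  x[which(cum >= q - 1e-12)[1L]]
}

.concentration <- function(w, width) {
  ws <- sort(w, decreasing = TRUE)
  k <- which(cumsum(ws) >= 0.5 * sum(w) - 1e-12)[1L]
  k * width
}

.modewidth <- function(w, width) {
  i0 <- which.max(w)
  half <- w[i0] / 2
  lo <- i0
  while (lo > 1L && w[lo - 1L] >= half) lo <- lo - 1L
  hi <- i0
  while (hi < length(w) && w[hi + 1L] >= half) hi <- hi + 1L
  (hi - lo + 1L) * width
}

.entropy_bits <- function(w) {
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.wmoments <- function(x, w) {
  p <- w / sum(w)
  mu <- sum(p * x)
  v <- sum(p * (x - mu)^2)
  s <- sqrt(v)
  if (s < 1e-12) return(c(mean = mu, sd = s, skew = 0, kurt = 0))
  c(mean = mu, sd = s,
    skew = sum(p * (x - mu)^3) / s^3,
    kurt = sum(p * (x - mu)^4) / s^4)
}

# autocorrelation envelope of a non-negative marginal; returns the
# area-median lag, the area inter-quartile spread, and the half-maximum
# half-width, all in axis units (step = axis spacing)
.corr_envelope <- function(w, step) {
  n <- length(w)
  denom <- sum(w^2)
  if (denom <= 0) return(c(median = 0, spread = 0, halfwidth = 0))
  r <- vapply(0:(n - 1L), function(k) {
    sum(w[1:(n - k)] * w[(1 + k):n]) / denom
  }, numeric(1))
  r <- pmax(r, 0)
  a <- cumsum(r)
  lag_at <- function(q) (which(a >= q * a[n] - 1e-12)[1L] - 1L) * step
  below <- which(r < 0.5)
  hw <- if (!length(below)) (n - 1L) * step else {
    k <- below[1L]
    if (k == 1L) 0 else (k - 2L + (r[k - 1L] - 0.5) / (r[k - 1L] - r[k])) * step
  }
  c(median = lag_at(0.5), spread = lag_at(0.75) - lag_at(0.25), halfwidth = hw)
}

#' Compute acoustic measurements for one call
#'
#' Evaluates the measurement registry (see [default_feature_spec]) on a
#' spectrogram. All measurements derive from the marginal energy
#' distributions of the spectrogram and from the per-frame peak-frequency
#' contour restricted to the 90-percent-energy time span, so adding silent
#' padding or rescaling the waveform leaves all duration, bandwidth,
#' concentration, entropy and contour measurements (essentially)
#' unchanged.
#'
#' @param spectrogram A `spectrogram` (see [compute_spectrogram]).
#' @param spec A feature specification; defaults to the full 95-entry
#'   registry. A subset (by row) restricts the output.
#' @return Named numeric vector, one finite value per spec entry.
#' @export
compute_features <- function(spectrogram, spec = default_feature_spec()) {
  P <- spectrogram$power
  tot <- sum(P)
  if (!is.finite(tot) || tot <= 0) stop("empty clip", call. = FALSE)
  times_ms <- spectrogram$times * 1000
  freqs <- spectrogram$freqs
  fs <- spectrogram$params$sample_rate
  hop_ms <- spectrogram$params$hop / fs * 1000
  bin_hz <- fs / spectrogram$params$nfft

  e <- rowSums(P)
  s <- colSums(P)
  m <- colSums(sqrt(P))

  qs <- c(0.025, 0.05, 0.25, 0.50, 0.75, 0.95, 0.975)
  tq <- vapply(qs, function(q) .wpctl(times_ms, e, q), numeric(1))
  fq <- vapply(qs, function(q) .wpctl(freqs, s, q), numeric(1))
  mq <- vapply(qs, function(q) .wpctl(freqs, m, q), numeric(1))

  tmom <- .wmoments(times_ms, e)
  fmom <- .wmoments(freqs, s)
  tcorr <- .corr_envelope(e, hop_ms)
  fcorr <- .corr_envelope(s, bin_hz)

  peak_cell <- arrayInd(which.max(P), dim(P))
  peak_freq <- freqs[which.max(s)]

  # peak-frequency contour over the 90%-energy time span
  sel <- which(times_ms >= tq[2] - 1e-9 & times_ms <= tq[6] + 1e-9)
  if (length(sel) < 2L) sel <- seq_along(times_ms)
  pk <- freqs[vapply(sel, function(i) which.max(P[i, ]), integer(1))]
  npk <- length(pk)
  span_ms <- max(times_ms[sel[npk]] - times_ms[sel[1L]], hop_ms)
  sm <- if (npk >= 3L) {
    c(pk[1L], (pk[-c(npk - 1L, npk)] + pk[-c(1L, npk)] + pk[-c(1L, 2L)]) / 3, pk[npk])
  } else pk
  d <- diff(sm)
  signs <- sign(d)
  signs <- signs[signs != 0]
  inflections <- if (length(signs) > 1L) sum(diff(signs) != 0) else 0
  upsweep <- if (npk > 1L) mean(diff(pk) > 0) else 0
  half <- max(2L, floor(npk / 2))
  slope_of <- function(idx) {
    dt <- times_ms[sel[idx[length(idx)]]] - times_ms[sel[idx[1L]]]
    if (dt <= 0) 0 else (pk[idx[length(idx)]] - pk[idx[1L]]) / dt
  }

  # per-frame spectral entropy over the span
  fe <- vapply(sel, function(i) {
    wi <- P[i, ]
    if (sum(wi) <= 0) 0 else .entropy_bits(wi)
  }, numeric(1))

  t_epeak <- times_ms[which.max(e)]
  attack <- t_epeak - tq[1]
  decay <- tq[7] - t_epeak
  denom_ad <- attack + decay
  f_span <- fq[7] - fq[1]

  quarters <- function(w, axis, lo, hi) {
    if (hi <= lo) return(c(1, 0, 0, 0))
    edges <- seq(lo, hi, length.out = 5L)
    inside <- axis >= lo - 1e-9 & axis <= hi + 1e-9
    wt <- sum(w[inside])
    if (wt <= 0) return(c(1, 0, 0, 0))
    vapply(1:4, function(k) {
      inq <- axis >= edges[k] - 1e-9 & (if (k < 4) axis < edges[k + 1] - 1e-9
                                        else axis <= edges[5] + 1e-9)
      sum(w[inside & inq]) / wt
    }, numeric(1))
  }

  flat <- {
    sa <- mean(s)
    if (sa <= 0 || any(s <= 0)) 0 else exp(mean(log(s))) / sa
  }

  vals <- c(
    tq, tq[6] - tq[2], tq[5] - tq[3], tq[7] - tq[1],
    .concentration(e, hop_ms), .modewidth(e, hop_ms),
    times_ms[which.max(e)], .entropy_bits(e), tmom[["skew"]], tmom[["kurt"]],
    tcorr,
    fq, fq[6] - fq[2], fq[5] - fq[3], fq[7] - fq[1],
    .concentration(s, bin_hz), .modewidth(s, bin_hz),
    freqs[which.max(s)], .entropy_bits(s), fmom[["skew"]], fmom[["kurt"]],
    peak_freq, fcorr,
    mq, mq[6] - mq[2], mq[5] - mq[3],
    .concentration(m, bin_hz), .modewidth(m, bin_hz),
    freqs[which.max(m)], .entropy_bits(m),
    .entropy_bits(as.vector(P)),
    max(P) / tot,
    times_ms[peak_cell[1L]],
    stats::median(pk), mean(pk), stats::IQR(pk), min(pk), max(pk),
    max(pk) - min(pk), pk[1L], pk[npk],
    (pk[npk] - pk[1L]) / span_ms,
    upsweep, inflections, stats::sd(pk),
    (which.min(pk) - 1) / max(npk - 1, 1), (which.max(pk) - 1) / max(npk - 1, 1),
    slope_of(1:half), slope_of(half:npk),
    tot / length(P), max(e),
    sqrt(max(e) / mean(e)), flat,
    mean(fe), max(fe), min(fe),
    attack, decay,
    if (denom_ad > 0) (attack - decay) / denom_ad else 0,
    fmom[["mean"]], fmom[["sd"]], .wpctl(freqs, s, 0.85),
    if (f_span > 0) (2 * peak_freq - fq[1] - fq[7]) / f_span else 0,
    tmom[["mean"]], tmom[["sd"]],
    quarters(s, freqs, fq[2], fq[6]),
    quarters(e, times_ms, tq[2], tq[6])
  )
  names(vals) <- .feature_registry$name
  if (npk < 2L) vals["contour_sd_hz"] <- 0
  if (!all(is.finite(vals))) {
    stop(sprintf("non-finite feature value(s): %s",
                 paste(names(vals)[!is.finite(vals)], collapse = ", ")),
         call. = FALSE)
  }
  vals[spec$name]
}

#' Compute a feature table for many clips
#'
#' Applies [compute_features] to every clip and joins per-call metadata.
#' Clips whose measurement fails (for example, silent clips) are reported
#' and skipped; the run continues.
#'
#' @param clips List of `call_clip` or [waveform] objects.
#' @param manifest Optional data frame with one row per clip (metadata
#'   columns such as `bird_id`, `sex`, `age`, `variant`); if `NULL`,
#'   metadata is taken from each clip's `meta` element when present.
#' @param spec Feature specification (default: full registry).
#' @return A data frame: metadata columns first (including `call_id`),
#'   then one column per feature. The attribute `"failures"` holds a data
#'   frame of skipped clips (`call_id`, `message`).
#' @export
batch_features <- function(clips, manifest = NULL, spec = default_feature_spec()) {
  n <- length(clips)
  meta_list <- vector("list", n)
  feat_list <- vector("list", n)
  fail <- list()
  for (i in seq_len(n)) {
    clip <- clips[[i]]
    meta <- if (!is.null(manifest)) {
      as.list(manifest[i, , drop = FALSE])
    } else if (!is.null(clip$meta)) {
      clip$meta[c("bird_id", "sex", "age", "variant", "duration_ms")]
    } else list()
    meta$call_id <- if (!is.null(manifest) && "file" %in% names(manifest)) {
      manifest$file[i]
    } else sprintf("call_%04d", i)
    fv <- tryCatch(compute_features(compute_spectrogram(clip), spec),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(call_id = meta$call_id,
                                              message = conditionMessage(fv),
                                              stringsAsFactors = FALSE)
      next
    }
    meta_list[[i]] <- meta
    feat_list[[i]] <- fv
  }
  keep <- !vapply(feat_list, is.null, logical(1))
  if (!any(keep)) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = nrow(spec)))
    names(out) <- spec$name
    out <- cbind(data.frame(call_id = character(), bird_id = character(),
                            sex = character(), age = character(),
                            variant = character(), stringsAsFactors = FALSE),
                 out)
  } else {
    feats <- do.call(rbind, feat_list[keep])
    metas <- do.call(rbind, lapply(meta_list[keep], function(mm) {
      as.data.frame(mm[!vapply(mm, is.null, logical(1))],
                    stringsAsFactors = FALSE)
    }))
    front <- intersect(.meta_cols, names(metas))
    out <- cbind(metas[, front, drop = FALSE], as.data.frame(feats))
    rownames(out) <- NULL
  }
  attr(out, "failures") <- if (length(fail)) do.call(rbind, fail) else
    data.frame(call_id = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}

#' Remove highly correlated features
#'
#' Computes all pairwise Pearson correlations among feature columns and
#' eliminates redundancy: zero-variance columns are dropped first, then
#' feature pairs with `|r| >=` the threshold are visited in descending
#' `|r|`; for each pair whose members both still survive, the member with
#' the larger mean absolute correlation to all other surviving features is
#' removed (ties break toward keeping the earlier column). The report
#' makes every removal auditable.
#'
#' @param table A feature table (metadata columns are ignored and kept).
#' @param threshold Correlation threshold in (0, 1]; default 0.95.
#' @return A list with `table` (the pruned feature table) and `report` (a
#'   data frame with columns `removed`, `partner`, `abs_r`, `reason`).
#' @export
prune_correlated <- function(table, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  }
  feats <- feature_columns(table)
  if (length(feats) < 2L) stop("need at least 2 feature columns", call. = FALSE)
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  X <- as.matrix(table[, feats, drop = FALSE])
  report <- data.frame(removed = character(), partner = character(),
                       abs_r = numeric(), reason = character(),
                       stringsAsFactors = FALSE)
  const <- feats[apply(X, 2, function(v) stats::sd(v) < 1e-12)]
  for (cn in const) {
    report <- rbind(report, data.frame(removed = cn, partner = NA_character_,
                                       abs_r = NA_real_, reason = "constant",
                                       stringsAsFactors = FALSE))
  }
  alive <- setdiff(feats, const)
  if (length(alive) >= 2L) {
    R <- abs(stats::cor(X[, alive, drop = FALSE]))
    diag(R) <- 0
    pairs <- which(upper.tri(R) & R >= threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(R[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      dead <- character()
      for (k in seq_len(nrow(pairs))) {
        a <- alive[pairs[k, 1L]]
        b <- alive[pairs[k, 2L]]
        if (a %in% dead || b %in% dead) next
        live <- setdiff(alive, dead)
        mean_r <- function(v) mean(R[v, setdiff(live, v)])
        victim <- if (mean_r(a) > mean_r(b)) a else b # tie keeps earlier (a)
        dead <- c(dead, victim)
        report <- rbind(report, data.frame(
          removed = victim, partner = if (victim == a) b else a,
          abs_r = R[a, b], reason = "correlated", stringsAsFactors = FALSE))
      }
      alive <- setdiff(alive, dead)
    }
  }
  keep_cols <- c(intersect(names(table), .meta_cols), alive)
  list(table = table[, keep_cols, drop = FALSE], report = report)
}

#' Subsample a fixed number of calls per bird
#'
#' Drops birds with fewer than `min_calls` calls, then draws exactly
#' `n_per_bird` calls per surviving bird uniformly without replacement.
#'
#' @param table Feature table with a `bird_id` column.
#' @param n_per_bird Calls retained per bird (default 5).
#' @param min_calls Minimum calls for a bird to be eligible (default 5).
#' @param seed Integer seed for the draw.
#' @return The subsampled feature table.
#' @export
subsample_calls <- function(table, n_per_bird = 5L, min_calls = 5L, seed = 1L) {
  if (!"bird_id" %in% names(table)) stop("table lacks 'bird_id'", call. = FALSE)
  if (n_per_bird > min_calls) {
    stop("'n_per_bird' cannot exceed 'min_calls'", call. = FALSE)
  }
  set.seed(seed)
  counts <- table(table$bird_id)
  eligible <- names(counts)[counts >= min_calls]
  idx <- unlist(lapply(eligible, function(b) {
    rows <- which(table$bird_id == b)
    sort(sample(rows, n_per_bird))
  }))
  out <- table[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check that a subsample is representative of the full dataset
#'
#' Compares per-feature means between the subsampled calls and the
#' remaining (non-subsampled) calls with Welch two-sample t-tests, and
#' combines them into an omnibus permutation test whose statistic is the
#' mean squared t across features (group labels permuted). When the
#' subset equals the full table the comparison degenerates and every mean
#' difference is exactly zero.
#'
#' @param full Full feature table (must contain a `call_id` column).
#' @param subset Subsampled feature table (rows identified by `call_id`).
#' @param level Significance level for flagging (default 0.05).
#' @param n_perm Permutations for the omnibus test (default 199).
#' @param seed Seed for the permutation stream.
#' @return A list with `per_feature` (data frame: feature, mean difference,
#'   t, p, flagged), `omnibus_stat`, `omnibus_p`, and `pass` (logical:
#'   omnibus p above `level`).
#' @export
subset_consistency <- function(full, subset, level = 0.05, n_perm = 199L,
                               seed = 1L) {
  feats <- feature_columns(full)
  if (!setequal(feats, feature_columns(subset))) {
    stop(sprintf("feature columns differ: %s",
                 paste(union(setdiff(feats, feature_columns(subset)),
                             setdiff(feature_columns(subset), feats)),
                       collapse = ", ")), call. = FALSE)
  }
  feats <- intersect(feats, feature_columns(subset))
  in_subset <- full$call_id %in% subset$call_id
  if (all(in_subset)) {
    per <- data.frame(feature = feats, mean_diff = 0, t = 0, p = 1,
                      flagged = FALSE, stringsAsFactors = FALSE)
    return(list(per_feature = per, omnibus_stat = 0, omnibus_p = 1,
                pass = TRUE))
  }
  A <- as.matrix(full[in_subset, feats, drop = FALSE])
  B <- as.matrix(full[!in_subset, feats, drop = FALSE])
  welch <- function(a, b) {
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    if (va + vb <= 0) return(c(d = mean(a) - mean(b), t = 0, p = 1))
    tt <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    c(d = mean(a) - mean(b), t = tt, p = 2 * stats::pt(-abs(tt), df))
  }
  res <- t(vapply(feats, function(f) welch(A[, f], B[, f]), numeric(3)))
  per <- data.frame(feature = feats, mean_diff = res[, 1], t = res[, 2],
                    p = res[, 3], flagged = res[, 3] < level,
                    stringsAsFactors = FALSE)
  omnibus <- function(lab, X) {
    mean(vapply(seq_len(ncol(X)), function(j) {
      welch(X[lab, j], X[!lab, j])[["t"]]
    }, numeric(1))^2)
  }
  X <- rbind(A, B)
  lab0 <- c(rep(TRUE, nrow(A)), rep(FALSE, nrow(B)))
  obs <- omnibus(lab0, X)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) omnibus(sample(lab0), X),
                 numeric(1))
  p_omni <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(per_feature = per, omnibus_stat = obs, omnibus_p = p_omni,
       pass = p_omni > level)
}

#' Read or write a feature table as CSV
#'
#' The on-disk layout puts metadata columns first
#' (`call_id,bird_id,sex,age,variant`, then features). `read_feature_table`
#' also ingests externally produced per-call measurement tables via
#' `column_map`, a named character vector mapping this package's metadata
#' names to the file's column names (for example
#' `c(bird_id = "Band.ID", sex = "Sex")`); unmapped non-numeric columns
#' are dropped, all remaining numeric columns become features.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector renaming external
#'   metadata columns.
#' @return A feature table data frame.
#' @export
read_feature_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) {
        stop(sprintf("column '%s' (mapped to '%s') not found in '%s'",
                     src, std, path), call. = FALSE)
      }
      names(df)[names(df) == src] <- std
    }
  }
  if (!"call_id" %in% names(df)) df$call_id <- sprintf("call_%04d", seq_len(nrow(df)))
  numeric_cols <- vapply(df, is.numeric, logical(1))
  keep <- names(df) %in% .meta_cols | numeric_cols
  df <- df[, keep, drop = FALSE]
  front <- intersect(.meta_cols, names(df))
  df[, c(front, setdiff(names(df), front)), drop = FALSE]
}

#' @rdname read_feature_table
#' @param table A feature table.
#' @export
write_feature_table <- function(path, table) {
  front <- intersect(.meta_cols, names(table))
  utils::write.csv(table[, c(front, setdiff(names(table), front)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}
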