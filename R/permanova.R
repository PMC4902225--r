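#' Pairwise distance matrix from a feature table
#'
#' Computes call-by-call distances from the feature columns after optional
#' per-feature standardisation. Euclidean distance on z-scored features is
#' the package default for acoustic measurements, which mix units (ms, Hz,
#' bits) and can be negative (ruling out Bray-Curtis unless features are
#' shifted).
#'
#' @param table Feature table (or a plain numeric matrix).
#' @param metric `"euclidean"`, `"manhattan"` or `"bray"`.
#' @param standardize `"zscore"` (default) or `"none"`.
#' @return A square symmetric matrix with zero diagonal; row/column names
#'   are call ids when available.
#' @export
distance_matrix <- function(table, metric = c("euclidean", "manhattan", "bray"),
                            standardize = c("zscore", "none")) {
  metric <- match.arg(metric)
  standardize <- match.arg(standardize)
  if (is.data.frame(table)) {
    ids <- if ("call_id" %in% names(table)) table$call_id else rownames(table)
    X <- as.matrix(table[, feature_columns(table), drop = FALSE])
  } else {
    ids <- rownames(table)
    X <- as.matrix(table)
  }
  if (!is.numeric(X)) stop("feature columns must be numeric", call. = FALSE)
  if (standardize == "zscore") {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  D <- if (metric == "bray") {
    if (any(X < 0)) {
      stop("Bray-Curtis requires non-negative values; standardized acoustic features are signed -- use euclidean or manhattan",
           call. = FALSE)
    }
    as.matrix(vegan::vegdist(X, method = "bray"))
  } else {
    as.matrix(stats::dist(X, method = metric))
  }
  dimnames(D) <- list(ids, ids)
  D
}

.check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 || any(diag(d) > 1e-8)) {
    stop("'dist' must be a symmetric matrix with zero diagonal", call. = FALSE)
  }
  d
}

# sums of squares for a grouping on a squared-distance matrix:
# SS_total = (1/n) sum_{i<j} d2_ij ; SS_within = sum_g (1/n_g) sum_{i<j in g} d2_ij
.ss_within <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' Permutational MANOVA for a single factor
#'
#' Distance-based one-way analysis of variance: partitions the total sum
#' of squared inter-point distances into among- and within-group parts and
#' tests the pseudo-F statistic by permuting group labels. For univariate
#' Euclidean input the pseudo-F equals the classical one-way ANOVA F.
#' The p-value uses the `(1 + exceedances) / (1 + n_perm)` estimator, so
#' its minimum attainable value is `1/(n_perm + 1)`.
#'
#' @param dist Square symmetric distance matrix (zero diagonal).
#' @param factor_labels Group label per row of `dist` (>= 2 levels, each
#'   with >= 2 observations).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `"permanova_result"`: a one-term table of
#'   df, sums of squares, pseudo-F, R-squared and permutation p.
#' @export
permanova_single <- function(dist, factor_labels, n_perm = 999L, seed = 1L) {
  d <- .check_dist(dist)
  n <- nrow(d)
  groups <- as.character(factor_labels)
  if (length(groups) != n) stop("label length must match 'dist'", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 factor levels", call. = FALSE)
  if (any(tab < 2L)) {
    stop(sprintf("every group needs >= 2 observations (group '%s' has %d)",
                 names(tab)[which.min(tab)], min(tab)), call. = FALSE)
  }
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  d2 <- d^2
  a <- length(tab)
  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(g) {
    ssw <- .ss_within(d2, g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ss_within <- .ss_within(d2, groups)
  ss_factor <- ss_total - ss_within
  f_obs <- ((ss_factor) / (a - 1)) / (ss_within / (n - a))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(sample(groups)) >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  terms <- data.frame(
    term = c("factor", "residual", "total"),
    df = c(a - 1L, n - a, n - 1L),
    sum_of_squares = c(ss_factor, ss_within, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    r_squared = c(ss_factor / ss_total, ss_within / ss_total, 1),
    p_value = c(p, NA, NA)
  )
  structure(list(terms = terms, n_permutations = n_perm, seed = seed, n = n),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("Permutational MANOVA (%d permutations, seed %d)\n",
              x$n_permutations, x$seed))
  print(format(x$terms, digits = 4), row.names = FALSE)
  invisible(x)
}

# Gower-centred inner-product matrix: G = -1/2 J A J with A = d^2
.gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a)
  a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a)
}

# projection matrix onto the column space of X
.proj <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

#' Permutational MANOVA with multiple terms and nested individuals
#'
#' Fits a sequential (Type I) distance-based linear model: squared
#' distances are Gower-centred into an inner-product matrix G, each
#' term's sum of squares is the increment in `tr(H G)` as the term's
#' columns join the model, and each pseudo-F is the term mean square over
#' the residual mean square. Permutation honours the sampling design: for
#' factors that are constant within an individual (for example sex or age
#' when each bird has one value), whole individuals are permuted as
#' blocks, so repeated calls from one bird are never treated as
#' independent; call-level factors are permuted freely.
#'
#' @param dist Square symmetric distance matrix.
#' @param design Named list of factor label vectors (one label per row of
#'   `dist`), e.g. `list(sex = ..., age = ..., variant = ...)`.
#' @param interactions Character vector of `"a:b"` interaction terms
#'   (fitted after the main effects, in the given order).
#' @param nest_in Optional vector of individual (bird) ids per row; when
#'   supplied, factors constant within individuals use block permutation.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `"permanova_result"` with one row per term plus residual and
#'   total; each term records its permutation scheme.
#' @export
permanova_terms <- function(dist, design, interactions = character(),
                            nest_in = NULL, n_perm = 999L, seed = 1L) {
  d <- .check_dist(dist)
  n <- nrow(d)
  stopifnot(is.list(design), length(design) >= 1L)
  design <- lapply(design, as.character)
  if (any(lengths(design) != n)) {
    stop("every design factor must have one label per row of 'dist'",
         call. = FALSE)
  }
  G <- .gower_center(d)
  ss_total <- sum(diag(G))

  term_names <- c(names(design), interactions)
  term_cols <- function(design_now) {
    lapply(term_names, function(tn) {
      if (grepl(":", tn, fixed = TRUE)) {
        parts <- strsplit(tn, ":", fixed = TRUE)[[1L]]
        f <- interaction(design_now[[parts[1L]]], design_now[[parts[2L]]],
                         drop = TRUE)
      } else {
        f <- factor(design_now[[tn]])
      }
      stats::model.matrix(~ f)[, -1L, drop = FALSE]
    })
  }

  fit <- function(design_now) {
    cols <- term_cols(design_now)
    X <- matrix(1, n, 1L)
    tr_prev <- sum(.proj(X) * G) # tr(HG) for symmetric G
    df_prev <- 0L
    ss <- numeric(length(term_names))
    df <- integer(length(term_names))
    for (k in seq_along(term_names)) {
      X <- cbind(X, cols[[k]])
      qrX <- qr(X)
      H <- tcrossprod(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE])
      tr_now <- sum(H * G)
      df_now <- qrX$rank - 1L
      ss[k] <- tr_now - tr_prev
      df[k] <- df_now - df_prev
      tr_prev <- tr_now
      df_prev <- df_now
    }
    if (any(df == 0L)) {
      stop(sprintf("term '%s' is aliased (adds no degrees of freedom) given the preceding terms",
                   term_names[which(df == 0L)[1L]]), call. = FALSE)
    }
    ss_resid <- ss_total - sum(ss)
    df_resid <- n - 1L - sum(df)
    f <- (ss / df) / (ss_resid / df_resid)
    list(ss = ss, df = df, ss_resid = ss_resid, df_resid = df_resid, f = f)
  }

  obs <- fit(design)

  # permutation scheme per term: block (whole-individual) when every
  # factor in the term is constant within individuals, free otherwise
  is_unit_level <- function(tn) {
    if (is.null(nest_in)) return(FALSE)
    parts <- strsplit(tn, ":", fixed = TRUE)[[1L]]
    all(vapply(parts, function(p) {
      all(tapply(design[[p]], nest_in, function(v) length(unique(v)) == 1L))
    }, logical(1)))
  }
  scheme <- vapply(term_names, is_unit_level, logical(1))

  permute_design <- function(block) {
    if (block) {
      units <- unique(nest_in)
      new_unit <- stats::setNames(sample(units), units)
      # reassign each individual's unit-level labels to a permuted individual
      idx_of_unit <- lapply(units, function(u) which(nest_in == u)[1L])
      names(idx_of_unit) <- units
      lapply(design, function(v) {
        if (all(tapply(v, nest_in, function(x) length(unique(x)) == 1L))) {
          v_new <- v
          for (u in units) {
            v_new[nest_in == u] <- v[idx_of_unit[[new_unit[[u]]]]]
          }
          v_new
        } else v[sample(length(v))]
      })
    } else {
      perm <- sample(n)
      lapply(design, function(v) v[perm])
    }
  }

  set.seed(seed)
  exceed <- matrix(0L, nrow = length(term_names), ncol = 1L)
  need_free <- any(!scheme)
  need_block <- any(scheme)
  for (i in seq_len(n_perm)) {
    f_free <- if (need_free) tryCatch(fit(permute_design(FALSE))$f,
                                      error = function(e) rep(NA_real_, length(term_names)))
    f_block <- if (need_block) tryCatch(fit(permute_design(TRUE))$f,
                                        error = function(e) rep(NA_real_, length(term_names)))
    for (k in seq_along(term_names)) {
      fk <- if (scheme[k]) f_block[k] else f_free[k]
      if (!is.na(fk) && fk >= obs$f[k] - 1e-12) exceed[k] <- exceed[k] + 1L
    }
  }
  p <- (1 + exceed[, 1L]) / (1 + n_perm)

  terms <- data.frame(
    term = c(term_names, "residual", "total"),
    df = c(obs$df, obs$df_resid, n - 1L),
    sum_of_squares = c(obs$ss, obs$ss_resid, ss_total),
    pseudo_F = c(obs$f, NA, NA),
    r_squared = c(obs$ss / ss_total, obs$ss_resid / ss_total, 1),
    p_value = c(p, NA, NA),
    permutation = c(ifelse(scheme, "individual-block", "free"), NA, NA)
  )
  structure(list(terms = terms, n_permutations = n_perm, seed = seed, n = n,
                 ss_order = "sequential"),
            class = "permanova_result")
}
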