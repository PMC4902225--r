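#' Unsupervised random-forest call-similarity matrix
#'
#' Builds a pairwise call-similarity matrix by the synthetic-contrast
#' unsupervised random-forest technique: a contrast set of the same size
#' is drawn by sampling each feature independently from its empirical
#' marginal (destroying the joint structure), a random-forest classifier
#' is trained to separate real calls from the contrast set with default
#' hyperparameters (`mtry = floor(sqrt(p))`, unlimited depth), and the
#' similarity of calls i and j is their proximity: the fraction of trees
#' in which they land in the same terminal node (counted over all trees).
#'
#' @param table Feature table; metadata columns are carried into the
#'   result's labels, feature columns feed the forest.
#' @param n_trees Number of trees (default 4999).
#' @param seed Integer seed (controls both the contrast sample and the
#'   forest).
#' @param oob_prox Count proximities over out-of-bag trees only
#'   (default `FALSE`: all trees).
#' @return An object of class `"similarity_matrix"`: a list with `values`
#'   (n x n symmetric matrix in \[0,1\], unit diagonal), `call_ids` and
#'   `bird_ids`.
#' @export
unsupervised_proximity <- function(table, n_trees = 4999L, seed = 1L,
                                   oob_prox = FALSE) {
  feats <- feature_columns(table)
  X <- table[, feats, drop = FALSE]
  not_num <- feats[!vapply(X, is.numeric, logical(1))]
  if (length(not_num)) {
    stop(sprintf("non-numeric feature column(s): %s",
                 paste(not_num, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 calls", call. = FALSE)
  set.seed(seed)
  contrast <- as.data.frame(lapply(X, function(col) sample(col, n, replace = TRUE)))
  names(contrast) <- feats
  dat <- rbind(X, contrast)
  y <- factor(rep(c("real", "synthetic"), each = n))
  rf <- randomForest::randomForest(x = dat, y = y, ntree = n_trees,
                                   proximity = TRUE, oob.prox = oob_prox)
  prox <- rf$proximity[seq_len(n), seq_len(n), drop = FALSE]
  prox <- (prox + t(prox)) / 2
  diag(prox) <- 1
  call_ids <- if ("call_id" %in% names(table)) table$call_id else
    sprintf("call_%04d", seq_len(n))
  dimnames(prox) <- list(call_ids, call_ids)
  structure(list(values = prox, call_ids = call_ids,
                 bird_ids = if ("bird_id" %in% names(table)) table$bird_id else NULL),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity matrix: %d calls%s>\n", length(x$call_ids),
              if (!is.null(x$bird_ids))
                sprintf(", %d birds", length(unique(x$bird_ids))) else ""))
  invisible(x)
}

#' Within- versus between-individual call similarity
#'
#' For each bird, averages the pairwise similarities among its own calls
#' (`choose(k, 2)` values for k calls) into a within-individual mean, and
#' the similarities between its calls and every other bird's calls into a
#' between-individual mean. The two per-bird samples are compared with a
#' two-sample t-test (Welch by default; the pooled-variance test is also
#' reported).
#'
#' @param sim A `similarity_matrix`, or a square similarity matrix plus
#'   `bird_ids`.
#' @param bird_ids Bird label per call (taken from `sim` when available).
#' @return A list of class `"within_between_result"`: per-bird
#'   `within_means` and `between_means`, contributing pair counts,
#'   `t_statistic`, `df`, `p_value` (Welch) and `t_pooled`, `df_pooled`,
#'   `p_pooled`.
#' @export
within_between_similarity <- function(sim, bird_ids = NULL) {
  if (inherits(sim, "similarity_matrix")) {
    values <- sim$values
    if (is.null(bird_ids)) bird_ids <- sim$bird_ids
  } else {
    values <- as.matrix(sim)
  }
  if (is.null(bird_ids)) stop("bird ids are required", call. = FALSE)
  n <- nrow(values)
  stopifnot(length(bird_ids) == n)
  birds <- unique(bird_ids)
  if (length(birds) < 2L) stop("need at least 2 birds", call. = FALSE)
  singletons <- birds[vapply(birds, function(b) sum(bird_ids == b) < 2L,
                             logical(1))]
  if (length(singletons)) {
    warning(sprintf("bird(s) with a single call excluded from within-means: %s",
                    paste(singletons, collapse = ", ")))
  }
  within <- c()
  between <- c()
  n_within <- c()
  n_between <- c()
  for (b in birds) {
    idx <- which(bird_ids == b)
    oth <- which(bird_ids != b)
    if (length(idx) >= 2L) {
      block <- values[idx, idx]
      within[b] <- mean(block[upper.tri(block)])
      n_within[b] <- choose(length(idx), 2)
    }
    between[b] <- mean(values[idx, oth, drop = FALSE])
    n_between[b] <- length(idx) * length(oth)
  }
  b2 <- between[names(within)]
  if (stats::sd(within) < 1e-12 && stats::sd(b2) < 1e-12) {
    # degenerate variances: the t-test is determined by the mean difference
    same <- abs(mean(within) - mean(b2)) < 1e-12
    null_t <- list(statistic = c(t = if (same) 0 else
                                   Inf * sign(mean(within) - mean(b2))),
                   parameter = c(df = NA_real_),
                   p.value = if (same) 1 else 0)
    tw <- tp <- null_t
  } else {
    tw <- stats::t.test(within, b2, var.equal = FALSE)
    tp <- stats::t.test(within, b2, var.equal = TRUE)
  }
  structure(list(
    within_means = within, between_means = between,
    n_within_pairs = n_within, n_between_entries = n_between,
    t_statistic = unname(tw$statistic), df = unname(tw$parameter),
    p_value = tw$p.value,
    t_pooled = unname(tp$statistic), df_pooled = unname(tp$parameter),
    p_pooled = tp$p.value
  ), class = "within_between_result")
}

#' @export
print.within_between_result <- function(x, ...) {
  cat(sprintf(
    "Within- vs between-individual similarity (%d birds)\n  mean within %.3f, mean between %.3f\n  Welch t = %.2f (df %.1f), p = %.3g; pooled t = %.2f (df %d)\n",
    length(x$between_means), mean(x$within_means), mean(x$between_means),
    x$t_statistic, x$df, x$p_value, x$t_pooled, round(x$df_pooled)))
  invisible(x)
}

#' Supervised random-forest feature importance
#'
#' Trains a random forest supervised by a factor (sex or call variant)
#' and returns both importance criteria: mean decrease in accuracy
#' (permutation importance) and mean decrease in Gini (impurity
#' importance).
#'
#' @param table Feature table.
#' @param labels Factor to supervise on (one label per row).
#' @param n_trees Number of trees (default 4999).
#' @param seed Integer seed.
#' @return A list of class `"importance_ranking"` with `importance` (data
#'   frame: feature, mean_decrease_accuracy, mean_decrease_gini),
#'   `by_accuracy` and `by_gini` (feature names in rank order).
#' @export
supervised_importance <- function(table, labels, n_trees = 4999L, seed = 1L) {
  feats <- feature_columns(table)
  X <- table[, feats, drop = FALSE]
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels must have at least 2 classes", call. = FALSE)
  if (any(table(y) < 2L)) stop("every class needs at least 2 rows", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
                    mean_decrease_gini = imp[, "MeanDecreaseGini"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(
    importance = out,
    by_accuracy = out$feature[order(out$mean_decrease_accuracy, decreasing = TRUE)],
    by_gini = out$feature[order(out$mean_decrease_gini, decreasing = TRUE)]
  ), class = "importance_ranking")
}

#' Convert a similarity matrix to a distance matrix
#'
#' `d(i, j) = 1 - similarity(i, j)`, with an exactly zero diagonal.
#'
#' @param sim A `similarity_matrix` or square numeric matrix in \[0, 1\].
#' @return A square distance matrix.
#' @export
similarity_to_distance <- function(sim) {
  values <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  d <- 1 - values
  diag(d) <- 0
  d
}

#' Persist or load a similarity matrix as CSV
#'
#' The CSV holds the square matrix with call ids as header and first
#' column.
#'
#' @param path CSV path.
#' @param sim A `similarity_matrix`.
#' @return `read_similarity_matrix` returns a `similarity_matrix` (without
#'   bird ids); `write_similarity_matrix` returns `path` invisibly.
#' @export
write_similarity_matrix <- function(path, sim) {
  df <- data.frame(call_id = sim$call_ids, sim$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, call_ids = ids, bird_ids = NULL),
            class = "similarity_matrix")
}

#' Plot a call-similarity matrix ordered by individual
#'
#' Renders the matrix as a heatmap with calls grouped by bird, darker
#' cells meaning more similar, and grid lines separating individuals.
#'
#' @param sim A `similarity_matrix` with bird ids.
#' @param ... Passed to [graphics::image].
#' @return Invisibly, the row order used.
#' @export
plot_similarity_heatmap <- function(sim, ...) {
  ord <- order(sim$bird_ids)
  v <- sim$values[ord, ord]
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, ]),
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = "call", ylab = "call", axes = FALSE, ...)
  breaks <- cumsum(table(sim$bird_ids[ord])[unique(sim$bird_ids[ord])])
  graphics::abline(v = breaks + 0.5, h = n - breaks + 0.5, col = "grey30",
                   lwd = 0.5)
  graphics::box()
  invisible(ord)
}
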