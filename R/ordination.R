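#' Principal coordinates analysis
#'
#' Metric embedding of a distance matrix: the squared distances are
#' Gower double-centred and eigendecomposed; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Negative
#' eigenvalues, which arise for non-Euclidean distances, are excluded
#' from the coordinates but reported.
#'
#' @param dist Square symmetric distance matrix.
#' @param k Number of retained axes (default 2).
#' @return A list of class `"ordination"` with `coordinates` (n x k),
#'   `eigenvalues` (all, descending), `method = "pcoa"`.
#' @export
pcoa <- function(dist, k = 2L) {
  d <- .check_dist(dist)
  n <- nrow(d)
  if (n < k + 1L) stop("need at least k + 1 points", call. = FALSE)
  G <- .gower_center(d)
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- sum(eig$values > max(eig$values) * 1e-10)
  if (k > pos) {
    stop(sprintf("only %d positive eigenvalue(s); cannot embed in %d dimensions",
                 pos, k), call. = FALSE)
  }
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 method = "pcoa"),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Rank-preserving embedding minimising Kruskal stress-1 by monotone
#' regression, taking the best of several seeded random restarts (the
#' engine is `vegan::monoMDS` via `metaMDS`).
#'
#' @param dist Square symmetric distance matrix.
#' @param k Embedding dimension (default 2).
#' @param restarts Random restarts (default 20).
#' @param seed Integer seed; fixes the embedding.
#' @return A list of class `"ordination"` with `coordinates`, `stress`
#'   (in \[0,1\]), `method = "nmds"`, `seed`.
#' @export
nmds <- function(dist, k = 2L, restarts = 20L, seed = 1L) {
  d <- .check_dist(dist)
  if (nrow(d) < 4L) stop("need at least 4 points", call. = FALSE)
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, try = restarts,
                        trymax = restarts, trace = FALSE,
                        autotransform = FALSE, wascores = FALSE)
  coords <- fit$points
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords, stress = fit$stress, method = "nmds",
                 seed = seed, converged = isTRUE(fit$converged)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<%s ordination: %d points, %d axes%s>\n", toupper(x$method),
              nrow(x$coordinates), ncol(x$coordinates),
              if (x$method == "nmds") sprintf(", stress %.4f", x$stress)
              else sprintf(", first eigenvalues %s",
                           paste(signif(utils::head(x$eigenvalues, 2), 3),
                                 collapse = ", "))))
  invisible(x)
}

#' Group confidence ellipses on an ordination
#'
#' One ellipse per group, describing the uncertainty of the group's
#' centroid: the covariance of the group's axis scores divided by the
#' group size (the standard error of the mean), scaled by the chi-square
#' quantile with 2 degrees of freedom at the requested confidence level.
#' Singleton groups get a centroid only; groups of identical points are
#' flagged as degenerate.
#'
#' @param ordination An `"ordination"` (first two axes are used).
#' @param labels Group label per point.
#' @param level Confidence level in (0, 1), default 0.99.
#' @return A list of `group_ellipse` entries: `group`, `center`,
#'   `semi_axes`, `angle` (radians, orientation of the major axis),
#'   `n`, `degenerate`.
#' @export
group_ellipses <- function(ordination, labels, level = 0.99) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  xy <- ordination$coordinates[, 1:2, drop = FALSE]
  stopifnot(nrow(xy) == length(labels))
  q <- stats::qchisq(level, df = 2)
  lapply(split(seq_along(labels), labels), function(idx) {
    pts <- xy[idx, , drop = FALSE]
    center <- colMeans(pts)
    if (length(idx) < 2L) {
      return(structure(list(group = labels[idx[1L]], center = center,
                            semi_axes = NULL, angle = NA_real_,
                            n = 1L, degenerate = TRUE),
                       class = "group_ellipse"))
    }
    S <- stats::cov(pts) / length(idx) # SE of the centroid
    eig <- eigen(S, symmetric = TRUE)
    semi <- sqrt(pmax(eig$values, 0) * q)
    structure(list(group = labels[idx[1L]], center = center,
                   semi_axes = semi,
                   angle = atan2(eig$vectors[2L, 1L], eig$vectors[1L, 1L]),
                   n = length(idx), degenerate = all(semi < 1e-12)),
              class = "group_ellipse")
  })
}

#' Plot an ordination with group centroids and confidence ellipses
#'
#' @param ordination An `"ordination"`.
#' @param labels Group label per point.
#' @param level Ellipse confidence level (default 0.99).
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, the list of [group_ellipses].
#' @export
plot_ordination <- function(ordination, labels, level = 0.99, ...) {
  xy <- ordination$coordinates[, 1:2, drop = FALSE]
  groups <- factor(labels)
  cols <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  graphics::plot(xy, col = cols[groups], pch = 19, cex = 0.6,
                 xlab = colnames(xy)[1], ylab = colnames(xy)[2], ...)
  ells <- group_ellipses(ordination, labels, level = level)
  th <- seq(0, 2 * pi, length.out = 120)
  for (el in ells) {
    gi <- which(levels(groups) == el$group)
    graphics::points(el$center[1], el$center[2], pch = 3, cex = 1.4,
                     col = cols[gi], lwd = 2)
    if (!is.null(el$semi_axes) && !el$degenerate) {
      rot <- matrix(c(cos(el$angle), sin(el$angle),
                      -sin(el$angle), cos(el$angle)), 2L)
      pts <- t(rot %*% rbind(el$semi_axes[1] * cos(th),
                             el$semi_axes[2] * sin(th))) +
        matrix(el$center, length(th), 2L, byrow = TRUE)
      graphics::lines(pts, col = cols[gi])
    }
  }
  graphics::legend("topright", legend = levels(groups), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(ells)
}
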