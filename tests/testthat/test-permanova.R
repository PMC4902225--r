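test_that("distance matrices match hand arithmetic and standardise correctly", {
  pts <- matrix(c(0, 0, 3, 0, 3, 4), ncol = 2, byrow = TRUE)
  rownames(pts) <- c("p1", "p2", "p3")
  D <- distance_matrix(pts, standardize = "none")
  expect_equal(D["p1", "p2"], 3)
  expect_equal(D["p2", "p3"], 4)
  expect_equal(D["p1", "p3"], 5)
  expect_equal(diag(D), c(p1 = 0, p2 = 0, p3 = 0))
  # identical rows are at distance zero
  D2 <- distance_matrix(rbind(pts, p4 = pts[3, ]), standardize = "none")
  expect_equal(D2["p3", "p4"], 0)
  # z-scoring gives unit-variance columns before distances
  set.seed(1)
  X <- matrix(rnorm(50, mean = 7, sd = 3), 25, 2)
  Dz <- distance_matrix(X, standardize = "zscore")
  expect_equal(Dz, as.matrix(dist(scale(X))), ignore_attr = TRUE)
  expect_error(distance_matrix(matrix(rnorm(20), 10), metric = "bray"),
               "non-negative")
})

test_that("pseudo-F reduces to the classical ANOVA F on univariate data", {
  set.seed(5)
  y <- rnorm(24) + rep(c(0, 0.8, 1.6), each = 8)
  g <- rep(c("a", "b", "c"), each = 8)
  D <- as.matrix(dist(y))
  res <- permanova_single(D, g, n_perm = 99, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$terms$pseudo_F[1], f_aov, tolerance = 1e-9)
  # SS decomposition conserved
  ss <- res$terms$sum_of_squares
  expect_equal(ss[1] + ss[2], ss[3], tolerance = 1e-9)
})

test_that("n = 6 toy data matches the exhaustive-permutation oracle", {
  set.seed(11)
  X <- matrix(rnorm(12), 6, 2) + c(0, 0, 0, 2, 2, 2)
  g <- c("a", "a", "a", "b", "b", "b")
  D <- as.matrix(dist(X))
  res <- permanova_single(D, g, n_perm = 999, seed = 2)
  oracle <- coord_f(X, g)
  expect_equal(res$terms$pseudo_F[1], oracle$F, tolerance = 1e-9)
  expect_equal(res$terms$sum_of_squares[3], oracle$ss_total, tolerance = 1e-9)
  # exact p over all 20 distinct assignments of 3 + 3 labels
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    gg <- rep("b", 6)
    gg[idx] <- "a"
    coord_f(X, gg)$F
  })
  p_exact <- mean(f_all >= oracle$F - 1e-12)
  expect_lt(abs(res$terms$p_value[1] - p_exact), 0.07)
})

test_that("the minimum attainable p-value is 1/(n_perm + 1)", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2) + rep(c(0, 10), each = 10) # huge effect
  g <- rep(c("a", "b"), each = 10)
  res <- permanova_single(as.matrix(dist(X)), g, n_perm = 999, seed = 4)
  expect_equal(res$terms$p_value[1], 1 / 1000)
})

test_that("pseudo-F is invariant to consistent reordering of calls", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), 10)
  D <- as.matrix(dist(X))
  perm <- sample(20)
  r1 <- permanova_single(D, g, n_perm = 49, seed = 1)
  r2 <- permanova_single(D[perm, perm], g[perm], n_perm = 49, seed = 1)
  expect_equal(r1$terms$pseudo_F[1], r2$terms$pseudo_F[1], tolerance = 1e-9)
})

test_that("group-size and argument validation errors are raised", {
  D <- as.matrix(dist(rnorm(5)))
  expect_error(permanova_single(D, c("a", "a", "a", "a", "b")), ">= 2")
  expect_error(permanova_single(D, rep("a", 5)), "levels")
  expect_error(permanova_single(D, c("a", "a", "a", "b", "b"), n_perm = 0),
               "n_perm")
  expect_error(permanova_single(D[1:4, 1:5], rep(c("a", "b"), 2)), "symmetric")
})

test_that("multi-term fit agrees with the single-factor path and with vegan", {
  set.seed(42)
  X <- matrix(rnorm(30 * 4), 30)
  f1 <- rep(c("a", "b"), 15)
  f2 <- rep(c("x", "y", "z"), each = 10)
  D <- as.matrix(dist(X))
  single <- permanova_single(D, f1, n_perm = 99, seed = 1)
  multi1 <- permanova_terms(D, list(f1 = f1), n_perm = 99, seed = 1)
  expect_equal(multi1$terms$pseudo_F[1], single$terms$pseudo_F[1],
               tolerance = 1e-9)
  expect_equal(multi1$terms$sum_of_squares[1:2],
               single$terms$sum_of_squares[1:2], tolerance = 1e-9)
  # independent cross-check of sequential SS against vegan's adonis2
  multi <- permanova_terms(D, list(f1 = f1, f2 = f2),
                           interactions = "f1:f2", n_perm = 99, seed = 1)
  veg <- vegan::adonis2(dist(X) ~ f1 * f2,
                        data = data.frame(f1 = f1, f2 = f2),
                        permutations = 99, by = "terms")
  expect_equal(multi$terms$sum_of_squares[1:3], veg$SumOfSqs[1:3],
               tolerance = 1e-6)
  expect_equal(multi$terms$pseudo_F[1:3], veg$F[1:3], tolerance = 1e-6)
  expect_equal(multi$terms$r_squared[1:3], veg$R2[1:3], tolerance = 1e-6)
  # SS decomposition conserved (3 terms + residual = total)
  ss <- multi$terms$sum_of_squares
  expect_equal(sum(ss[1:4]), ss[5], tolerance = 1e-9)
})

test_that("aliased terms are detected and named", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  f1 <- rep(c("a", "b"), each = 10)
  dup <- rep(c("u", "v"), each = 10) # one-to-one with f1
  expect_error(permanova_terms(as.matrix(dist(X)),
                               list(f1 = f1, dup = dup), n_perm = 9),
               "dup")
})

test_that("block permutation controls level under bird random effects", {
  # data with strong per-bird effects and a null bird-level factor:
  # free permutation of calls is pseudo-replicated, block permutation is not
  n_rep <- 40
  rej_free <- 0
  rej_block <- 0
  for (i in seq_len(n_rep)) {
    tab <- gaussian_table(12, 3, 4, seed = 600 + i,
                          bird_shift = rnorm(12, sd = 3))
    D <- distance_matrix(tab)
    age <- tab$age # constant within bird by construction
    p_free <- permanova_terms(D, list(age = age), n_perm = 59,
                              seed = i)$terms$p_value[1]
    p_block <- permanova_terms(D, list(age = age), nest_in = tab$bird_id,
                               n_perm = 59, seed = i)$terms$p_value[1]
    rej_free <- rej_free + (p_free <= 0.05)
    rej_block <- rej_block + (p_block <= 0.05)
  }
  expect_lte(rej_block, 7)        # near-nominal level
  expect_gt(rej_free, rej_block)  # free permutation inflates rejections
  expect_gte(rej_free, 10)        # grossly so
})

test_that("a strong multivariate sex shift is detected with high power", {
  detected <- 0
  for (i in 1:10) {
    set.seed(700 + i)
    X <- matrix(rnorm(180 * 84), 180)
    sex <- rep(c("M", "F"), each = 90)
    X[sex == "M", 1:10] <- X[sex == "M", 1:10] + 1.5
    res <- permanova_single(as.matrix(dist(X)), sex, n_perm = 99,
                            seed = i)
    detected <- detected + (res$terms$p_value[1] <= 0.05)
  }
  expect_gte(detected, 10 * 0.95)
})
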