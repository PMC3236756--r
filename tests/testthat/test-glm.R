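test_that("seed self- and orthogonal correlations behave as Fisher z", {
  g <- tiny_grid(c(2, 2, 1))
  tt <- seq_len(40)
  s <- sin(2 * pi * tt / 8)
  co <- cos(2 * pi * tt / 8) # orthogonal over full periods
  dat <- cbind(s, s, co, rnorm(40))
  b <- bold4d(dat, g, 2)
  seed_mask <- array(c(TRUE, FALSE, FALSE, FALSE), g$shape)
  z <- subject_icn_map(b, seed_mask)
  expect_equal(z[1, 1, 1], atanh(1 - 1e-7))
  expect_equal(z[2, 1, 1], atanh(1 - 1e-7))
  expect_lt(abs(z[1, 2, 1]), 1e-10)
})

test_that("a voxel equal to a nuisance regressor is silenced by residualization", {
  set.seed(41)
  g <- tiny_grid(c(2, 2, 1))
  glob <- rnorm(60)
  dat <- cbind(rnorm(60), glob, rnorm(60), rnorm(60))
  b <- bold4d(dat, g, 2)
  seed_mask <- array(c(TRUE, FALSE, FALSE, FALSE), g$shape)
  z <- subject_icn_map(b, seed_mask, nuisance = cbind(global = glob))
  expect_lt(abs(z[2, 1, 1]), 1e-8)
  # collinear nuisance columns are a named error
  expect_error(
    subject_icn_map(b, seed_mask, nuisance = cbind(a = glob, b = 2 * glob)),
    "collinear")
})

test_that("multi-seed and single-seed ICN maps agree", {
  set.seed(42)
  g <- tiny_grid(c(3, 3, 1))
  b <- bold4d(matrix(rnorm(50 * 9), 50, 9), g, 2)
  m1 <- array(FALSE, g$shape); m1[1, 1, 1] <- TRUE
  m2 <- array(FALSE, g$shape); m2[2:3, 2, 1] <- TRUE
  nuis <- cbind(rnorm(50))
  zz <- subject_icn_maps(b, list(m1, m2), nuis)
  expect_equal(zz[[1]], subject_icn_map(b, m1, nuis))
  expect_equal(zz[[2]], subject_icn_map(b, m2, nuis))
})

test_that("group one-sample t matches the textbook formula", {
  set.seed(43)
  g <- tiny_grid(c(5, 5, 2))
  n <- 30
  Y <- matrix(rnorm(n * prod(g$shape)), n)
  sm <- group_onesample_t(Y, g)
  expect_equal(sm$df, n - 1L)
  oracle <- apply(Y, 2, function(y) mean(y) / (sd(y) / sqrt(n)))
  expect_equal(as.vector(sm$t), oracle, tolerance = 1e-10)
})

test_that("identical maps with zero residual variance are capped, not NaN", {
  g <- tiny_grid(c(2, 2, 1))
  Y <- matrix(3, 10, 4)
  sm <- group_onesample_t(Y, g)
  expect_true(all(is.finite(sm$t)))
  expect_true(all(sm$t > 1e6))
  expect_true(all(sm$degenerate))
})

test_that("mean-centred covariates leave the intercept at the adjusted mean", {
  set.seed(44)
  g <- tiny_grid(c(1, 1, 1))
  n <- 40
  y <- rnorm(n, mean = 1)
  covar <- cbind(rnorm(n) + 0.5 * y)
  fit_plain <- group_onesample_t(matrix(y), g)
  fit_cov <- group_onesample_t(matrix(y), g, covariates = covar)
  # centring makes the intercept estimate the plain mean in both fits,
  # matching an explicit least-squares oracle; only df and SE change
  ls <- lm(y ~ scale(covar, scale = FALSE))
  expect_equal(fit_cov$df, n - 2L)
  expect_equal(fit_cov$t[1, 1, 1],
               summary(ls)$coefficients[1, "t value"], tolerance = 1e-10)
  expect_equal(fit_plain$df, n - 1L)
  # a covariate that IS the map leaves no residual variance: flagged
  t_exact <- group_onesample_t(matrix(y), g, covariates = cbind(y))
  expect_true(t_exact$degenerate[1, 1, 1])
})

test_that("across-subject covariance t has the closed form without covariates", {
  set.seed(45)
  g <- tiny_grid(c(5, 5, 2))
  n <- 20
  Y <- matrix(rnorm(n * prod(g$shape)), n)
  seedv <- rnorm(n)
  cm <- cohort_matrix(Y, g)
  sm <- crosssubject_covariance_map(cm, seedv)
  expect_equal(sm$df, n - 2L)
  r <- as.vector(cor(seedv, Y))
  expect_equal(as.vector(sm$t), r * sqrt(n - 2) / sqrt(1 - r^2),
               tolerance = 1e-8)
  # exactly orthogonal voxel -> t = 0
  v <- residuals(lm(rnorm(n) ~ seedv))
  Y2 <- cbind(v, Y[, -1])
  t0 <- crosssubject_covariance_map(cohort_matrix(Y2, g), seedv)$t[1]
  expect_lt(abs(t0), 1e-10)
})

test_that("the GLM engine equals the residualize-then-correlate oracle", {
  set.seed(46)
  n <- 50; V <- 200
  g <- tiny_grid(c(10, 5, 4))
  Y <- matrix(rnorm(n * V), n)
  seedv <- rnorm(n)
  covs <- matrix(rnorm(n * 3), n)
  sm <- crosssubject_covariance_map(cohort_matrix(Y, g), seedv, covs)
  expect_equal(sm$df, n - 2L - 3L)
  expect_lt(max(abs(as.vector(sm$t) - covariance_t_oracle(Y, seedv, covs))),
            1e-8)
})

test_that("t maps respect sign and permutation symmetries", {
  set.seed(47)
  n <- 25; V <- 60
  g <- tiny_grid(c(5, 4, 3))
  Y <- matrix(rnorm(n * V), n)
  seedv <- rnorm(n)
  covs <- matrix(rnorm(n * 2), n)
  t1 <- crosssubject_covariance_map(cohort_matrix(Y, g), seedv, covs)$t
  t_neg <- crosssubject_covariance_map(cohort_matrix(Y, g), -seedv, covs)$t
  expect_equal(t_neg, -t1)
  p <- sample(n)
  t_perm <- crosssubject_covariance_map(cohort_matrix(Y[p, ], g), seedv[p],
                                        covs[p, ])$t
  expect_equal(t_perm, t1, tolerance = 1e-12)
  expect_error(crosssubject_covariance_map(cohort_matrix(Y, g), rep(1, n)),
               "constant")
})

test_that("structural covariance reuses the covariance engine", {
  set.seed(48)
  n <- 30; g <- tiny_grid(c(4, 4, 2))
  Y <- matrix(rnorm(n * prod(g$shape)), n)
  seedv <- rnorm(n)
  covs <- matrix(rnorm(n * 2), n)
  a <- vbm_scn_map(cohort_matrix(Y, g), seedv, covs)
  b <- crosssubject_covariance_map(cohort_matrix(Y, g), seedv, covs)
  expect_equal(a$t, b$t)
  expect_equal(a$estimator, "VBM-SCN")
})

test_that("a planted shared structural factor is detected and global scaling removed", {
  set.seed(49)
  n <- 100
  g <- tiny_grid(c(5, 5, 2))
  V <- prod(g$shape)
  f <- rnorm(n) # shared factor between seed region and voxel 10
  planted_r <- 0.7
  Y <- matrix(rnorm(n * V), n)
  Y[, 10] <- planted_r * f + sqrt(1 - planted_r^2) * rnorm(n)
  seedv <- planted_r * f + sqrt(1 - planted_r^2) * rnorm(n)
  thr <- fwe_threshold(crosssubject_covariance_map(cohort_matrix(Y, g), seedv))
  expect_gt(thr$source$t[10], thr$t_crit)
  # a global scaling factor hits every voxel; including it as a covariate
  # leaves unrelated voxels sub-threshold
  scale_f <- rnorm(n)
  Y2 <- matrix(rnorm(n * V), n) + scale_f
  seed2 <- rnorm(n) + scale_f
  without_cov <- crosssubject_covariance_map(cohort_matrix(Y2, g), seed2)
  with_cov <- fwe_threshold(
    crosssubject_covariance_map(cohort_matrix(Y2, g), seed2,
                                covariates = cbind(scale_f)))
  # voxels look connected through the global factor until it is regressed
  # out; the adjusted map collapses towards the null
  expect_gt(median(abs(without_cov$t)), with_cov$t_crit)
  expect_lt(max(abs(with_cov$source$t)), max(abs(without_cov$t)))
  expect_lt(median(abs(with_cov$source$t)), 1.5)
})

test_that("Bonferroni critical values follow the t quantile", {
  g1 <- tiny_grid(c(1, 1, 1))
  sm <- stat_map(array(0, c(1, 1, 1)), g1, df = 28)
  thr <- fwe_threshold(sm, 0.05)
  expect_equal(thr$t_crit, qt(0.975, 28))
  gV <- tiny_grid(c(10, 10, 10))
  smV <- stat_map(array(0, c(10, 10, 10)), gV, df = 298)
  thrV <- fwe_threshold(smV, 0.05)
  expect_equal(thrV$t_crit, qt(1 - 0.05 / 2000, 298))
  expect_equal(formals(fwe_threshold)$alpha, 0.05)
})

test_that("threshold masks are disjoint and sign-correct", {
  set.seed(50)
  g <- tiny_grid(c(6, 6, 3))
  sm <- stat_map(array(rnorm(prod(g$shape), sd = 4), g$shape), g, df = 40)
  thr <- fwe_threshold(sm, 0.05)
  expect_false(any(thr$pos_mask & thr$neg_mask))
  expect_true(all(sm$t[thr$pos_mask] >= thr$t_crit))
  expect_true(all(sm$t[thr$neg_mask] <= -thr$t_crit))
})

test_that("cluster tables report components by size with peak coordinates", {
  g <- tiny_grid(c(9, 9, 9), 3)
  tv <- array(0, g$shape)
  # 5-voxel and 3-voxel positive blobs, far apart
  tv[2:4, 2, 2] <- c(8, 9, 8); tv[2, 3, 2] <- 8; tv[2, 2, 3] <- 8
  tv[7:9, 8, 8] <- c(7, 10, 7)
  sm <- stat_map(tv, g, df = 28)
  thr <- fwe_threshold(sm, 0.05)
  tab <- cluster_table(thr, min_voxels = 2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$voxels, c(5L, 3L))
  expect_equal(tab$peak_t, c(9, 10))
  # peak of the 3-voxel blob sits at voxel (8,8,8) -> mm via the affine
  expect_equal(unlist(tab[2, c("x", "y", "z")], use.names = FALSE),
               as.vector(voxel_to_mm(g, matrix(c(7, 7, 7), 1))))
  # single suprathreshold voxel is filtered out at min_voxels = 2
  tv2 <- array(0, g$shape); tv2[5, 5, 5] <- 20
  tab2 <- cluster_table(fwe_threshold(stat_map(tv2, g, df = 28)), 2)
  expect_equal(nrow(tab2), 0L)
  # empty masks give an empty table
  tab3 <- cluster_table(fwe_threshold(stat_map(array(0, g$shape), g, 28)), 1)
  expect_equal(nrow(tab3), 0L)
})

test_that("26-connectivity joins diagonal neighbours", {
  g <- tiny_grid(c(5, 5, 5), 3)
  tv <- array(0, g$shape)
  tv[2, 2, 2] <- 9; tv[3, 3, 3] <- 9 # touch only at a corner
  tab <- cluster_table(fwe_threshold(stat_map(tv, g, 28)), 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$voxels, 2L)
})

test_that("categorical covariates become centred dummies", {
  phen <- data.frame(center = c("a", "a", "b", "b"), sex = c("F", "M", "F", "M"),
                     age = c(20, 30, 40, 50))
  X <- covariate_matrix(phen, c("center", "sex", "age"))
  expect_equal(ncol(X), 3L)
  expect_equal(unname(colMeans(X)), rep(0, 3))
  expect_error(covariate_matrix(phen, c("center", "missing_col")), "missing_col")
  expect_equal(ncol(covariate_matrix(phen, character(0))), 0L)
})
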