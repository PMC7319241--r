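test_that("DTW distance matches its defining cases", {
  x <- c(0.3, 1.2, -0.5, 2)
  expect_equal(dtw_distance(x, x), 0)
  expect_equal(dtw_distance(0, 3), 3)
  expect_equal(dtw_distance(c(0, 0, 1), c(0, 1)), 0)
  expect_equal(dtw_distance(c(0, 0, 1), c(0, 1)),
               dtw_distance(c(0, 1), c(0, 0, 1)))  # symmetry
  expect_error(dtw_distance(numeric(0), 1), "nonempty")
  expect_error(dtw_distance(c(1, NA), 1), "finite")
})

test_that("DTW equals the exhaustive warping-path oracle on short series", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    x <- round(rnorm(n), 2)
    y <- round(rnorm(m), 2)
    expect_identical(dtw_distance(x, y), oracle_dtw(x, y))
  }
})

test_that("a Sakoe-Chiba window constrains the warping path", {
  x <- c(0, 0, 0, 5)
  y <- c(5, 0, 0, 0)
  expect_lte(dtw_distance(x, y), dtw_distance(x, y, window = 1))
})

test_that("the DTW matrix is symmetric with zero diagonal", {
  set.seed(2)
  series <- lapply(1:5, function(i) rnorm(7))
  D <- dtw_matrix(series, normalize = FALSE)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 5))
  # every entry equals the exhaustive path-enumeration oracle
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], oracle_dtw(series[[i]], series[[j]]))
  }
})

test_that("standardization maps identical and constant series sensibly", {
  a <- sin(1:20)
  D <- dtw_matrix(list(a, a, 3 + 2 * a))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 0, tolerance = 1e-12)  # z-scaling removes offset/scale
  Dc <- dtw_matrix(list(rep(4, 10), rep(9, 10)))
  expect_equal(Dc[1, 2], 0)  # constant series standardize to zeros
})

test_that("Ward clustering recovers well-separated groups and guards k", {
  g1 <- rep(0, 12); g2 <- rep(5, 12)
  series <- c(replicate(4, g1 + rnorm(12, 0, 1e-3), simplify = FALSE),
              replicate(4, g2 + rnorm(12, 0, 1e-3), simplify = FALSE))
  D <- dtw_matrix(series, normalize = FALSE)
  cl <- ward_cluster(D, k = 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_true(cl$labels[1] != cl$labels[5])
  # n = 2 trivially separates
  D2 <- dtw_matrix(list(c(0, 0), c(1, 5)), normalize = FALSE)
  expect_equal(sort(ward_cluster(D2, k = 2)$labels), c(1, 2))
  expect_error(ward_cluster(D2, k = 3), "k")
})

test_that("regime codes combine the two clusterings per the A/B/C rule", {
  ids <- paste0("m", 1:4)
  do <- setNames(c(1, 2, 2, 1), ids)
  bio <- setNames(c(1, 1, 2, 2), ids)
  codes <- combine_regimes(do, bio)
  expect_equal(unname(codes), c("A", "B", "C", "other"))
  expect_equal(unname(combine_regimes(setNames(c(1, 1), c("a", "b")),
                                      setNames(c(1, 1), c("b", "a")))),
               c("A", "A"))
  expect_error(combine_regimes(do, bio[1:3]), "same microcosms")
  expect_error(combine_regimes(setNames(c(1, 3), c("a", "b")),
                               setNames(c(1, 2), c("a", "b"))), "1/2")
})

test_that("association deviance matches the closed form and the GLM oracle", {
  # equal proportions in every group: no association
  out <- association_lrt(c(1, 0, 1, 0), c("a", "a", "b", "b"))
  expect_equal(out$deviance, 0)
  # 5/5 vs 0/5: deviance 2 * [0 - 10 ln(1/2)] = 20 ln 2, df = 1
  out <- association_lrt(rep(c(1, 0), each = 5), rep(c("a", "b"), each = 5))
  expect_equal(out$deviance, 20 * log(2), tolerance = 1e-12)
  expect_equal(out$df, 1)
  # hand-built 5-level table against the closed-form oracle
  k <- c(0, 1, 1, 2, 5); n <- rep(6, 5)
  outcome <- unlist(mapply(function(ki, ni) c(rep(1, ki), rep(0, ni - ki)),
                           k, n, SIMPLIFY = FALSE))
  trt <- rep(letters[1:5], times = n)
  out <- association_lrt(outcome, trt)
  expect_equal(out$deviance, oracle_lrt_deviance(k, n), tolerance = 1e-12)
  expect_equal(out$df, 4)
  # random tables against an iteratively-reweighted GLM fit
  set.seed(21)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.4)
    g <- sample(letters[1:4], 40, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    fit <- glm(y ~ factor(g), family = binomial())
    expect_equal(association_lrt(y, g)$deviance,
                 fit$null.deviance - fit$deviance, tolerance = 1e-6)
  }
})

test_that("association deviance is invariant to relabeling and level order", {
  set.seed(4)
  y <- rbinom(30, 1, 0.5)
  g <- rep(c("open", "add50", "closed"), each = 10)
  d1 <- association_lrt(y, g)$deviance
  expect_equal(association_lrt(1 - y, g)$deviance, d1, tolerance = 1e-12)
  expect_equal(association_lrt(y, factor(g, levels = c("closed", "open", "add50")))$deviance,
               d1, tolerance = 1e-12)
  expect_error(association_lrt(y, rep("a", 30)), "2 treatment levels")
})

test_that("metric ANOVA reproduces classical identities and the SS oracle", {
  set.seed(9)
  # two groups: F equals the square of the pooled t statistic
  y <- rnorm(16); g <- rep(c("a", "b"), each = 8)
  tab <- metric_anova(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(tab$F[tab$term == "treatment"], unname(tt^2), tolerance = 1e-10)
  # 5 groups of 6 against the textbook sums-of-squares computation
  y5 <- rnorm(30, rep(1:5, each = 6)); g5 <- rep(letters[1:5], each = 6)
  tab5 <- metric_anova(y5, g5)
  expect_equal(tab5$F[tab5$term == "treatment"], oracle_anova_F(y5, g5),
               tolerance = 1e-10)
  # additive ANCOVA agrees with the sequential lm ANOVA
  cl <- rep(rep(c("c1", "c2"), each = 3), 5)
  tab_cov <- metric_anova(y5, g5, cluster = cl)
  ref <- anova(lm(y5 ~ factor(g5) + factor(cl)))
  expect_equal(tab_cov$F[1:2], ref$`F value`[1:2], tolerance = 1e-10)
  expect_equal(nrow(metric_anova(y5, g5, cluster = cl, interaction = TRUE)), 4)
})

test_that("metric ANOVA reports undefined F under zero residual variance", {
  y <- rep(c(1, 2), each = 6)
  g <- rep(c("a", "b"), each = 6)
  tab <- metric_anova(y, g)
  expect_true(is.na(tab$F[tab$term == "treatment"]))
  expect_error(metric_anova(1:4, c("a", "a", "b", "b"),
                            cluster = c("x", "x", "y", "y")), "aliased")
})

test_that("regime clustering anchors cluster 1 to the reference dynamics", {
  ex <- small_experiment()
  cl_do <- cluster_regimes(ex, "O_liq")
  expect_s3_class(cl_do, "regime_clustering")
  expect_length(cl_do$labels, nrow(ex$microcosms))
  # cluster 1 carries the higher mean oxygen by construction
  series_means <- tapply(ex$samples$O_liq, ex$samples$microcosm, mean)
  series_means <- series_means[names(cl_do$labels)]
  if (length(unique(cl_do$labels)) == 2) {
    expect_gt(mean(series_means[cl_do$labels == 1]),
              mean(series_means[cl_do$labels == 2]))
  }
  cl_bio <- cluster_regimes(ex, "total_biomass")
  codes <- combine_regimes(cl_do$labels, cl_bio$labels)
  expect_true(all(codes %in% c("A", "B", "C", "other")))
})

test_that("planted low-oxygen regimes carry larger hysteresis on average", {
  ex <- small_experiment()
  paths <- microcosm_paths(ex, "O_liq")
  h <- vapply(paths, hysteresis, numeric(1))
  regime <- setNames(ex$microcosms$regime, ex$microcosms$microcosm)[names(h)]
  if (all(c("persistence", "extinction") %in% regime)) {
    expect_gt(mean(h[regime == "persistence"]), mean(h[regime == "extinction"]))
  }
})
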