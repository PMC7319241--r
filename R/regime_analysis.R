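# Detection of alternative dynamic regimes from replicated time series:
# dynamic time warping distances, Ward hierarchical clustering, combination
# of per-variable cluster labels, a likelihood-ratio test of the
# cluster-treatment association, and ANOVA/ANCOVA group comparisons of the
# response metrics.

#' Dynamic time warping distance
#'
#' Classic unconstrained DTW with absolute local cost and the symmetric step
#' pattern: \eqn{D(i,j) = |x_i - y_j| + \min(D(i-1,j), D(i,j-1),
#' D(i-1,j-1))}; the distance is `D(n, m)`. Optionally a Sakoe-Chiba band of
#' half-width `window` restricts the warping path. DTW is symmetric with
#' zero self-distance but does not satisfy the triangle inequality.
#'
#' @param x,y Numeric series (nonempty, finite).
#' @param window Optional Sakoe-Chiba half-width (default `NULL`,
#'   unconstrained).
#' @return The nonnegative alignment cost.
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1))  # 0: a zero-cost alignment exists
#' dtw_distance(0, 3)                 # 3
#' @export
dtw_distance <- function(x, y, window = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("series must be nonempty")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("series must be finite")
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    js <- if (is.null(window)) seq_len(m)
    else seq(max(1, i - window), min(m, i + window))
    for (j in js) {
      D[i + 1, j + 1] <- abs(x[i] - y[j]) +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

# z-standardize one series; a constant series standardizes to all zeros
zscore_series <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
}

#' Pairwise DTW distance matrix
#'
#' Computes all pairwise DTW distances between a set of equally sampled
#' series, optionally after per-series standardization (centering and
#' scaling to unit standard deviation, the usual preprocessing before
#' shape-based clustering; constant series standardize to all zeros).
#'
#' @param series A list of numeric vectors, or a matrix with one series per
#'   row.
#' @param normalize Standardize each series first (default `TRUE`).
#' @param window Optional Sakoe-Chiba half-width passed to
#'   [dtw_distance()].
#' @return A symmetric distance matrix with zero diagonal.
#' @export
dtw_matrix <- function(series, normalize = TRUE, window = NULL) {
  if (is.matrix(series)) series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
  if (length(series) < 2) stop("need at least 2 series")
  if (normalize) series <- lapply(series, zscore_series)
  n <- length(series)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- dtw_distance(series[[i]], series[[j]], window)
    }
  }
  dimnames(D) <- list(names(series), names(series))
  D
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion applied to squared
#' dissimilarities (`stats::hclust` method `"ward.D2"`, the modern Ward
#' dialect; method `"ward.D"` operates on the distances as given and is
#' available as an option), cut into `k` groups. `hclust` breaks merge ties
#' deterministically by the order of the observations.
#'
#' @param D Symmetric distance matrix (or a `dist` object).
#' @param k Number of clusters (default 2, `k <= n`).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return A list with `labels` (integer cluster per series) and `tree`
#'   (the `hclust` merge history).
#' @export
ward_cluster <- function(D, k = 2, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  d <- if (inherits(D, "dist")) D else as.dist(D)
  n <- attr(d, "Size")
  if (k > n) stop("`k` must not exceed the number of series")
  tree <- hclust(d, method = method)
  list(labels = cutree(tree, k = k), tree = tree)
}

#' Cluster the dynamic regimes of an experiment
#'
#' Full regime detection for one measured variable: extract each
#' microcosm's time series, standardize, compute the DTW distance matrix,
#' cluster with Ward's method and cut at `k` clusters. Cluster identities
#' are anchored by the mean raw series level so labels are reproducible:
#' for dissolved oxygen, cluster 1 is the cluster with the higher mean
#' oxygen (the stabilized regime); for total biomass, cluster 1 has the
#' lower mean biomass.
#'
#' @param x A `microcosm_experiment` or its `samples` data frame.
#' @param variable `"O_liq"` or `"total_biomass"`.
#' @param k Number of clusters (default 2).
#' @param normalize Standardize series before DTW (default `TRUE`).
#' @param window Optional Sakoe-Chiba half-width.
#' @param method Ward dialect for [ward_cluster()].
#' @return A list of class `regime_clustering`: `variable`, `dist`,
#'   `tree`, `labels` (named, anchored), `microcosms`.
#' @export
cluster_regimes <- function(x, variable = c("O_liq", "total_biomass"), k = 2,
                            normalize = TRUE, window = NULL,
                            method = c("ward.D2", "ward.D")) {
  variable <- match.arg(variable)
  samples <- if (inherits(x, "microcosm_experiment")) x$samples else x
  ids <- unique(samples$microcosm)
  series <- lapply(split(samples, samples$microcosm), function(d)
    d[[variable]][order(d$day)])[ids]
  D <- dtw_matrix(series, normalize = normalize, window = window)
  cl <- ward_cluster(D, k = k, method = match.arg(method))
  labels <- cl$labels
  means <- vapply(series, mean, numeric(1))
  cluster_means <- tapply(means, labels, mean)
  # anchor: cluster 1 = high-oxygen (for DO) resp. low-biomass (for biomass)
  anchor <- if (variable == "O_liq") which.max(cluster_means) else which.min(cluster_means)
  anchor <- as.integer(names(cluster_means)[anchor])
  # map the anchor cluster to 1; remaining clusters keep their relative order
  old <- sort(unique(labels))
  new_order <- c(anchor, setdiff(old, anchor))
  map <- setNames(seq_along(new_order), new_order)
  labels <- as.integer(map[as.character(labels)])
  names(labels) <- ids
  structure(list(variable = variable, dist = D, tree = cl$tree,
                 labels = labels, microcosms = ids),
            class = "regime_clustering")
}

#' @export
print.regime_clustering <- function(x, ...) {
  cat(sprintf("Regime clustering of %s: %d series, %d clusters (sizes: %s)\n",
              x$variable, length(x$labels), length(unique(x$labels)),
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Combine per-variable regime labels into joint codes
#'
#' Combines the k = 2 cluster labels obtained from the dissolved-oxygen and
#' total-biomass series into the joint regime codes: `A` for microcosms in
#' cluster 1 of both analyses, `B` for cluster 2 of oxygen but cluster 1 of
#' biomass, `C` for cluster 2 of both; the remaining combination (cluster 1
#' of oxygen, cluster 2 of biomass) is reported as `other` if it occurs.
#'
#' @param labels_do Named 1/2 labels from the oxygen clustering.
#' @param labels_biomass Named 1/2 labels from the biomass clustering (same
#'   microcosms).
#' @return A named character vector of codes.
#' @export
combine_regimes <- function(labels_do, labels_biomass) {
  if (!setequal(names(labels_do), names(labels_biomass)))
    stop("the two clusterings must label the same microcosms")
  labels_biomass <- labels_biomass[names(labels_do)]
  if (!all(labels_do %in% 1:2) || !all(labels_biomass %in% 1:2))
    stop("labels must be 1/2 cluster indices")
  code <- ifelse(labels_do == 1 & labels_biomass == 1, "A",
          ifelse(labels_do == 2 & labels_biomass == 1, "B",
          ifelse(labels_do == 2 & labels_biomass == 2, "C", "other")))
  setNames(code, names(labels_do))
}

#' Likelihood-ratio test of a cluster-treatment association
#'
#' Tests whether a binary regime label depends on the categorical treatment
#' by the likelihood-ratio (deviance) test of a Bernoulli model with one
#' probability per treatment level against the constant-probability null.
#' Because the predictor is categorical, the alternative's maximum
#' likelihood is attained at the group proportions, so the deviance
#' \eqn{2 (\ell_{groups} - \ell_{null})} has closed form (with
#' \eqn{0 \log 0 = 0}); this equals the likelihood-ratio test of a logistic
#' regression on the treatment factor. The p-value uses the chi-squared
#' reference with `levels - 1` degrees of freedom.
#'
#' @param outcome Binary vector (logical, 0/1, or two-level factor).
#' @param treatment Factor (or coercible) of treatment levels, same length.
#' @return A list of class `association_test`: `deviance`, `df`, `p_value`.
#' @examples
#' association_lrt(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'                 rep(c("closed", "open"), each = 5))  # deviance 20*log(2)
#' @export
association_lrt <- function(outcome, treatment) {
  treatment <- as.factor(treatment)
  if (length(outcome) != length(treatment))
    stop("`outcome` and `treatment` must have the same length")
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("`outcome` must be binary")
  if (nlevels(treatment) < 2) stop("need at least 2 treatment levels")
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  bernoulli_ll <- function(k, n) xlogx(k) + xlogx(n - k) - xlogx(n)
  # saturated-by-group and null log-likelihoods at their MLEs
  k_g <- tapply(outcome, treatment, sum)
  n_g <- tapply(outcome, treatment, length)
  ll_groups <- sum(bernoulli_ll(k_g, n_g))
  ll_null <- bernoulli_ll(sum(outcome), length(outcome))
  deviance <- 2 * (ll_groups - ll_null)
  df <- nlevels(treatment) - 1L
  structure(list(deviance = deviance, df = df,
                 p_value = pchisq(deviance, df, lower.tail = FALSE)),
            class = "association_test")
}

#' @export
print.association_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: deviance = %.4g, df = %d, p = %.4g\n",
              x$deviance, x$df, x$p_value))
  invisible(x)
}

#' ANOVA / ANCOVA of a response metric across treatments
#'
#' One-way analysis of variance of a metric (nonlinearity or hysteresis)
#' with the gas-exchange treatment as a categorical factor; optionally the
#' cluster membership is added as a second categorical factor, giving an
#' additive analysis of covariance (sequential F tests by nested
#' residual-sum-of-squares comparison, as in `stats::anova` on the linear
#' model), and `interaction = TRUE` also fits the interaction. When the
#' residual variance is zero the F statistics are undefined and reported as
#' `NA`.
#'
#' @param metric Numeric response values.
#' @param treatment Categorical factor (coercible), same length.
#' @param cluster Optional second categorical factor.
#' @param interaction Also fit the treatment x cluster interaction
#'   (default `FALSE`).
#' @return A `data.frame` with one row per model term: `term`, `df`,
#'   `sum_sq`, `F`, `p_value`, plus the residual row.
#' @export
metric_anova <- function(metric, treatment, cluster = NULL,
                         interaction = FALSE) {
  treatment <- as.factor(treatment)
  stopifnot(length(metric) == length(treatment))
  if (nlevels(droplevels(treatment)) < 2)
    stop("need at least 2 treatment levels")
  dat <- data.frame(metric = metric, treatment = treatment)
  form <- metric ~ treatment
  if (!is.null(cluster)) {
    dat$cluster <- as.factor(cluster)
    form <- if (interaction) metric ~ treatment * cluster
            else metric ~ treatment + cluster
  }
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("degenerate design: aliased terms ", paste(aliased, collapse = ", "))
  }
  # a zero-residual fit triggers an "unreliable F" warning; that case is
  # handled explicitly below by reporting the F statistics as undefined
  tab <- suppressWarnings(anova(fit))
  out <- data.frame(term = rownames(tab), df = tab$Df, sum_sq = tab$`Sum Sq`,
                    F = tab$`F value`, p_value = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  resid_ms <- out$sum_sq[out$term == "Residuals"] / out$df[out$term == "Residuals"]
  if (is.finite(resid_ms) && resid_ms <= .Machine$double.eps * max(1, mean(metric)^2)) {
    out$F[out$term != "Residuals"] <- NA_real_
    out$p_value[out$term != "Residuals"] <- NA_real_
  }
  out
}
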