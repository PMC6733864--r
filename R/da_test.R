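#' Median-of-ratios size factors
#'
#' Per-sample depth-normalisation factors computed as the median, over a
#' reference set of OTUs, of the ratio of the sample's count to the OTU's
#' geometric mean across samples. The reference set is the OTUs observed
#' in every sample; when no OTU qualifies (sparse tables), ratios fall back
#' to per-OTU geometric means computed on positive counts only, taken over
#' the sample's positive counts. Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param table An [otu_table].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(table) {
  m <- unclass(table)
  zero_samples <- rownames(m)[rowSums(m) == 0]
  if (length(zero_samples))
    stop("sample(s) with all-zero counts: ", paste(zero_samples, collapse = ", "))
  logm <- log(m)
  all_pos <- colSums(m > 0) == nrow(m)
  if (any(all_pos)) {
    loggeo <- colMeans(logm[, all_pos, drop = FALSE])
    sf <- apply(logm[, all_pos, drop = FALSE], 1L,
                function(r) exp(stats::median(r - loggeo)))
  } else {
    ## fallback: geometric mean over positive counts only
    loggeo <- apply(logm, 2L, function(col) mean(col[is.finite(col)]))
    sf <- apply(logm, 1L, function(r) {
      ok <- is.finite(r) & is.finite(loggeo)
      if (!any(ok)) stop("cannot estimate a size factor: no shared positive OTU")
      exp(stats::median(r[ok] - loggeo[ok]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, rownames(m))
}

#' Method-of-moments negative-binomial dispersions
#'
#' Per-OTU dispersion alpha estimated on size-factor-normalised counts as
#' `max(floor, (s^2 - mean) / mean^2)`; near-Poisson or constant OTUs hit
#' the floor.
#'
#' @param table An [otu_table].
#' @param size_factors Positive per-sample factors (defaults to
#'   [estimate_size_factors]).
#' @param floor Lower bound on the estimate.
#' @return Named numeric vector of dispersions, one per OTU.
#' @export
estimate_dispersion <- function(table, size_factors = estimate_size_factors(table),
                                floor = 1e-8) {
  stopifnot(all(size_factors > 0))
  k <- sweep(unclass(table), 1L, size_factors, "/")
  m <- colMeans(k)
  v <- apply(k, 2L, stats::var)
  a <- ifelse(m > 0, (v - m) / m^2, floor)
  stats::setNames(pmax(floor, a), colnames(table))
}

## Fisher scoring for the per-group NB log-mean with offset log(sf):
## mu_j = s_j * exp(eta). Vectorised across OTUs. Returns eta, Fisher
## information, and a convergence flag per OTU.
fit_nb_group <- function(counts, sf, alpha, tol = 1e-8, max_iter = 100L) {
  K <- ncol(counts)
  tot <- colSums(counts)
  eta <- ifelse(tot > 0, log(tot / sum(sf)), NA_real_)
  conv <- tot > 0
  active <- which(conv)
  alpha_m <- matrix(alpha, nrow = nrow(counts), ncol = K, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    mu <- sf %o% exp(eta[active])
    A <- 1 + alpha_m[, active, drop = FALSE] * mu
    score <- colSums((counts[, active, drop = FALSE] - mu) / A)
    info <- colSums(mu / A)
    step <- score / info
    step <- pmin(pmax(step, -5), 5)
    eta[active] <- eta[active] + step
    active <- active[abs(step) > tol]
  }
  if (length(active)) conv[active] <- FALSE  # hit max_iter
  mu <- sf %o% exp(ifelse(is.na(eta), 0, eta))
  info <- colSums(mu / (1 + alpha_m * mu))
  info[!conv | tot == 0] <- NA_real_
  eta[tot == 0] <- NA_real_
  list(eta = eta, info = info, converged = conv)
}

#' Negative-binomial Wald test between two sample groups
#'
#' For each OTU a negative-binomial log-link model with a group indicator
#' is fitted by Fisher scoring, with the log size factor as offset and the
#' dispersion fixed at its estimate. The log2 fold change is the group
#' coefficient divided by `ln 2`, positive when the group-2 mean exceeds
#' the group-1 mean; its standard error (`lfcse`) comes from the Fisher
#' information, the Wald statistic is `log2fc / lfcse`, two-sided p-values
#' are normal, and adjusted p-values follow Benjamini-Hochberg.
#'
#' This engine deliberately simplifies the DESeq2 model it emulates: there
#' is no dispersion shrinkage toward a fitted trend, no outlier handling,
#' no independent filtering, and no fold-change shrinkage; its calibration
#' is established by the package's recovery and type-I-error tests.
#'
#' @param table An [otu_table].
#' @param group Vector (length = samples) with exactly two levels; the
#'   second level in sort/factor order is "group 2".
#' @param size_factors,dispersions Optional precomputed values.
#' @param shrink_dispersion If `TRUE`, per-OTU dispersions are shrunk
#'   halfway (on the log scale) toward a trend fitted on the mean, a
#'   light-weight stabilisation for small sample sizes.
#' @return A `da_result` data frame with columns `otu_id`, `base_mean`,
#'   `log2fc`, `lfcse`, `wald_stat`, `p_value`, `p_adj`. OTUs with all-zero
#'   counts, or a group with no counts at all (fold change unbounded),
#'   carry `NA` statistics.
#' @export
nb_wald_test <- function(table, group,
                         size_factors = estimate_size_factors(table),
                         dispersions = estimate_dispersion(table, size_factors),
                         shrink_dispersion = FALSE) {
  m <- unclass(table)
  if (length(group) != nrow(m))
    stop("group must have one label per sample")
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  i1 <- which(g == levels(g)[1L])
  i2 <- which(g == levels(g)[2L])
  if (!length(i1) || !length(i2)) stop("both groups must be non-empty")

  alpha <- dispersions[colnames(m)]
  if (shrink_dispersion) {
    norm_mean <- colMeans(sweep(m, 1L, size_factors, "/"))
    ok <- norm_mean > 0 & alpha > 1e-8
    if (sum(ok) > 5) {
      fit <- stats::lm(log(alpha[ok]) ~ log(norm_mean[ok]))
      trend <- exp(stats::predict(fit, newdata = data.frame(
        `log(norm_mean[ok])` = log(pmax(norm_mean, min(norm_mean[ok]))),
        check.names = FALSE)))
      alpha <- exp((log(pmax(alpha, 1e-8)) + log(pmax(trend, 1e-8))) / 2)
    }
  }

  f1 <- fit_nb_group(m[i1, , drop = FALSE], size_factors[i1], alpha)
  f2 <- fit_nb_group(m[i2, , drop = FALSE], size_factors[i2], alpha)

  ln2 <- log(2)
  log2fc <- (f2$eta - f1$eta) / ln2
  lfcse <- sqrt(1 / f1$info + 1 / f2$info) / ln2
  wald <- log2fc / lfcse
  p <- 2 * stats::pnorm(-abs(wald))
  bad <- is.na(p)
  if (any(bad & colSums(m) > 0))
    message(sum(bad & colSums(m) > 0),
            " OTU(s) with one group unobserved or non-converged: statistics set to NA")
  p_adj <- rep(NA_real_, length(p))
  p_adj[!bad] <- benjamini_hochberg(p[!bad])

  out <- data.frame(
    otu_id = colnames(m),
    base_mean = colMeans(sweep(m, 1L, size_factors, "/")),
    log2fc = log2fc, lfcse = lfcse, wald_stat = wald,
    p_value = p, p_adj = p_adj,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("da_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector in `[0,1]`.
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Count significantly enriched OTUs per side
#'
#' An OTU counts for group 1 when `p_adj < alpha` and `log2fc < 0`
#' (enriched in group 1), for group 2 when `p_adj < alpha` and
#' `log2fc > 0`; a significant OTU with zero fold change counts nowhere.
#'
#' @param result A `da_result`.
#' @param alpha Adjusted-p significance threshold.
#' @return Named integer vector `c(n_enriched_group1, n_enriched_group2)`.
#' @export
count_enriched <- function(result, alpha = 0.05) {
  sig <- !is.na(result$p_adj) & result$p_adj < alpha
  c(n_enriched_group1 = sum(sig & result$log2fc < 0),
    n_enriched_group2 = sum(sig & result$log2fc > 0))
}
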