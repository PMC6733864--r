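#' Fold difference in enriched-OTU counts for one comparison
#'
#' The ratio of the number of OTUs enriched in group 1 (healthy) to the
#' number enriched in group 2 (disease). For plotting, raw values below 1
#' are inverted and made negative so a 2-fold excess on either side reads
#' as +2 or -2. A zero denominator is handled by the `zero_rule`:
#' `"substitute"` replaces it with `max(n2, 1)` and flags the record,
#' `"exclude"` flags it with `NA` fold difference; both-zero records are
#' always undefined and excluded from downstream t-tests.
#'
#' @param n1,n2 Non-negative OTU counts enriched in group 1 / group 2.
#' @param comparison_id Optional identifier carried through.
#' @param zero_rule `"substitute"` or `"exclude"`.
#' @return One-row data frame with `comparison_id`, `n_enriched_group1`,
#'   `n_enriched_group2`, `fold_difference`, `plot_value`, `flagged`.
#' @export
fold_difference <- function(n1, n2, comparison_id = NA_character_,
                            zero_rule = c("substitute", "exclude")) {
  zero_rule <- match.arg(zero_rule)
  stopifnot(n1 >= 0, n2 >= 0)
  flagged <- FALSE
  if (n1 == 0 && n2 == 0) {
    fd <- NA_real_; flagged <- TRUE
  } else if (n2 == 0) {
    flagged <- TRUE
    fd <- if (zero_rule == "substitute") n1 / max(n2, 1) else NA_real_
  } else {
    fd <- n1 / n2
  }
  plot_value <- if (is.na(fd)) NA_real_ else if (fd >= 1) fd else -1 / fd
  data.frame(comparison_id = comparison_id,
             n_enriched_group1 = n1, n_enriched_group2 = n2,
             fold_difference = fd, plot_value = plot_value,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' One-sample t-tests of fold-difference bias
#'
#' For each disease the (raw, untransformed) fold-difference ratios are
#' compared against an expected value of 1 with a two-sided one-sample
#' t-test; p-values are Holm-corrected across diseases. A significant
#' excess above 1 indicates more OTUs enriched in healthy than in disease
#' populations, i.e. loss-of-function dysbiosis. Records with undefined
#' fold difference are dropped; a disease with all values exactly 1 gets
#' `t = 0, p = 1`; zero variance away from 1 is degenerate and reported
#' as `p = 0` with a flag.
#'
#' @param records Data frame of fold-difference records (as produced by
#'   [fold_difference]) with a `disease` column.
#' @param scale `"ratio"` tests the raw ratios; `"log"` tests log2 ratios
#'   against 0.
#' @return Data frame with one row per disease: `disease`, `n_records`,
#'   `mean_fold`, `t_stat`, `p_value`, `p_holm`, `degenerate`.
#' @export
test_fold_bias <- function(records, scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  stopifnot(!is.null(records$disease), !is.null(records$fold_difference))
  usable <- records[!is.na(records$fold_difference), , drop = FALSE]
  out <- do.call(rbind, lapply(split(usable, usable$disease), function(d) {
    x <- d$fold_difference
    mu0 <- 1
    if (scale == "log") { x <- log2(x); mu0 <- 0 }
    if (length(x) < 2L)
      stop("need at least 2 usable fold-difference records for ", d$disease[1L])
    degenerate <- FALSE
    if (stats::sd(x) == 0) {
      if (all(x == mu0)) { tt <- 0; p <- 1 } else { tt <- Inf * sign(mean(x) - mu0); p <- 0; degenerate <- TRUE }
    } else {
      ht <- stats::t.test(x, mu = mu0)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(disease = d$disease[1L], n_records = length(x),
               mean_fold = mean(d$fold_difference), t_stat = tt, p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  out$p_holm <- holm_correct(out$p_value)
  rownames(out) <- NULL
  out
}

#' Genus presence-proportion matrices across comparisons
#'
#' For each disease and genus, the fraction of that disease's pairwise
#' comparisons in which the genus had at least one significantly enriched
#' OTU, computed separately for the healthy side ("potentially
#' beneficial") and the disease side ("potentially pathogenic").
#' Significant OTUs are reduced to genera first; OTUs unclassified at
#' genus level are removed. Genera with no signal on either side are
#' dropped; both matrices share the remaining column set.
#'
#' @param results Named list (by comparison id) of `da_result` objects.
#' @param diseases Named character vector mapping comparison id to disease.
#' @param taxonomy A `taxonomy_map`.
#' @param alpha Adjusted-p significance threshold.
#' @return List with matrices `enriched_in_healthy` and
#'   `enriched_in_disease` (rows = diseases, columns = genera) and
#'   `n_comparisons`, the per-disease comparison counts.
#' @export
genus_presence <- function(results, diseases, taxonomy, alpha = 0.05) {
  stopifnot(all(names(results) %in% names(diseases)))
  disease_levels <- unique(unname(diseases[names(results)]))
  hit <- function(res, side) {
    sig <- !is.na(res$p_adj) & res$p_adj < alpha &
      (if (side == "healthy") res$log2fc < 0 else res$log2fc > 0)
    unique(names(reduce_to_genus(res$otu_id[sig], taxonomy)))
  }
  hits_h <- lapply(results, hit, side = "healthy")
  hits_d <- lapply(results, hit, side = "disease")
  genera <- sort(unique(c(unlist(hits_h), unlist(hits_d))))
  build <- function(hits) {
    m <- matrix(0, nrow = length(disease_levels), ncol = length(genera),
                dimnames = list(disease_levels, genera))
    n_comp <- stats::setNames(numeric(length(disease_levels)), disease_levels)
    for (id in names(results)) {
      dis <- diseases[[id]]
      n_comp[dis] <- n_comp[dis] + 1
      m[dis, genera %in% hits[[id]]] <- m[dis, genera %in% hits[[id]]] + 1
    }
    sweep(m, 1L, pmax(n_comp, 1), "/")
  }
  n_comp <- table(factor(unname(diseases[names(results)]), levels = disease_levels))
  list(enriched_in_healthy = build(hits_h),
       enriched_in_disease = build(hits_d),
       n_comparisons = stats::setNames(as.numeric(n_comp), disease_levels))
}

## All internal-node leaf sets of an hclust tree, each encoded as a sorted
## label string so membership is invariant to input row order.
hclust_leaf_sets <- function(hc, labels) {
  n <- length(labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- unlist(lapply(kids, function(k) {
      if (k < 0) labels[-k] else sets[[k]]
    }))
    sets[[i]] <- leaves
  }
  vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1L))
}

row_distance <- function(m, method) {
  if (method == "correlation") {
    stats::as.dist(1 - stats::cor(t(m)))
  } else {
    stats::dist(m, method = method)
  }
}

#' Hierarchical clustering with multiscale-bootstrap AU/BP support
#'
#' Clusters the rows (diseases) of a genus-proportion matrix and attaches
#' to every internal node its bootstrap probability (BP) and approximately
#' unbiased (AU) support from a multiscale bootstrap: for each scale `r`
#' the genus columns are resampled with replacement to size
#' `ceiling(r * m)` `n_boot` times and the tree rebuilt; `bp(node, r)` is
#' the fraction of replicates containing the node's leaf set. AU comes
#' from a weighted least-squares fit of `qnorm(1 - bp(r)) = v * sqrt(r) +
#' c / sqrt(r)` evaluated as `AU = 1 - pnorm(v - c)`; BP is reported at
#' scale 1. Counts are clamped to `[1/(n_boot+1), n_boot/(n_boot+1)]`
#' before the probit. AU above 0.95 is flagged as significant support,
#' stored as a flag, never used as a filter.
#'
#' @param matrix Numeric matrix, rows = diseases, columns = genera (at
#'   least 3 rows).
#' @param n_boot Bootstrap replicates per scale.
#' @param scales Relative resampling sizes.
#' @param seed Integer seed; results are deterministic under it.
#' @param dist_method `"euclidean"` (default) or `"correlation"`.
#' @param linkage Agglomeration method passed to [stats::hclust].
#' @return List with `hclust` (the fitted tree) and `support`, a data
#'   frame with one row per internal node: `node`, `leaves`, `bp`, `au`,
#'   `significant`.
#' @export
cluster_with_support <- function(matrix, n_boot = 1000,
                                 scales = seq(0.5, 1.4, by = 0.1), seed = 1,
                                 dist_method = c("euclidean", "correlation"),
                                 linkage = "complete") {
  dist_method <- match.arg(dist_method)
  if (nrow(matrix) < 3L) stop("need at least 3 rows to cluster")
  labels <- rownames(matrix)
  if (is.null(labels)) labels <- rownames(matrix) <- paste0("row", seq_len(nrow(matrix)))
  hc <- stats::hclust(row_distance(matrix, dist_method), method = linkage)
  base_sets <- hclust_leaf_sets(hc, labels)
  m_col <- ncol(matrix)

  bp_mat <- withr::with_seed(seed, {
    vapply(scales, function(r) {
      size <- ceiling(r * m_col)
      hits <- numeric(length(base_sets))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(m_col, size, replace = TRUE)
        hcb <- stats::hclust(row_distance(matrix[, cols, drop = FALSE],
                                          dist_method), method = linkage)
        hits <- hits + (base_sets %in% hclust_leaf_sets(hcb, labels))
      }
      hits / n_boot
    }, numeric(length(base_sets)))
  })
  bp_mat <- matrix(bp_mat, nrow = length(base_sets))

  au <- vapply(seq_along(base_sets), function(i)
    fit_au(bp_mat[i, ], scales, n_boot), numeric(1L))
  bp1 <- if (any(scales == 1)) bp_mat[, which(scales == 1)[1L]] else
    bp_mat[, which.min(abs(scales - 1))]

  support <- data.frame(
    node = seq_along(base_sets),
    leaves = gsub("\r", ",", base_sets, fixed = TRUE),
    bp = bp1, au = au, significant = au > 0.95,
    stringsAsFactors = FALSE)
  list(hclust = hc, support = support, bp_by_scale = bp_mat, scales = scales)
}

## Multiscale-bootstrap AU fit for one node. z(r) = qnorm(1 - bp(r)) is
## regressed on (sqrt(r), 1/sqrt(r)) by WLS with binomial-variance
## weights; AU = 1 - pnorm(v - c). Scales with unanimous bp (exactly 0 or
## 1) carry no probit information and are excluded; when fewer than two
## informative scales remain the node is degenerate and AU is the mean bp
## (so a node present in every replicate at every scale gets AU = 1).
fit_au <- function(bp, scales, n_boot) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 2L || length(unique(scales[use])) < 2L) return(mean(bp))
  lo <- 1 / (n_boot + 1)
  bp_c <- pmin(pmax(bp[use], lo), 1 - lo)
  r <- scales[use]
  z <- stats::qnorm(1 - bp_c)
  w <- n_boot * stats::dnorm(z)^2 / (bp_c * (1 - bp_c))
  X <- cbind(v = sqrt(r), c = 1 / sqrt(r))
  fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(mean(bp))
  co <- fit$coefficients
  unname(1 - stats::pnorm(co[["v"]] - co[["c"]]))
}

#' Write a disease dendrogram and its node supports
#'
#' @param clust Result of [cluster_with_support].
#' @param prefix Output path prefix; writes `<prefix>.nwk` (Newick) and
#'   `<prefix>_support.tsv`.
#' @export
write_cluster_support <- function(clust, prefix) {
  ape::write.tree(ape::as.phylo(clust$hclust), paste0(prefix, ".nwk"))
  df <- clust$support
  df$bp <- round(df$bp, 6)
  df$au <- round(df$au, 6)
  utils::write.table(df, paste0(prefix, "_support.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
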