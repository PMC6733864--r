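#' Per-genus diversity and dysbiosis counts for one disease
#'
#' For each genus, the total number of OTUs classified to it among the
#' tested OTUs, and the number of dysbiotic OTUs: by default the unique
#' OTUs significant in at least one of the disease's comparisons
#' (`counting = "unique"`), or the sum of OTU-by-comparison significance
#' events (`counting = "weighted"`). Both dysbiosis sides are pooled by
#' default; `side` restricts to healthy- or disease-enriched OTUs.
#'
#' @param results Named list of `da_result` objects, the comparisons of
#'   one disease.
#' @param taxonomy A `taxonomy_map`.
#' @param alpha Adjusted-p significance threshold.
#' @param counting `"unique"` or `"weighted"`.
#' @param side `"both"`, `"healthy"`, or `"disease"`.
#' @return Data frame with columns `genus`, `total_otus`,
#'   `dysbiotic_otus`.
#' @export
genus_diversity_records <- function(results, taxonomy, alpha = 0.05,
                                    counting = c("unique", "weighted"),
                                    side = c("both", "healthy", "disease")) {
  counting <- match.arg(counting)
  side <- match.arg(side)
  all_ids <- unique(unlist(lapply(results, `[[`, "otu_id")))
  by_genus <- reduce_to_genus(all_ids, taxonomy)
  sig_ids <- lapply(results, function(res) {
    s <- !is.na(res$p_adj) & res$p_adj < alpha
    s <- s & switch(side,
                    both = res$log2fc != 0,
                    healthy = res$log2fc < 0,
                    disease = res$log2fc > 0)
    res$otu_id[s]
  })
  dys <- vapply(by_genus, function(ids) {
    if (counting == "unique") {
      length(intersect(ids, unique(unlist(sig_ids))))
    } else {
      sum(vapply(sig_ids, function(s) length(intersect(ids, s)), numeric(1L)))
    }
  }, numeric(1L))
  data.frame(genus = names(by_genus),
             total_otus = lengths(by_genus),
             dysbiotic_otus = as.numeric(dys),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman correlation of genus diversity with dysbiotic-OTU count
#'
#' Rank correlation (average ranks for ties) of the total number of OTUs
#' per genus against the number of dysbiotic OTUs per genus, with the
#' p-value from the large-sample t approximation. A significant positive
#' correlation indicates dysbiosis is driven partly by genus-level OTU
#' richness.
#'
#' @param records Data frame from [genus_diversity_records] (>= 4 genera).
#' @return List with `rho` and `p_value`.
#' @export
spearman_diversity_corr <- function(records) {
  if (nrow(records) < 4L) stop("need at least 4 genera")
  if (stats::sd(records$total_otus) == 0 || stats::sd(records$dysbiotic_otus) == 0)
    stop("correlation undefined: constant vector")
  ht <- suppressWarnings(
    stats::cor.test(records$total_otus, records$dysbiotic_otus,
                    method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Flag genera dysbiotic beyond their diversity expectation (three-sigma)
#'
#' The expected dysbiotic-OTU count is the fitted value of an ordinary
#' least-squares line of `dysbiotic_otus` on `total_otus`; the residual
#' standard deviation uses `n - 2` degrees of freedom. A genus is flagged
#' as highly associated with dysbiosis when its residual exceeds three
#' residual standard deviations *above* the line (one-sided; genera far
#' below the line are never flagged).
#'
#' @param records Data frame from [genus_diversity_records] (>= 4 genera).
#' @param model `"ols"` (default, free intercept), `"zero_intercept"`, or
#'   `"robust"` (least absolute deviations via iterated reweighting; the
#'   residual scale is then 1.4826 * MAD).
#' @return `records` with added columns `expected`, `residual_sd_units`,
#'   `flagged`.
#' @export
three_sigma_flags <- function(records, model = c("ols", "zero_intercept", "robust")) {
  model <- match.arg(model)
  if (nrow(records) < 4L) stop("need at least 4 genera")
  x <- records$total_otus; y <- records$dysbiotic_otus
  if (model == "ols") {
    fit <- stats::lm(y ~ x)
    expected <- stats::fitted(fit)
    s <- sqrt(sum(stats::residuals(fit)^2) / (length(y) - 2L))
  } else if (model == "zero_intercept") {
    fit <- stats::lm(y ~ x + 0)
    expected <- stats::fitted(fit)
    s <- sqrt(sum(stats::residuals(fit)^2) / (length(y) - 1L))
  } else {
    med_fit <- stats::lm(y ~ x)  # init; reweight toward L1
    for (i in 1:25) {
      wres <- pmax(abs(stats::residuals(med_fit)), 1e-6)
      med_fit <- stats::lm(y ~ x, weights = 1 / wres)
    }
    expected <- stats::fitted(med_fit)
    s <- stats::mad(y - expected)
  }
  res <- y - expected
  if (s == 0) {
    warning("zero residual variance: no genera flagged")
    records$expected <- expected
    records$residual_sd_units <- 0
    records$flagged <- FALSE
    return(records)
  }
  records$expected <- as.numeric(expected)
  records$residual_sd_units <- res / s
  records$flagged <- records$residual_sd_units > 3
  records
}
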