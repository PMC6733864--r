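#' 2x2 disease-by-antibiotic contingency table
#'
#' Rows are disease / healthy, columns antibiotic / no antibiotic:
#' `a` = disease with antibiotics, `b` = disease without, `c` = healthy
#' with, `d` = healthy without.
#'
#' @param a,b,c,d Non-negative integer cell counts (total > 0).
#' @return Integer 2x2 matrix with dimnames.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  matrix(as.integer(cells), nrow = 2L, byrow = TRUE,
         dimnames = list(c("disease", "healthy"), c("abx", "no_abx")))
}

#' Relative risk of antibiotic use in disease versus healthy
#'
#' `rr = [a/(a+b)] / [c/(c+d)]` with a 95% confidence interval from the
#' log-normal approximation
#' `exp(log(rr) +- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' With no exposed healthy individuals (`c = 0`) the ratio is infinite and
#' the interval is undefined; the record is flagged.
#'
#' @param t A 2x2 matrix from [contingency_2x2].
#' @return List with `rr`, `ci_low`, `ci_high`, `flagged`.
#' @export
relative_risk <- function(t) {
  a <- t[1L, 1L]; b <- t[1L, 2L]; c_ <- t[2L, 1L]; d <- t[2L, 2L]
  if (a + b == 0 || c_ + d == 0) stop("both row totals must be positive")
  if (c_ == 0)
    return(list(rr = Inf, ci_low = NA_real_, ci_high = NA_real_, flagged = TRUE))
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  if (a == 0)
    return(list(rr = 0, ci_low = NA_real_, ci_high = NA_real_, flagged = TRUE))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  list(rr = rr,
       ci_low = exp(log(rr) - 1.96 * se),
       ci_high = exp(log(rr) + 1.96 * se),
       flagged = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on the observed margins, the p-value is the total
#' hypergeometric probability of all tables whose probability does not
#' exceed that of the observed table (the probability-mass rule, not tail
#' doubling).
#'
#' @param t A 2x2 matrix from [contingency_2x2].
#' @return Two-sided p-value in `[0,1]`.
#' @export
fisher_exact <- function(t) {
  stats::fisher.test(t, alternative = "two.sided")$p.value
}

#' Holm step-down adjusted p-values
#'
#' @param p_values Numeric vector in `[0,1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_correct <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Antibiotic-disease association across a sample frame
#'
#' For every disease state, builds the 2x2 table of antibiotic use in the
#' last year against the healthy samples (listwise-excluding samples with
#' missing antibiotic metadata), computes the relative risk with its 95%
#' interval and a post-hoc Fisher's exact test, then Holm-corrects across
#' all diseases in the run. Significance stars mirror `p < 0.05 / 0.01 /
#' 0.001` on the corrected values.
#'
#' @param samples A `sample_frame` containing `"healthy"` plus at least
#'   one disease label in `health_status`.
#' @return Data frame, one row per disease: cells `a`..`d`, `rr`,
#'   `ci_low`, `ci_high`, `p_value`, `p_holm`, `stars`.
#' @export
antibiotic_association <- function(samples) {
  ok <- !is.na(samples$antibiotic_last_year)
  samples <- samples[ok, , drop = FALSE]
  healthy <- samples[samples$health_status == "healthy", , drop = FALSE]
  if (!nrow(healthy)) stop("no healthy samples with antibiotic metadata")
  diseases <- setdiff(unique(samples$health_status),
                      c("healthy", "stochastic_1", "stochastic_2"))
  if (!length(diseases)) stop("no disease samples")
  rows <- lapply(diseases, function(dis) {
    d <- samples[samples$health_status == dis, , drop = FALSE]
    t <- contingency_2x2(sum(d$antibiotic_last_year),
                         sum(!d$antibiotic_last_year),
                         sum(healthy$antibiotic_last_year),
                         sum(!healthy$antibiotic_last_year))
    rr <- relative_risk(t)
    data.frame(disease = dis, a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2],
               rr = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
               p_value = fisher_exact(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_correct(out$p_value)
  out$stars <- ifelse(out$p_holm < 0.001, "***",
                      ifelse(out$p_holm < 0.01, "**",
                             ifelse(out$p_holm < 0.05, "*", "")))
  rownames(out) <- NULL
  out
}
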