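#' Assign uniform random numbers to samples
#'
#' Attaches a `random_number` column of uniform `[0,1)` draws, unique
#' within each cohort (collisions are re-drawn so the rank-block
#' subdivision rule always has a strict order). Deterministic under
#' `seed`.
#'
#' @param samples A `sample_frame`.
#' @param seed Integer seed.
#' @return The sample frame with `random_number` filled.
#' @export
assign_random_numbers <- function(samples, seed) {
  withr::with_seed(seed, {
    r <- stats::runif(nrow(samples))
    for (coh in unique(samples$cohort_id)) {
      idx <- which(samples$cohort_id == coh)
      while (anyDuplicated(r[idx])) {
        dup <- idx[duplicated(r[idx])]
        r[dup] <- stats::runif(length(dup))
      }
    }
    samples$random_number <- r
  })
  samples
}

#' Subdivide one health status into independent populations
#'
#' Samples are ordered by their assigned random numbers and cut into
#' disjoint rank blocks (lowest `subset_size`, middle, highest, ...).
#' When fewer than `subset_size * n_subsets` samples are available the
#' number of subsets shrinks to what fits (a status with only
#' `subset_size` samples yields exactly one subset); fewer than one
#' block's worth is a design error.
#'
#' @param samples A `sample_frame` restricted to one health status, with
#'   `random_number` assigned.
#' @param subset_size Samples per subset.
#' @param n_subsets Maximum number of subsets.
#' @return List of character vectors of sample ids, one per subset.
#' @export
subdivide <- function(samples, subset_size = 100, n_subsets = 3) {
  if (is.null(samples$random_number) || anyNA(samples$random_number))
    stop("samples must carry assigned random numbers")
  n_fit <- floor(nrow(samples) / subset_size)
  k <- min(n_subsets, n_fit)
  if (k < 1L)
    stop("design error: ", nrow(samples), " samples cannot fill one subset of ",
         subset_size)
  ord <- order(samples$random_number)
  lapply(seq_len(k), function(i) {
    samples$sample_id[ord[((i - 1L) * subset_size + 1L):(i * subset_size)]]
  })
}

#' Assign stochastic group labels independent of metadata
#'
#' Draws fresh random numbers (ignoring all real metadata) and splits the
#' samples into stochastic groups 1 and 2, each subdivided into rank-block
#' subsets exactly as real health statuses are: the lowest
#' `n_subsets * subset_size` ranks become group 1's subsets, the next
#' block group 2's. These groups serve as the null for every dysbiosis
#' metric.
#'
#' @param samples A `sample_frame`.
#' @param subset_size Samples per subset.
#' @param n_subsets Subsets per stochastic group.
#' @param seed Integer seed (independent of the one used for real
#'   subdivisions).
#' @return List with elements `stochastic_1` and `stochastic_2`, each a
#'   list of sample-id subsets.
#' @export
make_stochastic_groups <- function(samples, subset_size = 100, n_subsets = 3,
                                   seed) {
  if (nrow(samples) < 2 * subset_size)
    stop("design error: need at least 2 * subset_size samples for stochastic groups")
  n_sub <- min(n_subsets, floor(nrow(samples) / (2 * subset_size)))
  relab <- assign_random_numbers(samples, seed)
  ord <- order(relab$random_number)
  block <- function(i) {
    relab$sample_id[ord[((i - 1L) * subset_size + 1L):(i * subset_size)]]
  }
  list(stochastic_1 = lapply(seq_len(n_sub), block),
       stochastic_2 = lapply(n_sub + seq_len(n_sub), block))
}

#' Enumerate pairwise comparisons between population subsets
#'
#' Two designs are supported. `"cross"` compares every group-1 subset with
#' every group-2 subset (three healthy by three disease subsets give nine
#' comparisons; three by one gives three), the design used when all
#' samples come from one source. `"study"` pairs subsets positionally,
#' one comparison per study, the design used when each study contributed
#' its own healthy and disease samples.
#'
#' @param group1_subsets,group2_subsets Lists of sample-id vectors
#'   (group 1 = healthy or stochastic group 1).
#' @param disease Label recorded on each comparison.
#' @param design `"cross"` or `"study"`.
#' @param cohort Cohort provenance string.
#' @return A `comparison_plan`: list of comparisons, each with
#'   `comparison_id`, `disease`, `cohort`, `group1`, `group2`.
#' @export
enumerate_comparisons <- function(group1_subsets, group2_subsets, disease,
                                  design = c("cross", "study"),
                                  cohort = "cohort1") {
  design <- match.arg(design)
  if (design == "cross") {
    pairs <- expand.grid(h = seq_along(group1_subsets),
                         d = seq_along(group2_subsets))
  } else {
    if (length(group1_subsets) != length(group2_subsets))
      stop("study design requires matched subset lists")
    pairs <- data.frame(h = seq_along(group1_subsets),
                        d = seq_along(group2_subsets))
  }
  plan <- lapply(seq_len(nrow(pairs)), function(i) {
    h <- pairs$h[i]; d <- pairs$d[i]
    g1 <- group1_subsets[[h]]; g2 <- group2_subsets[[d]]
    if (length(intersect(g1, g2)))
      stop("comparison groups overlap for ", disease)
    list(comparison_id = sprintf("%s_h%d_d%d", disease, h, d),
         disease = disease, cohort = cohort, group1 = g1, group2 = g2)
  })
  class(plan) <- "comparison_plan"
  plan
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat(sprintf("Comparison plan: %d comparisons (%s)\n", length(x),
              paste(unique(vapply(x, `[[`, "", "disease")), collapse = ", ")))
  invisible(x)
}

#' Serialise a comparison plan to JSON
#' @param plan A `comparison_plan`.
#' @param path Output path.
#' @export
write_comparison_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
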