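#' Weighted UniFrac distances
#'
#' For each pair of samples the raw weighted UniFrac distance is
#' `sum_i b_i * |p_i(A) - p_i(B)|` over tree branches `i` with length
#' `b_i`, where `p_i(X)` is the proportion of sample `X`'s counts
#' descending through branch `i`; the normalised variant divides by
#' `sum_i b_i * (p_i(A) + p_i(B))` and lies in `[0,1]`.
#'
#' Branch proportions are computed on relative abundances by default;
#' `normalization = "size_factor"` uses median-of-ratios-normalised counts
#' instead (the result is then not bounded by 1 for the raw variant).
#'
#' @param table An [otu_table]; every OTU with nonzero counts must be a
#'   tip of `tree`, and every sample must have a positive total.
#' @param tree A rooted `phylo` tree with non-negative branch lengths.
#' @param variant `"normalized"` (default) or `"raw"`.
#' @param normalization `"relative"` or `"size_factor"`.
#' @return A symmetric `dist`-convertible matrix with zero diagonal and
#'   the table's sample ids.
#' @export
weighted_unifrac <- function(table, tree,
                             variant = c("normalized", "raw"),
                             normalization = c("relative", "size_factor")) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  m <- unclass(table)
  if (any(rowSums(m) == 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  present <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry non-negative branch lengths")

  w <- if (normalization == "relative") {
    sweep(m, 1L, rowSums(m), "/")
  } else {
    sw <- sweep(m, 1L, estimate_size_factors(table), "/")
    sweep(sw, 1L, rowSums(sw), "/")
  }

  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  ## accumulate clade mass per (node, sample)
  mass <- matrix(0, nrow = n_node, ncol = nrow(m))
  idx <- match(tr$tip.label, colnames(w))
  has <- !is.na(idx)
  mass[which(has), ] <- t(w[, idx[has], drop = FALSE])
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    mass[par, ] <- mass[par, ] + mass[child, ]
  }
  P <- mass[tr$edge[, 2L], , drop = FALSE] * tr$edge.length  # b_i * p_i per edge
  d_raw <- as.matrix(stats::dist(t(P), method = "manhattan"))
  if (variant == "raw") {
    dimnames(d_raw) <- list(rownames(m), rownames(m))
    return(d_raw)
  }
  tot <- colSums(P)  # sum_i b_i p_i(X)
  denom <- outer(tot, tot, "+")
  d <- ifelse(denom > 0, d_raw / denom, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and keeps the components
#' with positive eigenvalues sorted descending; for Euclidean-embeddable
#' distance matrices the coordinates reproduce the distances. Negative
#' eigenvalues are dropped with a warning.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return List with `coordinates` (samples x axes) and `eigenvalues`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (all(dm == 0))
    return(list(coordinates = matrix(0, n, 1L, dimnames = list(rownames(dm), "PC1")),
                eigenvalues = 0))
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE))
  eig <- cs$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  keep <- which(eig > max(abs(eig)) * 1e-10)
  keep <- keep[keep <= ncol(cs$points)]
  coords <- cs$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(keep))
  list(coordinates = coords, eigenvalues = eig[keep])
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' `[SS_between/(a-1)] / [SS_within/(N-a)]` from the Gower-centred squared
#' distance matrix, with the p-value `(1 + #{permuted F >= observed}) /
#' (1 + n_perm)` under free permutation of sample labels. The permutation
#' engine is vegan's `adonis2`; results are deterministic under `seed`.
#'
#' @param d Symmetric distance matrix with sample ids.
#' @param labels Group label per sample; at least two groups, each with at
#'   least two samples.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `pseudo_f`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (length(labels) != nrow(dm)) stop("one label per sample required")
  if (nlevels(droplevels(labels)) < 2L)
    stop("at least two groups are required")
  if (any(table(labels) < 2L))
    stop("each group needs at least 2 samples")
  df <- data.frame(group = labels)
  fit <- withr::with_seed(seed,
    vegan::adonis2(stats::as.dist(dm) ~ group, data = df,
                   permutations = n_perm))
  list(pseudo_f = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
       n_permutations = n_perm)
}
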