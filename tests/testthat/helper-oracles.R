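# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately re-derive each
# quantity from its definition rather than calling the code under test.

## Benjamini-Hochberg step-up from the definition:
## p_adj(i) = min over j with rank(j) >= rank(i) of min(1, m * p(j) / rank(j))
brute_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(rk >= rk[i])
    min(1, min(m * p[js] / rk[js]))
  }, numeric(1))
}

## Holm step-down from the definition:
## sorted ascending, adj(i) = min(1, max_{j <= i} (m - j + 1) * p(j))
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, (m - j + 1) * p[o[j]])
    adj_sorted[j] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

## Two-sided Fisher p by hypergeometric enumeration with fixed margins
brute_fisher <- function(t) {
  a <- t[1, 1]
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Weighted UniFrac by explicit per-branch enumeration of descendant tips
brute_unifrac <- function(table, tree, variant = "normalized") {
  m <- unclass(table)
  w <- sweep(m, 1, rowSums(m), "/")
  n_tip <- length(tree$tip.label)
  descendants <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendants))
  }
  branch_p <- function(samp) {
    vapply(seq_len(nrow(tree$edge)), function(e) {
      tips <- descendants(tree$edge[e, 2])
      sum(w[samp, intersect(tips, colnames(w))])
    }, numeric(1))
  }
  P <- t(vapply(rownames(m), branch_p, numeric(nrow(tree$edge))))
  b <- tree$edge.length
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
    num <- sum(b * abs(P[i, ] - P[j, ]))
    if (variant == "raw") d[i, j] <- num
    else {
      den <- sum(b * (P[i, ] + P[j, ]))
      d[i, j] <- if (den > 0) num / den else 0
    }
  }
  d
}

## PERMANOVA pseudo-F from the sums-of-squares definition
pseudo_f_oracle <- function(d, labels) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  labels <- as.factor(labels)
  a <- nlevels(labels)
  ss_t <- sum(dm[upper.tri(dm)]) / n
  ss_w <- sum(vapply(levels(labels), function(l) {
    idx <- which(labels == l)
    sum(dm[idx, idx][upper.tri(dm[idx, idx])]) / length(idx)
  }, numeric(1)))
  ss_b <- ss_t - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

## Exact permutation p-value over all distinct two-group splits
permanova_enumerate <- function(d, labels) {
  labels <- as.factor(labels)
  idx1 <- which(labels == levels(labels)[1])
  n <- length(labels)
  f_obs <- pseudo_f_oracle(d, labels)
  splits <- combn(n, length(idx1))
  fs <- apply(splits, 2, function(s) {
    l <- rep(levels(labels)[2], n)
    l[s] <- levels(labels)[1]
    pseudo_f_oracle(d, l)
  })
  mean(fs >= f_obs - 1e-12)
}

## Small deterministic OTU table fixture
toy_table <- function(counts, samples = NULL, otus = NULL) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otus)) otus <- paste0("OTU", seq_len(ncol(counts)))
  dimnames(counts) <- list(samples, otus)
  otu_table(counts)
}

## Minimal da_result builder for summary-stage tests
fake_da <- function(otu_id, log2fc, p_adj) {
  structure(data.frame(otu_id = otu_id, base_mean = 1, log2fc = log2fc,
                       lfcse = 1, wald_stat = log2fc, p_value = p_adj,
                       p_adj = p_adj, stringsAsFactors = FALSE),
            class = c("da_result", "data.frame"))
}

## Greengenes-style taxonomy for OTUs named OTU<i>, genus chosen per OTU
fake_taxonomy <- function(otu_id, genus) {
  lin <- ifelse(is.na(genus),
                "k__Bacteria; p__P; c__C; o__O; f__F; g__; s__",
                sprintf("k__Bacteria; p__P; c__C; o__O; f__F; g__%s; s__", genus))
  taxonomy_map(setNames(lin, otu_id))
}
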