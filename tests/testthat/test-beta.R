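star2 <- function() {
  ape::read.tree(text = "(OTU1:1,OTU2:1);")
}

test_that("weighted UniFrac fundamentals: identity, disjoint tips, bounds", {
  tab <- toy_table(rbind(c(5, 5), c(5, 5), c(10, 0), c(0, 10)))
  d <- weighted_unifrac(tab, star2())
  expect_equal(d["S1", "S2"], 0)
  # fully disjoint communities on a two-tip star are at normalised distance 1
  expect_equal(d["S3", "S4"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("a three-tip caterpillar matches the per-branch oracle", {
  tree <- ape::read.tree(text = "((OTU1:0.3,OTU2:0.7):0.5,OTU3:1.2);")
  tab <- toy_table(rbind(c(8, 2, 0), c(1, 1, 8), c(3, 3, 4)))
  for (variant in c("normalized", "raw")) {
    mine <- weighted_unifrac(tab, tree, variant = variant)
    oracle <- brute_unifrac(tab, tree, variant = variant)
    expect_equal(unclass(mine), oracle, tolerance = 1e-12)
  }
})

test_that("random small trees agree with the brute-force oracle", {
  withr::with_seed(61, {
    for (i in 1:10) {
      n_tip <- sample(3:5, 1)
      tree <- ape::rcoal(n_tip, tip.label = paste0("OTU", 1:n_tip))
      m <- matrix(rpois(4 * n_tip, 20) + 1L, nrow = 4)
      tab <- toy_table(m, otus = paste0("OTU", 1:n_tip))
      expect_equal(unclass(weighted_unifrac(tab, tree)),
                   brute_unifrac(tab, tree), tolerance = 1e-12)
    }
  })
})

test_that("weighted UniFrac agrees with phyloseq on a fixture", {
  skip_if_not_installed("phyloseq")
  withr::with_seed(62, {
    tree <- ape::rcoal(12, tip.label = paste0("OTU", 1:12))
    m <- matrix(rnbinom(8 * 12, mu = 40, size = 1), nrow = 8)
    m[m == 0] <- 1L
    tab <- toy_table(m, otus = paste0("OTU", 1:12))
    mine <- weighted_unifrac(tab, tree)
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(unclass(tab), taxa_are_rows = FALSE), tree)
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
    expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-8)
  })
})

test_that("grafting a zero-length branch leaves distances unchanged", {
  tree <- ape::read.tree(text = "((OTU1:0.3,OTU2:0.7):0.5,OTU3:1.2);")
  # insert a zero-length internal branch carrying an absent zero-mass tip
  grafted <- ape::read.tree(
    text = "((OTU1:0.3,OTU2:0.7):0.5,(OTU3:1.2,OTUX:0.0):0.0);")
  tab <- toy_table(rbind(c(8, 2, 1), c(1, 1, 8)))
  expect_equal(unclass(weighted_unifrac(tab, tree)),
               unclass(weighted_unifrac(tab, grafted)), tolerance = 1e-12)
})

test_that("UniFrac validates its inputs", {
  tab <- toy_table(rbind(c(1, 2, 3), c(0, 0, 0)))
  expect_error(weighted_unifrac(tab, star2()), "zero-total")
  tab2 <- toy_table(rbind(c(1, 2, 3), c(2, 2, 2)))
  expect_error(weighted_unifrac(tab2, star2()), "OTU3")
})

test_that("PCoA reproduces simple geometries", {
  # two samples at distance d embed at +-d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-1.5, 1.5))
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-10)
  expect_length(p3$eigenvalues, 2)
  # pairwise distances are reproduced for Euclidean-embeddable input
  expect_equal(as.matrix(dist(p3$coordinates)), d3, tolerance = 1e-10,
               ignore_attr = TRUE)
  # degenerate all-zero matrix embeds at the origin
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(d0)$coordinates == 0))
})

test_that("PERMANOVA matches exhaustive enumeration at n = 6", {
  withr::with_seed(63, {
    coords <- matrix(rnorm(12), ncol = 2)
    coords[1:3, 1] <- coords[1:3, 1] + 2
    d <- as.matrix(dist(coords))
    dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
    labels <- rep(c("a", "b"), each = 3)
    exact_p <- permanova_enumerate(d, labels)
    res <- permanova(d, labels, n_perm = 999, seed = 5)
    expect_equal(res$pseudo_f, pseudo_f_oracle(d, labels), tolerance = 1e-10)
    expect_lt(abs(res$p_value - exact_p), 3 / (999 + 1))
    expect_gte(res$p_value, 1 / (999 + 1))
  })
})

test_that("PERMANOVA is deterministic under seed and validates groups", {
  withr::with_seed(64, {
    d <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
    dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
    labels <- rep(c("x", "y"), 5)
    a <- permanova(d, labels, n_perm = 99, seed = 7)
    b <- permanova(d, labels, n_perm = 99, seed = 7)
    expect_identical(a, b)
    # p-value invariant to monotone relabeling of groups
    relab <- ifelse(labels == "x", "zzz", "aaa")
    c <- permanova(d, relab, n_perm = 99, seed = 7)
    expect_equal(a$pseudo_f, c$pseudo_f)
    expect_error(permanova(d, rep("one", 10)), "two groups")
    expect_error(permanova(d, c(rep("a", 9), "b")), "at least 2 samples")
  })
})
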