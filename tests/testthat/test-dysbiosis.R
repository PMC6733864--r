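test_that("fold difference and its plotting transform are correct", {
  r <- fold_difference(10, 5)
  expect_equal(r$fold_difference, 2); expect_equal(r$plot_value, 2)
  r <- fold_difference(5, 10)
  expect_equal(r$fold_difference, 0.5); expect_equal(r$plot_value, -2)
  r <- fold_difference(7, 7)
  expect_equal(r$fold_difference, 1); expect_equal(r$plot_value, 1)
  # reciprocal pairs multiply to one
  for (p in list(c(3, 9), c(12, 5), c(1, 1))) {
    expect_equal(fold_difference(p[1], p[2])$fold_difference *
                   fold_difference(p[2], p[1])$fold_difference, 1)
  }
})

test_that("zero denominators follow the configured rule", {
  sub <- fold_difference(8, 0, zero_rule = "substitute")
  expect_equal(sub$fold_difference, 8)
  expect_true(sub$flagged)
  exc <- fold_difference(8, 0, zero_rule = "exclude")
  expect_true(is.na(exc$fold_difference))
  both <- fold_difference(0, 0)
  expect_true(is.na(both$fold_difference) && both$flagged)
})

test_that("the one-sample t-test against 1 matches the closed form", {
  recs <- rbind(
    cbind(fold_difference(3, 2, "a1"), disease = "a"),
    cbind(fold_difference(5, 2, "a2"), disease = "a"),
    cbind(fold_difference(4, 2, "a3"), disease = "a"))
  # values 1.5, 2.5, 2.0: t = (2 - 1) / (0.5 / sqrt(3))
  out <- test_fold_bias(recs)
  expect_equal(out$t_stat, (2 - 1) / (0.5 / sqrt(3)), tolerance = 1e-10)
  expect_equal(out$p_value, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-10)
  expect_equal(out$mean_fold, 2)
})

test_that("degenerate fold-difference sets are handled explicitly", {
  ones <- do.call(rbind, lapply(1:3, function(i)
    cbind(fold_difference(4, 4, paste0("c", i)), disease = "null_like")))
  out <- test_fold_bias(ones)
  expect_equal(out$t_stat, 0); expect_equal(out$p_value, 1)

  const <- do.call(rbind, lapply(1:3, function(i)
    cbind(fold_difference(6, 3, paste0("c", i)), disease = "deg")))
  out2 <- test_fold_bias(const)
  expect_equal(out2$p_value, 0)
  expect_true(out2$degenerate)
})

test_that("Holm correction spans the diseases in one run", {
  recs <- do.call(rbind, lapply(c("a", "b"), function(d) {
    do.call(rbind, lapply(1:4, function(i)
      cbind(fold_difference(10 + i * as.integer(d == "a"), 5, paste0(d, i)),
            disease = d)))
  }))
  out <- test_fold_bias(recs)
  expect_equal(out$p_holm, holm_correct(out$p_value))
})

test_that("genus presence proportions count comparisons with any hit", {
  tax <- fake_taxonomy(paste0("O", 1:6),
                       c("A", "A", "B", "B", "C", NA))
  # 9 comparisons for one disease; genus A hit on healthy side in 1,3,5
  results <- setNames(lapply(1:9, function(i) {
    hit_a <- i %in% c(1, 3, 5)
    fake_da(paste0("O", 1:6),
            log2fc = c(-1, 1 * (!hit_a), -2, -2, 2, -3),
            p_adj  = c(ifelse(hit_a, 0.01, 0.5), 0.5, 0.01, 0.01, 0.01, 0.01))
  }), paste0("cmp", 1:9))
  diseases <- setNames(rep("cvd", 9), names(results))
  gp <- genus_presence(results, diseases, tax, alpha = 0.05)
  expect_equal(gp$enriched_in_healthy["cvd", "A"], 3 / 9)
  expect_equal(gp$enriched_in_healthy["cvd", "B"], 1)     # hit in all 9
  expect_equal(gp$enriched_in_disease["cvd", "C"], 1)
  # unclassified O6 never appears; a genus with no signal is pruned
  expect_false("NA" %in% colnames(gp$enriched_in_healthy))
  expect_equal(gp$n_comparisons[["cvd"]], 9)
})

test_that("the AU fit reproduces its closed-form anchor points", {
  scales <- seq(0.5, 1.4, by = 0.1)
  # bp = 0.5 at every scale: v = c = 0 so AU = 0.5 exactly
  expect_equal(dysbiome:::fit_au(rep(0.5, 10), scales, 1000), 0.5)
  # unanimous support at every scale is degenerate: AU = 1
  expect_equal(dysbiome:::fit_au(rep(1, 10), scales, 1000), 1)
  expect_equal(dysbiome:::fit_au(rep(0, 10), scales, 1000), 0)
})

test_that("duplicated rows co-cluster with near-certain bootstrap support", {
  withr::with_seed(71, {
    m <- matrix(runif(5 * 30), nrow = 5,
                dimnames = list(paste0("dz", 1:5), paste0("g", 1:30)))
    m[2, ] <- m[1, ]  # exact duplicates
    cl <- cluster_with_support(m, n_boot = 200, seed = 8)
    pair <- cl$support[cl$support$leaves == "dz1,dz2", ]
    expect_equal(nrow(pair), 1)
    expect_gte(pair$bp, 0.99)
    expect_gte(pair$au, 0.95)
    expect_true(all(cl$support$bp >= 0 & cl$support$bp <= 1))
    expect_true(all(cl$support$au >= 0 & cl$support$au <= 1))
  })
})

test_that("cluster support is invariant to input row order", {
  withr::with_seed(72, {
    m <- matrix(runif(4 * 20), nrow = 4,
                dimnames = list(paste0("r", 1:4), paste0("g", 1:20)))
    a <- cluster_with_support(m, n_boot = 100, seed = 3)
    b <- cluster_with_support(m[c(3, 1, 4, 2), ], n_boot = 100, seed = 3)
    key <- function(cl) cl$support[order(cl$support$leaves), c("leaves", "bp", "au")]
    ka <- key(a); kb <- key(b)
    expect_equal(ka$leaves, kb$leaves)
    # bootstrap column draws differ in order, so supports agree statistically
    expect_lt(max(abs(ka$bp - kb$bp)), 0.15)
  })
})

test_that("clustering refuses fewer than three rows and writes outputs", {
  m <- matrix(runif(10), nrow = 2)
  expect_error(cluster_with_support(m), "at least 3")
  withr::with_seed(73, {
    m5 <- matrix(runif(5 * 12), nrow = 5,
                 dimnames = list(paste0("d", 1:5), paste0("g", 1:12)))
    cl <- cluster_with_support(m5, n_boot = 50, seed = 2)
    prefix <- file.path(withr::local_tempdir(), "dendro")
    write_cluster_support(cl, prefix)
    expect_true(file.exists(paste0(prefix, ".nwk")))
    tree <- ape::read.tree(paste0(prefix, ".nwk"))
    expect_setequal(tree$tip.label, paste0("d", 1:5))
  })
})
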