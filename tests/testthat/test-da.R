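test_that("size factors recover exact depth scaling", {
  base <- c(10, 20, 30, 40)
  tab <- toy_table(rbind(base, 2 * base))
  sf <- estimate_size_factors(tab)
  expect_equal(unname(sf[2] / sf[1]), 2)

  same <- toy_table(rbind(base, base, base))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))
})

test_that("size factors match the hand-computed median-of-ratios toy", {
  # 3 samples, 2 OTUs: geometric means 4 and 8; ratios give 1, 2, 0.5
  tab <- toy_table(rbind(c(4, 8), c(8, 16), c(2, 4)))
  expect_equal(unname(estimate_size_factors(tab)), c(1, 2, 0.5))
})

test_that("size factors agree with DESeq2 on a dense table", {
  skip_if_not_installed("DESeq2")
  co <- simulate_cohort(simulation_config(
    n_samples_per_group = 15, n_otus = 80, n_genera = 15,
    depth_log_mean = log(8000), seed = 21))
  m <- unclass(co$table)
  dense <- m[, colSums(m > 0) == nrow(m), drop = FALSE]
  skip_if(ncol(dense) < 5)
  tab <- otu_table(dense)
  mine <- estimate_size_factors(tab)
  ref <- DESeq2::estimateSizeFactorsForMatrix(t(dense))
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
})

test_that("a sample with all-zero counts is reported by name", {
  tab <- toy_table(rbind(c(1, 2), c(0, 0)), samples = c("good", "empty"))
  expect_error(estimate_size_factors(tab), "empty")
})

test_that("dispersion estimates behave under Poisson, NB, and constant data", {
  withr::with_seed(31, {
    pois <- toy_table(matrix(rpois(400 * 50, lambda = 100), nrow = 400))
    a <- estimate_dispersion(pois, rep(1, 400))
    expect_lt(median(a), 0.02)

    nb <- toy_table(matrix(rnbinom(200 * 60, mu = 100, size = 2), nrow = 200))
    a2 <- estimate_dispersion(nb, rep(1, 200))
    expect_gt(median(a2), 0.35); expect_lt(median(a2), 0.65)
  })
  const <- toy_table(matrix(7L, nrow = 10, ncol = 3))
  expect_equal(unname(estimate_dispersion(const, rep(1, 10))), rep(1e-8, 3))
})

test_that("identical groups give zero fold change and p = 1", {
  block <- rbind(c(5, 50, 500), c(10, 40, 400), c(20, 60, 300))
  tab <- toy_table(rbind(block, block))
  res <- nb_wald_test(tab, rep(c("g1", "g2"), each = 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_true(all(res$lfcse > 0))
})

test_that("the Wald fit matches a fixed-dispersion NB GLM", {
  skip_if_not_installed("MASS")
  withr::with_seed(41, {
    n <- 30
    sf <- exp(rnorm(2 * n, 0, 0.3))
    grp <- rep(c(0, 1), each = n)
    mu <- sf * 50 * 2^(grp * 1.2)
    y <- rnbinom(2 * n, mu = mu, size = 1 / 0.4)
    tab <- toy_table(matrix(y, ncol = 1))
    res <- nb_wald_test(tab, factor(grp), size_factors = setNames(sf, sample_ids(tab)),
                        dispersions = c(OTU1 = 0.4))
    fit <- stats::glm(y ~ grp + offset(log(sf)),
                      family = MASS::negative.binomial(theta = 1 / 0.4))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(res$log2fc, unname(co[2, 1]) / log(2), tolerance = 1e-6)
    expect_equal(res$lfcse, unname(co[2, 2]) / log(2), tolerance = 1e-6)
  })
})

test_that("a planted 4-fold depletion is recovered near log2fc = -2", {
  co <- simulate_cohort(simulation_config(
    n_samples_per_group = 50, n_otus = 100, n_genera = 20,
    frac_depleted_in_disease = 0.2, frac_enriched_in_disease = 0,
    effect_log2fc = 2, antibiotic_effect_log2fc = 0,
    depth_log_mean = log(10000), seed = 42))
  grp <- factor(co$samples$health_status, levels = c("healthy", "disease"))
  res <- nb_wald_test(co$table, grp)
  dep <- co$truth$otu$otu_id[co$truth$otu$dysbiotic_flag == "depleted"]
  est <- res$log2fc[res$otu_id %in% dep]
  expect_lt(abs(mean(est, na.rm = TRUE) + 2), 0.3)
  # and each estimate's CI typically covers the truth
  z <- (est + 2) / res$lfcse[res$otu_id %in% dep]
  expect_gt(mean(abs(z) < 1.96, na.rm = TRUE), 0.8)
})

test_that("the raw p-values are calibrated under the null", {
  withr::with_seed(43, {
    fracs <- vapply(1:10, function(i) {
      m <- matrix(rnbinom(40 * 50, mu = 60, size = 1 / 0.3), nrow = 40)
      res <- nb_wald_test(toy_table(m), rep(c("a", "b"), each = 20))
      mean(res$p_value < 0.05, na.rm = TRUE)
    }, numeric(1))
    expect_gt(mean(fracs), 0.02)
    expect_lt(mean(fracs), 0.08)
  })
})

test_that("swapping group labels negates fold changes, keeps p-values", {
  co <- simulate_cohort(simulation_config(
    n_samples_per_group = 20, n_otus = 50, n_genera = 10,
    depth_log_mean = log(4000), seed = 44))
  grp <- factor(co$samples$health_status, levels = c("healthy", "disease"))
  flipped <- factor(co$samples$health_status, levels = c("disease", "healthy"))
  a <- nb_wald_test(co$table, grp)
  b <- nb_wald_test(co$table, flipped)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-6)
  ca <- count_enriched(a); cb <- count_enriched(b)
  expect_equal(unname(ca), unname(rev(cb)))
})

test_that("size factors absorb a sample's depth change", {
  withr::with_seed(45, {
    m <- matrix(rnbinom(20 * 30, mu = 80, size = 4), nrow = 20)
    m2 <- m; m2[3, ] <- m2[3, ] * 5L
    grp <- rep(c("a", "b"), each = 10)
    sf1 <- estimate_size_factors(toy_table(m))
    sf2 <- estimate_size_factors(toy_table(m2))
    # the scaled sample's factor grows by exactly k relative to the others
    expect_equal(unname(sf2[3] / sf1[3]) / unname(sf2[1] / sf1[1]), 5,
                 tolerance = 1e-10)
    # with dispersions held fixed, the Wald statistics are essentially
    # unchanged (the NB likelihood re-weights scaled counts slightly, so
    # depth absorption through the offset is close but not an identity)
    disp <- estimate_dispersion(toy_table(m), sf1)
    r1 <- nb_wald_test(toy_table(m), grp, sf1, disp)
    r2 <- nb_wald_test(toy_table(m2), grp, sf2, disp)
    expect_gt(cor(r1$wald_stat, r2$wald_stat), 0.995)
    expect_lt(max(abs(r1$wald_stat - r2$wald_stat)), 0.15)
  })
})

test_that("rescaling all size factors by a constant is an exact no-op", {
  withr::with_seed(47, {
    m <- matrix(rnbinom(20 * 25, mu = 60, size = 3), nrow = 20)
    grp <- rep(c("a", "b"), each = 10)
    sf <- estimate_size_factors(toy_table(m))
    disp <- estimate_dispersion(toy_table(m), sf)
    r1 <- nb_wald_test(toy_table(m), grp, sf, disp)
    r2 <- nb_wald_test(toy_table(m), grp, 3 * sf, disp)
    expect_equal(r1$wald_stat, r2$wald_stat, tolerance = 1e-8)
    expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-8)
  })
})

test_that("Benjamini-Hochberg matches its step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0,1")
  withr::with_seed(46, {
    for (i in 1:25) {
      p <- runif(sample(1:12, 1))
      expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("enrichment counting respects threshold and sign", {
  res <- fake_da(paste0("O", 1:4), c(-2, 2, -1, 0.5),
                 c(0.01, 0.2, 0.04, 0.001))
  expect_equal(unname(count_enriched(res, 0.05)), c(2L, 1L))
  none <- fake_da("O1", -2, 0.9)
  expect_equal(unname(count_enriched(none)), c(0L, 0L))
})

test_that("all-zero OTUs carry absent statistics without failing", {
  m <- cbind(matrix(rpois(20, 50), nrow = 10), 0L)
  res <- suppressMessages(nb_wald_test(toy_table(m), rep(c("a", "b"), each = 5)))
  expect_true(is.na(res$p_value[3]))
  expect_false(anyNA(res$p_value[1:2]))
})
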