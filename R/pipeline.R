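#' Pipeline configuration
#'
#' Assembles the configuration for an end-to-end run: either simulation
#' mode (one synthetic cohort per named disease, each built from
#' [simulation_config] with per-disease overrides) or load mode (paths to
#' an OTU table, taxonomy, tree, and sample metadata). All seeds are
#' explicit so a run is fully deterministic.
#'
#' @param outdir Output directory.
#' @param diseases Simulation mode: named list of per-disease override
#'   lists for [simulation_config] (may be empty lists).
#' @param base Simulation mode: override list applied to every disease.
#' @param input Load mode: named list with paths `table`, `taxonomy`,
#'   `tree`, `samples` (any `tree = NULL` disables nothing; the beta stage
#'   fails if it needs a missing tree).
#' @param alpha Adjusted-p significance threshold for "differentially
#'   abundant".
#' @param min_total Low-count OTU filter threshold.
#' @param subset_size,n_subsets Population subdivision parameters.
#' @param seeds Named list of integer seeds: `simulation`, `subdivision`,
#'   `stochastic`, `bootstrap`, `permutation`.
#' @param n_boot,scales Cluster-support bootstrap parameters.
#' @param n_perm PERMANOVA permutations.
#' @param zero_rule Zero-denominator rule for [fold_difference].
#' @param run_beta Whether to run the beta-diversity stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            diseases = list(disease_A = list(),
                                            disease_B = list(),
                                            disease_C = list()),
                            base = list(),
                            input = NULL,
                            alpha = 0.05,
                            min_total = 10,
                            subset_size = 100,
                            n_subsets = 3,
                            seeds = list(simulation = 101, subdivision = 202,
                                         stochastic = 303, bootstrap = 404,
                                         permutation = 505),
                            n_boot = 1000,
                            scales = seq(0.5, 1.4, by = 0.1),
                            n_perm = 999,
                            zero_rule = "substitute",
                            run_beta = TRUE) {
  cfg <- as.list(environment())
  if (!is.null(input)) {
    needed <- c("table", "taxonomy", "samples")
    miss <- needed[!vapply(input[needed], function(p)
      !is.null(p) && file.exists(p), logical(1L))]
    if (length(miss))
      stop("load-mode input path(s) missing: ", paste(miss, collapse = ", "))
  }
  stopifnot(all(vapply(cfg$seeds, is.numeric, logical(1L))))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
}

prefix_ids <- function(cohort, prefix) {
  map <- function(x) paste0(prefix, "_", x)
  tab <- unclass(cohort$table)
  colnames(tab) <- map(colnames(tab))
  rownames(tab) <- map(rownames(tab))
  cohort$table <- otu_table(tab)
  cohort$taxonomy$otu_id <- map(cohort$taxonomy$otu_id)
  cohort$tree$tip.label <- map(cohort$tree$tip.label)
  cohort$samples$sample_id <- map(cohort$samples$sample_id)
  cohort$truth$otu$otu_id <- map(cohort$truth$otu$otu_id)
  cohort
}

## bind per-disease genus rows over the union of genus columns
merge_genus_rows <- function(rows) {
  genera <- sort(unique(unlist(lapply(rows, colnames))))
  out <- matrix(0, nrow = length(rows), ncol = length(genera),
                dimnames = list(names(rows), genera))
  for (d in names(rows)) out[d, colnames(rows[[d]])] <- rows[[d]][1L, ]
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full dysbiosis meta-analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), low-count
#' filtering, population subdivision with stochastic-label null groups,
#' per-comparison negative-binomial differential abundance, fold
#' difference summaries with one-sample t-tests, genus presence matrices
#' with bootstrap-supported clustering, diversity-adjusted three-sigma
#' genus flags, antibiotic-disease association, and weighted UniFrac /
#' PCoA / PERMANOVA beta diversity. Every stage writes its outputs under
#' `config$outdir`; a JSON manifest records file checksums, seeds, and
#' the package version, and is byte-identical across runs of one
#' configuration. A failing stage halts the pipeline with the stage
#' named; earlier outputs are retained.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "da"), showWarnings = FALSE)

  ## ---- simulate or load ----------------------------------------------
  cohorts <- run_stage("inputs", {
    if (is.null(config$input)) {
      cohorts <- list()
      for (i in seq_along(config$diseases)) {
        dis <- names(config$diseases)[i]
        args <- utils::modifyList(config$base, config$diseases[[i]])
        args$disease_label <- dis
        args$cohort_id <- dis
        args$seed <- config$seeds$simulation + i
        cohorts[[dis]] <- prefix_ids(do.call(simulation_config, args) |>
                                       simulate_cohort(), sprintf("c%02d", i))
      }
      cohorts
    } else {
      tab <- read_otu_table(config$input$table)
      tax <- read_taxonomy(config$input$taxonomy)
      samp <- read_sample_frame(config$input$samples)
      dis_labels <- setdiff(unique(samp$health_status),
                            c("healthy", "stochastic_1", "stochastic_2"))
      lapply(stats::setNames(dis_labels, dis_labels), function(dis) {
        keep <- samp$health_status %in% c("healthy", dis)
        s <- samp[keep, , drop = FALSE]
        list(table = otu_table(unclass(tab)[s$sample_id, , drop = FALSE]),
             taxonomy = tax, tree = NULL, samples = s, truth = NULL,
             config = NULL)
      })
    }
  })

  ## ---- low-count filter ----------------------------------------------
  cohorts <- run_stage("filter", lapply(cohorts, function(co) {
    co$table <- filter_low_count(co$table, config$min_total)
    co
  }))

  ## ---- comparison plan ------------------------------------------------
  plan <- run_stage("plan", {
    all_cmp <- list()
    for (dis in names(cohorts)) {
      co <- cohorts[[dis]]
      s <- assign_random_numbers(co$samples, config$seeds$subdivision)
      cohorts[[dis]]$samples <- s
      healthy <- subdivide(s[s$health_status == "healthy", , drop = FALSE],
                           config$subset_size, config$n_subsets)
      diseased <- subdivide(s[s$health_status == dis, , drop = FALSE],
                            config$subset_size, config$n_subsets)
      all_cmp <- c(all_cmp, unclass(
        enumerate_comparisons(healthy, diseased, dis, "cross", cohort = dis)))
    }
    ## stochastic-label null on the first cohort, ignoring real metadata
    st <- make_stochastic_groups(cohorts[[1L]]$samples, config$subset_size,
                                 config$n_subsets, config$seeds$stochastic)
    all_cmp <- c(all_cmp, unclass(
      enumerate_comparisons(st$stochastic_1, st$stochastic_2, "stochastic",
                            "cross", cohort = names(cohorts)[1L])))
    plan <- structure(all_cmp, class = "comparison_plan")
    write_comparison_plan(plan, file.path(outdir, "plan.json"))
    plan
  })

  ## ---- differential abundance per comparison -------------------------
  da <- run_stage("differential_abundance", {
    res <- list()
    for (cmp in plan) {
      tab <- cohorts[[cmp$cohort]]$table
      sub <- otu_table(unclass(tab)[c(cmp$group1, cmp$group2), , drop = FALSE])
      grp <- factor(rep(c("group1", "group2"),
                        c(length(cmp$group1), length(cmp$group2))),
                    levels = c("group1", "group2"))
      r <- nb_wald_test(sub, grp)
      write_tsv(r, file.path(outdir, "da", paste0(cmp$comparison_id, ".tsv")))
      res[[cmp$comparison_id]] <- r
    }
    res
  })
  cmp_disease <- vapply(plan, `[[`, "", "disease")
  names(cmp_disease) <- vapply(plan, `[[`, "", "comparison_id")

  ## ---- fold differences and bias t-tests ------------------------------
  fold <- run_stage("fold_difference", {
    recs <- do.call(rbind, lapply(names(da), function(id) {
      n <- count_enriched(da[[id]], config$alpha)
      cbind(fold_difference(n[[1L]], n[[2L]], id, config$zero_rule),
            disease = cmp_disease[[id]])
    }))
    usable <- table(recs$disease[!is.na(recs$fold_difference)])
    testable <- names(usable)[usable >= 2]
    tests <- test_fold_bias(recs[recs$disease %in% testable, , drop = FALSE])
    skipped <- setdiff(unique(recs$disease), testable)
    if (length(skipped))
      tests <- rbind(tests, data.frame(
        disease = skipped, n_records = 0, mean_fold = NA_real_,
        t_stat = NA_real_, p_value = NA_real_, degenerate = NA,
        p_holm = NA_real_))
    write_tsv(recs, file.path(outdir, "fold_differences.tsv"))
    write_tsv(tests, file.path(outdir, "fold_bias_tests.tsv"))
    list(records = recs, tests = tests)
  })

  ## ---- genus presence matrices + cluster support ----------------------
  genus <- run_stage("genus_clustering", {
    sides <- c("enriched_in_healthy", "enriched_in_disease")
    per_dis <- lapply(stats::setNames(names(cohorts), names(cohorts)),
                      function(dis) {
      ids <- names(cmp_disease)[cmp_disease == dis]
      genus_presence(da[ids], cmp_disease[ids], cohorts[[dis]]$taxonomy,
                     config$alpha)
    })
    mats <- lapply(stats::setNames(sides, sides), function(side)
      merge_genus_rows(lapply(per_dis, `[[`, side)))
    clusters <- list()
    for (side in sides) {
      write_tsv(data.frame(disease = rownames(mats[[side]]), mats[[side]],
                           check.names = FALSE),
                file.path(outdir, paste0("genus_presence_", side, ".tsv")))
      if (nrow(mats[[side]]) >= 3L && ncol(mats[[side]]) >= 2L) {
        cl <- cluster_with_support(mats[[side]], config$n_boot, config$scales,
                                   config$seeds$bootstrap)
        write_cluster_support(cl, file.path(outdir, paste0("dendrogram_", side)))
        clusters[[side]] <- cl
      }
    }
    list(matrices = mats, clusters = clusters)
  })

  ## ---- diversity adjustment (three-sigma genera) ----------------------
  diversity <- run_stage("diversity_adjustment", {
    rows <- lapply(stats::setNames(names(cohorts), names(cohorts)),
                   function(dis) {
      ids <- names(cmp_disease)[cmp_disease == dis]
      rec <- genus_diversity_records(da[ids], cohorts[[dis]]$taxonomy,
                                     config$alpha)
      ## degenerate inputs (few genera, no discoveries) yield NA summaries
      ## rather than halting the run
      rec <- tryCatch(suppressWarnings(three_sigma_flags(rec)),
                      error = function(e) {
                        rec$expected <- NA_real_
                        rec$residual_sd_units <- NA_real_
                        rec$flagged <- NA
                        rec
                      })
      corr <- tryCatch(spearman_diversity_corr(rec), error = function(e)
        list(rho = NA_real_, p_value = NA_real_))
      rec$disease <- dis
      rec$spearman_rho <- corr$rho
      rec$spearman_p <- corr$p_value
      rec
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    write_tsv(out, file.path(outdir, "diversity_adjustment.tsv"))
    out
  })

  ## ---- antibiotic association -----------------------------------------
  abx <- run_stage("antibiotic_association", {
    samp <- do.call(rbind, lapply(cohorts, `[[`, "samples"))
    samp <- samp[!duplicated(samp$sample_id), , drop = FALSE]
    res <- antibiotic_association(samp)
    write_tsv(res, file.path(outdir, "antibiotic_association.tsv"))
    res
  })

  ## ---- beta diversity --------------------------------------------------
  beta <- NULL
  if (config$run_beta) {
    beta <- run_stage("phylo_beta", {
      co <- cohorts[[1L]]
      tree <- co$tree
      if (is.null(tree)) {
        if (is.null(config$input$tree) || !file.exists(config$input$tree))
          stop("no phylogenetic tree available")
        tree <- ape::read.tree(config$input$tree)
      }
      d <- weighted_unifrac(co$table, tree)
      ord <- pcoa(d)
      labels <- co$samples$antibiotic_last_year[
        match(rownames(d), co$samples$sample_id)]
      perm <- permanova(d, factor(labels), config$n_perm,
                        config$seeds$permutation)
      utils::write.table(round(d, 10), file.path(outdir, "unifrac_distance.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(round(ord$coordinates, 10),
                         file.path(outdir, "pcoa_coordinates.tsv"),
                         sep = "\t", quote = FALSE)
      write_tsv(data.frame(pseudo_f = perm$pseudo_f, p_value = perm$p_value,
                           n_permutations = perm$n_permutations),
                file.path(outdir, "permanova.tsv"))
      list(distance = d, pcoa = ord, permanova = perm)
    })
  }

  ## ---- manifest --------------------------------------------------------
  manifest_path <- run_stage("manifest", {
    files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                          "manifest.json"))
    sums <- tools::md5sum(file.path(outdir, files))
    manifest <- list(
      package_version = as.character(utils::packageVersion("dysbiome")),
      seeds = config$seeds,
      alpha = config$alpha,
      files = stats::setNames(as.list(unname(sums)), files))
    p <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    p
  })

  invisible(list(plan = plan, da = da, fold = fold, genus = genus,
                 diversity = diversity, antibiotics = abx, beta = beta,
                 manifest = manifest_path, cohorts = cohorts))
}
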