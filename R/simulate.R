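#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set describing a simulated case/control 16S cohort:
#' negative-binomial OTU counts over lognormal library depths, a
#' genus-structured taxonomy with heterogeneous (power-law) genus sizes, a
#' random coalescent phylogeny, a disease effect realised predominantly as
#' depletion of a configurable OTU subset (loss-of-function dysbiosis) plus
#' a smaller enriched subset, and an antibiotic covariate that shifts
#' community composition.
#'
#' Defaults mirror the cohort structure the analysis targets: 300 samples
#' per health status with three times as many disease-depleted as
#' disease-enriched OTUs (a net loss of diversity in disease), a 4-fold
#' planted effect, and higher antibiotic prevalence among disease samples.
#'
#' @param n_samples_per_group Samples per health status.
#' @param n_otus Number of OTUs.
#' @param n_genera Number of genera OTUs are assigned to (must not exceed
#'   `n_otus`).
#' @param genus_size_exponent Power-law exponent for genus size
#'   heterogeneity; genus `k` receives OTUs with probability proportional
#'   to `k^-exponent`.
#' @param frac_unclassified_genus Fraction of OTUs left unclassified at
#'   genus level (lineage truncated at family).
#' @param abundance_sdlog Spread (sdlog) of the lognormal Dirichlet
#'   concentrations generating baseline relative abundances.
#' @param depth_log_mean,depth_log_sd Library sizes are drawn lognormal
#'   with these log-scale parameters.
#' @param nb_dispersion Negative-binomial dispersion alpha (> 0); variance
#'   is `mu + alpha * mu^2`.
#' @param frac_depleted_in_disease,frac_enriched_in_disease Fractions of
#'   OTUs depleted/enriched in disease; their sum must not exceed 1.
#' @param effect_log2fc Magnitude of the planted disease effect on the
#'   log2 scale (depleted OTUs get `-effect_log2fc`, enriched
#'   `+effect_log2fc`, disease relative to healthy).
#' @param antibiotic_effect_log2fc Magnitude of the antibiotic shift on
#'   affected OTUs (log2 scale, random sign).
#' @param frac_abx_affected Fraction of OTUs whose abundance responds to
#'   antibiotic use.
#' @param antibiotic_prevalence_healthy,antibiotic_prevalence_disease
#'   Probability that a healthy/disease sample reports antibiotic use in
#'   the last year.
#' @param planted_excess_genus If `TRUE`, depleted OTUs are concentrated
#'   into one designated genus at a rate far above its size share, planting
#'   a known positive for the three-sigma diversity adjustment.
#' @param disease_label Name recorded in `health_status` for cases.
#' @param cohort_id Cohort identifier written to the sample frame.
#' @param seed Integer seed; the same seed yields bit-identical cohorts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_group = 300,
                              n_otus = 800,
                              n_genera = 120,
                              genus_size_exponent = 1.5,
                              frac_unclassified_genus = 0.05,
                              abundance_sdlog = 1,
                              depth_log_mean = log(2e4),
                              depth_log_sd = 0.6,
                              nb_dispersion = 0.3,
                              frac_depleted_in_disease = 0.15,
                              frac_enriched_in_disease = 0.05,
                              effect_log2fc = 2,
                              antibiotic_effect_log2fc = 1,
                              frac_abx_affected = 0.2,
                              antibiotic_prevalence_healthy = 0.25,
                              antibiotic_prevalence_disease = 0.45,
                              planted_excess_genus = FALSE,
                              disease_label = "disease",
                              cohort_id = "cohort1",
                              seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_genera > cfg$n_otus)
    stop("infeasible config: n_genera > n_otus")
  if (cfg$frac_depleted_in_disease + cfg$frac_enriched_in_disease > 1)
    stop("frac_depleted_in_disease + frac_enriched_in_disease must be <= 1")
  prevs <- c(cfg$antibiotic_prevalence_healthy, cfg$antibiotic_prevalence_disease)
  if (any(prevs < 0 | prevs > 1)) stop("antibiotic prevalences must lie in [0,1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$effect_log2fc < 0 || cfg$antibiotic_effect_log2fc < 0)
    stop("effect sizes must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a case/control cohort with known ground truth
#'
#' Counts are drawn OTU-wise as negative binomial with mean
#' `rel_abundance * depth * 2^(disease * true_log2fc + abx * abx_log2fc)`
#' and dispersion `nb_dispersion`. Baseline relative abundances come from
#' a Dirichlet whose concentrations are lognormal, giving realistic
#' rank-abundance curves; the tree is a random coalescent over OTU tips.
#'
#' @param config A [simulation_config].
#' @return A list of class `cohort_simulation` with elements `table`
#'   ([otu_table]), `taxonomy` (`taxonomy_map`), `tree` (`phylo`),
#'   `samples` (`sample_frame`), `truth` (list with per-OTU data frame
#'   `otu` and per-genus data frame `genus`), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n_otu <- config$n_otus
    otu_id <- sprintf("OTU%05d", seq_len(n_otu))

    ## baseline composition: Dirichlet with lognormal concentrations
    conc <- stats::rlnorm(n_otu, meanlog = 0, sdlog = config$abundance_sdlog)
    rel <- stats::rgamma(n_otu, shape = conc, rate = 1)
    rel[rel <= 0] <- min(rel[rel > 0]) / 10
    rel <- rel / sum(rel)

    ## genus assignment with power-law size heterogeneity
    genus_names <- sprintf("Genus%03d", seq_len(config$n_genera))
    genus_prob <- seq_len(config$n_genera)^(-config$genus_size_exponent)
    genus <- sample(genus_names, n_otu, replace = TRUE,
                    prob = genus_prob / sum(genus_prob))
    unclassified <- stats::runif(n_otu) < config$frac_unclassified_genus
    genus[unclassified] <- NA_character_

    ## planted disease effect: depletion-dominant dysbiosis
    n_dep <- round(config$frac_depleted_in_disease * n_otu)
    n_enr <- round(config$frac_enriched_in_disease * n_otu)
    excess_genus <- NA_character_
    if (config$planted_excess_genus && n_dep > 0) {
      ## concentrate depletion in the largest classified genus
      tabg <- sort(table(genus[!is.na(genus)]), decreasing = TRUE)
      excess_genus <- names(tabg)[1L]
      in_g <- which(!is.na(genus) & genus == excess_genus)
      take <- in_g[seq_len(min(length(in_g), n_dep))]
      rest <- sample(setdiff(seq_len(n_otu), take), n_dep - length(take))
      dep_idx <- c(take, rest)
    } else {
      dep_idx <- sample(seq_len(n_otu), n_dep)
    }
    enr_idx <- sample(setdiff(seq_len(n_otu), dep_idx), n_enr)
    lfc <- numeric(n_otu)
    lfc[dep_idx] <- -config$effect_log2fc
    lfc[enr_idx] <- config$effect_log2fc
    flag <- ifelse(lfc < 0, "depleted", ifelse(lfc > 0, "enriched", "null"))

    ## antibiotic shift on a subset of OTUs, random direction
    abx_lfc <- numeric(n_otu)
    n_abx <- round(config$frac_abx_affected * n_otu)
    abx_idx <- sample(seq_len(n_otu), n_abx)
    abx_lfc[abx_idx] <- config$antibiotic_effect_log2fc *
      sample(c(-1, 1), n_abx, replace = TRUE)

    ## samples
    n_per <- config$n_samples_per_group
    n_samp <- 2L * n_per
    sid <- sprintf("S%04d", seq_len(n_samp))
    status <- rep(c("healthy", config$disease_label), each = n_per)
    is_dis <- as.numeric(status != "healthy")
    abx <- stats::rbinom(n_samp, 1L,
                         ifelse(is_dis == 1, config$antibiotic_prevalence_disease,
                                config$antibiotic_prevalence_healthy))
    depth <- stats::rlnorm(n_samp, config$depth_log_mean, config$depth_log_sd)

    ## counts: mean = rel * depth * 2^(status*lfc + abx*abx_lfc)
    log2shift <- outer(is_dis, lfc) + outer(as.numeric(abx), abx_lfc)
    mu <- (depth %o% rel) * 2^log2shift
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = n_samp, dimnames = list(sid, otu_id))

    ## taxonomy lineage strings (truncated at family when genus unknown)
    lineage <- ifelse(
      is.na(genus),
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__; s__",
      sprintf("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__%s; s__",
              genus))
    taxonomy <- taxonomy_map(stats::setNames(lineage, otu_id))

    tree <- ape::rcoal(n_otu, tip.label = otu_id)

    samples <- sample_frame(data.frame(
      sample_id = sid, cohort_id = config$cohort_id, health_status = status,
      antibiotic_last_year = abx == 1L, stringsAsFactors = FALSE))

    genus_truth <- data.frame(
      genus = genus_names,
      planted_excess_flag = !is.na(excess_genus) & genus_names == excess_genus,
      stringsAsFactors = FALSE)

    structure(list(
      table = otu_table(counts),
      taxonomy = taxonomy,
      tree = tree,
      samples = samples,
      truth = list(
        otu = data.frame(otu_id = otu_id, true_log2fc = lfc,
                         dysbiotic_flag = flag, abx_log2fc = abx_lfc,
                         genus = genus, stringsAsFactors = FALSE),
        genus = genus_truth),
      config = config), class = "cohort_simulation")
  })
}

#' Simulate a 2x2 antibiotic-by-disease contingency table
#'
#' Rows are disease/healthy, columns antibiotic/no antibiotic; each row
#' total equals `n_per_group` and exposed cells are binomial draws at the
#' stated prevalence.
#'
#' @param n_per_group Individuals per health status.
#' @param prev_healthy,prev_disease Antibiotic-use prevalences in `[0,1]`.
#' @param seed Integer seed.
#' @return Integer 2x2 matrix with dimnames.
#' @export
simulate_antibiotic_table <- function(n_per_group, prev_healthy, prev_disease,
                                      seed = 1) {
  stopifnot(prev_healthy >= 0, prev_healthy <= 1,
            prev_disease >= 0, prev_disease <= 1)
  withr::with_seed(seed, {
    a <- stats::rbinom(1L, n_per_group, prev_disease)
    c_ <- stats::rbinom(1L, n_per_group, prev_healthy)
    contingency_2x2(a, n_per_group - a, c_, n_per_group - c_)
  })
}

#' Write a simulated cohort to a directory of standard files
#'
#' Emits `otu_table.tsv`, `taxonomy.tsv`, `tree.nwk`, `samples.tsv` and a
#' ground-truth TSV `truth_otu.tsv` / `truth_genus.tsv`.
#'
#' @param cohort A `cohort_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(cohort$table, file.path(dir, "otu_table.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  write_sample_frame(cohort$samples, file.path(dir, "samples.tsv"))
  utils::write.table(cohort$truth$otu, file.path(dir, "truth_otu.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$genus, file.path(dir, "truth_genus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
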