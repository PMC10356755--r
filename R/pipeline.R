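#' Multiplicity stage: per-population gene multiplicity and treatment KS
#'
#' For every host population: restrict to
#' nonsynonymous/insertion/deletion mutations, compute gene multiplicity and
#' relative multiplicity, and build the rank-abundance view. Then compare the
#' pooled relative-multiplicity distributions of the +seed-bank and
#' -seed-bank populations within each phage stratum with a permutational KS
#' test.
#'
#' @param experiment result of [generate_experiment()] (or the same shape
#'   assembled from files).
#' @param n_perm permutations for the KS tests.
#' @param seed integer RNG seed.
#' @param unit permutation unit for the KS tests (`"value"` default;
#'   `"block"` permutes whole populations).
#' @param out_dir optional directory for figure-ready TSVs.
#' @return list: `multiplicity` (tibble over all populations, with `m_rel`),
#'   `rank_abundance` (list per population), `gene_counts` tibble,
#'   `ks` (list of `perm_test_result`, one per phage stratum).
#' @export
run_multiplicity_stage <- function(experiment, n_perm = 10000, seed = 1,
                                   unit = "value", out_dir = NULL) {
  ann <- experiment$annotation_host
  tabs <- lapply(experiment$communities, function(com) {
    recs <- filter_effect_classes(com$host)
    gene_multiplicity(recs, ann)
  })
  mult <- relative_multiplicity(dplyr::bind_rows(tabs))
  pops <- names(experiment$communities)
  ranks <- lapply(stats::setNames(pops, pops),
                  function(p) rank_abundance(mult, p))
  counts <- mult |>
    dplyr::count(.data$population_id, name = "n_genes") |>
    dplyr::left_join(experiment$manifest[, c("population_id",
                                             "treatment_seedbank",
                                             "treatment_phage")],
                     by = "population_id")
  man <- experiment$manifest
  ks <- list()
  for (ph in c("plus", "minus")) {
    pops_sb <- man$population_id[man$treatment_phage == ph &
                                   man$treatment_seedbank == "plus"]
    pops_no <- man$population_id[man$treatment_phage == ph &
                                   man$treatment_seedbank == "minus"]
    vals <- function(ps) lapply(ps, function(p)
      mult$m_rel[mult$population_id == p])
    ga <- vals(pops_sb)
    gb <- vals(pops_no)
    res <- if (unit == "block") {
      permutation_pvalue(ga, gb, ks_statistic, n_perm = n_perm,
                         seed = derive_seed(seed, match(ph, c("plus",
                                                              "minus"))),
                         unit = "block",
                         statistic_name = "KS D (relative multiplicity)")
    } else {
      permutation_pvalue(unlist(ga), unlist(gb), ks_statistic,
                         n_perm = n_perm,
                         seed = derive_seed(seed, match(ph, c("plus",
                                                              "minus"))),
                         unit = "value",
                         statistic_name = "KS D (relative multiplicity)")
    }
    ks[[paste0("phage_", ph)]] <- res
  }
  out <- list(multiplicity = mult, rank_abundance = ranks,
              gene_counts = counts, ks = ks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(mult, file.path(out_dir, "multiplicity.tsv"))
    rk <- dplyr::bind_rows(ranks, .id = "population_id")
    readr::write_tsv(rk, file.path(out_dir, "rank_abundance.tsv"))
    readr::write_tsv(perm_results_table(ks),
                     file.path(out_dir, "multiplicity_ks.tsv"))
  }
  out
}

#' Ratio of mutated-gene counts between seed-bank treatments
#'
#' Mean number of genes with positive multiplicity per +seed-bank host
#' population divided by the same mean for -seed-bank populations.
#'
#' @param gene_counts `gene_counts` tibble from [run_multiplicity_stage()].
#' @return scalar ratio.
#' @export
mutated_gene_ratio <- function(gene_counts) {
  mean(gene_counts$n_genes[gene_counts$treatment_seedbank == "plus"]) /
    mean(gene_counts$n_genes[gene_counts$treatment_seedbank == "minus"])
}

#' Composition stage: ordination and PERMANOVA of mutated-gene composition
#'
#' Builds the populations x genes feature matrix of relative multiplicities
#' (0 for genes unmutated in a population), computes Bray-Curtis distances
#' and a PCoA, retains the leading axes explaining more than `min_cum_prop`
#' of the variation, and runs a two-way PERMANOVA (seed bank, phage, and
#' their interaction; Euclidean distance on the retained coordinates).
#'
#' @param experiment result of [generate_experiment()].
#' @param n_perm PERMANOVA permutations.
#' @param seed integer RNG seed.
#' @param min_cum_prop cumulative variance for axis selection (default 0.9).
#' @param multiplicity optional precomputed multiplicity table.
#' @param out_dir optional directory for TSV outputs.
#' @return list: `feature_matrix`, `distance`, `ordination`, `axes`
#'   (selection), `permanova` tibble.
#' @export
run_composition_stage <- function(experiment, n_perm = 10000, seed = 1,
                                  min_cum_prop = 0.9, multiplicity = NULL,
                                  out_dir = NULL) {
  if (is.null(multiplicity)) {
    multiplicity <- run_multiplicity_stage(experiment, n_perm = 1,
                                           seed = seed)$multiplicity
  }
  feat <- multiplicity |>
    dplyr::select("population_id", "gene_id", "m_rel") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "m_rel",
                       values_fill = 0)
  fm <- as.matrix(feat[, -1, drop = FALSE])
  rownames(fm) <- feat$population_id
  man <- experiment$manifest
  fm <- fm[man$population_id, , drop = FALSE]
  d <- bray_curtis(fm)
  ord <- pcoa(d)
  axes <- select_top_axes(ord, min_cum_prop)
  pm <- permanova_two_way(axes$coordinates,
                          factor_a = man$treatment_seedbank,
                          factor_b = man$treatment_phage,
                          n_perm = n_perm, seed = derive_seed(seed, 3L))
  pm$term <- c("seed_bank", "phage", "seed_bank:phage", "residual", "total")
  out <- list(feature_matrix = fm, distance = d, ordination = ord,
              axes = axes, permanova = pm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    co <- tibble::as_tibble(ord$coordinates, rownames = "population_id")
    readr::write_tsv(co, file.path(out_dir, "pcoa_coordinates.tsv"))
    readr::write_tsv(tibble::tibble(axis = seq_along(ord$eigenvalues),
                                    eigenvalue = ord$eigenvalues,
                                    proportion = ord$proportion_explained),
                     file.path(out_dir, "pcoa_eigenvalues.tsv"))
    readr::write_tsv(pm, file.path(out_dir, "permanova.tsv"))
  }
  out
}

#' Coevolution stage: host-phage trajectory correlations vs permuted-time null
#'
#' For every infected community: filter host and phage mutations to the
#' analysed classes detected at `min_timepoints` or more timepoints, form
#' eligible trajectory pairs, compute observed Pearson correlations and the
#' permuted-time null, and test observed vs null. Observed and null
#' correlations are then pooled across the replicate communities of each
#' seed-bank treatment for the treatment-level tests.
#'
#' @param experiment result of [generate_experiment()].
#' @param n_null permuted-time rounds per community.
#' @param n_perm permutations for the KS p-values.
#' @param seed integer RNG seed.
#' @param min_nonzero pair-eligibility rule (default 3).
#' @param min_timepoints trajectory detection rule (default 3).
#' @param out_dir optional directory for TSV outputs.
#' @return list: `sets` (per-community `correlation_set`s with `null_r`),
#'   `obs_vs_null` (per seed-bank treatment, pooled), `treatment_comparison`
#'   (`perm_test_result`), `high_frequency` (per community host report),
#'   `counts` tibble of removals and exclusions.
#' @export
run_coevolution_stage <- function(experiment, n_null = 100, n_perm = 999,
                                  seed = 1, min_nonzero = 3,
                                  min_timepoints = 3, out_dir = NULL) {
  man <- experiment$manifest
  infected <- man$population_id[man$treatment_phage == "plus"]
  sets <- list()
  highf <- list()
  counts <- list()
  for (p in infected) {
    com <- experiment$communities[[p]]
    hrec <- filter_min_detection(filter_effect_classes(com$host),
                                 min_timepoints)
    prec <- filter_min_detection(filter_effect_classes(com$phage),
                                 min_timepoints)
    hm <- build_trajectory_matrix(hrec)
    pm <- build_trajectory_matrix(prec)
    highf[[p]] <- high_frequency_report(hrec)
    if (nrow(hm) == 0 || nrow(pm) == 0) next
    ep <- eligible_pairs(hm, pm, min_nonzero)
    cs <- pair_correlations(ep, hm, pm, community_id = p)
    # one run of permutation rounds supplies both the pooled reference null
    # (first n_null columns) and the test draws for the KS p-value
    nl <- permuted_time_null(hm, pm, cs$pairs, n_perm = n_null + n_perm,
                             seed = derive_seed(seed, 20L +
                                                  match(p, infected)))
    cs$null_r <- nl[, seq_len(n_null), drop = FALSE]
    cs$null_draws <- nl[, n_null + seq_len(n_perm), drop = FALSE]
    sets[[p]] <- cs
    counts[[p]] <- tibble::tibble(population_id = p,
                                  n_pairs = nrow(cs$pairs),
                                  n_pairs_removed = cs$n_pairs_removed,
                                  n_zero_variance = cs$n_zero_variance)
  }
  pool <- function(sb) {
    ids <- man$population_id[man$treatment_phage == "plus" &
                               man$treatment_seedbank == sb]
    ids <- intersect(ids, names(sets))
    list(obs = unlist(lapply(sets[ids], function(s) s$pairs$r)),
         null = do.call(rbind, lapply(sets[ids], function(s) s$null_r)),
         draws = do.call(rbind, lapply(sets[ids],
                                       function(s) s$null_draws)),
         sets = sets[ids])
  }
  pooled <- list(plus = pool("plus"), minus = pool("minus"))
  obs_vs_null <- lapply(stats::setNames(names(pooled), names(pooled)),
                        function(sb) {
    pl <- pooled[[sb]]
    if (length(pl$obs) == 0) return(NULL)
    compare_to_null(pl$obs, pl$null, n_perm = n_perm,
                    seed = derive_seed(seed, 30L + match(sb, names(pooled))),
                    test_draws = pl$draws)
  })
  treatment_comparison <-
    if (length(pooled$plus$obs) && length(pooled$minus$obs)) {
      compare_treatments(pooled$plus$sets, pooled$minus$sets,
                         n_perm = n_perm, seed = derive_seed(seed, 33L))
    }
  out <- list(sets = sets, obs_vs_null = obs_vs_null,
              treatment_comparison = treatment_comparison,
              high_frequency = highf,
              counts = dplyr::bind_rows(counts))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pairs <- dplyr::bind_rows(lapply(sets, function(s)
      tibble::tibble(community_id = s$community_id, s$pairs)))
    readr::write_tsv(pairs, file.path(out_dir, "pair_correlations.tsv"))
    tests <- c(obs_vs_null[!vapply(obs_vs_null, is.null, TRUE)],
               list(treatment_comparison = treatment_comparison))
    readr::write_tsv(perm_results_table(tests),
                     file.path(out_dir, "coevolution_tests.tsv"))
    readr::write_tsv(out$counts, file.path(out_dir, "coevolution_counts.tsv"))
  }
  out
}

#' Run the full pipeline on a synthetic experiment
#'
#' Generates (or accepts) an experiment and chains the multiplicity,
#' composition and coevolution stages with seeds derived from one master
#' seed.
#'
#' @param config a `synthetic_config` (ignored when `experiment` is given).
#' @param experiment optional pre-generated experiment.
#' @param n_perm permutations for all tests.
#' @param n_null permuted-time rounds per community.
#' @param seed master seed for the analysis stages.
#' @param out_dir optional output directory (one subdirectory per stage).
#' @return list with `experiment`, `multiplicity`, `composition`,
#'   `coevolution`.
#' @export
run_pipeline <- function(config = synthetic_config(), experiment = NULL,
                         n_perm = 1000, n_null = 100, seed = 1,
                         out_dir = NULL) {
  if (is.null(experiment)) experiment <- generate_experiment(config)
  sub <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir,
                                                                  name)
  mult <- run_multiplicity_stage(experiment, n_perm = n_perm,
                                 seed = derive_seed(seed, 101L),
                                 out_dir = sub("multiplicity"))
  comp <- run_composition_stage(experiment, n_perm = n_perm,
                                seed = derive_seed(seed, 102L),
                                multiplicity = mult$multiplicity,
                                out_dir = sub("composition"))
  coev <- run_coevolution_stage(experiment, n_null = n_null, n_perm = n_perm,
                                seed = derive_seed(seed, 103L),
                                out_dir = sub("coevolution"))
  list(experiment = experiment, multiplicity = mult, composition = comp,
       coevolution = coev)
}

#' Flatten permutation test results into a table
#'
#' @param results named list of `perm_test_result`s.
#' @return tibble `test_name, comparison, observed_statistic, p_value,
#'   n_permutations, seed`.
#' @export
perm_results_table <- function(results) {
  dplyr::bind_rows(lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.null(r)) return(NULL)
    tibble::tibble(test_name = r$statistic_name, comparison = nm,
                   observed_statistic = r$observed, p_value = r$p_value,
                   n_permutations = r$n_permutations, seed = r$seed)
  }))
}
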