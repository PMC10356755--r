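#' Configuration for the synthetic Pool-seq experiment
#'
#' Defines the study conditions the generator emulates: a 2x2 factorial
#' (seed bank x phage) with 3 replicate communities per cell, hosts in all 12
#' communities and phage in the 6 infected ones, 14 serial transfers with
#' sequencing at transfers 1, 4, 7, 10 and 14, Pool-seq binomial noise at
#' coverage 100 with a breseq-like reporting floor of 0.05, seed-bank
#' buffering that roughly doubles the number of mutated genes, and negatively
#' coupled host-phage driver trajectories whose coupling the seed bank
#' attenuates.
#'
#' Latent dynamics: each mutant lineage is a clone with a static background
#' log-fitness s (a normal draw; drivers instead get the time-varying
#' driver coefficient); per transfer,
#' frequencies follow the mean-field replicator update
#' f_i <- f_i exp(s_i - s_bar + sigma eps_i) with s_bar the
#' frequency-weighted mean log-fitness, normalised by the total mutant mass
#' when that exceeds 1 (mutations tag overlapping genotypes, so their
#' frequencies are not confined to a simplex). A
#' transfer-bottleneck loss then removes non-driver lineages with
#' probability exp(-f * bottleneck_scale); under the seed-bank treatment the
#' population frequency is mixed with a lagged spore-reservoir frequency,
#' f <- (1-c) f + c f_bank, with the reservoir refreshed by the 4:1
#' (new:old) rule shared with [seedbank_legacy_fraction()]. In infected
#' communities one host resistance driver sweeps under s_driver; a phage
#' counter-driver arises with per-transfer hazard gamma * h(t) and, once
#' spreading, turns the host driver's selection negative
#' (s_driver * (1 - 2 p)). The reciprocal sweep displaces the other phage
#' lineages while releasing the suppressed host lineages, which is what
#' produces the excess of negative host-phage trajectory correlations;
#' under the seed-bank treatment gamma is multiplied by
#' `gamma_sb_attenuation` and the reservoir damps both the sweep and the
#' release, attenuating the coupling.
#'
#' @param n_replicates replicate communities per treatment cell.
#' @param timepoints sequenced transfer grid.
#' @param n_transfers total serial transfers.
#' @param host_genes,phage_genes genome sizes (number of genes).
#' @param gene_length_meanlog,gene_length_sdlog lognormal gene-length
#'   parameters (nt); lengths are floored at `gene_length_min`.
#' @param gene_length_min minimum gene length (nt).
#' @param nonsyn_fraction nonsynonymous fraction of sites per gene.
#' @param lambda_host,lambda_phage mean new detectable mutations arising per
#'   transfer (Poisson).
#' @param init_freq_min,init_freq_max uniform range for the frequency at
#'   which a new mutant lineage enters the detectable pool.
#' @param s_driver selection coefficient of driver mutations per transfer.
#' @param s_background_sd standard deviation of the static background
#'   log-fitness drawn for each new host lineage (the fitness of the clone
#'   the mutation arose on; positive draws rise, negative draws fade).
#' @param phage_s_background_mean,phage_s_background_sd mean and spread of
#'   the background log-fitness of phage lineages; the positive mean
#'   reflects that most detectable phage mutations sit in tail genes under
#'   directional selection to counter host resistance.
#' @param burst_size mean number of extra host lineages arising in the
#'   first transfer of infected communities (the phage-triggered
#'   diversification burst whose losers later decline).
#' @param burst_freq_min,burst_freq_max frequency bounds for burst
#'   lineages.
#' @param sigma drift scale per transfer.
#' @param bottleneck_scale host transfer-bottleneck loss scale; a non-driver
#'   lineage at frequency f is lost with probability
#'   exp(-f * bottleneck_scale).
#' @param phage_bottleneck_scale same for phage lineages (weaker: phage
#'   populations pass the bottleneck at much larger census sizes).
#' @param seedbank_weight reservoir mixing weight c in [0, 1); 0 disables
#'   the seed-bank buffer.
#' @param gamma per-transfer hazard scale of the phage counter-driver.
#' @param gamma_sb_attenuation multiplier applied to gamma under the
#'   seed-bank treatment.
#' @param n_driver_genes_host,n_driver_genes_phage candidate driver genes
#'   (receptor-pathway hosts, tail-gene phages).
#' @param n_host_driver_mutations resistance driver mutations seeded in the
#'   first transfer of each infected community (replicate populations
#'   carried high-frequency mutations in several receptor-pathway genes).
#' @param sb_gene_pool number of host genes in the sporulation/stress
#'   pathway pool that experiences extra selection when the population
#'   cycles through dormancy.
#' @param sb_gene_fraction fraction of host arrivals drawn from that pool
#'   in +seed-bank communities (0 in -seed-bank communities); this is what
#'   gives the mutated-gene composition its seed-bank signature.
#' @param coverage Pool-seq coverage (reads per site).
#' @param reporting_floor minimum observed frequency reported.
#' @param arrivals_first_transfer concentrate the whole mutation supply
#'   (`lambda * n_transfers`) in the first transfer. Used for null
#'   calibration: a mutation arising mid-experiment is a step in time, i.e.
#'   temporal structure that time permutation destroys, so trajectories are
#'   only exchangeable under the null when every lineage is present from
#'   the start.
#' @param effect_class_probs arrival probabilities of mutation classes.
#' @param seed master seed; per-community and per-organism streams are
#'   derived from it by a fixed offset scheme.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_replicates = 3,
                             timepoints = c(1, 4, 7, 10, 14),
                             n_transfers = 14,
                             host_genes = 4000, phage_genes = 200,
                             gene_length_meanlog = log(800),
                             gene_length_sdlog = 0.45,
                             gene_length_min = 120,
                             nonsyn_fraction = 0.75,
                             lambda_host = 4, lambda_phage = 8,
                             init_freq_min = 0.02, init_freq_max = 0.15,
                             s_driver = 0.6,
                             s_background_sd = 0.05,
                             phage_s_background_mean = 0.2,
                             phage_s_background_sd = 0.1,
                             burst_size = 15,
                             burst_freq_min = 0.1,
                             burst_freq_max = 0.4,
                             sigma = 0.1,
                             bottleneck_scale = 10,
                             phage_bottleneck_scale = 60,
                             seedbank_weight = 0.78,
                             gamma = 0.8,
                             gamma_sb_attenuation = 0.4,
                             n_driver_genes_host = 4,
                             n_driver_genes_phage = 4,
                             n_host_driver_mutations = 1,
                             sb_gene_pool = 40,
                             sb_gene_fraction = 0.5,
                             coverage = 100,
                             reporting_floor = 0.05,
                             arrivals_first_transfer = FALSE,
                             effect_class_probs = c(nonsynonymous = 0.70,
                                                    insertion = 0.10,
                                                    deletion = 0.10,
                                                    synonymous = 0.05,
                                                    intergenic = 0.05),
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$seedbank_weight >= 0, cfg$seedbank_weight < 1,
            cfg$coverage >= 1, cfg$lambda_host >= 0, cfg$lambda_phage >= 0,
            cfg$sigma >= 0, cfg$gamma >= 0,
            all(cfg$timepoints <= cfg$n_transfers),
            abs(sum(cfg$effect_class_probs) - 1) < 1e-8)
  structure(cfg, class = "synthetic_config")
}

#' A small configuration for calibration studies
#'
#' Same structure as [synthetic_config()] but with reduced genome size and
#' mutation supply, used for replicated calibration runs.
#'
#' @param ... overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
synthetic_config_small <- function(...) {
  synthetic_config(host_genes = 300, phage_genes = 60, lambda_host = 4,
                   lambda_phage = 2, ...)
}

#' Generate a gene annotation set
#'
#' Gene lengths are lognormal (floored at the configured minimum) and the
#' nonsynonymous target size is a fixed fraction of the length, the
#' generator's convention for L_i.
#'
#' @param config a `synthetic_config`.
#' @param organism `"host"` or `"phage"`.
#' @param seed RNG seed (default derived from the config's master seed).
#' @return annotation tibble `gene_id, length_nt, nonsyn_sites`.
#' @export
generate_annotation <- function(config, organism = c("host", "phage"),
                                seed = NULL) {
  organism <- match.arg(organism)
  n <- if (organism == "host") config$host_genes else config$phage_genes
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, if (organism == "host") 1L else 2L)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  len <- pmax(config$gene_length_min,
              round(stats::rlnorm(n, config$gene_length_meanlog,
                                  config$gene_length_sdlog)))
  prefix <- if (organism == "host") "hg" else "pg"
  tibble::tibble(gene_id = sprintf("%s%05d", prefix, seq_len(n)),
                 length_nt = as.integer(len),
                 nonsyn_sites = config$nonsyn_fraction * len)
}

# fixed offset scheme for per-community / per-organism RNG streams;
# kept below 2^31 for 32-bit R integers
derive_seed <- function(master, offset) {
  (as.integer(master) + 7919L * as.integer(offset)) %% 2147483647L
}

#' Simulate one community (host population, and phage when infected)
#'
#' Runs the latent transfer-by-transfer dynamics described in
#' [synthetic_config()] jointly for host and phage, applies binomial
#' Pool-seq sampling at the sequenced timepoints, and reports mutations
#' observed at or above the reporting floor in the mutation-table dialect.
#'
#' @param config a `synthetic_config`.
#' @param seed_bank,phage `"plus"` or `"minus"` treatment flags.
#' @param replicate_id replicate number within the treatment cell.
#' @param annotation_host,annotation_phage annotation tibbles; generated
#'   from the config when omitted.
#' @param seed RNG seed for this community (default derived from the
#'   master seed and the treatment/replicate index).
#' @return list with `host` and (when infected) `phage` record tibbles,
#'   plus `population_id`.
#' @export
simulate_community <- function(config, seed_bank = c("plus", "minus"),
                               phage = c("plus", "minus"), replicate_id = 1,
                               annotation_host = NULL,
                               annotation_phage = NULL, seed = NULL) {
  seed_bank <- match.arg(seed_bank)
  phage <- match.arg(phage)
  if (is.null(annotation_host)) {
    annotation_host <- generate_annotation(config, "host")
  }
  if (is.null(annotation_phage) && phage == "plus") {
    annotation_phage <- generate_annotation(config, "phage")
  }
  if (is.null(seed)) {
    idx <- (seed_bank == "minus") * 6L + (phage == "minus") * 3L +
      as.integer(replicate_id)
    seed <- derive_seed(config$seed, 10L + idx)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  pop_id <- sprintf("SB%s_P%s_r%d", seed_bank, phage, replicate_id)
  has_sb <- seed_bank == "plus"
  has_phage <- phage == "plus"
  cfg <- config
  n_tp <- length(cfg$timepoints)
  gamma_eff <- cfg$gamma * if (has_sb) cfg$gamma_sb_attenuation else 1

  new_state <- function() {
    list(gene = integer(0), class = character(0), f = numeric(0),
         bank = numeric(0), s = numeric(0), driver = logical(0),
         latent = matrix(numeric(0), 0, n_tp))
  }
  host <- new_state()
  phg <- new_state()
  classes <- names(cfg$effect_class_probs)

  arrivals <- function(st, lambda, ann, fmin = cfg$init_freq_min,
                       fmax = cfg$init_freq_max,
                       s_mean = 0, s_sd = cfg$s_background_sd,
                       sb_pool = NULL) {
    k <- stats::rpois(1, lambda)
    if (k == 0) return(st)
    genes <- sample.int(nrow(ann), k, replace = TRUE,
                        prob = ann$nonsyn_sites)
    if (!is.null(sb_pool) && length(sb_pool) > 0 &&
        cfg$sb_gene_fraction > 0) {
      from_pool <- stats::runif(k) < cfg$sb_gene_fraction
      genes[from_pool] <- sample(sb_pool, sum(from_pool), replace = TRUE)
    }
    st$gene <- c(st$gene, genes)
    st$class <- c(st$class, sample(classes, k, replace = TRUE,
                                   prob = cfg$effect_class_probs))
    f0 <- stats::runif(k, fmin, fmax)
    st$f <- c(st$f, f0)
    # new lineages sporulate during their first growth cycle, so the
    # reservoir starts at the arrival frequency rather than empty
    st$bank <- c(st$bank, f0)
    # static background fitness of the clone each mutation arose on
    st$s <- c(st$s, stats::rnorm(k, s_mean, s_sd))
    st$driver <- c(st$driver, logical(k))
    st$latent <- rbind(st$latent, matrix(0, k, n_tp))
    st
  }
  add_driver <- function(st, gene_pool) {
    st$gene <- c(st$gene, sample(gene_pool, 1))
    st$class <- c(st$class, "nonsynonymous")
    f0 <- stats::runif(1, cfg$init_freq_min, cfg$init_freq_max)
    st$f <- c(st$f, f0)
    st$bank <- c(st$bank, f0)
    st$s <- c(st$s, 0)
    st$driver <- c(st$driver, TRUE)
    st$latent <- rbind(st$latent, matrix(0, 1, n_tp))
    st
  }
  # one serial transfer of mean-field multi-clone dynamics: every mutant
  # lineage carries a log-fitness s (drivers get the time-varying s_drv)
  # and allele frequencies follow the replicator update
  # f_i <- f_i exp(s_i - s_bar + sigma eps_i), where s_bar = sum f_j s_j is
  # the population's mean log-fitness (mutations tag overlapping genotypes,
  # so frequencies are not constrained to a simplex). Clonal interference
  # is automatic: a sweeping driver raises s_bar and displaces every other
  # lineage, releasing them when it collapses. Then transfer-bottleneck
  # loss (drivers, established sweeps, are exempt) and, under the seed-bank
  # treatment, reservoir mixing.
  step <- function(st, s_drv, bottleneck, use_bank) {
    n <- length(st$f)
    if (n == 0) return(st)
    drv <- st$driver
    s <- st$s
    s[drv] <- s_drv
    # frequency-weighted mean log-fitness; normalised by total mutant mass
    # when it exceeds 1 (overlapping mutations over-count genotypes) and
    # clamped at 0: when a sweeping driver collapses, the freed mass
    # returns to the ancestral genotype, not to the displaced mutants
    s_bar <- max(0, sum(st$f * s)) / max(1, sum(st$f))
    f <- st$f * exp(s - s_bar + cfg$sigma * stats::rnorm(n))
    f <- pmin(1, f)
    lost <- !drv & stats::runif(n) < exp(-f * bottleneck)
    f[lost] <- 0
    if (use_bank) {
      f <- (1 - cfg$seedbank_weight) * f + cfg$seedbank_weight * st$bank
      # reservoir refreshed with the 4:1 (new:old) volumetric mixing rule
      st$bank <- (4 * f + 1 * st$bank) / 5
    }
    st$f <- f
    st
  }

  host_driver_pool <- utils::head(order(-annotation_host$nonsyn_sites),
                                  cfg$n_driver_genes_host)
  # sporulation/stress pathway genes recurrently hit under +seed bank
  sb_pool <- if (has_sb && cfg$sb_gene_pool > 0) {
    ord <- order(-annotation_host$nonsyn_sites)
    ord[seq(cfg$n_driver_genes_host + 1,
            min(cfg$n_driver_genes_host + cfg$sb_gene_pool, length(ord)))]
  }
  phage_driver_pool <- if (has_phage) {
    utils::head(order(-annotation_phage$nonsyn_sites),
                cfg$n_driver_genes_phage)
  }
  counter_active <- FALSE

  lam_host <- function(t) {
    if (cfg$arrivals_first_transfer) {
      if (t == 1) cfg$lambda_host * cfg$n_transfers else 0
    } else {
      cfg$lambda_host
    }
  }
  for (t in seq_len(cfg$n_transfers)) {
    host <- arrivals(host, lam_host(t), annotation_host, sb_pool = sb_pool)
    if (has_phage && t == 1) {
      # infection triggers a burst of host diversification in the first
      # transfer: many lineages jump to moderate frequency at once, most of
      # which are later purged as the winning resistance genotype fixes
      host <- arrivals(host, cfg$burst_size, annotation_host,
                       fmin = cfg$burst_freq_min, fmax = cfg$burst_freq_max)
      if (cfg$s_driver > 0) {
        for (i in seq_len(cfg$n_host_driver_mutations)) {
          host <- add_driver(host, host_driver_pool)
        }
      }
    }
    if (has_phage) {
      # the phage mutation supply is dominated by counter-resistance
      # selection, which only operates once host resistance has risen; a
      # small baseline covers resistance-independent mutations
      h_now <- if (any(host$driver)) max(host$f[host$driver]) else 0
      lam <- if (cfg$arrivals_first_transfer) {
        if (t == 1) cfg$lambda_phage * cfg$n_transfers else 0
      } else {
        cfg$lambda_phage * (0.1 + 0.9 * min(1, gamma_eff * h_now))
      }
      phg <- arrivals(phg, lam, annotation_phage,
                      s_mean = cfg$phage_s_background_mean,
                      s_sd = cfg$phage_s_background_sd)
    }

    p_driver <- if (has_phage && any(phg$driver)) max(phg$f[phg$driver]) else 0
    # counter-resistance erodes the host driver's advantage and, once
    # common, turns it costly
    host <- step(host, s_drv = cfg$s_driver * (1 - 2 * p_driver),
                 bottleneck = cfg$bottleneck_scale, use_bank = has_sb)

    if (has_phage) {
      h_driver <- if (any(host$driver)) max(host$f[host$driver]) else 0
      if (!counter_active && stats::runif(1) < min(1, gamma_eff * h_driver)) {
        phg <- add_driver(phg, phage_driver_pool)
        counter_active <- TRUE
      }
      phg <- step(phg, s_drv = cfg$s_driver,
                  bottleneck = cfg$phage_bottleneck_scale, use_bank = FALSE)
    }

    grid_pos <- match(t, cfg$timepoints)
    if (!is.na(grid_pos)) {
      if (length(host$f)) host$latent[, grid_pos] <- host$f
      if (has_phage && length(phg$f)) phg$latent[, grid_pos] <- phg$f
    }
  }

  observe <- function(st, ann, organism) {
    n <- nrow(st$latent)
    if (n == 0) {
      obs <- matrix(numeric(0), 0, n_tp)
    } else {
      obs <- matrix(stats::rbinom(n * n_tp, cfg$coverage,
                                  as.vector(st$latent)) / cfg$coverage,
                    n, n_tp)
      obs[obs < cfg$reporting_floor] <- 0
    }
    keep <- rowSums(obs) > 0
    obs <- obs[keep, , drop = FALSE]
    gene <- st$gene[keep]
    cls <- st$class[keep]
    k <- nrow(obs)
    contig <- if (organism == "host") "chr1" else "phi1"
    pos_site <- sample.int(10000000L, k)
    alt <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    gene_id <- ifelse(cls == "intergenic", "intergenic", ann$gene_id[gene])
    rec <- tibble::tibble(
      population_id = rep(pop_id, k),
      treatment_seedbank = rep(seed_bank, k),
      treatment_phage = rep(phage, k),
      organism = rep(organism, k),
      mutation_id = sprintf("%s:%07d:%s", contig, pos_site, alt),
      gene_id = gene_id,
      effect_class = cls)
    fr <- as.data.frame(obs)
    names(fr) <- tp_cols(cfg$timepoints)
    rec <- tibble::as_tibble(cbind(rec, fr))
    rec <- rec[order(rec$mutation_id), , drop = FALSE]
    attr(rec, "timepoints") <- as.integer(cfg$timepoints)
    rec
  }

  out <- list(population_id = pop_id,
              host = observe(host, annotation_host, "host"))
  if (has_phage) out$phage <- observe(phg, annotation_phage, "phage")
  out
}

#' Generate the full synthetic experiment
#'
#' All 2 x 2 x `n_replicates` communities: 12 host populations and 6 phage
#' populations (phage only in infected cells) plus both annotations and a
#' manifest of treatments and per-community seeds, fully reproducible from
#' the master seed. Optionally writes everything as the TSV dialects of
#' [read_mutation_table()] / [read_gene_annotation()].
#'
#' @param config a `synthetic_config`.
#' @param out_dir optional output directory for the file set.
#' @param overwrite allow writing into an existing non-empty directory?
#' @return list: `annotation_host`, `annotation_phage`, `communities`
#'   (list of [simulate_community()] results), `manifest` tibble.
#' @export
generate_experiment <- function(config = synthetic_config(), out_dir = NULL,
                                overwrite = FALSE) {
  ann_h <- generate_annotation(config, "host")
  ann_p <- generate_annotation(config, "phage")
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        phage = c("plus", "minus"),
                        seed_bank = c("plus", "minus"),
                        stringsAsFactors = FALSE)
  communities <- vector("list", nrow(design))
  manifest <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    idx <- (d$seed_bank == "minus") * 6L + (d$phage == "minus") * 3L +
      as.integer(d$replicate)
    cseed <- derive_seed(config$seed, 10L + idx)
    communities[[i]] <- simulate_community(
      config, seed_bank = d$seed_bank, phage = d$phage,
      replicate_id = d$replicate, annotation_host = ann_h,
      annotation_phage = ann_p, seed = cseed)
    manifest[[i]] <- tibble::tibble(
      population_id = communities[[i]]$population_id,
      treatment_seedbank = d$seed_bank, treatment_phage = d$phage,
      replicate = d$replicate, seed = cseed,
      organisms = if (d$phage == "plus") "host,phage" else "host")
  }
  names(communities) <- vapply(communities, `[[`, "", "population_id")
  exp <- list(annotation_host = ann_h, annotation_phage = ann_p,
              communities = communities,
              manifest = dplyr::bind_rows(manifest), config = config)
  if (!is.null(out_dir)) write_experiment(exp, out_dir, overwrite)
  exp
}

write_experiment <- function(exp, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_annotation(exp$annotation_host,
                        file.path(out_dir, "annotation_host.tsv"))
  write_gene_annotation(exp$annotation_phage,
                        file.path(out_dir, "annotation_phage.tsv"))
  for (com in exp$communities) {
    write_mutation_table(com$host,
                         file.path(out_dir,
                                   paste0(com$population_id, "_host.tsv")))
    if (!is.null(com$phage)) {
      write_mutation_table(com$phage,
                           file.path(out_dir,
                                     paste0(com$population_id, "_phage.tsv")))
    }
  }
  utils::write.table(exp$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Configuration of the exchangeable null model
#'
#' All generator effects off: no coupling (gamma = 0), no seed-bank buffer
#' (c = 0), no selection or drift, no diversification burst, negligible
#' bottleneck loss, and the whole mutation supply arising in the first
#' transfer, so every observed trajectory is independent binomial sampling
#' noise around a constant latent frequency. Under this model timepoints
#' are exchangeable, which is the null hypothesis the permuted-time
#' machinery tests; it is the reference model for type-I calibration.
#'
#' @param host_genes,phage_genes,lambda_host,lambda_phage scaled-down
#'   problem sizes for replicated calibration runs.
#' @param ... further overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
null_calibration_config <- function(host_genes = 200, phage_genes = 50,
                                    lambda_host = 6, lambda_phage = 5, ...) {
  synthetic_config(gamma = 0, seedbank_weight = 0, s_driver = 0, sigma = 0,
                   burst_size = 0, s_background_sd = 0,
                   phage_s_background_mean = 0, phage_s_background_sd = 0,
                   sb_gene_fraction = 0, gamma_sb_attenuation = 1,
                   bottleneck_scale = 1e6, phage_bottleneck_scale = 1e6,
                   arrivals_first_transfer = TRUE,
                   host_genes = host_genes, phage_genes = phage_genes,
                   lambda_host = lambda_host, lambda_phage = lambda_phage,
                   ...)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror [synthetic_config()]
#' argument names; absent keys keep their defaults, unknown keys are an
#' error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(synthetic_config)))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, vals)
}
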