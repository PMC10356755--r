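# small in-code fixtures shared across test files

make_records <- function(freqs, gene_id = NULL, effect_class = "nonsynonymous",
                         population_id = "pop1", organism = "host",
                         seed_bank = "minus", phage = "plus",
                         timepoints = c(1, 4, 7, 10, 14)) {
  freqs <- if (is.matrix(freqs)) freqs else matrix(freqs, nrow = 1)
  n <- nrow(freqs)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(n))
  rec <- tibble::tibble(
    population_id = rep_len(population_id, n),
    treatment_seedbank = rep_len(seed_bank, n),
    treatment_phage = rep_len(phage, n),
    organism = rep_len(organism, n),
    mutation_id = sprintf("chr1:%06d:A", seq_len(n)),
    gene_id = rep_len(gene_id, n),
    effect_class = rep_len(effect_class, n))
  fr <- as.data.frame(freqs)
  names(fr) <- paste0("t", timepoints)
  out <- tibble::as_tibble(cbind(rec, fr))
  attr(out, "timepoints") <- as.integer(timepoints)
  out
}

make_annotation <- function(nonsyn_sites, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_along(nonsyn_sites))
  tibble::tibble(gene_id = gene_id,
                 length_nt = as.integer(ceiling(nonsyn_sites / 0.75)),
                 nonsyn_sites = nonsyn_sites)
}

# direct transcription of the multiplicity formula, kept deliberately naive
# and independent of gene_multiplicity()'s implementation
brute_force_multiplicity <- function(records, annotation) {
  cols <- grep("^t[0-9]+$", names(records), value = TRUE)
  L_bar <- mean(annotation$nonsyn_sites)
  out <- list()
  for (pop in unique(records$population_id)) {
    sub <- records[records$population_id == pop, ]
    for (g in unique(sub$gene_id)) {
      rows <- sub[sub$gene_id == g, ]
      f_meds <- c()
      for (i in seq_len(nrow(rows))) {
        traj <- as.numeric(rows[i, cols])
        pos <- traj[traj > 0]
        if (length(pos) > 0) f_meds <- c(f_meds, median(pos))
      }
      if (length(f_meds) == 0) next
      L_i <- annotation$nonsyn_sites[annotation$gene_id == g]
      out[[paste(pop, g)]] <- tibble::tibble(
        population_id = pop, gene_id = g,
        m = (L_bar / L_i) * sum(f_meds))
    }
  }
  dplyr::bind_rows(out)
}

random_toy_table <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:10, 1)
  ann <- make_annotation(round(runif(n_genes, 100, 1000), 2))
  n_mut <- sample(1:5, 1)
  freqs <- matrix(round(runif(n_mut * 5), 2) *
                    (runif(n_mut * 5) > 0.3), nrow = n_mut)
  genes <- sample(ann$gene_id, n_mut, replace = TRUE)
  rec <- make_records(freqs, gene_id = "x")
  rec$gene_id <- genes
  # drop all-zero mutations so multiplicity is defined
  keep <- rowSums(freqs) > 0
  list(records = rec[keep, , drop = FALSE], annotation = ann)
}
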