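#' Median of the nonzero entries of a trajectory
#'
#' Mutation frequencies of 0 mean "not detected"; the per-mutation weight is
#' the median frequency over time excluding those zeros. Returns 0 for an
#' all-zero trajectory (the caller drops such mutations).
#'
#' @param traj numeric vector of frequencies.
#' @return nonnegative scalar.
#' @export
median_nonzero_frequency <- function(traj) {
  stopifnot(length(traj) > 0)
  pos <- traj[traj > 0]
  if (length(pos) == 0) return(0)
  stats::median(pos)
}

#' Frequency-weighted gene multiplicity
#'
#' For gene i in population j,
#' \deqn{m_{i,j} = (\bar L / L_i) \sum_{k \in i} f_{med,j,k}}
#' where L_i is the gene's nonsynonymous target size, \eqn{\bar L} the mean
#' target size over *all* annotated genes (not only mutated ones), and
#' f_med the median nonzero frequency of mutation k over the timepoint grid.
#' Mutations never observed above 0 are dropped; genes with no retained
#' mutations are omitted (multiplicity is only defined for mutated genes).
#'
#' Records should already be restricted to nonsynonymous/insertion/deletion
#' classes via [filter_effect_classes()].
#'
#' @param records mutation record tibble (one or more populations).
#' @param annotation gene annotation tibble (`gene_id, length_nt,
#'   nonsyn_sites`).
#' @return tibble with columns `population_id, gene_id, n_mutations,
#'   f_med_sum, m`.
#' @export
gene_multiplicity <- function(records, annotation) {
  validate_annotation(annotation)
  cols <- tp_cols(record_timepoints(records))
  if (nrow(records) == 0) {
    return(tibble::tibble(population_id = character(), gene_id = character(),
                          n_mutations = integer(), f_med_sum = numeric(),
                          m = numeric()))
  }
  missing <- setdiff(unique(records$gene_id), annotation$gene_id)
  if (length(missing) > 0) {
    stop("mutated genes missing from annotation: ",
         paste(sort(missing), collapse = ", "))
  }
  f_med <- apply(as.matrix(records[, cols, drop = FALSE]), 1,
                 median_nonzero_frequency)
  keep <- f_med > 0
  records <- records[keep, , drop = FALSE]
  f_med <- f_med[keep]
  L_bar <- mean(annotation$nonsyn_sites)
  L <- stats::setNames(annotation$nonsyn_sites, annotation$gene_id)
  out <- tibble::tibble(population_id = records$population_id,
                        gene_id = records$gene_id, f_med = f_med) |>
    dplyr::group_by(.data$population_id, .data$gene_id) |>
    dplyr::summarise(n_mutations = dplyr::n(),
                     f_med_sum = sum(.data$f_med), .groups = "drop")
  out$m <- unname((L_bar / L[out$gene_id]) * out$f_med_sum)
  out
}

#' Relative gene multiplicity
#'
#' Normalises m within each population by the population's total m, so that
#' relative multiplicities sum to 1 per population and rank-abundance curves
#' are comparable across populations with different mutation loads.
#'
#' @param table multiplicity tibble from [gene_multiplicity()].
#' @param population_id optional single population to normalise; default all.
#' @return the table with an `m_rel` column added.
#' @export
relative_multiplicity <- function(table, population_id = NULL) {
  if (!is.null(population_id)) {
    table <- table[table$population_id %in% population_id, , drop = FALSE]
  }
  if (nrow(table) == 0 || any(tapply(table$m, table$population_id, sum) <= 0)) {
    stop("no normalizable multiplicity mass in population")
  }
  table |>
    dplyr::group_by(.data$population_id) |>
    dplyr::mutate(m_rel = .data$m / sum(.data$m)) |>
    dplyr::ungroup()
}

#' Rank-abundance view of relative multiplicity
#'
#' Genes of one population ordered by decreasing relative multiplicity; ties
#' broken lexicographically by gene_id so the ranking is deterministic.
#'
#' @param table multiplicity tibble with `m_rel` (see
#'   [relative_multiplicity()]).
#' @param population_id population to rank.
#' @return tibble `rank, gene_id, m_rel`, possibly empty.
#' @export
rank_abundance <- function(table, population_id) {
  sub <- table[table$population_id == population_id, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(rank = integer(), gene_id = character(),
                          m_rel = numeric()))
  }
  ord <- order(-sub$m_rel, sub$gene_id)
  tibble::tibble(rank = seq_len(nrow(sub)),
                 gene_id = sub$gene_id[ord],
                 m_rel = sub$m_rel[ord])
}
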