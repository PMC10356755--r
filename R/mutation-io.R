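#' @importFrom stats median cor rbinom rnorm runif rpois rlnorm setNames aggregate
#' @importFrom utils head
NULL

EFFECT_CLASSES <- c("nonsynonymous", "synonymous", "insertion", "deletion",
                    "intergenic", "other")

META_COLS <- c("population_id", "treatment_seedbank", "treatment_phage",
               "organism", "mutation_id", "gene_id", "effect_class")

#' Timepoint column names for a transfer grid
#'
#' @param timepoints integer vector of transfer numbers.
#' @return character vector like `c("t1", "t4", ...)`.
#' @keywords internal
tp_cols <- function(timepoints) paste0("t", timepoints)

#' Extract the timepoint grid from a record table
#'
#' The grid is stored as the `timepoints` attribute; if absent it is inferred
#' from the `t<n>` columns.
#'
#' @param records mutation record tibble.
#' @return increasing integer vector of transfer numbers.
#' @export
record_timepoints <- function(records) {
  tp <- attr(records, "timepoints")
  if (!is.null(tp)) return(tp)
  cols <- grep("^t[0-9]+$", names(records), value = TRUE)
  sort(as.integer(sub("^t", "", cols)))
}

#' Read a mutation frequency table
#'
#' Parses the tab-separated mutation-table dialect: one row per mutation per
#' population with metadata columns
#' `population_id, treatment_seedbank, treatment_phage, organism, mutation_id,
#' gene_id, effect_class` followed by one frequency column per sequenced
#' transfer (`t1`, `t4`, ...). A `.` or empty frequency field means the
#' mutation was not detected at that timepoint and is read as frequency 0.
#' Unknown effect classes are mapped to `"other"`.
#'
#' @param path path to a TSV file.
#' @param timepoints expected transfer grid (default `c(1, 4, 7, 10, 14)`).
#' @return a tibble of mutation records with a `timepoints` attribute.
#' @export
read_mutation_table <- function(path, timepoints = c(1, 4, 7, 10, 14)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty mutation table: ", path)
  expected <- c(META_COLS, tp_cols(timepoints))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    stop("mutation table header mismatch in ", path,
         "\n  expected: ", paste(expected, collapse = ", "),
         "\n  found:    ", paste(header, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  n_meta <- length(META_COLS)
  n_tp <- length(timepoints)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty frequency field is dropped by strsplit; restore it
  short <- nf == length(expected) - 1L & endsWith(body, "\t")
  fields[short] <- lapply(fields[short], function(x) c(x, ""))
  nf <- lengths(fields)
  bad <- which(nf != length(expected))
  if (length(bad) > 0) {
    stop("malformed row in ", path, " at line ", bad[1] + 1L,
         ": expected ", length(expected), " fields, found ", nf[bad[1]])
  }
  mat <- do.call(rbind, fields)
  meta <- as.data.frame(mat[, seq_len(n_meta), drop = FALSE],
                        stringsAsFactors = FALSE)
  names(meta) <- META_COLS
  fr <- mat[, n_meta + seq_len(n_tp), drop = FALSE]
  fr[fr == "." | fr == ""] <- "0"
  suppressWarnings(fnum <- matrix(as.numeric(fr), nrow = nrow(mat)))
  bad_num <- which(rowSums(is.na(fnum)) > 0)
  if (length(bad_num) > 0) {
    stop("non-numeric frequency in ", path, " at line ", bad_num[1] + 1L)
  }
  out_of_range <- which(rowSums(fnum < 0 | fnum > 1) > 0)
  if (length(out_of_range) > 0) {
    stop("frequency outside [0,1] in ", path, " at line ",
         out_of_range[1] + 1L)
  }
  key <- paste(meta$mutation_id, meta$population_id)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (mutation_id, population_id) in ", path, " at line ",
         d + 1L, ": ", key[d])
  }
  meta$effect_class[!(meta$effect_class %in% EFFECT_CLASSES)] <- "other"
  colnames(fnum) <- tp_cols(timepoints)
  records <- tibble::as_tibble(cbind(meta, as.data.frame(fnum)))
  attr(records, "timepoints") <- as.integer(timepoints)
  records
}

#' Write a mutation frequency table
#'
#' Inverse of [read_mutation_table()]. Output is byte-stable for identical
#' input: fixed column order, frequencies printed with 6 decimals, exact
#' zeros written as `.` (not detected).
#'
#' @param records mutation record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  tp <- record_timepoints(records)
  cols <- tp_cols(tp)
  fmt <- function(x) ifelse(x == 0, ".", sprintf("%.6f", x))
  out <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(unlist(records[i, META_COLS], use.names = FALSE),
            fmt(as.numeric(records[i, cols]))), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c(META_COLS, cols), collapse = "\t"), out), path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id, length_nt, nonsyn_sites`. `nonsyn_sites` is the
#' nonsynonymous target size L_i of each gene; the collection mean supplies
#' the genome-average target size used by [gene_multiplicity()].
#'
#' @param path path to a TSV file.
#' @return tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  tibble::as_tibble(ann)
}

#' Write a gene annotation table
#' @param annotation tibble with `gene_id, length_nt, nonsyn_sites`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  out <- sprintf("%s\t%d\t%.4f", annotation$gene_id,
                 as.integer(annotation$length_nt), annotation$nonsyn_sites)
  writeLines(c("gene_id\tlength_nt\tnonsyn_sites", out), path)
  invisible(path)
}

validate_annotation <- function(ann) {
  stopifnot(all(c("gene_id", "length_nt", "nonsyn_sites") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_ids in annotation")
  if (any(ann$length_nt <= 0) || any(ann$nonsyn_sites <= 0)) {
    stop("gene lengths and nonsynonymous site counts must be positive")
  }
  if (any(ann$nonsyn_sites > ann$length_nt)) {
    stop("nonsyn_sites exceeds length_nt for some genes")
  }
  invisible(ann)
}

#' Restrict records to the mutation classes analysed
#'
#' Keeps nonsynonymous mutations, insertions and deletions — the classes with
#' the largest potential fitness effect; synonymous, intergenic and other
#' records are dropped. Row order is preserved and the filter is idempotent.
#'
#' @param records mutation record tibble.
#' @param keep character vector of effect classes to retain.
#' @return filtered tibble.
#' @export
filter_effect_classes <- function(records,
                                  keep = c("nonsynonymous", "insertion",
                                           "deletion")) {
  out <- records[records$effect_class %in% keep, , drop = FALSE]
  attr(out, "timepoints") <- record_timepoints(records)
  out
}

#' Keep mutations detected at a minimum number of timepoints
#'
#' Used for trajectory analyses: a mutation's trajectory is only considered
#' when it was detected (frequency above `threshold`, default strictly
#' positive) in at least `min_timepoints` sequenced timepoints.
#'
#' @param records mutation record tibble.
#' @param min_timepoints minimum number of detected timepoints (default 3).
#' @param threshold detection threshold; a frequency is detected iff
#'   strictly greater than this value.
#' @return filtered tibble.
#' @export
filter_min_detection <- function(records, min_timepoints = 3, threshold = 0) {
  stopifnot(min_timepoints >= 1)
  cols <- tp_cols(record_timepoints(records))
  n_det <- rowSums(records[, cols, drop = FALSE] > threshold)
  out <- records[n_det >= min_timepoints, , drop = FALSE]
  attr(out, "timepoints") <- record_timepoints(records)
  out
}

#' Assemble a trajectory matrix for one population
#'
#' Rows are mutations (sorted by `mutation_id` for determinism), columns the
#' ordered transfer grid; unreported timepoints are 0. All records must come
#' from a single population and organism.
#'
#' @param records mutation record tibble for one population.
#' @param timepoints transfer grid; defaults to the records' grid.
#' @return numeric matrix with `population_id`, `organism`, `treatment`
#'   attributes.
#' @export
build_trajectory_matrix <- function(records, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- record_timepoints(records)
  cols <- tp_cols(timepoints)
  if (nrow(records) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(cols),
                dimnames = list(NULL, cols))
    return(m)
  }
  if (length(unique(records$population_id)) > 1 ||
      length(unique(records$organism)) > 1) {
    stop("records mix populations or organisms; build one matrix per ",
         "population")
  }
  ord <- order(records$mutation_id)
  records <- records[ord, , drop = FALSE]
  m <- as.matrix(records[, cols, drop = FALSE])
  rownames(m) <- records$mutation_id
  attr(m, "population_id") <- records$population_id[[1]]
  attr(m, "organism") <- records$organism[[1]]
  attr(m, "treatment") <- c(seed_bank = records$treatment_seedbank[[1]],
                            phage = records$treatment_phage[[1]])
  attr(m, "timepoints") <- as.integer(timepoints)
  m
}
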