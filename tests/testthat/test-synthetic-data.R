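small_cfg <- function(...) synthetic_config(host_genes = 200,
                                            phage_genes = 50, ...)

test_that("annotations are deterministic with the configured conventions", {
  cfg <- small_cfg(seed = 3)
  ann <- generate_annotation(cfg, "host")
  expect_equal(nrow(ann), 200)
  expect_equal(anyDuplicated(ann$gene_id), 0)
  expect_equal(ann$nonsyn_sites / ann$length_nt, rep(0.75, 200),
               tolerance = 1e-12)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_gene_annotation(ann, f1)
  write_gene_annotation(generate_annotation(cfg, "host"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero mutation supply yields empty tables", {
  cfg <- small_cfg(lambda_host = 0, lambda_phage = 0, burst_size = 0,
                   s_driver = 0)
  com <- simulate_community(cfg, "plus", "plus", 1,
                            generate_annotation(cfg, "host"),
                            generate_annotation(cfg, "phage"), seed = 1)
  expect_equal(nrow(com$host), 0)
  expect_equal(nrow(com$phage), 0)
})

test_that("observed frequencies live on the coverage lattice", {
  cfg <- small_cfg(seed = 2, coverage = 100)
  com <- simulate_community(cfg, "minus", "plus", 1,
                            generate_annotation(cfg, "host"),
                            generate_annotation(cfg, "phage"), seed = 7)
  cols <- paste0("t", cfg$timepoints)
  f <- as.matrix(com$host[, cols])
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(abs(f * 100 - round(f * 100)) < 1e-9))
  expect_true(all(f[f > 0] >= cfg$reporting_floor))
})

test_that("the full experiment has the 2x2x3 design and a seed manifest", {
  exp <- generate_experiment(small_cfg(seed = 4))
  expect_length(exp$communities, 12)
  phage_tabs <- Filter(Negate(is.null),
                       lapply(exp$communities, `[[`, "phage"))
  expect_length(phage_tabs, 6)
  expect_equal(nrow(exp$manifest), 12)
  expect_equal(anyDuplicated(exp$manifest$seed), 0)
  expect_equal(sort(table(exp$manifest$treatment_seedbank)), sort(c(6, 6)),
               ignore_attr = TRUE)
})

test_that("experiments are reproducible and directories are protected", {
  cfg <- small_cfg(seed = 9)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_equal(e1$communities[["SBplus_Pplus_r1"]]$host,
               e2$communities[["SBplus_Pplus_r1"]]$host)
  dir <- withr::local_tempdir()
  generate_experiment(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_error(generate_experiment(cfg, out_dir = dir), "overwrite")
  files <- list.files(dir)
  expect_equal(sum(grepl("^SB.*_host\\.tsv$", files)), 12)
  expect_equal(sum(grepl("^SB.*_phage\\.tsv$", files)), 6)
})

test_that("with the buffer off and symmetric coupling, treatments coincide", {
  cfg <- small_cfg(seed = 5, seedbank_weight = 0, gamma_sb_attenuation = 1,
                   sb_gene_fraction = 0)
  ann_h <- generate_annotation(cfg, "host")
  ann_p <- generate_annotation(cfg, "phage")
  a <- simulate_community(cfg, "plus", "plus", 1, ann_h, ann_p, seed = 33)
  b <- simulate_community(cfg, "minus", "plus", 1, ann_h, ann_p, seed = 33)
  cols <- c("mutation_id", "gene_id", "effect_class",
            paste0("t", cfg$timepoints))
  expect_equal(as.data.frame(a$host[, cols]), as.data.frame(b$host[, cols]))
  expect_equal(as.data.frame(a$phage[, cols]),
               as.data.frame(b$phage[, cols]))
})

test_that("stronger buffering weakly increases retained gene counts", {
  count_genes <- function(cw, s) {
    cfg <- small_cfg(seed = s, seedbank_weight = cw)
    com <- simulate_community(cfg, "plus", "minus", 1,
                              generate_annotation(cfg, "host"),
                              NULL, seed = s + 100)
    length(unique(filter_effect_classes(com$host)$gene_id))
  }
  lo <- vapply(1:10, function(s) count_genes(0.2, s), numeric(1))
  hi <- vapply(1:10, function(s) count_genes(0.7, s), numeric(1))
  expect_gte(mean(hi), mean(lo))
})

test_that("the exchangeable null model has uncorrelated trajectories", {
  cfg0 <- null_calibration_config()
  ann_h <- generate_annotation(cfg0, "host")
  ann_p <- generate_annotation(cfg0, "phage")
  rs <- unlist(lapply(1:8, function(s) {
    com <- simulate_community(cfg0, "minus", "plus", 1, ann_h, ann_p,
                              seed = s + 700)
    hm <- build_trajectory_matrix(
      filter_min_detection(filter_effect_classes(com$host), 3))
    pm <- build_trajectory_matrix(
      filter_min_detection(filter_effect_classes(com$phage), 3))
    if (nrow(hm) == 0 || nrow(pm) == 0) return(NULL)
    pair_correlations(eligible_pairs(hm, pm, 3), hm, pm)$pairs$r
  }))
  expect_gt(length(rs), 100)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.02)
})

test_that("infected no-seed-bank hosts carry a sweeping driver", {
  cfg <- synthetic_config(seed = 1)
  ann_h <- generate_annotation(cfg, "host")
  ann_p <- generate_annotation(cfg, "phage")
  drivers <- ann_h$gene_id[utils::head(order(-ann_h$nonsyn_sites),
                                       cfg$n_driver_genes_host)]
  hits <- vapply(1:15, function(s) {
    com <- simulate_community(cfg, "minus", "plus", 1, ann_h, ann_p,
                              seed = s + 2000)
    any(high_frequency_report(com$host, 0.3)$gene_id %in% drivers)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("generator configurations round trip through config files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 12", "host_genes: 150", "coverage: 60"), yml)
  cfg <- synthetic_config_from_file(yml)
  expect_equal(cfg$seed, 12)
  expect_equal(cfg$host_genes, 150)
  expect_equal(cfg$coverage, 60)
  expect_equal(cfg$n_replicates, 3)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_knob: 1", bad)
  expect_error(synthetic_config_from_file(bad), "unknown")
})
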