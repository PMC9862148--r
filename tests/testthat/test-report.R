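# small, fast pipeline configuration reused across report tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_snps_panel = 150L, n_snps_background = 150L,
             coseg_fraction = 0.1, invariant_rate = 0.1,
             missing_rate = 0.01,
             grid_shape = c(56L, 56L, 56L),
             mask_slices_per_axis = c(12L, 30L), seed = seed, ...)
}
small_cfg <- function(out_dir, seed = 1L, write_artifacts = FALSE, ...) {
  pipeline_config(simulation = small_sim(seed, ...),
                  roi_set = c("fusiform", "superior_temporal"),
                  morph_rois = unique(c(whole_cortex_rois(),
                                        reading_region_set()$rois)),
                  axes = "axial", out_dir = out_dir,
                  write_artifacts = write_artifacts)
}

test_that("the pipeline report has one ICC entry per pair, phenotype and region set", {
  rep <- run_pipeline(small_cfg(withr::local_tempdir()))
  icc <- rep$icc
  expect_identical(nrow(icc), 3L * 3L * 2L)
  counts <- table(icc$phenotype, icc$region_set)
  expect_true(all(counts == 3L))
  expect_setequal(unique(icc$pair), c("twin-twin", "SRD", "TD-OS"))
})

test_that("the same config and seed reproduce an identical report", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(small_cfg(d1, write_artifacts = TRUE))
  r2 <- run_pipeline(small_cfg(d2, write_artifacts = TRUE))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(render_summary(r1), render_summary(r2))
})

test_that("rendered summary carries the three sections with conserved tallies", {
  rep <- run_pipeline(small_cfg(withr::local_tempdir(), seed = 2L))
  txt <- render_summary(rep)
  for (h in c("== Genetics Results ==", "== Asymmetry Analyses ==",
              "== Image Analyses ==")) {
    expect_true(any(txt == h))
  }
  res <- rep$genetics$result
  gene_counts <- as.integer(sub(".*: (\\d+) SNP.*", "\\1",
                                grep(" SNP\\(s\\)$", txt, value = TRUE)))
  expect_identical(sum(gene_counts), length(res$matching_snps))
  expect_true(any(grepl("most similar", txt)))
  expect_true(all(rep$asymmetry$direction %in%
                    c("leftward", "rightward", "symmetric")))
})

test_that("planted mask structure drives the reported most-similar pairs", {
  # fusiform: TD twin and older sibling closest; superior temporal: SRD pair
  prof <- dplyr::bind_rows(
    tibble::tibble(roi = "fusiform",
                   subject_id = c("proband", "td_twin", "older_sib"),
                   scale = c(-0.20, 0, 0.05)),
    tibble::tibble(roi = "superior_temporal",
                   subject_id = c("proband", "td_twin", "older_sib"),
                   scale = c(0, -0.20, 0.05)))
  cfg <- small_cfg(withr::local_tempdir(), seed = 3L, mask_profile = prof)
  rep <- run_pipeline(cfg)
  ms <- rep$image$inter$most_similar
  expect_identical(ms$label[ms$roi == "fusiform"], "TD-OS")
  expect_identical(ms$label[ms$roi == "superior_temporal"], "SRD")
})

test_that("stage artifacts are written where requested", {
  d <- withr::local_tempdir()
  rep <- run_pipeline(small_cfg(d, write_artifacts = TRUE))
  for (f in c("family.vcf", "family.ped.tsv", "morphometry.tsv",
              "ground_truth.json", "icc_results.tsv",
              "asymmetry_table.tsv", "report.json", "report.txt",
              "genetics/coseg_results.json", "genetics/coseg_snps.tsv",
              "qq_summary.json")) {
    expect_true(file.exists(file.path(d, f)), info = f)
  }
  expect_gt(length(list.files(file.path(d, "masks"))), 0L)
  expect_gt(length(list.files(file.path(d, "composites"))), 0L)
  # ground-truth ledger agrees with the recomputed co-segregation set on
  # SNPs that survived QC
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  res <- jsonlite::read_json(file.path(d, "genetics/coseg_results.json"),
                             simplifyVector = TRUE)
  expect_true(all(res$matching_snps %in% gt$planted_coseg))
})

test_that("config validation rejects mixed or missing input sources", {
  expect_error(pipeline_config(simulation = NULL), class = "config_error")
  expect_error(pipeline_config(simulation = sim_config(), vcf = "x.vcf",
                               pedigree = "p", morphometry = "m",
                               mask_dir = "d"),
               class = "config_error")
})
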