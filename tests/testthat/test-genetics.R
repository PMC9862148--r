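coh <- family_cohort()

test_that("no-call QC masks scores at the boundary and keeps scores just above", {
  tab <- toy_genotype_table()
  tab$gc["t02", "proband"] <- 0.15        # exactly at threshold -> missing
  tab$gc["t04", "proband"] <- 0.1500001   # just above -> retained
  qc <- apply_gencall_qc(tab)
  expect_true(is.na(qc$gt["t02", "proband"]))
  expect_identical(qc$gt["t04", "proband"], tab$gt["t04", "proband"])
  # full-confidence table passes through unchanged
  clean <- toy_genotype_table()
  clean$gc[] <- 1
  clean$gc[is.na(clean$gt)] <- NA
  expect_identical(apply_gencall_qc(clean)$gt, clean$gt)
  # idempotent
  expect_identical(apply_gencall_qc(qc)$gt, qc$gt)
})

test_that("lowering the QC threshold never decreases retained calls", {
  cfg <- sim_config(n_snps_panel = 300L, missing_rate = 0.15, seed = 2L)
  g <- simulate_genotypes(coh, gene_panel(), cfg)
  retained <- vapply(c(0.5, 0.3, 0.15, 0.05, 0),
                     function(th) sum(!is.na(apply_gencall_qc(g, th)$gt)),
                     numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("invariant filter drops invariant and partially-missing SNPs", {
  tab <- toy_genotype_table()
  filt <- drop_family_invariant_snps(tab)
  expect_identical(nrow(filt$gt), 6L)    # 10 - 3 invariant - 1 missing
  expect_false(any(c("t01", "t03", "t05", "t08") %in% filt$info$snp_id))
  expect_error(drop_family_invariant_snps(tab, character(0)),
               class = "argument_error")
  # idempotent on its own output
  expect_identical(drop_family_invariant_snps(filt)$info$snp_id,
                   filt$info$snp_id)
})

test_that("co-segregation match uses unordered allele pairs", {
  subjects <- c("mother", "father", "proband", "td_twin", "older_sib")
  info <- tibble::tibble(snp_id = c("s1", "s2"), chrom = "chr1",
                         pos = c(10L, 20L), ref = "A", alt = "G")
  gt <- rbind(c("A/G", "A/G", "A/G", "A/A", "G/A"),  # matches (A/G == G/A)
              c("A/G", "A/G", "A/G", "G/A", "A/G"))  # twin equal -> no match
  colnames(gt) <- subjects
  gc <- matrix(1, 2, 5, dimnames = list(info$snp_id, subjects))
  tab <- genotype_table(info, gt, gc)
  res <- find_cosegregating_snps(tab, c("proband", "older_sib"), "td_twin")
  expect_identical(res$matching_snps, "s1")
  expect_error(find_cosegregating_snps(tab, "proband", "td_twin"),
               class = "argument_error")
})

test_that("pattern matching equals the brute-force triple loop on random tables", {
  for (seed in c(1L, 13L)) {
    cfg <- sim_config(n_snps_panel = 500L, coseg_fraction = 0.08,
                      invariant_rate = 0.1, missing_rate = 0.05, seed = seed)
    g <- simulate_genotypes(coh, gene_panel(), cfg)
    filt <- drop_family_invariant_snps(apply_gencall_qc(g))
    res <- find_cosegregating_snps(filt, coh$affected_sibling_ids,
                                   coh$discordant_id)
    expect_setequal(res$matching_snps,
                    oracle_coseg(filt$gt, "proband", "older_sib", "td_twin"))
  }
})

test_that("planted pattern SNPs are recovered exactly when nothing is missing", {
  cfg <- sim_config(n_snps_panel = 400L, coseg_fraction = 0.1,
                    invariant_rate = 0.15, missing_rate = 0, seed = 6L)
  g <- simulate_genotypes(coh, gene_panel(), cfg)
  filt <- drop_family_invariant_snps(apply_gencall_qc(g))
  res <- find_cosegregating_snps(filt, coh$affected_sibling_ids,
                                 coh$discordant_id)
  expect_setequal(res$matching_snps, attr(g, "truth")$planted)
})

test_that("per-gene and per-class tallies always sum to the match count", {
  cfg <- sim_config(n_snps_panel = 300L, coseg_fraction = 0.12,
                    missing_rate = 0.05, seed = 8L)
  g <- annotate_snps(simulate_genotypes(coh, gene_panel(), cfg),
                     gene_panel())
  filt <- drop_family_invariant_snps(apply_gencall_qc(g))
  res <- find_cosegregating_snps(filt, coh$affected_sibling_ids,
                                 coh$discordant_id)
  expect_identical(sum(res$per_gene_counts),
                   length(res$matching_snps))
  expect_identical(sum(res$per_class_counts),
                   length(res$matching_snps))
  expect_equal(res$panel_proportion,
               length(res$matching_snps) / res$n_panel_variable)
})

test_that("gene assignment matches a brute-force interval scan, flank included", {
  panel <- gene_panel(tibble::tibble(
    symbol = c("GENE_A", "GENE_B"),
    chrom = "chr1", start = c(1000L, 5000L), end = c(2000L, 6000L)),
    flank_bp = 500L)
  info <- tibble::tibble(
    snp_id = sprintf("s%d", 1:6), chrom = "chr1",
    pos = c(500L, 1500L, 2400L, 4600L, 5500L, 7000L),
    ref = "A", alt = "G")
  gt <- matrix("A/G", 6, 5,
               dimnames = list(info$snp_id,
                               c("mother", "father", "proband", "td_twin",
                                 "older_sib")))
  gc <- matrix(1, 6, 5, dimnames = dimnames(gt))
  tab <- annotate_snps(genotype_table(info, gt, gc), panel)

  brute <- vapply(info$pos, function(p) {
    hit <- which(p >= panel$start - 500L & p <= panel$end + 500L)
    if (length(hit) == 0L) NA_character_ else panel$symbol[hit[1]]
  }, character(1))
  expect_identical(tab$info$gene_symbol, brute)
  # interval fallback classes: body -> intronic, flank-only -> intergenic
  # (s1 at pos 500 sits exactly on the flank boundary 1000 - 500)
  expect_identical(tab$info$functional_class,
                   c("intergenic", "intronic", "intergenic", "intergenic",
                     "intronic", "unannotated"))
})

test_that("background comparison computes both proportions the same way", {
  cfg <- sim_config(n_snps_panel = 400L, n_snps_background = 400L,
                    coseg_fraction = 0.1, invariant_rate = 0.1,
                    missing_rate = 0, seed = 12L)
  g <- simulate_genotypes(coh, gene_panel(), cfg)
  bg <- simulate_genotypes(coh, NULL, cfg, n_snps = cfg$n_snps_background,
                           seed_offset = 50L)
  filt <- drop_family_invariant_snps(apply_gencall_qc(g))
  res <- find_cosegregating_snps(filt, coh$affected_sibling_ids,
                                 coh$discordant_id)
  res <- background_comparison(res, apply_gencall_qc(bg), coh)
  expect_equal(res$panel_proportion, 40 / 360, tolerance = 1e-12)
  expect_equal(res$background_proportion, 40 / 360, tolerance = 1e-12)
  # background with nothing planted
  cfg0 <- sim_config(n_snps_background = 200L, coseg_fraction = 0,
                     missing_rate = 0, seed = 12L)
  bg0 <- simulate_genotypes(coh, NULL, cfg0, n_snps = 200L, seed_offset = 51L)
  res0 <- background_comparison(res, apply_gencall_qc(bg0), coh)
  expect_identical(res0$background_proportion, 0)
})

test_that("QC -> invariant -> pattern pipeline is idempotent on its own output", {
  cfg <- sim_config(n_snps_panel = 200L, missing_rate = 0.05, seed = 3L)
  g <- simulate_genotypes(coh, gene_panel(), cfg)
  once <- drop_family_invariant_snps(apply_gencall_qc(g))
  twice <- drop_family_invariant_snps(apply_gencall_qc(once))
  expect_identical(twice$gt, once$gt)
})
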