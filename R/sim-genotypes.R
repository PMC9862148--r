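#' Simulate family genotypes with planted co-segregation structure
#'
#' Generates biallelic SNP calls for all five family members, Mendel-consistent
#' within the two trios (each child's genotype is built from one transmitted
#' allele per parent). Exactly `round(coseg_fraction * n_snps)` SNPs are
#' planted with the SRD co-segregation pattern (the two affected siblings
#' share a genotype, the unaffected twin differs); `invariant_rate * n_snps`
#' SNPs are identical across all five members; every remaining SNP is
#' guaranteed to be neither invariant nor pattern-matching, so the planted
#' set is recoverable exactly. A `missing_rate` fraction of calls receives a
#' confidence score at or below the 0.15 no-call threshold (the call itself
#' stays present until [apply_gencall_qc()] masks it).
#'
#' @param cohort A [family_cohort()].
#' @param panel A [gene_panel()], or `NULL` for background SNPs carrying no
#'   gene assignment (placed on chromosomes outside the panel).
#' @param cfg A [sim_config()].
#' @param n_snps Number of SNPs (default `cfg$n_snps_panel`; use
#'   `cfg$n_snps_background` with `panel = NULL` for a background set).
#' @param seed_offset Added to `cfg$seed` so several tables can be drawn from
#'   one config without sharing a stream (default 0).
#' @return A [genotype_table()] with attribute `truth`: a list with
#'   `planted` and `invariant` SNP-id vectors.
#' @export
simulate_genotypes <- function(cohort, panel, cfg,
                               n_snps = cfg$n_snps_panel,
                               seed_offset = 0L) {
  if (!inherits(cohort, "family_cohort")) {
    ts_abort("`cohort` must be a family_cohort", "cohort_error")
  }
  stopifnot(inherits(cfg, "sim_config"))
  n_snps <- assert_count(n_snps, "n_snps", min = 1L)
  if (!is.null(panel) && !inherits(panel, "gene_panel")) {
    ts_abort("`panel` must be a gene_panel or NULL", "argument_error")
  }
  if (!is.null(panel) && nrow(panel) == 0L) {
    ts_abort("panel must be non-empty", "argument_error")
  }

  subjects <- cohort$subjects$subject_id
  parents <- cohort$subjects$subject_id[cohort$subjects$role == "parent"]
  aff <- cohort$affected_sibling_ids
  disc <- cohort$discordant_id
  children <- c(aff[1], disc, aff[2])

  with_seed(cfg$seed + seed_offset, {
    loc <- place_snps(panel, n_snps)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    n_coseg <- round(cfg$coseg_fraction * n_snps)
    n_inv <- round(cfg$invariant_rate * n_snps)
    kind <- rep("other", n_snps)
    kind[sample.int(n_snps, n_coseg + n_inv)] <-
      rep(c("coseg", "invariant"), c(n_coseg, n_inv))

    gt <- matrix(NA_character_, n_snps, 5L,
                 dimnames = list(NULL, subjects))
    for (i in seq_len(n_snps)) {
      a <- ref[i]; b <- alt[i]
      gt[i, ] <- draw_family_genotypes(kind[i], a, b, subjects, parents,
                                       aff, disc)
    }

    # functional classes: realistic mix for panel SNPs, intergenic outside
    if (!is.null(panel)) {
      fclass <- sample(c("intronic", "exonic", "utr3", "intergenic"),
                       n_snps, replace = TRUE,
                       prob = c(0.72, 0.013, 0.013, 0.254))
    } else {
      fclass <- sample(c("intergenic", "unannotated"), n_snps,
                       replace = TRUE, prob = c(0.8, 0.2))
    }

    low <- matrix(runif(n_snps * 5L) < cfg$missing_rate, n_snps, 5L)
    gc <- matrix(runif(n_snps * 5L, 0.5, 1), n_snps, 5L)
    gc[low] <- runif(sum(low), 0.01, 0.15)

    info <- tibble::tibble(
      snp_id = loc$snp_id, chrom = loc$chrom, pos = loc$pos,
      ref = ref, alt = alt, gene_symbol = loc$gene_symbol,
      functional_class = fclass
    )
    tab <- genotype_table(info, gt, gc)
    attr(tab, "truth") <- list(planted = info$snp_id[kind == "coseg"],
                               invariant = info$snp_id[kind == "invariant"])
    tab
  })
}

# lay SNPs out along gene intervals (or background chromosomes), positions
# strictly increasing within each chromosome
place_snps <- function(panel, n_snps) {
  if (is.null(panel)) {
    chrom_levels <- paste0("chr", 10:15)
    counts <- as.vector(stats::rmultinom(1L, n_snps,
                                         rep(1, length(chrom_levels))))
    chrom <- rep(chrom_levels, counts)
    pos <- unlist(lapply(counts, function(k) sort(sample.int(5e7, k))),
                  use.names = FALSE)
    return(tibble::tibble(snp_id = sprintf("bg_%05d", seq_len(n_snps)),
                          chrom = chrom, pos = pos,
                          gene_symbol = NA_character_))
  }
  idx <- sort(rep_len(seq_len(nrow(panel)), n_snps))
  per_gene <- tabulate(idx, nbins = nrow(panel))
  out <- vector("list", nrow(panel))
  for (g in seq_len(nrow(panel))) {
    k <- per_gene[g]
    if (k == 0L) next
    out[[g]] <- tibble::tibble(
      chrom = panel$chrom[g],
      pos = sort(sample(seq(panel$start[g], panel$end[g]), k)),
      gene_symbol = panel$symbol[g]
    )
  }
  loc <- dplyr::bind_rows(out)
  loc <- loc[order(loc$chrom, loc$pos), ]
  loc$snp_id <- sprintf("snp_%05d", seq_len(nrow(loc)))
  loc
}

# one SNP's five genotypes honouring the requested pattern kind
draw_family_genotypes <- function(kind, a, b, subjects, parents, aff, disc) {
  g <- setNames(character(5L), subjects)
  hom_a <- paste(a, a, sep = "/"); hom_b <- paste(b, b, sep = "/")
  het <- paste(sort(c(a, b)), collapse = "/")
  if (kind == "invariant") {
    shared <- sample(c(hom_a, hom_b, het), 1L, prob = c(0.6, 0.2, 0.2))
    # het everywhere requires het parents; hom requires matching hom parents
    g[] <- shared
    return(g)
  }
  if (kind == "coseg") {
    # het x het parents make all three offspring genotypes reachable
    g[parents] <- het
    choices <- c(hom_a, het, hom_b)
    shared <- sample(choices, 1L, prob = c(0.25, 0.5, 0.25))
    differing <- sample(setdiff(choices, shared), 1L)
    g[aff] <- shared
    g[disc] <- differing
    return(g)
  }
  # "other": Mendel-consistent random genotypes that are neither invariant
  # across the family nor matching the co-segregation pattern
  repeat {
    p <- runif(1, 0.2, 0.8)
    par_al <- matrix(sample(c(a, b), 4L, replace = TRUE, prob = c(p, 1 - p)),
                     2L, 2L)
    g[parents] <- apply(par_al, 1L, function(al)
      paste(sort(al), collapse = "/"))
    kids <- vapply(seq_len(3L), function(i) {
      al <- c(par_al[1L, sample.int(2L, 1L)], par_al[2L, sample.int(2L, 1L)])
      paste(sort(al), collapse = "/")
    }, character(1))
    g[c(aff[1], disc, aff[2])] <- kids[c(1L, 2L, 3L)]
    invariant <- length(unique(g)) == 1L
    matches <- g[aff[1]] == g[aff[2]] && g[disc] != g[aff[1]]
    if (!invariant && !matches) return(g)
  }
}
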