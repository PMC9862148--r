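# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# triple-condition loop over raw genotype strings (allele-sorted comparison)
oracle_coseg <- function(gt, aff1, aff2, disc) {
  norm <- function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "/", fixed = TRUE)[[1]]), collapse = "/")
  }
  hits <- character(0)
  for (i in seq_len(nrow(gt))) {
    a <- norm(gt[i, aff1]); b <- norm(gt[i, aff2]); d <- norm(gt[i, disc])
    if (is.na(a) || is.na(b) || is.na(d)) next
    if (a == b && d != a) hits <- c(hits, rownames(gt)[i])
  }
  hits
}

# Mendelian check: every child genotype must be producible from one allele
# of each parent
oracle_mendel_ok <- function(gt, mother, father, children) {
  al <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(gt))) {
    gm <- gt[i, mother]; gf <- gt[i, father]
    if (is.na(gm) || is.na(gf)) next
    am <- al(gm); af <- al(gf)
    possible <- unique(vapply(
      seq_len(4L),
      function(k) paste(sort(c(am[(k - 1) %/% 2 + 1], af[(k - 1) %% 2 + 1])),
                        collapse = "/"),
      character(1)))
    for (ch in children) {
      g <- gt[i, ch]
      if (is.na(g)) next
      g <- paste(sort(al(g)), collapse = "/")
      if (!(g %in% possible)) return(FALSE)
    }
  }
  TRUE
}

# ICC forms from stats::aov mean squares (independent of icc_single)
oracle_icc_aov <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  item = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  two <- summary(stats::aov(y ~ item + rater, data = d))[[1]]
  MSR <- two["item", "Mean Sq"]; MSC <- two["rater", "Mean Sq"]
  MSE <- two["Residuals", "Mean Sq"]
  one <- summary(stats::aov(y ~ item, data = d))[[1]]
  MSW <- one["Residuals", "Mean Sq"]
  switch(form,
         "ICC(1,1)" = (MSR - MSW) / (MSR + (k - 1) * MSW),
         "ICC(2,1)" = (MSR - MSE) /
           (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
         "ICC(3,1)" = (MSR - MSE) / (MSR + (k - 1) * MSE))
}

# per-voxel projection count along one array dimension
oracle_projection_counts <- function(vox, d) {
  dims <- dim(vox)
  other <- setdiff(1:3, d)
  out <- matrix(0L, dims[other[1]], dims[other[2]])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (vox[i, j, k] == 0) next
      idx <- c(i, j, k)
      out[idx[other[1]], idx[other[2]]] <-
        out[idx[other[1]], idx[other[2]]] + 1L
    }
  out
}

# linear interpolation between order statistics at probability p
# (independent re-derivation of the type-7 rule)
oracle_quantile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# small deterministic genotype-table fixture built by hand
toy_genotype_table <- function() {
  subjects <- c("mother", "father", "proband", "td_twin", "older_sib")
  info <- tibble::tibble(
    snp_id = sprintf("t%02d", 1:10),
    chrom = "chr1", pos = seq(100L, 1000L, by = 100L),
    ref = "A", alt = "G",
    gene_symbol = rep(c("MRPL19", "ZNF385D"), each = 5L),
    functional_class = rep(c("intronic", "exonic", "utr3", "intergenic",
                             "intronic"), 2L)
  )
  het <- "A/G"; aa <- "A/A"; gg <- "G/G"
  gt <- rbind(
    c(aa, aa, aa, aa, aa),      # invariant
    c(het, het, aa, het, aa),   # coseg pattern (proband/older_sib AA, twin het)
    c(het, het, het, het, het), # invariant
    c(het, aa, het, aa, het),   # coseg pattern
    c(gg, gg, gg, gg, gg),      # invariant
    c(het, het, aa, aa, gg),    # variable, not matching (twin equals proband)
    c(het, het, het, aa, gg),   # variable, not matching (affected differ)
    c(aa, het, aa, het, NA),    # missing call
    c(het, het, gg, aa, gg),    # coseg pattern
    c(aa, het, het, aa, aa)     # variable, not matching? proband het, os aa -> differ
  )
  colnames(gt) <- subjects
  gc <- matrix(0.9, 10L, 5L, dimnames = list(info$snp_id, subjects))
  gc[is.na(gt)] <- NA
  genotype_table(info, gt, gc)
}
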