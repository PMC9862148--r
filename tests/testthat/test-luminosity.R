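test_that("slice_mask returns only nonzero slices in anatomical order", {
  vox <- array(0L, c(8, 8, 8))
  vox[3:5, 4, 4] <- 1L
  m <- mask_volume(vox, "s", "fusiform")
  st <- slice_mask(m, "sagittal")
  expect_identical(attr(st, "n_slices"), 3L)
  expect_identical(attr(slice_mask(m, "coronal"), "n_slices"), 1L)
  # single voxel: one slice per axis with one nonzero pixel
  v1 <- array(0L, c(8, 8, 8)); v1[2, 3, 4] <- 1L
  m1 <- mask_volume(v1, "s", "fusiform")
  for (ax in c("sagittal", "coronal", "axial")) {
    s1 <- slice_mask(m1, ax)
    expect_identical(attr(s1, "n_slices"), 1L)
    expect_identical(sum(s1[[1]]), 1L)
  }
})

test_that("composite luminosity follows the alpha-standardization rule", {
  # single slice, alpha_ref 1: foreground 255, background 0
  slice <- matrix(0L, 4, 4); slice[2, 2:3] <- 1L
  cmp <- build_composite(list(slice), 1L)
  expect_identical(sort(unique(as.vector(cmp$pixels))), c(0L, 255L))
  # pixel present in 20 of alpha_ref 40 slices -> round(255 * 20/40) = 128
  stack <- c(replicate(20, slice, simplify = FALSE),
             replicate(20, matrix(0L, 4, 4), simplify = FALSE))
  # zero slices would be dropped by slice_mask; emulate presence in 20 of 40
  cmp2 <- build_composite(stack[1:20], 40L)
  expect_identical(cmp2$pixels[2, 2], 128L)
  expect_identical(cmp2$pixels[1, 1], 0L)
  # alpha_ref below the stack size is a standardization error
  expect_error(build_composite(stack[1:20], 10L),
               class = "standardization_error")
})

test_that("composites equal the brute-force per-voxel projection on random masks", {
  set.seed(11)
  for (rep in 1:3) {
    vox <- array(as.integer(runif(8^3) < 0.3), c(8, 8, 8))
    if (sum(vox) == 0) vox[1, 1, 1] <- 1L
    m <- mask_volume(vox, "s", "fusiform")
    for (ax in c("sagittal", "coronal", "axial")) {
      d <- c(sagittal = 1L, coronal = 2L, axial = 3L)[[ax]]
      st <- slice_mask(m, ax)
      aref <- attr(st, "n_slices")
      cmp <- build_composite(st, aref)
      counts <- oracle_projection_counts(vox, d)
      expect_identical(cmp$pixels,
                       matrix(pmin(255L,
                                   as.integer(round(255 * counts / aref))),
                              nrow(counts), ncol(counts)))
    }
  }
})

test_that("distribution extraction matches a pixel scan under both background rules", {
  set.seed(5)
  vox <- array(as.integer(runif(16^3) < 0.4), c(16, 16, 16))
  m <- mask_volume(vox, "s", "fusiform")
  st <- slice_mask(m, "axial")
  cmp <- build_composite(st, attr(st, "n_slices"))
  d <- extract_distribution(cmp)
  px <- as.vector(cmp$pixels)
  expect_identical(sort(d$values), sort(px[px > 0]))
  d0 <- extract_distribution(cmp, "include_zero")
  expect_identical(sort(d0$values), sort(px))
  # uniform composite: one value with multiplicity = foreground count
  u <- build_composite(list(matrix(1L, 3, 3)), 2L)
  du <- extract_distribution(u)
  expect_identical(du$values, rep(128L, 9L))
  one <- build_composite(list(matrix(c(0L, 1L), 1, 2)), 1L)
  expect_identical(extract_distribution(one)$values, 255L)
})

test_that("quantiles match the order-statistics oracle; divergence behaves", {
  set.seed(23)
  x <- sample.int(255, 1000, replace = TRUE)
  dA <- structure(list(values = x, background_rule = "exclude_zero",
                       axis = "axial"), class = "luminosity_distribution")
  y <- pmin(x + 50, 255)
  dB <- structure(list(values = y, background_rule = "exclude_zero",
                       axis = "axial"), class = "luminosity_distribution")
  qq <- qq_compare(dA, dB)
  expect_equal(qq$qx, vapply(qq$probs, function(p) oracle_quantile(x, p),
                             numeric(1)), tolerance = 1e-10)
  expect_equal(qq$qy, vapply(qq$probs, function(p) oracle_quantile(y, p),
                             numeric(1)), tolerance = 1e-10)
  # shifted distribution: qy = qx + 50 away from the clip region
  away <- qq$qx < 180
  expect_equal(qq$qy[away], qq$qx[away] + 50, tolerance = 1e-8)
  # self-comparison sits on the identity line
  self <- qq_compare(dA, dA)
  expect_identical(self$divergence, 0)
  # symmetry and monotonicity
  expect_equal(qq_compare(dB, dA)$divergence, qq$divergence,
               tolerance = 1e-12)
  expect_true(all(diff(qq$qx) >= 0))
  expect_true(all(diff(qq$qy) >= 0))
})

test_that("alpha standardization keeps identical masks at zero divergence", {
  vox <- ellipsoid_mask(c(32, 32, 32), c(15, 12, 10))
  mA <- mask_volume(vox, "a", "fusiform")
  mB <- mask_volume(vox, "b", "fusiform")
  for (aref in c(15L, 30L, 60L)) {
    dA <- extract_distribution(build_composite(slice_mask(mA, "sagittal"),
                                               aref))
    dB <- extract_distribution(build_composite(slice_mask(mB, "sagittal"),
                                               aref))
    expect_identical(qq_compare(dA, dB)$divergence, 0)
  }
})

test_that("most similar pair takes minimal divergence with twin-twin tie-break", {
  curve <- function(div) structure(list(divergence = div),
                                   class = "qq_curve")
  res <- most_similar_pair(list("twin-twin" = curve(0.2),
                                "SRD" = curve(0.05),
                                "TD-OS" = curve(0.1)))
  expect_identical(res$label, "SRD")
  expect_false(res$tie)
  expect_equal(res$margin, 0.05)
  tie <- most_similar_pair(list("twin-twin" = curve(0.1),
                                "SRD" = curve(0.1),
                                "TD-OS" = curve(0.1)))
  expect_identical(tie$label, "twin-twin")
  expect_true(tie$tie)
  expect_error(most_similar_pair(list(a = curve(1), b = curve(2))),
               class = "argument_error")
})

test_that("planted mask-shape similarity is recovered via minimal divergence", {
  coh <- family_cohort()
  prof <- tibble::tibble(
    roi = "superior_temporal",
    subject_id = c("proband", "older_sib", "td_twin"),
    scale = c(0, 0.06, -0.18))
  hits <- 0L
  n_sim <- 50L
  for (s in seq_len(n_sim)) {
    cfg <- sim_config(mask_profile = prof, grid_shape = c(80L, 80L, 80L),
                      mask_slices_per_axis = c(20L, 50L),
                      seed = 3000L + s)
    masks <- simulate_masks(coh, "superior_temporal", cfg)
    dists <- luminosity_distributions(masks, axes = "axial")
    qq <- intersubject_qq(dists, coh)
    if (qq$most_similar$label[1] == "SRD") hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})
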