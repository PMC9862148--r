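test_that("asymmetry index evaluates the laterality formula", {
  expect_identical(asymmetry_index(2.5, 2.5), 0)
  expect_identical(asymmetry_index(3, 1), 1)
  expect_equal(asymmetry_index(1, 3), -1)
  expect_error(asymmetry_index(0, 1), class = "domain_error")
  expect_error(asymmetry_index(-1, 2), class = "domain_error")
})

test_that("asymmetry index is antisymmetric and scale-invariant", {
  set.seed(99)
  a <- runif(100, 0.5, 5); b <- runif(100, 0.5, 5)
  expect_equal(asymmetry_index(a, b), -asymmetry_index(b, a),
               tolerance = 1e-12)
  for (c0 in c(0.1, 2, 1000)) {
    expect_equal(asymmetry_index(c0 * a, c0 * b), asymmetry_index(a, b),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(asymmetry_index(a, b)) < 2))
})

test_that("direction classification respects sign convention and tolerance", {
  expect_identical(classify_direction(-0.217), "rightward")
  expect_identical(classify_direction(0.084), "leftward")
  expect_identical(classify_direction(0), "symmetric")
  expect_identical(classify_direction(0.009), "symmetric")
  expect_identical(classify_direction(0.009, epsilon = 0.001), "leftward")
  expect_error(classify_direction(NaN), class = "domain_error")
})

test_that("asymmetry table reproduces indices from raw L/R values", {
  set.seed(3)
  rois <- reading_region_set()$rois
  rows <- expand.grid(subject_id = c("s1", "s2", "s3"),
                      hemi = c("lh", "rh"), roi = rois,
                      phenotype = "thickness", stringsAsFactors = FALSE)
  rows$value <- runif(nrow(rows), 2, 3.5)
  m <- morphometry_table(rows)
  asym <- asymmetry_table(m, reading_region_set(), "thickness")
  expect_identical(nrow(asym), 3L * 7L)
  for (i in seq_len(nrow(asym))) {
    L <- rows$value[rows$subject_id == asym$subject_id[i] &
                      rows$roi == asym$roi[i] & rows$hemi == "lh"]
    R <- rows$value[rows$subject_id == asym$subject_id[i] &
                      rows$roi == asym$roi[i] & rows$hemi == "rh"]
    expect_equal(asym$index[i], (L - R) / ((L + R) / 2), tolerance = 1e-12)
  }
})

test_that("an all-symmetric table yields zero indices everywhere", {
  rows <- expand.grid(subject_id = "s1", hemi = c("lh", "rh"),
                      roi = c("fusiform", "angular", "supramarginal"),
                      phenotype = "volume", stringsAsFactors = FALSE)
  rows$value <- 5000
  asym <- asymmetry_table(morphometry_table(rows),
                          region_set("x", unique(rows$roi)), "volume")
  expect_true(all(asym$index == 0))
  expect_true(all(asym$direction == "symmetric"))
})

test_that("missing ROIs are skipped with a log, not fatal", {
  rows <- expand.grid(subject_id = "s1", hemi = c("lh", "rh"),
                      roi = "fusiform", phenotype = "area",
                      stringsAsFactors = FALSE)
  rows$value <- 3000
  asym <- asymmetry_table(morphometry_table(rows), reading_region_set(),
                          "area")
  expect_identical(nrow(asym), 1L)
  expect_true("supramarginal" %in% attr(asym, "skipped_rois"))
})

test_that("table validation rejects duplicates and lh-only ROIs by name", {
  rows <- expand.grid(subject_id = "s1", hemi = c("lh", "rh"),
                      roi = c("fusiform", "angular"),
                      phenotype = "thickness", stringsAsFactors = FALSE)
  rows$value <- 2.5
  dup <- rbind(rows, rows[1, ])
  expect_error(morphometry_table(dup), "duplicated",
               class = "validation_error")
  lonely <- rows[!(rows$roi == "angular" & rows$hemi == "rh"), ]
  expect_error(morphometry_table(lonely), "angular",
               class = "validation_error")
  neg <- rows; neg$value[1] <- -1
  expect_error(morphometry_table(neg), class = "validation_error")
})

test_that("morphometry TSV round-trips through the reader", {
  coh <- family_cohort()
  m <- simulate_morphometry(coh, reading_region_set()$rois,
                            sim_config(seed = 17L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_morphometry(m, f)
  rt <- read_morphometry(f)
  key <- function(t) t[order(t$subject_id, t$roi, t$hemi, t$phenotype), ]
  a <- key(tibble::as_tibble(m)); b <- key(tibble::as_tibble(rt))
  expect_equal(a$value, b$value, tolerance = 1e-9)
  expect_identical(a$roi, b$roi)
  expect_error(read_morphometry(withr::local_tempfile()), class = "io_error")
})
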