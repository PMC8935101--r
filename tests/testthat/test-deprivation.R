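# Deprivation index, quintile coding, and the design matrix.

test_that("deprivation index is a sign-oriented first principal component", {
  tr <- generate_covariates(bare_tracts(200, seed = 5), seed = 5)
  idx <- compute_deprivation_index(tr)
  expect_equal(mean(idx), 0, tolerance = 1e-10)
  # higher index = higher deprivation: positively associated with unemployment
  expect_gt(cor(idx, tr$unemployment), 0)
  # independent oracle: leading eigenvector of the correlation matrix
  x <- scale(as.matrix(tr[deprivation_indicators()]))
  ev <- eigen(cor(as.matrix(tr[deprivation_indicators()])))
  ref <- as.vector(x %*% ev$vectors[, 1])
  if (cor(ref, tr$unemployment) < 0) ref <- -ref
  expect_equal(idx, ref, tolerance = 1e-8)
})

test_that("degenerate and duplicated indicators are handled", {
  tr <- generate_covariates(bare_tracts(50, seed = 2), seed = 2)
  tr$unemployment <- 10
  expect_error(compute_deprivation_index(tr),
    class = "hurdlemap_degenerate_variance"
  )
  # a duplicated indicator table gives the same index (up to sign handling)
  tr2 <- generate_covariates(bare_tracts(50, seed = 3), seed = 3)
  expect_equal(
    compute_deprivation_index(tr2),
    compute_deprivation_index(tr2[rev(names(tr2))]),
    tolerance = 1e-10
  )
  # strictly increasing indicators give a strictly increasing index
  tr3 <- tibble::tibble(
    unemployment = c(5, 10, 20), manual_workers = c(30, 40, 55),
    temporary_workers = c(10, 15, 25), schooling = c(10, 20, 35),
    schooling_young = c(5, 8, 14), without_internet = c(20, 30, 45)
  )
  expect_true(all(diff(compute_deprivation_index(tr3)) > 0))
})

test_that("quintile coding follows the boundary and tie conventions", {
  q <- quintile_categorize(1:10, quintile_scheme("x", "Q1_ref_four_dummies"))
  expect_equal(as.character(q), rep(paste0("Q", 1:5), each = 2))
  g <- quintile_categorize(1:10, quintile_scheme("x", "Q123_ref_vs_Q45"))
  expect_equal(g, c(rep(0L, 6), rep(1L, 4)))
  g2 <- quintile_categorize(1:10, quintile_scheme("x", "Q45_ref_vs_Q123"))
  expect_equal(g2, c(rep(1L, 6), rep(0L, 4)))
  # ties go to the lower quintile: all-equal values are all reference
  same <- quintile_categorize(rep(3.3, 8), quintile_scheme("x", "Q1_ref_four_dummies"))
  expect_true(all(same == "Q1"))
  expect_warning(
    quintile_categorize(1:3, quintile_scheme("x", "Q123_ref_vs_Q45")),
    "best-effort"
  )
})

test_that("quintile coding is invariant to monotone transformations", {
  set.seed(8)
  v <- rlnorm(83)
  sch <- quintile_scheme("x", "Q1_ref_four_dummies")
  base <- quintile_categorize(v, sch)
  for (f in list(function(z) 10 * z + 3, log, sqrt, function(z) z^3)) {
    expect_equal(quintile_categorize(f(v), sch), base)
  }
})

test_that("preset boundaries decouple one tract's coding from the others", {
  v <- c(1, 4, 9, 12, 18, 22, 30, 31, 40, 55)
  sch <- quintile_scheme("x", "Q123_ref_vs_Q45",
    boundaries = unname(quantile(v, c(.2, .4, .6, .8)))
  )
  full <- quintile_categorize(v, sch)
  for (drop in seq_along(v)) {
    expect_equal(quintile_categorize(v[-drop], sch), full[-drop])
  }
})

test_that("design matrix carries the documented 16 columns and reference coding", {
  tr <- generate_covariates(bare_tracts(60, seed = 9), seed = 9)
  tr$deprivation <- compute_deprivation_index(tr)
  dm <- build_design_matrix(tr)
  expect_identical(names(dm), c("tract_id", design_columns()))
  expect_equal(length(design_columns()), 16L)
  # dummies are 0/1 and each categorised variable's dummies sum <= 1
  un <- as.matrix(dm[paste0("unemployment_q", 2:5)])
  expect_true(all(un %in% c(0, 1)))
  expect_true(all(rowSums(un) <= 1))
  # reference tract: lowest unemployment quintile has all four dummies 0
  ref <- which.min(tr$unemployment)
  expect_true(all(un[ref, ] == 0))
  # composition with the quintile oracle: unemployment 1..10 over 10 tracts
  tr10 <- generate_covariates(bare_tracts(10, seed = 10), seed = 10)
  tr10$unemployment <- 1:10
  tr10$deprivation <- compute_deprivation_index(tr10)
  dm10 <- build_design_matrix(tr10)
  expect_equal(sum(dm10$unemployment_q5), 2)
  expect_equal(which(dm10$unemployment_q5 == 1), c(9L, 10L))
  # grouped codings: deprivation/schooling Q4-Q5 flagged, young schooling Q1-Q3
  expect_equal(sum(dm$deprivation_q45), sum(tr$deprivation >
    quantile(tr$deprivation, 0.6)))
  expect_true(all(dm$schooling_young_q123 %in% c(0, 1)))
  # full column rank on generic data
  expect_equal(qr(as.matrix(dm[-1]))$rank, 16L)
  expect_error(
    build_design_matrix(tr[setdiff(names(tr), "foreign")]),
    regexp = "foreign", class = "hurdlemap_schema_error"
  )
})
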