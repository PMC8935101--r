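# Relative-risk surfaces, exceedance probabilities, hotspot labels, export.

# fabricate a fit whose latent draws are fully specified (3 tracts)
latent_fit <- function(eta_draws, s_draws) {
  stopifnot(all(dim(eta_draws) == dim(s_draws)))
  n <- ncol(eta_draws)
  tracts <- generate_tracts(n, extent = 1000, seed = 2)
  m <- cbind(eta_draws, s_draws)
  colnames(m) <- c(paste0("eta[", 1:n, "]"), paste0("S[", 1:n, "]"))
  structure(
    list(
      chains = list(m),
      par_names = colnames(m),
      design_columns = character(0),
      panel = list(tracts = tracts, n_tracts = n),
      estimate_alpha = FALSE
    ),
    class = "hurdle_fit"
  )
}

test_that("smoothed RR is the exponential of the summed latent draws", {
  eta <- matrix(0, 4, 3)
  s <- matrix(0, 4, 3)
  f <- latent_fit(eta, s)
  expect_true(all(smoothed_rr(f) == 1))
  s[1, 2] <- log(2)
  f2 <- latent_fit(eta, s)
  expect_equal(unname(smoothed_rr(f2)[1, 2]), 2)
  # direct recomputation oracle on arbitrary draws
  set.seed(3)
  eta3 <- matrix(rnorm(12), 4, 3)
  s3 <- matrix(rnorm(12), 4, 3)
  f3 <- latent_fit(eta3, s3)
  expect_equal(unname(smoothed_rr(f3)), exp(eta3 + s3), tolerance = 1e-12)
})

test_that("exceedance probability counts strict exceedances", {
  expect_equal(unname(exceedance_prob(matrix(c(0.5, 1.5, 2.0, 0.8)))), 0.5)
  expect_equal(unname(exceedance_prob(matrix(rep(1, 10)))), 0)
  set.seed(4)
  lognorm <- matrix(exp(rnorm(1e5)), ncol = 1)
  expect_equal(unname(exceedance_prob(lognorm)), 0.5, tolerance = 0.01)
  expect_error(exceedance_prob(matrix(numeric(0), 0, 1)),
    class = "hurdlemap_invalid_argument"
  )
})

test_that("hotspot classification follows the 80/20 rule with boundary to uncertain", {
  lab <- classify_hotspots(c(0.85, 0.15, 0.80, 0.20, 0.5))
  expect_equal(
    as.character(lab),
    c("hotspot", "coldspot", "uncertain", "uncertain", "uncertain")
  )
  expect_error(classify_hotspots(1.2), class = "hurdlemap_invalid_argument")
  # every tract gets exactly one label
  set.seed(5)
  p <- runif(200)
  lab2 <- classify_hotspots(p)
  expect_equal(length(lab2), 200L)
  expect_equal(sum(table(lab2)), 200L)
})

test_that("raising every RR draw of a tract weakly raises its exceedance", {
  set.seed(6)
  rr <- matrix(exp(rnorm(400)), 100, 4)
  base <- exceedance_prob(rr)
  for (shift in c(1.05, 1.5, 3)) {
    expect_true(all(exceedance_prob(rr * shift) >= base))
  }
})

test_that("risk layers round-trip through GeoJSON and CSV", {
  eta <- matrix(rnorm(40, sd = 0.1), 10, 4)
  s <- matrix(rnorm(40, sd = 0.1), 10, 4)
  f <- latent_fit(eta, s)
  surf <- risk_surface(f)
  expect_s3_class(surf, "risk_surface")
  expect_true(all(surf$prp >= 0 & surf$prp <= 1))
  out <- file.path(withr::local_tempdir(), "risk")
  paths <- export_layers(f$panel$tracts, surf, out)
  expect_true(all(file.exists(paths)))
  back <- read_geojson(paths[["geojson"]])
  expect_equal(back$tract_id, surf$tract_id)
  expect_equal(back$rr_mean, surf$rr_mean, tolerance = 1e-8)
  expect_equal(back$prp, surf$prp, tolerance = 1e-8)
  expect_equal(back$hotspot_label, as.character(surf$hotspot_label))
  csv <- readr::read_csv(paths[["csv"]], show_col_types = FALSE)
  expect_equal(csv$rr_high, surf$rr_high, tolerance = 1e-12)
  # a null posterior (draws symmetric around RR = 1) is all uncertain,
  # while a point mass exactly at 1 is a strict non-exceedance
  set.seed(9)
  sym <- matrix(rnorm(64, sd = 0.05), 16, 4)
  null_surf <- risk_surface(latent_fit(sym, -sym + 1e-3 * sym))
  expect_true(all(null_surf$hotspot_label == "uncertain"))
  point_surf <- risk_surface(latent_fit(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_true(all(point_surf$prp == 0))
  # missing geometry is a schema error naming the tract
  bad_tracts <- f$panel$tracts[-1, ]
  expect_error(
    export_layers(bad_tracts, surf, out),
    regexp = surf$tract_id[1], class = "hurdlemap_schema_error"
  )
})

test_that("the plot builds without error", {
  eta <- matrix(rnorm(20, sd = 0.2), 5, 4)
  f <- latent_fit(eta, eta)
  surf <- risk_surface(f)
  gg <- plot_risk_map(f$panel$tracts, surf)
  expect_s3_class(gg, "ggplot")
  expect_s3_class(autoplot(surf, tracts = f$panel$tracts), "ggplot")
})
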