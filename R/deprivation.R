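#' Names of the six deprivation indicators
#'
#' The deprivation index summarises six tract-level socioeconomic
#' indicators: unemployment, manual workers, temporary workers, population
#' without compulsory schooling, young population without compulsory
#' schooling, and homes without internet access (all percentages).
#'
#' @return Character vector of the six column names.
#' @export
deprivation_indicators <- function() {
  c(
    "unemployment", "manual_workers", "temporary_workers",
    "schooling", "schooling_young", "without_internet"
  )
}

# Full covariate set a tract frame must carry before design construction.
covariate_columns <- function() {
  c(
    deprivation_indicators(),
    "housing45", "housing4560",
    "foreign", "foreign_africa", "foreign_southamerican", "foreign_asian"
  )
}

#' Composite deprivation index from six indicators
#'
#' Computes a per-tract deprivation score as the first principal component
#' of the six standardised indicators, sign-oriented so that a higher score
#' means higher deprivation (positive loading on unemployment).  This is
#' the standard construction for small-area deprivation summaries when the
#' original index weights are not available.
#'
#' @param data Data frame with the six indicator columns of
#'   [deprivation_indicators()], numeric and complete.
#' @return Numeric vector of index values, zero mean by construction.
#' @examples
#' tr <- generate_covariates(generate_tracts(30, 5000, seed = 1), seed = 2)
#' idx <- compute_deprivation_index(tr)
#' round(mean(idx), 10)
#' @export
compute_deprivation_index <- function(data) {
  cols <- deprivation_indicators()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing indicator column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hurdlemap_schema_error"
    )
  }
  x <- as.matrix(data[cols])
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid("Indicator columns must be numeric with no missing values.")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(
      paste0(
        "Indicator(s) with zero variance: ",
        paste(cols[sds == 0], collapse = ", "),
        "; the deprivation index is undefined."
      ),
      class = "hurdlemap_degenerate_variance"
    )
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  flip <- if (load1["unemployment"] != 0) {
    sign(load1["unemployment"])
  } else {
    s <- sign(sum(load1))
    if (s == 0) 1 else s
  }
  as.vector(pc$x[, 1]) * flip
}

#' Quintile coding scheme
#'
#' Describes how a covariate is cut into quintiles and which quintiles form
#' the reference category.  Boundaries are the 20/40/60/80th percentiles of
#' the tract distribution; intervals are left-closed with ties assigned to
#' the lower quintile.
#'
#' @param variable Name of the covariate the scheme applies to.
#' @param grouping One of `"Q1_ref_four_dummies"` (quintile 1 is the
#'   reference, quintiles 2-5 get one dummy each), `"Q123_ref_vs_Q45"`
#'   (quintiles 1-3 are the reference, one dummy for quintiles 4-5), or
#'   `"Q45_ref_vs_Q123"` (quintiles 4-5 are the reference, one dummy for
#'   quintiles 1-3).
#' @param boundaries Optional numeric vector of four non-decreasing cut
#'   values; computed from the data in [quintile_categorize()] when `NULL`.
#' @return An object of class `quintile_scheme`.
#' @export
quintile_scheme <- function(variable,
                            grouping = c(
                              "Q1_ref_four_dummies",
                              "Q123_ref_vs_Q45",
                              "Q45_ref_vs_Q123"
                            ),
                            boundaries = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(boundaries)) {
    if (length(boundaries) != 4 || any(diff(boundaries) < 0)) {
      stop_invalid("`boundaries` must be four non-decreasing cut values.")
    }
  }
  structure(
    list(variable = variable, grouping = grouping, boundaries = boundaries),
    class = "quintile_scheme"
  )
}

# The conventional coding schemes, keyed by covariate.
default_quintile_schemes <- function() {
  list(
    deprivation = quintile_scheme("deprivation", "Q123_ref_vs_Q45"),
    unemployment = quintile_scheme("unemployment", "Q1_ref_four_dummies"),
    schooling = quintile_scheme("schooling", "Q123_ref_vs_Q45"),
    schooling_young = quintile_scheme("schooling_young", "Q45_ref_vs_Q123")
  )
}

#' Assign quintile categories
#'
#' Cuts `values` at the scheme's boundaries (20/40/60/80th percentiles when
#' not preset).  A value lying exactly on a boundary goes to the lower
#' quintile.  Grouped schemes collapse the five quintiles into a 0/1
#' indicator with the scheme's reference coded 0.
#'
#' @param values Numeric vector of covariate values (>= 5 for meaningful
#'   boundaries; fewer triggers a warning and best-effort boundaries).
#' @param scheme A [quintile_scheme()].
#' @return For `"Q1_ref_four_dummies"`, a factor with levels `Q1`-`Q5`;
#'   for the grouped schemes, an integer 0/1 indicator (reference = 0).
#' @examples
#' quintile_categorize(1:10, quintile_scheme("x", "Q1_ref_four_dummies"))
#' quintile_categorize(1:10, quintile_scheme("x", "Q123_ref_vs_Q45"))
#' @export
quintile_categorize <- function(values, scheme) {
  stopifnot(inherits(scheme, "quintile_scheme"))
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid("`values` must be numeric with no missing entries.")
  }
  if (length(values) < 5) {
    warn(paste0(
      "Only ", length(values), " observations: quintile boundaries are ",
      "best-effort and categories may collapse."
    ))
  }
  b <- scheme$boundaries %||%
    unname(quantile(values, c(0.2, 0.4, 0.6, 0.8), names = FALSE))
  # left-closed intervals, ties to the lower quintile: strict '>' on each cut
  q <- 1L + vapply(values, function(v) sum(v > b), integer(1))
  switch(scheme$grouping,
    Q1_ref_four_dummies = factor(paste0("Q", q), levels = paste0("Q", 1:5)),
    Q123_ref_vs_Q45 = as.integer(q >= 4L),
    Q45_ref_vs_Q123 = as.integer(q <= 3L)
  )
}

#' Design-matrix column order
#'
#' The fixed covariate-term order of the two link functions: the grouped
#' deprivation dummy, four unemployment quintile dummies, then the housing,
#' foreign-origin, worker, schooling and internet terms.
#'
#' @return Character vector of the 16 design column names.
#' @export
design_columns <- function() {
  c(
    "deprivation_q45",
    paste0("unemployment_q", 2:5),
    "housing45", "housing4560",
    "foreign", "foreign_africa", "foreign_southamerican", "foreign_asian",
    "manual_workers", "temporary_workers",
    "schooling_q45", "schooling_young_q123",
    "without_internet"
  )
}

#' Build the fixed-effects design matrix
#'
#' Produces one row per tract with the covariate coding used by both model
#' parts: deprivation as a single Q4-Q5 dummy (reference Q1-Q3),
#' unemployment as four dummies Q2-Q5 (reference Q1), without-compulsory-
#' schooling as a Q4-Q5 dummy, young-population schooling as a Q1-Q3 dummy
#' (reference Q4-Q5), and the remaining covariates as raw percentages.
#' Covariates are tract-level constants; panel rows reuse their tract's
#' design row across periods.
#'
#' @param tracts Tract frame carrying the twelve raw covariates (see
#'   [covariate_columns()]); a `deprivation` column is computed with
#'   [compute_deprivation_index()] when absent.
#' @param schemes Named list of [quintile_scheme()]s for the categorised
#'   covariates; defaults to the standard coding described above.
#' @return A tibble with `tract_id` and the 16 columns of
#'   [design_columns()], in that order.
#' @examples
#' tr <- generate_covariates(generate_tracts(25, 5000, seed = 1), seed = 2)
#' dm <- build_design_matrix(tr)
#' names(dm)
#' @export
build_design_matrix <- function(tracts, schemes = default_quintile_schemes()) {
  needed <- c("tract_id", covariate_columns())
  missing_cols <- setdiff(needed, names(tracts))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing covariate column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hurdlemap_schema_error"
    )
  }
  if (!"deprivation" %in% names(tracts)) {
    tracts$deprivation <- compute_deprivation_index(tracts)
  }
  unemp <- quintile_categorize(tracts$unemployment, schemes$unemployment)
  dummies <- vapply(
    paste0("Q", 2:5),
    function(lv) as.numeric(unemp == lv),
    numeric(nrow(tracts))
  )
  out <- tibble::tibble(
    tract_id = tracts$tract_id,
    deprivation_q45 = as.numeric(
      quintile_categorize(tracts$deprivation, schemes$deprivation)
    ),
    unemployment_q2 = dummies[, 1],
    unemployment_q3 = dummies[, 2],
    unemployment_q4 = dummies[, 3],
    unemployment_q5 = dummies[, 4],
    housing45 = tracts$housing45,
    housing4560 = tracts$housing4560,
    foreign = tracts$foreign,
    foreign_africa = tracts$foreign_africa,
    foreign_southamerican = tracts$foreign_southamerican,
    foreign_asian = tracts$foreign_asian,
    manual_workers = tracts$manual_workers,
    temporary_workers = tracts$temporary_workers,
    schooling_q45 = as.numeric(
      quintile_categorize(tracts$schooling, schemes$schooling)
    ),
    schooling_young_q123 = as.numeric(
      quintile_categorize(tracts$schooling_young, schemes$schooling_young)
    ),
    without_internet = tracts$without_internet
  )
  out[c("tract_id", design_columns())]
}
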