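# shared fixtures: the two corticosteroid trials whose counts anchor most
# worked examples, plus random-input generators for property-style tests

# absolute-difference comparison (expect_equal's tolerance is relative)
expect_near <- function(object, expected, tol = 1e-12, tolerance = NULL) {
  if (!is.null(tolerance)) tol <- tolerance
  expect_lte(abs(object - expected), tol)
}

recovery <- function() logodds_from_counts(95, 229, 283, 400,
                                           label = "RECOVERY")

remap_cap <- function() logodds_from_counts(26, 79, 29, 63,
                                            label = "REMAP-CAP")

cape_covid <- function() logodds_from_counts(11, 64, 20, 53,
                                             label = "CAPE COVID")

# random effect estimate; force (non-)significance at alpha when asked
random_estimate <- function(significant = NA, alpha = 0.05) {
  se <- runif(1, 0.05, 2)
  za <- qnorm(1 - alpha / 2)
  z <- if (isTRUE(significant)) sample(c(-1, 1), 1) * runif(1, za * 1.05, 6)
       else if (isFALSE(significant)) runif(1, -za * 0.95, za * 0.95)
       else rnorm(1, 0, 2)
  effect_estimate(z * se, se)
}

random_belief <- function() normal_belief(rnorm(1), runif(1, 0.1, 50))

# local accessor mirroring the package-internal row resolution, so the oracle
# above does not depend on unexported helpers
table_to_estimates_for_test <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    logodds_from_counts(tab$events_t[i], tab$total_t[i] - tab$events_t[i],
                        tab$events_c[i], tab$total_c[i] - tab$events_c[i]))
}

# helpers: push a data frame through the on-disk representation so the
# validation path under test is the same one read_studies() uses
read_studies_roundtrip <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(df, path, row.names = FALSE, na = "")
  read_studies(path)
}
read_studies_roundtrip_raw <- read_studies_roundtrip
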