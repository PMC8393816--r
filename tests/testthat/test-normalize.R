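make_measurements <- function(rows) {
  tibble::tibble(
    sample_id = rows$sample_id, compartment = "homogenate",
    group = rows$group %||% "mock",
    bio_replicate = rows$bio %||% 1L,
    tech_replicate = rows$tech, analyte = rows$analyte,
    intensity = rows$intensity)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

two_species_panel <- function() {
  analyte_panel(parse_analyte(c("PCaa C36:4", "PCaa C38:4")),
                default_standards())
}

test_that("analytes are divided by their class standard per replicate", {
  panel <- two_species_panel()
  tab <- make_measurements(list(
    sample_id = rep("s1", 3), tech = c(1L, 1L, 1L),
    analyte = c("PCaa C36:4", "PCaa C38:4", "IS PC 6:0"),
    intensity = c(500, 0, 250)))
  r <- normalize_to_standard(tab, panel)
  expect_equal(r$ratio[r$analyte == "PCaa C36:4"], 2.0)
  # zero analyte signal is kept as ratio 0, not treated as missing
  expect_equal(r$ratio[r$analyte == "PCaa C38:4"], 0.0)
  expect_false("IS PC 6:0" %in% r$analyte)
})

test_that("a zero standard invalidates the class for that sample", {
  panel <- two_species_panel()
  tab <- make_measurements(list(
    sample_id = rep(c("s1", "s2"), each = 3), tech = rep(1L, 6),
    analyte = rep(c("PCaa C36:4", "PCaa C38:4", "IS PC 6:0"), 2),
    intensity = c(500, 100, 0, 500, 100, 250)))
  expect_warning(r <- normalize_to_standard(tab, panel), "invalidated")
  expect_false("s1" %in% r$sample_id)
  expect_equal(sum(r$sample_id == "s2"), 2L)
  expect_equal(attr(r, "invalid")$sample_id, "s1")
})

test_that("technical replicates collapse by the arithmetic mean", {
  tab <- tibble::tibble(sample_id = "s1", compartment = "h",
                        group = "mock", bio_replicate = 1L,
                        tech_replicate = 1:3, analyte = "PCaa C36:4",
                        ratio = c(1, 2, 3))
  out <- collapse_technical(tab)
  expect_equal(out$ratio, 2.0)
  expect_false("tech_replicate" %in% names(out))
  # single technical replicate passes through unchanged
  out1 <- collapse_technical(tab[1, ])
  expect_equal(out1$ratio, 1.0)
  # a missing value means the mean of the remaining two, with a warning
  tab$ratio[2] <- NA
  expect_warning(out2 <- collapse_technical(tab), "missing values")
  expect_equal(out2$ratio, 2.0)
})

test_that("normalization is invariant to per-sample global scaling", {
  panel <- small_panel()
  d <- simulate_dataset(tiny_design(), panel, seed = 5)
  r1 <- collapse_technical(normalize_to_standard(d, panel))
  d2 <- d
  scale <- ifelse(d2$sample_id == d2$sample_id[1], 7.5, 1)
  d2$intensity <- d2$intensity * scale
  r2 <- collapse_technical(normalize_to_standard(d2, panel))
  expect_equal(r2$ratio, r1$ratio)
})

test_that("ratios are averaged over technical replicates, not intensities", {
  panel <- small_panel()
  d <- simulate_dataset(tiny_design(), panel, seed = 6)
  got <- collapse_technical(normalize_to_standard(d, panel))
  # oracle: per technical replicate, analyte/standard, then plain mean
  ann <- panel$species[, c("analyte", "standard")]
  std <- d[d$analyte %in% panel$standards$standard,
           c("sample_id", "tech_replicate", "analyte", "intensity")]
  names(std)[3:4] <- c("standard", "std_int")
  oracle <- merge(merge(d[!d$analyte %in% panel$standards$standard, ], ann,
                        by = "analyte"),
                  std, by = c("sample_id", "tech_replicate", "standard"))
  oracle$r <- oracle$intensity / oracle$std_int
  oracle <- aggregate(r ~ sample_id + analyte, oracle, mean)
  cmp <- merge(got, oracle, by = c("sample_id", "analyte"))
  expect_equal(cmp$ratio, cmp$r)
})

test_that("matrix-effect QC reports percent change against the reference", {
  panel <- two_species_panel()
  tab <- make_measurements(list(
    sample_id = c("s1", "s2"), group = c("mock", "APPswe"),
    bio = c(1L, 1L), tech = c(1L, 1L),
    analyte = rep("IS PC 6:0", 2), intensity = c(100, 103)))
  qc <- matrix_effect_qc(tab, panel, "mock")
  expect_equal(qc$detail$pct_change, 3.0)
  # identical means give 0%
  tab$intensity <- c(100, 100)
  expect_equal(matrix_effect_qc(tab, panel, "mock")$detail$pct_change, 0)
  # a standard missing from one group is not evaluable, never 0
  tab2 <- make_measurements(list(
    sample_id = c("s1", "s2", "s1"), group = c("mock", "APPswe", "mock"),
    bio = c(1L, 1L, 1L), tech = c(1L, 1L, 1L),
    analyte = c("IS PC 6:0", "IS PC 6:0", "IS lyso-PC 19:0"),
    intensity = c(100, 103, 50)))
  qc2 <- matrix_effect_qc(tab2, panel, "mock")
  lyso <- qc2$detail[qc2$detail$standard == "IS lyso-PC 19:0", ]
  expect_false(lyso$evaluable)
  expect_true(is.na(lyso$pct_change))
})

test_that("simulated matrix amplitude is recovered by the QC metric", {
  panel <- small_panel()
  des <- study_design(n_bio = 7L, n_tech = 3L)
  # without technical noise the measured change is exactly the amplitude
  d0 <- simulate_dataset(des, panel, NULL, noise_spec(0.15, 0, 0.012),
                         seed = 21)
  qc0 <- matrix_effect_qc(d0, panel, "mock")
  expect_equal(abs(qc0$detail$pct_change), rep(1.2, nrow(qc0$detail)))
  # with small technical noise the seed-averaged metric approaches it
  vals <- vapply(1:30, function(s) {
    d <- simulate_dataset(des, panel, NULL,
                          noise_spec(0.15, 0.005, 0.012), seed = 400 + s)
    matrix_effect_qc(d, panel, "mock")$overall_mean_abs_pct
  }, 0)
  expect_lt(abs(mean(vals) - 1.2), 3 * sd(vals) / sqrt(length(vals)) + 0.02)
})
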