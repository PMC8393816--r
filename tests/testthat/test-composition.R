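test_that("mol percent forms within-class proportions", {
  panel <- analyte_panel(
    parse_analyte(c("PCaa C36:4", "PCaa C38:4", "PCaa C40:4",
                    "lyso-PC C16:0")),
    default_standards())
  r <- tibble::tibble(sample_id = "s1", compartment = "h", group = "mock",
                      bio_replicate = 1L,
                      analyte = c("PCaa C36:4", "PCaa C38:4", "PCaa C40:4",
                                  "lyso-PC C16:0"),
                      ratio = c(2, 2, 4, 3))
  m <- mol_percent(r, panel)
  expect_equal(m$mol_pct[m$analyte %in%
                           c("PCaa C36:4", "PCaa C38:4", "PCaa C40:4")],
               c(25, 25, 50))
  # a single-species class sits at 100
  expect_equal(m$mol_pct[m$analyte == "lyso-PC C16:0"], 100)
  # uniform scaling of a sample leaves mol% unchanged
  m2 <- mol_percent(dplyr::mutate(r, ratio = ratio * 2), panel)
  expect_equal(m2$mol_pct, m$mol_pct)
  # zero class sum flags all species of the class in that sample
  r0 <- dplyr::mutate(r, ratio = ifelse(analyte == "lyso-PC C16:0",
                                        0, ratio))
  expect_warning(m0 <- mol_percent(r0, panel), "zero class sum")
  expect_true(is.na(m0$mol_pct[m0$analyte == "lyso-PC C16:0"]))
})

test_that("mol percent sums to 100 per sample and class on simulations", {
  panel <- default_panel()
  d <- simulate_dataset(study_design(), panel, seed = 41)
  r <- collapse_technical(normalize_to_standard(d, panel))
  m <- mol_percent(r, panel)
  ann <- annotate_species(dplyr::rename(m, ratio = mol_pct), panel)
  sums <- dplyr::summarise(
    ann, s = sum(ratio),
    .by = c("sample_id", "lipid_class", "linkage", "type"))
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("double-bond ratios contrast summed signals per replicate", {
  panel <- small_panel()
  # identical groups: 100% with p = 1 when numerator == denominator
  r <- noiseless_ratios(panel)
  same <- double_bond_ratio(r, panel, "PC", "ae", 4, 4,
                            "APPswe", "mock", "homogenate")
  expect_equal(same$mean_of_control, 100)
  expect_equal(same$p_value, 1)
  # noiseless doubling of the numerator species gives 200%
  eff <- planted_effect(2, compartment = "homogenate",
                        lipid_class = "PC", linkage = "ae",
                        double_bonds = 4L)
  r2 <- noiseless_ratios(panel, effects = eff)
  up <- double_bond_ratio(r2, panel, "PC", "ae", 4, 6,
                          "APPswe", "mock", "homogenate")
  expect_equal(up$mean_of_control, 200)
  # pooled "ax" linkage accepts aa + ae species
  ax <- double_bond_ratio(r2, panel, "PC", "ax", 4, c(5, 6),
                          "APPswe", "mock", "homogenate")
  expect_match(ax$name, "PCax")
  expect_gt(ax$mean_of_control, 100)
  expect_error(double_bond_ratio(r, panel, "PC", "ae", 9, 6,
                                 "APPswe", "mock", "homogenate"),
               "matches no species")
})

test_that("suppressing the omega-3 proxy species raises the ratio and n sharpens p", {
  panel <- small_panel()
  eff <- planted_effect(0.8, compartment = "homogenate",
                        lipid_class = "PC", linkage = "ae",
                        double_bonds = 6L)
  p_at_n <- vapply(c(4L, 14L), function(n) {
    d <- simulate_dataset(study_design(compartments = "homogenate",
                                       n_bio = n),
                          panel, eff, noise_spec(), seed = 77)
    r <- collapse_technical(normalize_to_standard(d, panel))
    res <- double_bond_ratio(r, panel, "PC", "ae", 4, 6,
                             "APPswe", "mock", "homogenate")
    expect_gt(res$mean_of_control, 100)
    res$p_value
  }, 0)
  expect_lt(p_at_n[2], p_at_n[1])
})

test_that("group aggregates partition the class and echo uniform effects", {
  panel <- small_panel()
  eff <- planted_effect(1.3, compartment = "homogenate",
                        lipid_class = "PC", linkage = "ae")
  r <- noiseless_ratios(panel, effects = eff)
  agg <- group_aggregate(r, panel, "double_bonds", "PC", "ae",
                         "APPswe", "mock", "homogenate")
  expect_true(all(abs(agg$mean_of_control - 130) < 1e-9))
  # partition identity: per replicate, level sums add to the class sum
  ann <- annotate_species(r, panel)
  pc_ae <- ann[ann$compartment == "homogenate" & !is.na(ann$linkage) &
                 ann$lipid_class == "PC" & ann$linkage == "ae", ]
  class_sum <- sum(pc_ae$ratio[pc_ae$sample_id == pc_ae$sample_id[1]])
  reps <- attr(double_bond_ratio(r, panel, "PC", "ae", c(4, 5, 6),
                                 c(4, 5, 6), "APPswe", "mock",
                                 "homogenate"), "replicates")
  expect_equal(reps$value[1], 1)  # numerator = denominator = class
  # carbon bins honour the configured edges
  aggc <- group_aggregate(r, panel, "carbons", "PC", "ax",
                          "APPswe", "mock", "homogenate",
                          carbon_bins = c(33, 39))
  expect_setequal(aggc$name, c("34-39", ">=40"))
  expect_gt(class_sum, 0)
})

test_that("carnitine panel arithmetic on a minimal set", {
  panel <- analyte_panel(parse_analyte(c("C0", "C2", "C3")),
                         default_standards())
  mk <- function(g, c0, c2, c3, i) tibble::tibble(
    sample_id = paste0(g, i), compartment = "homogenate", group = g,
    bio_replicate = i, analyte = c("C0", "C2", "C3"),
    ratio = c(c0, c2, c3))
  # control: C0 = 2, C2 = 1, C3 = 1 -> C0/C2 = 2, C2+C3 = 2,
  # C0/(C2+C3) = 1, CX/(C2+C3) = 1; treated doubles C0 only
  r <- dplyr::bind_rows(mk("mock", 2, 1, 1, 1L), mk("mock", 2, 1, 1, 2L),
                        mk("APPswe", 4, 1, 1, 1L),
                        mk("APPswe", 4, 1, 1, 2L))
  cp <- carnitine_panel(r, panel, "APPswe", "mock", "homogenate")
  get <- function(n) cp$fold_change[cp$name == n]
  expect_equal(get("C0"), 2)          # control C0/C2 = 2, doubled in treated
  expect_equal(get("C0/C2"), 2)
  expect_equal(get("C2+C3"), 1)
  expect_equal(get("C0/(C2+C3)"), 2)
  expect_equal(get("CX/(C2+C3)"), 1)
  # Ceven/Codd exclude their denominators; with only C0,C2,C3 the sums
  # are empty and the dependent ratio folds are 0/NaN-safe
  expect_equal(get("Ceven"), NA_real_)
  # absent C16/C18 makes the long-chain ratio not evaluable
  expect_equal(cp$note[cp$name == "(C16+C18)/C2"], "not_evaluable")
  # absent C2 flags every ratio depending on it
  panel2 <- analyte_panel(parse_analyte(c("C0", "C3")),
                          default_standards())
  r2 <- dplyr::filter(r, analyte != "C2")
  cp2 <- carnitine_panel(r2, panel2, "APPswe", "mock", "homogenate")
  expect_equal(cp2$note[cp2$name == "C0/C2"], "missing_input_species")
  expect_equal(cp2$note[cp2$name == "CX/(C2+C3)"], "missing_input_species")
})

test_that("carnitine ratios are scale-invariant and track planted shifts", {
  panel <- small_panel()
  r <- noiseless_ratios(panel)
  # planted 1.5x increase of C2 and C3 only
  eff <- dplyr::bind_rows(planted_effect(1.5, analyte = "C2"),
                          planted_effect(1.5, analyte = "C3"))
  r2 <- noiseless_ratios(panel, effects = eff)
  cp <- carnitine_panel(r2, panel, "APPswe", "mock", "homogenate")
  get <- function(n) cp$fold_change[cp$name == n]
  expect_equal(get("C2+C3"), 1.5)
  expect_equal(get("C0/C2"), 1 / 1.5)
  expect_equal(get("Codd/C3"), 1 / 1.5)
  # global scaling of all analytes in the treated group: ratios at fc 1
  r3 <- noiseless_ratios(panel, effects = planted_effect(3))
  cp3 <- carnitine_panel(r3, panel, "APPswe", "mock", "homogenate")
  ratios_only <- cp3[grepl("/", cp3$name), ]
  ok <- !is.na(ratios_only$fold_change)
  expect_true(all(abs(ratios_only$fold_change[ok] - 1) < 1e-9))
})
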