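# Shared fixtures built in code.

# A small panel: a handful of lipids across classes plus a carnitine set.
small_panel <- function() {
  names <- c("PCaa C36:4", "PCaa C40:1", "PCae C38:4", "PCae C38:6",
             "PCae C40:5", "lyso-PC C16:0", "PEaa C38:3", "PEaa C38:6",
             "PEae C38:6", "lyso-PE C20:3", "PG 18:2/16:0",
             "C0", "C2", "C3", "C5", "C8", "C16", "C18")
  analyte_panel(parse_analyte(names), default_standards())
}

tiny_design <- function(...) {
  study_design(compartments = "homogenate", n_bio = 3L, n_tech = 2L, ...)
}

# noiseless simulation -> collapsed ratio table
noiseless_ratios <- function(panel = small_panel(),
                             design = tiny_design(),
                             effects = NULL, seed = 1) {
  d <- simulate_dataset(design, panel, effects,
                        noise_spec(0, 0, 0), seed = seed)
  collapse_technical(normalize_to_standard(d, panel))
}

# A deterministic label table for compare-module tests: n_up species
# labeled up, n_down down, rest unchanged.
fake_labels <- function(analytes, n_up, n_down, compartment = "A") {
  lab <- rep("unchanged", length(analytes))
  if (n_up > 0) lab[seq_len(n_up)] <- "trend_up"
  if (n_down > 0) lab[n_up + seq_len(n_down)] <- "trend_down"
  tibble::tibble(analyte = analytes, compartment = compartment,
                 label = factor(lab, levels = c(
                   "significant_up", "significant_down", "trend_up",
                   "trend_down", "unchanged")))
}
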