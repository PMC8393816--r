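#' Study design for a simulated experiment
#'
#' Mirrors the layout of the fractionation study the pipeline targets:
#' two compartments (total cell homogenate and an enriched mitochondria
#' fraction), a reference (mock-transfected) and a treated (APP-Swedish)
#' group, seven biological replicates each measured in technical
#' triplicate.
#'
#' @param compartments character vector of compartment labels.
#' @param groups character vector of group labels.
#' @param reference the control group (must be in `groups`).
#' @param n_bio biological replicates per group (>= 2).
#' @param n_tech technical replicates per biological sample (>= 1).
#' @return a `study_design` list.
#' @export
study_design <- function(compartments = c("homogenate", "mitochondria"),
                         groups = c("mock", "APPswe"),
                         reference = "mock",
                         n_bio = 7L, n_tech = 3L) {
  stopifnot(length(compartments) >= 1, length(groups) >= 2,
            n_bio >= 2, n_tech >= 1)
  if (!reference %in% groups)
    stop("reference group '", reference, "' not among groups", call. = FALSE)
  structure(list(compartments = compartments, groups = groups,
                 reference = reference,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech)),
            class = "study_design")
}

#' Noise model for the simulator
#'
#' All noise is multiplicative log-normal with unit mean, so planted
#' fold changes propagate exactly in expectation. The biological
#' coefficient of variation acts once per biological sample and analyte
#' (shared across its technical replicates); the technical CV acts
#' independently per injection. Internal standards receive technical
#' noise only, plus a small per-group multiplicative matrix-effect shift
#' whose default amplitude (1.2%) matches the magnitude of matrix
#' effects typical for this assay.
#'
#' @param cv_bio biological CV (default 0.15).
#' @param cv_tech technical CV (default 0.05).
#' @param matrix_amplitude relative shift applied to standard
#'   intensities in non-reference groups (default 0.012).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(cv_bio = 0.15, cv_tech = 0.05,
                       matrix_amplitude = 0.012) {
  stopifnot(cv_bio >= 0, cv_tech >= 0, matrix_amplitude >= 0)
  structure(list(cv_bio = cv_bio, cv_tech = cv_tech,
                 matrix_amplitude = matrix_amplitude),
            class = "noise_spec")
}

#' Planted effect selectors
#'
#' One row per planted effect. A selector may target a single analyte,
#' a whole (class, linkage) set, or all species of a class with a given
#' double-bond count; `NA` fields are wildcards. Effects apply to all
#' non-reference groups in the selected compartment(s).
#'
#' @param fold_change positive multiplier on the expected intensity.
#' @param compartment,analyte,lipid_class,linkage,double_bonds selector
#'   fields; `NA` (default) matches everything.
#' @return one-row tibble; rows from several calls can be
#'   `dplyr::bind_rows()`-ed into an effect table.
#' @export
planted_effect <- function(fold_change, compartment = NA, analyte = NA,
                           lipid_class = NA, linkage = NA,
                           double_bonds = NA) {
  stopifnot(is.numeric(fold_change), fold_change > 0)
  tibble::tibble(fold_change = fold_change,
                 compartment = as.character(compartment),
                 analyte = as.character(analyte),
                 lipid_class = as.character(lipid_class),
                 linkage = as.character(linkage),
                 double_bonds = as.integer(double_bonds))
}

#' Default panel configuration
#'
#' A reconstruction of a 226-analyte targeted panel: per-(class,
#' linkage) grids of total carbons x total double bonds for the diacyl
#' and plasmalogen PC and PE families, a small set of named extras
#' beyond the regular grids (e.g. the highly unsaturated `PCae C40:8`
#' and `PEae C40:7`), explicit lyso-PC and lyso-PE lists, the six PG
#' chain-pair species relevant as cardiolipin precursors, and 19
#' carnitines (free carnitine C0, acetyl C2, propionyl C3, and chains
#' up to C20).
#'
#' @return a list of grid specifications consumed by [default_panel()].
#' @export
default_panel_config <- function() {
  list(
    lipid_grids = list(
      list(lipid_class = "PC", linkage = "aa",
           carbons = seq(28L, 42L, 2L), double_bonds = 0:5),
      list(lipid_class = "PC", linkage = "ae",
           carbons = seq(30L, 42L, 2L), double_bonds = 0:6),
      list(lipid_class = "PE", linkage = "aa",
           carbons = seq(32L, 42L, 2L), double_bonds = 0:6),
      list(lipid_class = "PE", linkage = "ae",
           carbons = seq(34L, 44L, 2L), double_bonds = 0:6)),
    extra_species = c(
      "PCaa C20:0", "PCaa C42:6", "PCae C40:8", "PEae C40:7",
      "lyso-PC C16:0", "lyso-PC C16:1", "lyso-PC C18:0", "lyso-PC C18:1",
      "lyso-PC C18:2", "lyso-PC C20:3", "lyso-PC C20:4",
      "lyso-PE C16:0", "lyso-PE C16:1", "lyso-PE C18:0", "lyso-PE C18:1",
      "lyso-PE C18:2", "lyso-PE C20:0", "lyso-PE C20:3", "lyso-PE C20:4",
      "lyso-PE C22:6"),
    pg_species = c("PG 18:2/16:0", "PG 18:2/16:1", "PG 18:2/18:1",
                   "PG 18:2/18:2", "PG 18:2/20:3", "PG 18:2/20:4"),
    carnitine_chains = c(0L, 2:18, 20L))
}

#' Default internal-standard assignment
#'
#' One standard per (class, linkage) group, modeled on the usual
#' per-class spike-ins for this assay: 19:0 lyso-PC, 6:0 PC, 12:0
#' diether PC for the PC family; 8:0 PE for the PE family (shared by
#' diacyl, plasmalogen and lyso species); 17:0-14:1 PG; deuterated
#' octanoyl- and palmitoyl-carnitine for short and long chains.
#'
#' @return tibble with `std_group`, `standard`.
#' @export
default_standards <- function() {
  tibble::tribble(
    ~std_group,         ~standard,
    "PC:lyso",          "IS lyso-PC 19:0",
    "PC:aa",            "IS PC 6:0",
    "PC:ae",            "IS PC O-12:0",
    "PE:aa",            "IS PE 8:0",
    "PE:ae",            "IS PE 8:0",
    "PE:lyso",          "IS PE 8:0",
    "PG:aa",            "IS PG 17:0-14:1",
    "carnitine:short",  "IS C8-d3",
    "carnitine:long",   "IS C16-d3")
}

#' Build the default analyte panel
#'
#' Expands the configured carbon/double-bond grids into species names,
#' deduplicates, and assigns internal standards per group.
#'
#' @param config a configuration list as from [default_panel_config()].
#' @param standards standard assignment table (see [default_standards()]).
#' @return an `analyte_panel`.
#' @examples
#' panel <- default_panel()
#' nrow(panel$species)  # 226 with the default configuration
#' @export
default_panel <- function(config = default_panel_config(),
                          standards = default_standards()) {
  grids <- lapply(config$lipid_grids, function(g) {
    if (!length(g$carbons) || !length(g$double_bonds))
      stop("empty carbon or double-bond range for ",
           g$lipid_class, g$linkage, call. = FALSE)
    grid <- expand.grid(carbons = g$carbons, double_bonds = g$double_bonds)
    render_lipid_fields(g$lipid_class, g$linkage,
                        grid$carbons, grid$double_bonds)
  })
  carn <- if (length(config$carnitine_chains))
    paste0("C", config$carnitine_chains) else character(0)
  names <- unique(c(unlist(grids), config$extra_species,
                    config$pg_species, carn))
  analyte_panel(parse_analyte(names), standards)
}

# unit-mean log-normal multipliers for a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a long-format measurement table
#'
#' Generates one counts-per-second intensity per (compartment, group,
#' biological replicate, technical replicate, analyte), plus standard
#' intensities per sample. The expected intensity of a planted species
#' in a non-reference group is exactly the reference expectation times
#' the planted fold change; noise is unit-mean log-normal so this holds
#' under noise as well. Randomness is drawn in a fixed documented order
#' (analyte baselines, then matrix-effect signs, then biological
#' factors, then technical factors), so a given seed reproduces the
#' table bit for bit.
#'
#' @param design a [study_design()].
#' @param panel an `analyte_panel`.
#' @param effects an effect table built from [planted_effect()] rows, or
#'   `NULL` for a null dataset.
#' @param noise a [noise_spec()].
#' @param seed integer seed; required for reproducibility.
#' @return A measurement tibble with columns `sample_id`, `compartment`,
#'   `group`, `bio_replicate`, `tech_replicate`, `analyte`, `intensity`.
#' @export
simulate_dataset <- function(design, panel, effects = NULL,
                             noise = noise_spec(), seed) {
  stopifnot(inherits(design, "study_design"),
            inherits(panel, "analyte_panel"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))

  sp <- panel$species
  analytes <- sp$analyte
  std_names <- unique(panel$standards$standard)

  # per-analyte baseline expectation, 1e3..1e5 cps; standards at 1e4-ish
  base <- stats::setNames(10^stats::runif(length(analytes), 3, 5), analytes)
  base_std <- stats::setNames(10^stats::runif(length(std_names), 3.8, 4.2),
                              std_names)

  # planted fold-change multiplier per (compartment, analyte)
  fc <- expand.grid(compartment = design$compartments, analyte = analytes,
                    stringsAsFactors = FALSE)
  fc$mult <- 1
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      hit <- rep(TRUE, nrow(sp))
      if (!is.na(e$analyte))      hit <- hit & sp$analyte == e$analyte
      if (!is.na(e$lipid_class))  hit <- hit & !is.na(sp$lipid_class) &
                                      sp$lipid_class == e$lipid_class
      if (!is.na(e$linkage))      hit <- hit & !is.na(sp$linkage) &
                                      sp$linkage == e$linkage
      if (!is.na(e$double_bonds)) hit <- hit & !is.na(sp$double_bonds) &
                                      sp$double_bonds == e$double_bonds
      if (!any(hit))
        stop("planted effect matches no panel species: ",
             paste(stats::na.omit(unlist(e[-1])), collapse = " "),
             call. = FALSE)
      rows <- fc$analyte %in% sp$analyte[hit]
      if (!is.na(e$compartment))
        rows <- rows & fc$compartment == e$compartment
      fc$mult[rows] <- fc$mult[rows] * e$fold_change
    }
  }

  # matrix-effect shift on standards: +/- amplitude per
  # (compartment, non-reference group, standard), sign drawn once
  me <- expand.grid(compartment = design$compartments,
                    group = design$groups, standard = std_names,
                    stringsAsFactors = FALSE)
  me$shift <- ifelse(me$group == design$reference, 0,
                     noise$matrix_amplitude *
                       sample(c(-1, 1), nrow(me), replace = TRUE))

  samples <- expand.grid(compartment = design$compartments,
                         group = design$groups,
                         bio_replicate = seq_len(design$n_bio),
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$compartment, samples$group,
                             samples$bio_replicate, sep = "_")

  # biological factors: one per (sample, analyte)
  bio <- tidyr::crossing(samples, analyte = analytes) |>
    dplyr::arrange(.data$sample_id, .data$analyte)
  bio$bio_factor <- rlnorm_cv(nrow(bio), noise$cv_bio)

  meas <- tidyr::crossing(bio, tech_replicate = seq_len(design$n_tech)) |>
    dplyr::left_join(fc, by = c("compartment", "analyte"))
  meas$mult <- ifelse(meas$group == design$reference, 1, meas$mult)
  meas$intensity <- unname(base[meas$analyte]) * meas$mult *
    meas$bio_factor * rlnorm_cv(nrow(meas), noise$cv_tech)

  stds <- tidyr::crossing(samples, standard = std_names,
                          tech_replicate = seq_len(design$n_tech)) |>
    dplyr::left_join(me, by = c("compartment", "group", "standard"))
  stds$intensity <- unname(base_std[stds$standard]) * (1 + stds$shift) *
    rlnorm_cv(nrow(stds), noise$cv_tech)
  stds$analyte <- stds$standard

  cols <- c("sample_id", "compartment", "group", "bio_replicate",
            "tech_replicate", "analyte", "intensity")
  out <- dplyr::bind_rows(meas[cols], stds[cols]) |>
    dplyr::arrange(.data$sample_id, .data$tech_replicate, .data$analyte)
  tibble::as_tibble(out)
}
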