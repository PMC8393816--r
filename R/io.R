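sniff_delim <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!startsWith(first, "#")][1]
  if (is.na(first)) stop("empty file: ", path, call. = FALSE)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read a long-format measurement table
#'
#' Expects delimited text (tab or comma, auto-detected) with the header
#' `sample_id, compartment, group, bio_replicate, tech_replicate,
#' analyte, intensity`; `tech_replicate` may be absent for already
#' collapsed tables. Lines starting with `#` are provenance comments
#' and skipped. Schema problems are reported with the offending column
#' or row numbers.
#'
#' @param path file path.
#' @return a measurement tibble.
#' @export
read_measurements <- function(path) {
  tab <- readr::read_delim(path, delim = sniff_delim(path), comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- c("sample_id", "compartment", "group", "bio_replicate",
                "analyte", "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("measurement file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  intensity <- suppressWarnings(as.numeric(tab$intensity))
  bad <- which(is.na(intensity) & !is.na(tab$intensity))
  if (length(bad))
    stop("non-numeric intensity at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  tab$intensity <- intensity
  tab$bio_replicate <- as.integer(tab$bio_replicate)
  if ("tech_replicate" %in% names(tab))
    tab$tech_replicate <- as.integer(tab$tech_replicate)
  keys <- intersect(c("sample_id", "tech_replicate", "analyte"), names(tab))
  dup <- duplicated(tab[keys])
  if (any(dup))
    stop("duplicate (sample, technical replicate, analyte) key at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  tab
}

#' Write a delimited table with a provenance header
#'
#' Prepends `#`-comment lines recording the package version, the seed
#' and a hash of the run configuration, then writes tab-separated
#' values. [read_measurements()] and [read_panel()] skip these lines.
#'
#' @param x a data frame.
#' @param path output path.
#' @param provenance named list echoed into the header (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_output_table <- function(x, path, provenance = list()) {
  ver <- as.character(utils::packageVersion("lipidshift"))
  hdr <- c(paste0("# lipidshift ", ver),
           vapply(names(provenance),
                  function(k) paste0("# ", k, ": ", provenance[[k]]), ""))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param design a [study_design()].
#' @param panel an `analyte_panel`.
#' @param treated,control contrast groups (must be in the design).
#' @param alpha significance level.
#' @param scope `"panel"` for panel-wide average-SEM guide lines or
#'   `"class"` for per-(class, linkage) analysis sets.
#' @param ratio_specs list of double-bond ratio specifications, each a
#'   list with `lipid_class`, `linkage`, `numerator_db`,
#'   `denominator_db` (and optional `name`).
#' @param carbon_bins chain-length bin edges (see [group_aggregate()]).
#' @param measurements path to a measurement file, or `NULL` to
#'   simulate.
#' @param effects planted effect table for simulation, or `NULL`.
#' @param noise a [noise_spec()] for simulation.
#' @param seed integer seed governing all randomness.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, design = study_design(),
                       panel = default_panel(),
                       treated = "APPswe", control = "mock",
                       alpha = 0.05, scope = c("panel", "class"),
                       ratio_specs = default_ratio_specs(),
                       carbon_bins = c(33, 39),
                       measurements = NULL, effects = NULL,
                       noise = noise_spec(), seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(inherits(design, "study_design"),
            inherits(panel, "analyte_panel"),
            alpha > 0, alpha < 1)
  for (g in c(treated, control))
    if (!g %in% design$groups)
      stop("contrast group '", g, "' is not in the study design",
           call. = FALSE)
  if (!is.null(measurements) && !file.exists(measurements))
    stop("measurement file not found: ", measurements, call. = FALSE)
  structure(list(out_dir = out_dir, design = design, panel = panel,
                 treated = treated, control = control, alpha = alpha,
                 scope = scope, ratio_specs = ratio_specs,
                 carbon_bins = carbon_bins, measurements = measurements,
                 effects = effects, noise = noise,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Default double-bond ratio panel
#'
#' The omega-6 / omega-3 proxy ratios evaluated by default: PCae
#' X:4/X:6 and X:4/(X:5+X:6), the pooled-linkage PCax versions, and
#' PEaa X:4/X:6.
#'
#' @return list of ratio specifications for [run_pipeline()].
#' @export
default_ratio_specs <- function() {
  list(
    list(lipid_class = "PC", linkage = "ae", numerator_db = 4,
         denominator_db = 6),
    list(lipid_class = "PC", linkage = "ae", numerator_db = 4,
         denominator_db = c(5, 6)),
    list(lipid_class = "PC", linkage = "ax", numerator_db = 4,
         denominator_db = 6),
    list(lipid_class = "PC", linkage = "ax", numerator_db = 4,
         denominator_db = c(5, 6)),
    list(lipid_class = "PE", linkage = "aa", numerator_db = 4,
         denominator_db = 6))
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: obtain measurements (read or
#' simulate), normalize each analyte to its class standard per
#' technical replicate, average the technical triplicates, then per
#' compartment compute species statistics and labels (raw and mol%
#' scale), the double-bond ratio panel, chain-length/saturation
#' aggregates and the carnitine panel, and finally the
#' cross-compartment shift test and Venn partition. All tables are
#' written as TSV with provenance headers into `config$out_dir`,
#' together with a machine-readable `summary.json` (label counts,
#' average SEMs, Fisher p-values, matrix-effect QC). Deterministic for
#' a given seed and configuration.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = config$seed,
               config_hash = rlang::hash(config[setdiff(names(config),
                                                        "out_dir")]))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  raw <- stage("input", {
    if (is.null(config$measurements)) {
      simulate_dataset(config$design, config$panel, config$effects,
                       config$noise, seed = config$seed)
    } else {
      read_measurements(config$measurements)
    }
  })
  message("input: ", nrow(raw), " records")

  ratios <- stage("normalize", {
    collapse_technical(normalize_to_standard(raw, config$panel))
  })
  message("normalize: ", nrow(ratios), " collapsed ratios")

  molpct <- stage("mol_percent", mol_percent(ratios, config$panel))

  qc <- stage("matrix_effect_qc",
              matrix_effect_qc(raw, config$panel,
                               config$design$reference))

  compartments <- config$design$compartments
  labels <- list(); labels_mol <- list()
  summary_counts <- list()
  for (comp in compartments) {
    st <- stage(paste0("differential:", comp),
                species_stats(ratios, config$treated, config$control,
                              compartment = comp))
    lab <- if (config$scope == "panel") {
      classify_species(st, alpha = config$alpha)
    } else {
      ann <- annotate_species(
        st, config$panel)[, c("analyte", "type", "lipid_class", "linkage")]
      sets <- ifelse(ann$type == "carnitine", "carnitine",
                     paste0(ann$lipid_class, ":", ann$linkage))
      dplyr::bind_rows(lapply(split(st, sets), classify_species,
                              alpha = config$alpha))
    }
    labels[[comp]] <- lab
    stm <- stage(paste0("differential_molpct:", comp),
                 species_stats(molpct, config$treated, config$control,
                               compartment = comp))
    labels_mol[[comp]] <- classify_species(stm, alpha = config$alpha)
    write_output_table(lab, file.path(config$out_dir,
                                      paste0("labels_", comp, ".tsv")), prov)
    write_output_table(volcano_table(lab),
                       file.path(config$out_dir,
                                 paste0("volcano_", comp, ".tsv")), prov)
    write_output_table(labels_mol[[comp]],
                       file.path(config$out_dir,
                                 paste0("labels_molpct_", comp, ".tsv")),
                       prov)
    summary_counts[[comp]] <- as.list(table(lab$label))
    message("differential ", comp, ": ", nrow(lab), " species classified")
  }

  ratio_rows <- stage("ratio_panel", dplyr::bind_rows(lapply(
    config$ratio_specs, function(s) {
      dplyr::bind_rows(lapply(compartments, function(comp)
        dplyr::mutate(
          double_bond_ratio(ratios, config$panel, s$lipid_class, s$linkage,
                            s$numerator_db, s$denominator_db,
                            config$treated, config$control, comp,
                            name = s$name),
          compartment = comp)))
    })))
  if (nrow(ratio_rows))
    write_output_table(ratio_rows,
                       file.path(config$out_dir, "ratio_panel.tsv"), prov)

  carn <- stage("carnitine_panel", dplyr::bind_rows(lapply(
    compartments, function(comp)
      dplyr::mutate(carnitine_panel(ratios, config$panel, config$treated,
                                    config$control, comp),
                    compartment = comp))))
  write_output_table(carn,
                     file.path(config$out_dir, "carnitine_panel.tsv"), prov)

  shift <- NULL; venn <- NULL
  if (length(compartments) >= 2) {
    shift <- stage("shift_test",
                   shift_test(labels[[1]], labels[[2]]))
    venn <- stage("venn_partition",
                  venn_partition(labels[[1]], labels[[2]]))
    write_output_table(venn$counts,
                       file.path(config$out_dir, "venn_counts.tsv"), prov)
  }

  summary <- list(
    seed = config$seed, config_hash = prov$config_hash,
    n_analytes = nrow(config$panel$species),
    label_counts = summary_counts,
    avg_sem = lapply(labels, function(l) attr(l, "avg_sem")),
    matrix_effect = list(
      by_compartment = qc$by_compartment,
      overall_mean_abs_pct = qc$overall_mean_abs_pct),
    shift = if (!is.null(shift))
      list(table = as.data.frame(shift$table), p_value = shift$p_value),
    venn = if (!is.null(venn)) as.list(stats::setNames(venn$counts$n,
                                                       venn$counts$cell)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
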