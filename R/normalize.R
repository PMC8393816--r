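#' Normalize analyte intensities to their class internal standard
#'
#' Divides every analyte intensity by the intensity of its
#' (class, linkage) internal standard measured in the same sample and
#' technical replicate. Standards themselves are removed from the
#' output. An optional per-sample `scale` column (e.g. a protein-amount
#' adjustment) is applied to intensities before division; since it
#' cancels in the ratio this only matters if standards were spiked
#' after scaling.
#'
#' A standard that is absent or non-positive in a (sample, technical
#' replicate) invalidates that whole standard group for the sample: the
#' affected records are dropped with a warning and returned in the
#' `invalid` attribute. A zero analyte intensity over a valid standard
#' is kept as ratio 0 — zero SRM signal is informative.
#'
#' @param table measurement tibble (see [simulate_dataset()] /
#'   [read_measurements()] for the schema).
#' @param panel the `analyte_panel` defining standard assignments.
#' @return A ratio tibble with the same keys and a `ratio` column in
#'   place of `intensity`; attribute `invalid` lists dropped
#'   (sample, standard group) pairs.
#' @export
normalize_to_standard <- function(table, panel) {
  stopifnot(is.data.frame(table), inherits(panel, "analyte_panel"))
  has_tech <- "tech_replicate" %in% names(table) &&
    !all(is.na(table$tech_replicate))
  keys <- if (has_tech) c("sample_id", "tech_replicate") else "sample_id"

  if ("scale" %in% names(table))
    table$intensity <- table$intensity * table$scale

  std_tbl <- table |>
    dplyr::filter(.data$analyte %in% panel$standards$standard) |>
    dplyr::inner_join(panel$standards, by = c(analyte = "standard"),
                      relationship = "many-to-many") |>
    dplyr::select(dplyr::all_of(keys), "std_group",
                  std_intensity = "intensity")

  analyte_map <- panel$species[, c("analyte", "std_group")]
  out <- table |>
    dplyr::filter(!.data$analyte %in% panel$standards$standard) |>
    dplyr::inner_join(analyte_map, by = "analyte") |>
    dplyr::left_join(std_tbl, by = c(keys, "std_group"))

  bad <- is.na(out$std_intensity) | out$std_intensity <= 0
  invalid <- unique(out[bad, c("sample_id", "std_group")])
  if (nrow(invalid)) {
    warning(nrow(invalid), " (sample, class) pair(s) invalidated by a ",
            "missing or non-positive internal standard", call. = FALSE)
    out <- out |>
      dplyr::anti_join(invalid, by = c("sample_id", "std_group"))
  }
  out$ratio <- out$intensity / out$std_intensity
  out <- out |>
    dplyr::select(-"intensity", -"std_intensity", -"std_group",
                  -dplyr::any_of("scale"))
  attr(out, "invalid") <- invalid
  out
}

#' Collapse technical replicates by averaging
#'
#' Forms the arithmetic mean per (sample, analyte) over technical
#' replicates and drops the technical-replicate dimension. It averages
#' whichever value column is present (`ratio` for normalized tables —
#' the intended order: ratios are formed per technical replicate first,
#' then averaged — or raw `intensity`). Missing values are excluded
#' from the mean with a warning; a (sample, analyte) with no usable
#' value is dropped with a warning.
#'
#' @param table a measurement or ratio tibble with a `tech_replicate`
#'   column.
#' @return the table averaged over technical replicates, without the
#'   `tech_replicate` column.
#' @export
collapse_technical <- function(table) {
  stopifnot(is.data.frame(table), "tech_replicate" %in% names(table))
  value_col <- if ("ratio" %in% names(table)) "ratio" else "intensity"
  if (anyNA(table[[value_col]]))
    warning("missing values excluded from technical-replicate means",
            call. = FALSE)
  keys <- setdiff(names(table), c("tech_replicate", value_col))
  out <- table |>
    dplyr::summarise(
      .value = mean(.data[[value_col]][!is.na(.data[[value_col]])]),
      .by = dplyr::all_of(keys))
  dropped <- is.nan(out$.value)
  if (any(dropped)) {
    warning(sum(dropped), " (sample, analyte) record(s) dropped: no ",
            "technical replicate carried a value", call. = FALSE)
    out <- out[!dropped, ]
  }
  names(out)[names(out) == ".value"] <- value_col
  out
}

#' Matrix-effect quality control
#'
#' Quantifies how much each internal standard's signal shifts between
#' groups: for every standard and non-reference group, the percent
#' change of the mean standard intensity relative to the reference
#' group, `(group - reference) / reference * 100`. Summaries report the
#' per-compartment maximum absolute change and mean absolute change,
#' plus the pooled average over all compartments. A standard absent in
#' some group is reported as not evaluable, never as a 0% change.
#'
#' @param table raw measurement tibble (standards included).
#' @param panel the `analyte_panel`.
#' @param reference_group label of the reference group.
#' @return a `matrix_effect_qc` list: `detail` (per standard x group x
#'   compartment percent change), `by_compartment` (max and mean
#'   absolute change), and `overall_mean_abs_pct`.
#' @export
matrix_effect_qc <- function(table, panel, reference_group) {
  stopifnot(is.data.frame(table))
  if (length(unique(table$group)) < 2)
    stop("matrix-effect QC needs at least two groups", call. = FALSE)
  stds <- table |>
    dplyr::filter(.data$analyte %in% panel$standards$standard) |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     .by = c("compartment", "analyte", "group"))
  ref <- stds |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::select("compartment", "analyte",
                  ref_intensity = "mean_intensity")
  grid <- tidyr::expand_grid(
    unique(stds[, c("compartment", "analyte")]),
    group = setdiff(unique(table$group), reference_group))
  detail <- grid |>
    dplyr::left_join(stds, by = c("compartment", "analyte", "group")) |>
    dplyr::left_join(ref, by = c("compartment", "analyte")) |>
    dplyr::mutate(
      pct_change = 100 * (.data$mean_intensity - .data$ref_intensity) /
        .data$ref_intensity,
      evaluable = !is.na(.data$pct_change)) |>
    dplyr::rename(standard = "analyte")
  by_comp <- detail |>
    dplyr::filter(.data$evaluable) |>
    dplyr::summarise(max_abs_pct = max(abs(.data$pct_change)),
                     mean_abs_pct = mean(abs(.data$pct_change)),
                     .by = "compartment")
  structure(list(
    detail = detail,
    by_compartment = by_comp,
    overall_mean_abs_pct =
      mean(abs(detail$pct_change[detail$evaluable]))),
    class = "matrix_effect_qc")
}

#' @export
print.matrix_effect_qc <- function(x, ...) {
  cat("<matrix_effect_qc>\n")
  for (i in seq_len(nrow(x$by_compartment)))
    cat(sprintf("  %-14s max |change| %.2f%%  mean |change| %.2f%%\n",
                x$by_compartment$compartment[i],
                x$by_compartment$max_abs_pct[i],
                x$by_compartment$mean_abs_pct[i]))
  cat(sprintf("  pooled mean |change| %.2f%%\n", x$overall_mean_abs_pct))
  n_bad <- sum(!x$detail$evaluable)
  if (n_bad) cat("  ", n_bad, "standard/group pair(s) not evaluable\n")
  invisible(x)
}
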