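#' Annotate a ratio table with parsed analyte attributes
#'
#' Joins the panel's parsed fields (type, class, linkage, carbons,
#' double bonds, carnitine chain length) onto a ratio table so
#' compositional aggregations can key on them.
#'
#' @param ratios ratio tibble.
#' @param panel an `analyte_panel`.
#' @return the ratio table with annotation columns added.
#' @export
annotate_species <- function(ratios, panel) {
  ann <- panel$species[, c("analyte", "type", "lipid_class", "linkage",
                           "carbons", "double_bonds", "chain_length",
                           "parity")]
  unknown <- setdiff(unique(ratios$analyte), ann$analyte)
  if (length(unknown))
    stop("analytes not in panel: ", paste(utils::head(unknown, 5),
                                          collapse = ", "), call. = FALSE)
  dplyr::left_join(ratios, ann, by = "analyte")
}

#' Within-class mol percent decomposition
#'
#' Expresses each species as a percentage of the summed signal of its
#' (class, linkage) set in the same sample, removing any whole-class
#' abundance effect: the "distribution within the lipid class" view.
#' Carnitines form their own set. Per sample and set the values sum to
#' 100 whenever the set sum is positive; a zero set sum makes all its
#' species not evaluable in that sample (`NA` with a note).
#'
#' @param ratios collapsed ratio tibble.
#' @param panel an `analyte_panel`.
#' @return tibble with the ratio keys and a `mol_pct` column; the
#'   downstream contrast machinery ([species_stats()],
#'   [classify_species()]) applies to it unchanged.
#' @export
mol_percent <- function(ratios, panel) {
  ann <- annotate_species(ratios, panel) |>
    dplyr::mutate(.set = ifelse(.data$type == "carnitine", "carnitine",
                                paste0(.data$lipid_class, ":", .data$linkage)))
  out <- ann |>
    dplyr::mutate(.set_sum = sum(.data$ratio),
                  .by = c("sample_id", ".set")) |>
    dplyr::mutate(
      mol_pct = ifelse(.data$.set_sum > 0,
                       100 * .data$ratio / .data$.set_sum, NA_real_),
      note = ifelse(.data$.set_sum > 0, NA_character_, "zero_class_sum"))
  if (any(!is.na(out$note)))
    warning("zero class sum in ", sum(!is.na(out$note)),
            " record(s); species flagged not evaluable", call. = FALSE)
  out |>
    dplyr::select(-"ratio", -".set", -".set_sum", -"type", -"lipid_class",
                  -"linkage", -"carbons", -"double_bonds", -"chain_length",
                  -"parity")
}

# Contrast a per-sample derived quantity between groups.
# values: tibble with sample_id, group, value. Returns one row with the
# treated mean as % of control (control = 100), SEM in % points, and a
# two-tailed pooled Student-t p across replicates.
contrast_derived <- function(values, treated, control, name,
                             as_percent = TRUE) {
  v_t <- values$value[values$group == treated]
  v_c <- values$value[values$group == control]
  scale <- if (as_percent) 100 else 1
  if (length(v_t) < 2 || length(v_c) < 2 || !any(is.finite(v_c)) ||
      mean(v_c) == 0) {
    return(tibble::tibble(name = name, mean_of_control = NA_real_,
                          sem = NA_real_, p_value = NA_real_,
                          n_treated = length(v_t), n_control = length(v_c),
                          note = "not_evaluable"))
  }
  scaled <- scale * v_t / mean(v_c)
  tt <- pooled_t_test(v_t, v_c)
  tibble::tibble(name = name, mean_of_control = mean(scaled),
                 sem = stats::sd(scaled) / sqrt(length(v_t)),
                 p_value = tt$p, n_treated = length(v_t),
                 n_control = length(v_c), note = tt$note)
}

#' Double-bond ratio panel
#'
#' Computes, per biological replicate, the ratio of summed ratios of
#' species with a numerator double-bond count to those with a
#' denominator double-bond count inside one lipid class — e.g. PCae
#' X:4 / PCae X:6, a proxy for the omega-6 / omega-3 balance (X:4
#' species typically carry arachidonic acid, X:5/X:6 species EPA/DHA).
#' The treated mean is expressed as a percentage of the control mean
#' (control = 100%), with the SEM in percentage points and a two-tailed
#' Student-t p across replicates.
#'
#' @param ratios collapsed ratio tibble.
#' @param panel an `analyte_panel`.
#' @param lipid_class `"PC"`, `"PE"` or `"PG"`.
#' @param linkage `"aa"`, `"ae"`, `"lyso"`, or `"ax"` to pool diacyl
#'   and ether species.
#' @param numerator_db,denominator_db double-bond counts to sum over.
#' @param treated,control group labels.
#' @param compartment compartment to evaluate in.
#' @param name optional label; autogenerated if `NULL`.
#' @return one-row tibble (`name`, `mean_of_control` in %, `sem`,
#'   `p_value`, `n_treated`, `n_control`, `note`); the per-replicate
#'   ratio values are attached as attribute `replicates`.
#' @export
double_bond_ratio <- function(ratios, panel, lipid_class, linkage,
                              numerator_db, denominator_db,
                              treated, control, compartment,
                              name = NULL) {
  stopifnot(length(numerator_db) >= 1, length(denominator_db) >= 1)
  comp <- compartment
  link <- if (identical(linkage, "ax")) c("aa", "ae") else linkage
  ann <- annotate_species(ratios, panel) |>
    dplyr::filter(.data$compartment == comp, .data$type == "lipid",
                  .data$lipid_class == !!lipid_class,
                  .data$linkage %in% link)
  if (!any(ann$double_bonds %in% numerator_db) ||
      !any(ann$double_bonds %in% denominator_db))
    stop("numerator or denominator double-bond set matches no species",
         call. = FALSE)
  if (is.null(name))
    name <- sprintf("%s%s X:%s/X:%s", lipid_class, linkage,
                    paste(numerator_db, collapse = "+"),
                    paste(denominator_db, collapse = "+"))
  per_rep <- ann |>
    dplyr::summarise(
      num = sum(.data$ratio[.data$double_bonds %in% numerator_db]),
      den = sum(.data$ratio[.data$double_bonds %in% denominator_db]),
      .by = c("sample_id", "group"))
  zero_den <- per_rep$den == 0
  if (any(zero_den)) {
    warning(sum(zero_den), " replicate(s) excluded: zero denominator sum",
            call. = FALSE)
    per_rep <- per_rep[!zero_den, ]
  }
  per_rep$value <- per_rep$num / per_rep$den
  out <- contrast_derived(per_rep, treated, control, name)
  attr(out, "replicates") <- per_rep[, c("sample_id", "group", "value")]
  out
}

#' Fold changes of summed signal by double bonds or chain length
#'
#' Groups the species of one (class, linkage) set by double-bond count
#' or by chain-length bin, sums the normalized ratios per biological
#' replicate within each level, and contrasts the sums between groups
#' as in [double_bond_ratio()] (treated mean as % of control). Empty
#' levels are omitted.
#'
#' @param ratios collapsed ratio tibble.
#' @param panel an `analyte_panel`.
#' @param by `"double_bonds"` or `"carbons"` (chain-length bins).
#' @param lipid_class,linkage class selector; `linkage = "ax"` pools
#'   `aa` and `ae`.
#' @param treated,control,compartment contrast definition.
#' @param carbon_bins upper edges of the first bins; the default
#'   `c(33, 39)` gives short (<= 33), mid (34-39) and long (>= 40)
#'   total-carbon bins.
#' @return tibble with one [double_bond_ratio()]-style row per level.
#' @export
group_aggregate <- function(ratios, panel, by = c("double_bonds", "carbons"),
                            lipid_class, linkage, treated, control,
                            compartment, carbon_bins = c(33, 39)) {
  by <- match.arg(by)
  comp <- compartment
  link <- if (identical(linkage, "ax")) c("aa", "ae") else linkage
  ann <- annotate_species(ratios, panel) |>
    dplyr::filter(.data$compartment == comp, .data$type == "lipid",
                  .data$lipid_class == !!lipid_class,
                  .data$linkage %in% link)
  if (!nrow(ann)) stop("no species in scope", call. = FALSE)
  if (by == "double_bonds") {
    ann$level <- paste0("X:", ann$double_bonds)
  } else {
    edges <- c(-Inf, sort(carbon_bins), Inf)
    lab <- c(paste0("<=", carbon_bins[1]),
             paste0(carbon_bins[1] + 1, "-", carbon_bins[2]),
             paste0(">=", carbon_bins[2] + 1))
    ann$level <- as.character(cut(ann$carbons, edges, labels = lab))
  }
  per_rep <- ann |>
    dplyr::summarise(value = sum(.data$ratio),
                     .by = c("level", "sample_id", "group"))
  dplyr::bind_rows(lapply(split(per_rep, per_rep$level), function(d)
    contrast_derived(d, treated, control, d$level[1])))
}

#' Carnitine carrier panel
#'
#' Derives the free/acyl-carnitine quantities that index mitochondrial
#' beta-oxidation and carnitine-shuttle activity, per biological
#' replicate, and contrasts them between groups:
#'
#' * `C0`, `C2`, `C3`, `C16`, `C18` — individual species;
#' * `Ceven` — sum of even-chain acyl-carnitines with chain >= 4
#'   (C2 is kept out because it serves as a denominator);
#' * `Codd` — sum of odd-chain acyl-carnitines with chain >= 5
#'   (likewise excluding C3);
#' * `CX` — all acyl-carnitines (chain >= 2; free carnitine C0 is not
#'   an acyl-carnitine and is excluded);
#' * ratios `C0/C2`, `Ceven/C2`, `Codd/C3`, `CX/(C2+C3)`, `C2+C3`,
#'   `C0/(C2+C3)`, `(C16+C18)/C2`.
#'
#' Each quantity is computed per replicate first, then contrasted as a
#' fold change versus the control mean (control = 1) with SEM and a
#' two-tailed Student-t p. A ratio whose denominator is 0 in a
#' replicate, or whose input species are absent from the panel, is
#' flagged not evaluable.
#'
#' @param ratios collapsed ratio tibble.
#' @param panel an `analyte_panel`.
#' @param treated,control group labels.
#' @param compartment compartment to evaluate in.
#' @return tibble with one row per quantity: `name`, `fold_change`
#'   (control = 1), `sem`, `p_value`, `n_treated`, `n_control`, `note`.
#' @export
carnitine_panel <- function(ratios, panel, treated, control, compartment) {
  comp <- compartment
  carn <- annotate_species(ratios, panel) |>
    dplyr::filter(.data$compartment == comp, .data$type == "carnitine")
  if (!nrow(carn)) stop("no carnitine analytes present", call. = FALSE)
  sums <- carn |>
    dplyr::summarise(
      C0   = sum(.data$ratio[.data$chain_length == 0]),
      C2   = sum(.data$ratio[.data$chain_length == 2]),
      C3   = sum(.data$ratio[.data$chain_length == 3]),
      C16  = sum(.data$ratio[.data$chain_length == 16]),
      C18  = sum(.data$ratio[.data$chain_length == 18]),
      Ceven = sum(.data$ratio[.data$parity == "even" &
                                .data$chain_length >= 4]),
      Codd  = sum(.data$ratio[.data$parity == "odd" &
                                .data$chain_length >= 5]),
      CX    = sum(.data$ratio[.data$chain_length >= 2]),
      .by = c("sample_id", "group"))
  have <- function(chain) any(carn$chain_length == chain)
  quantities <- list(
    C0 = function(s) s$C0, C2 = function(s) s$C2, C3 = function(s) s$C3,
    Ceven = function(s) s$Ceven, Codd = function(s) s$Codd,
    CX = function(s) s$CX,
    `C2+C3` = function(s) s$C2 + s$C3,
    `C0/C2` = function(s) safe_div(s$C0, s$C2),
    `Ceven/C2` = function(s) safe_div(s$Ceven, s$C2),
    `Codd/C3` = function(s) safe_div(s$Codd, s$C3),
    `CX/(C2+C3)` = function(s) safe_div(s$CX, s$C2 + s$C3),
    `C0/(C2+C3)` = function(s) safe_div(s$C0, s$C2 + s$C3),
    `(C16+C18)/C2` = function(s) safe_div(s$C16 + s$C18, s$C2))
  needs <- list(`C0/C2` = 2, `Ceven/C2` = 2, `Codd/C3` = 3,
                `CX/(C2+C3)` = c(2, 3), `C0/(C2+C3)` = c(2, 3),
                `(C16+C18)/C2` = 2)
  rows <- lapply(names(quantities), function(nm) {
    if (nm %in% names(needs) && !all(vapply(needs[[nm]], have, TRUE)))
      return(tibble::tibble(name = nm, mean_of_control = NA_real_,
                            sem = NA_real_, p_value = NA_real_,
                            n_treated = NA_integer_,
                            n_control = NA_integer_,
                            note = "missing_input_species"))
    vals <- tibble::tibble(sample_id = sums$sample_id, group = sums$group,
                           value = quantities[[nm]](sums))
    bad <- !is.finite(vals$value)
    if (any(bad)) vals <- vals[!bad, ]
    out <- contrast_derived(vals, treated, control, nm, as_percent = FALSE)
    if (any(bad) && is.na(out$note))
      out$note <- "replicates_with_zero_denominator_excluded"
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::rename(fold_change = "mean_of_control")
}

safe_div <- function(num, den) ifelse(den == 0, NaN, num / den)
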