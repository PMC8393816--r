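#' Per-species contrast statistics
#'
#' For each analyte in one compartment, compares the treated group to
#' the control group on the collapsed (per-biological-replicate)
#' normalized ratios:
#'
#' * each replicate's ratio is scaled by the control mean, so the
#'   control sits at 1;
#' * `fold_change` is the mean of the scaled treated values;
#' * `sem` is the standard deviation of the scaled treated values over
#'   the square root of the treated sample size (the per-species error
#'   bar on the fold-change scale);
#' * `p_value` comes from a two-tailed pooled-variance Student t-test on
#'   the unscaled per-replicate ratios.
#'
#' Degenerate cases: zero variance in both groups with equal means gives
#' p = 1 (note `"degenerate"`); a zero control mean makes the species
#' not evaluable (`NA` statistics, note `"zero_control_mean"`).
#'
#' @param ratios collapsed ratio tibble (one value per sample and
#'   analyte; see [normalize_to_standard()] and [collapse_technical()]).
#'   A mol' percent table works identically.
#' @param treated,control group labels to contrast.
#' @param compartment optional compartment to restrict to; required when
#'   `ratios` spans several compartments.
#' @return tibble of per-species statistics: `analyte`, `compartment`,
#'   `fold_change`, `sem`, `p_value`, `n_control`, `n_treated`, `note`.
#' @export
species_stats <- function(ratios, treated, control, compartment = NULL) {
  stopifnot(is.data.frame(ratios))
  value_col <- if ("mol_pct" %in% names(ratios)) "mol_pct" else "ratio"
  if (!is.null(compartment)) {
    comp <- compartment
    ratios <- dplyr::filter(ratios, .data$compartment %in% comp)
  }
  if (length(unique(ratios$compartment)) > 1)
    stop("ratios span several compartments; pass `compartment`",
         call. = FALSE)
  if (!all(c(treated, control) %in% ratios$group))
    stop("contrast group(s) absent from the table", call. = FALSE)
  ratios |>
    dplyr::filter(.data$group %in% c(treated, control)) |>
    dplyr::summarise(
      one_species_stats(.data[[value_col]][.data$group == treated],
                        .data[[value_col]][.data$group == control]),
      .by = c("analyte", "compartment"))
}

one_species_stats <- function(x_treated, x_control) {
  n_t <- length(x_treated); n_c <- length(x_control)
  if (n_t < 2 || n_c < 2)
    stop("both groups need at least 2 biological replicates", call. = FALSE)
  m_c <- mean(x_control)
  if (m_c == 0) {
    return(tibble::tibble(fold_change = NA_real_, sem = NA_real_,
                          p_value = NA_real_, n_control = n_c,
                          n_treated = n_t, note = "zero_control_mean"))
  }
  scaled_t <- x_treated / m_c
  tt <- pooled_t_test(x_treated, x_control)
  tibble::tibble(fold_change = mean(scaled_t),
                 sem = stats::sd(scaled_t) / sqrt(n_t),
                 p_value = tt$p, n_control = n_c, n_treated = n_t,
                 note = tt$note)
}

# classical two-sample pooled-variance Student t, two-tailed
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p = 1, note = "degenerate"))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = df, p = 0,
                note = "zero_variance"))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), note = NA_character_)
}

#' Trend / significance classification
#'
#' Applies the two-tier classification used throughout this style of
#' analysis: a species is *significant* (up or down, by the sign of
#' `fold_change - 1`) when p <= alpha; otherwise it is a *trend* when
#' its effect strength `|fold_change - 1|` exceeds the average SEM of
#' the analysis set (the dashed guide lines next to 0 on the volcano
#' plots); otherwise *unchanged*. The average SEM is computed over the
#' species passed in, so calling this on one lipid class reproduces the
#' per-class guide lines and calling it on the whole panel reproduces
#' the panel-wide ones.
#'
#' A Benjamini-Hochberg adjusted p-value is attached as supplementary
#' output (`p_adj_bh`); it plays no role in the labels.
#'
#' @param stats a [species_stats()] table for one compartment and
#'   contrast.
#' @param alpha significance level (default 0.05).
#' @return `stats` with `label` (factor with levels `significant_up`,
#'   `significant_down`, `trend_up`, `trend_down`, `unchanged`),
#'   `avg_sem` and `p_adj_bh` columns; the average SEM is also attached
#'   as attribute `avg_sem`.
#' @export
classify_species <- function(stats, alpha = 0.05) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0,
            alpha > 0, alpha < 1)
  if (length(unique(stats$compartment)) > 1)
    stop("classification is per compartment; got several", call. = FALSE)
  ok <- !is.na(stats$fold_change)
  avg_sem <- mean(stats$sem[ok])
  effect <- stats$fold_change - 1
  label <- dplyr::case_when(
    !ok                                  ~ NA_character_,
    stats$p_value <= alpha & effect >= 0 ~ "significant_up",
    stats$p_value <= alpha & effect < 0  ~ "significant_down",
    abs(effect) > avg_sem & effect > 0   ~ "trend_up",
    abs(effect) > avg_sem & effect < 0   ~ "trend_down",
    .default = "unchanged")
  out <- stats
  out$label <- factor(label, levels = classification_levels())
  out$avg_sem <- avg_sem
  out$p_adj_bh <- stats::p.adjust(stats$p_value, method = "BH")
  attr(out, "avg_sem") <- avg_sem
  out
}

classification_levels <- function() {
  c("significant_up", "significant_down", "trend_up", "trend_down",
    "unchanged")
}

#' Volcano-plot table
#'
#' Exports the coordinates a volcano plot needs: the effect strength
#' `fold_change - 1` (0 at no change; the guide lines sit at
#' `+/- avg_sem` on this axis) and `-log10(p)`. A p-value of exactly 0
#' is clamped to the smallest positive double before the logarithm and
#' noted.
#'
#' @param labeled a [classify_species()] table.
#' @return tibble with `analyte`, `compartment`, `effect`,
#'   `neg_log10_p`, `label`, `avg_sem`, `note`.
#' @export
volcano_table <- function(labeled) {
  stopifnot(is.data.frame(labeled), "label" %in% names(labeled))
  p <- labeled$p_value
  clamped <- !is.na(p) & p == 0
  p[clamped] <- .Machine$double.xmin
  tibble::tibble(
    analyte = labeled$analyte,
    compartment = labeled$compartment,
    effect = labeled$fold_change - 1,
    neg_log10_p = -log10(p),
    label = labeled$label,
    avg_sem = labeled$avg_sem,
    note = ifelse(clamped, "p_clamped_to_double_xmin", NA_character_))
}
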