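#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by the minimum-likelihood
#' convention standard in statistical software: conditioning on the
#' margins, the p-value is the sum of hypergeometric point
#' probabilities of every table whose probability does not exceed that
#' of the observed table. A relative tolerance of 1e-12 on the
#' probability comparison guards against floating-point ties.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return the p-value in `[0, 1]`; an all-zero table returns 1.
#' @examples
#' fisher_exact(matrix(c(86, 8, 1, 10), nrow = 2))
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)))
    stop("fisher_exact needs a 2x2 table", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(1, p)
}

#' Compartment shift test on up/down species counts
#'
#' Builds the 2x2 table of changed species — rows are the two
#' compartments, columns are increased (`significant_up` + `trend_up`)
#' and decreased (`significant_down` + `trend_down`) — and tests with
#' [fisher_exact()] whether the increased/decreased distribution
#' differs between the compartments. If either compartment has no
#' changed species in either direction the counts are still reported
#' but the p-value is not evaluable (`NA`).
#'
#' @param labels_a,labels_b [classify_species()] tables for the two
#'   compartments over the same analysis set.
#' @return a `shift_result`: list with the 2x2 `table` and `p_value`.
#' @export
shift_test <- function(labels_a, labels_b) {
  count_dir <- function(lab) c(
    increased = sum(lab$label %in% c("significant_up", "trend_up"),
                    na.rm = TRUE),
    decreased = sum(lab$label %in% c("significant_down", "trend_down"),
                    na.rm = TRUE))
  tab <- rbind(count_dir(labels_a), count_dir(labels_b))
  rownames(tab) <- c(unique(as.character(labels_a$compartment))[1],
                     unique(as.character(labels_b$compartment))[1])
  p <- if (any(rowSums(tab) == 0)) NA_real_ else fisher_exact(tab)
  structure(list(table = tab, p_value = p), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat("<shift_result> increased/decreased species by compartment\n")
  print(x$table)
  if (is.na(x$p_value)) {
    cat("Fisher exact p: not evaluable (a compartment has no changed",
        "species)\n")
  } else {
    cat(sprintf("Fisher exact p = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' Venn partition of changed species across two compartments
#'
#' Partitions the union of changed species (any trend or significant
#' label) into six exclusive cells: up or down exclusively in the first
#' compartment, up or down exclusively in the second, changed in both
#' with the same direction, and changed in both with opposite
#' directions.
#'
#' @param labels_a,labels_b [classify_species()] tables over the same
#'   analyte set.
#' @return a `venn_partition`: list of membership character vectors
#'   (`a_only_up`, `a_only_down`, `b_only_up`, `b_only_down`,
#'   `shared_same_direction`, `shared_opposite_direction`) plus a
#'   `counts` tibble.
#' @export
venn_partition <- function(labels_a, labels_b) {
  if (!setequal(labels_a$analyte, labels_b$analyte)) {
    diff <- c(setdiff(labels_a$analyte, labels_b$analyte),
              setdiff(labels_b$analyte, labels_a$analyte))
    stop("label tables cover different analytes: ",
         paste(utils::head(diff, 5), collapse = ", "), call. = FALSE)
  }
  dir_of <- function(lab) {
    d <- dplyr::case_when(
      lab$label %in% c("significant_up", "trend_up") ~ "up",
      lab$label %in% c("significant_down", "trend_down") ~ "down",
      .default = NA_character_)
    stats::setNames(d, lab$analyte)
  }
  da <- dir_of(labels_a); db <- dir_of(labels_b)[names(da)]
  cells <- list(
    a_only_up    = names(da)[!is.na(da) & da == "up" & is.na(db)],
    a_only_down  = names(da)[!is.na(da) & da == "down" & is.na(db)],
    b_only_up    = names(da)[is.na(da) & !is.na(db) & db == "up"],
    b_only_down  = names(da)[is.na(da) & !is.na(db) & db == "down"],
    shared_same_direction =
      names(da)[!is.na(da) & !is.na(db) & da == db],
    shared_opposite_direction =
      names(da)[!is.na(da) & !is.na(db) & da != db])
  counts <- tibble::tibble(cell = names(cells),
                           n = vapply(cells, length, 1L))
  structure(c(cells, list(counts = counts)), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> changed species across two compartments\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-26s %d\n", x$counts$cell[i], x$counts$n[i]))
  invisible(x)
}
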