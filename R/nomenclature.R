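#' Parse glycerophospholipid species names
#'
#' Parses analyte names in the shotgun-lipidomics dialect used for
#' sum-composition species: `<CLASS><linkage> C<carbons>:<double_bonds>`
#' (e.g. `"PCaa C40:1"`, `"PEae C38:6"`), the lyso form
#' `lyso-<CLASS> C<carbons>:<double_bonds>` and the two-chain form
#' `PG 18:2/16:0`. Because only precursor/fragment sum composition is
#' observed, `carbons` and `double_bonds` are totals over the sn-1 and
#' sn-2 chains; individual fatty acids are not resolved.
#'
#' Parsing is case-insensitive and tolerant of extra whitespace and
#' hyphens (`"PC aa C36:4"`, `"lysoPC C16:0"` are accepted). When a name
#' gives two explicit chains they are summed into the total composition
#' and retained in the `sn1`/`sn2` annotation columns.
#'
#' @param name character vector of species names.
#' @return A tibble with one row per input: `analyte` (canonical name),
#'   `lipid_class` (`"PC"`, `"PE"` or `"PG"`), `linkage` (`"aa"` diacyl,
#'   `"ae"` ether/plasmalogen, `"lyso"`), `carbons`, `double_bonds`, and
#'   chain annotations `sn1`, `sn2` (`NA` unless the name listed chains).
#' @examples
#' parse_lipid(c("PCaa C40:1", "lyso-PE C20:3", "PG 18:2/16:0"))
#' @export
parse_lipid <- function(name) {
  stopifnot(is.character(name), length(name) > 0)
  rows <- lapply(name, parse_lipid_one)
  dplyr::bind_rows(rows)
}

parse_lipid_one <- function(name) {
  raw <- name
  x <- gsub("\\s+", " ", trimws(name))
  # two-chain dialect, e.g. "PG 18:2/16:0"
  m <- regmatches(x, regexec(
    "^(pc|pe|pg)[- ]?(aa)? ?C?([0-9]+):([0-9]+) ?/ ?C?([0-9]+):([0-9]+)$",
    x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    c1 <- as.integer(m[4]); d1 <- as.integer(m[5])
    c2 <- as.integer(m[6]); d2 <- as.integer(m[7])
    return(new_lipid_row(raw, toupper(m[2]), "aa", c1 + c2, d1 + d2,
                         sn1 = paste0(m[4], ":", m[5]),
                         sn2 = paste0(m[6], ":", m[7])))
  }
  # lyso dialect, e.g. "lyso-PC C16:0"
  m <- regmatches(x, regexec(
    "^lyso[- ]?(pc|pe|pg) ?C?([0-9]+):([0-9]+)$", x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    return(new_lipid_row(raw, toupper(m[2]), "lyso",
                         as.integer(m[3]), as.integer(m[4])))
  }
  # diacyl / ether dialect, e.g. "PCaa C40:1", "PE ae C38:6"
  m <- regmatches(x, regexec(
    "^(pc|pe|pg)[- ]?(aa|ae) ?C?([0-9]+):([0-9]+)$", x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    return(new_lipid_row(raw, toupper(m[2]), tolower(m[3]),
                         as.integer(m[4]), as.integer(m[5])))
  }
  # a recognisable class with an unknown linkage token gets a pointed error
  m <- regmatches(x, regexec(
    "^(pc|pe|pg)[- ]?([a-z]+)\\b.*$", x, ignore.case = TRUE))[[1]]
  if (length(m) && !tolower(m[3]) %in% c("aa", "ae")) {
    stop("unknown linkage token '", m[3], "' in lipid name '", raw, "'",
         call. = FALSE)
  }
  stop("cannot parse lipid name '", raw, "'", call. = FALSE)
}

new_lipid_row <- function(raw, lipid_class, linkage, carbons, double_bonds,
                          sn1 = NA_character_, sn2 = NA_character_) {
  if (is.na(carbons) || carbons < 2)
    stop("invalid carbon count in lipid name '", raw, "'", call. = FALSE)
  if (is.na(double_bonds) || double_bonds < 0 || double_bonds > 12)
    stop("invalid double-bond count in lipid name '", raw, "'", call. = FALSE)
  tibble::tibble(
    analyte = render_lipid_fields(lipid_class, linkage, carbons, double_bonds,
                                  sn1, sn2),
    lipid_class = lipid_class, linkage = linkage,
    carbons = as.integer(carbons), double_bonds = as.integer(double_bonds),
    sn1 = sn1, sn2 = sn2)
}

render_lipid_fields <- function(lipid_class, linkage, carbons, double_bonds,
                                sn1 = NA_character_, sn2 = NA_character_) {
  n <- max(lengths(list(lipid_class, linkage, carbons, double_bonds)))
  r <- function(x) rep_len(x, n)
  lipid_class <- r(lipid_class); linkage <- r(linkage)
  carbons <- r(carbons); double_bonds <- r(double_bonds)
  sn1 <- r(sn1); sn2 <- r(sn2)
  out <- paste0(lipid_class, linkage, " C", carbons, ":", double_bonds)
  out[linkage == "lyso"] <- paste0("lyso-", lipid_class, " C", carbons,
                                   ":", double_bonds)[linkage == "lyso"]
  chained <- !is.na(sn1) & !is.na(sn2)
  out[chained] <- paste0(lipid_class, " ", sn1, "/", sn2)[chained]
  out
}

#' Render a parsed lipid back to its canonical name
#'
#' Canonical forms are `"PCaa C36:4"` for diacyl/ether species,
#' `"lyso-PC C16:0"` for lyso species, and `"PG 18:2/16:0"` when the
#' chain pair is annotated.
#'
#' @param species a tibble as returned by [parse_lipid()].
#' @return character vector of canonical names.
#' @export
render_lipid <- function(species) {
  render_lipid_fields(species$lipid_class, species$linkage, species$carbons,
                      species$double_bonds, species$sn1, species$sn2)
}

#' Parse acyl-carnitine names
#'
#' Carnitine analytes are named `C<chain length>`, optionally
#' zero-padded (`"C02"` and `"C2"` are the same analyte). Chain length 0
#' is free carnitine; 2 is acetyl-carnitine, the end product of
#' beta-oxidation; 3 is propionyl-carnitine.
#'
#' @param name character vector of carnitine names.
#' @return A tibble with `analyte` (canonical, unpadded), `chain_length`
#'   and `parity` (`"even"`/`"odd"`; C0 is labeled even).
#' @examples
#' parse_carnitine(c("C0", "C02", "C16"))
#' @export
parse_carnitine <- function(name) {
  stopifnot(is.character(name), length(name) > 0)
  m <- regmatches(trimws(name),
                  regexec("^[Cc]0*([0-9]+)$", trimws(name)))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad))
    stop("cannot parse carnitine name '", name[bad][1], "'", call. = FALSE)
  chain <- vapply(m, function(g) as.integer(g[2]), 1L)
  if (any(chain > 26))
    stop("carnitine chain length out of range in '",
         name[chain > 26][1], "'", call. = FALSE)
  tibble::tibble(
    analyte = paste0("C", chain),
    chain_length = chain,
    parity = ifelse(chain %% 2 == 0, "even", "odd"))
}

is_carnitine_name <- function(name) {
  grepl("^[Cc]0*[0-9]+$", trimws(name))
}

#' Parse a mixed vector of lipid and carnitine analyte names
#'
#' Dispatches each name to [parse_lipid()] or [parse_carnitine()] and
#' returns one annotation table with a `type` column.
#'
#' @param name character vector of analyte names.
#' @return tibble with columns `analyte`, `type` (`"lipid"`/`"carnitine"`),
#'   the lipid fields (`NA` for carnitines) and `chain_length`, `parity`
#'   (`NA` for lipids).
#' @export
parse_analyte <- function(name) {
  stopifnot(is.character(name), length(name) > 0)
  carn <- is_carnitine_name(name)
  out <- vector("list", length(name))
  if (any(carn)) {
    pc <- parse_carnitine(name[carn])
    out[which(carn)] <- split(pc, seq_len(nrow(pc)))
  }
  if (any(!carn)) {
    pl <- parse_lipid(name[!carn])
    out[which(!carn)] <- split(pl, seq_len(nrow(pl)))
  }
  full <- tibble::tibble(analyte = character(), lipid_class = character(),
                         linkage = character(), carbons = integer(),
                         double_bonds = integer(), sn1 = character(),
                         sn2 = character(), chain_length = integer(),
                         parity = character())
  dplyr::bind_rows(full, dplyr::bind_rows(out)) |>
    dplyr::mutate(type = ifelse(carn, "carnitine", "lipid"),
                  .after = "analyte")
}

#' Construct an analyte panel
#'
#' A panel couples the measured species with the internal-standard
#' assignment used for normalization: every glycerophospholipid maps to
#' the deuterated (or short-chain) standard of its (class, linkage)
#' group, and carnitines map to a short-chain or long-chain carnitine
#' standard.
#'
#' @param species tibble of parsed analytes ([parse_analyte()] columns).
#' @param standards tibble with columns `std_group` and `standard`
#'   (standard analyte identifier); groups are `"<CLASS>:<linkage>"` for
#'   lipids and `"carnitine:short"` / `"carnitine:long"` for carnitines.
#' @param long_chain_min carnitine chain length at which the long-chain
#'   standard applies (default 11, splitting octanoyl- from
#'   palmitoyl-carnitine territory).
#' @return An `analyte_panel`: a list with `species` (annotated tibble
#'   including the `std_group` and `standard` columns) and `standards`.
#' @export
analyte_panel <- function(species, standards, long_chain_min = 11L) {
  stopifnot(is.data.frame(species), is.data.frame(standards),
            all(c("std_group", "standard") %in% names(standards)))
  if (anyDuplicated(species$analyte))
    stop("duplicate species in panel: ",
         paste(unique(species$analyte[duplicated(species$analyte)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(standards$std_group))
    stop("more than one standard assigned to a group", call. = FALSE)
  species <- species |>
    dplyr::mutate(std_group = ifelse(
      .data$type == "carnitine",
      ifelse(.data$chain_length >= long_chain_min,
             "carnitine:long", "carnitine:short"),
      paste0(.data$lipid_class, ":", .data$linkage)))
  missing <- setdiff(species$std_group, standards$std_group)
  if (length(missing))
    stop("no internal standard for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  species <- dplyr::left_join(species, standards, by = "std_group")
  structure(list(species = species,
                 standards = tibble::as_tibble(standards)),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  n_lip <- sum(x$species$type == "lipid")
  n_car <- sum(x$species$type == "carnitine")
  cat("<analyte_panel> ", nrow(x$species), " analytes (",
      n_lip, " lipids, ", n_car, " carnitines), ",
      nrow(x$standards), " internal standards\n", sep = "")
  counts <- table(x$species$std_group)
  for (g in names(counts))
    cat("  ", format(g, width = 16), counts[[g]], "\n")
  invisible(x)
}

#' Read / write a panel file
#'
#' The panel file is two-column delimited text (tab or comma) with
#' columns `analyte` and `standard`. Standard-group membership is derived
#' from the analyte names; the file must assign a single consistent
#' standard per group.
#'
#' @param path file path.
#' @param panel an `analyte_panel` (for writing).
#' @return `read_panel()` returns an `analyte_panel`;
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path) {
  raw <- readr::read_delim(path, delim = sniff_delim(path),
                           col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
  if (!all(c("analyte", "standard") %in% names(raw)))
    stop("panel file must have columns 'analyte' and 'standard'",
         call. = FALSE)
  species <- parse_analyte(raw$analyte)
  species$analyte <- raw$analyte  # keep file spelling as the identifier
  long_min <- 11L
  grp <- ifelse(species$type == "carnitine",
                ifelse(species$chain_length >= long_min,
                       "carnitine:long", "carnitine:short"),
                paste0(species$lipid_class, ":", species$linkage))
  std <- unique(tibble::tibble(std_group = grp, standard = raw$standard))
  analyte_panel(species, std, long_chain_min = long_min)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  readr::write_tsv(panel$species[, c("analyte", "standard")], path)
  invisible(path)
}
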