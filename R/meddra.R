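#' Load a preferred-term dictionary
#'
#' The MedDRA dictionary is licensed and cannot ship with the package, so
#' term correction consumes a user-supplied mapping: a TSV with columns
#' `verbatim_pt`, `current_pt`, `soc` giving, for each verbatim preferred
#' term as it may appear in reports, its current-version PT and system organ
#' class. Lookup is case-insensitive and whitespace-normalized. A small
#' synthetic dictionary covering the package's fixtures ships in
#' `inst/extdata/synthetic_meddra_mini.tsv`.
#'
#' @param path Path to the TSV file.
#' @return A `pt_dictionary` tibble with columns `verbatim_norm`,
#'   `current_pt`, `soc`.
#' @export
read_pt_dictionary <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("verbatim_pt", "current_pt", "soc")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    pv_abort(paste0("Dictionary lacks column(s): ",
                    paste(missing_cols, collapse = ", ")),
             class = "faerspv_error_schema")
  }
  dict <- raw |>
    mutate(verbatim_norm = norm_string(.data$verbatim_pt)) |>
    dplyr::distinct(.data$verbatim_norm, .data$current_pt, .data$soc)
  dup <- dict |> dplyr::count(.data$verbatim_norm) |> dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    pv_abort(paste0("Conflicting dictionary entries for: ",
                    paste(utils::head(dup$verbatim_norm, 5), collapse = ", ")),
             class = "faerspv_error_config")
  }
  # a current PT must map to exactly one SOC
  soc_conflict <- dict |>
    dplyr::distinct(.data$current_pt, .data$soc) |>
    dplyr::count(.data$current_pt) |>
    dplyr::filter(.data$n > 1)
  if (nrow(soc_conflict)) {
    pv_abort(paste0("Current PT mapped to several SOCs: ",
                    paste(utils::head(soc_conflict$current_pt, 5),
                          collapse = ", ")),
             class = "faerspv_error_config")
  }
  structure(dict, class = c("pt_dictionary", class(dict)))
}

#' Map verbatim preferred terms to the current dictionary version
#'
#' Vectorized lookup of verbatim PTs against a [read_pt_dictionary()] table.
#' Unmapped terms are returned flagged (`mapped = FALSE`) and counted in a
#' message — never silently dropped. Empty verbatim strings are a validation
#' error.
#'
#' @param pt_verbatim Character vector of verbatim preferred terms.
#' @param dict A `pt_dictionary`.
#' @param quiet Suppress the unmapped-count message.
#' @return A tibble with columns `pt_verbatim`, `current_pt`, `soc`, `mapped`.
#' @examples
#' dict <- read_pt_dictionary(
#'   system.file("extdata", "synthetic_meddra_mini.tsv", package = "faerspv"))
#' normalize_pt(c("CYTOKINE RELEASE SYNDROME", "no such term"), dict)
#' @export
normalize_pt <- function(pt_verbatim, dict, quiet = FALSE) {
  if (any(is.na(pt_verbatim) | !nzchar(stringr::str_trim(pt_verbatim)))) {
    pv_abort("Empty verbatim PT.", class = "faerspv_error_validation")
  }
  out <- tibble(pt_verbatim = pt_verbatim,
                verbatim_norm = norm_string(pt_verbatim)) |>
    dplyr::left_join(as_tibble(dict), by = "verbatim_norm") |>
    mutate(mapped = !is.na(.data$current_pt)) |>
    dplyr::select("pt_verbatim", "current_pt", "soc", "mapped")
  n_unmapped <- sum(!out$mapped)
  if (n_unmapped > 0 && !quiet) {
    inform(sprintf("%d of %d verbatim PT(s) not in dictionary (flagged).",
                   n_unmapped, nrow(out)))
  }
  out
}

#' Load composite term-group definitions
#'
#' Composite adverse events pool several related PTs under one label (for
#' example "Tremor" covering tremor, intention tremor, dystonic tremor and
#' the other tremor variants; "Hypotension" covering hypotension, capillary
#' leak syndrome and orthostatic hypotension). Definitions live in a YAML
#' file mapping each label to its member list and a provenance note; the
#' groups used for CAR T-cell screening ship in
#' `inst/extdata/term_groups.yaml`. Members must be disjoint across groups.
#'
#' @param path Path to the YAML file.
#' @return A `term_groups` tibble with columns `label`, `member`,
#'   `member_norm`, `provenance`.
#' @export
read_term_groups <- function(path) {
  raw <- yaml::read_yaml(path)
  tbl <- purrr::imap(raw, function(entry, label) {
    members <- if (is.list(entry)) entry$members %||% entry else entry
    if (!length(members)) {
      pv_abort(sprintf("Term group '%s' has no members.", label),
               class = "faerspv_error_config")
    }
    tibble(label = label,
           member = as.character(members),
           provenance = entry$provenance %||% NA_character_)
  }) |>
    dplyr::bind_rows() |>
    mutate(member_norm = norm_string(.data$member))
  overlap <- tbl |>
    dplyr::distinct(.data$label, .data$member_norm) |>
    dplyr::count(.data$member_norm) |>
    dplyr::filter(.data$n > 1)
  if (nrow(overlap)) {
    pv_abort(paste0("PT(s) belong to more than one term group: ",
                    paste(overlap$member_norm, collapse = ", ")),
             class = "faerspv_error_config")
  }
  structure(tbl, class = c("term_groups", class(tbl)))
}

#' Replace grouped PTs by their composite label
#'
#' Each PT that is a member of a group is replaced by the group label; PTs in
#' no group pass through unchanged. At the case level use
#' [group_case_events()], which additionally applies set semantics (a case
#' contributes once per label however many members it reported).
#'
#' @param pts Character vector of current PTs.
#' @param groups A `term_groups` table (or `NULL` for pass-through).
#' @return Character vector of event labels, same length as `pts`.
#' @examples
#' groups <- read_term_groups(
#'   system.file("extdata", "term_groups.yaml", package = "faerspv"))
#' apply_term_groups(c("Intention tremor", "Pyrexia"), groups)
#' @export
apply_term_groups <- function(pts, groups) {
  if (is.null(groups) || nrow(groups) == 0) return(pts)
  idx <- match(norm_string(pts), groups$member_norm)
  out <- pts
  out[!is.na(idx)] <- groups$label[idx[!is.na(idx)]]
  out
}

#' Case-level event labels with set semantics
#'
#' Applies [apply_term_groups()] to a case-by-PT incidence table and keeps
#' distinct (case, label) pairs, so a case reporting several members of the
#' same group counts once for that group — matching report-level counting in
#' the contingency tables.
#'
#' @param case_events Tibble with columns `case_id` and `current_pt` (extra
#'   columns are dropped).
#' @param groups A `term_groups` table or `NULL`.
#' @return A tibble `case_id`, `event_label` (distinct).
#' @export
group_case_events <- function(case_events, groups = NULL) {
  case_events |>
    mutate(event_label = apply_term_groups(.data$current_pt, groups)) |>
    dplyr::distinct(.data$case_id, .data$event_label)
}

#' Load pathogen-class rules for infection terms
#'
#' Infection PTs can be pooled by pathogen type (bacterial, fungal, viral) in
#' the spirit of MedDRA's high-level group terms. Because the MedDRA
#' hierarchy is licensed, the classes are explicit, user-editable PT lists in
#' YAML (`inst/extdata/pathogen_classes.yaml` ships an illustrative,
#' synthetic transcription). Classes must be disjoint.
#'
#' @param path Path to the YAML file (keys `bacterial`, `fungal`, `viral`).
#' @return A `pathogen_rules` tibble with columns `class_label`, `member`,
#'   `member_norm`.
#' @export
read_pathogen_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("bacterial", "fungal", "viral")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    pv_abort(paste0("Unknown pathogen class(es): ", paste(bad, collapse = ", ")),
             class = "faerspv_error_config")
  }
  tbl <- purrr::imap(raw, function(members, cls) {
    if (is.list(members)) members <- members$members %||% members
    tibble(class_label = cls, member = as.character(members))
  }) |>
    dplyr::bind_rows() |>
    mutate(member_norm = norm_string(.data$member))
  overlap <- tbl |> dplyr::count(.data$member_norm) |> dplyr::filter(.data$n > 1)
  if (nrow(overlap)) {
    pv_abort(paste0("PT(s) in more than one pathogen class: ",
                    paste(overlap$member_norm, collapse = ", ")),
             class = "faerspv_error_config")
  }
  structure(tbl, class = c("pathogen_rules", class(tbl)))
}

#' Classify infection PTs by pathogen type
#'
#' @param current_pt Character vector of current PTs.
#' @param rules A `pathogen_rules` table.
#' @return Character vector: `"bacterial"`, `"fungal"`, `"viral"` or `NA`
#'   for PTs covered by no rule.
#' @export
classify_infection <- function(current_pt, rules) {
  idx <- match(norm_string(current_pt), rules$member_norm)
  ifelse(is.na(idx), NA_character_, rules$class_label[idx])
}
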