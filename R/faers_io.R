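FAERS_TABLE_KINDS <- c("demo", "drug", "reac", "ther", "outc", "indi")

# Mandatory columns per table kind. Files may carry more; extras are kept.
faers_required_cols <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT"),
  drug = c("PRIMARYID", "CASEID", "DRUGNAME", "ROLE_COD"),
  reac = c("PRIMARYID", "CASEID", "PT"),
  ther = c("PRIMARYID", "CASEID", "START_DT"),
  outc = c("PRIMARYID", "CASEID", "OUTC_COD"),
  indi = c("PRIMARYID", "CASEID", "INDI_PT")
)

# Outcome codes that make a report "serious" (FAERS convention: everything
# except OT = other).
SERIOUS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI")

#' Read one FAERS-format ASCII table
#'
#' FAERS quarterly packets distribute each table as `"$"`-delimited text with
#' a header row of column names (e.g. `DEMO17Q4.txt`). All columns are read
#' as character; typing happens in the entity accessors so that ingestion is
#' lossless.
#'
#' @param path Path to a `"$"`-delimited text file with a header row.
#' @param kind Table kind, one of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"outc"`, `"indi"`; governs which columns are mandatory.
#'
#' @return A tibble of character columns with upper-case FAERS names.
#' @export
read_faers_table <- function(path, kind) {
  kind <- rlang::arg_match(kind, FAERS_TABLE_KINDS)
  if (!file.exists(path)) {
    pv_abort(sprintf("FAERS %s table not found: %s", toupper(kind), path),
             class = "faerspv_error_io")
  }
  tbl <- readr::read_delim(
    path, delim = "$",
    col_types = readr::cols(.default = readr::col_character()),
    na = "", trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  names(tbl) <- toupper(names(tbl))
  missing_cols <- setdiff(faers_required_cols[[kind]], names(tbl))
  if (length(missing_cols)) {
    pv_abort(
      sprintf("FAERS %s table %s lacks mandatory column(s): %s",
              toupper(kind), path, paste(missing_cols, collapse = ", ")),
      class = "faerspv_error_schema"
    )
  }
  tbl
}

#' Read the six tables of one FAERS quarterly packet
#'
#' Locates `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`, `THERyyQq.txt`,
#' `OUTCyyQq.txt` and `INDIyyQq.txt` in a directory and parses each. DEMO,
#' DRUG and REAC are mandatory; the remaining tables are optional (an absent
#' file yields an empty table and a message). Per-table record counts are
#' reported as messages.
#'
#' @param dir Directory holding the quarter's files.
#' @param quarter Quarter label (`"YYYYQn"`).
#' @param quiet Suppress record-count messages.
#'
#' @return A `faers_bundle`: a named list of raw character tibbles
#'   (`demo`, `drug`, `reac`, `ther`, `outc`, `indi`) with the quarter label
#'   as an attribute.
#' @export
read_faers_quarter <- function(dir, quarter, quiet = FALSE) {
  tag <- quarter_file_tag(quarter)
  bundle <- purrr::map(rlang::set_names(FAERS_TABLE_KINDS), function(kind) {
    path <- file.path(dir, paste0(toupper(kind), tag, ".txt"))
    if (!file.exists(path)) {
      if (kind %in% c("demo", "drug", "reac")) {
        pv_abort(sprintf("Mandatory FAERS file missing for %s: %s",
                         quarter, path),
                 class = "faerspv_error_io")
      }
      if (!quiet) inform(sprintf("%s: no %s table; treated as empty.",
                                 quarter, toupper(kind)))
      return(empty_faers_table(kind))
    }
    read_faers_table(path, kind)
  })
  if (!quiet) {
    counts <- purrr::map_int(bundle, nrow)
    inform(sprintf("%s: %s", quarter,
                   paste(sprintf("%s=%d", toupper(names(counts)), counts),
                         collapse = " ")))
  }
  structure(bundle, class = "faers_bundle", quarter = quarter)
}

empty_faers_table <- function(kind) {
  cols <- faers_required_cols[[kind]]
  as_tibble(rlang::set_names(rep(list(character()), length(cols)), cols))
}

#' Combine several quarterly bundles
#'
#' Row-binds the corresponding tables of a list of `faers_bundle`s into one
#' bundle spanning all quarters.
#'
#' @param bundles List of `faers_bundle` objects.
#' @return A single `faers_bundle`.
#' @export
bind_faers <- function(bundles) {
  out <- purrr::map(rlang::set_names(FAERS_TABLE_KINDS), function(kind) {
    dplyr::bind_rows(purrr::map(bundles, kind))
  })
  structure(out, class = "faers_bundle",
            quarter = purrr::map_chr(bundles, ~ attr(.x, "quarter") %||% NA_character_))
}

#' Write a bundle back to FAERS-dialect files
#'
#' Serializes each table of a bundle as `"$"`-delimited text with a header
#' row, using the standard FAERS file names for the given quarter. Missing
#' values are written as empty fields. Reading the files back with
#' [read_faers_quarter()] reproduces the bundle field-for-field.
#'
#' @param bundle A `faers_bundle` (or named list of tibbles).
#' @param dir Output directory (created if needed).
#' @param quarter Quarter label used to name the files.
#' @return Invisibly, the paths written.
#' @export
write_faers <- function(bundle, dir, quarter) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- quarter_file_tag(quarter)
  paths <- purrr::imap_chr(bundle[FAERS_TABLE_KINDS], function(tbl, kind) {
    path <- file.path(dir, paste0(toupper(kind), tag, ".txt"))
    readr::write_delim(tbl, path, delim = "$", na = "")
    path
  })
  invisible(paths)
}

# ---- typed entity accessors -------------------------------------------------

# AGE_COD unit -> multiplier to years
AGE_UNIT_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                      DY = 1 / 365, HR = 1 / 8760)

normalize_age_years <- function(age, age_cod) {
  age_num <- suppressWarnings(as.numeric(age))
  unit <- AGE_UNIT_FACTORS[toupper(stringr::str_trim(age_cod %||% ""))]
  unit[is.na(unit)] <- NA_real_
  # missing unit code defaults to years (FAERS convention)
  unit[is.na(age_cod) & !is.na(age_num)] <- 1
  years <- unname(age_num * unit)
  years[!is.na(years) & (years < 0 | years > 120)] <- NA_real_
  years
}

map_sex <- function(x) {
  x <- toupper(stringr::str_trim(x %||% ""))
  dplyr::case_when(x == "F" ~ "female", x == "M" ~ "male",
                   .default = "unknown")
}

map_reporter <- function(occp_cod) {
  x <- toupper(stringr::str_trim(occp_cod %||% ""))
  dplyr::case_when(
    x %in% c("MD", "PH", "OT", "HP", "RN") ~ "health_professional",
    x == "CN" ~ "consumer",
    .default = "unknown"
  )
}

#' Typed case reports from a raw bundle
#'
#' Converts the raw DEMO table into one row per report version with typed
#' demographics: sex, age normalized to years from the `AGE`/`AGE_COD` pair
#' (DEC, YR, MON, WK, DY, HR; results outside 0-120 years become missing),
#' reporter occupation, country, receipt date and event date with explicit
#' precision.
#'
#' @param bundle A `faers_bundle`.
#' @return A tibble with columns `primary_id`, `case_id`, `fda_date`, `sex`,
#'   `age_years`, `reporter`, `country`, `event_date`,
#'   `event_date_precision`.
#' @export
faers_cases <- function(bundle) {
  demo <- bundle$demo
  col <- function(name) if (name %in% names(demo)) demo[[name]] else rep(NA_character_, nrow(demo))
  ev <- parse_faers_date(col("EVENT_DT"))
  tibble(
    primary_id = demo$PRIMARYID,
    case_id = demo$CASEID,
    fda_date = parse_faers_date(demo$FDA_DT)$date,
    sex = map_sex(col("SEX")),
    age_years = normalize_age_years(col("AGE"), col("AGE_COD")),
    reporter = map_reporter(col("OCCP_COD")),
    country = col("REPORTER_COUNTRY"),
    event_date = ev$date,
    event_date_precision = ev$precision
  )
}

#' Typed drug exposures from a raw bundle
#'
#' Converts the raw DRUG table into exposures with the four FAERS role codes
#' (PS = primary suspect, SS = secondary suspect, C = concomitant,
#' I = interacting). When a THER table is present its `START_DT` is joined on
#' by drug sequence number to provide the therapy start date with precision.
#'
#' @param bundle A `faers_bundle`.
#' @return A tibble with columns `primary_id`, `case_id`, `drug_seq`,
#'   `drug_name`, `active_ingredient`, `role`, `start_date`,
#'   `start_date_precision`.
#' @export
faers_exposures <- function(bundle) {
  drug <- bundle$drug
  col <- function(name) if (name %in% names(drug)) drug[[name]] else rep(NA_character_, nrow(drug))
  out <- tibble(
    primary_id = drug$PRIMARYID,
    case_id = drug$CASEID,
    drug_seq = col("DRUG_SEQ"),
    drug_name = drug$DRUGNAME,
    active_ingredient = col("PROD_AI"),
    role = toupper(stringr::str_trim(drug$ROLE_COD))
  )
  bad_role <- !is.na(out$role) & !out$role %in% c("PS", "SS", "C", "I")
  if (any(bad_role)) {
    warn(sprintf("%d exposure row(s) with unrecognized ROLE_COD kept as-is.",
                 sum(bad_role)))
  }
  ther <- bundle$ther
  if (!is.null(ther) && nrow(ther) > 0 && "DSG_DRUG_SEQ" %in% names(ther)) {
    st <- parse_faers_date(ther$START_DT)
    ther_tbl <- tibble(
      primary_id = ther$PRIMARYID,
      drug_seq = ther$DSG_DRUG_SEQ,
      start_date = st$date,
      start_date_precision = st$precision
    ) |>
      dplyr::distinct(.data$primary_id, .data$drug_seq, .keep_all = TRUE)
    out <- dplyr::left_join(out, ther_tbl, by = c("primary_id", "drug_seq"))
    out$start_date_precision[is.na(out$start_date_precision)] <- "missing"
  } else {
    out$start_date <- as.Date(NA)
    out$start_date_precision <- "missing"
  }
  out
}

#' Typed reaction records from a raw bundle
#'
#' One row per (report version, verbatim preferred term). Duplicate rows for
#' the same case and PT within a packet collapse to one; empty PTs are
#' dropped with a message.
#'
#' @param bundle A `faers_bundle`.
#' @return A tibble with columns `primary_id`, `case_id`, `pt_verbatim`.
#' @export
faers_reactions <- function(bundle) {
  reac <- bundle$reac
  out <- tibble(
    primary_id = reac$PRIMARYID,
    case_id = reac$CASEID,
    pt_verbatim = stringr::str_trim(reac$PT)
  )
  empty <- is.na(out$pt_verbatim) | out$pt_verbatim == ""
  if (any(empty)) {
    inform(sprintf("Dropped %d reaction row(s) with empty PT.", sum(empty)))
    out <- out[!empty, ]
  }
  dplyr::distinct(out)
}

#' Typed outcome records from a raw bundle
#'
#' @param bundle A `faers_bundle`.
#' @return A tibble with columns `primary_id`, `case_id`, `outcome_code`
#'   (one of DE, LT, HO, DS, CA, RI, OT).
#' @export
faers_outcomes <- function(bundle) {
  outc <- bundle$outc
  tibble(
    primary_id = outc$PRIMARYID,
    case_id = outc$CASEID,
    outcome_code = toupper(stringr::str_trim(outc$OUTC_COD))
  ) |>
    dplyr::distinct()
}

#' Typed indication records from a raw bundle
#'
#' @param bundle A `faers_bundle`.
#' @return A tibble with columns `primary_id`, `case_id`, `indication`.
#' @export
faers_indications <- function(bundle) {
  indi <- bundle$indi
  tibble(
    primary_id = indi$PRIMARYID,
    case_id = indi$CASEID,
    indication = stringr::str_trim(indi$INDI_PT)
  ) |>
    dplyr::distinct()
}

#' Normalize a raw bundle into typed entity tables
#'
#' @param bundle A `faers_bundle`.
#' @return A `faers_data` list with elements `cases`, `exposures`,
#'   `reactions`, `outcomes`, `indications`.
#' @export
normalize_faers <- function(bundle) {
  structure(
    list(
      cases = faers_cases(bundle),
      exposures = faers_exposures(bundle),
      reactions = faers_reactions(bundle),
      outcomes = faers_outcomes(bundle),
      indications = faers_indications(bundle)
    ),
    class = "faers_data"
  )
}

# ---- deduplication ----------------------------------------------------------

#' Deduplicate case report versions
#'
#' FAERS re-publishes a safety report each time it is amended, so one case
#' identifier can appear with several report versions. Following the FDA's
#' recommended procedure, the version with the most recent receipt date
#' (`FDA_DT`) is kept; when receipt dates tie, the numerically larger
#' `PRIMARYID` wins (the successor of the legacy ISR key). The operation is
#' idempotent and leaves exactly one row per `case_id`.
#'
#' @param cases Tibble of case reports, as from [faers_cases()].
#' @return The deduplicated tibble, one row per `case_id`.
#' @export
deduplicate_cases <- function(cases) {
  if (nrow(cases) == 0) return(cases)
  dup <- cases |>
    dplyr::add_count(.data$case_id, name = "n_versions")
  pid_num <- suppressWarnings(as.numeric(dup$primary_id))
  needs_tiebreak <- dup$n_versions > 1L
  if (any(needs_tiebreak & is.na(pid_num))) {
    bad <- unique(dup$primary_id[needs_tiebreak & is.na(pid_num)])
    pv_abort(
      paste0("PRIMARYID not numerically comparable for tie-breaking: ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "faerspv_error_validation"
    )
  }
  dup |>
    mutate(.pid_num = pid_num) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(dplyr::desc(.data$fda_date), dplyr::desc(.data$.pid_num),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".pid_num", -"n_versions") |>
    dplyr::arrange(.data$case_id)
}

#' Deduplicate a full `faers_data` object
#'
#' Applies [deduplicate_cases()] to the case table and restricts every other
#' entity table to the surviving report versions.
#'
#' @param data A `faers_data` list from [normalize_faers()].
#' @return A `faers_data` with attribute `n_duplicates_removed`.
#' @export
dedup_faers <- function(data) {
  before <- nrow(data$cases)
  cases <- deduplicate_cases(data$cases)
  keep <- cases$primary_id
  out <- structure(
    list(
      cases = cases,
      exposures = dplyr::filter(data$exposures, .data$primary_id %in% keep),
      reactions = dplyr::filter(data$reactions, .data$primary_id %in% keep),
      outcomes = dplyr::filter(data$outcomes, .data$primary_id %in% keep),
      indications = dplyr::filter(data$indications, .data$primary_id %in% keep)
    ),
    class = "faers_data"
  )
  attr(out, "n_duplicates_removed") <- before - nrow(cases)
  out
}

# ---- primary-suspect filtering ----------------------------------------------

#' Attribute cases to products via primary-suspect exposures
#'
#' A case is attributed to a product if and only if it has at least one
#' exposure with role `PS` whose `DRUGNAME` or `PROD_AI` exactly matches one
#' of the product's synonyms after normalization (upper-cased, trimmed,
#' internal whitespace collapsed). A case matching several products is
#' attributed to each.
#'
#' @param exposures Tibble of exposures, as from [faers_exposures()].
#' @param products Named list: product name -> character vector of
#'   `DRUGNAME`/`PROD_AI` synonyms. An empty synonym vector is a
#'   configuration error.
#' @return A tibble with columns `product`, `case_id` (distinct pairs).
#' @export
filter_primary_suspect <- function(exposures, products) {
  if (!length(products) || is.null(names(products)) ||
      any(!nzchar(names(products)))) {
    pv_abort("`products` must be a named list of synonym vectors.",
             class = "faerspv_error_config")
  }
  empty <- purrr::map_lgl(products, ~ length(.x) == 0 || all(!nzchar(.x)))
  if (any(empty)) {
    pv_abort(paste0("Empty synonym list for product(s): ",
                    paste(names(products)[empty], collapse = ", ")),
             class = "faerspv_error_config")
  }
  ps <- dplyr::filter(exposures, .data$role == "PS")
  if (nrow(ps) == 0) {
    return(tibble(product = character(), case_id = character()))
  }
  ps <- ps |>
    mutate(.name = norm_string(.data$drug_name),
           .ai = norm_string(.data$active_ingredient))
  syn_tbl <- purrr::imap(products, function(syns, prod) {
    tibble(product = prod, synonym = norm_string(syns))
  }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  by_name <- dplyr::inner_join(ps, syn_tbl, by = c(".name" = "synonym"),
                               relationship = "many-to-many")
  by_ai <- dplyr::inner_join(ps, syn_tbl, by = c(".ai" = "synonym"),
                             relationship = "many-to-many")
  dplyr::bind_rows(by_name, by_ai) |>
    dplyr::distinct(.data$product, .data$case_id) |>
    dplyr::arrange(.data$product, .data$case_id)
}

#' Seriousness of cases from outcome codes
#'
#' A case is serious iff it carries at least one outcome code in
#' DE, LT, HO, DS, CA, RI; `OT` alone is non-serious.
#'
#' @param case_ids Character vector of case identifiers to classify.
#' @param outcomes Tibble of outcomes, as from [faers_outcomes()].
#' @return A tibble `case_id`, `serious` (logical).
#' @export
case_seriousness <- function(case_ids, outcomes) {
  serious_ids <- outcomes |>
    dplyr::filter(.data$outcome_code %in% SERIOUS_OUTCOME_CODES) |>
    dplyr::pull(.data$case_id) |>
    unique()
  tibble(case_id = unique(case_ids)) |>
    mutate(serious = .data$case_id %in% serious_ids)
}
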