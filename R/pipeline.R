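#' Read product synonym lists
#'
#' A YAML file mapping each product name to the `DRUGNAME`/`PROD_AI`
#' synonyms that identify it (brand and non-proprietary names). The six
#' CAR T-cell products ship in `inst/extdata/car_t_products.yaml`.
#'
#' @param path Path to the YAML file.
#' @return A named list of character vectors.
#' @export
read_product_synonyms <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw, as.character)
}

#' SOC lookup for grouped event labels
#'
#' Builds an `event_label -> soc` map covering both plain current PTs and
#' composite group labels (a group inherits the SOC of its first member
#' found in the dictionary).
#'
#' @param dict A `pt_dictionary`.
#' @param groups A `term_groups` table or `NULL`.
#' @return A tibble `event_label`, `soc`.
#' @export
build_soc_map <- function(dict, groups = NULL) {
  base <- as_tibble(dict) |>
    dplyr::distinct(event_label = .data$current_pt, .data$soc)
  if (is.null(groups) || nrow(groups) == 0) return(base)
  grp <- as_tibble(groups) |>
    dplyr::left_join(
      as_tibble(dict) |>
        dplyr::distinct(member_norm = norm_string(.data$current_pt), .data$soc),
      by = "member_norm") |>
    dplyr::filter(!is.na(.data$soc)) |>
    dplyr::distinct(event_label = .data$label, .data$soc) |>
    dplyr::distinct(.data$event_label, .keep_all = TRUE)
  dplyr::bind_rows(grp, dplyr::anti_join(base, grp, by = "event_label")) |>
    dplyr::distinct(.data$event_label, .keep_all = TRUE)
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates ingestion (real quarterly packets or the synthetic
#' emulator), deduplication, primary-suspect attribution, term
#' normalization and grouping, disproportionality screening and the
#' descriptive profiling layers. Writes `signals.tsv` (plus a
#' full-precision companion), `demographics.tsv`, `onset_bins.tsv`,
#' `overlap.tsv`, `soc_distribution.tsv` and `manifest.json` into
#' `out_dir`. The manifest records package version, a hash of the resolved
#' configuration, the seed and per-stage record counts that telescope
#' (emitted versions = deduplicated cases + duplicates removed; onset
#' candidates = retained + each exclusion class). Identical configuration
#' and seed produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param products Named list of synonym vectors (see
#'   [read_product_synonyms()]).
#' @param dictionary Path to the PT dictionary TSV, or a `pt_dictionary`.
#' @param groups Path to the term-group YAML, a `term_groups` table, or
#'   `NULL` for no grouping.
#' @param faers_dir,start,end Directory of quarterly packets and the
#'   inclusive quarter range to ingest (ignored when `synth` is given).
#' @param synth A [synth_config()] to generate input instead of reading
#'   files.
#' @param seed Seed forwarded to the synthetic generator (defaults to the
#'   config's own seed).
#' @param criteria A [signal_criteria()].
#' @param comparator,correction,yates Passed to [screen_signals()].
#' @param bins Onset bin edges, passed to [onset_binning()].
#' @param crs_label Event label treated as CRS for overlap profiling.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory results (`screen`,
#'   `demographics`, `onset`, `onset_bins`, `overlap`, `soc_distribution`,
#'   `manifest`) and the paths written.
#' @export
run_pipeline <- function(out_dir,
                         products,
                         dictionary,
                         groups = NULL,
                         faers_dir = NULL, start = NULL, end = NULL,
                         synth = NULL, seed = NULL,
                         criteria = signal_criteria(),
                         comparator = "full",
                         correction = "none",
                         yates = FALSE,
                         bins = c(7, 30, 60),
                         crs_label = "Cytokine release syndrome",
                         quiet = TRUE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- stage: ingest ----------------------------------------------------------
  if (!is.null(synth)) {
    if (inherits(synth, "faers_bundle")) {
      bundle <- synth
    } else {
      sim <- synth_faers(synth, seed = seed)
      bundle <- sim$bundle
    }
    say("ingest: synthetic bundle with %d DEMO row(s)", nrow(bundle$demo))
  } else {
    if (is.null(faers_dir) || is.null(start) || is.null(end)) {
      pv_abort("Provide either `synth` or `faers_dir` with `start`/`end`.",
               class = "faerspv_error_config")
    }
    qs <- faers_quarters(start, end)$label
    bundle <- bind_faers(purrr::map(qs, ~ read_faers_quarter(faers_dir, .x,
                                                             quiet = quiet)))
    say("ingest: %d quarter(s), %d DEMO row(s)", length(qs), nrow(bundle$demo))
  }

  data <- normalize_faers(bundle)
  n_versions <- nrow(data$cases)

  # -- stage: deduplicate -----------------------------------------------------
  dd <- dedup_faers(data)
  n_cases <- nrow(dd$cases)
  n_dupes <- attr(dd, "n_duplicates_removed")
  say("dedup: %d version(s) -> %d case(s) (%d removed)",
      n_versions, n_cases, n_dupes)

  # -- stage: attribute products ----------------------------------------------
  product_cases <- filter_primary_suspect(dd$exposures, products)
  say("products: %d attributed case-product pair(s)", nrow(product_cases))

  # -- stage: normalize + group terms -----------------------------------------
  dict <- if (inherits(dictionary, "pt_dictionary")) dictionary
          else read_pt_dictionary(dictionary)
  grp <- if (is.null(groups) || inherits(groups, "term_groups")) groups
         else read_term_groups(groups)
  mapped <- normalize_pt(dd$reactions$pt_verbatim, dict, quiet = TRUE)
  n_unmapped <- sum(!mapped$mapped)
  say("normalize: %d reaction row(s), %d unmapped PT(s)",
      nrow(mapped), n_unmapped)
  case_pts <- dplyr::bind_cols(
    dplyr::select(dd$reactions, "case_id"), mapped) |>
    dplyr::filter(.data$mapped)
  universe <- group_case_events(case_pts, grp)
  soc_map <- build_soc_map(dict, grp)

  # -- stage: screen ----------------------------------------------------------
  screen <- screen_signals(universe, product_cases, criteria = criteria,
                           comparator = comparator, correction = correction,
                           yates = yates, universe_ids = dd$cases$case_id,
                           soc_map = soc_map)
  say("screen: %d pair(s), %d signal(s)", nrow(screen), sum(screen$is_signal))

  # -- stage: profile ---------------------------------------------------------
  demographics <- demographics_table(dd, product_cases)
  onset <- case_onset(dd, product_cases)
  onset_bins <- onset |>
    dplyr::filter(.data$status == "retained") |>
    dplyr::group_by(.data$product) |>
    dplyr::reframe(onset_binning(.data$days, edges = bins))
  onset_accounting <- dplyr::count(onset, .data$status, name = "n")
  cohort_universe <- dplyr::semi_join(universe, product_cases, by = "case_id")
  overlap <- withCallingHandlers(
    crs_overlap(cohort_universe,
                sort(setdiff(unique(cohort_universe$event_label), crs_label)),
                crs_labels = crs_label),
    message = function(m) if (quiet) invokeRestart("muffleMessage")
  )
  soc_distribution <- withCallingHandlers(
    if (any(screen$is_signal)) soc_signal_distribution(screen)
    else tibble(product = character(), soc = character(),
                n = integer(), share = numeric()),
    message = function(m) if (quiet) invokeRestart("muffleMessage")
  )

  # -- stage: write -----------------------------------------------------------
  paths <- c(
    signals = file.path(out_dir, "signals.tsv"),
    demographics = file.path(out_dir, "demographics.tsv"),
    onset_bins = file.path(out_dir, "onset_bins.tsv"),
    overlap = file.path(out_dir, "overlap.tsv"),
    soc_distribution = file.path(out_dir, "soc_distribution.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_signal_tsv(screen, paths[["signals"]])
  readr::write_tsv(demographics, paths[["demographics"]])
  readr::write_tsv(onset_bins, paths[["onset_bins"]])
  readr::write_tsv(overlap, paths[["overlap"]])
  readr::write_tsv(soc_distribution, paths[["soc_distribution"]])

  resolved <- list(
    products = products, criteria = unclass(criteria),
    comparator = comparator, correction = correction, yates = yates,
    bins = bins, crs_label = crs_label,
    synth = if (!is.null(synth) && inherits(synth, "synth_config"))
      unclass(synth) else NULL,
    quarters = if (!is.null(start)) c(start, end) else NULL
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("faerspv")),
    config_hash = rlang::hash(resolved),
    seed = seed %||% (if (inherits(synth, "synth_config")) synth$seed else NA),
    counts = list(
      demo_rows = n_versions,
      cases_deduplicated = n_cases,
      duplicates_removed = n_dupes,
      product_case_pairs = nrow(product_cases),
      reaction_rows = nrow(mapped),
      unmapped_pts = n_unmapped,
      pairs_screened = nrow(screen),
      signals_flagged = sum(screen$is_signal),
      onset = as.list(rlang::set_names(onset_accounting$n,
                                       onset_accounting$status))
    )
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(screen = screen, demographics = demographics,
                 onset = onset, onset_bins = onset_bins, overlap = overlap,
                 soc_distribution = soc_distribution, manifest = manifest,
                 paths = paths))
}
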