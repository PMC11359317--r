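# Synthetic FAERS emulator: quarterly packets with known ground truth.
#
# Drug-event associations are planted on the odds scale: an event with
# background per-report probability r has background odds o = r/(1-r), and a
# case exposed to a product carrying a planted multiplier m reports the
# event with probability o*m/(1 + o*m). The true reporting odds ratio of a
# planted pair is therefore m by construction, which makes recovery tests
# exact in expectation.

# run code under a private RNG state seeded from `seed`, restoring the
# caller's stream afterwards
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

default_synth_events <- function() {
  tibble(
    pt = c("Cytokine release syndrome", "Neurotoxicity",
           "Immune effector cell-associated neurotoxicity syndrome",
           "Pyrexia", "Hypotension", "Tremor", "Hypoxia", "Tachycardia",
           "Bacterial infection", "Viral infection", "Fungal infection",
           "Hypogammaglobulinaemia", "Platelet count decreased",
           "White blood cell count decreased", "Fatigue", "Nausea",
           "Headache", "Diarrhoea", "Rash", "Dyspnoea"),
    rate = c(0.02, 0.015, 0.01, 0.08, 0.05, 0.02, 0.015, 0.03,
             0.02, 0.015, 0.008, 0.005, 0.02, 0.02, 0.1, 0.12,
             0.09, 0.08, 0.06, 0.05),
    soc = c("Immune system disorders", "Nervous system disorders",
            "Nervous system disorders", "General disorders",
            "Vascular disorders", "Nervous system disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Cardiac disorders", "Infections and infestations",
            "Infections and infestations", "Infections and infestations",
            "Immune system disorders", "Investigations", "Investigations",
            "General disorders", "Gastrointestinal disorders",
            "Nervous system disorders", "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders",
            "Respiratory, thoracic and mediastinal disorders")
  )
}

#' Configuration for the synthetic FAERS emulator
#'
#' Defines the generative model: case count, per-product exposure
#' prevalences, per-event background reporting rates, planted (product,
#' event) odds multipliers, duplicate-version and date-corruption rates,
#' the log-normal onset model and a single integer seed governing all
#' randomness.
#'
#' @param n_cases Number of distinct cases to generate.
#' @param products Tibble with columns `name`, `prevalence` (each in (0,1),
#'   summing to < 1; the remainder of cases are background reports on other
#'   drugs).
#' @param events Tibble with columns `pt`, `rate` (background per-report
#'   probability in (0,1)), `soc`. Defaults to a 20-event panel drawn from
#'   the package's synthetic mini-dictionary.
#' @param planted Tibble with columns `product`, `event`, `multiplier`
#'   (odds multiplier >= 0) referencing declared products/events; empty for
#'   a null universe.
#' @param duplicate_rate Expected fraction of emitted DEMO rows that are
#'   superseded duplicate versions, in [0, 1).
#' @param partial_date_rate Fraction of cases whose emitted `EVENT_DT` is
#'   truncated to month precision, in [0, 1).
#' @param missing_date_rate Fraction of cases whose emitted `EVENT_DT` is
#'   blank, in [0, 1).
#' @param onset_meanlog,onset_sdlog Parameters of the log-normal onset-day
#'   model (defaults give a median of about 5 days post-infusion).
#' @param quarters Character vector of quarter labels over which cases are
#'   spread.
#' @param seed Integer seed for the single generator stream.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cases = 10000,
                         products = tibble(name = c("ACMECEL", "BETACEL"),
                                           prevalence = c(0.05, 0.05)),
                         events = default_synth_events(),
                         planted = tibble(product = character(),
                                          event = character(),
                                          multiplier = numeric()),
                         duplicate_rate = 0.05,
                         partial_date_rate = 0.03,
                         missing_date_rate = 0.05,
                         onset_meanlog = log(5),
                         onset_sdlog = 0.9,
                         quarters = c("2023Q1", "2023Q2", "2023Q3", "2023Q4"),
                         seed = 20170101) {
  cfg <- list(n_cases = n_cases, products = as_tibble(products),
              events = as_tibble(events), planted = as_tibble(planted),
              duplicate_rate = duplicate_rate,
              partial_date_rate = partial_date_rate,
              missing_date_rate = missing_date_rate,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              quarters = quarters, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  fail <- function(msg) pv_abort(msg, class = "faerspv_error_config")
  if (!is.numeric(cfg$n_cases) || cfg$n_cases < 1) fail("n_cases must be >= 1.")
  p <- cfg$products
  if (!all(c("name", "prevalence") %in% names(p))) {
    fail("products needs columns name, prevalence.")
  }
  if (any(p$prevalence <= 0 | p$prevalence >= 1) || sum(p$prevalence) >= 1) {
    fail("Product prevalences must lie in (0,1) and sum to < 1.")
  }
  ev <- cfg$events
  if (!all(c("pt", "rate", "soc") %in% names(ev))) {
    fail("events needs columns pt, rate, soc.")
  }
  if (any(ev$rate <= 0 | ev$rate >= 1)) fail("Event rates must lie in (0,1).")
  pl <- cfg$planted
  if (nrow(pl)) {
    if (!all(c("product", "event", "multiplier") %in% names(pl))) {
      fail("planted needs columns product, event, multiplier.")
    }
    if (any(!pl$product %in% p$name)) fail("planted references unknown product.")
    if (any(!pl$event %in% ev$pt)) fail("planted references unknown event.")
    if (any(pl$multiplier < 0)) fail("planted multipliers must be >= 0.")
  }
  for (r in c("duplicate_rate", "partial_date_rate", "missing_date_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) fail(paste(r, "must lie in [0,1)."))
  }
  parse_quarter(cfg$quarters)  # validates labels
  invisible(cfg)
}

quarter_start_date <- function(label) {
  q <- parse_quarter(label)
  as.Date(sprintf("%04d-%02d-01", q$year, (q$quarter - 1L) * 3L + 1L))
}

#' Draw the latent case-level universe for a synthetic configuration
#'
#' Generates the ground-truth layer only — exposures, true event sets, true
#' onset days, demographics — without duplicate versions or date
#' corruption. This is the fast path for calibration loops; [synth_faers()]
#' adds the file-level noise and renders FAERS tables.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with tibbles `cases` (one row per case: ids, dates,
#'   demographics, product), `case_events` (case_id, pt), and `truth`
#'   (the planted table).
#' @export
synth_universe <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(seed %||% config$seed, {
    n <- config$n_cases
    case_id <- as.character(seq_len(n) + 10000000L)

    # exposure assignment: at most one target product per case
    prev <- config$products$prevalence
    u <- stats::runif(n)
    prod_idx <- findInterval(u, c(0, cumsum(prev)), left.open = TRUE)
    product <- config$products$name[prod_idx]  # idx past the end -> NA
    background_drug <- paste0("BACKGROUND DRUG ",
                              sample.int(12L, n, replace = TRUE))

    # event incidence: odds-scale planting
    ev <- config$events
    inc <- purrr::map(seq_len(nrow(ev)), function(j) {
      odds <- ev$rate[j] / (1 - ev$rate[j])
      mult <- rep(1, n)
      pl <- dplyr::filter(config$planted, .data$event == ev$pt[j])
      if (nrow(pl)) {
        for (k in seq_len(nrow(pl))) {
          mult[!is.na(product) & product == pl$product[k]] <- pl$multiplier[k]
        }
      }
      p <- odds * mult / (1 + odds * mult)
      hit <- stats::runif(n) < p
      if (!any(hit)) return(NULL)
      tibble(case_id = case_id[hit], pt = ev$pt[j])
    }) |>
      dplyr::bind_rows()

    # every report carries at least one reaction
    with_event <- case_id %in% inc$case_id
    if (any(!with_event)) {
      inc <- dplyr::bind_rows(inc, tibble(case_id = case_id[!with_event],
                                          pt = "Product quality issue"))
    }

    quarter <- sample(config$quarters, n, replace = TRUE)
    q_start <- quarter_start_date(quarter)
    start_date <- q_start + sample.int(60L, n, replace = TRUE) - 1L
    onset_days <- pmax(0L, as.integer(round(stats::rlnorm(
      n, config$onset_meanlog, config$onset_sdlog))))
    event_date <- start_date + onset_days
    fda_date <- event_date + stats::rpois(n, 20)

    sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(0.31, 0.48, 0.21))
    age <- round(stats::runif(n, 1, 90), 1)
    age[stats::runif(n) < 0.3] <- NA
    occp <- sample(c("MD", "PH", "CN", NA), n, replace = TRUE,
                   prob = c(0.55, 0.2, 0.12, 0.13))
    country <- sample(c("US", "CA", "FR", "DE", "GB", "JP", "CN", NA), n,
                      replace = TRUE,
                      prob = c(0.55, 0.06, 0.08, 0.06, 0.06, 0.04, 0.02, 0.13))

    cases <- tibble(
      case_id = case_id, quarter = quarter, product = product,
      background_drug = background_drug,
      start_date = start_date, onset_days = onset_days,
      event_date = event_date, fda_date = fda_date,
      sex = sex, age = age, occp = occp, country = country
    )
    list(cases = cases, case_events = inc, truth = config$planted)
  })
}

#' Generate FAERS-dialect quarterly files with known ground truth
#'
#' Renders a [synth_universe()] draw into the six-table FAERS relational
#' structure, then adds the file-level artifacts real packets exhibit:
#' superseded duplicate case versions (re-emissions with a later `FDA_DT`
#' and a higher `PRIMARYID`, clinical content untouched) and partial or
#' missing event dates. Identical config and seed give byte-identical files
#' when written with [write_synth_faers()].
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list: `bundle` (a `faers_bundle` of raw character tables),
#'   `universe` (the latent draw), `truth` (planted pairs), `config`.
#' @export
synth_faers <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- seed %||% config$seed
  uni <- synth_universe(config, seed = seed)
  with_rng(seed + 1L, {
    cases <- uni$cases
    n <- nrow(cases)
    pid <- function(case_id, version) {
      sprintf("%s%02d", case_id, version)
    }

    # event-date corruption (emission only; ground truth keeps true onset)
    ev_dt <- format(cases$event_date, "%Y%m%d")
    u <- stats::runif(n)
    ev_dt[u < config$partial_date_rate] <-
      format(cases$event_date[u < config$partial_date_rate], "%Y%m")
    miss <- u >= config$partial_date_rate &
      u < config$partial_date_rate + config$missing_date_rate
    ev_dt[miss] <- NA_character_

    demo <- tibble(
      PRIMARYID = pid(cases$case_id, 1L),
      CASEID = cases$case_id,
      CASEVERSION = "1",
      FDA_DT = format(cases$fda_date, "%Y%m%d"),
      EVENT_DT = ev_dt,
      SEX = cases$sex,
      AGE = as.character(cases$age),
      AGE_COD = ifelse(is.na(cases$age), NA_character_, "YR"),
      OCCP_COD = cases$occp,
      REPORTER_COUNTRY = cases$country,
      QUARTER = cases$quarter
    )

    # duplicate re-emissions: later FDA_DT, higher PRIMARYID, same content
    p_extra <- config$duplicate_rate / (1 - config$duplicate_rate)
    dup_sel <- stats::runif(n) < p_extra
    dup_rows <- demo[dup_sel, ]
    if (nrow(dup_rows)) {
      # the re-emission supersedes the original
      orig_fda <- cases$fda_date[dup_sel]
      dup_rows$FDA_DT <- format(orig_fda + 30L, "%Y%m%d")
      dup_rows$PRIMARYID <- pid(dup_rows$CASEID, 2L)
      dup_rows$CASEVERSION <- "2"
      demo <- dplyr::bind_rows(demo, dup_rows)
    }
    kept_pid <- ifelse(dup_sel, pid(cases$case_id, 2L), pid(cases$case_id, 1L))

    # all-version join key so child tables follow every demo row
    versions <- demo |> dplyr::select("PRIMARYID", "CASEID")

    drug_one <- tibble(
      CASEID = cases$case_id,
      DRUG_SEQ = "1",
      ROLE_COD = "PS",
      DRUGNAME = dplyr::coalesce(cases$product, cases$background_drug),
      PROD_AI = dplyr::coalesce(cases$product, cases$background_drug)
    )
    conc_sel <- stats::runif(n) < 0.2
    drug_conc <- tibble(
      CASEID = cases$case_id[conc_sel],
      DRUG_SEQ = "2",
      ROLE_COD = "C",
      DRUGNAME = paste0("CONCOMITANT DRUG ",
                        sample.int(5L, sum(conc_sel), replace = TRUE)),
      PROD_AI = NA_character_
    )
    drug <- dplyr::bind_rows(drug_one, drug_conc) |>
      dplyr::inner_join(versions, by = "CASEID",
                        relationship = "many-to-many") |>
      dplyr::select("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD",
                    "DRUGNAME", "PROD_AI")

    reac <- uni$case_events |>
      dplyr::rename(CASEID = "case_id", PT = "pt") |>
      dplyr::inner_join(versions, by = "CASEID",
                        relationship = "many-to-many") |>
      dplyr::select("PRIMARYID", "CASEID", "PT")

    ther <- tibble(
      CASEID = cases$case_id,
      DSG_DRUG_SEQ = "1",
      START_DT = format(cases$start_date, "%Y%m%d")
    ) |>
      dplyr::inner_join(versions, by = "CASEID",
                        relationship = "many-to-many") |>
      dplyr::select("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT")

    outc_codes <- purrr::map(seq_len(n), function(i) {
      codes <- c(
        if (stats::runif(1) < 0.35) "HO",
        if (stats::runif(1) < 0.15) "DE",
        if (stats::runif(1) < 0.08) "LT",
        if (stats::runif(1) < 0.5) "OT"
      )
      codes
    })
    outc <- tibble(CASEID = rep(cases$case_id, lengths(outc_codes)),
                   OUTC_COD = unlist(outc_codes)) |>
      dplyr::inner_join(versions, by = "CASEID",
                        relationship = "many-to-many") |>
      dplyr::select("PRIMARYID", "CASEID", "OUTC_COD")

    indi <- tibble(
      CASEID = cases$case_id,
      INDI_DRUG_SEQ = "1",
      INDI_PT = ifelse(is.na(cases$product), "Indication unknown",
                       paste("Indication for", cases$product))
    ) |>
      dplyr::inner_join(versions, by = "CASEID",
                        relationship = "many-to-many") |>
      dplyr::select("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT")

    bundle <- structure(
      list(demo = demo, drug = drug, reac = reac, ther = ther,
           outc = outc, indi = indi),
      class = "faers_bundle", quarter = config$quarters
    )
    list(bundle = bundle, universe = uni,
         truth = list(planted = uni$truth,
                      kept_primary_ids = kept_pid,
                      case_products = dplyr::filter(
                        dplyr::select(cases, "case_id", "product"),
                        !is.na(.data$product)),
                      case_events = uni$case_events,
                      onset = dplyr::select(cases, "case_id", "onset_days")),
         config = config)
  })
}

#' Write a synthetic bundle as quarterly FAERS packets
#'
#' Splits the DEMO table by each case's assigned quarter and writes one set
#' of six `"$"`-delimited files per quarter (child tables follow their
#' report versions), plus `ground_truth.tsv` listing the planted pairs.
#'
#' @param sim Result of [synth_faers()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_synth_faers <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- sim$bundle$demo
  quarters <- sort(unique(demo$QUARTER))
  paths <- purrr::map(quarters, function(q) {
    pids <- demo$PRIMARYID[demo$QUARTER == q]
    sub <- list(
      demo = dplyr::select(demo[demo$QUARTER == q, ], -"QUARTER"),
      drug = dplyr::filter(sim$bundle$drug, .data$PRIMARYID %in% pids),
      reac = dplyr::filter(sim$bundle$reac, .data$PRIMARYID %in% pids),
      ther = dplyr::filter(sim$bundle$ther, .data$PRIMARYID %in% pids),
      outc = dplyr::filter(sim$bundle$outc, .data$PRIMARYID %in% pids),
      indi = dplyr::filter(sim$bundle$indi, .data$PRIMARYID %in% pids)
    )
    write_faers(sub, dir, q)
  })
  truth_path <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(sim$truth$planted, truth_path)
  invisible(c(unlist(paths), truth_path))
}
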