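# Screening cascade: solubility flags, clean screen, theoretical-Rmax hit
# calling with superstoichiometric and calibration-range exclusions.

#' Triage configuration
#'
#' Thresholds of the screening cascade. Inequality directions follow the
#' printed criteria exactly: exclusions are strict (`>`), the hit criterion
#' is inclusive (`>=`).
#'
#' @param clean_threshold Residual-binding threshold in RU; compounds with a
#'   residual report point strictly above it fail the clean screen
#'   (default 5.0 RU at 10 s post injection).
#' @param residual_offset Seconds after injection stop at which the residual
#'   report point is read (default 10).
#' @param screen_conc Screening concentration in M (default 500 µM).
#' @param hit_fraction Minimal fraction of theoretical Rmax for a hit
#'   (default 0.60).
#' @param superstoich_factor Responses strictly above this multiple of the
#'   theoretical Rmax are excluded as superstoichiometric (default 2).
#' @param stoich_n Assumed binding stoichiometry for the Rmax computation
#'   (default 1).
#' @param abnormal_negative_RU Magnitude of negative binding (RU) beyond
#'   which a sensorgram shape is considered abnormal; a residual point
#'   exceeding both the binding point and this level triggers the same
#'   flag. Heuristic; the underlying instrument criterion is qualitative.
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(clean_threshold = 5.0, residual_offset = 10,
                          screen_conc = 500e-6, hit_fraction = 0.60,
                          superstoich_factor = 2.0, stoich_n = 1,
                          abnormal_negative_RU = 1.0) {
  for (nm in c("clean_threshold", "residual_offset", "screen_conc",
               "hit_fraction", "superstoich_factor", "stoich_n",
               "abnormal_negative_RU")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  if (hit_fraction >= superstoich_factor) {
    abort("`hit_fraction` must be below `superstoich_factor`")
  }
  structure(
    list(clean_threshold = clean_threshold, residual_offset = residual_offset,
         screen_conc = screen_conc, hit_fraction = hit_fraction,
         superstoich_factor = superstoich_factor, stoich_n = stoich_n,
         abnormal_negative_RU = abnormal_negative_RU),
    class = "triage_config"
  )
}

#' Theoretical maximal binding response
#'
#' Rmax = immobilization level (RU) x (MW analyte / MW ligand) x n. For a
#' 92 kDa ligand immobilized at 9200 RU, a 276 Da fragment has a theoretical
#' Rmax of 27.6 RU at n = 1.
#'
#' @param surface A [surface_def()] (or a list/one-row data frame with
#'   `ligand_mw` and `immobilization`).
#' @param mw Analyte molecular weight(s) in Da.
#' @param n Binding stoichiometry.
#' @return Theoretical Rmax in RU (vectorized over `mw`).
#' @examples
#' theoretical_rmax(surface_def("C1r", 92000, 9200), 276) # 27.6
#' @export
theoretical_rmax <- function(surface, mw, n = 1) {
  if (is.null(surface$immobilization) || is.null(surface$ligand_mw)) {
    abort("`surface` must carry `immobilization` and `ligand_mw`")
  }
  check_number(surface$immobilization, "immobilization", positive = TRUE)
  check_number(surface$ligand_mw, "ligand_mw", positive = TRUE)
  if (any(!is.finite(mw) | mw <= 0)) abort("analyte `mw` must be positive")
  surface$immobilization * (mw / surface$ligand_mw) * n
}

#' Clean screen
#'
#' Flags non-specific ("sticky") binders: a compound fails when its
#' residual binding report point, read 10 s after injection stop, is
#' strictly greater than the threshold (default 5.0 RU). A residual of
#' exactly 5.0 RU passes.
#'
#' @param residual Residual report-point values in RU, or a tibble from
#'   [report_point()] (its `kind` must be `residual_post_injection`).
#' @param config A [triage_config()].
#' @return Logical vector: `TRUE` = pass, `FALSE` = fail.
#' @export
clean_screen <- function(residual, config = triage_config()) {
  if (is.data.frame(residual)) {
    if (!is.null(residual$kind) &&
        any(residual$kind != "residual_post_injection")) {
      abort("clean screen needs report points of kind residual_post_injection")
    }
    residual <- residual$value
  }
  !(residual > config$clean_threshold)
}

#' Score screened compounds and call hits
#'
#' Applies the full triage cascade to corrected report points: insolubility
#' (an input flag from visual inspection, never computed), clean screen,
#' solvent-calibration range, superstoichiometric exclusion, abnormal-shape
#' heuristic, and the percent-of-Rmax hit criterion. A compound is a hit iff
#' it carries no exclusion flag and its corrected binding response is at
#' least `hit_fraction` of its theoretical Rmax.
#'
#' @param report Tibble from [process_campaign()] (columns `compound_id`,
#'   `binding_RU`, `residual_RU`, `in_range`).
#' @param library Compound tibble with `id` and `mw` (e.g. [load_library()]).
#' @param surface A [surface_def()].
#' @param config A [triage_config()].
#' @param insoluble Character vector of compound ids flagged insoluble.
#' @return A tibble of screen records: `compound_id`, `binding_RU`,
#'   `residual_RU`, `rmax_theoretical`, `pct_rmax`, the logical flag columns
#'   `flag_insoluble`, `flag_clean_fail`, `flag_out_of_calibration`,
#'   `flag_superstoichiometric`, `flag_abnormal_shape`, and `hit`.
#' @export
screen_compounds <- function(report, library, surface,
                             config = triage_config(),
                             insoluble = character()) {
  check_columns(report, c("compound_id", "binding_RU", "residual_RU", "in_range"),
                "report")
  check_columns(library, c("id", "mw"), "library")
  # insoluble compounds are removed before any cycle is run, but they are
  # still part of the campaign bookkeeping: emit a flagged record for them
  unscreened <- setdiff(insoluble, report$compound_id)
  if (length(unscreened) > 0) {
    report <- dplyr::bind_rows(report, tibble(
      compound_id = unscreened, binding_RU = NA_real_,
      residual_RU = NA_real_, in_range = TRUE
    ))
  }
  rec <- dplyr::left_join(
    report,
    dplyr::select(library, compound_id = "id", "mw"),
    by = "compound_id"
  )
  if (any(is.na(rec$mw))) {
    abort(sprintf("compound(s) missing from library: %s",
                  paste(unique(rec$compound_id[is.na(rec$mw)]), collapse = ", ")))
  }
  rec$rmax_theoretical <- theoretical_rmax(surface, rec$mw, n = config$stoich_n)
  if (any(rec$rmax_theoretical <= 0)) abort("non-positive theoretical Rmax")
  rec$pct_rmax <- 100 * rec$binding_RU / rec$rmax_theoretical

  rec$flag_insoluble <- rec$compound_id %in% insoluble
  rec$flag_clean_fail <- !clean_screen(rec$residual_RU, config)
  rec$flag_out_of_calibration <- !rec$in_range
  rec$flag_superstoichiometric <-
    rec$binding_RU > config$superstoich_factor * rec$rmax_theoretical
  rec$flag_abnormal_shape <-
    (rec$binding_RU < -config$abnormal_negative_RU) |
    (rec$residual_RU > pmax(rec$binding_RU, config$abnormal_negative_RU))

  not_run <- is.na(rec$binding_RU)
  for (fl in c("flag_clean_fail", "flag_out_of_calibration",
               "flag_superstoichiometric", "flag_abnormal_shape")) {
    rec[[fl]][not_run] <- FALSE
  }
  flags <- rec[, grep("^flag_", names(rec))]
  rec$hit <- !Reduce(`|`, flags) & rec$pct_rmax >= 100 * config$hit_fraction
  rec$hit[not_run] <- FALSE
  dplyr::select(
    rec, "compound_id", "binding_RU", "residual_RU", "rmax_theoretical",
    "pct_rmax", dplyr::starts_with("flag_"), "hit"
  )
}

#' Campaign bookkeeping from records
#'
#' Totals and per-sublibrary breakdowns of the screening cascade:
#' insoluble, clean-screen failures, compounds carried forward, hits, and
#' the hit rate as a percentage of the full library (one decimal, rounded
#' half up).
#'
#' @param records Screen-record tibble from [screen_compounds()].
#' @param library Compound tibble with `id` and `sublibrary`.
#' @return A tibble with one row per sublibrary plus a `total` row:
#'   `sublibrary`, `n`, `insoluble`, `clean_fail`, `carried_forward`,
#'   `hits`, `hit_rate_pct` (rate only on the total row).
#' @export
campaign_summary <- function(records, library) {
  check_columns(records, c("compound_id", "flag_insoluble", "flag_clean_fail", "hit"),
                "records")
  check_columns(library, c("id", "sublibrary"), "library")
  joined <- dplyr::left_join(
    records,
    dplyr::select(library, compound_id = "id", "sublibrary"),
    by = "compound_id"
  )
  per <- joined |>
    dplyr::group_by(sublibrary = as.character(.data$sublibrary)) |>
    dplyr::summarise(
      n = dplyr::n(),
      insoluble = sum(.data$flag_insoluble),
      clean_fail = sum(.data$flag_clean_fail & !.data$flag_insoluble),
      carried_forward = sum(!.data$flag_insoluble & !.data$flag_clean_fail),
      hits = sum(.data$hit),
      .groups = "drop"
    )
  total <- per |>
    dplyr::summarise(
      sublibrary = "total",
      dplyr::across(c("n", "insoluble", "clean_fail", "carried_forward", "hits"), sum)
    )
  total$hit_rate_pct <- round_half_up(100 * total$hits / total$n, 1)
  per$hit_rate_pct <- NA_real_
  dplyr::bind_rows(per, total)
}

#' Campaign bookkeeping from stage counts
#'
#' The same arithmetic as [campaign_summary()] when only stage counts are
#' available (e.g. reproducing a published cascade): per-sublibrary
#' clean-screen failures, the library size, and the number of hits.
#'
#' @param library_size Total number of screened compounds.
#' @param clean_failures Named integer vector of clean-screen failures per
#'   sublibrary.
#' @param hits Number of hits called.
#' @param insoluble Number of compounds removed as insoluble before the
#'   clean screen.
#' @return A one-row tibble: `n`, `insoluble`, `clean_fail_total`,
#'   `carried_forward`, `hits`, `hit_rate_pct` (one decimal, half-up).
#' @examples
#' screening_counts(2000, c(`2D-FL` = 15, `3D-FL` = 33, NPB = 20,
#'                          SPI = 73, PPI = 240), hits = 95)
#' @export
screening_counts <- function(library_size, clean_failures, hits, insoluble = 0) {
  check_number(library_size, "library_size", positive = TRUE)
  clean_fail_total <- sum(clean_failures)
  tibble(
    n = library_size,
    insoluble = insoluble,
    clean_fail_total = clean_fail_total,
    carried_forward = library_size - insoluble - clean_fail_total,
    hits = hits,
    hit_rate_pct = round_half_up(100 * hits / library_size, 1)
  )
}

#' Triage performance against planted truth
#'
#' Confusion-matrix summaries of a synthetic campaign: sensitivity and
#' specificity of the clean screen for planted sticky compounds, and of hit
#' calling for planted clean binders.
#'
#' @param records Screen-record tibble from [screen_compounds()].
#' @param truth Planted-truth tibble from [simulate_campaign()]
#'   (columns `compound_id`, `class`).
#' @return A tibble with columns `task`, `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
triage_performance <- function(records, truth) {
  joined <- dplyr::inner_join(records, truth, by = "compound_id")
  confusion <- function(pred, is_pos, task) {
    tp <- sum(pred & is_pos); fn <- sum(!pred & is_pos)
    fp <- sum(pred & !is_pos); tn <- sum(!pred & !is_pos)
    tibble(task = task,
           sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
           tp = tp, fp = fp, tn = tn, fn = fn)
  }
  dplyr::bind_rows(
    confusion(joined$flag_clean_fail, joined$class == "sticky", "clean_screen"),
    confusion(joined$hit, joined$class == "clean_binder", "hit_calling")
  )
}
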