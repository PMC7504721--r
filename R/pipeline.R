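# End-to-end campaign orchestration: simulate -> process -> triage ->
# affinity -> activity, with a machine-readable summary.

#' Generate a synthetic screening library
#'
#' Compound table with the composition of a typical fragment campaign:
#' five subsets (two- and three-dimensional fragment libraries,
#' natural-product-based, serine-protease-inhibitor-biased and
#' protein-protein-interaction collections) in 250:250:250:250:1000
#' proportion, with molecular weights, heavy-atom counts, H-bond donors and
#' clogP drawn from ranges typical of each subset.
#'
#' @param n Library size (default 2000).
#' @param seed Integer seed.
#' @return A validated compound tibble (see [load_library()]).
#' @export
synthetic_library <- function(n = 2000, seed = 1L) {
  with_seed(seed, {
    base <- c(`2D-FL` = 250, `3D-FL` = 250, NPB = 250, SPI = 250, PPI = 1000)
    counts <- round(base / sum(base) * n)
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    sub <- rep(names(base), times = counts)
    is_frag <- sub != "PPI"
    mw <- ifelse(is_frag, stats::runif(n, 120, 300), stats::runif(n, 250, 500))
    tbl <- tibble(
      id = sprintf("CMP-%04d", seq_len(n)),
      sublibrary = sub,
      mw = round(mw, 1),
      heavy_atoms = pmax(5, round(mw / 13.5)),
      hbd = sample(0:4, n, replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.15, 0.05)),
      clogp = round(stats::rnorm(n, 1.5, 1), 2)
    )
    load_library(tbl)
  })
}

#' Pipeline configuration
#'
#' Single validated configuration object for [run_pipeline()]. Unknown
#' names are rejected so typos cannot silently fall back to defaults.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_compounds Library size for the synthetic campaign.
#' @param class_fractions,frac_insoluble,kd_range,sticky_residual_ru,super_n
#'   Passed to [simulate_campaign()].
#' @param noise_sd Sensorgram noise (RU).
#' @param surface Active [surface_def()].
#' @param triage A [triage_config()].
#' @param n_affinity Number of top hits taken into dose-response affinity
#'   confirmation.
#' @param affinity_replicates Replicate dilution series per confirmed hit.
#' @param elisa_ic50 Named vector of true IC50s (M) for the simulated ELISA
#'   stage (names are compound labels).
#' @param elisa_noise_cv ELISA multiplicative noise level.
#' @param output_dir Optional directory; when set, stage tables are written
#'   as CSV and the summary as JSON + text.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_compounds = 200,
                            class_fractions = c(clean_binder = 0.10,
                                                non_binder = 0.78,
                                                sticky = 0.08,
                                                superstoichiometric = 0.04),
                            frac_insoluble = 0.02,
                            kd_range = c(5e-5, 2.5e-4),
                            sticky_residual_ru = 8,
                            super_n = 2.5,
                            noise_sd = 0.3,
                            surface = surface_def("C1r", 92000, 9200),
                            triage = triage_config(),
                            n_affinity = 3,
                            affinity_replicates = 3,
                            elisa_ic50 = c(`CMP-A` = 660e-6, `CMP-B` = 520e-6),
                            elisa_noise_cv = 0.05,
                            output_dir = NULL) {
  cfg <- list(
    seed = seed, n_compounds = n_compounds, class_fractions = class_fractions,
    frac_insoluble = frac_insoluble, kd_range = kd_range,
    sticky_residual_ru = sticky_residual_ru, super_n = super_n,
    noise_sd = noise_sd, surface = surface, triage = triage,
    n_affinity = n_affinity, affinity_replicates = affinity_replicates,
    elisa_ic50 = elisa_ic50, elisa_noise_cv = elisa_noise_cv,
    output_dir = output_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full screening pipeline on a synthetic campaign
#'
#' Simulates a library and single-concentration campaign, processes raw
#' cycles into corrected report points, applies the triage cascade, fits
#' steady-state affinities for the top hits from simulated dose series, and
#' runs the simulated ELISA inhibition stage. Identical configuration and
#' seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `campaign_report`: `library`, `records`,
#'   `summary`, `performance`, `affinity`, `activity`, `truth`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  library_tbl <- synthetic_library(config$n_compounds, seed = derive_seed(seed, 1))
  campaign <- simulate_campaign(
    library_tbl,
    class_fractions = config$class_fractions,
    kd_range = config$kd_range,
    surface = config$surface,
    artifacts = artifact_model(noise_sd = config$noise_sd),
    sticky_residual_ru = config$sticky_residual_ru,
    super_n = config$super_n,
    frac_insoluble = config$frac_insoluble,
    seed = derive_seed(seed, 2)
  )
  report <- process_campaign(campaign)
  records <- screen_compounds(
    report, library_tbl, config$surface, config$triage,
    insoluble = campaign$truth$compound_id[campaign$truth$insoluble]
  )
  summary_tbl <- campaign_summary(records, library_tbl)
  performance <- triage_performance(records, campaign$truth)

  # affinity confirmation for the strongest hits
  hits <- records |>
    dplyr::filter(.data$hit) |>
    dplyr::arrange(dplyr::desc(.data$pct_rmax)) |>
    head(config$n_affinity)
  affinity <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    id <- hits$compound_id[i]
    tr <- campaign$truth[campaign$truth$compound_id == id, ]
    prof <- compound_profile(
      id, "clean_binder", mw = tr$mw,
      kinetics = kinetic_model(ka = 0.5 / tr$kd_eq, kd_rate = 0.5)
    )
    ds <- simulate_dose_series(
      prof, surface = config$surface,
      artifacts = artifact_model(noise_sd = 0.5),
      replicates = config$affinity_replicates,
      seed = derive_seed(seed, 100 + i)
    )
    pts <- process_campaign(ds)
    rmax <- theoretical_rmax(config$surface, tr$mw)
    res <- fit_affinity(pts, rmax)
    dplyr::mutate(dplyr::select(res, -"kd_per_replicate"),
                  compound_id = id, kd_true_M = tr$kd_eq, .before = 1)
  })
  if (nrow(affinity) == 0) {
    affinity <- tibble(compound_id = character(), kd_true_M = numeric(),
                       kd_mean_M = numeric(), kd_sd_M = numeric(),
                       n_replicates = integer(), rss_total = numeric(),
                       provisional = logical())
  }

  # ELISA inhibition stage
  activity <- purrr::imap_dfr(config$elisa_ic50, function(ic50, id) {
    plate <- simulate_elisa_plate(
      ic50 = ic50, concentrations = dose_series_default(),
      noise_cv = config$elisa_noise_cv, compound_id = id,
      seed = derive_seed(seed, 200 + match(id, names(config$elisa_ic50)))
    )
    pct <- percent_activity(plate)
    samples <- pct[pct$role == "sample", ]
    fit <- fit_ic50(dplyr::select(samples, "conc_M", "pct_activity"))
    top <- samples$pct_activity[samples$conc_M == max(samples$conc_M)]
    ctrl <- pct$pct_activity[pct$role == "positive_control"]
    sdt <- single_dose_test(top, ctrl)
    dplyr::mutate(glance(fit), compound_id = id, ic50_true_M = ic50,
                  p_single_dose = sdt$p_value, .before = 1)
  })
  if (nrow(activity) == 0) {
    activity <- tibble(compound_id = character(), ic50_true_M = numeric(),
                       p_single_dose = numeric(), ic50 = numeric(),
                       hill = numeric(), ci_lo = numeric(), ci_hi = numeric())
  }

  bundle <- structure(
    list(
      library = library_tbl, records = records, summary = summary_tbl,
      performance = performance, affinity = affinity, activity = activity,
      truth = campaign$truth, config = config
    ),
    class = "campaign_report"
  )
  if (!is.null(config$output_dir)) write_report(bundle, config$output_dir)
  bundle
}

write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$records, file.path(dir, "screen_records.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary, file.path(dir, "campaign_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$affinity, file.path(dir, "affinity_results.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$activity, file.path(dir, "activity_results.csv"),
                   row.names = FALSE)
  rendered <- render_summary(bundle)
  writeLines(rendered$text, file.path(dir, "summary.txt"))
  jsonlite::write_json(rendered$json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Render a campaign report as text and JSON
#'
#' Produces a human-readable text summary and a machine-readable JSON
#' object that mirrors every number in the text.
#'
#' @param bundle A `campaign_report` from [run_pipeline()].
#' @return A list with elements `text` (character vector of lines) and
#'   `json` (a nested list serializable with jsonlite).
#' @export
render_summary <- function(bundle) {
  tot <- bundle$summary[bundle$summary$sublibrary == "total", ]
  if (nrow(tot) == 0) {
    tot <- tibble(n = 0, insoluble = 0, clean_fail = 0,
                  carried_forward = 0, hits = 0, hit_rate_pct = NA_real_)
  }
  json <- list(
    screening = list(
      n_screened = tot$n, insoluble = tot$insoluble,
      clean_fail = tot$clean_fail, carried_forward = tot$carried_forward,
      hits = tot$hits, hit_rate_pct = tot$hit_rate_pct
    ),
    affinity = purrr::pmap(
      bundle$affinity[, c("compound_id", "kd_mean_M", "kd_sd_M", "n_replicates")],
      function(compound_id, kd_mean_M, kd_sd_M, n_replicates) {
        list(compound_id = compound_id, kd_mean_M = kd_mean_M,
             kd_sd_M = kd_sd_M, n_replicates = n_replicates)
      }
    ),
    activity = purrr::pmap(
      bundle$activity[, c("compound_id", "ic50", "ci_lo", "ci_hi")],
      function(compound_id, ic50, ci_lo, ci_hi) {
        list(compound_id = compound_id, ic50_M = ic50,
             ci_lo_M = ci_lo, ci_hi_M = ci_hi)
      }
    )
  )
  text <- c(
    sprintf("Screened compounds:      %d", tot$n),
    sprintf("Insoluble:               %d", tot$insoluble),
    sprintf("Clean-screen failures:   %d", tot$clean_fail),
    sprintf("Carried forward:         %d", tot$carried_forward),
    sprintf("Hits:                    %d", tot$hits),
    sprintf("Hit rate:                %.1f%%", tot$hit_rate_pct),
    "",
    "Affinity (steady-state KD):",
    purrr::pmap_chr(
      bundle$affinity[, c("compound_id", "kd_mean_M", "kd_sd_M", "n_replicates")],
      function(compound_id, kd_mean_M, kd_sd_M, n_replicates) {
        sprintf("  %s: %.0f +/- %.0f uM (n = %d)", compound_id,
                kd_mean_M * 1e6, kd_sd_M * 1e6, n_replicates)
      }
    ),
    "",
    "Activity (ELISA IC50):",
    purrr::pmap_chr(
      bundle$activity[, c("compound_id", "ic50", "ci_lo", "ci_hi")],
      function(compound_id, ic50, ci_lo, ci_hi) {
        sprintf("  %s: %.0f uM (95%% CI %.0f-%.0f uM)", compound_id,
                ic50 * 1e6, ci_lo * 1e6, ci_hi * 1e6)
      }
    )
  )
  list(text = text, json = json)
}

#' @export
print.campaign_report <- function(x, ...) {
  writeLines(render_summary(x)$text)
  invisible(x)
}
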