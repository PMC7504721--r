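# Raw cycles -> corrected report points: double referencing, excluded-volume
# DMSO solvent correction, and report-point extraction.

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && isTRUE(all.equal(a$time_s, b$time_s, tolerance = 1e-9))
}

interp_to <- function(s, grid) {
  y <- stats::approx(s$time_s, s$response_RU, xout = grid, rule = 2)$y
  sensorgram(grid, y, sg_marker(s, "t_start"), sg_marker(s, "t_stop"),
             meta = attr(s, "meta"))
}

#' Double referencing
#'
#' Subtracts the reference flow cell and a blank (buffer) cycle from an
#' analyte cycle: corrected = (active - reference) - (blank_active -
#' blank_reference). Common-mode artifacts (drift, bulk shifts seen equally
#' by both cells, systematic injection artifacts captured by the blank)
#' cancel; binding and the active-cell excluded-volume offset remain.
#'
#' @param active,reference Analyte-cycle sensorgrams, or `active` may be an
#'   `spr_cycle` (then its own reference trace is used and `reference` is
#'   treated as the blank cycle).
#' @param blank_active,blank_reference Blank-cycle sensorgrams, or an
#'   `spr_cycle` passed as `blank_active`. Omitted blanks are treated as
#'   zero.
#' @param interpolate Linearly interpolate traces onto the active grid when
#'   time grids differ (otherwise mismatched grids are an error).
#' @return A corrected [sensorgram()] with the active cycle's metadata.
#' @export
double_reference <- function(active, reference = NULL,
                             blank_active = NULL, blank_reference = NULL,
                             interpolate = FALSE) {
  if (inherits(active, "spr_cycle")) {
    if (inherits(reference, "spr_cycle") && is.null(blank_active)) {
      blank_active <- reference$active
      blank_reference <- reference$reference
    }
    reference <- active$reference
    active <- active$active
  }
  if (inherits(blank_active, "spr_cycle")) {
    blank_reference <- blank_active$reference
    blank_active <- blank_active$active
  }
  grid <- active$time_s
  align <- function(s) {
    if (is.null(s)) return(NULL)
    if (same_grid(active, s)) return(s)
    if (!interpolate) abort("time grids differ; set `interpolate = TRUE`")
    interp_to(s, grid)
  }
  reference <- align(reference)
  blank_active <- align(blank_active)
  blank_reference <- align(blank_reference)

  resp <- active$response_RU
  if (!is.null(reference)) resp <- resp - reference$response_RU
  if (!is.null(blank_active)) {
    blank <- blank_active$response_RU
    if (!is.null(blank_reference)) blank <- blank - blank_reference$response_RU
    resp <- resp - blank
  }
  sensorgram(grid, resp, sg_marker(active, "t_start"), sg_marker(active, "t_stop"),
             meta = attr(active, "meta"))
}

#' Extract a report point
#'
#' Mean response over a short window. Two kinds are supported:
#' `binding_late_association` averages the end of the association phase
#' (steady-state read-out), `residual_post_injection` averages around a
#' configurable offset after injection stop (non-specific clean-screen
#' read-out, default 10 s post injection).
#'
#' @param s A [sensorgram()].
#' @param kind Report-point kind.
#' @param width Window width in seconds (default 2 s for the binding point,
#'   1 s for the residual point). Averaging over a window rather than a
#'   single sample resists point noise.
#' @param residual_offset Seconds after injection stop for the residual
#'   point (default 10).
#' @return A one-row tibble: `value`, `center_s`, `width_s`, `kind`.
#' @export
report_point <- function(s, kind = c("binding_late_association",
                                     "residual_post_injection"),
                         width = NULL, residual_offset = 10) {
  kind <- match.arg(kind)
  t_stop <- sg_marker(s, "t_stop")
  if (is.null(width)) width <- if (kind == "binding_late_association") 2 else 1
  check_number(width, "width", positive = TRUE)
  center <- if (kind == "binding_late_association") {
    t_stop - width / 2
  } else {
    t_stop + residual_offset
  }
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < min(s$time_s) || hi > max(s$time_s)) {
    abort("report-point window falls outside the trace")
  }
  sel <- s$time_s >= lo - 1e-9 & s$time_s <= hi + 1e-9
  tibble(value = mean(s$response_RU[sel]), center_s = center,
         width_s = width, kind = kind)
}

# bulk response of a trace: mean during the late injection window minus the
# pre-injection baseline
bulk_response <- function(s, width = 2) {
  t_start <- sg_marker(s, "t_start")
  base_sel <- s$time_s < t_start
  base <- if (any(base_sel)) mean(s$response_RU[base_sel]) else 0
  report_point(s, "binding_late_association", width = width)$value - base
}

#' Fit a DMSO solvent-correction calibration
#'
#' From solvent-only calibration cycles spanning the DMSO range, fits a
#' polynomial (default degree 2) of the active-minus-reference excluded-
#' volume offset versus the reference-cell bulk response. The observed bulk
#' range is recorded; analyte cycles whose bulk falls outside it must be
#' flagged rather than extrapolated.
#'
#' @param calibration_cycles List of `spr_cycle` objects from solvent-only
#'   injections.
#' @param degree Polynomial degree (default 2).
#' @return An object of class `solvent_calibration`: coefficients, validity
#'   range, number of points, and the per-cycle calibration table.
#' @export
fit_solvent_calibration <- function(calibration_cycles, degree = 2) {
  if (length(calibration_cycles) < 3) {
    abort("need at least 3 solvent-only calibration cycles")
  }
  pts <- purrr::map_dfr(calibration_cycles, function(cyc) {
    rb <- bulk_response(cyc$reference)
    off <- bulk_response(cyc$active) - rb
    tibble(ref_bulk_RU = rb, offset_RU = off)
  })
  if (stats::sd(pts$ref_bulk_RU) < 1e-9) {
    abort("degenerate calibration: all reference bulk responses equal")
  }
  fit <- lm(offset_RU ~ poly(ref_bulk_RU, degree, raw = TRUE), data = pts)
  structure(
    list(
      coefficients = unname(coef(fit)),
      degree = degree,
      range = range(pts$ref_bulk_RU),
      n_points = nrow(pts),
      points = pts
    ),
    class = "solvent_calibration"
  )
}

predict_offset <- function(cal, ref_bulk) {
  co <- cal$coefficients
  co[is.na(co)] <- 0
  vapply(ref_bulk, function(b) sum(co * b^(seq_along(co) - 1)), numeric(1))
}

#' Apply solvent correction to report points
#'
#' Subtracts the calibrated excluded-volume offset at the observed
#' reference bulk response. Values whose bulk response lies outside the
#' calibration's validity range are flagged `in_range = FALSE` (they are
#' corrected anyway, but downstream triage must exclude them); out-of-range
#' is a flag, never an error.
#'
#' @param value Report-point value(s), RU.
#' @param ref_bulk Reference-cell bulk response(s), RU.
#' @param cal A [fit_solvent_calibration()] result.
#' @return A tibble with columns `corrected` and `in_range`.
#' @export
apply_solvent_correction <- function(value, ref_bulk, cal) {
  stopifnot(inherits(cal, "solvent_calibration"))
  tibble(
    corrected = value - predict_offset(cal, ref_bulk),
    in_range = ref_bulk >= cal$range[1] - 1e-9 & ref_bulk <= cal$range[2] + 1e-9
  )
}

# reconstruct spr_cycle objects from a campaign's long table ----------------
campaign_cycle <- function(campaign, cycle_no) {
  sub <- campaign$sensorgrams[campaign$sensorgrams$cycle == cycle_no, ]
  sch <- campaign$schedule
  mk <- function(role) {
    part <- sub[sub$role == role, ]
    sensorgram(part$time_s, part$response_RU, sch$t_start, sch$t_stop,
               meta = list(cycle = cycle_no, role = role))
  }
  structure(list(active = mk("active"), reference = mk("reference")),
            class = "spr_cycle")
}

#' Process a campaign into corrected report points
#'
#' Runs the full correction chain on every analyte cycle of a simulated (or
#' loaded) campaign: double referencing against the nearest preceding blank
#' cycle, piecewise DMSO solvent correction from the calibration blocks
#' bracketing each cycle span, and extraction of the late-association
#' binding and the 10 s post-injection residual report points.
#'
#' @param campaign An `spr_campaign` (from [simulate_campaign()] or
#'   [simulate_dose_series()]).
#' @param cal_degree Polynomial degree for the solvent calibration.
#' @param solvent_correct Apply solvent correction (TRUE when the campaign
#'   contains calibration cycles).
#' @return A tibble with one row per analyte cycle: `cycle`, `compound_id`,
#'   `conc_M`, `replicate` (if present), `binding_RU`, `residual_RU`,
#'   `ref_bulk_RU`, `in_range`.
#' @export
process_campaign <- function(campaign, cal_degree = 2, solvent_correct = NULL) {
  cycles <- campaign$cycles
  if (is.null(solvent_correct)) solvent_correct <- any(cycles$is_calibration)

  # calibration blocks: consecutive runs of calibration cycles
  cal_fit <- NULL
  cal_spans <- NULL
  if (solvent_correct) {
    calib_idx <- cycles$cycle[cycles$is_calibration]
    blocks <- split(calib_idx, cumsum(c(1, diff(calib_idx) > 1)))
    fits <- purrr::map(blocks, function(idx) {
      fit_solvent_calibration(purrr::map(idx, ~ campaign_cycle(campaign, .x)),
                              degree = cal_degree)
    })
    block_pos <- vapply(blocks, max, numeric(1))
    # each analyte cycle uses the nearest calibration block (piecewise)
    cal_fit <- fits
    cal_spans <- block_pos
  }

  blank_idx <- cycles$cycle[cycles$is_blank]
  sample_rows <- cycles[!cycles$is_blank & !cycles$is_calibration, ]

  out <- purrr::map_dfr(seq_len(nrow(sample_rows)), function(i) {
    row <- sample_rows[i, ]
    cyc <- campaign_cycle(campaign, row$cycle)
    blank <- NULL
    if (length(blank_idx) > 0) {
      nb <- blank_idx[which.min(abs(blank_idx - row$cycle))]
      blank <- campaign_cycle(campaign, nb)
    }
    corrected <- double_reference(cyc, blank)
    binding <- report_point(corrected, "binding_late_association")$value
    residual <- report_point(corrected, "residual_post_injection")$value
    rb <- bulk_response(cyc$reference)
    if (!is.null(cal_fit)) {
      fit <- cal_fit[[which.min(abs(cal_spans - row$cycle))]]
      sc <- apply_solvent_correction(binding, rb, fit)
      binding <- sc$corrected
      in_range <- sc$in_range
    } else {
      in_range <- TRUE
    }
    res <- tibble(
      cycle = row$cycle, compound_id = row$compound_id, conc_M = row$conc_M,
      binding_RU = binding, residual_RU = residual,
      ref_bulk_RU = rb, in_range = in_range
    )
    if ("replicate" %in% names(row)) res$replicate <- row$replicate
    res
  })
  out
}
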