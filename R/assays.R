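# ELISA-based complement activity analysis: control normalization,
# single-dose significance testing, constrained IC50 fitting, pathway
# selectivity, and progress-curve rate extraction.

#' Percent activity from plate controls
#'
#' Normalizes well absorbances against the controls of the same plate
#' column: the positive-control mean (full activity, no inhibitor) is
#' defined as 100% and the negative-control mean (no serum) as 0%. Values
#' are not clipped and may fall outside `[0, 100]`.
#'
#' @param plate Data frame with columns `col`, `role` (`sample`,
#'   `positive_control`, `negative_control`) and `absorbance`.
#' @param tol Minimal positive-negative control separation (AU); smaller
#'   separations are a degenerate-controls error.
#' @return The plate tibble with an added `pct_activity` column.
#' @export
percent_activity <- function(plate, tol = 1e-6) {
  check_columns(plate, c("col", "role", "absorbance"), "plate")
  plate <- as_tibble(plate)
  ctrl <- plate |>
    dplyr::group_by(.data$col) |>
    dplyr::summarise(
      pos = mean(.data$absorbance[.data$role == "positive_control"]),
      neg = mean(.data$absorbance[.data$role == "negative_control"]),
      .groups = "drop"
    )
  if (any(!is.finite(ctrl$pos)) || any(!is.finite(ctrl$neg))) {
    abort("every column needs at least one positive and one negative control")
  }
  if (any(abs(ctrl$pos - ctrl$neg) < tol)) {
    abort("degenerate controls: positive and negative means coincide")
  }
  out <- dplyr::left_join(plate, ctrl, by = "col")
  out$pct_activity <- 100 * (out$absorbance - out$neg) / (out$pos - out$neg)
  dplyr::select(out, -"pos", -"neg")
}

#' Single-dose significance test
#'
#' Two-sided unpaired t-test of sample percent activity against the
#' no-inhibitor control, equal-variance (Student's) by default.
#'
#' @param sample,control Numeric vectors of percent activity (>= 2 values
#'   each).
#' @param var_equal Use the classical equal-variance test (default); set
#'   `FALSE` for Welch.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `t`, `df`, `p_value`, `significant`,
#'   `mean_sample`, `mean_control`.
#' @export
single_dose_test <- function(sample, control, var_equal = TRUE, alpha = 0.05) {
  if (length(sample) < 2 || length(control) < 2) {
    abort("need at least 2 values per group")
  }
  if (sd(sample) == 0 && sd(control) == 0) {
    # degenerate: no within-group variance
    equal <- isTRUE(all.equal(mean(sample), mean(control)))
    return(tibble(
      t = if (equal) 0 else Inf * sign(mean(sample) - mean(control)),
      df = length(sample) + length(control) - 2,
      p_value = if (equal) 1 else 0,
      significant = !equal,
      mean_sample = mean(sample), mean_control = mean(control)
    ))
  }
  tt <- t.test(sample, control, var.equal = var_equal)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < alpha,
    mean_sample = mean(sample), mean_control = mean(control)
  )
}

#' Constrained dose-response IC50 fit
#'
#' Fits percent activity versus inhibitor concentration to the constrained
#' inhibition model pct(C) = 100 / (1 + (C / IC50)^h), i.e. the top and
#' bottom of the curve fixed at 100 and 0. The `fixed_slope` model pins the
#' Hill slope at 1 (the "log(inhibitor) vs response" convention); the
#' `variable_slope` model frees it. IC50 is log-parameterized internally;
#' the 95% confidence interval comes from the asymptotic covariance of the
#' fit on the log scale.
#'
#' @param doses Data frame with columns `conc_M` and `pct_activity`
#'   (>= 4 distinct concentrations; replicate rows welcome).
#' @param model `"fixed_slope"` (h = 1) or `"variable_slope"`.
#' @param min_span Minimal fitted inhibition span (percentage points)
#'   across the tested range below which the response is declared not
#'   dose-dependent.
#' @param aggregate Average replicate wells per concentration before
#'   fitting (default `TRUE`). Replicate wells of one plate column are
#'   normalized against the same controls and are therefore not
#'   independent; the per-concentration mean is the experimental unit, and
#'   fitting the raw wells would understate the IC50 uncertainty.
#' @return An object of class `dose_response_fit`: `ic50` (M), `hill`,
#'   `ci95` (M), `rss`, `n_points`, `model`, `extrapolated` (IC50 outside
#'   the tested span), and the data with fitted values.
#' @examples
#' conc <- dose_series_default()
#' pct <- 100 / (1 + conc / 520e-6)
#' fit_ic50(data.frame(conc_M = conc, pct_activity = pct))
#' @export
fit_ic50 <- function(doses, model = c("fixed_slope", "variable_slope"),
                     min_span = 20, aggregate = TRUE) {
  model <- match.arg(model)
  check_columns(doses, c("conc_M", "pct_activity"), "doses")
  doses <- doses[complete.cases(doses[, c("conc_M", "pct_activity")]), ]
  if (length(unique(doses$conc_M)) < 4) {
    abort("need at least 4 distinct concentrations")
  }
  if (any(doses$conc_M <= 0)) abort("concentrations must be positive")
  if (aggregate) {
    doses <- doses |>
      dplyr::group_by(.data$conc_M) |>
      dplyr::summarise(pct_activity = mean(.data$pct_activity), .groups = "drop")
  }

  lc <- log(doses$conc_M)
  y <- doses$pct_activity
  # start IC50 at the concentration whose response is closest to 50%
  start_lp <- lc[which.min(abs(y - 50))]

  fit <- tryCatch(
    if (model == "fixed_slope") {
      minpack.lm::nlsLM(
        y ~ 100 / (1 + exp(lc - lp)),
        start = list(lp = start_lp),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        y ~ 100 / (1 + exp(h * (lc - lp))),
        start = list(lp = start_lp, h = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) abort(paste("no dose dependence:", conditionMessage(e)))
  )
  est <- coef(fit)
  lp <- est[["lp"]]
  h <- if (model == "fixed_slope") 1 else est[["h"]]
  pred <- function(l) 100 / (1 + exp(h * (l - lp)))
  span <- pred(min(lc)) - pred(max(lc))
  if (!is.finite(span) || span < min_span) {
    abort("no dose dependence: fitted inhibition span below threshold")
  }
  # large-sample normal interval on the log-IC50 scale
  se_lp <- sqrt(vcov(fit)["lp", "lp"])
  ci <- exp(lp + c(-1, 1) * stats::qnorm(0.975) * se_lp)
  ic50 <- exp(lp)
  out <- list(
    ic50 = ic50, hill = h, ci95 = ci,
    rss = sum(stats::resid(fit)^2), n_points = length(y), model = model,
    extrapolated = ic50 < min(doses$conc_M) || ic50 > max(doses$conc_M),
    data = tibble(conc_M = doses$conc_M, pct_activity = y,
                  fitted_pct = pred(lc))
  )
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "Constrained dose-response fit (%s): IC50 = %.3g M (95%% CI %.3g-%.3g), h = %.2f, n = %d%s\n",
    x$model, x$ic50, x$ci95[1], x$ci95[2], x$hill, x$n_points,
    if (x$extrapolated) " [extrapolated]" else ""
  ))
  invisible(x)
}

#' @rdname fit_ic50
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    term = c("ic50", "hill"),
    estimate = c(x$ic50, x$hill),
    conf.low = c(x$ci95[1], NA),
    conf.high = c(x$ci95[2], NA)
  )
}

#' @rdname fit_ic50
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
         rss = x$rss, n_points = x$n_points, model = x$model,
         extrapolated = x$extrapolated)
}

#' Pathway selectivity profile
#'
#' Labels each compound by which complement pathways it inhibits at the
#' single tested dose: `"inactive"` when none, `"<pathway>-specific"` when
#' exactly one, and the `+`-joined pathway list otherwise.
#'
#' @param results Data frame with columns `pathway`, `p_value` and
#'   optionally `compound_id` (one row per compound-pathway test, >= 2
#'   pathways per compound).
#' @param alpha Significance level (default 0.05).
#' @return The input tibble with `inhibits` and a per-compound `profile`
#'   column.
#' @export
selectivity_table <- function(results, alpha = 0.05) {
  check_columns(results, c("pathway", "p_value"), "results")
  out <- as_tibble(results)
  if (!"compound_id" %in% names(out)) out$compound_id <- "compound"
  out$inhibits <- out$p_value < alpha
  out |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::mutate(profile = {
      hit_paths <- sort(unique(.data$pathway[.data$inhibits]))
      if (length(hit_paths) == 0) {
        "inactive"
      } else if (length(hit_paths) == 1) {
        paste0(hit_paths, "-specific")
      } else {
        paste(hit_paths, collapse = "+")
      }
    }) |>
    dplyr::ungroup()
}

#' Initial rate of a progress curve
#'
#' Least-squares slope of absorbance versus time over the initial window of
#' a reaction progress curve (e.g. proenzyme autoactivation tracked by
#' substrate turnover).
#'
#' @param curve Data frame with columns `time_s` and `absorbance`.
#' @param window Length (s) of the initial window, measured from the first
#'   time point (default: the whole curve). At least 5 points must fall in
#'   the window.
#' @return Initial rate in AU/s.
#' @export
initial_rate <- function(curve, window = Inf) {
  check_columns(curve, c("time_s", "absorbance"), "curve")
  sel <- curve$time_s <= min(curve$time_s) + window
  if (sum(sel) < 5) abort("need at least 5 points in the rate window")
  unname(coef(lm(absorbance ~ time_s, data = curve[sel, ]))[2])
}

#' @rdname initial_rate
#' @param treated,control Rates (AU/s) or progress-curve data frames.
#' @param threshold Treated/control rate ratio below which the reaction is
#'   called inhibited (default 0.5).
#' @return `compare_rates()`: a one-row tibble with `rate_treated`,
#'   `rate_control`, `ratio`, `inhibited`.
#' @export
compare_rates <- function(treated, control, threshold = 0.5) {
  if (is.data.frame(treated)) treated <- initial_rate(treated)
  if (is.data.frame(control)) control <- initial_rate(control)
  check_number(control, "control")
  if (control == 0) abort("control rate is zero; ratio undefined")
  ratio <- treated / control
  tibble(rate_treated = treated, rate_control = control,
         ratio = ratio, inhibited = ratio < threshold)
}
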