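# Constrained steady-state 1:1 affinity fitting and stoichiometry-normalized
# domain mapping.

#' Constrained steady-state affinity fit
#'
#' Fits plateau (steady-state) responses versus concentration to the 1:1
#' Langmuir binding isotherm Req(C) = C * Rmax / (C + KD), with Rmax fixed
#' to the theoretical value computed from the analyte molecular weight and
#' the surface ([theoretical_rmax()]). Fixing Rmax is what keeps KD
#' estimable when the top tested concentration is below KD, the usual
#' situation for fragments; KD is the only free parameter (an optional
#' constant offset can be profiled in). The search is log-parameterized over
#' KD in `[1e-9, 10]` M for numerical stability, and the fit is unweighted
#' least squares in linear response space.
#'
#' @param series Data frame with columns `conc_M` and `req_RU` (one
#'   replicate's dilution series; at least 4 distinct concentrations).
#' @param rmax_constraint Theoretical Rmax in RU (> 0), held fixed.
#' @param offset Fit a constant response offset as a nuisance parameter
#'   (default `FALSE`).
#' @param kd_bounds Search bounds for KD in M.
#' @return An object of class `steady_state_fit`: `kd` (M), `rss`,
#'   `rmax`, `offset`, `saturation` (max tested C divided by KD), `n_points`
#'   and the input data with fitted values.
#' @examples
#' conc <- dose_series_default()
#' req <- conc * 27.6 / (conc + 480e-6)
#' fit_steady_state(data.frame(conc_M = conc, req_RU = req), 27.6)
#' @export
fit_steady_state <- function(series, rmax_constraint, offset = FALSE,
                             kd_bounds = c(1e-9, 10)) {
  check_columns(series, c("conc_M", "req_RU"), "series")
  check_number(rmax_constraint, "rmax_constraint", positive = TRUE)
  series <- series[complete.cases(series[, c("conc_M", "req_RU")]), ]
  if (length(unique(series$conc_M)) < 4) {
    abort("need at least 4 distinct concentrations")
  }
  if (any(series$conc_M <= 0)) abort("concentrations must be positive")
  if (all(abs(series$req_RU) < 1e-12)) abort("all responses are zero; nothing to fit")

  C <- series$conc_M
  y <- series$req_RU
  model <- function(log10_kd) {
    kd <- 10^log10_kd
    mu <- C * rmax_constraint / (C + kd)
    b <- if (offset) mean(y - mu) else 0
    list(mu = mu + b, b = b)
  }
  sse <- function(log10_kd) {
    m <- model(log10_kd)
    sum((y - m$mu)^2)
  }
  opt <- optimize(sse, interval = log10(kd_bounds), tol = 1e-12)
  log10_kd <- opt$minimum
  span <- log10(kd_bounds)
  if (min(log10_kd - span[1], span[2] - log10_kd) < 1e-6) {
    warn("fitted KD at the search bound; estimate is not identified")
  }
  kd <- 10^log10_kd
  m <- model(log10_kd)
  out <- list(
    kd = kd,
    rss = opt$objective,
    rmax = rmax_constraint,
    offset = m$b,
    saturation = max(C) / kd,
    n_points = length(C),
    data = tibble(conc_M = C, req_RU = y, fitted_RU = m$mu)
  )
  class(out) <- "steady_state_fit"
  out
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf(
    "Steady-state 1:1 fit: KD = %.3g M (Rmax fixed at %.3g RU)\n  RSS = %.3g, max(C)/KD = %.2f, n = %d\n",
    x$kd, x$rmax, x$rss, x$saturation, x$n_points
  ))
  invisible(x)
}

#' @rdname fit_steady_state
#' @param x A `steady_state_fit`.
#' @param ... Unused.
#' @export
tidy.steady_state_fit <- function(x, ...) {
  tibble(term = "kd", estimate = x$kd, constraint = "free")
}

#' @rdname fit_steady_state
#' @export
glance.steady_state_fit <- function(x, ...) {
  tibble(kd = x$kd, rmax = x$rmax, rss = x$rss,
         saturation = x$saturation, n_points = x$n_points)
}

#' Aggregate replicate affinity fits
#'
#' The reported affinity is the arithmetic mean and sample standard
#' deviation of the per-replicate KD estimates (on the KD scale, not log
#' KD). Fewer than three replicates yields a provisional result.
#'
#' @param fits A list of [fit_steady_state()] objects, a numeric vector of
#'   KD values (M), or a data frame with a `kd` column.
#' @return A one-row tibble: `kd_mean_M`, `kd_sd_M`, `n_replicates`,
#'   `rss_total`, `provisional`, plus a list-column `kd_per_replicate`.
#' @examples
#' aggregate_replicates(c(400e-6, 500e-6, 600e-6))
#' @export
aggregate_replicates <- function(fits) {
  if (is.numeric(fits)) {
    kds <- fits
    rss <- NA_real_
  } else if (is.data.frame(fits)) {
    check_columns(fits, "kd", "fits")
    kds <- fits$kd
    rss <- if ("rss" %in% names(fits)) sum(fits$rss) else NA_real_
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "steady_state_fit")))
    kds <- vapply(fits, `[[`, numeric(1), "kd")
    rss <- sum(vapply(fits, `[[`, numeric(1), "rss"))
  }
  if (length(kds) == 0 || any(kds <= 0)) abort("KD values must be positive")
  tibble(
    kd_mean_M = mean(kds),
    kd_sd_M = if (length(kds) > 1) sd(kds) else NA_real_,
    n_replicates = length(kds),
    rss_total = rss,
    provisional = length(kds) < 3,
    kd_per_replicate = list(kds)
  )
}

#' Fit affinities from processed dose-series report points
#'
#' Convenience wrapper: splits a [process_campaign()] table by replicate,
#' fits each replicate's series with [fit_steady_state()], and aggregates
#' with [aggregate_replicates()].
#'
#' @param report Tibble with `conc_M`, `binding_RU` and `replicate`.
#' @param rmax_constraint Theoretical Rmax in RU.
#' @param ... Passed to [fit_steady_state()].
#' @return The [aggregate_replicates()] tibble.
#' @export
fit_affinity <- function(report, rmax_constraint, ...) {
  check_columns(report, c("conc_M", "binding_RU", "replicate"), "report")
  fits <- lapply(split(report, report$replicate), function(d) {
    fit_steady_state(tibble(conc_M = d$conc_M, req_RU = d$binding_RU),
                     rmax_constraint, ...)
  })
  aggregate_replicates(fits)
}

#' Stoichiometry-normalized domain mapping
#'
#' Converts raw binding responses of one analyte across several immobilized
#' surfaces (full-length protein and domain truncations) into fractional
#' occupancies comparable across surfaces: each response is corrected for
#' the analyte molecular weight and for the immobilization level and
#' molecular weight of the surface ligand, occupancy = raw * MW_ligand /
#' (immobilization * MW_analyte * n). An occupancy of 1 is full
#' stoichiometric saturation of that surface.
#'
#' @param responses Data frame with columns `surface` and `raw_RU`.
#' @param surfaces Data frame with columns `name`, `ligand_mw`,
#'   `immobilization` (or a list of [surface_def()]).
#' @param mw_analyte Analyte molecular weight in Da.
#' @param n Binding stoichiometry.
#' @return The responses tibble with an added `occupancy` column.
#' @export
domain_map <- function(responses, surfaces, mw_analyte, n = 1) {
  check_columns(responses, c("surface", "raw_RU"), "responses")
  check_number(mw_analyte, "mw_analyte", positive = TRUE)
  if (!is.data.frame(surfaces)) {
    surfaces <- purrr::map_dfr(surfaces, ~ tibble(
      name = .x$name, ligand_mw = .x$ligand_mw, immobilization = .x$immobilization
    ))
  }
  check_columns(surfaces, c("name", "ligand_mw", "immobilization"), "surfaces")
  if (any(surfaces$immobilization <= 0)) abort("zero or negative immobilization")
  out <- dplyr::left_join(
    as_tibble(responses),
    dplyr::rename(surfaces, surface = "name"),
    by = "surface"
  )
  if (any(is.na(out$immobilization))) {
    abort("response rows reference surfaces missing from `surfaces`")
  }
  out$occupancy <- out$raw_RU * out$ligand_mw /
    (out$immobilization * mw_analyte * n)
  dplyr::select(out, "surface", "raw_RU", "occupancy")
}
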