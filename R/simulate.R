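# Synthetic SPR campaign generator. Binding follows closed-form 1:1 Langmuir
# kinetics; DMSO bulk artifacts, baseline drift, sticky (non-specific)
# residuals and superstoichiometric binding are layered on top so every
# downstream stage can be exercised with known ground truth.

#' Constructors for simulation inputs
#'
#' @description
#' * `kinetic_model()` — a 1:1 Langmuir interaction: association rate `ka`
#'   (1/M/s), dissociation rate `kd_rate` (1/s), binding stoichiometry
#'   `stoich_n`. The equilibrium constant `kd_eq = kd_rate / ka` is derived.
#' * `injection_schedule()` — cycle timing in seconds: baseline until
#'   `t_start`, association until `t_stop`, dissociation until
#'   `t_dissoc_end`, sampled at `hz` Hz.
#' * `artifact_model()` — instrument artifacts: nominal and actual DMSO
#'   percentage (v/v), bulk refractive-index response per percent mismatch
#'   (`bulk_coeff`, RU/%), an excluded-volume mismatch polynomial
#'   (`excess_poly`, RU offset of active minus reference as a function of
#'   reference bulk RU), linear baseline `drift` (RU/s) and Gaussian
#'   `noise_sd` (RU).
#' * `surface_def()` — an immobilized flow cell: ligand name, ligand
#'   molecular weight (Da) and immobilization level (RU).
#' * `compound_profile()` — one library member's generative truth: its
#'   class (`clean_binder`, `non_binder`, `sticky`, `superstoichiometric`),
#'   molecular weight, kinetics, and the non-specific residual (RU) a sticky
#'   compound leaves on the surface.
#'
#' @param ka Association rate constant, 1/M/s.
#' @param kd_rate Dissociation rate constant, 1/s.
#' @param stoich_n Binding stoichiometry (>= 0).
#' @return Each constructor returns a plain list with a matching S3 class.
#' @name simulation-inputs
NULL

#' @rdname simulation-inputs
#' @export
kinetic_model <- function(ka, kd_rate, stoich_n = 1) {
  check_number(ka, "ka", positive = TRUE)
  check_number(kd_rate, "kd_rate", positive = TRUE)
  check_number(stoich_n, "stoich_n", non_negative = TRUE)
  structure(
    list(ka = ka, kd_rate = kd_rate, stoich_n = stoich_n, kd_eq = kd_rate / ka),
    class = "kinetic_model"
  )
}

#' @rdname simulation-inputs
#' @param t_start,t_stop,t_dissoc_end Phase boundaries in seconds.
#' @param hz Sampling rate in Hz.
#' @export
injection_schedule <- function(t_start = 5, t_stop = 35, t_dissoc_end = 55, hz = 10) {
  if (!(t_start < t_stop && t_stop < t_dissoc_end)) {
    abort("need t_start < t_stop < t_dissoc_end")
  }
  check_number(hz, "hz", positive = TRUE)
  structure(
    list(t_start = t_start, t_stop = t_stop, t_dissoc_end = t_dissoc_end, hz = hz),
    class = "injection_schedule"
  )
}

#' @rdname simulation-inputs
#' @param dmso_nominal,dmso_actual DMSO percentage (v/v) of running buffer
#'   and sample.
#' @param bulk_coeff Bulk response per percent DMSO mismatch, RU/%.
#' @param excess_poly Coefficients (intercept, linear, quadratic) of the
#'   active-minus-reference excluded-volume offset as a function of the
#'   reference bulk response.
#' @param drift Baseline drift, RU/s (common to both flow cells).
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @export
artifact_model <- function(dmso_nominal = 5, dmso_actual = 5, bulk_coeff = 100,
                           excess_poly = c(0, 0.05, 2e-4), drift = 0,
                           noise_sd = 0.3) {
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  stopifnot(length(excess_poly) >= 1, length(excess_poly) <= 3)
  excess_poly <- c(excess_poly, rep(0, 3 - length(excess_poly)))
  structure(
    list(
      dmso_nominal = dmso_nominal, dmso_actual = dmso_actual,
      bulk_coeff = bulk_coeff, excess_poly = excess_poly,
      drift = drift, noise_sd = noise_sd
    ),
    class = "artifact_model"
  )
}

#' @rdname simulation-inputs
#' @param name Ligand name.
#' @param ligand_mw Ligand molecular weight in Da.
#' @param immobilization Immobilization level in RU.
#' @param flow_cell Flow cell index.
#' @param is_reference Whether this is the (unmodified) reference cell.
#' @export
surface_def <- function(name, ligand_mw, immobilization, flow_cell = 2L,
                        is_reference = FALSE) {
  if (!is_reference) {
    check_number(ligand_mw, "ligand_mw", positive = TRUE)
    check_number(immobilization, "immobilization", positive = TRUE)
  }
  structure(
    list(
      name = name, ligand_mw = ligand_mw, immobilization = immobilization,
      flow_cell = as.integer(flow_cell), is_reference = is_reference
    ),
    class = "surface_def"
  )
}

#' @rdname simulation-inputs
#' @param id Compound id.
#' @param class Generator class, one of `"clean_binder"`, `"non_binder"`,
#'   `"sticky"`, `"superstoichiometric"`.
#' @param mw Compound molecular weight in Da.
#' @param kinetics A [kinetic_model()] (ignored for pure non-binders).
#' @param residual_ru Non-specific residual left on the surface (RU); used by
#'   the `"sticky"` class.
#' @export
compound_profile <- function(id, class = c("clean_binder", "non_binder",
                                           "sticky", "superstoichiometric"),
                             mw, kinetics = NULL, residual_ru = 0) {
  class <- match.arg(class)
  check_number(mw, "mw", positive = TRUE)
  if (is.null(kinetics) && class %in% c("clean_binder", "superstoichiometric")) {
    abort("`kinetics` required for binding classes")
  }
  structure(
    list(id = id, class = class, mw = mw, kinetics = kinetics,
         residual_ru = residual_ru),
    class = "compound_profile"
  )
}

# closed-form 1:1 Langmuir response on a time grid ---------------------------
langmuir_response <- function(times, conc, ka, kd_rate, rmax_eff,
                              t_start, t_stop) {
  r <- numeric(length(times))
  if (conc > 0 && rmax_eff > 0) {
    kobs <- ka * conc + kd_rate
    req <- conc * rmax_eff / (conc + kd_rate / ka)
    assoc <- times >= t_start & times <= t_stop
    r[assoc] <- req * (1 - exp(-kobs * (times[assoc] - t_start)))
    r_end <- req * (1 - exp(-kobs * (t_stop - t_start)))
    dis <- times > t_stop
    r[dis] <- r_end * exp(-kd_rate * (times[dis] - t_stop))
  }
  r
}

# sticky-compound residual: fast build-up during injection, very slow decay
# afterwards so the 10 s post-injection report point still sees it
sticky_residual <- function(times, residual_ru, t_start, t_stop,
                            tau_on = 5, t_half_off = 600) {
  r <- numeric(length(times))
  if (residual_ru > 0) {
    assoc <- times >= t_start & times <= t_stop
    r[assoc] <- residual_ru * (1 - exp(-(times[assoc] - t_start) / tau_on))
    r_end <- residual_ru * (1 - exp(-(t_stop - t_start) / tau_on))
    dis <- times > t_stop
    r[dis] <- r_end * exp(-log(2) * (times[dis] - t_stop) / t_half_off)
  }
  r
}

#' Construct a sensorgram
#'
#' A sensorgram is a tibble with columns `time_s` and `response_RU` plus
#' phase markers (`t_start`, `t_stop`) and cycle metadata carried as
#' attributes.
#'
#' @param time_s Strictly increasing time points in seconds.
#' @param response_RU Response in resonance units.
#' @param t_start,t_stop Injection start/stop markers in seconds.
#' @param meta Named list of cycle metadata (compound id, concentration,
#'   DMSO percentage, flow cell, role, ...).
#' @return A tibble of class `sensorgram`.
#' @export
sensorgram <- function(time_s, response_RU, t_start, t_stop, meta = list()) {
  if (is.unsorted(time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing")
  }
  if (t_start < min(time_s) || t_stop > max(time_s)) {
    abort("phase markers must lie within the time range")
  }
  out <- tibble(time_s = time_s, response_RU = response_RU)
  attr(out, "t_start") <- t_start
  attr(out, "t_stop") <- t_stop
  attr(out, "meta") <- meta
  class(out) <- c("sensorgram", class(out))
  out
}

sg_marker <- function(s, which = c("t_start", "t_stop")) {
  attr(s, match.arg(which), exact = TRUE)
}

#' Simulate one injection cycle
#'
#' Generates active- and reference-cell traces for a single analyte
#' injection. The active trace carries 1:1 Langmuir binding (plus a slowly
#' decaying non-specific residual for sticky compounds); both traces carry
#' the DMSO bulk jump during the injection window, baseline drift and
#' Gaussian noise. The active cell additionally sees the excluded-volume
#' mismatch offset that solvent correction later removes.
#'
#' @param profile A [compound_profile()].
#' @param conc Analyte concentration in M (>= 0).
#' @param surface A [surface_def()] for the active flow cell.
#' @param schedule An [injection_schedule()].
#' @param artifacts An [artifact_model()].
#' @param seed Optional integer seed for the noise stream.
#' @return A list of class `spr_cycle` with elements `active` and
#'   `reference`, each a [sensorgram()].
#' @examples
#' prof <- compound_profile("C1", "clean_binder", mw = 250,
#'                          kinetics = kinetic_model(1e3, 0.5))
#' surf <- surface_def("C1r", 92000, 9200)
#' cyc <- simulate_cycle(prof, 5e-4, surf, injection_schedule(),
#'                       artifact_model(noise_sd = 0), seed = 1)
#' @export
simulate_cycle <- function(profile, conc, surface, schedule = injection_schedule(),
                           artifacts = artifact_model(), seed = NULL) {
  check_number(conc, "conc", non_negative = TRUE)
  if (!surface$is_reference) check_number(surface$immobilization, "immobilization", positive = TRUE)

  with_seed(seed, {
    times <- seq(0, schedule$t_dissoc_end, by = 1 / schedule$hz)
    t_start <- schedule$t_start
    t_stop <- schedule$t_stop

    # binding on the active surface
    bind <- numeric(length(times))
    if (profile$class != "non_binder" && !is.null(profile$kinetics)) {
      km <- profile$kinetics
      rmax1 <- theoretical_rmax(surface, profile$mw, n = 1)
      bind <- langmuir_response(times, conc, km$ka, km$kd_rate,
                                rmax1 * km$stoich_n, t_start, t_stop)
    }
    if (profile$class == "sticky" && conc > 0) {
      bind <- bind + sticky_residual(times, profile$residual_ru, t_start, t_stop)
    }

    # bulk refractive-index jump during the injection window (both cells)
    mismatch <- artifacts$dmso_actual - artifacts$dmso_nominal
    bulk_ref <- artifacts$bulk_coeff * mismatch
    in_plug <- times >= t_start & times <= t_stop
    bulk_trace <- ifelse(in_plug, bulk_ref, 0)
    # excluded-volume mismatch: active cell responds slightly differently
    ep <- artifacts$excess_poly
    excess <- ep[1] + ep[2] * bulk_ref + ep[3] * bulk_ref^2
    excess_trace <- ifelse(in_plug, excess, 0)

    drift_trace <- artifacts$drift * times
    noise <- function() {
      if (artifacts$noise_sd > 0) rnorm(length(times), 0, artifacts$noise_sd) else 0
    }

    meta_common <- list(
      compound_id = profile$id, conc_M = conc,
      dmso_pct = artifacts$dmso_actual, class = profile$class
    )
    active <- sensorgram(
      times, bind + bulk_trace + excess_trace + drift_trace + noise(),
      t_start, t_stop,
      meta = c(meta_common, list(flow_cell = surface$flow_cell, role = "active"))
    )
    reference <- sensorgram(
      times, bulk_trace + drift_trace + noise(),
      t_start, t_stop,
      meta = c(meta_common, list(flow_cell = 1L, role = "reference"))
    )
    structure(list(active = active, reference = reference), class = "spr_cycle")
  })
}

#' Default two-fold dilution series
#'
#' Seven two-fold dilutions from 500 µM down to 7.8 µM, the standard
#' dose-response series for fragment confirmation.
#'
#' @param top Top concentration in M.
#' @param n_points Number of two-fold dilutions.
#' @return Ascending numeric vector of concentrations in M.
#' @export
dose_series_default <- function(top = 500e-6, n_points = 7) {
  sort(top / 2^(seq_len(n_points) - 1))
}

cycles_to_long <- function(cycles_list) {
  purrr::imap_dfr(cycles_list, function(cyc, i) {
    dplyr::bind_rows(
      dplyr::mutate(as_tibble(cyc$active), role = "active"),
      dplyr::mutate(as_tibble(cyc$reference), role = "reference")
    ) |>
      dplyr::mutate(cycle = as.integer(i), .before = 1)
  })
}

#' Simulate a single-concentration screening campaign
#'
#' Generates one injection cycle per library compound at the screening
#' concentration, a blank (buffer) cycle per calibration block for double
#' referencing, and DMSO calibration cycles at the beginning, the end and
#' every `calib_every` cycles. Each compound is assigned a generative class
#' (clean binder, non-binder, sticky, superstoichiometric) and the planted
#' truth is returned for confusion-matrix testing.
#'
#' @param library Compound tibble from [load_library()] (columns `id`, `mw`).
#' @param class_fractions Named fractions over the four generator classes;
#'   must sum to 1.
#' @param kd_range Range (M) from which clean-binder equilibrium constants
#'   are drawn (log-uniform).
#' @param surface Active-surface [surface_def()].
#' @param schedule An [injection_schedule()].
#' @param artifacts Base [artifact_model()]; per-cycle actual DMSO is drawn
#'   uniformly from `dmso_jitter` around the nominal value.
#' @param screen_conc Screening concentration in M (default 500 µM).
#' @param dmso_jitter Half-width (%) of the per-cycle DMSO mismatch.
#' @param sticky_residual_ru Residual (RU) planted for sticky compounds.
#' @param super_n Stoichiometry planted for superstoichiometric compounds.
#' @param super_kd_range Apparent-KD range (M) for superstoichiometric
#'   compounds; aggregation-driven binding presents as steep, apparently
#'   tight occupancy, so the default sits below the clean-binder range.
#' @param frac_insoluble Fraction of compounds flagged insoluble on visual
#'   inspection (excluded before any cycle is run).
#' @param calib_every Calibration-cycle cadence (default every 50 cycles).
#' @param calib_dmso DMSO percentages of each calibration block.
#' @param seed Integer seed; the campaign is bit-reproducible given the seed.
#' @return A list of class `spr_campaign`: `sensorgrams` (long tibble:
#'   `cycle`, `role`, `time_s`, `response_RU`), `cycles` (per-cycle metadata:
#'   `cycle`, `compound_id`, `conc_M`, `dmso_pct`, `is_calibration`,
#'   `is_blank`, `replicate`), `truth` (planted labels), plus the `surface`,
#'   `schedule` and base `artifacts` used.
#' @export
simulate_campaign <- function(library,
                              class_fractions = c(clean_binder = 0.10,
                                                  non_binder = 0.78,
                                                  sticky = 0.08,
                                                  superstoichiometric = 0.04),
                              kd_range = c(5e-5, 2.5e-4),
                              surface = surface_def("C1r", 92000, 9200),
                              schedule = injection_schedule(),
                              artifacts = artifact_model(),
                              screen_conc = 500e-6,
                              dmso_jitter = 0.4,
                              sticky_residual_ru = 8,
                              super_n = 2.5,
                              super_kd_range = c(1e-5, 1e-4),
                              frac_insoluble = 0,
                              calib_every = 50,
                              calib_dmso = seq(4, 5.5, by = 0.25),
                              seed = 1L) {
  if (nrow(library) == 0) abort("empty library")
  if (abs(sum(class_fractions) - 1) > 1e-8) abort("class fractions must sum to 1")
  classes <- c("clean_binder", "non_binder", "sticky", "superstoichiometric")
  if (!all(names(class_fractions) %in% classes)) {
    abort("unknown class in `class_fractions`")
  }

  with_seed(seed, {
    n <- nrow(library)
    counts <- floor(class_fractions[classes] * n)
    counts[is.na(counts)] <- 0
    # distribute the remainder to the largest fraction
    counts[which.max(class_fractions[classes])] <-
      counts[which.max(class_fractions[classes])] + n - sum(counts)
    class_vec <- sample(rep(classes, times = counts))

    truth <- tibble(
      compound_id = library$id,
      mw = library$mw,
      class = class_vec,
      insoluble = seq_len(n) %in% sample(n, round(frac_insoluble * n)),
      kd_eq = NA_real_, stoich_n = NA_real_, residual_ru = 0
    )
    is_clean <- truth$class == "clean_binder"
    truth$kd_eq[is_clean] <- exp(stats::runif(sum(is_clean),
                                              log(kd_range[1]), log(kd_range[2])))
    truth$stoich_n[is_clean] <- 1
    n_super <- sum(truth$class == "superstoichiometric")
    truth$kd_eq[truth$class == "superstoichiometric"] <-
      exp(stats::runif(n_super, log(super_kd_range[1]), log(super_kd_range[2])))
    truth$stoich_n[truth$class == "superstoichiometric"] <-
      stats::runif(n_super, super_n, super_n + 1.5)
    truth$residual_ru[truth$class == "sticky"] <- sticky_residual_ru
    # sticky compounds may also bind weakly; keep them pure non-binders here
    # so the clean screen is the only filter that should catch them

    screened <- truth[!truth$insoluble, ]

    cycles_meta <- list()
    cycles_sg <- list()
    cycle_no <- 0L

    add_cycle <- function(profile, conc, dmso_actual, is_calib, is_blank) {
      cycle_no <<- cycle_no + 1L
      art <- artifact_model(
        dmso_nominal = artifacts$dmso_nominal, dmso_actual = dmso_actual,
        bulk_coeff = artifacts$bulk_coeff, excess_poly = artifacts$excess_poly,
        drift = artifacts$drift, noise_sd = artifacts$noise_sd
      )
      cyc <- simulate_cycle(profile, conc, surface, schedule, art)
      cycles_sg[[cycle_no]] <<- cyc
      cycles_meta[[cycle_no]] <<- tibble(
        cycle = cycle_no,
        compound_id = if (is_blank || is_calib) NA_character_ else profile$id,
        conc_M = conc, dmso_pct = dmso_actual,
        is_calibration = is_calib, is_blank = is_blank
      )
    }

    blank_profile <- compound_profile("blank", "non_binder", mw = 1)
    add_calibration_block <- function() {
      for (d in calib_dmso) add_cycle(blank_profile, 0, d, TRUE, FALSE)
      add_cycle(blank_profile, 0, artifacts$dmso_nominal, FALSE, TRUE)
    }

    add_calibration_block()
    for (i in seq_len(nrow(screened))) {
      row <- screened[i, ]
      kin <- if (row$class %in% c("clean_binder", "superstoichiometric")) {
        # fix kd_rate around 0.5/s (fast-off fragment) and set ka from kd_eq
        kinetic_model(ka = 0.5 / row$kd_eq, kd_rate = 0.5, stoich_n = row$stoich_n)
      } else NULL
      prof <- compound_profile(row$compound_id, row$class, mw = row$mw,
                               kinetics = kin, residual_ru = row$residual_ru)
      dmso_i <- artifacts$dmso_nominal + stats::runif(1, -dmso_jitter, dmso_jitter)
      add_cycle(prof, screen_conc, dmso_i, FALSE, FALSE)
      if (i %% calib_every == 0 && i < nrow(screened)) add_calibration_block()
    }
    add_calibration_block()

    structure(
      list(
        sensorgrams = cycles_to_long(cycles_sg),
        cycles = dplyr::bind_rows(cycles_meta),
        truth = truth,
        surface = surface, schedule = schedule, artifacts = artifacts,
        screen_conc = screen_conc
      ),
      class = "spr_campaign"
    )
  })
}

#' Simulate a dose-response dilution series
#'
#' One cycle per concentration per replicate, plus one blank cycle per
#' replicate, with independent noise per replicate.
#'
#' @inheritParams simulate_cycle
#' @param concentrations Concentrations in M (default the two-fold
#'   7.8-500 µM series).
#' @param replicates Number of independent replicate series (>= 1).
#' @param seed Integer seed.
#' @return An `spr_campaign` list as in [simulate_campaign()]; `cycles`
#'   additionally carries `replicate`.
#' @export
simulate_dose_series <- function(profile, concentrations = dose_series_default(),
                                 surface = surface_def("C1r", 92000, 9200),
                                 schedule = injection_schedule(),
                                 artifacts = artifact_model(noise_sd = 0.5),
                                 replicates = 3, seed = 1L) {
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (replicates < 1) abort("`replicates` must be >= 1")

  with_seed(seed, {
    cycles_meta <- list()
    cycles_sg <- list()
    cycle_no <- 0L
    blank_profile <- compound_profile("blank", "non_binder", mw = 1)
    for (rep_i in seq_len(replicates)) {
      for (is_blank in c(TRUE, FALSE)) {
        concs <- if (is_blank) 0 else concentrations
        for (conc in concs) {
          cycle_no <- cycle_no + 1L
          prof <- if (is_blank) blank_profile else profile
          cyc <- simulate_cycle(prof, conc, surface, schedule, artifacts)
          cycles_sg[[cycle_no]] <- cyc
          cycles_meta[[cycle_no]] <- tibble(
            cycle = cycle_no,
            compound_id = if (is_blank) NA_character_ else profile$id,
            conc_M = conc, dmso_pct = artifacts$dmso_actual,
            is_calibration = FALSE, is_blank = is_blank,
            replicate = rep_i
          )
        }
      }
    }
    structure(
      list(
        sensorgrams = cycles_to_long(cycles_sg),
        cycles = dplyr::bind_rows(cycles_meta),
        truth = tibble(compound_id = profile$id, class = profile$class,
                       kd_eq = if (is.null(profile$kinetics)) NA_real_ else profile$kinetics$kd_eq,
                       stoich_n = if (is.null(profile$kinetics)) NA_real_ else profile$kinetics$stoich_n),
        surface = surface, schedule = schedule, artifacts = artifacts
      ),
      class = "spr_campaign"
    )
  })
}

#' Simulate an ELISA inhibition plate
#'
#' Emits a plate table in which each column holds one concentration of the
#' dose series (replicate wells down the column) together with a positive
#' control (full activity, no inhibitor) and a negative control (no serum).
#' Well signal follows a Hill inhibition model between the control levels
#' with multiplicative noise.
#'
#' @param ic50 True half-maximal inhibitory concentration in M.
#' @param hill Hill slope of the inhibition curve.
#' @param concentrations Tested concentrations in M.
#' @param replicates Sample wells per column.
#' @param noise_cv Multiplicative (lognormal-free, Gaussian CV) noise level.
#' @param pos_abs,neg_abs Mean absorbance of positive / negative controls
#'   (AU at 450 nm).
#' @param compound_id Compound label carried into the table.
#' @param seed Integer seed.
#' @return A tibble with columns `plate`, `well`, `row`, `col`, `role`,
#'   `compound_id`, `conc_M`, `absorbance`.
#' @export
simulate_elisa_plate <- function(ic50, hill = 1,
                                 concentrations = dose_series_default(),
                                 replicates = 3, noise_cv = 0.05,
                                 pos_abs = 1.2, neg_abs = 0.08,
                                 compound_id = "CMP", seed = 1L) {
  check_number(ic50, "ic50", positive = TRUE)
  with_seed(seed, {
    inhibition <- function(C) C^hill / (C^hill + ic50^hill)
    rows_per_col <- replicates + 2L
    out <- purrr::imap_dfr(concentrations, function(conc, col_i) {
      clean <- neg_abs + (pos_abs - neg_abs) * (1 - inhibition(conc))
      mk <- function(row_i, role, mean_abs, conc_val) {
        tibble(
          plate = 1L,
          well = paste0(LETTERS[row_i], col_i),
          row = row_i, col = col_i, role = role,
          compound_id = ifelse(role == "sample", compound_id, NA_character_),
          conc_M = conc_val,
          absorbance = mean_abs * (1 + if (noise_cv > 0) rnorm(1, 0, noise_cv) else 0)
        )
      }
      dplyr::bind_rows(
        purrr::map_dfr(seq_len(replicates), mk, role = "sample",
                       mean_abs = clean, conc_val = conc),
        mk(replicates + 1L, "positive_control", pos_abs, NA_real_),
        mk(replicates + 2L, "negative_control", neg_abs, NA_real_)
      )
    })
    out
  })
}
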