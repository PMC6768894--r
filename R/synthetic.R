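#' Mosteller body surface area
#'
#' `BSA = sqrt(height * mass / 3600)` with height in cm and mass in kg,
#' the formula used for the subject table.
#'
#' @param height_cm height (cm, `> 0`).
#' @param mass_kg body mass (kg, `> 0`).
#' @return body surface area (m^2), unrounded.
#' @examples
#' mosteller_bsa(168, 58)  # 1.65 m^2
#' @export
mosteller_bsa <- function(height_cm, mass_kg) {
  if (any(height_cm <= 0) || any(mass_kg <= 0))
    stop("height and mass must be positive")
  sqrt(height_cm * mass_kg / 3600)
}

#' Study tables shipped with the package
#'
#' Verbatim transcriptions of the study's printed tables, installed as CSV:
#' the per-subject anthropometry and respiratory parameters
#' (`table_subjects()`), the per-session mean radon concentrations in the
#' bath water (`table_water_concentrations()`, MBq m^-3) and the per-session
#' radon-transfer values with their normalizations
#' (`table_radon_transfer()`; `session_type` distinguishes the seven
#' standard 20-minute baths from the 30-minute and pre-heated sessions).
#'
#' @return a data frame.
#' @export
table_subjects <- function() {
  utils::read.csv(system.file("extdata", "subjects_table.csv",
                              package = "radonskin"))
}

#' @rdname table_subjects
#' @export
table_water_concentrations <- function() {
  utils::read.csv(system.file("extdata", "water_concentrations.csv",
                              package = "radonskin"))
}

#' @rdname table_subjects
#' @export
table_radon_transfer <- function() {
  utils::read.csv(system.file("extdata", "radon_transfer_table.csv",
                              package = "radonskin"))
}

#' Subject profile from the shipped study table
#'
#' @param sn subject number (1-6).
#' @return an [rn_subject()] with the printed values.
#' @export
subject_from_table <- function(sn) {
  tab <- table_subjects()
  row <- tab[tab$sn == sn, ]
  if (nrow(row) != 1L) stop("unknown subject number: ", sn)
  rn_subject(row$sn, row$gender, height_cm = row$height_cm,
             mass_kg = row$mass_kg, bsa_m2 = row$bsa_m2,
             v_rt_l = row$v_rt_l, v_t_l = row$v_t_l,
             rf_per_min = row$rf_per_min, rmv_l_per_h = row$rmv_l_per_h,
             age_y = row$age_y, body_fat_kg = row$body_fat_kg)
}

#' Sample a plausible subject profile
#'
#' Draws anthropometry and respiratory parameters uniformly within the
#' per-gender ranges of the shipped subject table; body surface area is
#' recomputed from the sampled height and mass with [mosteller_bsa()] and the
#' respiratory minute volume is set to `v_t * rf * 60`, so every generated
#' profile satisfies the subject invariants by construction.
#'
#' @param gender `"F"` or `"M"`.
#' @param seed optional integer seed for reproducibility.
#' @return an [rn_subject()].
#' @export
generate_subject <- function(gender = c("F", "M"), seed = NULL) {
  gender <- match.arg(gender)
  if (!is.null(seed)) set.seed(seed)
  tab <- table_subjects()
  tab <- tab[tab$gender == gender, ]
  r <- function(col) stats::runif(1, min(tab[[col]]), max(tab[[col]]))
  height <- r("height_cm"); mass <- r("mass_kg")
  v_rt <- r("v_rt_l"); v_t <- r("v_t_l"); rf <- r("rf_per_min")
  rn_subject(paste0("synthetic-", gender), gender, height_cm = height,
             mass_kg = mass, bsa_m2 = mosteller_bsa(height, mass),
             v_rt_l = v_rt, v_t_l = v_t, rf_per_min = rf,
             rmv_l_per_h = v_t * rf * 60, age_y = round(r("age_y")),
             body_fat_kg = r("body_fat_kg"))
}

#' Default single-breath sampling times for a scenario
#'
#' Bag samples are taken every `interval_min` minutes, starting 2 minutes
#' into each phase (bath and rest), matching the roughly 4-minute spacing of
#' the measurement protocol.
#'
#' @param scenario an [rn_scenario()].
#' @param interval_min sampling spacing (minutes).
#' @return numeric vector of sample times (minutes from scenario start).
#' @export
protocol_sampling_times <- function(scenario, interval_min = 4) {
  ends <- cumsum(vapply(scenario$phases, function(p) p$duration_min,
                        numeric(1)))
  starts <- c(0, ends[-length(ends)])
  unlist(lapply(seq_along(starts), function(i) {
    if (ends[i] - starts[i] < 2) return(numeric(0))
    seq(starts[i] + 2, ends[i], by = interval_min)
  }))
}

#' Generate a synthetic exhalation measurement series
#'
#' Simulates the biokinetic model for a subject and scenario, samples the
#' exhaled concentration at the single-breath bag times, and applies
#' multiplicative lognormal measurement noise with coefficient of variation
#' `noise_cv` (the combined counting and breathing errors of the protocol are
#' 5-15%). The lognormal factors have unit mean and are truncated at four
#' standard deviations on the log scale; `noise_kind = "additive"` replaces
#' them with truncated Gaussian factors `1 + cv * z` for sensitivity checks.
#' With `as_measured = TRUE` the samples are additionally diluted by the
#' instrument dead-space factor, emulating raw bag measurements.
#'
#' The generating parameter set, permeability scale and noise settings are
#' recorded in the `ground_truth` attribute so that recovery studies can
#' compare estimates against the truth.
#'
#' @param subject an [rn_subject()].
#' @param scenario an [rn_scenario()].
#' @param params an [rn_parameters()] object.
#' @param k_scale multiplier applied to the baseline permeability before
#'   simulating (the ground truth of recovery studies).
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param noise_kind `"lognormal"` (default) or `"additive"`.
#' @param seed optional integer seed.
#' @param times_min sample times; default [protocol_sampling_times()].
#' @param interval_min sampling spacing used for the default times.
#' @param as_measured logical; apply dead-space dilution.
#' @return an `exhalation_series` with noise and ground-truth metadata.
#' @export
generate_exhalation_series <- function(subject, scenario,
                                       params = rn_parameters(),
                                       k_scale = 1, noise_cv = 0.10,
                                       noise_kind = c("lognormal", "additive"),
                                       seed = NULL, times_min = NULL,
                                       interval_min = params$instrument$sampling_interval_min,
                                       as_measured = FALSE) {
  noise_kind <- match.arg(noise_kind)
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times_min))
    times_min <- protocol_sampling_times(scenario, interval_min)
  sim_params <- scale_permeability(params, k_scale)
  traj <- simulate_scenario(scenario, sim_params, subject,
                            times_min = times_min)
  model <- exhaled_concentration(traj)
  keep <- match(times_min, model$time_min)
  c_ex <- model$c_ex_Bq_per_m3[keep]
  if (noise_cv > 0) {
    z <- pmin(pmax(stats::rnorm(length(c_ex)), -4), 4)
    fac <- if (noise_kind == "lognormal") {
      sdlog <- sqrt(log1p(noise_cv^2))
      exp(z * sdlog - sdlog^2 / 2)
    } else {
      pmax(1 + noise_cv * z, 0)
    }
    c_ex <- c_ex * fac
  }
  corrected <- TRUE
  if (isTRUE(as_measured)) {
    c_ex <- c_ex * dead_space_factor(subject$v_t_l, params$instrument$v_dead_l)
    corrected <- FALSE
  }
  new_exhalation_series(times_min, c_ex, corrected = corrected,
                        subject = subject, scenario = scenario,
                        phases = traj$phases,
                        noise = list(cv = noise_cv, kind = noise_kind,
                                     seed = seed),
                        ground_truth = list(k_scale = k_scale,
                                            params = sim_params))
}

#' Scale the baseline skin permeability of a parameter set
#'
#' @param params an [rn_parameters()] object.
#' @param k_scale multiplier on the baseline permeability coefficient.
#' @param kds_scale multiplier on the dermal-subcutaneous transfer
#'   coefficient.
#' @return the modified parameter set (provenance of the touched fields set
#'   to `"user"`).
#' @export
scale_permeability <- function(params, k_scale = 1, kds_scale = 1) {
  if (k_scale <= 0 || kds_scale <= 0) stop("scales must be positive")
  if (k_scale != 1) {
    params$skin$k0_m_per_s <- params$skin$k0_m_per_s * k_scale
    params$provenance[["skin.k0_m_per_s"]] <- "user"
  }
  if (kds_scale != 1) {
    params$skin$k_ds_per_h <- params$skin$k_ds_per_h * kds_scale
    params$provenance[["skin.k_ds_per_h"]] <- "user"
  }
  params
}
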