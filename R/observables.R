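#' Exhaled radon concentration from a trajectory
#'
#' The exhaled concentration of a single breath equals the radon
#' concentration in the respiratory-tract air, `C_EX = Q_RT / V_RT`,
#' reported in Bq m^-3.
#'
#' @param traj an `rn_trajectory` from [simulate_scenario()].
#' @return an `exhalation_series`: data frame with columns `time_min` and
#'   `c_ex_Bq_per_m3`, carrying attributes `dead_space_corrected` (`TRUE`
#'   for a model curve: no instrument dilution), `subject` and `scenario`.
#' @export
exhaled_concentration <- function(traj) {
  stopifnot(inherits(traj, "rn_trajectory"))
  c_ex <- traj$states[, "rt_air"] / traj$volumes[["rt_air"]] * 1000
  new_exhalation_series(traj$time_min, c_ex, corrected = TRUE,
                        subject = traj$subject, scenario = traj$scenario,
                        phases = traj$phases)
}

#' Construct an exhalation series
#'
#' Low-level constructor validating the series invariants (strictly
#' increasing sample times, non-negative concentrations).
#'
#' @param time_min sample times (minutes).
#' @param c_ex exhaled concentrations (Bq m^-3).
#' @param corrected logical; `TRUE` if the values are free of instrument
#'   dead-space dilution.
#' @param subject,scenario,phases,noise,ground_truth optional metadata
#'   attached as attributes.
#' @return an `exhalation_series`.
#' @export
new_exhalation_series <- function(time_min, c_ex, corrected, subject = NULL,
                                  scenario = NULL, phases = NULL,
                                  noise = NULL, ground_truth = NULL) {
  if (is.unsorted(time_min, strictly = TRUE))
    stop("sample times must be strictly increasing")
  if (any(c_ex < 0)) stop("concentrations must be non-negative")
  structure(data.frame(time_min = time_min, c_ex_Bq_per_m3 = c_ex),
            dead_space_corrected = corrected, subject = subject,
            scenario = scenario, phases = phases, noise = noise,
            ground_truth = ground_truth,
            class = c("exhalation_series", "data.frame"))
}

#' Instrument dead-space dilution factor
#'
#' At the switch from inhalation to exhalation, the dead-space volume between
#' the instrument valves is filled with (nearly radon-free) outside air, so a
#' collected breath contains only the fraction `(V_T - V_D) / V_T` of
#' respiratory-tract air. Measured concentrations are divided by this factor
#' to recover the undiluted value; model curves are multiplied by it to
#' emulate a measurement.
#'
#' @param v_t tidal volume (litres).
#' @param v_d instrument dead-space volume (litres), `0 <= v_d < v_t`.
#' @return dilution factor in `(0, 1]`.
#' @examples
#' dead_space_factor(0.56, 0.110)  # 0.8036
#' @export
dead_space_factor <- function(v_t, v_d) {
  if (any(v_d < 0)) stop("dead space must be non-negative")
  if (any(v_d >= v_t)) stop("dead space must be smaller than the tidal volume")
  (v_t - v_d) / v_t
}

#' Apply or invert the dead-space dilution of a series
#'
#' @param series an `exhalation_series`.
#' @param v_t tidal volume (litres).
#' @param v_d dead-space volume (litres).
#' @return the series with concentrations multiplied (`dilute_series`) or
#'   divided (`correct_series`) by [dead_space_factor()] and the
#'   `dead_space_corrected` attribute updated.
#' @export
dilute_series <- function(series, v_t, v_d) {
  f <- dead_space_factor(v_t, v_d)
  series$c_ex_Bq_per_m3 <- series$c_ex_Bq_per_m3 * f
  attr(series, "dead_space_corrected") <- FALSE
  series
}

#' @rdname dilute_series
#' @export
correct_series <- function(series, v_t, v_d) {
  f <- dead_space_factor(v_t, v_d)
  series$c_ex_Bq_per_m3 <- series$c_ex_Bq_per_m3 / f
  attr(series, "dead_space_corrected") <- TRUE
  series
}

#' Radon transfer statistic
#'
#' Total radon activity taken up through the skin and exhaled via the lungs:
#' the respiratory minute volume times the time integral of the exhaled
#' concentration, `RT = RMV * integral(C_EX dt)`, evaluated by the
#' trapezoidal rule on the series grid. The default integration window runs
#' from the start to the end of the exposure (the convention of the published
#' per-subject table); `window = "full"` extends it to the end of the series
#' (exposure plus rest).
#'
#' @param series an `exhalation_series`, dead-space corrected.
#' @param rmv respiratory minute volume (l h^-1).
#' @param t1,t2 integration window (minutes); default per `window`.
#' @param window `"exposure"` (start to end of bath, the default) or
#'   `"full"`. Used only when `t1`/`t2` are not given and the series carries
#'   phase markers.
#' @param c_water optional water concentration (MBq m^-3) for the normalized
#'   value RT/Rn in Bq/(MBq m^-3).
#' @param bsa optional body surface area (m^2) for the additionally
#'   normalized value RT/(Rn BSA) in Bq/(MBq m^-5).
#' @return an object of class `radon_transfer`: list with `rt_Bq`, the
#'   normalized values (when the divisors are given) and the window.
#' @examples
#' s <- new_exhalation_series(seq(0, 40, 4), rep(1000, 11), corrected = TRUE)
#' radon_transfer(s, rmv = 514, t1 = 0, t2 = 40)$rt_Bq  # 0.514 * 1000 * 2/3
#' @export
radon_transfer <- function(series, rmv, t1 = NULL, t2 = NULL,
                           window = c("exposure", "full"),
                           c_water = NULL, bsa = NULL) {
  window <- match.arg(window)
  phases <- attr(series, "phases")
  if (is.null(t1)) t1 <- min(series$time_min)
  if (is.null(t2)) {
    t2 <- if (window == "exposure" && !is.null(phases) &&
              any(phases$kind == "bath")) {
      max(phases$end_min[phases$kind == "bath"])
    } else {
      max(series$time_min)
    }
  }
  if (t1 >= t2) stop("empty integration window")
  if (t1 < min(series$time_min) - 1e-9 || t2 > max(series$time_min) + 1e-9)
    stop("integration window outside the series span")
  tt <- series$time_min
  cc <- series$c_ex_Bq_per_m3
  grid <- sort(unique(c(t1, tt[tt > t1 & tt < t2], t2)))
  vals <- stats::approx(tt, cc, xout = grid)$y
  integral_h <- sum(diff(grid / 60) * (utils::head(vals, -1) + vals[-1]) / 2)
  rt <- (rmv / 1000) * integral_h        # RMV in m^3 h^-1 x Bq m^-3 h
  out <- list(rt_Bq = rt, t1_min = t1, t2_min = t2, window = window,
              rmv_l_per_h = rmv)
  if (!is.null(c_water)) {
    if (c_water <= 0) stop("c_water must be positive")
    out$rt_per_rn_Bq_per_MBq_m3 <- rt / c_water
    if (!is.null(bsa)) {
      if (bsa <= 0) stop("bsa must be positive")
      out$rt_per_rn_bsa_Bq_per_MBq_m5 <- rt / (c_water * bsa)
    }
  }
  structure(out, class = "radon_transfer")
}

#' @export
print.radon_transfer <- function(x, ...) {
  cat(sprintf("Radon transfer over [%g, %g] min: RT = %.1f Bq\n",
              x$t1_min, x$t2_min, x$rt_Bq))
  if (!is.null(x$rt_per_rn_Bq_per_MBq_m3))
    cat(sprintf("  RT/Rn       = %.1f Bq/(MBq m^-3)\n",
                x$rt_per_rn_Bq_per_MBq_m3))
  if (!is.null(x$rt_per_rn_bsa_Bq_per_MBq_m5))
    cat(sprintf("  RT/(Rn BSA) = %.1f Bq/(MBq m^-5)\n",
                x$rt_per_rn_bsa_Bq_per_MBq_m5))
  invisible(x)
}

#' Linear rescaling of a radon-transfer value to another water concentration
#'
#' The compartment system is linear in the water concentration, so a
#' radon-transfer value measured at one concentration converts to another by
#' simple proportion; used to compare published values obtained at different
#' treatment concentrations.
#'
#' @param rt radon transfer (Bq) measured at `c_from`.
#' @param c_from,c_to water concentrations (same unit, e.g. MBq m^-3).
#' @return the rescaled radon transfer (Bq).
#' @examples
#' rescale_radon_transfer(1000, c_from = 2, c_to = 0.9)  # 450
#' @export
rescale_radon_transfer <- function(rt, c_from, c_to) {
  if (c_from <= 0 || c_to < 0) stop("concentrations must be positive")
  rt * c_to / c_from
}

#' Normalize an exhalation series
#'
#' Divides the exhaled concentrations by the water concentration (giving
#' Bq m^-3 per MBq m^-3) and optionally by the body surface area, the
#' normalizations used to compare exhalation curves across subjects.
#'
#' @param series an `exhalation_series`.
#' @param c_water water concentration (MBq m^-3, `> 0`).
#' @param bsa optional body surface area (m^2, `> 0`).
#' @return the normalized series.
#' @export
normalize_series <- function(series, c_water, bsa = NULL) {
  if (c_water <= 0) stop("c_water must be positive")
  series$c_ex_Bq_per_m3 <- series$c_ex_Bq_per_m3 / c_water
  if (!is.null(bsa)) {
    if (bsa <= 0) stop("bsa must be positive")
    series$c_ex_Bq_per_m3 <- series$c_ex_Bq_per_m3 / bsa
  }
  series
}

#' Organ and tissue radon concentrations
#'
#' Converts compartment activities into concentrations `Q_i / V_i`
#' (Bq m^-3). The default selection covers the panel used to discuss organ
#' retention: respiratory-tract air, arterial blood, the two fat-like slow
#' compartments (fat 1 and exposed subcutaneous skin), kidneys and red
#' marrow.
#'
#' @param traj an `rn_trajectory`.
#' @param compartments compartment names; `NULL` selects all.
#' @return matrix (time x compartment) of concentrations in Bq m^-3.
#' @export
organ_concentrations <- function(traj, compartments = NULL) {
  stopifnot(inherits(traj, "rn_trajectory"))
  if (is.null(compartments)) compartments <- colnames(traj$states)
  missing <- setdiff(compartments, colnames(traj$states))
  if (length(missing) > 0)
    stop("unknown compartments: ", paste(missing, collapse = ", "))
  sweep(traj$states[, compartments, drop = FALSE], 2,
        traj$volumes[compartments], "/") * 1000
}

#' Default organ panel for retention plots
#' @return character vector of compartment names.
#' @export
organ_panel <- function() {
  c("rt_air", "blood_a", "fat_1", "ss_exp", "kidneys", "red_marrow")
}

#' Read and write exhalation series as CSV
#'
#' Columns `time_min`, `c_ex_Bq_per_m3`, `corrected` (0/1); comma separator,
#' `.` decimal, header mandatory.
#'
#' @param series an `exhalation_series`.
#' @param path file path.
#' @export
write_exhalation_csv <- function(series, path) {
  df <- data.frame(time_min = series$time_min,
                   c_ex_Bq_per_m3 = series$c_ex_Bq_per_m3,
                   corrected = as.integer(isTRUE(attr(series,
                                                      "dead_space_corrected"))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_exhalation_csv
#' @export
read_exhalation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "c_ex_Bq_per_m3")
  if (!all(need %in% names(df)))
    stop("malformed series CSV: expected columns ", paste(need, collapse = ", "))
  new_exhalation_series(df$time_min, df$c_ex_Bq_per_m3,
                        corrected = if ("corrected" %in% names(df))
                          all(df$corrected == 1) else TRUE)
}
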