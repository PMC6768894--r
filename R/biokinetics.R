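#' Time-dependent modulation of skin parameters during immersion
#'
#' During a warm bath the dermal permeability coefficient and the skin blood
#' flows rise with skin temperature, linearly from their baseline to
#' `ramp_factor` times the baseline over the first `ramp_end_min` minutes of
#' immersion, and stay at the plateau afterwards. In subjects whose exhalation
#' curves saturate, swelling of the stratum corneum additionally reduces the
#' permeability (but not the blood flow): from `swell_start_min` the
#' permeability multiplier declines linearly from `ramp_factor` to
#' `ramp_factor / swell_factor` at `swell_end_min` and is constant afterwards.
#' The dermal-subcutaneous transfer coefficient follows the permeability
#' multiplier with fractional strength `kds_coupling`:
#' `m_k = 1 + kds_coupling * (m_K - 1)`.
#'
#' If the subject was pre-heated in radon-free water the temperature ramp is
#' already complete at `t = 0` and both multipliers start at `ramp_factor`.
#'
#' @param t_min minutes since entering the water (vectorized, `>= 0`).
#' @param settings modulation settings list (`ramp_factor`, `ramp_end_min`,
#'   `swell_start_min`, `swell_factor`, `swell_end_min`, `kds_coupling`,
#'   `apply_swelling`), e.g. `rn_parameters()$modulation`.
#' @param preheated logical; start with the temperature ramp saturated.
#' @return list with numeric vectors `m_K` (permeability multiplier), `m_F`
#'   (skin blood-flow multiplier) and `m_k` (dermal-subcutaneous transfer
#'   multiplier), each the length of `t_min`.
#' @examples
#' m <- modulation(c(0, 10, 20), rn_parameters()$modulation)
#' m$m_K  # 1 at entry, 4 at the end of the ramp
#' @export
modulation <- function(t_min, settings, preheated = FALSE) {
  if (any(t_min < 0)) stop("immersion time must be non-negative")
  rf <- settings$ramp_factor
  ramp <- if (isTRUE(preheated)) {
    rep(rf, length(t_min))
  } else {
    1 + (rf - 1) * pmin(t_min / settings$ramp_end_min, 1)
  }
  m_f <- ramp
  m_k_perm <- ramp
  if (isTRUE(settings$apply_swelling)) {
    ss <- settings$swell_start_min
    se <- settings$swell_end_min
    lo <- rf / settings$swell_factor
    sw <- t_min > ss
    if (any(sw)) {
      frac <- if (se > ss) pmin((t_min[sw] - ss) / (se - ss), 1) else 1
      m_k_perm[sw] <- rf - (rf - lo) * frac
    }
  }
  list(m_K = m_k_perm, m_F = m_f,
       m_k = 1 + settings$kds_coupling * (m_k_perm - 1))
}

#' Assemble the compartmental rate matrix for one exposure phase
#'
#' Writes the coupled mass-balance equations of the model in the canonical
#' linear form `dQ/dt = A Q + b` (activities `Q` in Bq, rates in h^-1,
#' sources in Bq h^-1). Rows cover respiratory-tract air, arterial and venous
#' blood, the dermal and subcutaneous skin chains (water-exposed and
#' air-exposed, split in proportion to surface area), and one row per tissue
#' compartment:
#' * tissues gain from arterial blood at `F_i / V_BA` and lose to venous
#'   blood at `F_i / (P_i V_i)`;
#' * RT-air exchanges with the environment at `lambda_E` (scaled by the
#'   subject's respiratory minute volume), transfers to arterial blood at
#'   `F P_BA / V_RT` and is supplied from venous blood at `F / V_BV`;
#' * the exposed dermal skin takes up radon from water with flux
#'   `K A C_W` during bathing (permeability in m s^-1, area in m^2,
#'   concentration in Bq m^-3, converted to Bq h^-1) and releases it at
#'   `K A / (P_SW V_DS)`; in the resting phase the water source is replaced
#'   by exchange with room air at the dry-skin permeability
#'   `kappa_dry * K0` against `P_SA`; the air-exposed chain exchanges with
#'   room air in every phase;
#' * the dermal and subcutaneous chains exchange at the transfer coefficient
#'   `k_DS`; radioactive decay `lambda_r` acts on every compartment.
#'
#' During bath phases the permeability, the skin blood flows and `k_DS` are
#' scaled by [modulation()] evaluated at `t_phase_min`.
#'
#' @param params an [rn_parameters()] object.
#' @param subject an [rn_subject()]; its body surface area sets the total
#'   skin exchange area and its respiratory values set `lambda_E` and `V_RT`.
#' @param phase a phase list as built by [bath_scenario()] and friends
#'   (fields `kind`, `c_water`, `c_air`, `c_inhale`, `preheated`, optional
#'   `modulation` overrides).
#' @param t_phase_min time since the start of the phase (minutes), used for
#'   the modulation schedule in bath phases.
#' @param closed logical; drop every environment coupling (breathing source
#'   and loss, skin-water and skin-air exchange). With `lambda_r = 0` the
#'   resulting matrix has zero column sums: the closed system conserves
#'   total activity.
#' @return list with the rate matrix `A`, source vector `b`, compartment
#'   names, and the compartment volumes (litres).
#' @export
build_system <- function(params, subject, phase, t_phase_min = 0,
                         closed = FALSE) {
  kind <- phase$kind
  if (!kind %in% c("bath", "rest", "air_inhalation"))
    stop("unknown phase kind: ", kind)
  mod_set <- utils::modifyList(params$modulation, phase$modulation %||% list())
  m <- if (kind == "bath") {
    modulation(t_phase_min, mod_set, preheated = isTRUE(phase$preheated))
  } else {
    list(m_K = 1, m_F = 1, m_k = 1)
  }
  .assemble_system(params, subject, kind, m,
                   c_water = phase$c_water %||% 0,
                   c_air = phase$c_air %||% 0,
                   c_inhale = phase$c_inhale %||% (phase$c_air %||% 0),
                   closed = closed)
}

# Core matrix assembly. Concentrations in Bq m^-3; internal activities Bq,
# volumes litres, rates h^-1. The permeability flux K[m/s]*A[m2]*C[Bq/m3]
# converts to Bq/h via *3600; the back-transfer divides Q/V [Bq/l] and needs
# the additional factor 1000 l/m3.
.assemble_system <- function(params, subject, kind, m, c_water, c_air,
                             c_inhale, closed = FALSE) {
  sk <- params$skin
  bl <- params$blood
  ti <- params$tissues
  lambda_r <- params$physical$lambda_r_per_h
  Fco <- bl$cardiac_output_l_per_h
  v_ba <- bl$v_arterial_l
  v_bv <- bl$v_venous_l
  v_rt <- subject$v_rt_l
  rmv_ref <- if (subject$gender == "M") params$respiration$rmv_icrp_male_l_per_h
             else params$respiration$rmv_icrp_female_l_per_h
  lam_e <- params$respiration$lambda_e_per_d / 24 * subject$rmv_l_per_h / rmv_ref

  f_exp <- sk$exposed_fraction
  chains <- list()
  if (f_exp > 0)
    chains$exp <- list(frac = f_exp,
                       wet = kind == "bath")   # water contact during bath
  if (f_exp < 1)
    chains$non <- list(frac = 1 - f_exp, wet = FALSE)

  comp <- c("rt_air", "blood_a", "blood_v",
            unlist(lapply(names(chains), function(ch) paste0(c("ds_", "ss_"), ch))),
            ti$name)
  n <- length(comp)
  idx <- stats::setNames(seq_len(n), comp)
  A <- matrix(0, n, n, dimnames = list(comp, comp))
  b <- stats::setNames(numeric(n), comp)
  vols <- stats::setNames(numeric(n), comp)
  vols["rt_air"] <- v_rt
  vols["blood_a"] <- v_ba
  vols["blood_v"] <- v_bv

  rt <- idx["rt_air"]; ba <- idx["blood_a"]; bv <- idx["blood_v"]
  A[rt, rt] <- -Fco * bl$p_blood_air / v_rt - lambda_r
  if (!closed) {
    A[rt, rt] <- A[rt, rt] - lam_e
    b[rt] <- lam_e * (c_inhale / 1000) * v_rt
  }
  A[rt, bv] <- Fco / v_bv
  A[ba, rt] <- Fco * bl$p_blood_air / v_rt
  A[bv, bv] <- -Fco / v_bv - lambda_r

  flow_out_ba <- 0   # accumulated arterial outflow (l h^-1)

  for (i in seq_len(nrow(ti))) {
    r <- idx[ti$name[i]]
    Fi <- ti$flow_fraction[i] * Fco
    A[r, ba] <- Fi / v_ba
    A[r, r] <- -Fi / (ti$partition[i] * ti$volume_l[i]) - lambda_r
    A[bv, r] <- Fi / (ti$partition[i] * ti$volume_l[i])
    vols[r] <- ti$volume_l[i]
    flow_out_ba <- flow_out_ba + Fi
  }

  area_total <- subject$bsa_m2
  for (ch in names(chains)) {
    fr <- chains[[ch]]$frac
    wet <- chains[[ch]]$wet
    ds <- idx[paste0("ds_", ch)]; ss <- idx[paste0("ss_", ch)]
    v_ds <- sk$v_ds_l * fr
    v_ss <- sk$v_ss_l * fr
    vols[ds] <- v_ds; vols[ss] <- v_ss
    area <- area_total * fr
    F_ds <- m$m_F * sk$flow_fraction_ds * Fco * fr
    F_ss <- m$m_F * sk$flow_fraction_ss * Fco * fr
    k_ds <- m$m_k * sk$k_ds_per_h

    A[ds, ba] <- F_ds / v_ba
    A[ds, ds] <- -F_ds / (sk$p_dsb * v_ds) - k_ds - lambda_r
    A[ds, ss] <- k_ds
    A[bv, ds] <- F_ds / (sk$p_dsb * v_ds)
    A[ss, ba] <- F_ss / v_ba
    A[ss, ds] <- k_ds
    A[ss, ss] <- -F_ss / (sk$p_ssb * v_ss) - k_ds - lambda_r
    A[bv, ss] <- F_ss / (sk$p_ssb * v_ss)
    flow_out_ba <- flow_out_ba + F_ds + F_ss

    if (!closed) {
      if (wet) {
        kx <- m$m_K * sk$k0_m_per_s      # wet skin, temperature-modulated
        p_env <- sk$p_sw
        c_env <- c_water
      } else {
        kx <- sk$kappa_dry * sk$k0_m_per_s  # dry skin against room air
        p_env <- sk$p_sa
        c_env <- c_air
      }
      kw <- kx * area * 3600              # m^3 h^-1
      A[ds, ds] <- A[ds, ds] - kw * 1000 / (p_env * v_ds)
      b[ds] <- kw * c_env
    }
  }
  A[ba, ba] <- -flow_out_ba / v_ba - lambda_r

  list(A = A, b = b, compartments = comp, volumes = vols)
}

#' Simulate an exposure scenario
#'
#' Integrates the linear, time-varying compartment system over the ordered
#' phases of a scenario, starting (by default) from zero activity in every
#' compartment. Within each phase the coefficients are affine in time between
#' the modulation breakpoints (ramp end, swelling start and end), so the
#' integration is performed piecewise on those segments with the rate matrix
#' interpolated exactly; phase boundaries are never smoothed. A stiff-capable
#' adaptive integrator (`deSolve::lsoda`) is used.
#'
#' @param scenario an [rn_scenario()].
#' @param params an [rn_parameters()] object.
#' @param subject an [rn_subject()]; defaults to the reference female.
#' @param grid_min output resolution in minutes.
#' @param times_min optional explicit output times (minutes from scenario
#'   start); overrides `grid_min`.
#' @param state0 optional named initial state (Bq per compartment).
#' @param rtol,atol solver tolerances (relative, and absolute in Bq).
#' @param closed logical; integrate the closed system (all environment
#'   couplings removed), used for conservation checks.
#' @return an object of class `rn_trajectory`: time grid (minutes and hours),
#'   the matrix of compartment activities (Bq), phase boundary markers, the
#'   compartment volumes, and references to scenario, subject and parameters.
#' @examples
#' traj <- simulate_scenario(bath_scenario(), grid_min = 1)
#' max(traj$states[, "rt_air"])
#' @export
simulate_scenario <- function(scenario, params = rn_parameters(),
                              subject = reference_subject(params = params),
                              grid_min = 0.1, times_min = NULL, state0 = NULL,
                              rtol = 1e-8, atol = 1e-12, closed = FALSE) {
  stopifnot(inherits(scenario, "rn_scenario"))
  durations <- vapply(scenario$phases, function(p) p$duration_min, numeric(1))
  if (any(durations < 0)) stop("phase durations must be non-negative")
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  total <- ends[length(ends)]

  probe <- build_system(params, subject, scenario$phases[[1]], 0)
  comp <- probe$compartments
  n <- length(comp)
  y <- stats::setNames(numeric(n), comp)
  if (!is.null(state0)) {
    if (is.null(names(state0)) && length(state0) == n) names(state0) <- comp
    y[names(state0)] <- state0
  }

  out_times <- if (is.null(times_min)) {
    sort(unique(c(seq(0, total, by = grid_min), ends, starts)))
  } else {
    sort(unique(c(0, times_min)))
  }
  if (any(out_times < 0 | out_times > total + 1e-9))
    stop("requested output times outside the scenario span")

  states <- matrix(NA_real_, length(out_times), n,
                   dimnames = list(NULL, comp))
  states[1, ] <- y
  if (total == 0) {
    return(.new_trajectory(out_times, states, scenario, starts, ends,
                           params, subject, probe$volumes))
  }

  for (ip in seq_along(scenario$phases)) {
    phase <- scenario$phases[[ip]]
    if (phase$duration_min == 0) next
    mod_set <- utils::modifyList(params$modulation, phase$modulation %||% list())
    brk <- if (phase$kind == "bath") {
      c(if (!isTRUE(phase$preheated)) mod_set$ramp_end_min,
        if (isTRUE(mod_set$apply_swelling))
          c(mod_set$swell_start_min, mod_set$swell_end_min))
    } else NULL
    seg <- sort(unique(c(0, brk[brk > 0 & brk < phase$duration_min],
                         phase$duration_min)))
    for (is in seq_len(length(seg) - 1L)) {
      s0 <- seg[is]; s1 <- seg[is + 1L]
      sys0 <- build_system(params, subject, phase, s0, closed = closed)
      sys1 <- build_system(params, subject, phase, s1, closed = closed)
      t_abs0 <- starts[ip] + s0
      t_abs1 <- starts[ip] + s1
      sel <- out_times > t_abs0 + 1e-12 & out_times <= t_abs1 + 1e-12
      loc <- (out_times[sel] - t_abs0) / 60        # hours within segment
      dt_h <- (s1 - s0) / 60
      times <- sort(unique(c(0, loc, dt_h)))
      A0 <- sys0$A; A1 <- sys1$A; b0 <- sys0$b; b1 <- sys1$b
      dA <- (A1 - A0) / dt_h
      db <- (b1 - b0) / dt_h
      deriv <- function(t, yy, p) {
        list((A0 + t * dA) %*% yy + (b0 + t * db))
      }
      sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                            rtol = rtol, atol = atol, maxsteps = 50000)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("integration failed at t = %.3f min",
                     t_abs0 + 60 * sol[nrow(sol), 1]))
      ysol <- sol[, -1, drop = FALSE]
      ysol[ysol < 0 & ysol > -1e-6] <- 0   # solver-level negative round-off
      if (any(sel))
        states[sel, ] <- ysol[match(round(loc, 12), round(sol[, 1], 12)), ,
                              drop = FALSE]
      y <- ysol[nrow(ysol), ]
      names(y) <- comp
    }
  }
  .new_trajectory(out_times, states, scenario, starts, ends, params, subject,
                  probe$volumes)
}

.new_trajectory <- function(time_min, states, scenario, starts, ends,
                            params, subject, volumes) {
  phases <- data.frame(
    kind = vapply(scenario$phases, function(p) p$kind, character(1)),
    start_min = starts, end_min = ends)
  structure(list(time_min = time_min, time_h = time_min / 60, states = states,
                 phases = phases, scenario = scenario, params = params,
                 subject = subject, volumes = volumes),
            class = "rn_trajectory")
}

#' @export
print.rn_trajectory <- function(x, ...) {
  cat(sprintf("Radon biokinetic trajectory: '%s', %d compartments, %d time points over %.1f min\n",
              x$scenario$label, ncol(x$states), nrow(x$states),
              max(x$time_min)))
  cat("  phases:", paste(sprintf("%s [%g-%g min]", x$phases$kind,
                                 x$phases$start_min, x$phases$end_min),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rn_trajectory <- function(x, compartments = c("rt_air", "blood_a", "ss_exp"),
                               log = "", ...) {
  conc <- organ_concentrations(x, compartments = compartments)
  matplot(x$time_min, conc, type = "l", lty = 1,
          xlab = "time (min)", ylab = expression(Bq ~ m^-3), log = log, ...)
  graphics::legend("topright", legend = colnames(conc), lty = 1,
                   col = seq_len(ncol(conc)), bty = "n")
  graphics::abline(v = x$phases$end_min, lty = 3, col = "grey50")
  invisible(x)
}

#' Exact propagation of a frozen-coefficient system
#'
#' Closed-form solution of the affine system `dQ/dt = A Q + b` with constant
#' coefficients over a step `dt`, via the matrix exponential of the standard
#' augmented matrix `[[A, b], [0, 0]]`. Serves as an analytic oracle for the
#' numerical integrator; the augmented construction needs no invertibility
#' of `A`.
#'
#' @param A rate matrix (h^-1).
#' @param b source vector (Bq h^-1).
#' @param state0 initial activities (Bq).
#' @param dt_h step length (hours).
#' @return the propagated state vector.
#' @export
matrix_exponential_solution <- function(A, b, state0, dt_h) {
  n <- nrow(A)
  aug <- rbind(cbind(A, b), 0)
  prop <- as.matrix(Matrix::expm(Matrix::Matrix(aug * dt_h)))
  drop(prop[seq_len(n), , drop = FALSE] %*% c(state0, 1))
}

#' Steady state under constant inhalation
#'
#' Solves `A Q = -b` for the constant-coefficient air-inhalation phase: the
#' long-run activity distribution under continuous breathing of air at
#' concentration `c_e`, e.g. the environmental background level. With zero
#' decay every tissue satisfies the partition identity
#' `Q_i / V_i = P_i * Q_BA / V_BA`.
#'
#' @param params an [rn_parameters()] object.
#' @param subject an [rn_subject()].
#' @param c_e air radon concentration (Bq m^-3, `>= 0`).
#' @return named state vector (Bq per compartment) with the compartment
#'   volumes attached as attribute `volumes`.
#' @export
steady_state_inhalation <- function(params = rn_parameters(),
                                    subject = reference_subject(params = params),
                                    c_e = 100) {
  if (c_e < 0) stop("air concentration must be non-negative")
  phase <- list(kind = "air_inhalation", c_air = c_e, c_inhale = c_e,
                duration_min = Inf)
  sys <- build_system(params, subject, phase, 0)
  q <- tryCatch(solve(sys$A, -sys$b),
                error = function(e) stop("singular system matrix: ",
                                         conditionMessage(e)))
  structure(stats::setNames(q, sys$compartments), volumes = sys$volumes)
}
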