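#' Piecewise-frozen matrix-exponential reference solution
#'
#' Independent reference propagation of a scenario: the rate matrix is frozen
#' at the midpoint of short sub-steps and each step is propagated exactly
#' with [matrix_exponential_solution()]. Converges to the true solution as
#' the step shrinks and shares no code path with the adaptive integrator, so
#' it serves as the cross-check oracle for [simulate_scenario()].
#'
#' @param scenario an [rn_scenario()].
#' @param params an [rn_parameters()] object.
#' @param subject an [rn_subject()].
#' @param step_min sub-step length (minutes).
#' @param closed logical; propagate the closed system.
#' @return list with `time_min` and the matrix of compartment activities at
#'   the step boundaries.
#' @export
oracle_trajectory <- function(scenario, params = rn_parameters(),
                              subject = reference_subject(params = params),
                              step_min = 0.05, closed = FALSE) {
  durations <- vapply(scenario$phases, function(p) p$duration_min, numeric(1))
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  probe <- build_system(params, subject, scenario$phases[[1]], 0,
                        closed = closed)
  y <- stats::setNames(numeric(length(probe$compartments)),
                       probe$compartments)
  times <- 0
  states <- matrix(y, 1, dimnames = list(NULL, probe$compartments))
  for (ip in seq_along(scenario$phases)) {
    phase <- scenario$phases[[ip]]
    if (phase$duration_min == 0) next
    grid <- unique(c(seq(0, phase$duration_min, by = step_min),
                     phase$duration_min))
    for (is in seq_len(length(grid) - 1L)) {
      s0 <- grid[is]; s1 <- grid[is + 1L]
      sys <- build_system(params, subject, phase, (s0 + s1) / 2,
                          closed = closed)
      y <- matrix_exponential_solution(sys$A, sys$b, y, (s1 - s0) / 60)
      times <- c(times, starts[ip] + s1)
      states <- rbind(states, y)
    }
  }
  list(time_min = times, states = states)
}

#' Run the model property suite
#'
#' Checks the structural properties the compartment system must satisfy and
#' returns a pass/fail report:
#'
#' * closed-system conservation: with zero decay and all environment
#'   couplings removed, total activity is constant (relative drift below
#'   1e-8) over the standard bath scenario;
#' * superposition: trajectories are linear in the water concentration;
#' * oracle agreement: the adaptive integration matches the piecewise-frozen
#'   matrix-exponential reference within 1e-5 relative on the standard
#'   scenario;
#' * steady state: under constant inhalation with negligible decay every
#'   tissue reaches the partition equilibrium `Q_i/V_i = P_i Q_BA/V_BA`;
#' * resting decline: the exhaled concentration is strictly decreasing
#'   after leaving the bath;
#' * washout retention: the long inhalation-validation scenario runs to
#'   completion and late washout activity is dominated by the fat-like
#'   compartments (two-phase decline).
#'
#' @param params an [rn_parameters()] object.
#' @param subject an [rn_subject()].
#' @param quick logical; use a coarser oracle step (the default keeps each
#'   property under a few seconds).
#' @return an object of class `rn_validation`: data frame with columns
#'   `property`, `metric`, `value`, `threshold`, `pass`.
#' @export
validate_model <- function(params = rn_parameters(),
                           subject = reference_subject(params = params),
                           quick = TRUE) {
  rows <- list()
  add <- function(property, metric, value, threshold, pass)
    rows[[length(rows) + 1L]] <<- data.frame(property = property,
                                             metric = metric, value = value,
                                             threshold = threshold,
                                             pass = pass)
  scn <- bath_scenario()

  # conservation: closed system, no decay, positive initial state
  p0 <- params
  p0$physical$lambda_r_per_h <- 0
  sys <- build_system(p0, subject, scn$phases[[1]], 5, closed = TRUE)
  n <- length(sys$compartments)
  y0 <- stats::setNames(seq(1, 2, length.out = n), sys$compartments)
  traj <- simulate_scenario(scn, p0, subject, grid_min = 2, state0 = y0,
                            closed = TRUE)
  totals <- rowSums(traj$states)
  drift <- max(abs(totals - totals[1])) / totals[1]
  add("closed-system conservation", "max relative drift", drift, 1e-8,
      drift < 1e-8)
  colsum <- max(abs(colSums(sys$A)))
  add("closed-system column sums", "max |column sum|", colsum, 1e-10,
      colsum < 1e-10)

  # superposition in the water concentration
  t1 <- simulate_scenario(scn, params, subject, grid_min = 2)
  scn2 <- bath_scenario(c_water = 2 * 0.9e6, c_air = 0, c_mask = 0)
  scn1 <- bath_scenario(c_water = 0.9e6, c_air = 0, c_mask = 0)
  ta <- simulate_scenario(scn1, params, subject, grid_min = 2)
  tb <- simulate_scenario(scn2, params, subject, grid_min = 2)
  denom <- max(tb$states)
  superr <- max(abs(tb$states - 2 * ta$states)) / denom
  add("superposition in C_W", "max relative deviation", superr, 1e-6,
      superr < 1e-6)

  # oracle agreement on the standard scenario
  step <- if (quick) 0.05 else 0.02
  orc <- oracle_trajectory(scn, params, subject, step_min = step)
  sim <- simulate_scenario(scn, params, subject,
                           times_min = orc$time_min)
  keep <- match(round(orc$time_min, 9), round(sim$time_min, 9))
  ref <- orc$states
  num <- sim$states[keep, , drop = FALSE]
  scalemax <- max(ref)
  orcerr <- max(abs(num - ref)) / scalemax
  add("matrix-exponential oracle", "max relative deviation", orcerr, 1e-5,
      orcerr < 1e-5)

  # steady-state partition identity at negligible decay
  p0 <- params
  p0$physical$lambda_r_per_h <- 1e-12
  ss <- steady_state_inhalation(p0, subject, c_e = 100)
  vols <- attr(ss, "volumes")
  ti <- params$tissues
  conc_ba <- ss[["blood_a"]] / vols[["blood_a"]]
  ratio <- (ss[ti$name] / vols[ti$name]) / (ti$partition * conc_ba)
  sserr <- max(abs(ratio - 1))
  add("steady-state partition identity", "max |Q_i/(V_i P_i C_BA) - 1|",
      sserr, 1e-6, sserr < 1e-6)

  # strict decline of the exhaled concentration during rest
  cex <- exhaled_concentration(t1)
  rest <- cex$time_min > 20 & cex$time_min <= 40
  decl <- all(diff(cex$c_ex_Bq_per_m3[rest]) < 0)
  add("resting-phase decline", "all increments negative", as.numeric(decl),
      1, decl)

  # long washout: completes and fat-like compartments dominate late retention
  val <- inhalation_validation_scenario()
  tv <- simulate_scenario(val, params, subject, grid_min = 10)
  fat_cols <- intersect(c("fat_1", "ss_exp", "ss_non", "breast_a"),
                        colnames(tv$states))
  late <- which.min(abs(tv$time_min - 50 * 60))
  fat_share <- sum(tv$states[late, fat_cols]) / sum(tv$states[late, ])
  add("late washout fat dominance", "fat-like share at 50 h", fat_share,
      0.5, fat_share > 0.5)

  report <- do.call(rbind, rows)
  structure(report, class = c("rn_validation", "data.frame"))
}

#' @export
print.rn_validation <- function(x, ...) {
  cat("Model property suite:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-32s %s = %.3g (threshold %.3g)\n",
                if (x$pass[i]) "ok" else "FAIL", x$property[i], x$metric[i],
                x$value[i], x$threshold[i]))
  if (all(x$pass)) cat("all properties pass\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' `write_trajectory_csv()` writes the tidy long form (`time_min`,
#' `compartment`, `activity_Bq`); `as.data.frame` on a trajectory gives the
#' wide form.
#'
#' @param traj an `rn_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  comp <- colnames(traj$states)
  df <- data.frame(time_min = rep(traj$time_min, times = length(comp)),
                   compartment = rep(comp, each = length(traj$time_min)),
                   activity_Bq = as.vector(traj$states))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.rn_trajectory <- function(x, ...) {
  data.frame(time_min = x$time_min, x$states, check.names = FALSE)
}
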