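test_that("modulation follows the ramp, swelling and coupling schedule", {
  set_sw <- utils::modifyList(PARAMS$modulation, list(apply_swelling = TRUE))
  m0 <- modulation(0, PARAMS$modulation)
  expect_equal(c(m0$m_K, m0$m_F, m0$m_k), c(1, 1, 1))
  m10 <- modulation(10, PARAMS$modulation)
  expect_equal(c(m10$m_K, m10$m_F), c(4, 4))
  expect_equal(m10$m_k, 1 + 0.2 * (4 - 1))      # 20% coupling
  m5 <- modulation(5, PARAMS$modulation)
  expect_equal(m5$m_K, 2.5)                     # halfway up the ramp
  m20 <- modulation(20, set_sw)
  expect_equal(m20$m_K, 4 / 2.5)                # fully swollen
  expect_equal(m20$m_F, 4)                      # blood flow never declines
  m16 <- modulation(16.25, set_sw)
  expect_equal(m16$m_K, (4 + 1.6) / 2)          # midway through the decline
  mp <- modulation(0, PARAMS$modulation, preheated = TRUE)
  expect_equal(mp$m_K, 4)                       # ramp already complete
  expect_error(modulation(-1, PARAMS$modulation), "non-negative")
})

test_that("the closed system conserves activity and honours equilibria", {
  p0 <- PARAMS
  p0$physical$lambda_r_per_h <- 0
  phase <- bath_scenario()$phases[[1]]
  sys <- build_system(p0, REF_F, phase, t_phase_min = 5, closed = TRUE)
  expect_lt(max(abs(colSums(sys$A))), 1e-10)
  offdiag <- sys$A - diag(diag(sys$A))
  expect_true(all(offdiag >= 0))
  # tissue at blood-equilibrium concentration has zero net derivative
  ti <- p0$tissues[p0$tissues$name == "kidneys", ]
  q <- setNames(numeric(length(sys$compartments)), sys$compartments)
  q["blood_a"] <- 5
  q["kidneys"] <- ti$partition * ti$volume_l * 5 / p0$blood$v_arterial_l
  dq <- sys$A %*% q + sys$b
  expect_equal(dq[match("kidneys", sys$compartments)], 0, tolerance = 1e-12)
})

test_that("doubling the water concentration doubles the source, not the matrix", {
  ph1 <- rn_phase("bath", 20, c_water = 1e5, c_air = 0, c_inhale = 0)
  ph2 <- rn_phase("bath", 20, c_water = 2e5, c_air = 0, c_inhale = 0)
  s1 <- build_system(PARAMS, REF_F, ph1, 5)
  s2 <- build_system(PARAMS, REF_F, ph2, 5)
  expect_identical(s1$A, s2$A)
  expect_equal(s2$b, 2 * s1$b)
})

test_that("the matrix-exponential propagator matches trivial closed forms", {
  y0 <- c(a = 3, b = 1, c = 0.5)
  expect_equal(matrix_exponential_solution(matrix(0, 3, 3), rep(0, 3), y0, 2),
               unname(y0))
  lam <- 0.3
  out <- matrix_exponential_solution(diag(-lam, 3), rep(0, 3), y0, 1.5)
  expect_equal(out, unname(y0) * exp(-lam * 1.5), tolerance = 1e-12)
})

test_that("the matrix-exponential propagator agrees with a fine RK4 oracle", {
  for (seed in c(11, 23)) {
    A <- random_rate_matrix(5, seed)
    b <- runif(5, 0, 3)
    y0 <- runif(5, 0, 10)
    ref <- rk4_affine(A, b, y0, dt_h = 0.5, n_steps = 20000)
    out <- matrix_exponential_solution(A, b, y0, 0.5)
    expect_equal(out, ref, tolerance = 1e-8)
  }
})

test_that("simulation handles degenerate and analytic cases", {
  # zero-duration scenario returns the initial state unchanged
  scn0 <- rn_scenario(list(rn_phase("rest", 0)), "empty")
  comp <- build_system(PARAMS, REF_F, rn_phase("rest", 1), 0)$compartments
  y0 <- setNames(rep(2, length(comp)), comp)
  t0 <- simulate_scenario(scn0, PARAMS, REF_F, state0 = y0)
  expect_identical(nrow(t0$states), 1L)
  expect_equal(unname(t0$states[1, ]), unname(y0))
  # sources off, closed system, lambda_r > 0: pure exponential decay
  scn <- rn_scenario(list(rn_phase("rest", 120)), "decay")
  tr <- simulate_scenario(scn, PARAMS, REF_F, grid_min = 20, state0 = y0,
                          closed = TRUE)
  totals <- rowSums(tr$states)
  expect_equal(totals,
               totals[1] * exp(-PARAMS$physical$lambda_r_per_h * tr$time_h),
               tolerance = 1e-7)
})

test_that("a constant-coefficient interval matches the exact propagation", {
  scn <- rn_scenario(list(rn_phase("rest", 30, c_air = 100, c_inhale = 100)),
                     "rest only")
  probe <- build_system(PARAMS, REF_F, scn$phases[[1]], 0)
  y0 <- setNames(seq_along(probe$compartments) / 2, probe$compartments)
  tr <- simulate_scenario(scn, PARAMS, REF_F, grid_min = 30, state0 = y0)
  exact <- matrix_exponential_solution(probe$A, probe$b, y0, 0.5)
  expect_equal(unname(tr$states[nrow(tr$states), ]), unname(exact),
               tolerance = 1e-6)
})

test_that("piecewise-frozen exact propagation matches the adaptive solver", {
  scn <- bath_scenario()
  orc <- oracle_trajectory(scn, PARAMS, REF_F, step_min = 0.05)
  sim <- simulate_scenario(scn, PARAMS, REF_F, times_min = orc$time_min)
  keep <- match(round(orc$time_min, 9), round(sim$time_min, 9))
  expect_false(anyNA(keep))
  relerr <- max(abs(sim$states[keep, ] - orc$states)) / max(orc$states)
  expect_lt(relerr, 1e-5)
})

test_that("trajectories are linear in the source concentrations", {
  scn1 <- bath_scenario(c_water = 0.9e6, c_air = 0, c_mask = 0)
  scn2 <- bath_scenario(c_water = 1.8e6, c_air = 0, c_mask = 0)
  ta <- simulate_scenario(scn1, PARAMS, REF_F, grid_min = 2)
  tb <- simulate_scenario(scn2, PARAMS, REF_F, grid_min = 2)
  expect_lt(max(abs(tb$states - 2 * ta$states)) / max(tb$states), 1e-6)
  expect_true(all(ta$states >= 0))
})

test_that("constant inhalation converges to the algebraic steady state", {
  expect_equal(max(abs(steady_state_inhalation(PARAMS, REF_F, c_e = 0))), 0)
  # partition identity at negligible decay
  p0 <- PARAMS
  p0$physical$lambda_r_per_h <- 1e-12
  ss <- steady_state_inhalation(p0, REF_F, c_e = 100)
  vols <- attr(ss, "volumes")
  ti <- p0$tissues
  conc_ba <- ss[["blood_a"]] / vols[["blood_a"]]
  expect_equal(unname(ss[ti$name] / vols[ti$name]),
               ti$partition * conc_ba, tolerance = 1e-9)
  # dynamic long run reaches the steady state within 0.1%
  ssd <- steady_state_inhalation(PARAMS, REF_F, c_e = 100)
  tr <- simulate_scenario(environmental_scenario(100, 240), PARAMS, REF_F,
                          grid_min = 60)
  final <- tr$states[nrow(tr$states), names(ssd)]
  expect_equal(as.numeric(final / ssd), rep(1, length(ssd)), tolerance = 1e-3)
})

test_that("the immersed-fraction setting controls the skin chain structure", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(skin = list(exposed_fraction = 1.0))), cfg)
  p1 <- load_parameters(cfg)
  sys <- build_system(p1, REF_F, bath_scenario()$phases[[1]], 0)
  expect_false(any(c("ds_non", "ss_non") %in% sys$compartments))
  expect_true(all(c("ds_exp", "ss_exp") %in% sys$compartments))
  expect_error(build_system(PARAMS, REF_F,
                            list(kind = "sauna", duration_min = 5), 0),
               "unknown phase kind")
})
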