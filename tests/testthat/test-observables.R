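test_that("exhaled concentration is the RT-air concentration in Bq m^-3", {
  tr <- simulate_scenario(bath_scenario(), PARAMS, REF_F, grid_min = 1)
  cex <- exhaled_concentration(tr)
  expect_equal(cex$c_ex_Bq_per_m3,
               unname(tr$states[, "rt_air"] / REF_F$v_rt_l * 1000))
  # 1 Bq per litre of RT air is 1000 Bq m^-3
  i <- which.max(tr$states[, "rt_air"])
  expect_equal(cex$c_ex_Bq_per_m3[i],
               unname(tr$states[i, "rt_air"]) / REF_F$v_rt_l * 1000)
  # the maximum occurs at the end of the bath phase
  expect_equal(cex$time_min[which.max(cex$c_ex_Bq_per_m3)], 20)
})

test_that("dead-space dilution follows (V_T - V_D)/V_T", {
  expect_equal(dead_space_factor(0.56, 0), 1.0)
  expect_equal(dead_space_factor(0.56, 0.110), 0.45 / 0.56)
  expect_equal(round(dead_space_factor(0.56, 0.110), 4), 0.8036)
  expect_equal(round(dead_space_factor(0.72, 0.110), 4), 0.8472)
  expect_error(dead_space_factor(0.5, 0.5), "smaller than")
  expect_error(dead_space_factor(0.5, -0.1), "non-negative")
  # dilution followed by correction is the identity
  s <- new_exhalation_series(c(2, 6, 10), c(100, 300, 500), corrected = TRUE)
  rt <- correct_series(dilute_series(s, 0.56, 0.110), 0.56, 0.110)
  expect_equal(rt$c_ex_Bq_per_m3, s$c_ex_Bq_per_m3)
  expect_true(attr(rt, "dead_space_corrected"))
})

test_that("radon transfer reproduces closed forms and quadrature properties", {
  # all-zero series
  z <- new_exhalation_series(seq(0, 40, 4), rep(0, 11), corrected = TRUE)
  expect_equal(radon_transfer(z, rmv = 514, t1 = 0, t2 = 40)$rt_Bq, 0)
  # constant concentration: rectangle value RMV * C * dt
  s <- new_exhalation_series(seq(0, 40, 4), rep(1000, 11), corrected = TRUE)
  expect_equal(radon_transfer(s, rmv = 514, t1 = 0, t2 = 40)$rt_Bq,
               0.514 * 1000 * 40 / 60, tolerance = 1e-12)
  # piecewise-linear series: trapezoid equals fine-grid quadrature
  set.seed(4)
  tt <- seq(0, 40, 4)
  cc <- cumsum(runif(11, 0, 200))
  pw <- new_exhalation_series(tt, cc, corrected = TRUE)
  fine_t <- seq(0, 40, 0.01)
  fine_c <- approx(tt, cc, xout = fine_t)$y
  fine <- sum(diff(fine_t / 60) * (head(fine_c, -1) + fine_c[-1]) / 2) * 0.514
  expect_equal(radon_transfer(pw, 514, t1 = 0, t2 = 40)$rt_Bq, fine,
               tolerance = 1e-3)
  # additivity over a split window on a shared grid
  whole <- radon_transfer(pw, 514, t1 = 0, t2 = 40)$rt_Bq
  left <- radon_transfer(pw, 514, t1 = 0, t2 = 20)$rt_Bq
  right <- radon_transfer(pw, 514, t1 = 20, t2 = 40)$rt_Bq
  expect_equal(left + right, whole, tolerance = 1e-12)
  # window validation
  expect_error(radon_transfer(pw, 514, t1 = 10, t2 = 5), "empty")
  expect_error(radon_transfer(pw, 514, t1 = -5, t2 = 20), "outside")
})

test_that("radon transfer scales linearly with the water concentration", {
  s1 <- generate_exhalation_series(REF_F, bath_scenario(c_water = 0.9e6,
                                                        c_air = 0, c_mask = 0),
                                   PARAMS, noise_cv = 0)
  s2 <- generate_exhalation_series(REF_F, bath_scenario(c_water = 1.8e6,
                                                        c_air = 0, c_mask = 0),
                                   PARAMS, noise_cv = 0)
  r1 <- radon_transfer(s1, REF_F$rmv_l_per_h)$rt_Bq
  r2 <- radon_transfer(s2, REF_F$rmv_l_per_h)$rt_Bq
  expect_equal(r2 / r1, 2, tolerance = 1e-6)
})

test_that("normalization divides by water concentration and body surface", {
  s <- new_exhalation_series(c(2, 6), c(900, 1800), corrected = TRUE)
  expect_equal(normalize_series(s, c_water = 1)$c_ex_Bq_per_m3, c(900, 1800))
  n <- normalize_series(s, c_water = 0.9)
  expect_equal(n$c_ex_Bq_per_m3, c(1000, 2000))
  nb <- normalize_series(s, c_water = 0.9, bsa = 2)
  expect_equal(nb$c_ex_Bq_per_m3, c(500, 1000))
  expect_error(normalize_series(s, c_water = 0), "positive")
})

test_that("the Grunewald-style rescaling is exact proportionality", {
  expect_equal(rescale_radon_transfer(1000, c_from = 2, c_to = 0.9), 450)
  expect_equal(rescale_radon_transfer(450, c_from = 0.9, c_to = 2), 1000)
})

test_that("organ concentrations contrast fast and fat-buffered compartments", {
  tr <- simulate_scenario(bath_scenario(), PARAMS, REF_F, grid_min = 0.5)
  oc <- organ_concentrations(tr, c("kidneys", "fat_1", "rt_air"))
  t20 <- match(20, tr$time_min)
  t22 <- match(22, tr$time_min)
  t25 <- match(25, tr$time_min)
  # kidneys track blood and drop immediately after the end of the bath
  expect_lt(oc[t22, "kidneys"], 0.7 * oc[t20, "kidneys"])
  # fat 1 stays near its maximum for several minutes into the rest phase
  expect_gt(oc[t25, "fat_1"], 0.85 * max(oc[, "fat_1"]))
  expect_error(organ_concentrations(tr, "spleen"), "unknown compartments")
  # zero trajectory maps to zero concentrations
  z <- tr
  z$states[] <- 0
  expect_true(all(organ_concentrations(z) == 0))
})

test_that("a day of background inhalation restores non-fat organs to the environmental level", {
  tr <- simulate_scenario(environmental_scenario(100, 24), PARAMS, REF_F,
                          grid_min = 30)
  ss <- steady_state_inhalation(PARAMS, REF_F, 100)
  final <- tr$states[nrow(tr$states), names(ss)]
  nonfat <- setdiff(names(ss), c("fat_1", "ss_exp", "ss_non", "breast_a"))
  expect_true(all(abs(final[nonfat] / ss[nonfat] - 1) < 0.05))
})

test_that("exhalation series round-trip through CSV", {
  s <- new_exhalation_series(c(2, 6, 10), c(100, 300, 500), corrected = TRUE)
  path <- tempfile(fileext = ".csv")
  write_exhalation_csv(s, path)
  r <- read_exhalation_csv(path)
  expect_equal(r$time_min, s$time_min)
  expect_equal(r$c_ex_Bq_per_m3, s$c_ex_Bq_per_m3)
  expect_true(attr(r, "dead_space_corrected"))
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_exhalation_csv(bad), "malformed")
})
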