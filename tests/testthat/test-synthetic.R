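test_that("the Mosteller formula reproduces the printed surface areas", {
  expect_equal(round(mosteller_bsa(168, 58), 2), 1.65)   # subject 1
  expect_equal(round(mosteller_bsa(184, 90), 2), 2.14)   # subject 5
  expect_equal(mosteller_bsa(60, 60), 1.0)               # height*mass = 3600
  expect_error(mosteller_bsa(-1, 60), "positive")
})

test_that("the shipped study tables carry the printed values", {
  sub <- table_subjects()
  expect_equal(nrow(sub), 6)
  expect_equal(sub$rmv_l_per_h[sub$sn == 2], 640)
  expect_equal(sub$v_rt_l[sub$sn == 6], 4.14)
  expect_equal(sub$bsa_m2, round(mosteller_bsa(sub$height_cm, sub$mass_kg), 2))
  wat <- table_water_concentrations()
  expect_equal(nrow(wat), 11)
  expect_equal(wat$c_water_MBq_per_m3[wat$sn == 3], 0.960)
  rt <- table_radon_transfer()
  expect_equal(nrow(rt), 11)
  expect_equal(sum(rt$session_type == "bath20"), 7)
  # every subject profile passes the subject invariants
  for (sn in sub$sn) expect_s3_class(subject_from_table(sn), "rn_subject")
})

test_that("fixture tables are unmodified (checksum pin)", {
  files <- c(subjects_table.csv = "45ae73e9b5328904594df65b6071f20b",
             water_concentrations.csv = "618f0b8370b8ae6cf2fab1244fdb5e65",
             radon_transfer_table.csv = "47431e49d034b00727b2d5c544efe00a")
  for (f in names(files)) {
    path <- system.file("extdata", f, package = "radonskin")
    expect_identical(unname(tools::md5sum(path)), unname(files[[f]]),
                     label = f)
  }
})

test_that("generated subjects stay inside the per-gender study ranges", {
  tab <- table_subjects()
  for (g in c("F", "M")) {
    sub <- generate_subject(g, seed = 99)
    rows <- tab[tab$gender == g, ]
    expect_gte(sub$height_cm, min(rows$height_cm))
    expect_lte(sub$height_cm, max(rows$height_cm))
    expect_gte(sub$v_t_l, min(rows$v_t_l))
    expect_lte(sub$v_t_l, max(rows$v_t_l))
    expect_equal(sub$bsa_m2, mosteller_bsa(sub$height_cm, sub$mass_kg))
    expect_equal(sub$rmv_l_per_h, sub$v_t_l * sub$rf_per_min * 60)
  }
  # female BSA implied by the table ranges
  f <- generate_subject("F", seed = 3)
  expect_gte(f$bsa_m2, sqrt(160 * 52 / 3600) - 1e-9)
  expect_lte(f$bsa_m2, sqrt(168 * 62 / 3600) + 1e-9)
  # determinism under a fixed seed
  expect_identical(generate_subject("F", seed = 42),
                   generate_subject("F", seed = 42))
})

test_that("noise-free synthetic series equal the model curve at the protocol times", {
  scn <- bath_scenario()
  expect_equal(protocol_sampling_times(scn),
               c(2, 6, 10, 14, 18, 22, 26, 30, 34, 38))
  ser <- generate_exhalation_series(REF_F, scn, PARAMS, noise_cv = 0)
  tr <- simulate_scenario(scn, PARAMS, REF_F, grid_min = 0.5)
  model <- exhaled_concentration(tr)
  expect_equal(ser$c_ex_Bq_per_m3, cex_at(model, ser$time_min),
               tolerance = 1e-9)
  expect_true(attr(ser, "dead_space_corrected"))
  # measured mode applies the subject's dead-space dilution
  raw <- generate_exhalation_series(REF_F, scn, PARAMS, noise_cv = 0,
                                    as_measured = TRUE)
  f <- dead_space_factor(REF_F$v_t_l, PARAMS$instrument$v_dead_l)
  expect_equal(raw$c_ex_Bq_per_m3, ser$c_ex_Bq_per_m3 * f, tolerance = 1e-9)
  expect_false(attr(raw, "dead_space_corrected"))
})

test_that("synthetic series are reproducible and carry the stated noise level", {
  scn <- bath_scenario()
  a <- generate_exhalation_series(REF_F, scn, PARAMS, noise_cv = 0.1, seed = 5)
  b <- generate_exhalation_series(REF_F, scn, PARAMS, noise_cv = 0.1, seed = 5)
  expect_identical(a$c_ex_Bq_per_m3, b$c_ex_Bq_per_m3)
  # short protocol keeps the ensemble affordable; the noise model is the same
  short <- rn_scenario(list(rn_phase("bath", 8, c_water = 0.9e6, c_air = 100,
                                     c_inhale = 10),
                            rn_phase("rest", 8, c_air = 100, c_inhale = 10)),
                       "short")
  set.seed(11)
  reps <- replicate(300, generate_exhalation_series(REF_F, short, PARAMS,
                                                    noise_cv = 0.1)$c_ex_Bq_per_m3)
  cv <- apply(reps, 1, function(x) sd(x) / mean(x))
  expect_true(all(abs(cv - 0.10) < 0.015))
  # unit-mean noise: ensemble mean matches the noise-free curve within 3 SE
  clean <- generate_exhalation_series(REF_F, short, PARAMS, noise_cv = 0)
  se <- 0.1 / sqrt(300)
  expect_true(all(abs(rowMeans(reps) / clean$c_ex_Bq_per_m3 - 1) < 3 * se))
})
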