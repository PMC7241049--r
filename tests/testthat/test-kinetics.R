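test_that("the rate law obeys half-saturation, saturation and monotonicity", {
  expect_equal(mm_rate(3, 10, 3), 5)  # S = K_S gives Vmax/2
  expect_equal(mm_rate(10.6, 53.9, 10.6), 53.9 / 2)
  expect_equal(mm_rate(1e9, 53.9, 10.6), 53.9, tolerance = 1e-6)
  s <- seq(0, 50, length.out = 100)
  v <- mm_rate(s, 10, 3)
  expect_true(all(diff(v) > 0))          # monotone
  expect_true(all(diff(diff(v)) < 0))    # concave
  expect_true(all(v <= 10))
  expect_equal(mm_rate(5, 0, 0), 0)
  expect_error(mm_rate(0, 5, 0), "0/0")
  expect_error(mm_rate(-1, 5, 1), ">= 0")
})

test_that("dilution correction reproduces the simulator's consumption ledger", {
  sim <- simulate_incubation(10, 3, schedule = seq(0, 96, 12))
  dc <- dilution_correct(sim)
  expect_equal(dc$consumed_nmol, sim$truth$consumed_interval,
               tolerance = 1e-6)
  # no consumption and replacement equal to chamber water: zero consumed
  ch0 <- chamber_config(replacement = c(ch4 = chamber_config()$init_ch4_uM,
                                        co2 = 16, o2 = 283))
  sim0 <- simulate_incubation(0, 0, ch0, schedule = seq(0, 48, 12))
  expect_equal(dilution_correct(sim0)$consumed_nmol, rep(0, 4),
               tolerance = 1e-9)
  # zero withdrawal reduces to naive differencing
  chn <- chamber_config(withdrawal_mL = 0)
  simn <- simulate_incubation(10, 3, chn, schedule = seq(0, 48, 12))
  dcn <- dilution_correct(simn)
  naive <- -diff(simn$conc$ch4) * simn$water_volume
  expect_equal(dcn$consumed_nmol, naive)
})

test_that("blank correction recovers sediment-only consumption", {
  expect_warning(blank_correct(data.frame(consumed_nmol = 1, dt = 1), NULL),
                 "no blank")
  ch <- chamber_config(); chb <- chamber_config(sediment_mass_g = 0)
  sch <- seq(0, 48, 12)
  sed <- simulate_incubation(2, 3, ch, schedule = sch, seed = 1)
  rates <- dilution_correct(sed)
  # blank equal to the sediment chamber zeroes everything
  z <- blank_correct(rates, rates)
  expect_equal(z$consumed_nmol, rep(0, nrow(rates)))
  # 10% streamwater MOX split between chambers: correction recovers the
  # sediment-only truth within 2% while concentrations stay comparable
  aw <- 0.1 * ch$sediment_area_m2 * 2 / ch$water_volume_mL
  sedw <- simulate_incubation(2, 3, ch, schedule = sch, water_vmax = aw,
                              water_ks = 3, seed = 1)
  bl <- simulate_incubation(0, 3, chb, schedule = sch, blank = TRUE,
                            water_vmax = aw, water_ks = 3, seed = 2)
  corrected <- suppressWarnings(
    blank_correct(dilution_correct(sedw), dilution_correct(bl)))
  pure <- dilution_correct(simulate_incubation(2, 3, ch, schedule = sch,
                                               seed = 1))
  expect_equal(corrected$consumed_nmol, pure$consumed_nmol,
               tolerance = 0.02)
})

test_that("trajectory fits recover the planted parameters", {
  reps <- lapply(1:3, function(r)
    simulate_incubation(10, 3, schedule = seq(0, 96, 12), site_id = "s",
                        replicate = r))
  fit <- mm_kinetics(reps)
  expect_s3_class(fit, "mm_kinetics")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(10, 3), tolerance = 0.01)
  expect_equal(predict(fit, S = 3), fit$vmax * 3 / (fit$ks + 3))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  s <- summary(fit)
  expect_s3_class(s, "summary.mm_kinetics")
})

test_that("pointwise mode agrees with trajectory mode on dense series", {
  reps <- lapply(1:3, function(r)
    simulate_incubation(8, 4, schedule = seq(0, 96, 6), site_id = "s",
                        replicate = r))
  ft <- mm_kinetics(reps, mode = "trajectory")
  fp <- mm_kinetics(reps, mode = "pointwise")
  expect_equal(unname(coef(fp)), unname(coef(ft)), tolerance = 0.05)
})

test_that("zero-consumption series return the no-MOX convention", {
  reps <- lapply(1:3, function(r)
    simulate_incubation(0, 0, schedule = seq(0, 96, 12), replicate = r))
  fit <- mm_kinetics(reps)
  expect_equal(unname(coef(fit)), c(0, 0))
  expect_true(fit$converged)
})

test_that("fitted K_S is invariant to rescaling sediment area", {
  sim <- simulate_incubation(10, 3, schedule = seq(0, 96, 12))
  f1 <- mm_kinetics(sim)
  sim2 <- sim
  sim2$sediment_area <- sim$sediment_area * 2
  f2 <- mm_kinetics(sim2)
  expect_equal(f2$ks, f1$ks, tolerance = 1e-4)
  expect_equal(f2$vmax, f1$vmax / 2, tolerance = 1e-4)
})

test_that("direct rate points can be fit and V(K_S) = Vmax/2 holds", {
  pts <- data.frame(S = c(0.5, 1, 2, 4, 8, 16),
                    V = mm_rate(c(0.5, 1, 2, 4, 8, 16), 12, 2.5))
  fit <- mm_kinetics(pts)
  expect_equal(unname(coef(fit)), c(12, 2.5), tolerance = 1e-3)
  expect_equal(predict(fit, S = fit$ks), fit$vmax / 2)
})

test_that("in-situ rates and carbon fixation follow the worked arithmetic", {
  # evaluated at S = K_S with the panel maxima, the putative in-situ rate
  # rounds to 27 nmol CH4 m-2 h-1 and fixes 13.5 nmol C m-2 h-1 at CUE 0.5
  r <- in_situ_rate(list(vmax = 53.9, ks = 10.6), 10.6)
  expect_equal(r, 26.95)
  expect_equal(round(r), 27)
  expect_equal(carbon_fixation(27, 0.5), 13.5)
  expect_equal(carbon_fixation(0), 0)
  expect_equal(carbon_fixation(11, 1), 11)
  expect_error(carbon_fixation(1, 1.2), "cue")
  expect_equal(in_situ_rate(list(vmax = 0, ks = 0), 5), 0)
  expect_equal(in_situ_rate(list(vmax = 10, ks = 3), 0), 0)
})

test_that("per-area normalization is a plain division", {
  expect_equal(normalize_per_area(100, 2), 50)
  expect_equal(normalize_per_area(0, 2), 0)
  expect_equal(normalize_per_area(10, 4), normalize_per_area(10, 2) / 2)
  expect_error(normalize_per_area(1, 0), "positive")
})

test_that("simulate method regenerates series under the fitted parameters", {
  sim <- simulate_incubation(10, 3, schedule = seq(0, 96, 12))
  fit <- mm_kinetics(sim)
  new <- simulate(fit, nsim = 2, seed = 9)
  expect_length(new, 2)
  expect_s3_class(new[[1]], "incubation_series")
  refit <- mm_kinetics(new)
  expect_equal(unname(coef(refit)), unname(coef(fit)), tolerance = 0.02)
})
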