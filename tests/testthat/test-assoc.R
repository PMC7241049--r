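test_that("linear association equals the closed-form OLS solution", {
  set.seed(5)
  x <- setNames(rnorm(12), paste0("s", 1:12))
  y <- 1.5 + 2 * x + rnorm(12, 0, 0.3)
  fit <- fit_linear(x, y, labels = c("x", "y"))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$r2, r2, tolerance = 1e-10)
  exact <- suppressWarnings(fit_linear(x, 2 * x, labels = c("x", "y")))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r2, 1)
  expect_error(fit_linear(setNames(rep(1, 5), letters[1:5]),
                          setNames(rnorm(5), letters[1:5])), "constant")
})

test_that("exclusions change only through the excluded rows", {
  set.seed(6)
  x <- setNames(rnorm(10), paste0("s", 1:10))
  y <- setNames(2 * x + rnorm(10, 0, 0.1), names(x))
  full <- fit_linear(x, y, labels = c("x", "y"))
  excl <- fit_linear(x, y, exclude = c("s1", "s2"), labels = c("x", "y"))
  expect_equal(excl$n, 8)
  expect_equal(excl$excluded_sites, "s1,s2")
  manual <- fit_linear(x[-(1:2)], y[-(1:2)], labels = c("x", "y"))
  expect_equal(excl$slope, manual$slope)
  # re-including reproduces the unexcluded fit
  again <- fit_linear(x, y, exclude = character(0), labels = c("x", "y"))
  expect_equal(again$slope, full$slope)
  expect_error(fit_linear(x, y, exclude = paste0("s", 1:8)), "at least 3")
})

test_that("slope p-values are uniform under the null", {
  set.seed(7)
  x <- setNames(rnorm(20), paste0("s", 1:20))
  p <- vapply(1:400, function(i) {
    fit_linear(x, setNames(rnorm(20), names(x)), labels = c("x", "y"))$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Vmax tracks streamwater CH4 on the synthetic panel", {
  panel <- default_panel()
  v <- setNames(panel$truth$vmax, panel$truth$site_id)
  cs <- setNames(panel$sites$ch4_stream, panel$sites$site_id)
  fit <- fit_linear(cs, v, labels = c("ch4_stream", "vmax"))
  expect_gt(fit$r2, 0.9)
  expect_gt(fit$slope, 0)
})

test_that("K_S sits near the porewater CH4 concentration", {
  panel <- default_panel()
  fits <- data.frame(site_id = panel$truth$site_id,
                     vmax = panel$truth$vmax, ks = panel$truth$ks)
  low <- panel$truth$site_id[panel$truth$special == "low_pore"]
  kr <- ks_vs_porewater_ratio(fits, panel$sites, exclude = low)
  expect_gt(kr$mean, 50)
  expect_lt(kr$mean, 150)
  # hand-checkable cases
  f1 <- data.frame(site_id = "a", vmax = 5, ks = 2)
  s1 <- data.frame(site_id = "a", ch4_pore = 2)
  expect_equal(ks_vs_porewater_ratio(f1, s1)$per_site$pct, 100)
  f0 <- data.frame(site_id = c("a", "b"), vmax = c(5, 0), ks = c(0, 3))
  s0 <- data.frame(site_id = c("a", "b"), ch4_pore = c(2, 2))
  kr0 <- ks_vs_porewater_ratio(f0, s0)
  expect_equal(kr0$per_site$pct, 0)      # ks = 0 gives 0%
  expect_equal(nrow(kr0$per_site), 1)    # vmax = 0 site auto-excluded
  expect_error(ks_vs_porewater_ratio(f0[2, ], s0), "excluded")
})

test_that("pmoA fractions are percentages with censoring propagation", {
  expect_equal(pmoa_fraction(1e8, 1e8), 100)
  expect_equal(pmoa_fraction(0, 1e8), 0)
  expect_equal(pmoa_fraction(2.65e6, 1e8), 2.65)
  expect_true(is.na(pmoa_fraction(NA, 1e8)))
  expect_error(pmoa_fraction(1, 0), "positive")
})

test_that("the association battery runs with per-analysis exclusions", {
  panel <- default_panel()
  fits <- data.frame(site_id = panel$truth$site_id,
                     vmax = panel$truth$vmax, ks = panel$truth$ks)
  wet <- panel$truth$site_id[panel$truth$special == "wetland"]
  tab <- associate(panel$sites, fits, exclude = list(default = wet))
  expect_s3_class(tab, "data.frame")
  expect_true(all(c("ch4_stream", "ch4_pore") %in% tab$predictor))
  expect_true(all(tab$excluded_sites == wet))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  tadj <- associate(panel$sites, fits, p_adjust = "BH")
  expect_true("p_adj" %in% names(tadj))
  expect_true(all(tadj$p_adj >= tadj$p - 1e-12))
})
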