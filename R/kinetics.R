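#' Michaelis-Menten rate law
#'
#' \eqn{V = V_{max} S / (K_S + S)}: the methane-oxidation velocity at
#' substrate concentration S. Monotone increasing and concave in S, bounded
#' by `vmax`, and equal to `vmax/2` at `S = ks`.
#'
#' @param S substrate (CH4) concentration, uM; vectorized.
#' @param vmax maximum velocity, nmol m-2 h-1.
#' @param ks half-saturation constant, uM.
#' @return rate in the units of `vmax`.
#' @examples
#' mm_rate(3, 10, 3)  # half saturation: 5
#' @export
mm_rate <- function(S, vmax, ks) {
  if (any(S < 0) || vmax < 0 || ks < 0) stop("mm_rate: inputs must be >= 0")
  if (vmax == 0) return(rep(0, length(S)))
  if (ks == 0 && any(S == 0))
    stop("mm_rate: 0/0 form (ks = 0 and S = 0) - invalid parameters")
  vmax * S / (ks + S)
}

#' Per-interval consumption with dilution correction
#'
#' Converts a chamber concentration time series into per-interval consumed
#' CH4 amounts, correcting for the withdrawal/replacement sampling events.
#' For the interval opening at sampling time \eqn{t_i}, the start
#' concentration is adjusted by the event jump
#' \eqn{C (V_w - v)/V_w + C_{repl} v / V_w} and the consumed amount is
#' \eqn{V_w (C^{adj}_{start} - C_{end})} (nmol). The interval-representative
#' substrate concentration is the geometric mean of adjusted start and end
#' concentrations (concentration decays roughly exponentially when
#' \eqn{S \ll K_S}).
#'
#' @param series an [incubation_series()] (or simulated equivalent).
#' @param analyte which analyte to difference (default CH4).
#' @return data frame with one row per interval: `t0`, `t1`, `dt` (h), `S`
#'   (uM), `consumed_nmol`, `rate_nmol_h` (per chamber, not per area), and
#'   `o2_limited` (TRUE when dissolved O2 dropped below 50 uM in the
#'   interval, a quality-control flag).
#' @export
dilution_correct <- function(series, analyte = "ch4") {
  stopifnot(inherits(series, "incubation_series"))
  conc <- series$conc[[analyte]]
  times <- series$times
  vw <- series$water_volume
  ev <- series$events
  n <- length(times)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    j <- which(abs(ev$time_h - times[i]) < 1e-9)
    c_start <- conc[i]
    if (length(j) == 1 && ev$withdrawn_mL[j] > 0) {
      repl_col <- paste0("repl_", analyte)
      if (is.null(ev[[repl_col]]) || is.na(ev[[repl_col]][j]))
        stop("missing replacement concentration for event at t = ",
             ev$time_h[j], " h")
      v <- ev$withdrawn_mL[j]
      c_start <- c_start * (vw - v) / vw + ev[[repl_col]][j] * v / vw
    }
    c_end <- conc[i + 1]
    o2 <- series$conc$o2[c(i, i + 1)]
    out[[i]] <- data.frame(
      t0 = times[i], t1 = times[i + 1], dt = times[i + 1] - times[i],
      S = sqrt(max(c_start, 0) * max(c_end, 0)),
      consumed_nmol = vw * (c_start - c_end),
      o2_limited = isTRUE(any(o2 < 50)))
  }
  out <- do.call(rbind, out)
  out$rate_nmol_h <- out$consumed_nmol / out$dt
  out
}

#' Blank correction of per-interval consumption
#'
#' Subtracts the interval-matched mean consumption of sediment-free blank
#' chambers (streamwater community activity) from a sediment chamber's
#' per-interval consumption. Amounts are per chamber (nmol), i.e. before any
#' per-area normalization. Corrected consumptions are floored at zero with a
#' warning if the blanks exceed the sediment chambers.
#'
#' @param rates data frame from [dilution_correct()] for a sediment chamber.
#' @param blank_rates one data frame, or a list of data frames, from
#'   [dilution_correct()] applied to blank chambers; `NULL` or empty gives a
#'   pass-through with a warning.
#' @return `rates` with corrected `consumed_nmol` and `rate_nmol_h`.
#' @export
blank_correct <- function(rates, blank_rates) {
  if (is.null(blank_rates) || length(blank_rates) == 0) {
    warning("no blank chambers available; returning uncorrected rates")
    return(rates)
  }
  if (is.data.frame(blank_rates)) blank_rates <- list(blank_rates)
  nb <- vapply(blank_rates, nrow, integer(1))
  if (any(nb != nrow(rates)))
    stop("blank chambers must have the same sampling intervals")
  blank_mean <- Reduce(`+`, lapply(blank_rates, `[[`, "consumed_nmol")) /
    length(blank_rates)
  corrected <- rates$consumed_nmol - blank_mean
  if (any(corrected < -1e-9 * max(abs(rates$consumed_nmol), 1)))
    warning("blank consumption exceeds sediment-chamber consumption in ",
            sum(corrected < 0), " interval(s); flooring at 0")
  rates$consumed_nmol <- pmax(corrected, 0)
  rates$rate_nmol_h <- rates$consumed_nmol / rates$dt
  rates
}

# exact model prediction of the measured concentrations of one chamber:
# propagate the Michaelis-Menten state through the event ledger
.predict_trajectory <- function(series, vmax, ks, c0 = NULL) {
  times <- series$times
  vw <- series$water_volume
  a <- series$sediment_area * vmax / vw
  ev <- series$events
  state <- c0 %||% series$conc$ch4[1]
  pred <- numeric(length(times))
  pred[1] <- state
  for (i in seq_len(length(times) - 1)) {
    j <- which(abs(ev$time_h - times[i]) < 1e-9)
    if (length(j) == 1 && ev$withdrawn_mL[j] > 0) {
      v <- ev$withdrawn_mL[j]
      state <- state * (vw - v) / vw + ev$repl_ch4[j] * v / vw
    }
    state <- mm_conc_closed(state, a, ks, times[i + 1] - times[i])
    pred[i + 1] <- state
  }
  pred
}

#' Fit Michaelis-Menten methane-oxidation kinetics
#'
#' Estimates \eqn{V_{max}} and \eqn{K_S} from chamber incubation series.
#' The default `"trajectory"` mode minimizes the squared error between the
#' observed concentrations and the exactly integrated Michaelis-Menten
#' model propagated through the withdrawal/replacement event ledger, using
#' all measurements; `"pointwise"` mode first forms per-interval rate points
#' (dilution- and, when blanks are given, blank-corrected) and fits the rate
#' law by nonlinear least squares. Replicate chambers are fit jointly with
#' shared parameters. Optimization is bounded (\eqn{V_{max}} in
#' `[0, 10 x max observed rate]`, \eqn{K_S} in `[1e-3, 10 x max S]`) on the
#' log scale with seeded multi-start; ties are broken by lowest residual sum
#' of squares, then lowest \eqn{K_S}. A series with no detectable
#' consumption returns \eqn{V_{max} = 0, K_S = 0} by convention (the
#' "no detectable MOX" case). Intervals where dissolved O2 fell below
#' `do_min` are excluded as potentially oxygen-limited.
#'
#' @param x an `incubation_series`, a list of replicate series, or (for
#'   pointwise fitting) a data frame with columns `S` (uM) and `V`
#'   (nmol m-2 h-1).
#' @param mode `"trajectory"` or `"pointwise"`.
#' @param blanks optional blank chamber series (list), used for the
#'   zero-consumption decision and, in pointwise mode, for blank correction.
#'   Trajectory mode assumes streamwater activity is negligible relative to
#'   the sediment; use pointwise mode to subtract measured blanks.
#' @param n_starts number of seeded optimizer starts.
#' @param seed integer seed for the multi-start jitter.
#' @param bounds optional list with elements `vmax` and `ks`, each `c(lo,
#'   hi)`, overriding the defaults.
#' @param do_min dissolved-O2 quality-control threshold, uM.
#' @param zero_tol total consumed CH4 (as a fraction of initial chamber
#'   content) below which the series is declared to show no detectable MOX;
#'   a series whose total consumption is not statistically distinguishable
#'   from zero (t < 2 against the interval-to-interval scatter) is treated
#'   the same way.
#' @return an object of class `"mm_kinetics"` with components `vmax`, `ks`,
#'   `se_vmax`, `se_ks`, `rss`, `n`, `converged`, `mode`, plus the data used.
#'   Methods: [coef()], [vcov()], [predict()], [residuals()], [plot()],
#'   [summary()], [simulate()].
#' @examples
#' sim <- simulate_incubation(10, 3, schedule = seq(0, 96, 12))
#' fit <- mm_kinetics(sim)
#' coef(fit)
#' @export
mm_kinetics <- function(x, mode = c("trajectory", "pointwise"),
                        blanks = NULL, n_starts = 5, seed = 1,
                        bounds = NULL, do_min = 50, zero_tol = 1e-3) {
  mode <- match.arg(mode)
  if (is.data.frame(x) && all(c("S", "V") %in% names(x))) {
    pts <- x[x$S >= 0 & is.finite(x$V), ]
    return(.fit_mm_points(pts, n_starts, seed, bounds,
                          series = NULL, site_id = "points"))
  }
  series <- if (inherits(x, "incubation_series")) list(x) else x
  stopifnot(all(vapply(series, inherits, logical(1), "incubation_series")))
  if (!is.null(blanks) && inherits(blanks, "incubation_series"))
    blanks <- list(blanks)
  site_id <- series[[1]]$site_id

  rates <- lapply(series, dilution_correct)
  if (!is.null(blanks)) {
    brates <- lapply(blanks, dilution_correct)
    rates <- lapply(rates, blank_correct, blank_rates = brates)
  }
  keep <- lapply(rates, function(r) !r$o2_limited)
  n_obs <- sum(lengths(keep))
  if (n_obs < 4)
    stop("need at least 4 informative intervals to fit two parameters")

  # no-detectable-consumption convention: total consumption is either
  # negligible against the chamber inventory or statistically
  # indistinguishable from zero given the interval-to-interval scatter
  consumed <- unlist(lapply(seq_along(rates), function(i)
    rates[[i]]$consumed_nmol[keep[[i]]]))
  total_consumed <- sum(consumed)
  initial_mass <- sum(vapply(series, function(s)
    s$conc$ch4[1] * s$water_volume, numeric(1)))
  scatter <- stats::sd(consumed)
  insignificant <- is.finite(scatter) && scatter > 0 &&
    total_consumed / (scatter * sqrt(length(consumed))) < 2 &&
    total_consumed <= 0.2 * initial_mass
  if (total_consumed <= zero_tol * initial_mass || insignificant) {
    return(.mm_fit_object(0, 0, NA, NA, rss = NA_real_, n = n_obs,
                          converged = TRUE, mode = mode, series = series,
                          rates = rates, site_id = site_id,
                          note = "no detectable consumption"))
  }

  if (mode == "pointwise") {
    pts <- do.call(rbind, lapply(seq_along(rates), function(i) {
      r <- rates[[i]][keep[[i]], ]
      data.frame(S = r$S, V = r$rate_nmol_h / series[[i]]$sediment_area)
    }))
    return(.fit_mm_points(pts, n_starts, seed, bounds, series, site_id))
  }

  # trajectory mode: least squares on observed concentrations
  max_rate <- max(unlist(lapply(seq_along(rates), function(i)
    rates[[i]]$rate_nmol_h / series[[i]]$sediment_area)), na.rm = TRUE)
  max_S <- max(unlist(lapply(series, function(s) s$conc$ch4)))
  lo <- c(vmax = 1e-6 * max_rate, ks = 1e-3)
  hi <- c(vmax = 10 * max_rate, ks = 10 * max_S)
  if (!is.null(bounds)) {
    if (!is.null(bounds$vmax)) { lo[1] <- max(bounds$vmax[1], 1e-12); hi[1] <- bounds$vmax[2] }
    if (!is.null(bounds$ks)) { lo[2] <- max(bounds$ks[1], 1e-12); hi[2] <- bounds$ks[2] }
  }
  # least squares on log concentrations: measurement noise is multiplicative
  # lognormal, so residuals are homoscedastic on the log scale and the
  # information in the low-concentration tail (which identifies K_S) is not
  # drowned by the early high-concentration points
  eps <- 1e-9 * max_S
  obj <- function(lpar) {
    vmax <- exp(lpar[1]); ks <- exp(lpar[2])
    rss <- 0
    for (s in series) {
      pred <- .predict_trajectory(s, vmax, ks)
      w <- c(TRUE, !dilated_o2_flag(s, do_min))
      rss <- rss + sum((log(pred[w] + eps) - log(s$conc$ch4[w] + eps))^2)
    }
    rss
  }
  fit <- .multistart_optim(obj, lo, hi,
                           start_center = c(max(max_rate, lo[1] * 10),
                                            0.5 * max_S),
                           n_starts = n_starts, seed = seed)
  n <- sum(vapply(series, function(s) length(s$times), numeric(1)))
  se <- .mm_se(function(p) obj(log(p)), fit$par, n, 2)
  rss_lin <- sum(vapply(series, function(s)
    sum((.predict_trajectory(s, fit$par[1], fit$par[2]) - s$conc$ch4)^2),
    numeric(1)))
  .mm_fit_object(fit$par[1], fit$par[2], se[1], se[2], rss_lin, n,
                 fit$converged, "trajectory", series, rates, site_id)
}

# per-measurement O2 QC flags for trajectory weighting (one per non-initial
# observation)
dilated_o2_flag <- function(s, do_min) {
  o2 <- s$conc$o2[-1]
  !is.na(o2) & o2 < do_min
}

.fit_mm_points <- function(pts, n_starts, seed, bounds, series, site_id) {
  if (nrow(pts) < 4)
    stop("need at least 4 rate points to fit two parameters")
  if (all(pts$V <= 0)) {
    return(.mm_fit_object(0, 0, NA, NA, NA_real_, nrow(pts), TRUE,
                          "pointwise", series, NULL, site_id,
                          note = "no detectable consumption"))
  }
  max_rate <- max(pts$V)
  lo <- c(vmax = 1e-6 * max_rate, ks = 1e-3)
  hi <- c(vmax = 10 * max_rate, ks = 10 * max(pts$S))
  if (!is.null(bounds)) {
    if (!is.null(bounds$vmax)) { lo[1] <- max(bounds$vmax[1], 1e-12); hi[1] <- bounds$vmax[2] }
    if (!is.null(bounds$ks)) { lo[2] <- max(bounds$ks[1], 1e-12); hi[2] <- bounds$ks[2] }
  }
  obj <- function(lpar) {
    vmax <- exp(lpar[1]); ks <- exp(lpar[2])
    sum((pts$V - vmax * pts$S / (ks + pts$S))^2)
  }
  fit <- .multistart_optim(obj, lo, hi,
                           start_center = c(max_rate, stats::median(pts$S)),
                           n_starts = n_starts, seed = seed)
  se <- .mm_se(function(p) obj(log(p)), fit$par, nrow(pts), 2)
  out <- .mm_fit_object(fit$par[1], fit$par[2], se[1], se[2], fit$value,
                        nrow(pts), fit$converged, "pointwise", series, NULL,
                        site_id)
  out$rate_points <- pts
  out
}

# bounded multi-start minimization on the log scale; returns natural-scale
# parameters, tie-break lowest value then lowest ks. Starts are spread over
# a fixed grid of plausible (vmax, ks) scale multiples -- covering the
# near-zero-order and high-affinity corners that trap single-start fits --
# plus seeded jitter for any starts beyond the grid.
.multistart_optim <- function(obj, lo, hi, start_center, n_starts, seed) {
  llo <- log(lo); lhi <- log(hi)
  grid <- rbind(c(1, 0.3), c(2, 1), c(5, 3), c(1.5, 0.03), c(3, 0.1),
                c(1, 1), c(8, 0.5))
  base <- t(t(grid) * start_center)
  with_seed(seed, {
    k <- min(n_starts, nrow(base))
    starts <- log(base[seq_len(k), , drop = FALSE])
    if (n_starts > k) {
      jit <- matrix(stats::runif(2 * (n_starts - k), -1.5, 1.5),
                    n_starts - k, 2)
      extra <- matrix(log(start_center), n_starts - k, 2, byrow = TRUE) + jit
      starts <- rbind(starts, extra)
    }
    starts <- pmin(pmax(starts, rep(llo, each = n_starts)),
                   rep(lhi, each = n_starts))
    best <- NULL
    for (i in seq_len(n_starts)) {
      res <- tryCatch(
        stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = llo, upper = lhi,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) ||
          res$value < best$value - 1e-12 ||
          (abs(res$value - best$value) <= 1e-12 &&
           res$par[2] < best$par[2])) best <- res
    }
  })
  if (is.null(best)) stop("optimization failed for all starts")
  list(par = exp(best$par), value = best$value,
       converged = best$convergence == 0)
}

# standard errors from the local quadratic approximation of the RSS surface
.mm_se <- function(rss_fn, par, n, p) {
  if (n <= p) return(c(NA_real_, NA_real_))
  h <- pmax(abs(par) * 1e-4, 1e-8)
  H <- matrix(0, 2, 2)
  f0 <- rss_fn(par)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, j] <- (rss_fn(par + ei) - 2 * f0 + rss_fn(par - ei)) / h[i]^2
    } else {
      H[i, j] <- (rss_fn(par + ei + ej) - rss_fn(par + ei - ej) -
                  rss_fn(par - ei + ej) + rss_fn(par - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  sigma2 <- f0 / (n - p)
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e)
    matrix(NA_real_, 2, 2))
  sqrt(pmax(diag(cov), 0))
}

.mm_fit_object <- function(vmax, ks, se_vmax, se_ks, rss, n, converged,
                           mode, series, rates, site_id, note = NULL) {
  structure(list(vmax = vmax, ks = ks, se_vmax = se_vmax, se_ks = se_ks,
                 rss = rss, n = n, converged = converged, mode = mode,
                 series = series, rates = rates, site_id = site_id,
                 note = note), class = "mm_kinetics")
}

#' @export
print.mm_kinetics <- function(x, ...) {
  cat(sprintf("Michaelis-Menten MOX kinetics (%s fit, site %s)\n",
              x$mode, x$site_id))
  cat(sprintf("  V_max = %.3g nmol m-2 h-1 (se %.3g)\n", x$vmax, x$se_vmax))
  cat(sprintf("  K_S   = %.3g uM (se %.3g)\n", x$ks, x$se_ks))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.mm_kinetics <- function(object, ...) {
  out <- list(coef = cbind(Estimate = c(vmax = object$vmax, ks = object$ks),
                           `Std. Error` = c(object$se_vmax, object$se_ks)),
              rss = object$rss, n = object$n, mode = object$mode,
              converged = object$converged,
              n_series = length(object$series), note = object$note)
  class(out) <- "summary.mm_kinetics"
  out
}

#' @export
print.summary.mm_kinetics <- function(x, ...) {
  cat(sprintf("Michaelis-Menten kinetic fit (%s mode, %d chamber(s), %d obs)\n",
              x$mode, x$n_series, x$n))
  print(signif(x$coef, 4))
  cat(sprintf("RSS %.4g; converged: %s\n", x$rss, x$converged))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.mm_kinetics <- function(object, ...) c(vmax = object$vmax, ks = object$ks)

#' @export
vcov.mm_kinetics <- function(object, ...) {
  v <- diag(c(object$se_vmax^2, object$se_ks^2))
  dimnames(v) <- list(c("vmax", "ks"), c("vmax", "ks"))
  v
}

#' Predicted MOX rates or fitted trajectories
#'
#' With `S` given, evaluates the fitted rate law at those concentrations.
#' Without `S`, returns fitted values on the fitting scale: predicted
#' concentrations per chamber for trajectory fits, fitted rates at the
#' observed rate points for pointwise fits.
#'
#' @param object an `mm_kinetics` fit.
#' @param S optional CH4 concentrations, uM.
#' @param ... unused.
#' @export
predict.mm_kinetics <- function(object, S = NULL, ...) {
  if (!is.null(S)) return(mm_rate(S, object$vmax, object$ks))
  if (object$mode == "pointwise")
    return(mm_rate(object$rate_points$S, object$vmax, object$ks))
  lapply(object$series, .predict_trajectory,
         vmax = object$vmax, ks = object$ks)
}

#' @export
residuals.mm_kinetics <- function(object, ...) {
  if (object$mode == "pointwise")
    return(object$rate_points$V - predict(object))
  pred <- predict(object)
  unlist(lapply(seq_along(object$series), function(i)
    object$series[[i]]$conc$ch4 - pred[[i]]))
}

#' @export
fitted.mm_kinetics <- function(object, ...) {
  p <- predict(object)
  if (is.list(p)) unlist(p) else p
}

#' @export
plot.mm_kinetics <- function(x, ...) {
  if (x$mode == "pointwise" && !is.null(x$rate_points)) {
    pts <- x$rate_points
    plot(pts$S, pts$V, xlab = "CH4 (uM)",
         ylab = "MOX rate (nmol m-2 h-1)",
         main = sprintf("site %s: V = %.3g S/(%.3g + S)", x$site_id,
                        x$vmax, x$ks), ...)
    s <- seq(0, max(pts$S) * 1.05, length.out = 200)
    graphics::lines(s, mm_rate(s, x$vmax, max(x$ks, 1e-12)), col = 2)
  } else {
    pred <- predict(x)
    s1 <- x$series[[1]]
    plot(s1$times, s1$conc$ch4, xlab = "time (h)", ylab = "CH4 (uM)",
         main = sprintf("site %s trajectory fit", x$site_id),
         ylim = range(unlist(lapply(x$series, function(s) s$conc$ch4)),
                      0), ...)
    for (i in seq_along(x$series)) {
      graphics::points(x$series[[i]]$times, x$series[[i]]$conc$ch4,
                       col = i)
      graphics::lines(x$series[[i]]$times, pred[[i]], col = i, lty = 2)
    }
  }
  invisible(x)
}

#' Simulate incubation series from a fitted kinetic model
#'
#' Draws new chamber incubation series under the fitted \eqn{V_{max}},
#' \eqn{K_S}, using the chamber geometry and schedule of the data the model
#' was fit to.
#'
#' @param object an `mm_kinetics` fit carrying its series.
#' @param nsim number of replicate series.
#' @param seed integer seed.
#' @param noise_cv measurement noise CV for the simulated measurements.
#' @param ... unused.
#' @return a list of `incubation_series`.
#' @export
simulate.mm_kinetics <- function(object, nsim = 1, seed = 1,
                                 noise_cv = 0, ...) {
  if (is.null(object$series)) stop("fit carries no chamber geometry")
  s <- object$series[[1]]
  ch <- chamber_config(sediment_mass_g = 25,
                       specific_area_m2_g = s$sediment_area / 25)
  lapply(seq_len(nsim), function(i)
    simulate_incubation(object$vmax, max(object$ks, 1e-3), ch,
                        schedule = s$times, noise_cv = noise_cv,
                        seed = seed + i - 1, site_id = object$site_id,
                        replicate = i))
}

#' Putative in-situ methane oxidation rate
#'
#' Evaluates the fitted rate law at an environmental (in-situ) CH4
#' concentration. The result is a lab-kinetics extrapolation ("putative"
#' rate): kinetics measured at 20 C applied to the field concentration.
#'
#' @param fit an `mm_kinetics` object (must have converged), or a list with
#'   elements `vmax` and `ks`.
#' @param S_env in-situ CH4 concentration, uM.
#' @return rate, nmol CH4 m-2 h-1.
#' @examples
#' in_situ_rate(list(vmax = 53.9, ks = 10.6), 10.6)  # 26.95
#' @export
in_situ_rate <- function(fit, S_env) {
  if (inherits(fit, "mm_kinetics") && !fit$converged)
    stop("kinetic fit did not converge; no in-situ rate")
  mm_rate(S_env, fit$vmax, fit$ks)
}

#' Methane-derived carbon fixation rate
#'
#' Converts a methane-oxidation rate into a biomass carbon-fixation rate
#' assuming a carbon-use efficiency `cue` (fraction of oxidized CH4 carbon
#' assimilated; 1 C per CH4).
#'
#' @param mox_rate MOX rate, nmol CH4 m-2 h-1.
#' @param cue carbon-use efficiency in \[0, 1\]; default 0.5.
#' @return carbon fixation, nmol C m-2 h-1.
#' @examples
#' carbon_fixation(27)  # 13.5
#' @export
carbon_fixation <- function(mox_rate, cue = 0.5) {
  if (cue < 0 || cue > 1) stop("cue must lie in [0, 1]")
  mox_rate * cue
}

#' Normalize a per-chamber amount to sediment surface area
#'
#' @param amount per-chamber quantity (e.g., nmol or cells).
#' @param area sediment surface area, m2; must be positive.
#' @return amount per m2.
#' @export
normalize_per_area <- function(amount, area) {
  if (any(area <= 0)) stop("area must be positive")
  amount / area
}
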