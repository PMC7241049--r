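#' Incubation chamber configuration
#'
#' Geometry and protocol of the closed, headspace-free incubation chambers:
#' a Plexiglas cylinder (11 cm diameter, 8 cm height, 760 cm3) holding a thin
#' layer of wet sediment and CH4-amended streamwater, sampled by withdrawing
#' `withdrawal_mL` of water and simultaneously replacing it with
#' air-equilibrated streamwater. Sediment surface area is wet mass times a
#' specific surface area (free configuration parameter carried through all
#' per-area normalizations); the water volume is the chamber volume minus the
#' sediment's displaced volume.
#'
#' @param volume_mL chamber volume (cm3 = mL).
#' @param sediment_mass_g wet sediment mass; 0 for blank chambers.
#' @param specific_area_m2_g specific sediment surface area, m2 per g wet mass.
#' @param sediment_density_g_cm3 wet-sediment bulk density, used only to
#'   compute displaced volume.
#' @param withdrawal_mL water withdrawn (and replaced) at each sampling.
#' @param temperature incubation temperature, degrees Celsius.
#' @param amendment_ch4_atm CH4 partial pressure the incubation water was
#'   pre-equilibrated with (1% CH4 in air by default); sets the initial
#'   dissolved CH4 via the solubility model.
#' @param replacement named numeric: dissolved CH4/CO2/O2 (uM) of the
#'   replacement water; defaults to air equilibrium at `temperature`
#'   (1.9 ppmv CH4, 420 ppmv CO2, 20.95% O2).
#' @return a list of class `"chamber_config"`.
#' @export
chamber_config <- function(volume_mL = 760, sediment_mass_g = 25,
                           specific_area_m2_g = 1,
                           sediment_density_g_cm3 = 1.6,
                           withdrawal_mL = 30, temperature = 20,
                           amendment_ch4_atm = 0.01,
                           replacement = NULL) {
  if (volume_mL <= withdrawal_mL)
    stop("chamber volume must exceed the withdrawal volume")
  if (sediment_mass_g < 0 || withdrawal_mL < 0) stop("negative configuration")
  if (is.null(replacement))
    replacement <- c(
      ch4 = equilibrium_conc("CH4", 1.9e-6, temperature),
      co2 = equilibrium_conc("CO2", 420e-6, temperature),
      o2  = equilibrium_conc("O2", 0.2095, temperature))
  water_volume <- volume_mL - sediment_mass_g / sediment_density_g_cm3
  structure(list(
    volume_mL = volume_mL,
    sediment_mass_g = sediment_mass_g,
    sediment_area_m2 = sediment_mass_g * specific_area_m2_g,
    water_volume_mL = water_volume,
    withdrawal_mL = withdrawal_mL,
    temperature = temperature,
    amendment_ch4_atm = amendment_ch4_atm,
    init_ch4_uM = equilibrium_conc("CH4", amendment_ch4_atm, temperature),
    init_co2_uM = equilibrium_conc("CO2", 420e-6, temperature),
    init_o2_uM = equilibrium_conc("O2", 0.2095, temperature),
    replacement = replacement), class = "chamber_config")
}

#' Closed-form Michaelis-Menten batch concentration
#'
#' Concentration after time `t` in a well-mixed closed volume consuming
#' substrate by Michaelis-Menten kinetics, obtained from the implicit
#' integrated form \eqn{K_S \ln(C_0/C) + (C_0 - C) = a t} (with `a` the
#' volumetric maximum rate, uM h-1), solved by a safeguarded Newton
#' iteration. Exact up to root-finding tolerance (1e-13 relative).
#'
#' @param C0 initial concentration, uM.
#' @param a volumetric maximum rate `A * V_max / V_w`, uM h-1.
#' @param ks half-saturation constant, uM; `ks = 0` gives the zero-order
#'   solution `max(C0 - a t, 0)`.
#' @param t elapsed time, h (vectorized).
#' @return concentration(s), uM.
#' @export
mm_conc_closed <- function(C0, a, ks, t) {
  vapply(t, function(tt) {
    if (a <= 0 || tt <= 0 || C0 <= 0) return(C0)
    if (ks == 0) return(max(C0 - a * tt, 0))
    target <- a * tt
    lo <- C0 * 1e-300; hi <- C0
    g <- function(C) ks * log(C0 / C) + (C0 - C) - target
    # Newton with bisection safeguard; g is strictly decreasing on (0, C0]
    C <- C0 * exp(-target / (ks + C0))
    for (it in 1:100) {
      gc <- g(C)
      if (gc > 0) lo <- C else hi <- C
      if (abs(gc) < 1e-13 * max(C0, target)) break
      step <- gc / (-ks / C - 1)
      Cn <- C - step
      if (!is.finite(Cn) || Cn <= lo || Cn >= hi) Cn <- (lo + hi) / 2
      if (abs(Cn - C) < 1e-15 * C0) { C <- Cn; break }
      C <- Cn
    }
    C
  }, numeric(1))
}

#' Simulate a closed-chamber incubation with discrete sampling events
#'
#' Integrates the chamber mass balance between sampling events with an
#' adaptive stiff-capable solver ([deSolve::lsoda()], relative tolerance
#' 1e-11): CH4 is consumed at the sediment's Michaelis-Menten rate
#' \eqn{dC/dt = -(A/V_w)\,V_{max}\,C/(K_S+C)} plus an optional volumetric
#' streamwater-community term; CO2 is produced and O2 consumed in
#' configurable stoichiometric ratios. At each sampling event the measured
#' (pre-withdrawal) concentrations are recorded, then concentrations jump to
#' \eqn{C (V_w - v)/V_w + C_{repl}\, v/V_w}. Multiplicative lognormal noise
#' with coefficient of variation `noise_cv` is applied to the reported
#' measurements only; the internal state and the mass ledger stay exact.
#'
#' @param vmax true maximum MOX velocity, nmol m-2 h-1.
#' @param ks true half-saturation constant, uM. `ks = 0` with `vmax > 0` is
#'   rejected unless `allow_zero_order = TRUE` (zero-order consumption).
#' @param chamber a [chamber_config()]; use `sediment_mass_g = 0` together
#'   with `blank = TRUE` for sediment-free control chambers.
#' @param schedule sampling times in hours, strictly increasing, starting
#'   at 0. A withdrawal/replacement event occurs at every sampling except
#'   the last.
#' @param noise_cv lognormal CV of the reported concentrations.
#' @param seed integer seed for the measurement noise.
#' @param site_id,replicate labels carried into the output.
#' @param blank if `TRUE` the sediment term is dropped.
#' @param water_vmax,water_ks volumetric Michaelis-Menten parameters of the
#'   streamwater community (uM h-1 and uM); present in blanks and sediment
#'   chambers alike.
#' @param cue carbon-use efficiency; O2:CH4 stoichiometry is
#'   `2 (1 - cue) + cue`.
#' @param co2_per_ch4 mol CO2 produced per mol CH4 oxidized.
#' @param allow_zero_order permit `ks = 0` with `vmax > 0`.
#' @param rtol solver relative tolerance.
#' @return an object of class `"incubation_series"`: measured `conc`
#'   (data frame time_h/ch4/co2/o2), the `events` ledger (time_h,
#'   withdrawn_mL, replacement concentrations), chamber metadata, and a
#'   `truth` component holding the exact state, the per-interval consumed
#'   CH4 (nmol) and the cumulative mass ledger.
#' @export
simulate_incubation <- function(vmax, ks, chamber = chamber_config(),
                                schedule = seq(0, 96, by = 12),
                                noise_cv = 0, seed = 1,
                                site_id = "site", replicate = 1L,
                                blank = FALSE,
                                water_vmax = 0, water_ks = ks,
                                cue = 0.5, co2_per_ch4 = 1,
                                allow_zero_order = FALSE,
                                rtol = 1e-11) {
  if (vmax < 0 || ks < 0) stop("vmax and ks must be non-negative")
  if (ks == 0 && vmax > 0 && !allow_zero_order)
    stop("ks = 0 with vmax > 0 is an undefined Michaelis-Menten form; ",
         "set allow_zero_order = TRUE for zero-order kinetics")
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing")
  if (schedule[1] != 0) schedule <- c(0, schedule)

  vw <- chamber$water_volume_mL
  if (blank) vw <- chamber$volume_mL
  area <- if (blank) 0 else chamber$sediment_area_m2
  a_sed <- area * vmax / vw                      # uM / h
  o2_per_ch4 <- 2 * (1 - cue) + cue
  v <- chamber$withdrawal_mL
  repl <- chamber$replacement

  rate <- function(ch4) {
    r_sed <- if (a_sed > 0) {
      if (ks > 0) a_sed * ch4 / (ks + ch4) else a_sed * (ch4 > 1e-12)
    } else 0
    r_wat <- if (water_vmax > 0) {
      if (water_ks > 0) water_vmax * ch4 / (water_ks + ch4)
      else water_vmax * (ch4 > 1e-12)
    } else 0
    r_sed + r_wat
  }
  deriv <- function(t, y, parms) {
    r <- rate(y[1])
    list(c(-r, co2_per_ch4 * r, -o2_per_ch4 * r, r * vw))
  }

  state <- c(ch4 = chamber$init_ch4_uM, co2 = chamber$init_co2_uM,
             o2 = chamber$init_o2_uM, consumed = 0)
  n <- length(schedule)
  exact <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("ch4", "co2", "o2")))
  consumed_interval <- numeric(n - 1)
  removed <- added <- c(ch4 = 0, co2 = 0, o2 = 0)
  initial <- state[1:3] * vw
  ledger <- vector("list", n)

  for (i in seq_len(n)) {
    if (i > 1) {
      sol <- deSolve::lsoda(state, c(schedule[i - 1], schedule[i]), deriv,
                            parms = NULL, rtol = rtol, atol = 1e-12)
      newstate <- sol[nrow(sol), -1]
      consumed_interval[i - 1] <- newstate["consumed"] - state["consumed"]
      state <- newstate
    }
    exact[i, ] <- state[1:3]
    ledger[[i]] <- data.frame(
      time_h = schedule[i],
      initial_nmol = initial["ch4"],
      added_nmol = added["ch4"], removed_nmol = removed["ch4"],
      consumed_nmol = unname(state["consumed"]),
      remaining_nmol = unname(state["ch4"] * vw))
    if (i < n && v > 0) {  # withdrawal + replacement event
      removed <- removed + state[1:3] * v
      added <- added + repl[c("ch4", "co2", "o2")] * v
      state[1:3] <- state[1:3] * (vw - v) / vw +
        repl[c("ch4", "co2", "o2")] * v / vw
    }
  }
  ledger <- do.call(rbind, ledger)
  ledger$residual_nmol <- ledger$initial_nmol + ledger$added_nmol -
    ledger$removed_nmol - ledger$consumed_nmol - ledger$remaining_nmol
  meas <- exact
  with_seed(seed, {
    if (noise_cv > 0) meas <- apply(exact, 2, lnoise, cv = noise_cv)
  })

  ev_times <- schedule[-n]
  events <- data.frame(time_h = ev_times,
                       withdrawn_mL = rep(v, length(ev_times)),
                       repl_ch4 = repl[["ch4"]], repl_co2 = repl[["co2"]],
                       repl_o2 = repl[["o2"]])
  structure(list(
    chamber_id = sprintf("%s_r%d%s", site_id, as.integer(replicate),
                         if (blank) "_blank" else ""),
    site_id = site_id, replicate = as.integer(replicate), is_blank = blank,
    sediment_area = area, water_volume = vw,
    times = schedule,
    conc = data.frame(time_h = schedule, ch4 = meas[, "ch4"],
                      co2 = meas[, "co2"], o2 = meas[, "o2"]),
    events = events,
    truth = list(exact = data.frame(time_h = schedule, exact),
                 consumed_interval = consumed_interval,
                 ledger = ledger,
                 vmax = vmax, ks = ks, water_vmax = water_vmax,
                 water_ks = water_ks)),
    class = "incubation_series")
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf("Incubation chamber %s (site %s, replicate %d%s)\n",
              x$chamber_id, x$site_id, x$replicate,
              if (x$is_blank) ", blank" else ""))
  cat(sprintf("  %d samplings over %.1f h; water %.0f mL; sediment %.2f m2\n",
              length(x$times), max(x$times), x$water_volume, x$sediment_area))
  cat(sprintf("  CH4 %.2f -> %.2f uM\n", x$conc$ch4[1],
              x$conc$ch4[nrow(x$conc)]))
  invisible(x)
}

#' Construct an incubation series from measured data
#'
#' Builds the container consumed by [dilution_correct()] and [mm_kinetics()]
#' from plain vectors/data frames (e.g., after reading CSV files), enforcing
#' its invariants: strictly increasing times, non-negative concentrations,
#' event times within the sampled range.
#'
#' @param times sampling times, h.
#' @param ch4,co2,o2 measured concentrations, uM (`co2`, `o2` optional).
#' @param events data frame with `time_h`, `withdrawn_mL`, `repl_ch4` (and
#'   optionally `repl_co2`, `repl_o2`).
#' @param site_id,replicate,is_blank metadata labels.
#' @param sediment_area sediment surface area in the chamber, m2.
#' @param water_volume chamber water volume, mL.
#' @return an `"incubation_series"` object.
#' @export
incubation_series <- function(times, ch4, co2 = NULL, o2 = NULL,
                              events = NULL, site_id = "site",
                              replicate = 1L, is_blank = FALSE,
                              sediment_area = 25, water_volume = 744) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (length(ch4) != length(times)) stop("ch4 length must match times")
  if (any(ch4 < 0, na.rm = TRUE)) stop("negative CH4 concentration")
  if (is.null(events))
    events <- data.frame(time_h = times[-length(times)], withdrawn_mL = 0,
                         repl_ch4 = 0)
  if (any(events$time_h < min(times) | events$time_h > max(times)))
    stop("event outside the sampled time range")
  structure(list(
    chamber_id = sprintf("%s_r%d%s", site_id, as.integer(replicate),
                         if (is_blank) "_blank" else ""),
    site_id = site_id, replicate = as.integer(replicate), is_blank = is_blank,
    sediment_area = sediment_area, water_volume = water_volume,
    times = times,
    conc = data.frame(time_h = times, ch4 = ch4,
                      co2 = co2 %||% rep(NA_real_, length(times)),
                      o2 = o2 %||% rep(NA_real_, length(times))),
    events = events, truth = NULL), class = "incubation_series")
}
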