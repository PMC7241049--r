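#' Default synthetic stream-gradient specification
#'
#' Defines the three site archetypes the generator draws from -- alpine
#' (natural vegetation, cold, CH4-poor), forested (elevated streamwater CH4)
#' and agricultural/urban (elevated porewater CH4, ions and pH) -- together
#' with the coefficients that link CH4 supply to the true Michaelis-Menten
#' parameters of each site. Archetype values are means; site-to-site spread
#' is multiplicative lognormal with coefficient of variation `noise_cv`.
#'
#' Two designated sites break the plain gradient, mirroring common field
#' situations: one forested site drains a wetland (`wetland_factor` scales
#' both CH4 pools up, producing the panel's kinetic maxima) and one forested
#' site has unusually low porewater CH4 (porewater below streamwater, so its
#' half-saturation constant greatly exceeds its porewater concentration).
#'
#' Ground-truth kinetics: `V_max = vmax_per_ch4_stream * ch4_stream` (zero at
#' alpine sites), `K_S = ks_frac_of_pore * ch4_pore` clamped to `ks_range`.
#'
#' @param noise_cv site-to-site lognormal coefficient of variation for
#'   concentrations (0 gives exactly the archetype means).
#' @return a list with components `archetypes`, `vmax_per_ch4_stream`
#'   (nmol m-2 h-1 per uM), `ks_frac_of_pore`, `ks_range` (uM),
#'   `wetland_factor`, `low_pore_factor`, `noise_cv`.
#' @export
default_gradient_spec <- function(noise_cv = 0.15) {
  arche <- list(
    alpine = list(
      n = 2, altitude = 2000, temperature = 6, ph = 7.2,
      land_cover = c(rock = 0.50, grassland = 0.40, forest = 0.07,
                     arable = 0.02, urban = 0.01),
      ions = c(NO3 = 5, SO4 = 30, Cl = 5, Ca = 200), doc = 0.6,
      ch4_stream = 0.006, ch4_pore = 0.05, co2_stream = 30, co2_pore = 60,
      do_stream = 340, do_pore = 310),
    forested = list(
      n = 4, altitude = 800, temperature = 12, ph = 7.4,
      land_cover = c(rock = 0.05, grassland = 0.25, forest = 0.45,
                     arable = 0.15, urban = 0.10),
      ions = c(NO3 = 60, SO4 = 90, Cl = 40, Ca = 800), doc = 2.5,
      ch4_stream = 0.18, ch4_pore = 4.5, co2_stream = 110, co2_pore = 450,
      do_stream = 320, do_pore = 120),
    agricultural = list(
      n = 8, altitude = 450, temperature = 16, ph = 8.0,
      land_cover = c(rock = 0.01, grassland = 0.14, forest = 0.15,
                     arable = 0.45, urban = 0.25),
      ions = c(NO3 = 250, SO4 = 180, Cl = 120, Ca = 1500), doc = 3.5,
      ch4_stream = 0.10, ch4_pore = 8.5, co2_stream = 130, co2_pore = 600,
      do_stream = 310, do_pore = 100))
  list(archetypes = arche,
       vmax_per_ch4_stream = 150,
       ks_frac_of_pore = 0.88,
       ks_range = c(0.5, 10.6),
       wetland_factor = 2,      # applied to forested site 2
       low_pore_factor = 0.03,  # applied to forested site 1
       noise_cv = noise_cv)
}

#' Generate a synthetic panel of stream sites with known kinetic truth
#'
#' Draws `n_sites` sites from the archetypes in `gradient_spec` and assigns
#' each site its true maximum methane-oxidation velocity and half-saturation
#' constant as a deterministic function of its CH4 supply. Alpine sites have
#' no detectable methane oxidation (`V_max = 0`, `K_S = 0` by convention).
#' Porewater CH4 always exceeds streamwater CH4 except at the designated
#' low-porewater site.
#'
#' @param n_sites number of sites (>= 3). When it equals the sum of archetype
#'   counts in the spec (14 by default) those counts are used; otherwise
#'   sites are allocated round-robin across archetypes.
#' @param gradient_spec see [default_gradient_spec()].
#' @param seed integer seed; identical seeds give identical panels.
#' @return a list with `sites` (data frame, one row per site: identity,
#'   land-cover fractions `lc_*`, ion concentrations uM, DOC mg C L-1, and
#'   stream/porewater CH4, CO2 and DO in uM) and `truth` (data frame of
#'   per-site true `vmax` nmol m-2 h-1 and `ks` uM plus special-site labels,
#'   with the generating coefficients as attributes).
#' @export
gen_sites <- function(n_sites = 14, gradient_spec = default_gradient_spec(),
                      seed = 1) {
  if (length(n_sites) != 1 || n_sites < 3)
    stop("n_sites must be a single integer >= 3")
  arche <- gradient_spec$archetypes
  for (a in arche) {
    if (abs(sum(a$land_cover) - 1) > 1e-9)
      stop("archetype land-cover fractions must sum to 1")
  }
  counts <- vapply(arche, `[[`, numeric(1), "n")
  if (sum(counts) != n_sites)
    counts <- as.vector(table(factor(rep(seq_along(arche),
                                         length.out = n_sites),
                                     levels = seq_along(arche))))
  cv <- gradient_spec$noise_cv
  with_seed(seed, {
    rows <- list()
    for (k in seq_along(arche)) {
      a <- arche[[k]]
      nm <- names(arche)[k]
      for (i in seq_len(counts[k])) {
        site_id <- sprintf("%s-%d", substr(nm, 1, 3), i)
        special <- "none"
        wet <- lowp <- 1
        if (nm == "forested" && i == 2) { special <- "wetland"; wet <- gradient_spec$wetland_factor }
        if (nm == "forested" && i == 1) { special <- "low_pore"; lowp <- gradient_spec$low_pore_factor }
        lc <- a$land_cover
        if (cv > 0) {
          lc <- pmax(lc + stats::rnorm(length(lc), 0, 0.05 * cv / 0.15), 0)
          lc <- lc / sum(lc)
        }
        ch4s <- lnoise(a$ch4_stream * wet, cv, 1)
        ch4p <- lnoise(a$ch4_pore * wet * lowp, cv, 1)
        if (special != "low_pore") ch4p <- max(ch4p, 1.05 * ch4s)
        row <- data.frame(
          site_id = site_id, archetype = nm,
          altitude = a$altitude * exp(if (cv > 0) stats::rnorm(1, 0, 0.05) else 0),
          temperature = a$temperature + (if (cv > 0) stats::rnorm(1, 0, 0.8) else 0),
          ph = a$ph + (if (cv > 0) stats::rnorm(1, 0, 0.1) else 0),
          t(lc)[1, , drop = TRUE] |> as.list() |> setNames(paste0("lc_", names(lc))),
          as.list(lnoise(a$ions, cv)) |> setNames(paste0(tolower(names(a$ions)), "_uM")),
          doc = lnoise(a$doc, cv, 1),
          ch4_stream = ch4s, ch4_pore = ch4p,
          co2_stream = lnoise(a$co2_stream, cv, 1),
          co2_pore = lnoise(a$co2_pore * wet, cv, 1),
          do_stream = lnoise(a$do_stream, cv / 3, 1),
          do_pore = lnoise(a$do_pore, cv / 3, 1),
          stringsAsFactors = FALSE)
        row$do_pore <- min(row$do_pore, row$do_stream)
        rows[[length(rows) + 1L]] <- row
      }
    }
    sites <- do.call(rbind, rows)
    rownames(sites) <- NULL
    vmax <- ifelse(sites$archetype == "alpine", 0,
                   gradient_spec$vmax_per_ch4_stream * sites$ch4_stream)
    ks <- ifelse(vmax > 0,
                 pmin(pmax(gradient_spec$ks_frac_of_pore * sites$ch4_pore,
                           gradient_spec$ks_range[1]),
                      gradient_spec$ks_range[2]),
                 0)
    special <- rep("none", nrow(sites))
    special[sites$archetype == "forested"] <-
      c("low_pore", "wetland", "none", "none")[
        seq_len(sum(sites$archetype == "forested"))]
    truth <- data.frame(site_id = sites$site_id, vmax = vmax, ks = ks,
                        archetype = sites$archetype, special = special,
                        stringsAsFactors = FALSE)
    attr(truth, "coef") <- gradient_spec[c("vmax_per_ch4_stream",
                                           "ks_frac_of_pore", "ks_range")]
    attr(truth, "seed") <- seed
    validate_sites(sites)
    list(sites = sites, truth = truth)
  })
}

#' Validate a site table
#'
#' Checks the structural invariants of a site panel: land-cover fractions in
#' \[0,1\] summing to 1 per site, and non-negative concentrations.
#'
#' @param sites data frame as returned by [gen_sites()].
#' @return the table, invisibly; errors describe the offending site.
#' @export
validate_sites <- function(sites) {
  lc <- as.matrix(sites[grep("^lc_", names(sites))])
  bad <- which(abs(rowSums(lc) - 1) > 1e-9)
  if (length(bad))
    stop("land-cover fractions do not sum to 1 for site ",
         sites$site_id[bad[1]])
  if (any(lc < 0 | lc > 1)) stop("land-cover fraction outside [0,1]")
  conc <- as.matrix(sites[c("ch4_stream", "ch4_pore", "co2_stream",
                            "co2_pore", "do_stream", "do_pore", "doc")])
  if (any(conc < 0)) stop("negative concentration in site table")
  invisible(sites)
}

#' Generate a streambed depth profile for one site
#'
#' Produces CH4, CO2 and dissolved-oxygen concentrations down the sediment
#' column. CH4 shows the characteristic subsurface bump centered at
#' `peak_depth` (10 cm by default) whose height is the site's porewater CH4;
#' at depth 0 (streamwater) concentrations equal the site's streamwater
#' values exactly. DO decreases monotonically with depth toward the porewater
#' value. Multiplicative lognormal noise is applied below the surface only.
#'
#' @param site one-row data frame (or list) with the site's stream/porewater
#'   concentrations.
#' @param depths sampling depths in cm, must contain 0; all non-negative.
#' @param seed integer seed.
#' @param noise_cv measurement noise CV (0 = deterministic).
#' @param peak_depth,peak_width center and Gaussian width of the CH4 bump, cm.
#' @return data frame with columns `site_id`, `depth`, `ch4`, `co2`, `do`.
#' @export
gen_depth_profile <- function(site, depths = c(0, 2, 5, 10, 15, 20, 30),
                              seed = 1, noise_cv = 0,
                              peak_depth = 10, peak_width = 5) {
  if (any(depths < 0)) stop("depths must be non-negative")
  if (!any(depths == 0)) stop("depths must include 0 (streamwater)")
  depths <- sort(depths)
  z <- depths
  ch4 <- site$ch4_stream +
    (site$ch4_pore - site$ch4_stream) * exp(-(z - peak_depth)^2 / (2 * peak_width^2))
  co2 <- site$co2_stream + (site$co2_pore - site$co2_stream) * (1 - exp(-z / 10))
  dox <- site$do_stream + (site$do_pore - site$do_stream) * (1 - exp(-z / 10))
  ch4[z == 0] <- site$ch4_stream
  with_seed(seed, {
    sub <- z > 0
    ch4[sub] <- lnoise(ch4[sub], noise_cv)
    co2[sub] <- lnoise(co2[sub], noise_cv)
    dox[sub] <- lnoise(dox[sub], noise_cv)
  })
  dox <- cummin(dox)  # DO is non-increasing with depth by construction
  data.frame(site_id = site$site_id %||% "site", depth = z,
             ch4 = pmax(ch4, 0), co2 = pmax(co2, 0), do = pmax(dox, 0))
}
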