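#' Linear association between two per-site quantities
#'
#' Ordinary least squares of `y` on `x` with exact t-based inference on the
#' slope, and explicit site-exclusion bookkeeping: excluded sites are
#' dropped from the fit and recorded in the result, so re-including them
#' reproduces the unexcluded fit.
#'
#' @param x,y named per-site numeric vectors (names are site ids).
#' @param exclude site ids to drop before fitting.
#' @param labels length-2 character: predictor and response names.
#' @param log_x log10-transform the predictor first (requires positive x).
#' @return a one-row data frame of class `"mox_assoc"`: `predictor`,
#'   `response`, `slope`, `intercept`, `r2`, `p`, `n`, `excluded_sites`.
#' @export
fit_linear <- function(x, y, exclude = character(),
                       labels = c(deparse(substitute(x)),
                                  deparse(substitute(y))),
                       log_x = FALSE) {
  force(labels)
  if (is.null(names(x))) names(x) <- names(y) %||% seq_along(x)
  if (is.null(names(y))) names(y) <- names(x)
  keep <- setdiff(intersect(names(x), names(y)), exclude)
  xv <- x[keep]; yv <- y[keep]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 sites after exclusion")
  if (log_x) {
    if (any(xv <= 0)) stop("log transform requires positive predictor")
    xv <- log10(xv)
  }
  if (stats::sd(xv) == 0) stop("constant predictor")
  m <- stats::lm(yv ~ xv)
  sm <- summary(m)
  out <- data.frame(predictor = labels[1], response = labels[2],
                    slope = unname(stats::coef(m)[2]),
                    intercept = unname(stats::coef(m)[1]),
                    r2 = sm$r.squared,
                    p = sm$coefficients[2, 4],
                    n = length(xv),
                    excluded_sites = paste(exclude, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("mox_assoc", "data.frame")
  out
}

#' Half-saturation constants relative to porewater CH4
#'
#' Expresses each site's fitted \eqn{K_S} as a percentage of its measured
#' porewater CH4 concentration. Sites without detectable MOX
#' (\eqn{V_{max} = 0}) are excluded automatically, further sites by name.
#'
#' @param fits data frame with `site_id`, `vmax`, `ks` (as produced by
#'   [fit_site_panel()]), or a named list of `mm_kinetics` fits.
#' @param sites site table with `site_id` and `ch4_pore` (uM, > 0 for
#'   included sites).
#' @param exclude site ids to drop.
#' @return list: `per_site` (site_id, ks, ch4_pore, pct), `mean`, `range`.
#' @export
ks_vs_porewater_ratio <- function(fits, sites, exclude = character()) {
  if (!is.data.frame(fits))
    fits <- data.frame(site_id = names(fits),
                       vmax = vapply(fits, function(f) f$vmax, numeric(1)),
                       ks = vapply(fits, function(f) f$ks, numeric(1)))
  d <- merge(fits, sites[, c("site_id", "ch4_pore")], by = "site_id")
  d <- d[!(d$site_id %in% exclude) & d$vmax > 0, ]
  if (nrow(d) == 0) stop("all sites excluded")
  if (any(d$ch4_pore <= 0))
    stop("porewater CH4 must be positive for included sites")
  d$pct <- 100 * d$ks / d$ch4_pore
  list(per_site = d[, c("site_id", "ks", "ch4_pore", "pct")],
       mean = mean(d$pct), range = range(d$pct))
}

#' pmoA-harboring cells as a percentage of total cells
#'
#' Assumes one pmoA copy per genome, so copies m-2 translate directly into
#' cells m-2. Censored pmoA values (NA) propagate as censored percentages.
#'
#' @param pmoa pmoA copies m-2 (NA = below detection).
#' @param cells total cells m-2 (> 0).
#' @return percent of total cell abundance.
#' @examples
#' pmoa_fraction(2.65e6, 1e8)  # 2.65
#' @export
pmoa_fraction <- function(pmoa, cells) {
  if (any(cells <= 0)) stop("total cell abundance must be positive")
  100 * pmoa / cells
}

#' The panel association table
#'
#' Reproduces the standard regression battery over a fitted site panel:
#' kinetic parameters against stream- and porewater CH4, MOB relative
#' abundance against streamwater CH4, and \eqn{V_{max}} against MOB
#' relative abundance and pmoA counts. P-values are reported raw by default
#' (`p_adjust = "BH"` applies Benjamini-Hochberg).
#'
#' @param sites site table.
#' @param fits per-site kinetic fits (data frame `site_id`, `vmax`, `ks`).
#' @param mob_relab optional named per-site MOB relative abundance.
#' @param pmoa optional named per-site pmoA copies m-2.
#' @param exclude named list of per-analysis exclusion vectors; the special
#'   name `"default"` applies everywhere.
#' @param log_ch4 log10-transform CH4 predictors.
#' @param p_adjust `"none"` or a method for [stats::p.adjust()].
#' @return data frame of association results.
#' @export
associate <- function(sites, fits, mob_relab = NULL, pmoa = NULL,
                      exclude = list(), log_ch4 = FALSE,
                      p_adjust = "none") {
  v <- stats::setNames(fits$vmax, fits$site_id)
  k <- stats::setNames(fits$ks, fits$site_id)
  cs <- stats::setNames(sites$ch4_stream, sites$site_id)
  cp <- stats::setNames(sites$ch4_pore, sites$site_id)
  ex <- function(nm) unique(c(exclude$default, exclude[[nm]]))
  rows <- list(
    fit_linear(cs, v, ex("vmax_ch4_stream"), c("ch4_stream", "vmax"), log_ch4),
    fit_linear(cp, v, ex("vmax_ch4_pore"), c("ch4_pore", "vmax"), log_ch4),
    fit_linear(cs, k, ex("ks_ch4_stream"), c("ch4_stream", "ks"), log_ch4),
    fit_linear(cp, k, ex("ks_ch4_pore"), c("ch4_pore", "ks"), log_ch4))
  if (!is.null(mob_relab)) {
    rows <- c(rows, list(
      fit_linear(cs, mob_relab, ex("mob_ch4_stream"),
                 c("ch4_stream", "mob_relab"), log_ch4),
      fit_linear(mob_relab, v, ex("vmax_mob"), c("mob_relab", "vmax"))))
  }
  if (!is.null(pmoa))
    rows <- c(rows, list(
      fit_linear(pmoa, v, ex("vmax_pmoa"), c("pmoa", "vmax"))))
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  rownames(out) <- NULL
  out
}
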