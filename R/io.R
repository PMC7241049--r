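#' Write and read the site table
#'
#' Plain TSV, one row per site, as produced by [gen_sites()].
#'
#' @param sites site data frame.
#' @param path file path.
#' @return `read_sites` returns the validated site table.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  sites <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  validate_sites(sites)
  sites
}

#' Write and read an OTU table
#'
#' TSV with rows = OTUs: an `otu_id` column, one integer count column per
#' site, then `taxonomy` and `is_mob`.
#'
#' @param table a `"mox_otu_table"`.
#' @param path file path.
#' @return `read_otu_table` returns a validated `"mox_otu_table"`.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "mox_otu_table"))
  df <- data.frame(otu_id = colnames(table$counts),
                   t(table$counts), check.names = FALSE)
  df$taxonomy <- unname(table$taxonomy)
  df$is_mob <- unname(table$is_mob)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty OTU table: ", path)
  need <- c("otu_id", "taxonomy", "is_mob")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("OTU table is missing column(s): ", paste(miss, collapse = ", "))
  site_cols <- setdiff(names(df), need)
  if (length(site_cols) == 0) stop("OTU table has no site columns")
  cm <- as.matrix(df[site_cols])
  if (!is.numeric(cm)) stop("non-numeric counts in OTU table")
  bad <- which(cm != round(cm) | cm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count %s at OTU '%s', site '%s'",
                 format(cm[bad[1, , drop = FALSE]]),
                 df$otu_id[bad[1, 1]], site_cols[bad[1, 2]]))
  counts <- t(cm)
  dimnames(counts) <- list(site_cols, df$otu_id)
  structure(list(counts = counts,
                 taxonomy = stats::setNames(as.character(df$taxonomy),
                                            df$otu_id),
                 is_mob = stats::setNames(as.logical(df$is_mob),
                                          df$otu_id)),
            class = "mox_otu_table")
}

#' Write and read incubation series
#'
#' Long-format CSVs: `incubations.csv` holds one row per chamber, analyte
#' and time (`chamber, site, replicate, is_blank, sediment_area_m2,
#' water_volume_mL, time_h, analyte, value_uM`); `events.csv` holds the
#' withdrawal/replacement ledger (`chamber, time_h, withdrawn_mL, repl_ch4,
#' repl_co2, repl_o2`).
#'
#' @param series_list list of `incubation_series`.
#' @param series_path,events_path file paths.
#' @return `read_incubations` returns a list of `incubation_series`.
#' @export
write_incubations <- function(series_list, series_path, events_path) {
  if (inherits(series_list, "incubation_series"))
    series_list <- list(series_list)
  long <- do.call(rbind, lapply(series_list, function(s) {
    do.call(rbind, lapply(c("ch4", "co2", "o2"), function(a)
      data.frame(chamber = s$chamber_id, site = s$site_id,
                 replicate = s$replicate, is_blank = s$is_blank,
                 sediment_area_m2 = s$sediment_area,
                 water_volume_mL = s$water_volume,
                 time_h = s$conc$time_h, analyte = toupper(a),
                 value_uM = s$conc[[a]])))
  }))
  utils::write.csv(long, series_path, row.names = FALSE, quote = FALSE)
  ev <- do.call(rbind, lapply(series_list, function(s)
    cbind(chamber = s$chamber_id, s$events)))
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  invisible(series_path)
}

#' @rdname write_incubations
#' @export
read_incubations <- function(series_path, events_path) {
  long <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(ev$chamber), unique(long$chamber))
  if (length(unknown))
    stop("events reference unknown chamber(s): ",
         paste(unknown, collapse = ", "))
  lapply(split(long, long$chamber), function(ch) {
    wide <- lapply(split(ch, ch$analyte), function(a)
      a[order(a$time_h), "value_uM"])
    times <- sort(unique(ch$time_h))
    if (anyDuplicated(times)) stop("duplicated times for ", ch$chamber[1])
    evc <- ev[ev$chamber == ch$chamber[1],
              setdiff(names(ev), "chamber"), drop = FALSE]
    incubation_series(times = times, ch4 = wide$CH4, co2 = wide$CO2,
                      o2 = wide$O2, events = evc,
                      site_id = ch$site[1], replicate = ch$replicate[1],
                      is_blank = as.logical(ch$is_blank[1]),
                      sediment_area = ch$sediment_area_m2[1],
                      water_volume = ch$water_volume_mL[1])
  })
}

#' Read a run configuration
#'
#' A single nested key/value YAML file with a mandatory global `seed` and
#' optional per-stage parameter blocks (`sites`, `incubation`, `otu`,
#' `landscape`, `associate`).
#'
#' @param path YAML file.
#' @return named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run configuration must define a global seed")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Fit Michaelis-Menten kinetics for a panel of sites
#'
#' Simulates (or accepts) triplicate chamber incubations per site and fits
#' shared-parameter kinetics, returning the per-site parameter table.
#'
#' @param truth per-site truth (`site_id`, `vmax`, `ks`) from [gen_sites()].
#' @param chamber a [chamber_config()].
#' @param schedule sampling times, h.
#' @param n_replicates chambers per site.
#' @param noise_cv measurement noise CV.
#' @param seed integer seed.
#' @param mode fitting mode, see [mm_kinetics()].
#' @return data frame: `site_id`, `vmax`, `ks`, `se_vmax`, `se_ks`, `rss`,
#'   `n`, `converged`, `mode`, plus `true_vmax`, `true_ks`.
#' @export
fit_site_panel <- function(truth, chamber = chamber_config(),
                           schedule = seq(0, 96, by = 12),
                           n_replicates = 3, noise_cv = 0, seed = 1,
                           mode = "trajectory") {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    reps <- lapply(seq_len(n_replicates), function(r)
      simulate_incubation(truth$vmax[i], truth$ks[i], chamber,
                          schedule = schedule, noise_cv = noise_cv,
                          seed = seed + 1000 * i + r,
                          site_id = truth$site_id[i], replicate = r))
    f <- mm_kinetics(reps, mode = mode, seed = seed + i)
    data.frame(site_id = truth$site_id[i], vmax = f$vmax, ks = f$ks,
               se_vmax = f$se_vmax, se_ks = f$se_ks, rss = f$rss, n = f$n,
               converged = f$converged, mode = f$mode,
               true_vmax = truth$vmax[i], true_ks = truth$ks[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic pipeline
#'
#' simulate -> kinetics -> landscape -> associate -> report, driven by a
#' configuration list (see [read_run_config()]); omitted blocks use the
#' package defaults.
#'
#' @param config a `run_config` (or list) with at least `seed`.
#' @return list with `sites`, `truth`, `fits`, `otu`, `landscape`, `pmoa`,
#'   `assoc`, `report`.
#' @export
run_pipeline <- function(config = list(seed = 1)) {
  seed <- as.integer(config$seed %||% 1)
  noise <- config$sites$noise_cv %||% 0.15
  panel <- gen_sites(config$sites$n_sites %||% 14,
                     default_gradient_spec(noise_cv = noise), seed = seed)
  fits <- fit_site_panel(panel$truth,
                         schedule = seq(0, config$incubation$hours %||% 96,
                                        by = config$incubation$every_h %||% 12),
                         n_replicates = config$incubation$replicates %||% 3,
                         noise_cv = config$incubation$noise_cv %||% 0.05,
                         seed = seed)
  otu <- gen_otu_table(panel$sites, config$otu$n_otus %||% 2000,
                       seed = seed)
  land <- mob_landscape(otu$table,
                        cutoff = config$landscape$cutoff %||% 0.5,
                        k = config$landscape$k %||% 2, seed = seed)
  relab <- relative_abundance(otu$table)
  mob_relab <- rowSums(relab[, otu$table$is_mob, drop = FALSE])
  cells <- stats::setNames(rep(1e8, nrow(panel$sites)),
                           panel$sites$site_id)
  pmoa <- gen_pmoa_counts(mob_relab, cells, seed = seed)
  assoc <- associate(panel$sites, fits, mob_relab = mob_relab,
                     exclude = list(default = config$associate$exclude %||%
                                      character()))
  rep_out <- report(fits = fits, landscape = land, assoc = assoc)
  list(sites = panel$sites, truth = panel$truth, fits = fits, otu = otu,
       landscape = land, pmoa = pmoa, assoc = assoc, report = rep_out)
}

#' Summarize a pipeline run
#'
#' Builds a deterministic, human-readable summary plus a machine-readable
#' JSON string from completed stage outputs. Missing stages are listed
#' explicitly with a warning rather than failing.
#'
#' @param fits per-site kinetic table ([fit_site_panel()]).
#' @param landscape a `"mob_landscape"`.
#' @param assoc association table ([associate()]).
#' @param path optional file to write the JSON to.
#' @return list of class `"mox_report"`: `text` (character lines), `json`
#'   (string), `missing` (character).
#' @export
report <- function(fits = NULL, landscape = NULL, assoc = NULL,
                   path = NULL) {
  missing <- c(if (is.null(fits)) "fits", if (is.null(landscape)) "landscape",
               if (is.null(assoc)) "assoc")
  if (length(missing))
    warning("missing stage output(s): ", paste(missing, collapse = ", "))
  txt <- c("streamMOX pipeline report", "=========================")
  payload <- list(missing_stages = missing)
  if (!is.null(fits)) {
    txt <- c(txt, "", "Per-site Michaelis-Menten kinetics:",
             utils::capture.output(print(
               fits[, c("site_id", "vmax", "ks", "converged")],
               digits = 3, row.names = FALSE)))
    payload$kinetics <- fits
  }
  if (!is.null(landscape)) {
    sizes <- as.list(landscape$cluster_sizes)
    txt <- c(txt, "", sprintf(
      "Landscape: %d peaks; MOB clusters %s; stress %.4f",
      nrow(landscape$peaks),
      paste(sprintf("%s=%d", names(sizes), unlist(sizes)), collapse = " "),
      landscape$ordination$stress))
    payload$landscape <- list(
      n_peaks = nrow(landscape$peaks), cluster_sizes = sizes,
      stress = landscape$ordination$stress,
      excluded_sites = landscape$excluded_sites,
      hull_counts = lapply(landscape$hull_members, length))
  }
  if (!is.null(assoc)) {
    txt <- c(txt, "", "Associations:",
             utils::capture.output(print(assoc, digits = 3,
                                         row.names = FALSE)))
    payload$associations <- assoc
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  structure(list(text = txt, json = as.character(json), missing = missing),
            class = "mox_report")
}

#' @export
print.mox_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
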