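#' Default design of the planted methanotroph community structure
#'
#' Controls [gen_otu_table()]: the number of core (cluster-1) MOB OTUs
#' present across the panel with abundance scaling with streamwater CH4, the
#' number of cluster-2 MOB OTUs restricted to a declared site subset
#' (forested sites plus one agricultural site by default), and low-abundant
#' outlier MOB OTUs that belong to neither guild. A fraction of the non-MOB
#' background co-varies with each MOB cluster, which is what the convex-hull
#' co-occurrence analysis is meant to recover; these co-varying OTUs are
#' enriched in Gammaproteobacteria, Deltaproteobacteria and Acidobacteria
#' lineages so that taxonomic overrepresentation has a planted signal.
#'
#' @param n_cluster1,n_cluster2,n_outliers MOB OTU counts (23, 7 and 6 by
#'   default, i.e. 36 MOB OTUs).
#' @param cluster2_share fraction of a site's MOB abundance carried by
#'   cluster 2 at the cluster-2 sites.
#' @param cov_frac1,cov_frac2 fractions of non-MOB OTUs co-varying with each
#'   cluster.
#' @param mob_max_frac MOB relative abundance at the highest-CH4 site; MOB
#'   relative abundance scales linearly with streamwater CH4.
#' @param member_jitter lognormal sdlog of within-cluster, per-site abundance
#'   jitter (0 = perfectly tight planted clusters).
#' @param noise if `FALSE`, counts are deterministic rounded expectations;
#'   if `TRUE`, multinomial sampling at the site library size.
#' @param library_size reads per site (range when `noise`, midpoint
#'   otherwise).
#' @return a list of class `"mob_spec"`.
#' @export
default_mob_spec <- function(n_cluster1 = 23, n_cluster2 = 7, n_outliers = 6,
                             cluster2_share = 0.65, cov_frac1 = 0.10,
                             cov_frac2 = 0.04, mob_max_frac = 0.02,
                             member_jitter = 0.15, noise = TRUE,
                             library_size = c(150000, 250000)) {
  structure(list(n_cluster1 = n_cluster1, n_cluster2 = n_cluster2,
                 n_outliers = n_outliers, cluster2_share = cluster2_share,
                 cov_frac1 = cov_frac1, cov_frac2 = cov_frac2,
                 mob_max_frac = mob_max_frac, member_jitter = member_jitter,
                 noise = noise, library_size = library_size),
            class = "mob_spec")
}

.mob_genera1 <- c("Crenothrix", "Methylobacter", "Methylomonas")
.mob_genera2 <- c("Methylomonas", "Methylogaea", "Methylosarcina",
                  "Crenothrix", "Clonothrix")
.mob_lineage <- function(genus)
  paste0("k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; ",
         "o__Methylococcales; f__Methylococcaceae; g__", genus)

.bg_taxa <- data.frame(
  lineage = c(
    "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Burkholderiales; f__Comamonadaceae; g__Rhodoferax",
    "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Sphingomonadales; f__Sphingomonadaceae; g__Novosphingobium",
    "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Xanthomonadales; f__Xanthomonadaceae; g__unclassified",
    "k__Bacteria; p__Proteobacteria; c__Deltaproteobacteria; o__Myxococcales; f__unclassified; g__unclassified",
    "k__Bacteria; p__Bacteroidetes; c__Sphingobacteria; o__Sphingobacteriales; f__Chitinophagaceae; g__unclassified",
    "k__Bacteria; p__Acidobacteria; c__Acidobacteria_Gp6; o__unclassified; f__unclassified; g__unclassified",
    "k__Bacteria; p__Nitrospirae; c__Nitrospira; o__Nitrospirales; f__Nitrospiraceae; g__Nitrospira",
    "unclassified"),
  stringsAsFactors = FALSE)
.bg_weights  <- c(0.22, 0.20, 0.05, 0.06, 0.07, 0.05, 0.05, 0.30)
.cov1_weights <- c(0.03, 0.02, 0.35, 0.20, 0.02, 0.10, 0.03, 0.25)
.cov2_weights <- c(0.02, 0.02, 0.05, 0.04, 0.02, 0.15, 0.02, 0.68)

#' Generate a synthetic OTU table with planted MOB co-occurrence clusters
#'
#' Builds a sites x OTUs count table in which methanotrophic
#' (*Methylococcaceae*) OTUs form two planted co-occurrence clusters plus a
#' handful of unaffiliated low-abundance outliers, on top of a background
#' community turning over smoothly along the environmental gradient. Total
#' MOB relative abundance scales linearly with streamwater CH4 (zero noise
#' gives correlation ~1). The oligotrophic alpine sites (or, lacking an
#' `archetype` column, the site with the lowest streamwater CH4) carry
#' exactly one MOB OTU, the dominant core member, so the landscape
#' exclusion rule has samples to act on.
#'
#' @param sites site table from [gen_sites()] (needs `site_id`, `archetype`,
#'   `ch4_stream`).
#' @param n_otus total number of OTUs (MOB included).
#' @param mob_spec a [default_mob_spec()].
#' @param cluster2_sites site ids hosting cluster 2; default all forested
#'   sites plus the first agricultural site.
#' @param seed integer seed.
#' @return list with `table` (class `"mox_otu_table"`: `counts` sites x OTUs
#'   integer matrix, `taxonomy`, `is_mob`) and `truth` (per-OTU planted
#'   cluster assignment `"1"`, `"2"`, `"outlier"` or `"none"`, plus the
#'   per-site target MOB fraction).
#' @export
gen_otu_table <- function(sites, n_otus = 2000,
                          mob_spec = default_mob_spec(),
                          cluster2_sites = NULL, seed = 1) {
  ns <- nrow(sites)
  ms <- mob_spec
  n_mob <- ms$n_cluster1 + ms$n_cluster2 + ms$n_outliers
  if (n_otus <= n_mob + 10) stop("n_otus too small for the MOB design")
  if (is.null(cluster2_sites)) {
    cluster2_sites <- c(sites$site_id[sites$archetype == "forested"],
                        head(sites$site_id[sites$archetype == "agricultural"], 1))
  }
  if (ms$n_cluster2 > 0 && length(cluster2_sites) == 0)
    stop("cluster-2 OTUs requested but the cluster-2 site subset is empty")

  with_seed(seed, {
    # gradient positions: primary axis g follows the land-use gradient,
    # secondary axis h displaces the cluster-2 (mostly forested) sites
    arch_base <- c(alpine = 0.03, forested = 0.5, agricultural = 0.95)
    g <- arch_base[sites$archetype] + stats::runif(ns, -0.15, 0.15)
    # independent local-habitat coordinate: sites of one land-use class are
    # not replicates, and without this spread the between-site ranks become
    # block-structured and the nMDS collapses site groups to single points
    h <- ifelse(sites$site_id %in% cluster2_sites,
                stats::runif(ns, 0.75, 1.0), stats::runif(ns, 0.05, 0.55))

    n_cov1 <- round(ms$cov_frac1 * n_otus)
    n_cov2 <- round(ms$cov_frac2 * n_otus)
    n_bg <- n_otus - n_mob - n_cov1 - n_cov2

    frac <- ms$mob_max_frac * sites$ch4_stream / max(sites$ch4_stream)
    s2 <- ifelse(sites$site_id %in% cluster2_sites, ms$cluster2_share, 0)
    mass1 <- (1 - s2) * frac
    mass2 <- s2 * frac

    jit <- function(nr, nc) {
      if (ms$member_jitter <= 0) return(matrix(1, nr, nc))
      matrix(exp(stats::rnorm(nr * nc, 0, ms$member_jitter)), nr, nc)
    }

    # MOB blocks: per-OTU weights lognormal, sorted so the first core OTU
    # dominates the methanotrophic fraction panel-wide
    w1 <- sort(exp(stats::rnorm(ms$n_cluster1, 0, 1.2)), decreasing = TRUE)
    w1 <- w1 / sum(w1)
    mob1 <- outer(mass1, w1) * jit(ns, ms$n_cluster1)
    w2 <- if (ms$n_cluster2 > 0) {
      w <- sort(exp(stats::rnorm(ms$n_cluster2, 0, 1)), decreasing = TRUE)
      w / sum(w)
    } else numeric(0)
    mob2 <- outer(mass2, w2) * jit(ns, ms$n_cluster2)

    oligo <- if ("archetype" %in% names(sites) &&
                 any(sites$archetype == "alpine"))
      which(sites$archetype == "alpine") else which.min(sites$ch4_stream)
    mob_out <- matrix(0, ns, ms$n_outliers)
    if (ms$n_outliers > 0) {
      # each outlier occupies a single distinct non-alpine site: its species
      # score then sits at that site's position, peripheral to both cluster
      # centroids (which are abundance-weighted averages over many sites)
      hosts <- setdiff(seq_len(ns), oligo)
      hosts <- hosts[order(-abs(g[hosts] - mean(g[hosts])))]
      for (o in seq_len(ms$n_outliers)) {
        host <- hosts[((o - 1) %% length(hosts)) + 1]
        mob_out[host, o] <- 2e-5 * stats::runif(1, 0.5, 1.5)
      }
    }

    # background: 2-D Gaussian niches along (g, h). Roughly half the
    # community is cosmopolitan (very broad niches): stream communities
    # share most of their abundant taxa across sites, and without that core
    # the between-site dissimilarities saturate and the ordination
    # degenerates
    lam <- exp(stats::rnorm(n_bg, 0, 1.5))
    ug <- stats::runif(n_bg); uh <- stats::runif(n_bg)
    cosmo <- stats::runif(n_bg) < 0.45
    tau <- ifelse(cosmo, stats::runif(n_bg, 0.9, 2),
                  stats::runif(n_bg, 0.12, 0.35))
    bg <- t(lam * exp(-((outer(ug, g, function(u, x) (u - x)^2) +
                          outer(uh, h, function(u, x) (u - x)^2)) /
                         (2 * tau^2))))

    # co-varying non-MOB OTUs follow the cluster site-profiles
    lam1 <- exp(stats::rnorm(n_cov1, 0, 1))
    cov1 <- outer(mass1 / max(mean(mass1), 1e-12), lam1) * jit(ns, n_cov1)
    lam2 <- exp(stats::rnorm(n_cov2, 0, 1))
    cov2 <- outer(mass2 / max(mean(mass2), 1e-12), lam2) * jit(ns, n_cov2)

    nonmob <- cbind(bg, cov1, cov2)
    nonmob_tot <- rowSums(nonmob)
    mob_tot_target <- frac / (1 - frac) * nonmob_tot
    mobsum <- rowSums(mob1) + rowSums(mob2)
    scale_mob <- ifelse(mobsum > 0, mob_tot_target / mobsum, 0)
    mob1 <- mob1 * scale_mob
    mob2 <- mob2 * scale_mob
    mob_out <- mob_out * nonmob_tot

    # oligotrophic (alpine) sites carry a single MOB OTU, the dominant core
    # member; the landscape exclusion rule therefore drops them
    if (ms$n_cluster1 > 0) {
      keep1 <- mob1[oligo, 1]
      mob1[oligo, ] <- 0; mob1[oligo, 1] <- keep1
    }
    if (ms$n_cluster2 > 0) mob2[oligo, ] <- 0
    if (ms$n_outliers > 0) mob_out[oligo, ] <- 0

    intensity <- cbind(mob1, mob2, mob_out, nonmob)
    p <- intensity / rowSums(intensity)

    libsize <- if (ms$noise)
      round(stats::runif(ns, ms$library_size[1], ms$library_size[2]))
    else rep(round(mean(ms$library_size)), ns)
    counts <- t(vapply(seq_len(ns), function(i) {
      if (ms$noise) stats::rmultinom(1, libsize[i], p[i, ])[, 1]
      else round(libsize[i] * p[i, ])
    }, numeric(n_otus)))

    otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
    dimnames(counts) <- list(sites$site_id, otu_ids)

    cluster <- c(rep("1", ms$n_cluster1), rep("2", ms$n_cluster2),
                 rep("outlier", ms$n_outliers), rep("none", ncol(nonmob)))
    is_mob <- cluster %in% c("1", "2", "outlier")
    tax <- character(n_otus)
    tax[cluster == "1"] <- .mob_lineage(
      sample(.mob_genera1, ms$n_cluster1, TRUE, prob = c(0.6, 0.25, 0.15)))
    tax[cluster == "2"] <- .mob_lineage(
      sample(.mob_genera2, ms$n_cluster2, TRUE,
             prob = c(0.3, 0.25, 0.2, 0.15, 0.1)))
    tax[cluster == "outlier"] <- .mob_lineage(
      sample(c(.mob_genera1, .mob_genera2), ms$n_outliers, TRUE))
    nbg_all <- ncol(nonmob)
    bg_tax <- c(sample(.bg_taxa$lineage, n_bg, TRUE, prob = .bg_weights),
                sample(.bg_taxa$lineage, n_cov1, TRUE, prob = .cov1_weights),
                sample(.bg_taxa$lineage, n_cov2, TRUE, prob = .cov2_weights))
    tax[cluster == "none"] <- bg_tax

    table <- structure(list(counts = counts, taxonomy = stats::setNames(tax, otu_ids),
                            is_mob = stats::setNames(is_mob, otu_ids)),
                       class = "mox_otu_table")
    truth <- list(mob_cluster = stats::setNames(cluster, otu_ids),
                  mob_frac_target = stats::setNames(frac, sites$site_id),
                  cluster2_sites = cluster2_sites,
                  single_mob_site = sites$site_id[oligo], seed = seed)
    list(table = table, truth = truth)
  })
}

#' @export
print.mox_otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d sites x %d OTUs (%d methanotrophic)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_mob)))
  cat(sprintf("  library sizes %d-%d reads\n", min(rowSums(x$counts)),
              max(rowSums(x$counts))))
  invisible(x)
}

#' Synthetic pmoA gene counts per site
#'
#' pmoA copies per m2, proportional to the true MOB relative abundance times
#' total cell abundance (one pmoA copy per MOB genome), with multiplicative
#' lognormal noise; values below the detection limit are reported censored.
#'
#' @param mob_frac per-site MOB relative abundance (fraction of cells).
#' @param total_cells per-site total cell abundance, cells m-2.
#' @param prop proportionality constant (pmoA-harboring cells per unit MOB
#'   relative abundance); must be positive.
#' @param noise_cv lognormal CV of the counts.
#' @param detection_limit copies m-2 below which the value is censored.
#' @param seed integer seed.
#' @return data frame `site_id`, `pmoa_m2` (NA when censored), `censored`,
#'   `detection_limit`.
#' @export
gen_pmoa_counts <- function(mob_frac, total_cells, prop = 1,
                            noise_cv = 0, detection_limit = 1e4, seed = 1) {
  if (prop <= 0) stop("proportionality constant must be positive")
  if (any(total_cells <= 0)) stop("total_cells must be positive")
  ids <- names(mob_frac) %||% paste0("site", seq_along(mob_frac))
  with_seed(seed, {
    pmoa <- lnoise(prop * mob_frac * total_cells, noise_cv)
  })
  censored <- pmoa < detection_limit
  data.frame(site_id = ids,
             pmoa_m2 = ifelse(censored, NA_real_, pmoa),
             censored = censored, detection_limit = detection_limit,
             row.names = NULL)
}
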