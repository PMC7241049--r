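#' Relative abundances per site
#'
#' @param x a `"mox_otu_table"` or a sites x OTUs count matrix.
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "mox_otu_table")) x$counts else as.matrix(x)
  if (any(m < 0)) stop("negative counts")
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("site(s) with zero total counts: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  m / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)}: zero for
#' identical rows, one for rows with disjoint support, symmetric, bounded in
#' \[0, 1\].
#'
#' @param m sites x OTUs non-negative matrix (counts or proportions).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative input")
  if (any(rowSums(m) == 0)) stop("all-zero row: dissimilarity undefined")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <-
      sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Rank-based ordination minimizing Kruskal's stress-1
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} by alternating isotonic
#' regression (disparities monotone in the input dissimilarities) with
#' Guttman-transform configuration updates, over `n_starts` seeded restarts
#' (the first start is the classical-scaling solution, the rest are random).
#' Within each restart the stress trace is non-increasing by construction
#' (an update that would increase stress terminates the restart). The final
#' configuration is centered and rotated to its principal axes. Species
#' scores are relative-abundance-weighted averages of the sample scores.
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param k embedding dimension (2 by default); needs `n >= k + 2`.
#' @param n_starts number of restarts.
#' @param seed integer seed.
#' @param maxit,tol iteration cap and stress-change convergence tolerance
#'   per restart.
#' @param abundances optional sites x OTUs matrix (counts or proportions)
#'   from which species scores are computed.
#' @return an ordination object (class `"mox_ordination"`): `points` (n x k
#'   sample scores), `species` (OTU scores or NULL), `stress`,
#'   `stress_trace` of the winning restart, `converged`, `method = "nmds"`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1, maxit = 500,
                 tol = 1e-6, abundances = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 2) stop("need at least k + 2 points for nMDS")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  dl <- d[lower.tri(d)]
  if (all(dl == 0)) stop("all dissimilarities are zero")
  ord_delta <- order(dl)

  run_start <- function(X) {
    trace <- numeric(0)
    best_X <- X
    prev_stress <- Inf
    for (it in seq_len(maxit)) {
      D <- as.matrix(stats::dist(X))
      dv <- D[lower.tri(D)]
      iso <- stats::isoreg(seq_along(ord_delta), dv[ord_delta])
      dhat_v <- numeric(length(dv))
      dhat_v[ord_delta] <- iso$yf
      stress <- sqrt(sum((dv - dhat_v)^2) / sum(dv^2))
      if (stress > prev_stress + 1e-12) break  # guard: keep monotone descent
      trace <- c(trace, stress)
      best_X <- X
      if (prev_stress - stress < tol && it > 1) break
      prev_stress <- stress
      Dhat <- matrix(0, n, n)
      Dhat[lower.tri(Dhat)] <- dhat_v
      Dhat <- Dhat + t(Dhat)
      ratio <- ifelse(D > 1e-12, Dhat / D, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    list(X = best_X, stress = utils::tail(trace, 1), trace = trace)
  }

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      X0 <- if (s == 1) {
        cm <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
        if (is.null(cm) || ncol(cm) < k)
          matrix(stats::rnorm(n * k), n, k) else cm
      } else matrix(stats::rnorm(n * k), n, k)
      res <- run_start(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
  })
  X <- scale(best$X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v  # principal-axis rotation
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  species <- NULL
  if (!is.null(abundances)) {
    a <- as.matrix(abundances)
    a <- a / rowSums(a)
    w <- colSums(a)
    keep <- w > 0
    species <- matrix(NA_real_, ncol(a), k,
                      dimnames = list(colnames(a), colnames(X)))
    species[keep, ] <- t(a[, keep, drop = FALSE]) %*% X / w[keep]
  }
  structure(list(points = X, species = species, stress = best$stress,
                 stress_trace = best$trace, method = "nmds",
                 converged = length(best$trace) < maxit),
            class = "mox_ordination")
}

#' Principal component analysis of site environmental variables
#'
#' Centered (and by default unit-scaled) PCA via singular value
#' decomposition, for characterizing the environmental gradient.
#'
#' @param env sites x variables numeric matrix or data frame.
#' @param scale scale columns to unit variance (constant columns are then an
#'   error).
#' @return `"mox_ordination"` with `points` (scores), `rotation`
#'   (loadings), `var_frac` (non-increasing explained-variance fractions),
#'   `method = "pca"`.
#' @export
pca_env <- function(env, scale = TRUE) {
  env <- as.matrix(env)
  if (nrow(env) < 2) stop("need at least 2 sites")
  if (scale && any(apply(env, 2, stats::sd) == 0))
    stop("constant column(s) cannot be scaled: ",
         paste(colnames(env)[apply(env, 2, stats::sd) == 0], collapse = ", "))
  p <- stats::prcomp(env, center = TRUE, scale. = scale)
  structure(list(points = p$x, rotation = p$rotation,
                 var_frac = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev,
                 center = p$center, scale = p$scale,
                 species = NULL, stress = NULL, method = "pca"),
            class = "mox_ordination")
}

#' @export
print.mox_ordination <- function(x, ...) {
  if (x$method == "nmds") {
    cat(sprintf("nMDS ordination: %d samples, %d dims, stress-1 = %.4f\n",
                nrow(x$points), ncol(x$points), x$stress))
    if (!is.null(x$species))
      cat(sprintf("  species scores for %d OTUs\n", nrow(x$species)))
  } else {
    cat(sprintf("PCA: %d samples; variance explained %s\n", nrow(x$points),
                paste(sprintf("%.1f%%", 100 * utils::head(x$var_frac, 3)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each variable, regresses the (centered) variable on the first two
#' ordination axes; the arrow is the unit direction of steepest increase
#' scaled by the multiple correlation, the goodness of fit is the squared
#' multiple correlation R2, and significance is assessed by permuting the
#' variable's values over sites.
#'
#' @param ord a `"mox_ordination"` (or any list with `points`).
#' @param vars sites x variables data frame/matrix, rows matching the
#'   ordination samples.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return data frame: `variable`, arrow components `dx`, `dy` (scaled by
#'   sqrt(R2)), `r2`, `p`.
#' @export
fit_vectors <- function(ord, vars, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- ord$points[, 1:2, drop = FALSE]
  vars <- as.data.frame(vars)
  if (nrow(vars) != nrow(X)) stop("vars must have one row per sample")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  XtXi <- solve(crossprod(Xc))
  Pmat <- Xc %*% XtXi %*% t(Xc)
  r2_of <- function(y) {
    yc <- y - mean(y)
    ss <- sum(yc^2)
    drop(crossprod(yc, Pmat %*% yc)) / ss
  }
  with_seed(seed, {
    out <- lapply(names(vars), function(v) {
      y <- vars[[v]]
      if (stats::sd(y) == 0)
        stop("variable '", v, "' is constant; direction undefined")
      r2 <- r2_of(y)
      b <- drop(XtXi %*% crossprod(Xc, y - mean(y)))
      u <- b / sqrt(sum(b^2))
      perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(y)),
                     numeric(1))
      p <- (1 + sum(perm >= r2)) / (n_perm + 1)
      data.frame(variable = v, dx = u[1] * sqrt(r2), dy = u[2] * sqrt(r2),
                 r2 = r2, p = p)
    })
  })
  do.call(rbind, out)
}

#' Smooth surface of a site variable over ordination space
#'
#' Fits a penalized low-rank thin-plate smoother (via [mgcv::gam()], GCV
#' penalty selection) of a per-site variable over the first two ordination
#' axes, and reports a leave-one-out cross-validated R2.
#'
#' @param ord a `"mox_ordination"`.
#' @param var per-site values.
#' @param k basis dimension (capped at n - 2).
#' @return list: `model` (the gam), `fitted`, `loo_r2`, and `predict_fun`
#'   (function of new x/y).
#' @export
fit_surface <- function(ord, var, k = 10) {
  X <- ord$points[, 1:2, drop = FALSE]
  n <- nrow(X)
  if (n < 6) stop("need at least 6 sites for a surface")
  dat <- data.frame(y = var, x1 = X[, 1], x2 = X[, 2])
  kk <- min(k, n - 2)
  fit_one <- function(d) mgcv::gam(y ~ s(x1, x2, k = kk), data = d,
                                   method = "GCV.Cp")
  m <- fit_one(dat)
  loo <- vapply(seq_len(n), function(i) {
    mi <- fit_one(dat[-i, ])
    as.numeric(stats::predict(mi, dat[i, , drop = FALSE]))
  }, numeric(1))
  ss_tot <- sum((var - mean(var))^2)
  loo_r2 <- if (ss_tot > 0) 1 - sum((var - loo)^2) / ss_tot else NA_real_
  list(model = m, fitted = stats::fitted(m), loo_r2 = loo_r2,
       predict_fun = function(x, y)
         as.numeric(stats::predict(m, data.frame(x1 = x, x2 = y))))
}

#' Kernel-density landscape of species scores
#'
#' Two-dimensional Gaussian kernel density of OTU ordination scores on a
#' regular grid covering the scores with a margin, the "community
#' composition landscape" whose peaks mark groups of co-occurring taxa.
#' Default bandwidth is Scott's rule per axis
#' (\eqn{h_d = \sigma_d\, n^{-1/6}}).
#'
#' @param scores OTUs x 2 matrix of species scores.
#' @param bandwidth `"scott"` or a numeric length-2 (or 1) bandwidth.
#' @param grid_n grid resolution per axis.
#' @param margin fractional margin added around the score range.
#' @return class `"mox_density"`: grid vectors `x`, `y`, density matrix `z`
#'   (`grid_n` x `grid_n`, `z[i, j]` at `(x[i], y[j])`), `bandwidth`.
#' @export
density_landscape <- function(scores, bandwidth = "scott", grid_n = 100,
                              margin = 0.05) {
  scores <- as.matrix(scores)
  scores <- scores[stats::complete.cases(scores), , drop = FALSE]
  n <- nrow(scores)
  if (n < 2) stop("need at least 2 OTUs")
  if (all(apply(scores, 2, stats::sd) == 0))
    stop("degenerate scores: all points identical")
  if (identical(bandwidth, "scott")) {
    bw <- apply(scores, 2, stats::sd) * n^(-1 / 6)
    bw[bw == 0] <- diff(range(scores)) * 0.01 + 1e-9
  } else {
    bw <- rep(as.numeric(bandwidth), length.out = 2)
  }
  rng <- apply(scores, 2, range)
  span <- rng[2, ] - rng[1, ]
  # pad by the larger of the fractional margin and the kernel tail (3.5 sd)
  # so the density integrates to ~1 over the grid
  pad <- pmax(margin * span, 3.5 * bw)
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = grid_n)
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = grid_n)
  Kx <- outer(gx, scores[, 1], function(g, s) stats::dnorm(g, s, bw[1]))
  Ky <- outer(gy, scores[, 2], function(g, s) stats::dnorm(g, s, bw[2]))
  z <- (Kx %*% t(Ky)) / n
  structure(list(x = gx, y = gy, z = z, bandwidth = bw, n = n),
            class = "mox_density")
}

#' Density peaks above a cutoff
#'
#' Connected components (8-connectivity on the grid) of the region where the
#' density exceeds `cutoff`; each component is reported with the location
#' and height of its maximum. The number of peaks is non-increasing in the
#' cutoff.
#'
#' @param dens a [density_landscape()] result.
#' @param cutoff density threshold (>= 0); a cutoff above the global maximum
#'   yields zero peaks.
#' @return data frame `peak`, `x`, `y`, `height`, `n_cells`, ordered by
#'   decreasing height.
#' @export
find_peaks <- function(dens, cutoff = 0.5) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  z <- dens$z
  mask <- z > cutoff
  if (!any(mask)) return(data.frame(peak = integer(0), x = numeric(0),
                                    y = numeric(0), height = numeric(0),
                                    n_cells = integer(0)))
  nr <- nrow(z); nc <- ncol(z)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    i0 <- idx[s, 1]; j0 <- idx[s, 2]
    if (lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1, 2)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  out <- lapply(seq_len(cur), function(cc) {
    cells <- which(lab == cc, arr.ind = TRUE)
    h <- z[cells]
    m <- which.max(h)
    data.frame(peak = cc, x = dens$x[cells[m, 1]], y = dens$y[cells[m, 2]],
               height = h[m], n_cells = nrow(cells))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$height), ]
  out$peak <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cluster methanotrophic OTUs in ordination space
#'
#' Seeded multi-start k-means of the MOB species scores, with an explicit
#' outlier rule: an OTU is left unassigned when it lies farther than
#' `outlier_rule` times the cluster's median radius (floored at 10% of the
#' smallest inter-centroid distance, so the rule is well defined for
#' perfectly tight clusters) from every centroid. Centroids are refit on the
#' retained members and clusters are relabeled by decreasing size.
#'
#' @param mob_scores MOB-OTUs x 2 score matrix.
#' @param k number of clusters.
#' @param n_init k-means restarts.
#' @param seed integer seed.
#' @param outlier_rule distance multiplier of the rule above; `Inf` disables
#'   it.
#' @return character vector (named by OTU) of labels `"1"`, ..., `"k"` or
#'   `"unassigned"`.
#' @export
cluster_mob <- function(mob_scores, k = 2, n_init = 20, seed = 1,
                        outlier_rule = 3) {
  mob_scores <- as.matrix(mob_scores)
  if (nrow(mob_scores) < k) stop("fewer MOB OTUs than clusters")
  with_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(mob_scores, centers = k, nstart = n_init,
                    iter.max = 100))
  })
  centers <- km$centers
  dists <- vapply(seq_len(k), function(c)
    sqrt(rowSums((mob_scores - matrix(centers[c, ], nrow(mob_scores), 2,
                                      byrow = TRUE))^2)),
    numeric(nrow(mob_scores)))
  dists <- matrix(dists, ncol = k)
  if (k >= 2 && is.finite(outlier_rule)) {
    floor_d <- 0.1 * min(stats::dist(centers))
    thr <- vapply(seq_len(k), function(c) {
      rad <- stats::median(dists[km$cluster == c, c])
      outlier_rule * max(rad, floor_d)
    }, numeric(1))
    unassigned <- vapply(seq_len(nrow(mob_scores)), function(i)
      all(dists[i, ] > thr), logical(1))
  } else {
    unassigned <- rep(FALSE, nrow(mob_scores))  # rule needs >= 2 centroids
  }
  lab <- km$cluster
  if (any(unassigned) && any(!unassigned)) {
    centers <- t(vapply(seq_len(k), function(c) {
      mem <- !unassigned & lab == c
      if (any(mem)) colMeans(mob_scores[mem, , drop = FALSE])
      else centers[c, ]
    }, numeric(2)))
    d2 <- vapply(seq_len(k), function(c)
      rowSums((mob_scores - matrix(centers[c, ], nrow(mob_scores), 2,
                                   byrow = TRUE))^2),
      numeric(nrow(mob_scores)))
    lab <- max.col(-matrix(d2, ncol = k))
  }
  sizes <- table(factor(lab[!unassigned], levels = seq_len(k)))
  remap <- order(order(-as.numeric(sizes)))  # largest cluster becomes "1"
  out <- as.character(remap[lab])
  out[unassigned] <- "unassigned"
  stats::setNames(out, rownames(mob_scores))
}

# boundary-inclusive point-in-polygon (even-odd rule + on-edge test)
.point_in_poly <- function(px, py, vx, vy) {
  nv <- length(vx)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
      cross <- (xj - xi) * (y - yi) - (x - xi) * (yj - yi)
      if (abs(cross) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12)
        return(TRUE)  # on the boundary counts as inside
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    inside
  }, logical(1))
}

#' Non-MOB OTUs inside a MOB cluster's convex hull
#'
#' Draws the convex hull around a MOB cluster's species scores and returns
#' the non-MOB OTUs whose scores fall inside it (boundary points count as
#' inside). Collinear clusters degrade to a thin buffered segment with a
#' warning.
#'
#' @param cluster_scores scores of the cluster's MOB OTUs (>= 3 rows).
#' @param all_scores species scores of all OTUs (rownames = OTU ids).
#' @param mob_flags logical per OTU in `all_scores`; only `FALSE` entries
#'   are candidates.
#' @return character vector of co-occurring non-MOB OTU ids.
#' @export
hull_members <- function(cluster_scores, all_scores, mob_flags) {
  cluster_scores <- as.matrix(cluster_scores)
  all_scores <- as.matrix(all_scores)
  if (nrow(cluster_scores) < 3) stop("need at least 3 cluster points")
  hull <- grDevices::chull(cluster_scores)
  vx <- cluster_scores[hull, 1]; vy <- cluster_scores[hull, 2]
  if (length(hull) < 3) {
    warning("collinear cluster scores; using a buffered segment")
    ends <- cluster_scores[hull, , drop = FALSE]
    u <- ends[2, ] - ends[1, ]
    nrm <- c(-u[2], u[1])
    nrm <- nrm / max(sqrt(sum(nrm^2)), 1e-12) * 0.01 * sqrt(sum(u^2))
    quad <- rbind(ends[1, ] + nrm, ends[2, ] + nrm,
                  ends[2, ] - nrm, ends[1, ] - nrm)
    vx <- quad[, 1]; vy <- quad[, 2]
  }
  cand <- which(!mob_flags & stats::complete.cases(all_scores))
  inside <- .point_in_poly(all_scores[cand, 1], all_scores[cand, 2], vx, vy)
  rownames(all_scores)[cand[inside]]
}

.rank_prefix <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__")

#' Extract a taxonomic rank from lineage strings
#'
#' @param taxonomy character lineage strings
#'   (`"k__...; p__...; c__...; ..."`); entries without the rank yield
#'   `"unclassified"`.
#' @param rank one of kingdom/phylum/class/order/family/genus.
#' @return character vector of taxa.
#' @export
taxon_at_rank <- function(taxonomy, rank = "class") {
  pre <- .rank_prefix[[match.arg(rank, names(.rank_prefix))]]
  out <- rep("unclassified", length(taxonomy))
  hit <- regmatches(taxonomy,
                    regexpr(paste0(pre, "[^;]+"), taxonomy))
  has <- grepl(paste0(pre, "[^;]+"), taxonomy)
  val <- sub(pre, "", hit, fixed = TRUE)
  val <- trimws(val)
  out[has] <- val
  out[out == "" | is.na(out)] <- "unclassified"
  out
}

#' Identify methanotrophic OTUs from taxonomy
#'
#' @param taxonomy lineage strings.
#' @param patterns taxa marking obligate methanotrophs (family
#'   *Methylococcaceae* by default); matched anywhere in the lineage.
#' @return logical vector.
#' @export
is_mob_taxonomy <- function(taxonomy, patterns = "Methylococcaceae") {
  Reduce(`|`, lapply(patterns, grepl, x = taxonomy, fixed = TRUE))
}

#' Taxonomic overrepresentation of a set of OTUs
#'
#' For each taxon at the chosen rank: its share among the member OTUs, its
#' share in the background, and the ratio of the two (> 1 means
#' overrepresented among the members). Optionally a one-sided permutation
#' p-value from random member sets of equal size.
#'
#' @param members OTU ids (subset of `background`).
#' @param taxonomy named lineage strings covering the background.
#' @param background all OTU ids.
#' @param rank taxonomic rank.
#' @param n_perm permutations (0 = none).
#' @param seed integer seed.
#' @return data frame `taxon`, `share_in`, `share_bg`, `ratio` (and `p`).
#' @export
overrepresentation <- function(members, taxonomy, background,
                               rank = "class", n_perm = 0, seed = 1) {
  if (length(members) == 0) stop("empty member list")
  if (!all(members %in% background))
    stop("members must be a subset of the background")
  tx <- taxon_at_rank(taxonomy[background], rank)
  names(tx) <- background
  taxa <- sort(unique(tx))
  share_bg <- as.numeric(table(factor(tx, taxa))) / length(background)
  tm <- factor(tx[members], taxa)
  share_in <- as.numeric(table(tm)) / length(members)
  out <- data.frame(taxon = taxa, share_in = share_in, share_bg = share_bg,
                    ratio = ifelse(share_bg > 0, share_in / share_bg, NA))
  if (n_perm > 0) {
    with_seed(seed, {
      perm <- matrix(0, n_perm, length(taxa))
      for (b in seq_len(n_perm)) {
        smp <- sample(background, length(members))
        perm[b, ] <- as.numeric(table(factor(tx[smp], taxa))) /
          length(members)
      }
    })
    out$p <- vapply(seq_along(taxa), function(j)
      (1 + sum(perm[, j] >= share_in[j])) / (n_perm + 1), numeric(1))
  }
  out
}

#' The MOB community-landscape pipeline
#'
#' Runs the full enterotype-style analysis on an OTU table: drop samples
#' containing at most one methanotrophic OTU (such oligotrophic samples
#' cannot inform MOB co-occurrence), compute relative abundances,
#' Bray-Curtis dissimilarities and a 2-D nMDS with species scores, build the
#' kernel-density landscape of all OTU scores and call its peaks, k-means
#' cluster the MOB OTUs (with the unassigned-outlier rule), collect non-MOB
#' OTUs inside each cluster's convex hull and tabulate their taxonomic
#' overrepresentation.
#'
#' @param table a `"mox_otu_table"` (counts, taxonomy, is_mob). If `is_mob`
#'   is missing it is derived from the taxonomy via [is_mob_taxonomy()].
#' @param k number of MOB clusters.
#' @param cutoff density cutoff for peak calling.
#' @param seed integer seed driving nMDS restarts and k-means.
#' @param n_starts nMDS restarts.
#' @param grid_n,bandwidth density grid resolution and bandwidth rule.
#' @param outlier_rule see [cluster_mob()].
#' @param overrep_rank taxonomic rank for the overrepresentation tables.
#' @param min_mob_otus samples with fewer MOB OTUs than this are excluded
#'   (2, i.e. "more than one", by default).
#' @return class `"mob_landscape"`: `ordination`, `density`, `peaks`,
#'   `mob_clusters` (labels), `cluster_sizes`, `hull_members`, `overrep`,
#'   `excluded_sites`, `params`.
#' @export
mob_landscape <- function(table, k = 2, cutoff = 0.5, seed = 1,
                          n_starts = 20, grid_n = 100, bandwidth = "scott",
                          outlier_rule = 3, overrep_rank = "class",
                          min_mob_otus = 2) {
  stopifnot(inherits(table, "mox_otu_table"))
  counts <- table$counts
  is_mob <- table$is_mob %||% is_mob_taxonomy(table$taxonomy)
  mob_per_site <- rowSums(counts[, is_mob, drop = FALSE] > 0)
  excluded <- rownames(counts)[mob_per_site < min_mob_otus]
  keep_sites <- setdiff(rownames(counts), excluded)
  m <- counts[keep_sites, , drop = FALSE]
  present <- colSums(m) > 0
  m <- m[, present, drop = FALSE]
  mobp <- is_mob[present]

  relab <- relative_abundance(m)
  d <- bray_curtis(relab)
  ord <- nmds(d, k = 2, n_starts = n_starts, seed = seed,
              abundances = relab)
  dens <- density_landscape(ord$species, bandwidth = bandwidth,
                            grid_n = grid_n)
  peaks <- find_peaks(dens, cutoff = cutoff)
  mob_scores <- ord$species[mobp, , drop = FALSE]
  labels <- cluster_mob(mob_scores, k = k, seed = seed,
                        outlier_rule = outlier_rule)
  sizes <- table(factor(labels, c(as.character(seq_len(k)), "unassigned")))
  hulls <- overrep <- list()
  otu_ids <- colnames(m)
  for (cl in as.character(seq_len(k))) {
    mem <- names(labels)[labels == cl]
    if (length(mem) >= 3) {
      hm <- hull_members(ord$species[mem, , drop = FALSE], ord$species,
                         mobp)
      hulls[[cl]] <- hm
      if (length(hm) > 0)
        overrep[[cl]] <- overrepresentation(hm, table$taxonomy,
                                            otu_ids[!mobp],
                                            rank = overrep_rank)
    }
  }
  structure(list(ordination = ord, density = dens, peaks = peaks,
                 mob_clusters = labels, cluster_sizes = sizes,
                 hull_members = hulls, overrep = overrep,
                 excluded_sites = excluded,
                 params = list(k = k, cutoff = cutoff, seed = seed,
                               outlier_rule = outlier_rule,
                               bandwidth = bandwidth, grid_n = grid_n)),
            class = "mob_landscape")
}

#' @export
print.mob_landscape <- function(x, ...) {
  cat("MOB community landscape\n")
  cat(sprintf("  nMDS stress-1 %.4f over %d samples (excluded: %s)\n",
              x$ordination$stress, nrow(x$ordination$points),
              if (length(x$excluded_sites)) paste(x$excluded_sites,
                                                  collapse = ", ")
              else "none"))
  cat(sprintf("  %d density peaks above cutoff %.2f (max density %.2f)\n",
              nrow(x$peaks), x$params$cutoff, max(x$density$z)))
  cat("  MOB clusters:",
      paste(sprintf("%s=%d", names(x$cluster_sizes), x$cluster_sizes),
            collapse = ", "), "\n")
  for (cl in names(x$hull_members))
    cat(sprintf("  cluster %s hull contains %d non-MOB OTUs\n", cl,
                length(x$hull_members[[cl]])))
  invisible(x)
}

#' @export
plot.mob_landscape <- function(x, ...) {
  graphics::image(x$density$x, x$density$y, x$density$z,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "NMDS1", ylab = "NMDS2",
                  main = "MOB community landscape", ...)
  graphics::contour(x$density$x, x$density$y, x$density$z,
                    levels = x$params$cutoff, add = TRUE, lwd = 0.5)
  sp <- x$ordination$species
  lab <- x$mob_clusters
  mob_ids <- names(lab)
  cols <- c(`1` = "red", `2` = "blue", unassigned = "grey40")
  graphics::points(sp[mob_ids, 1], sp[mob_ids, 2], pch = 19,
                   col = cols[lab], cex = 0.8)
  invisible(x)
}
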