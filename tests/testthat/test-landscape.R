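test_that("relative abundance rows sum to one", {
  expect_equal(unname(relative_abundance(matrix(c(0, 7), 1))), t(c(0, 1)))
  m <- matrix(3, 2, 5)
  expect_true(all(relative_abundance(m) == 0.2))
  set.seed(1)
  r <- relative_abundance(matrix(rpois(60, 4) + 1, 6, 10))
  expect_equal(rowSums(r), rep(1, 6), tolerance = 1e-12)
  expect_error(relative_abundance(matrix(c(1, 0, 0, 0), 2)), "zero total")
})

test_that("Bray-Curtis satisfies its axioms", {
  expect_equal(bray_curtis(rbind(c(1, 0), c(0.5, 0.5)))[1, 2], 0.5)
  set.seed(2)
  m <- matrix(rexp(80), 8, 10)
  d <- bray_curtis(m)
  expect_equal(diag(d), rep(0, 8), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(bray_curtis(rbind(a = c(1, 2, 0), b = c(0, 0, 5)))[1, 2], 1)
  expect_equal(bray_curtis(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  expect_error(bray_curtis(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("nMDS embeds line-like and planted 2-D configurations", {
  x <- seq(0, 1, length.out = 10)
  ordl <- nmds(as.matrix(dist(x)), seed = 1)
  expect_lt(ordl$stress, 0.01)
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  ord <- nmds(as.matrix(dist(X)), n_starts = 20, seed = 1, maxit = 1000,
              tol = 1e-9)
  expect_lt(procrustes_error(X, ord$points), 1e-3)
})

test_that("nMDS stress descends monotonically within the winning restart", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 400, seed = 4)
  keep <- rowSums(ot$table$counts[, ot$table$is_mob] > 0) >= 2
  relab <- relative_abundance(ot$table$counts[keep, ])
  ord <- nmds(bray_curtis(relab), abundances = relab, seed = 2)
  expect_true(all(diff(ord$stress_trace) <= 1e-12))
  expect_equal(ord$stress, tail(ord$stress_trace, 1))
  # species scores are abundance-weighted averages of sample scores
  j <- which(colSums(relab) > 0)[5]
  w <- relab[, j]
  expect_equal(unname(ord$species[j, ]),
               unname(colSums(ord$points * w) / sum(w)))
})

test_that("nMDS stress agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 400, seed = 5)
  relab <- relative_abundance(ot$table)
  d <- bray_curtis(relab)
  ours <- nmds(d, seed = 1)
  ref <- vegan::monoMDS(as.dist(d), k = 2, model = "global")
  expect_lt(abs(ours$stress - ref$stress), 0.03)
})

test_that("environmental PCA matches the closed-form eigendecomposition", {
  set.seed(3)
  S <- matrix(c(2, 1.2, 1.2, 1), 2)
  X <- matrix(rnorm(4000), 2000, 2) %*% chol(S)
  ord <- pca_env(X, scale = FALSE)
  ev <- eigen(cov(X))
  expect_equal(abs(sum(ord$rotation[, 1] * ev$vectors[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(ord$var_frac, ev$values / sum(ev$values), tolerance = 1e-8)
  expect_true(all(diff(ord$var_frac) <= 0))
  expect_lt(abs(cor(ord$points[, 1], ord$points[, 2])), 1e-8)
  # reconstruction from all components is exact
  rec <- ord$points %*% t(ord$rotation) +
    matrix(ord$center, nrow(X), 2, byrow = TRUE)
  expect_equal(rec, X, ignore_attr = TRUE)
  # duplicated variable adds no new variance direction
  ord2 <- pca_env(cbind(X, X[, 1]), scale = FALSE)
  expect_lt(ord2$var_frac[3], 1e-12)
  expect_error(pca_env(cbind(X, 1)), "constant")
})

test_that("vector fitting recovers axis-aligned variables and rejects
           constants", {
  panel <- default_panel()
  ord <- pca_env(panel$sites[, c("altitude", "temperature", "ph", "doc")])
  fv <- fit_vectors(ord, data.frame(ax1 = ord$points[, 1]), n_perm = 199,
                    seed = 1)
  expect_equal(fv$r2, 1, tolerance = 1e-9)
  expect_equal(abs(fv$dx), 1, tolerance = 1e-6)
  expect_equal(fv$dy, 0, tolerance = 1e-6)
  expect_lt(fv$p, 0.05)
  expect_error(fit_vectors(ord, data.frame(k = rep(1, 14))), "constant")
  expect_error(fit_vectors(ord, data.frame(a = rnorm(14)), n_perm = 0),
               "n_perm")
})

test_that("vector fitting agrees with vegan envfit", {
  skip_if_not_installed("vegan")
  panel <- default_panel()
  ord <- pca_env(panel$sites[, c("altitude", "temperature", "ph", "doc")])
  vars <- data.frame(ch4 = panel$sites$ch4_stream,
                     pore = panel$sites$ch4_pore)
  ours <- fit_vectors(ord, vars, n_perm = 499, seed = 1)
  ref <- vegan::envfit(ord$points[, 1:2], vars, permutations = 499)
  expect_equal(ours$r2, unname(ref$vectors$r), tolerance = 1e-8)
  expect_equal(abs(ours$p - unname(ref$vectors$pvals)) < 0.1, c(TRUE, TRUE))
})

test_that("surface fitting reproduces planes, constants and bowls", {
  set.seed(3)
  ord <- list(points = cbind(runif(14, -1, 1), runif(14, -1, 1)))
  lin <- 2 + 3 * ord$points[, 1] - ord$points[, 2]
  fs <- fit_surface(ord, lin)
  expect_equal(fs$fitted, lin, tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(fs$loo_r2, 0.95)
  fc <- fit_surface(ord, rep(2, 14))
  expect_equal(unname(fc$fitted), rep(2, 14), tolerance = 1e-8)
  bowl <- ord$points[, 1]^2 + ord$points[, 2]^2
  fb <- fit_surface(ord, bowl)
  rmse <- sqrt(mean((fb$fitted - bowl)^2))
  expect_lt(rmse / diff(range(bowl)), 0.05)
  expect_error(fit_surface(list(points = ord$points[1:4, ]), 1:4),
               "at least 6")
})

test_that("the density landscape is a proper 2-D kernel density", {
  set.seed(1)
  one <- matrix(rnorm(300, 0, 0.3), 150, 2)
  d1 <- density_landscape(one, grid_n = 80)
  expect_true(all(d1$z >= 0))
  pk <- find_peaks(d1, 0.5 * max(d1$z))
  expect_equal(nrow(pk), 1)
  expect_lt(sqrt(sum((c(pk$x, pk$y) - colMeans(one))^2)), 0.15)
  expect_equal(sum(d1$z) * diff(d1$x)[1] * diff(d1$y)[1], 1,
               tolerance = 0.02)
  blobs <- rbind(matrix(rnorm(300, 0, 0.2), 150, 2),
                 matrix(rnorm(300, 3, 0.2), 150, 2))
  d2 <- density_landscape(blobs, grid_n = 80)
  expect_equal(sum(d2$z) * diff(d2$x)[1] * diff(d2$y)[1], 1,
               tolerance = 0.02)
  expect_error(density_landscape(matrix(1, 5, 2)), "degenerate")
  expect_error(density_landscape(matrix(1, 1, 2)), "at least 2")
})

test_that("peak calling respects the cutoff and connectivity", {
  set.seed(1)
  blobs <- rbind(matrix(rnorm(300, 0, 0.2), 150, 2),
                 matrix(rnorm(300, 3, 0.2), 150, 2))
  dn <- density_landscape(blobs, grid_n = 80)
  expect_equal(nrow(find_peaks(dn, 0)), 1)  # positive grid is one component
  expect_equal(nrow(find_peaks(dn, max(dn$z) * 1.01)), 0)
  # saddle height between the two planted blobs computed from the grid
  ridge <- vapply(seq_along(dn$x), function(i) max(dn$z[i, ]), numeric(1))
  mid <- dn$x > 0.8 & dn$x < 2.2
  saddle <- min(ridge[mid])
  peak_min <- min(max(dn$z[dn$x < 1, ]), max(dn$z[dn$x > 2, ]))
  cut <- (saddle + peak_min) / 2
  expect_equal(nrow(find_peaks(dn, cut)), 2)
  cuts <- seq(0, max(dn$z), length.out = 12)
  n_pk <- vapply(cuts, function(cc) nrow(find_peaks(dn, cc)), integer(1))
  expect_true(all(diff(n_pk[cuts > saddle]) <= 0))
  expect_error(find_peaks(dn, -1), ">= 0")
})

test_that("MOB clustering recovers planted groups and flags outliers", {
  set.seed(7)
  g1 <- matrix(rnorm(46, 0, 0.05), 23, 2)
  g2 <- matrix(rnorm(14, 2, 0.05), 7, 2)
  pts <- rbind(g1, g2)
  rownames(pts) <- paste0("m", 1:30)
  lab <- cluster_mob(pts, k = 2, seed = 1)
  expect_equal(streamMOX:::adjusted_rand(lab, rep(c("1", "2"), c(23, 7))), 1)
  expect_equal(unname(table(lab)["1"]), 23L)  # relabeled by size
  one <- cluster_mob(pts, k = 1, seed = 1)
  expect_true(all(one == "1"))
  # far scattered points are left unassigned
  out <- rbind(pts, o1 = c(1, -1.5), o2 = c(1, 3.5), o3 = c(-1.2, 1.4))
  labo <- cluster_mob(out, k = 2, seed = 1)
  expect_true(all(labo[c("o1", "o2", "o3")] == "unassigned"))
  expect_equal(sum(labo == "1"), 23)
  expect_equal(sum(labo == "2"), 7)
  expect_error(cluster_mob(pts[1, , drop = FALSE], k = 2), "fewer")
})

test_that("a table built to the reference design yields clusters of 23 and 7
           with 6 unassigned", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 2000, seed = 2)
  land <- mob_landscape(ot$table, seed = 2)
  sizes <- land$cluster_sizes
  expect_equal(unname(sizes[["1"]]), 23)
  expect_equal(unname(sizes[["2"]]), 7)
  expect_equal(unname(sizes[["unassigned"]]), 6)
})

test_that("hull membership is boundary-inclusive and geometrically sound", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  rownames(square) <- paste0("m", 1:5)
  far <- matrix(5 + runif(10), 5, 2)
  all_pts <- rbind(square, far)
  rownames(all_pts) <- c(rownames(square), paste0("b", 1:5))
  flags <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_length(hull_members(square, all_pts, flags), 0)
  # cluster's own members (including boundary vertices) are all inside
  inside <- hull_members(square, all_pts, rep(FALSE, 10))
  expect_true(all(rownames(square) %in% inside))
  # uniform scatter: the count matches the area expectation
  set.seed(11)
  n <- 4000
  u <- cbind(runif(n, -1, 2), runif(n, -1, 2))  # area 9
  rownames(u) <- paste0("u", seq_len(n))
  got <- length(hull_members(square, rbind(square, u),
                             c(rep(TRUE, 5), rep(FALSE, n))))
  expected <- n * 1 / 9
  bound <- 3 * sqrt(n * (1 / 9) * (8 / 9))  # ~99% binomial envelope
  expect_lt(abs(got - expected), bound)
  expect_error(hull_members(square[1:2, ], all_pts, flags), "at least 3")
  coll <- cbind(1:5, 2 * (1:5))
  expect_warning(hull_members(coll, all_pts, flags), "collinear")
})

test_that("overrepresentation shares, ratios and errors are correct", {
  tax <- setNames(c(rep("k__B; p__P1; c__A; o__x; f__x; g__x", 6),
                    rep("k__B; p__P2; c__B; o__x; f__x; g__x", 4)),
                  paste0("t", 1:10))
  bg <- names(tax)
  ov <- overrepresentation(paste0("t", 1:3), tax, bg, rank = "class")
  expect_equal(ov$share_in[ov$taxon == "A"], 1)
  expect_equal(ov$share_bg[ov$taxon == "A"], 0.6)
  expect_equal(ov$ratio[ov$taxon == "A"], 1 / 0.6)
  expect_equal(ov$ratio[ov$taxon == "B"], 0)
  expect_equal(sum(ov$share_in), 1)
  expect_equal(sum(ov$share_bg), 1)
  expect_error(overrepresentation(character(0), tax, bg), "empty")
  expect_error(overrepresentation("zz", tax, bg), "subset")
})

test_that("uniformly drawn members show no overrepresentation", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 600, seed = 3)
  bg <- names(ot$table$taxonomy)
  set.seed(21)
  members <- sample(bg, 150)
  ov <- overrepresentation(members, ot$table$taxonomy, bg, n_perm = 499,
                           seed = 2)
  expect_gte(mean(ov$p > 0.05), 0.9)
  expect_true(all(abs(ov$ratio[ov$share_bg > 0.1] - 1) < 0.5))
})

test_that("taxon extraction handles ranks and unclassified lineages", {
  tx <- c("k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__X; f__Y; g__Z",
          "unclassified")
  expect_equal(taxon_at_rank(tx, "class"),
               c("Gammaproteobacteria", "unclassified"))
  expect_equal(taxon_at_rank(tx, "phylum")[1], "Proteobacteria")
  expect_equal(taxon_at_rank(tx, "genus")[1], "Z")
})

test_that("the landscape pipeline excludes low-MOB samples and is seeded", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 2000, seed = 1)
  land <- mob_landscape(ot$table, seed = 1)
  alp <- panel$sites$site_id[panel$sites$archetype == "alpine"]
  expect_setequal(land$excluded_sites, alp)
  expect_false(any(alp %in% rownames(land$ordination$points)))
  land2 <- mob_landscape(ot$table, seed = 1)
  expect_identical(land$mob_clusters, land2$mob_clusters)
  expect_identical(land$peaks, land2$peaks)
  # hull co-occurrence returns non-MOB OTUs only
  hm <- unlist(land$hull_members)
  expect_false(any(ot$table$is_mob[hm]))
  expect_gt(length(land$hull_members[["1"]]), 0)
  # overrepresentation tables accompany non-empty hulls
  expect_true(all(names(land$overrep) %in% c("1", "2")))
})

test_that("the internal adjusted Rand index matches mclust", {
  skip_if_not_installed("mclust")
  set.seed(19)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(streamMOX:::adjusted_rand(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(streamMOX:::adjusted_rand(1:5, 1:5), 1)
})
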