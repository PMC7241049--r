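test_that("the planted MOB design has the requested cluster structure", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 800, seed = 1)
  cl <- ot$truth$mob_cluster
  expect_equal(sum(cl == "1"), 23)
  expect_equal(sum(cl == "2"), 7)
  expect_equal(sum(cl == "outlier"), 6)
  expect_equal(sum(ot$table$is_mob), 36)
  expect_identical(names(ot$table$is_mob)[ot$table$is_mob],
                   names(cl)[cl != "none"])
  # MOB lineages sit in Methylococcaceae genera
  mob_tax <- ot$table$taxonomy[ot$table$is_mob]
  expect_true(all(grepl("Methylococcaceae", mob_tax)))
  expect_true(all(grepl(
    "Crenothrix|Methylobacter|Methylomonas|Methylogaea|Methylosarcina|Clonothrix",
    mob_tax)))
  # cluster-2 members appear only at the declared site subset
  c2 <- names(cl)[cl == "2"]
  off <- setdiff(rownames(ot$table$counts), ot$truth$cluster2_sites)
  expect_true(all(ot$table$counts[off, c2] == 0))
})

test_that("counts are non-negative integers and seed-deterministic", {
  panel <- default_panel()
  a <- gen_otu_table(panel$sites, 500, seed = 3)
  b <- gen_otu_table(panel$sites, 500, seed = 3)
  expect_identical(a, b)
  cm <- a$table$counts
  expect_true(all(cm >= 0))
  expect_true(all(cm == round(cm)))
  ms <- default_mob_spec()
  expect_true(all(rowSums(cm) >= 0.8 * ms$library_size[1]))
  expect_true(all(rowSums(cm) <= 1.2 * ms$library_size[2]))
})

test_that("MOB relative abundance tracks streamwater CH4 when noise-free", {
  panel <- default_panel()
  spec0 <- default_mob_spec(member_jitter = 0, noise = FALSE)
  ot <- gen_otu_table(panel$sites, 800, spec0, seed = 1)
  relab <- relative_abundance(ot$table)
  mobfrac <- rowSums(relab[, ot$table$is_mob, drop = FALSE])
  expect_gt(cor(mobfrac, panel$sites$ch4_stream), 0.9)
})

test_that("a zero-MOB design and bad designs are handled", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 300,
                      default_mob_spec(n_cluster1 = 0, n_cluster2 = 0,
                                       n_outliers = 0), seed = 1)
  expect_false(any(ot$table$is_mob))
  expect_error(
    gen_otu_table(panel$sites, 300, default_mob_spec(n_cluster2 = 3),
                  cluster2_sites = character(0)),
    "subset is empty")
})

test_that("alpine sites carry at most one methanotrophic OTU", {
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 800, seed = 2)
  counts <- ot$table$counts
  alp <- panel$sites$site_id[panel$sites$archetype == "alpine"]
  n_mob <- rowSums(counts[alp, ot$table$is_mob, drop = FALSE] > 0)
  expect_true(all(n_mob <= 1))
})

test_that("pmoA counts scale with MOB abundance and censor correctly", {
  expect_true(gen_pmoa_counts(c(s = 0), c(s = 1e8))$censored)
  pm <- gen_pmoa_counts(c(a = 0.002), c(a = 1e8), prop = 0.01,
                        detection_limit = 0)
  expect_equal(pm$pmoa_m2 / 1e8, 0.002 * 0.01)
  panel <- default_panel()
  ot <- gen_otu_table(panel$sites, 800, seed = 1)
  relab <- relative_abundance(ot$table)
  mobfrac <- rowSums(relab[, ot$table$is_mob, drop = FALSE])
  cells <- stats::setNames(rep(1e8, 14), panel$sites$site_id)
  pm2 <- gen_pmoa_counts(mobfrac, cells, noise_cv = 0.2, seed = 1)
  frac <- pmoa_fraction(pm2$pmoa_m2, cells)
  expect_true(all(frac[!pm2$censored] <= 5))
  expect_error(gen_pmoa_counts(c(a = 0.1), c(a = 1e8), prop = -1),
               "positive")
})
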