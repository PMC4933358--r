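# Synthetic genotype / pathway / effect generator and scenario runner.

test_that("simulated allele frequencies hit their targets", {
  g <- simulate_genotypes(10000, 3, maf = c(0.25, 0.25, 0.25),
                          ld_rho = 0, seed = 1)
  af <- colMeans(g$G) / 2
  se <- sqrt(0.25 * 0.75 / (2 * 10000))
  expect_true(all(abs(af - 0.25) < 3.5 * se))
  expect_true(all(g$G %in% 0:2))
})

test_that("LD structure follows the block copula", {
  g0 <- simulate_genotypes(2000, 2, maf = c(0.3, 0.3), ld_rho = 0, seed = 2)
  r0 <- cor(g0$G[, 1], g0$G[, 2])
  expect_lt(abs(r0), 3 / sqrt(2000))
  g8 <- simulate_genotypes(2000, 2, maf = c(0.45, 0.45), ld_block_size = 2,
                           ld_rho = 0.8, seed = 3)
  expect_gt(cor(g8$G[, 1], g8$G[, 2]), 0.5)
  # variants in different blocks stay independent
  g2 <- simulate_genotypes(2000, 4, maf = rep(0.3, 4), ld_block_size = 2,
                           ld_rho = 0.8, seed = 4)
  expect_lt(abs(cor(g2$G[, 2], g2$G[, 3])), 3 / sqrt(2000))
  expect_error(simulate_genotypes(10, 2, maf = c(0.6, 0.1)), "0.5")
})

test_that("pathways partition the gene set at zero overlap", {
  pw <- build_pathways(n_genes = 50, n_pathways = 5, size_range = c(10, 10),
                       overlap = 0, variants_per_gene_mean = 3, seed = 5)
  members <- unlist(pw$db$pathways)
  expect_equal(length(members), 50)
  expect_equal(anyDuplicated(members), 0)
  expect_setequal(members, pw$genes)
  expect_true(all(pw$n_borrowed == 0))
})

test_that("pathway sizes stay in range and borrowing matches its target", {
  pw <- build_pathways(n_genes = 300, n_pathways = 40, size_range = c(10, 100),
                       overlap = 0.1, variants_per_gene_mean = 5, seed = 6)
  expect_true(all(pw$sizes >= 10 & pw$sizes <= 100))
  expect_equal(unname(lengths(pw$db$pathways)), pw$sizes)
  # every pathway shares at least the configured fraction
  expect_true(all(pw$n_borrowed >= pmin(round(0.1 * pw$sizes), pw$sizes - 1)))
  # every gene has at least one variant
  expect_setequal(unique(pw$variant_map$gene), pw$genes)
  expect_error(build_pathways(1000, 5, size_range = c(10, 20)), "infeasible")
})

test_that("effect assignment follows the hierarchical model", {
  pw <- build_pathways(60, 4, size_range = c(15, 15), overlap = 0,
                       variants_per_gene_mean = 4, seed = 7)
  maf <- rep(c(0.001, 0.1), length.out = nrow(pw$variant_map))
  # null law: all zero
  e0 <- assign_effects(pw$db, pw$variant_map, maf, effect_law = "null")
  expect_true(all(e0$beta == 0))
  expect_true(is.na(e0$central_pathway))
  # log10 law: rarer variants get larger magnitudes
  e2 <- assign_effects(pw$db, pw$variant_map, maf, effect_law = "log10maf",
                       seed = 8)
  cb <- abs(e2$beta[e2$causal_variants])
  cm <- maf[match(e2$causal_variants, pw$variant_map$variant)]
  expect_true(all(abs(cb - abs(log10(cm))) < 1e-12))
  expect_gt(min(cb[cm == 0.001]), max(cb[cm == 0.1]))
  # causal genes come from the central pathway at the configured fraction
  expect_equal(length(e2$causal_genes), round(0.5 * 15))
  expect_true(all(e2$causal_genes %in% pw$db$pathways[[e2$central_pathway]]))
  # inverse-sd law magnitude
  e3 <- assign_effects(pw$db, pw$variant_map, maf, effect_law = "inv_sd_maf",
                       seed = 9)
  cb3 <- abs(e3$beta[e3$causal_variants])
  cm3 <- maf[match(e3$causal_variants, pw$variant_map$variant)]
  expect_equal(unname(cb3), 1 / sqrt(cm3 * (1 - cm3)), tolerance = 1e-12)
})

test_that("sign fractions hold in expectation across seeds", {
  pw <- build_pathways(40, 2, size_range = c(20, 20), overlap = 0,
                       variants_per_gene_mean = 3, seed = 10)
  maf <- runif(nrow(pw$variant_map), 0.01, 0.5)
  signs <- unlist(lapply(1:200, function(s) {
    e <- assign_effects(pw$db, pw$variant_map, maf, effect_law = "log10maf",
                        seed = s)
    g <- e$beta[e$causal_variants]
    # gene sign x variant sign is positive with prob .8*.8 + .2*.2 = 0.68
    sign(g)
  }))
  p_pos <- mean(signs > 0)
  expect_lt(abs(p_pos - 0.68), 3 * sqrt(0.68 * 0.32 / length(signs)))
})

test_that("noise scaling hits the heritability target", {
  expect_equal(scale_noise_to_heritability(c(-1, 1) * sqrt(0.5), 0.2), 4)
  gv <- rnorm(100)
  expect_equal(scale_noise_to_heritability(gv, 0.5), var(gv))
  expect_error(scale_noise_to_heritability(rep(1, 10), 0.2), "zero variance")
  # realized heritability across replicates
  set.seed(12)
  h <- replicate(100, {
    gv <- rnorm(500, sd = 2)
    s2 <- scale_noise_to_heritability(gv, 0.2)
    y <- gv + rnorm(500, sd = sqrt(s2))
    var(gv) / (var(gv) + var(y - gv))
  })
  expect_lt(abs(mean(h) - 0.2), 0.015)
})

test_that("gene weight schemes match their formulas", {
  expect_equal(gene_weights("uniform", n_genes = 4), rep(2, 4))
  expect_equal(gene_weights("gene_size", snp_counts = rep(7, 5)), rep(2, 5))
  expect_equal(gene_weights("gene_size", snp_counts = c(2, 4, 8)),
               2 * 4 / c(2, 4, 8))
  expect_equal(gene_weights("maf_common", gene_maf = 0.5), 1)
  expect_equal(gene_weights("maf_rare", gene_maf = 0.5), 4)
  # information-criterion weights: positive, median-2 after flooring
  set.seed(13)
  n <- 120
  G <- random_dosages(n, runif(12, 0.05, 0.4))
  y <- rnorm(n)
  idx <- split(1:12, rep(1:4, each = 3))
  d <- gene_ic_delta(y, G, idx, criterion = "aic")
  w <- gene_weights("aic", ic_delta = d)
  expect_true(all(w > 0))
  expect_equal(median(w), 2)
  # a gene with real signal gets a larger delta
  y2 <- rnorm(n) + G[, 1] * 1.5
  d2 <- gene_ic_delta(y2, G, idx, criterion = "bic")
  expect_gt(d2[1], max(d2[-1]))
})

test_that("run_scenario is deterministic and guards the null-power case", {
  scn <- sim_scenario(1, n_subjects = 80, n_pathways = 4, n_genes = 40,
                      genes_per_pathway = c(10, 10), variants_per_gene_mean = 3)
  r1 <- run_scenario(scn, replicates = 20, cov_B = 100, seed = 14,
                     weight_schemes = c("uniform", "aic"))
  r2 <- run_scenario(scn, replicates = 20, cov_B = 100, seed = 14,
                     weight_schemes = c("uniform", "aic"))
  expect_identical(r1$results, r2$results)
  expect_false(r1$power_defined)
  expect_true(all(is.na(r1$results$stringent_power)))
  expect_error(run_scenario(scn, replicates = 5), "at least 20")
})

test_that("power increases with heritability", {
  base <- list(n_subjects = 250, n_pathways = 8, n_genes = 80,
               genes_per_pathway = c(10, 10), variants_per_gene_mean = 6)
  pow <- vapply(c(0.02, 0.15, 0.5), function(h2) {
    scn <- do.call(sim_scenario, c(list(scenario = 2, h2 = h2), base))
    run_scenario(scn, replicates = 25, cov_B = 100, seed = 15,
                 weight_schemes = "uniform")$results$stringent_power
  }, numeric(1))
  # non-decreasing within Monte-Carlo error
  expect_true(all(diff(pow) > -0.125))
  expect_gt(pow[3], pow[1])
})
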