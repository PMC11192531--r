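test_that("generators are deterministic given config and seed", {
  cfg <- sim_config(seed = 5, populations = c("A", "B"), n_individuals = 6,
                    gene_pool_size = 80)
  expect_identical(simulate_presence(cfg)$data, simulate_presence(cfg)$data)
  pm <- simulate_presence(cfg)
  expect_identical(simulate_read_counts(pm, seed = 2)$data,
                   simulate_read_counts(pm, seed = 2)$data)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(lapply(g1, `[[`, "gt"), lapply(g2, `[[`, "gt"))
  expect_identical(simulate_model_curve(100, 1.3, 10, 2, seed = 9)$G,
                   simulate_model_curve(100, 1.3, 10, 2, seed = 9)$G)
  # written artifacts are byte-identical too
  d <- withr::local_tempdir()
  write_genotypes_vcf(g1, file.path(d, "a.vcf"))
  write_genotypes_vcf(g2, file.path(d, "b.vcf"))
  expect_identical(readLines(file.path(d, "a.vcf")),
                   readLines(file.path(d, "b.vcf")))
})

test_that("model curves are exact at zero noise and stay monotone with noise", {
  cur <- simulate_model_curve(178.274, 1.43356, 8, 0)
  expect_equal(cur$G[1], 178.274)                 # y(1) = alpha
  expect_equal(cur$G, 178.274 * gharmonic(1:8, 1.43356))
  noisy <- simulate_model_curve(100, 1.3, 30, noise_sd = 5, seed = 4)
  expect_true(all(noisy$delta >= 0))
  expect_true(all(diff(noisy$G) >= 0))
})

test_that("fixed_spectrum places genes in exactly m individuals", {
  n <- 10
  cfg <- sim_config(seed = 2, populations = "P", n_individuals = n,
                    gene_pool_size = 2,
                    occupancy_model = list(model = "fixed_spectrum",
                                           m = c(n, 1)))
  pm <- simulate_presence(cfg)
  occ <- occupancy(pm, "P")
  expect_identical(sort(occ$m), c(1L, 10L))
  # ubiquitous + singleton: G(1) = 1 + 1/n by the closed form
  cur <- accumulation_curve(pm, "P")
  expect_equal(cur$G[1], 1 + 1 / n)
})

test_that("all-carrier pool yields a flat accumulation curve", {
  cfg <- sim_config(seed = 3, populations = "P", n_individuals = 6,
                    gene_pool_size = 5,
                    occupancy_model = list(model = "fixed_spectrum",
                                           m = rep(6, 5)))
  cur <- accumulation_curve(simulate_presence(cfg), "P")
  expect_equal(cur$G, rep(5, 6))
})

test_that("beta-mixture defaults land in the empirical regime", {
  cfg <- sim_config(seed = 11)
  pm <- simulate_presence(cfg)
  per_fish <- colSums(pm$data)
  expect_true(all(per_fish >= 100 & per_fish <= 550))
  part <- classify_occupancy(pm, "ALL")
  expect_lt(part$fractions[["core"]], 0.10)
  fit <- fit_saturation(accumulation_curve(pm, "ALL"))
  expect_gt(fit$beta, 1)
})

test_that("read counts honour presence, depth, dispersion and thinning", {
  cfg <- sim_config(seed = 7, populations = "P", n_individuals = 8,
                    gene_pool_size = 100)
  pm <- simulate_presence(cfg)
  cm <- simulate_read_counts(pm, mean_depth = 20, dispersion = 0, seed = 1)
  expect_true(all(cm$data[pm$data == 0L] == 0L))
  expect_true(all(cm$data[pm$data == 1L] >= 1L))
  expect_equal(mean(cm$data[pm$data == 1L]), 20, tolerance = 0.05)
  # presence round-trips at min_reads = 1
  expect_identical(presence_from_counts(cm, 1L)$data, pm$data)
  # thinning one fish drops its recovered gene count at higher thresholds
  th <- setNames(rep(1, 8), individual_ids(pm))
  th[1] <- 0.1
  thin <- simulate_read_counts(pm, mean_depth = 20, dispersion = 0.5,
                               thinning = th, seed = 1)
  full <- simulate_read_counts(pm, mean_depth = 20, dispersion = 0.5,
                               seed = 1)
  rec_thin <- colSums(presence_from_counts(thin, 3L)$data)
  rec_full <- colSums(presence_from_counts(full, 3L)$data)
  expect_lt(rec_thin[[1]], rec_full[[1]])
})

test_that("neutral genotype simulator is calibrated", {
  cfg <- sim_config(seed = 13, populations = "P", n_individuals = 20,
                    snp_model = list(n_exons = c(`B30.2` = 250L),
                                     l = c(`B30.2` = 540L),
                                     theta = c(`B30.2` = 0.005)))
  tabs <- simulate_genotypes(cfg)
  div <- diversity_table(tabs, "P")
  # theta_w unbiased within Monte-Carlo error
  tw <- div$theta_w
  se <- sd(tw) / sqrt(length(tw))
  expect_lt(abs(mean(tw) - 0.005), 3 * se)
  # mean pi/thetaW ratio near the neutral expectation of 1
  r <- div$ratio[!is.na(div$ratio)]
  se_r <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 1), 3 * se_r)
})

test_that("theta of zero-ish produces monomorphic exons", {
  cfg <- sim_config(seed = 1, populations = "P", n_individuals = 10,
                    snp_model = list(n_exons = c(`B30.2` = 30L),
                                     l = c(`B30.2` = 540L),
                                     theta = c(`B30.2` = 1e-9)))
  tabs <- simulate_genotypes(cfg)
  div <- diversity_table(tabs, "P")
  expect_equal(monomorphic_fraction(div, "P"), 1.0)
  expect_true(all(div$theta_pi == 0))
})

test_that("simulated VCFs round-trip through read_genotypes", {
  cfg <- sim_config(seed = 9, populations = c("A", "B"), n_individuals = 4,
                    snp_model = list(n_exons = c(`B30.2` = 5L),
                                     l = c(`B30.2` = 540L),
                                     theta = c(`B30.2` = 0.008)))
  tabs <- simulate_genotypes(cfg)
  d <- withr::local_tempdir()
  write_genotypes_vcf(tabs, file.path(d, "sim.vcf"))
  write_exon_table(tabs, file.path(d, "exons.tsv"))
  write_populations(tabs, file.path(d, "pops.tsv"))
  back <- read_genotypes(file.path(d, "sim.vcf"), file.path(d, "exons.tsv"),
                         file.path(d, "pops.tsv"))
  expect_identical(attr(back, "skipped"), 0L)
  for (ex in names(tabs)) {
    expect_equal(back[[ex]]$pos, tabs[[ex]]$pos)
    expect_equal(unname(back[[ex]]$gt), unname(tabs[[ex]]$gt))
  }
  # diversity computed before and after the round trip agrees
  expect_equal(diversity_table(back, "A")$theta_pi,
               diversity_table(tabs, "A")$theta_pi)
})
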