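test_that("scenario_config validates its invariants", {
  expect_error(scenario_config(10, seed = 1, ld_rho = 1),
               "ld_rho")
  expect_error(scenario_config(10, seed = 1, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(scenario_config(10, seed = 1, causal1 = list(11, 0.2)),
               "causal indices")
  expect_error(scenario_config(10, seed = 1, causal1 = list(3, Inf)),
               "finite")
  expect_error(scenario_config(10), "seed")
  cfg <- scenario_config(5, seed = 1)
  expect_s3_class(cfg, "scenario_config")
  expect_true(all(diff(cfg$positions) > 0))
})

test_that("haplotype panel is reproducible and respects frequencies", {
  cfg <- scenario_config(20, ld_rho = 0.5, seed = 7, n_haplotypes = 4000)
  p1 <- simulate_haplotype_panel(cfg)
  p2 <- simulate_haplotype_panel(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_true(all(p1$haplotypes %in% c(0L, 1L)))
  emp <- colMeans(p1$haplotypes)
  expect_lt(max(abs(emp - p1$meta$freq)), 0.04)
})

test_that("rho = 0 panels have vanishing LD at large size", {
  cfg <- scenario_config(6, ld_rho = 0, seed = 11, n_haplotypes = 50000)
  panel <- simulate_haplotype_panel(cfg)
  r2 <- r2_matrix(panel)
  off <- r2[upper.tri(r2)]
  expect_lt(max(off), 0.01)
})

test_that("adjacent-variant LD matches the bivariate-normal orthant oracle", {
  # two adjacent variants, latent rho = 0.9, both frequencies 0.5
  cfg <- scenario_config(2, ld_rho = 0.9, maf_range = c(0.5, 0.5),
                         seed = 13, n_haplotypes = 50000)
  panel <- simulate_haplotype_panel(cfg)
  expected_r <- oracle_copula_hap_cor(0.9, 0.5, 0.5)
  emp_r <- cor(panel$haplotypes[, 1], panel$haplotypes[, 2])
  expect_equal(emp_r, expected_r, tolerance = 0.02)
  # and the r^2 form seen by the LD module
  expect_equal(unname(r2_matrix(panel)[1, 2]), expected_r^2,
               tolerance = 0.05)
})

test_that("case-control simulation hits requested counts and prevalence intercept", {
  cfg <- scenario_config(10, ld_rho = 0.3, seed = 5)
  panel <- simulate_haplotype_panel(cfg)
  co <- simulate_case_control(panel, NULL, prevalence = 0.2,
                              n_cases = 500, n_controls = 700, seed = 9)
  expect_equal(sum(co$phenotype == 1), 500)
  expect_equal(sum(co$phenotype == 0), 700)
  expect_true(all(co$genotypes %in% 0:2))
  expect_equal(ncol(co$genotypes), nrow(co$meta))
  # with no causal effects alpha is just logit(prevalence)
  expect_equal(co$alpha, qlogis(0.2), tolerance = 1e-6)
})

test_that("unreachable case counts abort after bounded draws", {
  cfg <- scenario_config(5, ld_rho = 0, seed = 5, n_haplotypes = 1000)
  panel <- simulate_haplotype_panel(cfg)
  expect_error(
    simulate_case_control(panel, NULL, prevalence = 1e-6,
                          n_cases = 5000, n_controls = 10, seed = 1,
                          max_draw_factor = 1e-4),
    "unreachable")
})

test_that("null cohorts give uniform association p-values", {
  # 500 independent null variants, one cohort
  cfg <- scenario_config(500, ld_rho = 0, seed = 21,
                         n_cases1 = 2000, n_controls1 = 2000)
  panel <- simulate_haplotype_panel(cfg)
  co <- simulate_case_control(panel, NULL, 0.1, 2000, 2000, seed = 22)
  rec <- score_variants(co)
  p <- rec$p[rec$flag == "ok"]
  expect_gt(length(p), 450)
  # ties among count-based Wald p-values are possible and harmless here
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects are recovered without bias", {
  # one causal variant, beta = ln(1.5); fitted log-OR within +-3 SE in
  # >= 99% of replicates, and unbiased on average
  beta_true <- log(1.5)
  reps <- 200
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- scenario_config(1, ld_rho = 0, maf_range = c(0.3, 0.3),
                           seed = 1000 + r, n_haplotypes = 4000,
                           causal1 = list(1, beta_true),
                           n_cases1 = 5000, n_controls1 = 5000)
    panel <- simulate_haplotype_panel(cfg)
    co <- simulate_case_control(panel, cfg$causal1, 0.1, 5000, 5000,
                                seed = 2000 + r)
    rec <- score_variants(co)
    est[r] <- rec$beta[1]; se[r] <- rec$se[1]
  }
  cover <- mean(abs(est - beta_true) < 3 * se)
  expect_gte(cover, 0.99)
  expect_lt(abs(mean(est) - beta_true), 3 * sd(est) / sqrt(reps) + 0.01)
})

test_that("allele frequency is conserved in controls at null variants", {
  cfg <- scenario_config(20, ld_rho = 0.5, seed = 31,
                         n_haplotypes = 20000)
  panel <- simulate_haplotype_panel(cfg)
  co <- simulate_case_control(panel, NULL, 0.1, 100, 10000, seed = 32)
  ctrl <- co$genotypes[co$phenotype == 0, ]
  expect_lt(max(abs(colMeans(ctrl) / 2 - panel$meta$freq)), 0.02)
})

test_that("two-trait scenarios share a panel and record the truth", {
  cfg <- scenario_config(
    50, ld_rho = 0.9, seed = 41,
    causal1 = list(25, 0.3), causal2 = list(25, -0.3),
    n_cases1 = 200, n_controls1 = 200, n_cases2 = 200, n_controls2 = 200)
  sc <- simulate_two_trait_scenario(cfg)
  expect_equal(sc$direction, "discordant")
  expect_true(sc$truth$shared)
  expect_equal(sc$truth$index, 25L)

  cfg$causal2 <- data.frame(index = 25L, beta = 0.3)
  expect_equal(simulate_two_trait_scenario(cfg)$direction, "concordant")

  # distinct causals at negligible LD
  cfg2 <- distinct_causal_config(43, n = 200, at1 = 10, at2 = 190)
  sc2 <- simulate_two_trait_scenario(cfg2)
  expect_equal(sc2$direction, "distinct")
  expect_lt(index_ld(sc2$panel, "var00010", "var00190"), 0.05)

  # null scenario: empty truth
  sc3 <- simulate_two_trait_scenario(null_config(44, n = 100))
  expect_equal(sc3$direction, "null")
  expect_equal(nrow(sc3$truth), 0L)
})

test_that("identical seeds reproduce identical cohorts end to end", {
  cfg <- shared_causal_config(77, n = 300, n_variants = 30,
                              causal_at = 15)
  a <- simulate_two_trait_scenario(cfg)
  b <- simulate_two_trait_scenario(cfg)
  expect_identical(a$cohort1$genotypes, b$cohort1$genotypes)
  expect_identical(a$cohort2$phenotype, b$cohort2$phenotype)
  expect_identical(score_variants(a$cohort1), score_variants(b$cohort1))
})

test_that("cohort VCF and truth round-trip through files", {
  skip_if_not_installed("vcfR")
  cfg <- scenario_config(8, ld_rho = 0.4, seed = 51,
                         n_cases1 = 50, n_controls1 = 50)
  sc <- simulate_two_trait_scenario(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_cohort_vcf(sc$cohort1, vcf)
  panel2 <- read_vcf_panel(vcf)
  expect_false(panel2$haploid)  # unphased genotypes
  expect_equal(dim(panel2$haplotypes), dim(sc$cohort1$genotypes))
  expect_true(all(panel2$haplotypes == sc$cohort1$genotypes))
  pheno <- as.integer(readLines(paste0(vcf, ".pheno")))
  expect_identical(pheno, sc$cohort1$phenotype)
})

test_that("scenario config round-trips through JSON", {
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_variants = 12, ld_rho = 0.5, seed = 3,
                            causal1 = list(c(4, 0.25)),
                            n_cases1 = 100, n_controls1 = 100),
                       cfg_json, auto_unbox = TRUE)
  cfg <- read_scenario_config(cfg_json)
  expect_equal(cfg$n_variants, 12L)
  expect_equal(cfg$causal1$index, 4L)
  expect_equal(cfg$causal1$beta, 0.25)
  jsonlite::write_json(list(n_variants = 5), cfg_json, auto_unbox = TRUE)
  expect_error(read_scenario_config(cfg_json), "seed")
})
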