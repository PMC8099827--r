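make_region_cohort <- function(seed, causal = NULL, n = 4000,
                               n_variants = 60, rho = 0.9) {
  cfg <- scenario_config(n_variants, ld_rho = rho, seed = seed,
                         causal1 = causal, n_cases1 = n, n_controls1 = n,
                         n_cases2 = 100, n_controls2 = 100)
  panel <- simulate_haplotype_panel(cfg)
  cohort <- simulate_case_control(panel, cfg$causal1, 0.1, n, n,
                                  seed = seed + 5e5)
  list(cohort = cohort, panel = panel,
       region = region_of("1", 1L, max(cfg$positions)))
}

test_that("conditional scan with empty set equals the marginal scan", {
  x <- make_region_cohort(301, causal = list(10, 0.3), n = 1000,
                          n_variants = 20)
  marg <- score_variants(x$cohort)
  cond <- conditional_scan(x$cohort, x$region, character())
  expect_equal(cond, marg)
})

test_that("conditioning on a perfect proxy flags collinearity", {
  x <- make_region_cohort(302, n = 500, n_variants = 10)
  co <- x$cohort
  co$genotypes <- cbind(co$genotypes, co$genotypes[, 5])
  co$meta <- rbind(co$meta, co$meta[5, ])
  co$meta$id[11] <- "proxy"
  co$meta$pos[11] <- co$meta$pos[10] + 1000L
  region <- region_of("1", 1L, co$meta$pos[11])
  cond <- conditional_scan(co, region, condition_on = "proxy")
  v5 <- cond[cond$id == co$meta$id[5], ]
  expect_equal(v5$flag, "collinear")
  expect_true(is.na(v5$p))
  # other variants agree with explicit glm conditional fits
  v2 <- cond[cond$id == co$meta$id[2], ]
  fit <- glm(co$phenotype ~ co$genotypes[, 2] + co$genotypes[, 5],
             family = binomial)
  expect_equal(v2$beta, unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(v2$se, unname(sqrt(vcov(fit)[2, 2])), tolerance = 1e-5)
})

test_that("conditioning on the causal variant flattens the region", {
  # remaining conditional p approximately uniform once the single causal
  # is in the model
  x <- make_region_cohort(303, causal = list(30, log(1.5)), n = 4000,
                          n_variants = 40, rho = 0.6)
  cond <- conditional_scan(x$cohort, x$region, condition_on = "var00030")
  p <- cond$p[cond$flag == "ok"]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_true(all(p > 1e-4))
})

test_that("stepwise p_enter limits behave as documented", {
  x <- make_region_cohort(304, causal = list(10, 0.5), n = 800,
                          n_variants = 12)
  expect_length(forward_stepwise(x$cohort, x$region, p_enter = 0), 0)
  sel_all <- forward_stepwise(x$cohort, x$region, p_enter = 1,
                              max_signals = 50)
  # with p_enter = 1 variants accumulate until nothing scoreable remains
  expect_gt(length(sel_all), 5)
})

test_that("null regions select nothing at the default threshold", {
  empties <- vapply(1:20, function(r) {
    x <- make_region_cohort(320 + r, n = 1000, n_variants = 30)
    length(forward_stepwise(x$cohort, x$region))
  }, numeric(1))
  expect_gte(mean(empties == 0), 0.95)
})

test_that("a strong causal variant (or a tight proxy) is selected first", {
  hits <- vapply(1:15, function(r) {
    x <- make_region_cohort(350 + r, causal = list(30, log(1.4)),
                            n = 10000, n_variants = 60)
    sel <- forward_stepwise(x$cohort, x$region)
    length(sel) >= 1 && index_ld(x$panel, sel[1], "var00030") > 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("two weakly linked causals are both recovered", {
  hits <- vapply(1:10, function(r) {
    cfg <- scenario_config(
      100, ld_rho = 0.9, seed = 370 + r,
      causal1 = data.frame(index = c(25, 75), beta = log(1.3)),
      n_cases1 = 10000, n_controls1 = 10000,
      n_cases2 = 100, n_controls2 = 100)
    panel <- simulate_haplotype_panel(cfg)
    cohort <- simulate_case_control(panel, cfg$causal1, 0.1, 10000, 10000,
                                    seed = 470 + r)
    sel <- forward_stepwise(cohort, region_of("1", 1L, 200000L))
    length(sel) >= 2 &&
      any(vapply(sel, function(s) index_ld(panel, s, "var00025") > 0.8,
                 logical(1))) &&
      any(vapply(sel, function(s) index_ld(panel, s, "var00075") > 0.8,
                 logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("signals carry ranks and conditioning sets consistently", {
  cfg <- scenario_config(
    80, ld_rho = 0.9, seed = 381,
    causal1 = data.frame(index = c(20, 60), beta = log(1.35)),
    n_cases1 = 8000, n_controls1 = 8000,
    n_cases2 = 100, n_controls2 = 100)
  panel <- simulate_haplotype_panel(cfg)
  cohort <- simulate_case_control(panel, cfg$causal1, 0.1, 8000, 8000,
                                  seed = 481)
  region <- region_of("1", 1L, 160000L)
  sigs <- enumerate_signals(cohort, region, trait = "t1")
  expect_gte(length(sigs), 1)
  for (k in seq_along(sigs)) {
    s <- sigs[[k]]
    expect_equal(s$rank, k)
    expect_equal(length(s$condition_on), k - 1L)
    expect_false(s$index_id %in% s$condition_on)
    ok <- s$records$flag == "ok"
    expect_equal(s$index_id,
                 s$records$id[ok][which.min(s$records$p[ok])])
  }
  # serialization dialect
  path <- tempfile(fileext = ".tsv")
  write_signals(sigs, path)
  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_true(all(c("SIGNAL_RANK", "CONDITIONED_ON") %in% names(tab)))
  expect_true("-" %in% tab$CONDITIONED_ON)
})

test_that("cojo conditioning is exact in its algebraic limits", {
  rec <- random_records(6, seed = 390)
  R <- diag(6); dimnames(R) <- list(rec$id, rec$id)
  # empty conditioning set: identity
  expect_equal(cojo_conditional(rec, R, character()), rec)
  # orthogonal LD: conditioning on one leaves the others untouched
  out <- cojo_conditional(rec, R, rec$id[1])
  expect_equal(out$beta, rec$beta[-1], tolerance = 1e-12)
  expect_equal(out$se, rec$se[-1], tolerance = 1e-12)
})

test_that("cojo conditioning is invariant to conditioning-set order", {
  set.seed(391)
  rec <- random_records(10, seed = 391)
  L <- matrix(rnorm(100), 10)
  R <- cov2cor(crossprod(L) + diag(0.5, 10))
  dimnames(R) <- list(rec$id, rec$id)
  a <- cojo_conditional(rec, R, c("v001", "v005", "v008"))
  b <- cojo_conditional(rec, R, c("v008", "v001", "v005"))
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("cojo drops variants with mismatched panel frequencies", {
  rec <- random_records(4, seed = 392)
  rec$alt_frq <- c(0.1, 0.5, 0.5, 0.9)
  R <- diag(4); dimnames(R) <- list(rec$id, rec$id)
  pf <- setNames(c(0.1, 0.5, 0.2, 0.9), rec$id)
  out <- cojo_conditional(rec, R, character(), panel_freq = pf)
  expect_setequal(out$id, rec$id[-3])
})

test_that("summary-level conditioning tracks individual-level conditional z", {
  cfg <- scenario_config(
    100, ld_rho = 0.9, seed = 395,
    causal1 = data.frame(index = c(30, 70), beta = c(log(1.3), log(1.25))),
    n_cases1 = 10000, n_controls1 = 10000,
    n_cases2 = 100, n_controls2 = 100)
  panel <- simulate_haplotype_panel(cfg)
  cohort <- simulate_case_control(panel, cfg$causal1, 0.1, 10000, 10000,
                                  seed = 495)
  region <- region_of("1", 1L, 200000L)
  sel <- forward_stepwise(cohort, region)
  skip_if(length(sel) == 0, "stepwise selected nothing in this draw")
  cond_ind <- conditional_scan(cohort, region, condition_on = sel)
  rec <- score_variants(cohort)
  R <- cor_matrix(panel)
  cond_sum <- cojo_conditional(rec, R, condition_on = sel)
  m <- match(cond_sum$id, cond_ind$id)
  ok <- cond_ind$flag[m] == "ok"
  z_ind <- (cond_ind$beta / cond_ind$se)[m][ok]
  z_sum <- (cond_sum$beta / cond_sum$se)[ok]
  expect_gt(cor(z_ind, z_sum), 0.95)
})
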