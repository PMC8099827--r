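# Shared scenario builders for simulation-based tests. Scenario
# conditions (effect sizes, cohort sizes, region size) follow the study
# design the package validates against; helpers only bundle them.

shared_causal_config <- function(seed, beta1 = log(1.3), beta2 = log(1.3),
                                 causal_at = 100L, n_variants = 200L,
                                 n = 10000L) {
  scenario_config(
    n_variants = n_variants, ld_rho = 0.9,
    causal1 = list(causal_at, beta1), causal2 = list(causal_at, beta2),
    n_cases1 = n, n_controls1 = n, n_cases2 = n, n_controls2 = n,
    seed = seed)
}

# distinct causal variants, far apart so that r^2 < 0.05
distinct_causal_config <- function(seed, beta = log(1.3),
                                   n_variants = 200L, n = 10000L,
                                   at1 = 50L, at2 = 150L) {
  scenario_config(
    n_variants = n_variants, ld_rho = 0.9,
    causal1 = list(at1, beta), causal2 = list(at2, beta),
    n_cases1 = n, n_controls1 = n, n_cases2 = n, n_controls2 = n,
    seed = seed)
}

null_config <- function(seed, n_variants = 100L, n = 2000L) {
  scenario_config(n_variants = n_variants, ld_rho = 0.9,
                  n_cases1 = n, n_controls1 = n, n_cases2 = n,
                  n_controls2 = n, seed = seed)
}

# simulate, score both cohorts, harmonize, run coloc; returns the result
coloc_replicate <- function(cfg, priors = coloc_priors()) {
  sc <- simulate_two_trait_scenario(cfg)
  h <- harmonize(score_variants(sc$cohort1), score_variants(sc$cohort2))
  list(res = coloc_posteriors(h$rec1, h$rec2, priors = priors),
       scenario = sc, h = h)
}

# random summary-stat records over m variants for algebra-level tests
random_records <- function(m, seed, chrom = "1", beta_sd = 0.15) {
  set.seed(seed)
  se <- runif(m, 0.02, 0.2)
  data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom,
             pos = seq_len(m) * 1000L, ref = "A", alt = "G",
             alt_frq = runif(m, 0.05, 0.95),
             beta = rnorm(m, 0, beta_sd), se = se,
             p = runif(m), n_cases = 1000L, n_controls = 1000L,
             flag = "ok", stringsAsFactors = FALSE)
}

region_of <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             region_id = sprintf("%s:%d-%d", chrom, start, end),
             stringsAsFactors = FALSE)
}
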