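# Seeded generator of LD-structured haplotypes and two-trait case-control
# cohorts under a logistic disease model. The latent haplotype model is a
# Gaussian copula with AR(1) correlation (optionally block-diagonal), so the
# implied pairwise LD has a closed form through the bivariate-normal orthant
# probability and can be checked against numerical integration.

#' Scenario configuration for a synthetic two-trait experiment
#'
#' Bundles everything needed to simulate one locus (or a small genome) for
#' two case-control traits: the variant grid, the latent AR(1) LD parameter,
#' the allele-frequency range, the causal variants and log odds ratios per
#' trait, baseline prevalences, cohort sizes and the seed.
#'
#' @param n_variants Number of variants.
#' @param positions Optional 1-based base-pair positions, strictly
#'   increasing; default a regular grid with `spacing_bp` spacing.
#' @param chrom Chromosome label applied to all variants (default `"1"`).
#' @param spacing_bp Grid spacing used when `positions` is not supplied
#'   (default 2000 bp).
#' @param ld_rho Latent AR(1) autocorrelation in `[0, 1)`.
#' @param ld_blocks Optional integer vector of block sizes summing to
#'   `n_variants`; correlation is zero across blocks.
#' @param maf_range Length-2 vector of allele-frequency bounds in
#'   `(0, 0.5]`; panel frequencies are drawn uniformly in this range.
#' @param causal1,causal2 Causal specification per trait: a two-column
#'   object (list, matrix or data.frame) of variant index (1-based) and
#'   log odds ratio, or `NULL` for no causal variants.
#' @param prevalence1,prevalence2 Baseline disease prevalence per trait,
#'   in `(0, 1)`.
#' @param n_cases1,n_controls1,n_cases2,n_controls2 Cohort sizes.
#' @param n_haplotypes Haplotype panel size (default 10000).
#' @param seed Integer seed (mandatory).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_variants, positions = NULL, chrom = "1",
                            spacing_bp = 2000L, ld_rho = 0.9,
                            ld_blocks = NULL, maf_range = c(0.05, 0.5),
                            causal1 = NULL, causal2 = NULL,
                            prevalence1 = 0.1, prevalence2 = 0.1,
                            n_cases1 = 5000L, n_controls1 = 5000L,
                            n_cases2 = 5000L, n_controls2 = 5000L,
                            n_haplotypes = 10000L, seed) {
  if (missing(seed)) stop_param("'seed' is mandatory")
  check_scalar(n_variants, "n_variants", lo = 1)
  check_scalar(ld_rho, "ld_rho", lo = 0, hi = 1, open_hi = TRUE)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_param("'maf_range' must be an increasing pair in (0, 0.5]")
  if (is.null(positions)) {
    positions <- seq.int(from = spacing_bp, by = spacing_bp,
                         length.out = n_variants)
  }
  if (length(positions) != n_variants || any(diff(positions) <= 0))
    stop_param("'positions' must be strictly increasing, length n_variants")
  if (!is.null(ld_blocks) && sum(ld_blocks) != n_variants)
    stop_param("'ld_blocks' must sum to n_variants")
  norm_causal <- function(x, label) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(index = integer(), beta = numeric()))
    x <- as.data.frame(x)
    names(x) <- c("index", "beta")
    x$index <- as.integer(x$index)
    if (any(x$index < 1L) || any(x$index > n_variants))
      stop_param("causal indices for %s outside [1, n_variants]", label)
    if (any(!is.finite(x$beta)))
      stop_param("causal log-ORs for %s must be finite", label)
    x
  }
  for (p in c(prevalence1, prevalence2))
    check_scalar(p, "prevalence", lo = 0, hi = 1,
                 open_lo = TRUE, open_hi = TRUE)
  structure(list(
    n_variants = as.integer(n_variants), positions = as.integer(positions),
    chrom = as.character(chrom), ld_rho = ld_rho, ld_blocks = ld_blocks,
    maf_range = maf_range,
    causal1 = norm_causal(causal1, "trait 1"),
    causal2 = norm_causal(causal2, "trait 2"),
    prevalence1 = prevalence1, prevalence2 = prevalence2,
    n_cases1 = as.integer(n_cases1), n_controls1 = as.integer(n_controls1),
    n_cases2 = as.integer(n_cases2), n_controls2 = as.integer(n_controls2),
    n_haplotypes = as.integer(n_haplotypes), seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario_config: %d variants (chr%s), ld_rho=%.2f, seed=%d\n",
    x$n_variants, x$chrom, x$ld_rho, x$seed))
  cat(sprintf("  trait 1: %d causal, %d/%d cases/controls, prevalence %.3g\n",
              nrow(x$causal1), x$n_cases1, x$n_controls1, x$prevalence1))
  cat(sprintf("  trait 2: %d causal, %d/%d cases/controls, prevalence %.3g\n",
              nrow(x$causal2), x$n_cases2, x$n_controls2, x$prevalence2))
  invisible(x)
}

#' Read a scenario configuration from a JSON file
#'
#' Keys mirror the [scenario_config()] arguments; `seed` is mandatory.
#' Causal specifications are arrays of `[index, beta]` pairs.
#'
#' @param path JSON path.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop_param("config file must set 'seed'")
  args <- x[intersect(names(x), names(formals(scenario_config)))]
  do.call(scenario_config, args)
}

# latent AR(1) (optionally block-diagonal) Gaussian matrix, n_hap x m
ar1_latent <- function(n_hap, m, rho, blocks = NULL) {
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (rho == 0 || m == 1L) return(z)
  block_start <- if (is.null(blocks)) 1L else
    cumsum(c(1L, head(blocks, -1L)))
  w <- sqrt(1 - rho^2)
  for (j in 2:m) {
    if (j %in% block_start) next
    z[, j] <- rho * z[, j - 1L] + w * z[, j]
  }
  z
}

#' Simulate an LD-structured haplotype panel
#'
#' Draws `n_haplotypes` binary haplotypes over `n_variants` variants from a
#' Gaussian copula whose latent correlation is AR(1) with parameter
#' `ld_rho` (block-diagonal if `ld_blocks` is set). Each variant's allele
#' frequency is drawn uniformly in `maf_range` and the latent Gaussian is
#' thresholded at its normal quantile, so `P(allele = 1) = freq`.
#'
#' @param config A [scenario_config()].
#' @return An [ld_panel()] object with a 0/1 haplotype matrix and variant
#'   metadata.
#' @export
simulate_haplotype_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  m <- config$n_variants
  freq <- runif(m, config$maf_range[1], config$maf_range[2])
  z <- ar1_latent(config$n_haplotypes, m, config$ld_rho, config$ld_blocks)
  hap <- matrix(0L, nrow(z), m)
  thr <- qnorm(freq)
  for (j in seq_len(m)) hap[, j] <- as.integer(z[, j] < thr[j])
  meta <- data.frame(
    id = sprintf("var%05d", seq_len(m)), chrom = config$chrom,
    pos = config$positions, ref = "A", alt = "G",
    freq = freq, stringsAsFactors = FALSE)
  ld_panel(hap, meta, haploid = TRUE, population = "synthetic")
}

# intercept alpha solving population prevalence under the logistic model,
# by bisection on E[plogis(alpha + eta)] over the panel's genotype risks;
# eta takes few distinct values (3^k for k causal variants), so the
# expectation is computed on the aggregated value/weight table
solve_prevalence_alpha <- function(eta, prevalence) {
  ue <- sort(unique(eta))
  if (length(ue) <= 1000) {
    w <- tabulate(match(eta, ue), nbins = length(ue)) / length(eta)
  } else {
    ue <- eta
    w <- rep(1 / length(eta), length(eta))
  }
  f <- function(a) sum(w * plogis(a + ue)) - prevalence
  lo <- -30; hi <- 30
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate a case-control cohort from a haplotype panel
#'
#' Individuals are formed by pairing haplotypes drawn with replacement from
#' the panel; disease status follows the logistic model
#' `logit P(case) = alpha + sum_k beta_k g_k`, with `alpha` solved so the
#' population prevalence equals `prevalence`. Cases and controls are
#' accumulated by rejection sampling until the requested counts are
#' reached.
#'
#' @param panel An [ld_panel()] of haplotypes.
#' @param causal Two-column causal specification (variant index, log-OR)
#'   or `NULL`.
#' @param prevalence Baseline prevalence in `(0, 1)`.
#' @param n_cases,n_controls Requested counts.
#' @param seed Integer seed.
#' @param max_draw_factor Abort after drawing more than
#'   `max_draw_factor * expected draws` individuals (default 50).
#' @return A `cohort`: list with `genotypes` (individuals x variants,
#'   dosages 0/1/2), `phenotype` (0 control / 1 case) and `meta`.
#' @export
simulate_case_control <- function(panel, causal, prevalence, n_cases,
                                  n_controls, seed, max_draw_factor = 50) {
  stopifnot(inherits(panel, "ld_panel"))
  check_scalar(prevalence, "prevalence", lo = 0, hi = 1,
               open_lo = TRUE, open_hi = TRUE)
  if (is.null(causal) || NROW(causal) == 0L) {
    causal <- data.frame(index = integer(), beta = numeric())
  } else {
    causal <- as.data.frame(causal)
    names(causal) <- c("index", "beta")
  }
  if (any(!is.finite(causal$beta))) stop_param("causal effects must be finite")
  set.seed(seed)
  n_hap <- nrow(panel$haplotypes)
  m <- ncol(panel$haplotypes)
  ci <- as.integer(causal$index)
  cb <- as.numeric(causal$beta)

  # population linear predictor over random mating pairs; alpha from a
  # large reference draw of causal genotypes only
  ref_n <- 50000L
  i1 <- sample.int(n_hap, ref_n, replace = TRUE)
  i2 <- sample.int(n_hap, ref_n, replace = TRUE)
  eta_ref <- if (length(ci))
    (panel$haplotypes[i1, ci, drop = FALSE] +
       panel$haplotypes[i2, ci, drop = FALSE]) %*% cb
  else rep(0, ref_n)
  alpha <- solve_prevalence_alpha(as.numeric(eta_ref), prevalence)

  need_case <- n_cases; need_ctrl <- n_controls
  exp_draws <- n_cases / prevalence + n_controls / (1 - prevalence)
  max_draws <- max_draw_factor * exp_draws + 10000
  case_idx <- matrix(0L, 0L, 2L); ctrl_idx <- matrix(0L, 0L, 2L)
  drawn <- 0
  while (need_case > 0L || need_ctrl > 0L) {
    batch <- as.integer(min(2e5, max(
      1e4, 1.3 * max(need_case / prevalence, need_ctrl / (1 - prevalence)))))
    drawn <- drawn + batch
    if (drawn > max_draws)
      stop_param(paste0("requested case/control counts unreachable at ",
                        "prevalence %g after %d draws"), prevalence, drawn)
    i1 <- sample.int(n_hap, batch, replace = TRUE)
    i2 <- sample.int(n_hap, batch, replace = TRUE)
    eta <- if (length(ci))
      as.numeric((panel$haplotypes[i1, ci, drop = FALSE] +
                    panel$haplotypes[i2, ci, drop = FALSE]) %*% cb)
    else rep(0, batch)
    y <- rbinom(batch, 1L, plogis(alpha + eta))
    if (need_case > 0L) {
      take <- which(y == 1L)[seq_len(min(need_case, sum(y)))]
      case_idx <- rbind(case_idx, cbind(i1[take], i2[take]))
      need_case <- n_cases - nrow(case_idx)
    }
    if (need_ctrl > 0L) {
      take <- which(y == 0L)[seq_len(min(need_ctrl, batch - sum(y)))]
      ctrl_idx <- rbind(ctrl_idx, cbind(i1[take], i2[take]))
      need_ctrl <- n_controls - nrow(ctrl_idx)
    }
  }
  idx <- rbind(case_idx, ctrl_idx)
  geno <- panel$haplotypes[idx[, 1L], , drop = FALSE] +
    panel$haplotypes[idx[, 2L], , drop = FALSE]
  storage.mode(geno) <- "integer"
  colnames(geno) <- panel$meta$id
  structure(list(
    genotypes = geno,
    phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
    meta = panel$meta,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    alpha = alpha),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d cases / %d controls, %d variants\n",
              x$n_cases, x$n_controls, ncol(x$genotypes)))
  invisible(x)
}

#' Simulate a full two-trait scenario
#'
#' Draws one haplotype panel and two independent case-control cohorts on it
#' (no sample overlap), one per trait, and returns a truth record naming
#' the causal variants, their effects and the direction relationship
#' between the traits at shared variants.
#'
#' @param config A [scenario_config()].
#' @return List with `panel`, `cohort1`, `cohort2`, and `truth`
#'   (data.frame: variant id, index, beta per trait, shared flag) plus a
#'   `direction` label: `"concordant"`, `"discordant"`, `"mixed"`,
#'   `"distinct"` or `"null"`.
#' @export
simulate_two_trait_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  panel <- simulate_haplotype_panel(config)
  # child seeds kept below 2^31
  s1 <- (config$seed * 2654435761) %% 2147483647
  s2 <- (config$seed * 2654435761 + 97) %% 2147483647
  cohort1 <- simulate_case_control(panel, config$causal1,
                                   config$prevalence1, config$n_cases1,
                                   config$n_controls1, seed = s1)
  cohort2 <- simulate_case_control(panel, config$causal2,
                                   config$prevalence2, config$n_cases2,
                                   config$n_controls2, seed = s2)
  idx <- sort(unique(c(config$causal1$index, config$causal2$index)))
  truth <- data.frame(
    id = panel$meta$id[idx], index = idx,
    beta1 = config$causal1$beta[match(idx, config$causal1$index)],
    beta2 = config$causal2$beta[match(idx, config$causal2$index)],
    stringsAsFactors = FALSE)
  truth$shared <- !is.na(truth$beta1) & !is.na(truth$beta2)
  direction <- if (nrow(truth) == 0L) "null"
  else if (any(truth$shared)) {
    s <- sign(truth$beta1[truth$shared]) * sign(truth$beta2[truth$shared])
    if (all(s > 0)) "concordant" else if (all(s < 0)) "discordant"
    else "mixed"
  } else "distinct"
  list(panel = panel, cohort1 = cohort1, cohort2 = cohort2,
       truth = truth, direction = direction, config = config)
}
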