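# Bayesian colocalisation by Wakefield approximate Bayes factors and
# enumeration of the five regional hypotheses:
#   H0 no association; H1/H2 one trait only; H3 both traits, distinct
#   causal variants; H4 both traits, one shared causal variant.
# All sums are taken in log space (log-sum-exp): per-variant Bayes
# factors exceed exp(700) for strong GWAS signals and would overflow.

#' Colocalisation priors
#'
#' Per-variant prior probabilities: `p1` (associated with trait 1 only),
#' `p2` (trait 2 only), `p12` (associated with both). Defaults are the
#' conservative recommendation for two-disease colocalisation:
#' `p1 = p2 = 1e-4`, `p12 = 5e-6`.
#'
#' @param p1,p2,p12 Priors; must satisfy `0 < p12 <= min(p1, p2)`.
#' @return `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  check_scalar(p1, "p1", 0, 1, TRUE, TRUE)
  check_scalar(p2, "p2", 0, 1, TRUE, TRUE)
  check_scalar(p12, "p12", 0, 1, TRUE, TRUE)
  if (p12 > min(p1, p2))
    stop_param("p12 must not exceed min(p1, p2)")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an effect estimate `beta` with standard error `se` under a
#' `N(0, W)` effect prior with `W = prior_sd_w^2`:
#' `lABF = 0.5 * (log(1 - r) + r * z^2)` with `r = W / (V + W)`,
#' `V = se^2`, `z = beta / se`. Symmetric in the sign of `beta`.
#'
#' @param beta Effect estimate(s) (log odds ratio).
#' @param se Standard error(s), `> 0`.
#' @param prior_sd_w Prior standard deviation of the true effect on the
#'   log-OR scale (default 0.2, i.e. `W = 0.04`).
#' @return Numeric vector of log Bayes factors.
#' @export
labf <- function(beta, se, prior_sd_w = 0.2) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0) ||
      !is.finite(prior_sd_w) || prior_sd_w <= 0)
    stop_param("labf: beta finite, se > 0 and prior_sd_w > 0 required")
  V <- se^2
  W <- prior_sd_w^2
  r <- W / (V + W)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

#' Colocalisation posteriors for a pair of signals
#'
#' Enumerates the five hypotheses from per-variant log Bayes factors
#' `l1(i)`, `l2(i)` over the shared variant set:
#' `S0 = 1`; `S1 = p1 * sum(exp(l1))`; `S2 = p2 * sum(exp(l2))`;
#' `S3 = p1*p2 * (sum(exp(l1)) * sum(exp(l2)) - sum(exp(l1 + l2)))`;
#' `S4 = p12 * sum(exp(l1 + l2))`; `PPh = Sh / sum(S)`, all in log
#' space.
#'
#' @param rec1,rec2 Summary-statistic data.frames harmonized to the same
#'   allele frame; variants matched on `id` (intersection, at least 1).
#' @param priors A [coloc_priors()].
#' @param prior_sd_w1,prior_sd_w2 Effect-prior sd per trait (default 0.2
#'   each).
#' @return `coloc_result`: `pp` (named pp0..pp4), `n_variants`,
#'   `priors`, `h4_contrib` (named per-variant posterior weight within
#'   H4, sums to 1), `top_h4_id`, `snps` and the per-trait `lbf`
#'   matrices.
#' @export
coloc_posteriors <- function(rec1, rec2, priors = coloc_priors(),
                             prior_sd_w1 = 0.2, prior_sd_w2 = 0.2) {
  ok1 <- rec1[(is.na(rec1$flag) | rec1$flag == "ok") & is.finite(rec1$beta)
              & is.finite(rec1$se), , drop = FALSE]
  ok2 <- rec2[(is.na(rec2$flag) | rec2$flag == "ok") & is.finite(rec2$beta)
              & is.finite(rec2$se), , drop = FALSE]
  shared <- intersect(ok1$id, ok2$id)
  if (!length(shared))
    stop_param(paste0("no shared variants between the two traits' ",
                      "records: harmonize() both traits to a common ",
                      "frame first"))
  r1 <- ok1[match(shared, ok1$id), ]
  r2 <- ok2[match(shared, ok2$id), ]
  l1 <- labf(r1$beta, r1$se, prior_sd_w1)
  l2 <- labf(r2$beta, r2$se, prior_sd_w2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lS0 <- 0
  lS1 <- log(priors$p1) + lsum1
  lS2 <- log(priors$p2) + lsum2
  # sum over distinct-variant pairs. The factored form
  # sum(BF1)*sum(BF2) - sum(BF1*BF2) cancels catastrophically when one
  # variant dominates both traits, so sum the off-diagonal terms
  # directly (n^2 terms; regions here are a few hundred variants).
  n_var <- length(l1)
  lS3 <- if (n_var == 1L) -Inf else {
    M <- outer(l1, l2, "+")
    diag(M) <- -Inf
    log(priors$p1) + log(priors$p2) + logsumexp(M)
  }
  lS4 <- log(priors$p12) + lsum12
  lS <- c(lS0, lS1, lS2, lS3, lS4)
  lZ <- logsumexp(lS)
  pp <- setNames(exp(lS - lZ), paste0("pp", 0:4))
  h4_contrib <- setNames(exp(l1 + l2 - lsum12), shared)
  structure(list(pp = pp, n_variants = length(shared), priors = priors,
                 prior_sd_w = c(prior_sd_w1, prior_sd_w2),
                 h4_contrib = h4_contrib,
                 top_h4_id = shared[which.max(h4_contrib)],
                 snps = shared,
                 beta1 = setNames(r1$beta, shared),
                 beta2 = setNames(r2$beta, shared)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d variants: ", x$n_variants))
  cat(paste(sprintf("%s=%.3g", names(x$pp), x$pp), collapse = " "), "\n")
  cat(sprintf("  top H4 variant: %s (weight %.2f)\n", x$top_h4_id,
              x$h4_contrib[x$top_h4_id]))
  invisible(x)
}

#' Direction of effect of a shared signal
#'
#' At the variant with the largest per-variant H4 contribution, compares
#' `sign(beta1) * sign(beta2)`: positive is `"concordant"` (the risk
#' allele raises risk of both diseases), negative `"discordant"`. Falls
#' back to `fallback_id` (e.g. the trait-2 index variant) when a beta is
#' missing at the top variant.
#'
#' @param result A `coloc_result` (expected to satisfy the H4 decision
#'   threshold; not enforced here).
#' @param fallback_id Optional variant id used if the top-H4 variant
#'   lacks a beta in either trait.
#' @return `"concordant"` or `"discordant"`.
#' @export
classify_direction <- function(result, fallback_id = NULL) {
  pick <- function(id) {
    b1 <- result$beta1[id]; b2 <- result$beta2[id]
    if (is.na(b1) || is.na(b2)) return(NULL)
    if (sign(b1) * sign(b2) >= 0) "concordant" else "discordant"
  }
  d <- pick(result$top_h4_id)
  if (!is.null(d)) return(d)
  if (!is.null(fallback_id)) {
    d <- pick(fallback_id)
    if (!is.null(d)) return(d)
  }
  stop_param("no variant with effect estimates in both traits")
}
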