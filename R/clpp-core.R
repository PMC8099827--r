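# eCAVIAR-style fine-mapping and colocalisation posterior probability.
# Model: observed z-scores z ~ MVN(R lambda, R) with LD matrix R; each
# variant is causal independently with prior gamma; non-zero standardized
# effects lambda_i ~ N(0, sigma^2). Marginally over lambda, a causal
# configuration C gives z ~ MVN(0, R + sigma^2 R[,C] R[C,]), whose
# likelihood reduces (matrix determinant lemma / Woodbury with R^-1 R = I)
# to |C| x |C| algebra:
#   log det = log det R + log det(I + sigma^2 R[C,C])
#   quad    = z' R^-1 z - sigma^2 * z_C' (I + sigma^2 R[C,C])^-1 z_C
# wait-free form used below: with A = (sigma^-2 I + R[C,C])^-1,
#   quad = z' R^-1 z - z_C' A z_C.

config_logpost <- function(zC, RCC, sigma2, c_size, n, log_gamma,
                           log_1mgamma) {
  lp_prior <- c_size * log_gamma + (n - c_size) * log_1mgamma
  if (c_size == 0L) return(lp_prior)
  M <- diag(c_size) + sigma2 * RCC
  ch <- chol(M)
  logdet <- 2 * sum(log(diag(ch)))
  A <- chol2inv(chol(RCC + diag(1 / sigma2, c_size)))
  quad_red <- as.numeric(t(zC) %*% A %*% zC)
  lp_prior - 0.5 * logdet + 0.5 * quad_red
}

#' LD-aware fine-mapping by exhaustive configuration enumeration
#'
#' Enumerates all causal configurations of size `<= max_causal`, scores
#' each by prior x multivariate-normal marginal likelihood of the
#' z-scores, and reports per-variant posterior inclusion probabilities
#' (PIPs). The null (empty) configuration is included, so PIPs need not
#' sum to 1.
#'
#' @param records Summary-statistic data.frame; z = beta / se.
#' @param ld Signed correlation matrix with dimnames covering
#'   `records$id` (eigenvalue-floored internally, see [psd_floor()]).
#' @param max_causal Maximum causal set size `c` (default 2).
#' @param prior_gamma Per-variant causal prior (default 0.01).
#' @param prior_sigma Standardized-effect prior sd (default 5).
#' @param max_configs Enumeration guard: error if `choose(n, c)` exceeds
#'   this (default 1e7); reduce `max_causal` or restrict the region.
#' @param eig_floor Eigenvalue floor applied to `ld` (default 1e-8).
#' @return `finemap_posterior`: `ids`, `pip` (named), `max_causal`,
#'   `log_evidence`, and `config_logpost` for diagnostics.
#' @export
finemap <- function(records, ld, max_causal = 2L, prior_gamma = 0.01,
                    prior_sigma = 5, max_configs = 1e7,
                    eig_floor = 1e-8) {
  records <- records[(is.na(records$flag) | records$flag == "ok") &
                       is.finite(records$beta) & is.finite(records$se), ,
                     drop = FALSE]
  ids <- records$id
  n <- length(ids)
  if (n < 1L) stop_param("finemap: no usable records")
  if (max_causal < 1L) stop_param("finemap: max_causal must be >= 1")
  if (!all(ids %in% colnames(ld)))
    stop_param("finemap: LD matrix does not cover the records")
  if (choose(n, max_causal) > max_configs)
    stop_param(paste0("finemap: %d variants at c = %d exceeds the ",
                      "enumeration guard; reduce max_causal or restrict ",
                      "the region"), n, max_causal)
  R <- psd_floor(ld[ids, ids, drop = FALSE], eig_floor)
  z <- records$beta / records$se
  sigma2 <- prior_sigma^2
  lg <- log(prior_gamma); l1g <- log1p(-prior_gamma)
  configs <- list(integer())
  for (c_size in seq_len(min(max_causal, n))) {
    cc <- combn(n, c_size)
    configs <- c(configs, lapply(seq_len(ncol(cc)), function(k) cc[, k]))
  }
  lp <- vapply(configs, function(C) {
    config_logpost(z[C], R[C, C, drop = FALSE], sigma2, length(C), n,
                   lg, l1g)
  }, numeric(1))
  lZ <- logsumexp(lp)
  post <- exp(lp - lZ)
  pip <- numeric(n)
  for (k in seq_along(configs))
    pip[configs[[k]]] <- pip[configs[[k]]] + post[k]
  structure(list(ids = ids, pip = setNames(pmin(pip, 1), ids),
                 max_causal = as.integer(max_causal),
                 log_evidence = lZ,
                 config_logpost = lp),
            class = "finemap_posterior")
}

#' @export
print.finemap_posterior <- function(x, ...) {
  top <- head(sort(x$pip, decreasing = TRUE), 5L)
  cat(sprintf("finemap: %d variants, c = %d; top PIPs: %s\n",
              length(x$ids), x$max_causal,
              paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
  invisible(x)
}

#' Colocalisation posterior probability (CLPP)
#'
#' Per-variant `CLPP(i) = PIP1(i) * PIP2(i)`; regional CLPP is their
#' sum — the probability that some variant is causal for both traits,
#' treating the two fine-mappings as independent.
#'
#' @param post1,post2 `finemap_posterior` objects over identical variant
#'   lists.
#' @return `clpp_result`: `per_variant` (named), `regional`,
#'   `top_id`.
#' @export
clpp <- function(post1, post2) {
  if (!identical(post1$ids, post2$ids))
    stop_param(paste0("clpp: variant lists differ; harmonize the two ",
                      "traits' records before fine-mapping"))
  pv <- post1$pip * post2$pip
  structure(list(per_variant = pv, regional = min(sum(pv), 1),
                 top_id = post1$ids[which.max(pv)]),
            class = "clpp_result")
}

#' @export
print.clpp_result <- function(x, ...) {
  cat(sprintf("regional CLPP = %.4f (top variant %s, CLPP %.4f)\n",
              x$regional, x$top_id, x$per_variant[x$top_id]))
  invisible(x)
}

#' Write per-variant and regional CLPP as TSV
#' @param result A `clpp_result`.
#' @param path Output path.
#' @export
write_clpp <- function(result, path) {
  out <- data.frame(SNP = names(result$per_variant),
                    CLPP = as.numeric(result$per_variant),
                    REGIONAL_CLPP = result$regional)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
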