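# Conditional dissection of a region into independent association
# signals: forward stepwise logistic selection on individual-level data,
# conditional scans given a conditioning set, and a COJO-style
# summary-statistic approximation when only marginal statistics and an LD
# reference are available.

region_variant_ids <- function(cohort, region) {
  meta <- cohort$meta
  meta$id[meta$chrom == region$chrom &
            meta$pos >= region$start & meta$pos <= region$end]
}

# Weighted-cell Newton solver for y ~ 1 + g + C where all columns are
# hard-called dosages: the likelihood depends only on case/control counts
# per distinct (g, C) cell (at most 3^(k+1)), so each fit costs O(n) for
# aggregation plus a few (k+2)-dimensional Newton steps.
logistic_cell_fit <- function(cells, n1, n0, max_iter = 40L, tol = 1e-10) {
  X <- cbind(1, cells)
  p <- ncol(X)
  ntot <- n1 + n0
  b <- c(qlogis(sum(n1) / sum(ntot)), rep(0, p - 1L))
  for (it in seq_len(max_iter)) {
    mu <- plogis(as.numeric(X %*% b))
    w <- ntot * mu * (1 - mu)
    grad <- crossprod(X, n1 - ntot * mu)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    sc <- max(abs(step))
    if (sc > 5) step <- step * (5 / sc)
    b <- b + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(as.numeric(X %*% b))
  w <- ntot * mu * (1 - mu)
  H <- crossprod(X * w, X)
  cv <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  list(beta = b[2L], se = sqrt(cv[2L, 2L]),
       converged = max(abs(step)) < 1e-6)
}

# logistic fit of y ~ 1 + X, returning beta/se/p of each column of X
logistic_joint_fit <- function(X, y) {
  X1 <- cbind(1, X)
  fit <- suppressWarnings(
    glm.fit(X1, y, family = binomial(), control = list(maxit = 50)))
  cf <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(X1 * sqrt(w))
  cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cv) || anyNA(cf))
    return(NULL)
  se <- sqrt(diag(cv))
  list(beta = cf[-1L], se = se[-1L],
       p = 2 * pnorm(-abs(cf[-1L] / se[-1L])),
       converged = fit$converged)
}

#' Conditional association scan within a region
#'
#' For every region variant not in `condition_on`, fits
#' `phenotype ~ dosage_j + dosages(condition_on)` by logistic regression
#' and reports the Wald statistics of the `j` term. With an empty
#' conditioning set this reduces exactly to [score_variants()] on the
#' region. Candidates collinear with the conditioning set (|r| > 0.99
#' with the model span) are flagged `"collinear"` and their statistics
#' set missing.
#'
#' @param cohort A `cohort`.
#' @param region One-row region data.frame (`chrom, start, end`).
#' @param condition_on Character vector of variant ids (possibly empty).
#' @param collinear_r Collinearity guard on |r| between a candidate and
#'   its projection onto the conditioning dosages (default 0.99).
#' @param verbose Log skipped candidates.
#' @return Summary-statistic data.frame ([score_variants()] schema) over
#'   the region variants not conditioned on.
#' @export
conditional_scan <- function(cohort, region, condition_on = character(),
                             collinear_r = 0.99, verbose = FALSE) {
  ids <- setdiff(region_variant_ids(cohort, region), condition_on)
  if (!length(condition_on))
    return(score_variants(cohort, ids = ids, verbose = verbose))
  jC <- match(condition_on, cohort$meta$id)
  if (anyNA(jC)) stop_param("conditioning variants not in cohort")
  C <- cohort$genotypes[, jC, drop = FALSE]
  y <- cohort$phenotype
  out <- score_variants(cohort, ids = ids, verbose = FALSE)
  jG <- match(out$id, cohort$meta$id)
  G <- cohort$genotypes[, jG, drop = FALSE]

  # collinearity with the span of [1, C], all candidates at once
  qrC <- qr(cbind(1, C))
  RES <- qr.resid(qrC, G)
  tss <- colSums(sweep(G, 2L, colMeans(G))^2)
  r2_span <- 1 - colSums(RES^2) / tss

  k <- ncol(C)
  hard <- is.integer(cohort$genotypes) || all(C %in% 0:2)
  cell_of_C <- if (hard && k <= 5)
    as.integer(C %*% 3^(seq_len(k) - 1L)) else NULL
  case <- y == 1L

  for (i in seq_len(nrow(out))) {
    if (out$flag[i] != "ok") next
    if (!is.finite(r2_span[i]) || r2_span[i] > collinear_r^2) {
      out$flag[i] <- "collinear"
      out$beta[i] <- out$se[i] <- out$p[i] <- NA_real_
      dc_log(verbose, "skipping %s: collinear with conditioning set",
             out$id[i])
      next
    }
    g <- G[, i]
    fit <- NULL
    if (!is.null(cell_of_C)) {
      code <- g + 3L * cell_of_C
      ncells <- 3L * 3L^k
      n1 <- tabulate(code[case] + 1L, nbins = ncells)
      n0 <- tabulate(code[!case] + 1L, nbins = ncells)
      present <- which(n1 + n0 > 0L)
      cells <- cbind((present - 1L) %% 3L,
                     matrix(((present - 1L) %/% 3L) %/%
                              rep(3L^(seq_len(k) - 1L),
                                  each = length(present)) %% 3L,
                            length(present), k))
      fit <- logistic_cell_fit(cells, n1[present], n0[present])
    } else {
      fj <- logistic_joint_fit(cbind(g, C), y)
      if (!is.null(fj))
        fit <- list(beta = fj$beta[1L], se = fj$se[1L],
                    converged = fj$converged)
    }
    if (is.null(fit) || !fit$converged || !is.finite(fit$se) ||
        abs(fit$beta) > 15) {
      out$flag[i] <- "separated"
      out$beta[i] <- out$se[i] <- out$p[i] <- NA_real_
      next
    }
    out$beta[i] <- fit$beta
    out$se[i] <- fit$se
    out$p[i] <- max(2 * pnorm(-abs(fit$beta / fit$se)),
                    .Machine$double.xmin)
  }
  out
}

#' Forward stepwise selection of independent signals in a region
#'
#' Repeatedly adds the variant with the smallest conditional Wald p-value
#' among those not yet selected, as long as that p-value is below
#' `p_enter`. Candidates collinear with the selected set are skipped.
#'
#' @inheritParams conditional_scan
#' @param p_enter Entry threshold on the conditional p-value (default
#'   1e-5).
#' @param max_signals Safety cap on the number of selected variants
#'   (default 10).
#' @return Character vector of selected index-variant ids, in selection
#'   order (possibly empty).
#' @export
forward_stepwise <- function(cohort, region, p_enter = 1e-5,
                             collinear_r = 0.99, max_signals = 10L,
                             verbose = FALSE) {
  if (p_enter <= 0) return(character())
  selected <- character()
  repeat {
    scan <- conditional_scan(cohort, region, condition_on = selected,
                             collinear_r = collinear_r, verbose = verbose)
    ok <- scan$flag == "ok" & is.finite(scan$p)
    if (!any(ok)) break
    best <- which.min(replace(scan$p, !ok, Inf))
    if (!(scan$p[best] < p_enter)) break
    selected <- c(selected, scan$id[best])
    dc_log(verbose, "stepwise: added %s (p = %.3g)", scan$id[best],
           scan$p[best])
    if (length(selected) >= max_signals) break
  }
  selected
}

#' Enumerate conditionally independent signals for one trait in a region
#'
#' Runs [forward_stepwise()] and builds one signal per selected variant:
#' the rank-k signal conditions on the k-1 previously selected indices and
#' carries the conditional summary statistics of the remaining region
#' variants. When nothing passes `p_enter`, a single rank-1 signal with
#' the best marginal variant and an empty conditioning set is returned so
#' an FDR-selected region is still analysed.
#'
#' @inheritParams forward_stepwise
#' @param trait Trait label stored on the signals.
#' @return List of `signal` objects: `trait, region_id, index_id,
#'   condition_on, rank, records`.
#' @export
enumerate_signals <- function(cohort, region, trait = "trait",
                              p_enter = 1e-5, collinear_r = 0.99,
                              verbose = FALSE) {
  sel <- forward_stepwise(cohort, region, p_enter = p_enter,
                          collinear_r = collinear_r, verbose = verbose)
  make_signal <- function(index_id, cond, rank, records) {
    structure(list(trait = trait,
                   region_id = region$region_id %||%
                     sprintf("%s:%d-%d", region$chrom, region$start,
                             region$end),
                   index_id = index_id, condition_on = cond,
                   rank = rank, records = records),
              class = "dc_signal")
  }
  if (!length(sel)) {
    rec <- conditional_scan(cohort, region, character(), verbose = verbose)
    ok <- rec$flag == "ok"
    if (!any(ok)) return(list())
    idx <- rec$id[ok][which.min(rec$p[ok])]
    return(list(make_signal(idx, character(), 1L, rec)))
  }
  lapply(seq_along(sel), function(k) {
    cond <- sel[seq_len(k - 1L)]
    rec <- conditional_scan(cohort, region, cond, collinear_r = collinear_r,
                            verbose = verbose)
    make_signal(sel[k], cond, k, rec)
  })
}

#' @export
print.dc_signal <- function(x, ...) {
  cat(sprintf("signal [%s] %s rank %d index %s | conditioned on: %s\n",
              x$trait, x$region_id, x$rank, x$index_id,
              if (length(x$condition_on))
                paste(x$condition_on, collapse = ",") else "-"))
  invisible(x)
}

#' COJO-style conditional summary statistics from marginals and LD
#'
#' Approximates conditional effects without individual-level data. In
#' standardized units (`beta_std = beta * sqrt(2 f (1 - f))`),
#' `beta_cond(j) = beta(j) - R[j,C] R[C,C]^-1 beta(C)` and the variance is
#' scaled by the Schur complement `1 - R[j,C] R[C,C]^-1 R[C,j]`, then
#' de-standardized back to the log-OR scale. A singular conditioning
#' block is ridge-regularized (logged); variants whose panel frequency
#' differs from the records' by more than 0.2 are dropped.
#'
#' @param records Summary-statistic data.frame, harmonized to the LD
#'   panel's allele frame (same ids).
#' @param ld Signed correlation matrix with id dimnames covering the
#'   records (e.g. [cor_matrix()]).
#' @param condition_on Ids to condition on (subset of `records$id`).
#' @param panel_freq Optional named frequency vector from the LD panel
#'   for the frequency-mismatch guard.
#' @param ridge Ridge added to a computationally singular `R[C,C]`
#'   (default 1e-8).
#' @param verbose Log regularization and drops.
#' @return Conditional records for the variants not in `condition_on`,
#'   same schema as the input.
#' @export
cojo_conditional <- function(records, ld, condition_on = character(),
                             panel_freq = NULL, ridge = 1e-8,
                             verbose = FALSE) {
  records <- records[is.na(records$flag) | records$flag %in% "ok", ,
                     drop = FALSE]
  if (!is.null(panel_freq)) {
    mm <- abs(records$alt_frq - panel_freq[records$id]) > 0.2
    mm[is.na(mm)] <- TRUE
    if (any(mm)) {
      dc_log(verbose, "cojo: dropping %d variant(s), frequency mismatch > 0.2",
             sum(mm))
      records <- records[!mm, , drop = FALSE]
    }
  }
  if (!length(condition_on)) return(records)
  if (!all(condition_on %in% records$id))
    stop_param("conditioning variants missing from records")
  keep <- !(records$id %in% condition_on)
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  sd_g <- sqrt(2 * records$alt_frq * (1 - records$alt_frq))
  names(sd_g) <- records$id
  b_std <- records$beta * sd_g
  s_std <- records$se * sd_g
  names(b_std) <- names(s_std) <- records$id
  C <- condition_on
  J <- out$id
  RCC <- ld[C, C, drop = FALSE]
  RJC <- ld[J, C, drop = FALSE]
  sol <- tryCatch(solve(RCC, t(RJC)), error = function(e) NULL)
  if (is.null(sol)) {
    dc_log(verbose, "cojo: singular R[C,C], ridge %g applied", ridge)
    RCC <- RCC + diag(ridge, nrow(RCC))
    sol <- solve(RCC, t(RJC))
  }
  bC <- solve(RCC, b_std[C])
  b_cond <- b_std[J] - as.numeric(RJC %*% bC)
  schur <- pmax(1 - rowSums(RJC * t(sol)), 1e-12)
  s_cond <- s_std[J] * sqrt(schur)
  out$beta <- b_cond / sd_g[J]
  out$se <- s_cond / sd_g[J]
  out$p <- pmax(2 * pnorm(-abs(b_cond / s_cond)), .Machine$double.xmin)
  out
}

#' Write signals' conditional statistics as TSV
#'
#' Same dialect as [write_sumstats()] plus `SIGNAL_RANK` and
#' `CONDITIONED_ON` (comma-joined ids, `-` for none).
#'
#' @param signals List of signals from [enumerate_signals()].
#' @param path Output path.
#' @export
write_signals <- function(signals, path) {
  rows <- lapply(signals, function(s) {
    out <- s$records[, sumstat_cols]
    names(out) <- names(sumstat_cols)
    out$SIGNAL_RANK <- s$rank
    out$CONDITIONED_ON <- if (length(s$condition_on))
      paste(s$condition_on, collapse = ",") else "-"
    out
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", na = ".",
                     quote = FALSE)
  invisible(path)
}
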