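# Per-variant logistic association, Benjamini-Hochberg FDR and allele
# harmonization. The marginal scan is a vectorized Newton solver for the
# two-parameter (intercept + dosage) logistic model across all variants at
# once; covariate-adjusted fits go through glm.fit.

# Vectorized single-variant logistic regression: y ~ 1 + g_j for every
# column j of G simultaneously. For hard-called dosages (0/1/2) the
# likelihood depends only on the six genotype x phenotype counts per
# variant, so Newton iterations run on count summaries across all
# variants at once; arbitrary dosages fall back to a dense vectorized
# IRLS.
logistic_scan_fast <- function(G, y, max_iter = 30L, tol = 1e-10) {
  hard_calls <- if (is.integer(G)) {
    rg <- range(G)
    rg[1] >= 0L && rg[2] <= 2L
  } else all(G %in% c(0, 1, 2))
  if (!hard_calls)
    return(logistic_scan_dense(G, y))
  case <- y == 1L
  Gc <- G[case, , drop = FALSE]
  Gt <- G[!case, , drop = FALSE]
  # counts: rows = variants, cols = genotype 0/1/2, split by phenotype
  n1 <- cbind(colSums(Gc == 0L), colSums(Gc == 1L), colSums(Gc == 2L))
  n0 <- cbind(colSums(Gt == 0L), colSums(Gt == 1L), colSums(Gt == 2L))
  ntot <- n1 + n0
  m <- ncol(G)
  g <- c(0, 1, 2)
  a <- rep(qlogis(mean(y)), m)
  b <- rep(0, m)
  conv <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    # per-variant score and information over the three genotype cells
    eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
    mu <- cbind(plogis(eta0), plogis(eta1), plogis(eta2))
    w <- ntot * mu * (1 - mu)
    r <- n1 - ntot * mu
    u0 <- rowSums(r)
    u1 <- r[, 2L] + 2 * r[, 3L]
    s0 <- rowSums(w)
    s1 <- w[, 2L] + 2 * w[, 3L]
    s2 <- w[, 2L] + 4 * w[, 3L]
    det <- s0 * s2 - s1 * s1
    det[det <= 0] <- NA_real_
    da <- (s2 * u0 - s1 * u1) / det
    db <- (s0 * u1 - s1 * u0) / det
    bad <- !is.finite(da) | !is.finite(db)
    da[bad] <- 0; db[bad] <- 0
    step <- pmax(abs(da), abs(db))
    scale <- ifelse(step > 5, 5 / step, 1)
    a <- a + da * scale
    b <- b + db * scale
    conv <- abs(da) < tol & abs(db) < tol
    if (all(conv | bad)) break
  }
  eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
  mu <- cbind(plogis(eta0), plogis(eta1), plogis(eta2))
  w <- ntot * mu * (1 - mu)
  s0 <- rowSums(w)
  s1 <- w[, 2L] + 2 * w[, 3L]
  s2 <- w[, 2L] + 4 * w[, 3L]
  det <- s0 * s2 - s1 * s1
  se <- sqrt(ifelse(det > 0, s0 / det, NA_real_))
  list(beta = b, se = se, converged = conv,
       separated = !conv | abs(b) > 15 | !is.finite(se))
}

logistic_scan_dense <- function(G, y, max_iter = 25L, tol = 1e-8) {
  n <- length(y); m <- ncol(G)
  a <- rep(qlogis(mean(y)), m)   # intercepts
  b <- rep(0, m)                 # slopes
  conv <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    eta <- sweep(G * rep(b, each = n), 2L, a, "+")
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    s0 <- colSums(w); s1 <- colSums(w * G); s2 <- colSums(w * G * G)
    u0 <- colSums(r); u1 <- colSums(r * G)
    det <- s0 * s2 - s1 * s1
    det[det <= 0] <- NA_real_
    da <- (s2 * u0 - s1 * u1) / det
    db <- (s0 * u1 - s1 * u0) / det
    bad <- !is.finite(da) | !is.finite(db)
    da[bad] <- 0; db[bad] <- 0
    # dampen huge steps (separation drifts to +-Inf otherwise)
    step <- pmax(abs(da), abs(db))
    scale <- ifelse(step > 5, 5 / step, 1)
    a <- a + da * scale
    b <- b + db * scale
    conv <- abs(da) < tol & abs(db) < tol
    if (all(conv | bad)) break
  }
  eta <- sweep(G * rep(b, each = n), 2L, a, "+")
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  s0 <- colSums(w); s1 <- colSums(w * G); s2 <- colSums(w * G * G)
  det <- s0 * s2 - s1 * s1
  se <- sqrt(ifelse(det > 0, s0 / det, NA_real_))
  list(beta = b, se = se, converged = conv,
       separated = !conv | abs(b) > 15 | !is.finite(se))
}

#' Per-variant association scan on a cohort
#'
#' Fits `phenotype ~ intercept + dosage` by logistic regression for every
#' variant and reports the Wald statistics with the alternative allele as
#' the effect allele. Monomorphic variants and variants with (quasi-)
#' separated fits are flagged and get missing statistics; downstream
#' stages drop flagged records.
#'
#' @param cohort A `cohort` from [simulate_case_control()], or any list
#'   with `genotypes`, `phenotype`, `meta`, `n_cases`, `n_controls`.
#' @param ids Optional subset of variant ids to score.
#' @param verbose Log flagged variants.
#' @return data.frame of summary-statistic records: `id, chrom, pos, ref,
#'   alt, alt_frq, beta, se, p, n_cases, n_controls, flag` (`"ok"`,
#'   `"monomorphic"` or `"separated"`).
#' @export
score_variants <- function(cohort, ids = NULL, verbose = FALSE) {
  G <- cohort$genotypes
  y <- cohort$phenotype
  if (length(unique(y)) < 2L)
    stop_param("cohort has a single phenotype class")
  meta <- cohort$meta
  if (!is.null(ids)) {
    j <- match(ids, meta$id)
    if (anyNA(j)) stop_param("unknown variant ids requested")
    G <- G[, j, drop = FALSE]
    meta <- meta[j, , drop = FALSE]
  }
  m <- ncol(G)
  if (!m)
    return(data.frame(id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), alt_frq = numeric(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n_cases = integer(), n_controls = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  frq <- colMeans(G) / 2
  mono <- frq == 0 | frq == 1
  beta <- se <- p <- rep(NA_real_, m)
  flag <- rep("ok", m)
  flag[mono] <- "monomorphic"
  if (any(!mono)) {
    fit <- logistic_scan_fast(G[, !mono, drop = FALSE], y)
    beta[!mono] <- fit$beta
    se[!mono] <- fit$se
    sep <- fit$separated
    flag[!mono][sep] <- "separated"
    beta[!mono][sep] <- NA_real_
    se[!mono][sep] <- NA_real_
  }
  ok <- flag == "ok"
  p[ok] <- 2 * pnorm(-abs(beta[ok] / se[ok]))
  p[ok] <- pmax(p[ok], .Machine$double.xmin)  # keep p in (0, 1]
  if (any(!ok))
    dc_log(verbose, "%d variant(s) flagged (%s)", sum(!ok),
           paste(unique(flag[!ok]), collapse = ", "))
  data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
             ref = meta$ref, alt = meta$alt, alt_frq = frq,
             beta = beta, se = se, p = p,
             n_cases = cohort$n_cases, n_controls = cohort$n_controls,
             flag = flag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= i} p(j) * m / j` after sorting ascending, capped at
#' 1; ties share a q-value and the step-up monotonicity holds by
#' construction.
#'
#' @param p Numeric p-values in `(0, 1]`; names (variant ids) preserved.
#' @return Named numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(setNames(numeric(), character()))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_param("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  names(q) <- names(p)
  q
}

is_palindromic <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Harmonize two traits' summary statistics to a shared allele frame
#'
#' Matches records by chromosome and position, flips the second trait's
#' beta sign and mirrors its frequency when its ref/alt are swapped
#' relative to the first, drops strand-ambiguous (A/T, C/G) variants with
#' alternative-allele frequency in `[0.42, 0.58]` in either trait, and
#' drops irreconcilable allele pairs (reason logged). Flagged records
#' (monomorphic/separated) are removed first. Output is position-sorted.
#'
#' @param rec1,rec2 Summary-statistic data.frames ([score_variants()]
#'   schema).
#' @param drop_palindromic_window Frequency window for palindromic
#'   exclusion, default `c(0.42, 0.58)`.
#' @param verbose Log dropped variants.
#' @return List with `rec1` and `rec2`: equal-length data.frames on the
#'   frame of `rec1`'s alt allele, plus a `dropped` data.frame of id and
#'   reason.
#' @export
harmonize <- function(rec1, rec2, drop_palindromic_window = c(0.42, 0.58),
                      verbose = FALSE) {
  keep_ok <- function(r) r[is.na(r$flag) | r$flag == "ok", , drop = FALSE]
  if (!is.null(rec1$flag)) rec1 <- keep_ok(rec1)
  if (!is.null(rec2$flag)) rec2 <- keep_ok(rec2)
  key1 <- paste(rec1$chrom, rec1$pos)
  key2 <- paste(rec2$chrom, rec2$pos)
  j <- match(key1, key2)
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  hit <- !is.na(j)
  r1 <- rec1[hit, , drop = FALSE]
  r2 <- rec2[j[hit], , drop = FALSE]
  if (!nrow(r1))
    return(list(rec1 = r1, rec2 = r2, dropped = dropped))
  same <- r1$ref == r2$ref & r1$alt == r2$alt
  swapped <- r1$ref == r2$alt & r1$alt == r2$ref
  bad <- !(same | swapped)
  if (any(swapped)) {
    r2$beta[swapped] <- -r2$beta[swapped]
    r2$alt_frq[swapped] <- 1 - r2$alt_frq[swapped]
    r2$ref[swapped] <- r1$ref[swapped]
    r2$alt[swapped] <- r1$alt[swapped]
  }
  pal <- is_palindromic(r1$ref, r1$alt) &
    r1$alt_frq >= drop_palindromic_window[1] &
    r1$alt_frq <= drop_palindromic_window[2]
  drop <- bad | pal
  if (any(drop)) {
    dropped <- data.frame(
      id = r1$id[drop],
      reason = ifelse(bad[drop], "allele_mismatch", "palindromic_ambiguous"),
      stringsAsFactors = FALSE)
    dc_log(verbose, "harmonize: dropped %d variant(s): %s", sum(drop),
           paste(r1$id[drop], dropped$reason, collapse = "; "))
  }
  r1 <- r1[!drop, , drop = FALSE]
  r2 <- r2[!drop, , drop = FALSE]
  o <- order(r1$chrom, r1$pos)
  list(rec1 = r1[o, , drop = FALSE], rec2 = r2[o, , drop = FALSE],
       dropped = dropped)
}

sumstat_cols <- c(SNP = "id", CHR = "chrom", BP = "pos", REF = "ref",
                  ALT = "alt", ALT_FRQ = "alt_frq", BETA = "beta",
                  SE = "se", P = "p", N_CASES = "n_cases",
                  N_CONTROLS = "n_controls")

#' Write summary statistics as TSV
#'
#' Columns `SNP CHR BP REF ALT ALT_FRQ BETA SE P N_CASES N_CONTROLS`, with
#' `.` for missing values; gzip-transparent via the file extension.
#'
#' @param records Summary-statistic data.frame.
#' @param path Output path (`.gz` for gzipped).
#' @export
write_sumstats <- function(records, path) {
  out <- records[, sumstat_cols]
  names(out) <- names(sumstat_cols)
  data.table::fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#' @param path TSV path (gzip-transparent).
#' @return data.frame in the internal record schema, `flag = "ok"`.
#' @export
read_sumstats <- function(path) {
  x <- if (grepl("\\.gz$", path)) {
    utils::read.delim(gzfile(path), sep = "\t", na.strings = ".",
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(data.table::fread(path, sep = "\t", na.strings = "."))
  }
  missing_cols <- setdiff(names(sumstat_cols), names(x))
  if (length(missing_cols))
    stop_param("summary-statistic file lacks columns: %s",
               paste(missing_cols, collapse = ", "))
  out <- x[, names(sumstat_cols)]
  names(out) <- sumstat_cols
  out$chrom <- as.character(out$chrom)
  out$flag <- "ok"
  out
}
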