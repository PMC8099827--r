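# LD panels and r2 computation. Panels hold either phased haplotypes
# (0/1 rows) or genotype dosages (0/1/2); correlations are haplotype-based
# in the first case and composite (genotype-dosage) in the second.

#' Construct an LD panel
#'
#' @param mat Matrix, rows = haplotypes (0/1) or individuals (dosage
#'   0/1/2), columns = variants.
#' @param meta data.frame with columns `id, chrom, pos, ref, alt, freq`
#'   (freq recomputed from `mat` if missing).
#' @param haploid `TRUE` if rows are haplotypes.
#' @param population Free-text population label.
#' @return `ld_panel` object.
#' @export
ld_panel <- function(mat, meta, haploid = TRUE, population = "unknown") {
  mat <- as.matrix(mat)
  if (nrow(meta) != ncol(mat))
    stop_param("metadata rows (%d) != variant columns (%d)",
               nrow(meta), ncol(mat))
  ploidy <- if (haploid) 1 else 2
  if (is.null(meta$freq)) meta$freq <- colMeans(mat) / ploidy
  structure(list(haplotypes = mat, meta = meta, haploid = haploid,
                 population = population),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d %s x %d variants (%s)\n", nrow(x$haplotypes),
              if (x$haploid) "haplotypes" else "individuals",
              ncol(x$haplotypes), x$population))
  invisible(x)
}

panel_columns <- function(panel, ids) {
  j <- match(ids, panel$meta$id)
  if (anyNA(j))
    stop_param("variants not in panel: %s",
               paste(ids[is.na(j)], collapse = ", "))
  j
}

#' Pairwise r-squared matrix from a panel
#'
#' Squared Pearson correlation between variant columns (haplotype alleles
#' or genotype dosages). Monomorphic variants are excluded with a message.
#'
#' @param panel An [ld_panel()].
#' @param ids Variant ids (default all).
#' @param verbose Log exclusions.
#' @return Symmetric matrix of r-squared values in `[0, 1]`, dimnames =
#'   retained variant ids.
#' @export
r2_matrix <- function(panel, ids = panel$meta$id, verbose = FALSE) {
  cor_matrix(panel, ids, verbose = verbose)^2
}

#' Signed correlation matrix from a panel
#'
#' @inheritParams r2_matrix
#' @return Symmetric correlation matrix (alt-allele dosage scale).
#' @export
cor_matrix <- function(panel, ids = panel$meta$id, verbose = FALSE) {
  j <- panel_columns(panel, ids)
  x <- panel$haplotypes[, j, drop = FALSE]
  v <- apply(x, 2L, function(col) var(col) > 0)
  if (any(!v)) {
    dc_log(verbose, "excluding %d monomorphic variant(s): %s", sum(!v),
           paste(ids[!v], collapse = ", "))
    x <- x[, v, drop = FALSE]
    ids <- ids[v]
  }
  if (!ncol(x)) stop_param("no polymorphic variants among those requested")
  r <- cor(x)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  r
}

#' r-squared between two variants
#'
#' @param panel An [ld_panel()].
#' @param id_a,id_b Variant ids.
#' @return Scalar r-squared.
#' @export
index_ld <- function(panel, id_a, id_b) {
  if (identical(id_a, id_b)) return(1.0)
  unname(r2_matrix(panel, c(id_a, id_b))[1L, 2L])
}

#' Floor the eigenvalues of a correlation matrix
#'
#' Re-symmetrizes and lifts eigenvalues below `floor` so downstream
#' Cholesky factorizations succeed on near-singular sample LD.
#'
#' @param R Correlation matrix.
#' @param floor Minimum eigenvalue (default 1e-8).
#' @return Adjusted symmetric positive-definite matrix, unit diagonal
#'   restored.
#' @export
psd_floor <- function(R, floor = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  v <- pmax(e$values, floor)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

#' Read a genotype panel from a VCF file
#'
#' Keeps biallelic SNVs with a GT field; multiallelic or indel records and
#' records without GT are skipped (counts logged). Phased haplotypes are
#' expanded when every GT is phased; otherwise dosages are used.
#'
#' @param path VCF path (plain or gzipped).
#' @param population Population label.
#' @param verbose Log skip counts.
#' @return An [ld_panel()].
#' @export
read_vcf_panel <- function(path, population = "vcf", verbose = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_param("reading VCF panels requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  has_gt <- rowSums(!is.na(gt)) == ncol(gt)
  skipped <- sum(!(keep & has_gt))
  dc_log(verbose, "VCF: kept %d/%d records (%d skipped: non-SNV or no GT)",
         sum(keep & has_gt), nrow(fix), skipped)
  keep <- keep & has_gt
  if (!any(keep)) stop_param("no usable biallelic SNV records in %s", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  phased <- all(grepl("|", gt, fixed = TRUE))
  if (phased) {
    a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow(gt))
    a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow(gt))
    mat <- t(cbind(a1, a2))
  } else {
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dose <- matrix(as.integer(substr(clean, 1L, 1L)) +
                     as.integer(substr(clean, 3L, 3L)), nrow(gt))
    mat <- t(dose)
  }
  meta <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ld_panel(mat, meta, haploid = phased, population = population)
}

#' Write an LD matrix with a sidecar variant list
#'
#' @param R Matrix with variant-id dimnames.
#' @param path Output path for the whitespace-separated matrix; the ids go
#'   to `<path>.vars`.
#' @export
write_ld_matrix <- function(R, path) {
  utils::write.table(format(R, digits = 10), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(R), paste0(path, ".vars"))
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#' @param path Matrix path (expects `<path>.vars` beside it).
#' @return Matrix with dimnames.
#' @export
read_ld_matrix <- function(path) {
  R <- as.matrix(utils::read.table(path, header = FALSE))
  ids <- readLines(paste0(path, ".vars"))
  dimnames(R) <- list(ids, ids)
  R
}
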