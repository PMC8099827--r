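# End-to-end orchestration: simulate (or load) two cohorts -> per-variant
# association -> BH FDR per trait -> harmonize -> regions significant in
# both traits -> stepwise signal dissection per trait -> coloc of every
# trait-1 x trait-2 signal pair -> CLPP corroboration per region ->
# direction classification. Reporting follows the perspective of the
# trait-2 (designated large-GWAS) index variant and its ALT allele.

#' Analysis parameters for the pipeline
#'
#' @param fdr FDR threshold for the two-trait overlap (default 0.01,
#'   strict `<`).
#' @param window_bp Analysis window span (default 500000).
#' @param priors A [coloc_priors()].
#' @param h4_threshold Posterior probability at or above which a signal
#'   pair is declared shared (default 0.9).
#' @param prior_sd_w Effect-prior sd on the log-OR scale (default 0.2).
#' @param p_enter Stepwise entry threshold (default 1e-5).
#' @param max_causal Fine-mapping causal-set bound (default 2).
#' @param run_clpp Run the CLPP corroboration (default TRUE).
#' @param verbose Structured per-stage logging.
#' @return `pipeline_params` list.
#' @export
pipeline_params <- function(fdr = 0.01, window_bp = 5e5,
                            priors = coloc_priors(), h4_threshold = 0.9,
                            prior_sd_w = 0.2, p_enter = 1e-5,
                            max_causal = 2L, run_clpp = TRUE,
                            verbose = FALSE) {
  structure(list(fdr = fdr, window_bp = window_bp, priors = priors,
                 h4_threshold = h4_threshold, prior_sd_w = prior_sd_w,
                 p_enter = p_enter, max_causal = as.integer(max_causal),
                 run_clpp = run_clpp, verbose = verbose),
            class = "pipeline_params")
}

#' Run the full two-disease colocalisation pipeline
#'
#' @param scenario Either a [scenario_config()] (data are simulated) or a
#'   list with `cohort1`, `cohort2` and `panel` already built.
#' @param params A [pipeline_params()].
#' @param out_dir Optional directory for artifacts (results TSV, regions
#'   BED, manifest JSON, per-region plot data). Created if missing; on a
#'   stage failure partial outputs are removed.
#' @return `pipeline_result`: `table` (one row per analysed signal
#'   pair), `regions`, `manifest`, `signals1`, `signals2`, `coloc`
#'   (list of `coloc_result`), `clpp` (per region).
#' @export
run_pipeline <- function(scenario, params = pipeline_params(),
                         out_dir = NULL) {
  verbose <- params$verbose
  if (inherits(scenario, "scenario_config")) {
    dc_log(verbose, "stage simulate: seed %d", scenario$seed)
    scenario <- simulate_two_trait_scenario(scenario)
  }
  cohort1 <- scenario$cohort1; cohort2 <- scenario$cohort2
  panel <- scenario$panel
  stage <- "assoc"
  result <- tryCatch({
    dc_log(verbose, "stage assoc: scoring %d variants x 2 traits",
           ncol(cohort1$genotypes))
    rec1 <- score_variants(cohort1, verbose = verbose)
    rec2 <- score_variants(cohort2, verbose = verbose)
    h <- harmonize(rec1, rec2, verbose = verbose)
    q1 <- bh_fdr(setNames(h$rec1$p, h$rec1$id))
    q2 <- bh_fdr(setNames(h$rec2$p, h$rec2$id))

    stage <- "regions"
    pos <- setNames(h$rec1$pos, h$rec1$id)
    chrom <- setNames(h$rec1$chrom, h$rec1$id)
    overlap <- find_overlap_variants(q1, q2, pos, params$fdr)
    qmax <- pmax(q1, q2[names(q1)])
    regions <- build_regions(overlap, chrom, pos, qmax, params$window_bp)
    dc_log(verbose, "stage regions: %d overlap variants -> %d regions",
           length(overlap), nrow(regions))

    stage <- "signals"
    rows <- list(); coloc_list <- list(); clpp_list <- list()
    sig1_all <- list(); sig2_all <- list()
    n_pairs <- 0L
    for (ri in seq_len(nrow(regions))) {
      region <- regions[ri, ]
      stage <- paste0("signals:", region$region_id)
      sig1 <- enumerate_signals(cohort1, region, trait = "trait1",
                                p_enter = params$p_enter,
                                verbose = verbose)
      sig2 <- enumerate_signals(cohort2, region, trait = "trait2",
                                p_enter = params$p_enter,
                                verbose = verbose)
      sig1_all[[region$region_id]] <- sig1
      sig2_all[[region$region_id]] <- sig2
      dc_log(verbose, "region %s: %d x %d signals", region$region_id,
             length(sig1), length(sig2))
      if (!length(sig1) || !length(sig2)) next

      stage <- paste0("clpp:", region$region_id)
      region_clpp <- NULL
      if (isTRUE(params$run_clpp)) {
        ids_r <- intersect(
          h$rec1$id[h$rec1$chrom == region$chrom &
                      h$rec1$pos >= region$start &
                      h$rec1$pos <= region$end],
          panel$meta$id)
        R <- cor_matrix(panel, ids_r)
        ids_r <- colnames(R)
        fm1 <- finemap(h$rec1[match(ids_r, h$rec1$id), ], R,
                       max_causal = params$max_causal)
        fm2 <- finemap(h$rec2[match(ids_r, h$rec2$id), ], R,
                       max_causal = params$max_causal)
        region_clpp <- clpp(fm1, fm2)
        clpp_list[[region$region_id]] <- region_clpp
      }

      stage <- paste0("coloc:", region$region_id)
      for (s1 in sig1) for (s2 in sig2) {
        cres <- coloc_posteriors(s1$records, s2$records,
                                 priors = params$priors,
                                 prior_sd_w1 = params$prior_sd_w,
                                 prior_sd_w2 = params$prior_sd_w)
        n_pairs <- n_pairs + 1L
        pair_id <- sprintf("%s|r%d|r%d", region$region_id, s1$rank,
                           s2$rank)
        coloc_list[[pair_id]] <- cres
        shared <- cres$pp["pp4"] >= params$h4_threshold
        direction <- if (shared)
          classify_direction(cres, fallback_id = s2$index_id)
        else NA_character_
        idx2 <- s2$records[s2$records$id == s2$index_id, ]
        idx1 <- s1$records[s1$records$id == s1$index_id, ]
        r2_idx <- tryCatch(
          index_ld(panel, s1$index_id, s2$index_id),
          error = function(e) NA_real_)
        rows[[pair_id]] <- data.frame(
          region_id = region$region_id, chrom = region$chrom,
          index2_id = s2$index_id, index2_pos = idx2$pos[1],
          ref = idx2$ref[1], alt = idx2$alt[1],
          cond2 = if (length(s2$condition_on))
            paste(s2$condition_on, collapse = ",") else "-",
          or2 = exp(idx2$beta[1]),
          or2_lo = exp(idx2$beta[1] - 1.96 * idx2$se[1]),
          or2_hi = exp(idx2$beta[1] + 1.96 * idx2$se[1]),
          p2 = idx2$p[1],
          r2_index = r2_idx, index1_id = s1$index_id,
          cond1 = if (length(s1$condition_on))
            paste(s1$condition_on, collapse = ",") else "-",
          or1 = exp(idx1$beta[1]),
          or1_lo = exp(idx1$beta[1] - 1.96 * idx1$se[1]),
          or1_hi = exp(idx1$beta[1] + 1.96 * idx1$se[1]),
          p1 = idx1$p[1],
          pp0 = cres$pp[["pp0"]], pp1 = cres$pp[["pp1"]],
          pp2 = cres$pp[["pp2"]], pp3 = cres$pp[["pp3"]],
          pp4 = cres$pp[["pp4"]],
          top_h4_id = cres$top_h4_id,
          regional_clpp = if (is.null(region_clpp)) NA_real_
          else region_clpp$regional,
          shared = unname(shared), direction = direction,
          stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
    if (nrow(tab))
      tab <- tab[order(tab$chrom, tab$index2_pos), , drop = FALSE]
    rownames(tab) <- NULL
    manifest <- list(
      seed = scenario$config$seed %||% NA,
      params = list(fdr = params$fdr, window_bp = params$window_bp,
                    p1 = params$priors$p1, p2 = params$priors$p2,
                    p12 = params$priors$p12,
                    h4_threshold = params$h4_threshold,
                    prior_sd_w = params$prior_sd_w,
                    p_enter = params$p_enter,
                    max_causal = params$max_causal),
      package_version = as.character(utils::packageVersion("dualcoloc")),
      n_variants = ncol(cohort1$genotypes),
      n_overlap_variants = length(overlap),
      n_regions = nrow(regions),
      n_signal_pairs = n_pairs,
      n_shared = if (nrow(tab)) sum(tab$shared) else 0L)
    structure(list(table = tab, regions = regions, manifest = manifest,
                   signals1 = sig1_all, signals2 = sig2_all,
                   coloc = coloc_list, clpp = clpp_list,
                   records1 = h$rec1, records2 = h$rec2,
                   q1 = q1, q2 = q2, panel = panel),
              class = "pipeline_result")
  }, error = function(e) {
    if (!is.null(out_dir) && dir.exists(out_dir))
      unlink(file.path(out_dir, c("results.tsv", "regions.bed",
                                  "manifest.json")), force = TRUE)
    stop_param("pipeline failed at stage '%s': %s", stage,
               conditionMessage(e))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(result$table))
      data.table::fwrite(result$table, file.path(out_dir, "results.tsv"),
                         sep = "\t", na = ".", quote = FALSE)
    if (nrow(result$regions))
      write_regions_bed(result$regions, file.path(out_dir, "regions.bed"))
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("pipeline: %d overlap variants, %d regions, ",
                     "%d signal-pair colocalisation analyses, ",
                     "%d shared (pp4 >= threshold)\n"),
              m$n_overlap_variants, m$n_regions, m$n_signal_pairs,
              m$n_shared))
  invisible(x)
}

#' Regional association series for plotting
#'
#' Aligns per-variant position, `-log10 p` for both traits (marginal or
#' conditional records as supplied) and r-squared to a chosen index
#' variant, for a regional Manhattan plot coloured by LD to the index.
#'
#' @param rec1,rec2 Harmonized summary-statistic data.frames over one
#'   region.
#' @param panel [ld_panel()] providing LD; if the index is monomorphic
#'   in the panel the r2 column is `NA` and flagged.
#' @param index_id Index variant id (must be present in the records).
#' @param genes Optional data.frame of gene-track intervals
#'   (`name, start, end`), carried through.
#' @return `regional_plot_data`: data.frame `id, pos, nlp1, nlp2,
#'   r2_index` plus attributes `index_id`, `genes`, `r2_ok`.
#' @export
make_regional_plot_data <- function(rec1, rec2, panel, index_id,
                                    genes = NULL) {
  shared <- intersect(rec1$id, rec2$id)
  if (!(index_id %in% shared))
    stop_param("index variant %s absent from the shared records", index_id)
  r1 <- rec1[match(shared, rec1$id), ]
  r2 <- rec2[match(shared, rec2$id), ]
  r2v <- rep(NA_real_, length(shared))
  r2_ok <- TRUE
  ids_p <- intersect(shared, panel$meta$id)
  r2m <- tryCatch(r2_matrix(panel, ids_p), error = function(e) NULL)
  if (is.null(r2m) || !(index_id %in% colnames(r2m))) {
    r2_ok <- FALSE
  } else {
    hit <- match(colnames(r2m), shared)
    r2v[hit] <- r2m[, index_id]
  }
  out <- data.frame(id = shared, pos = r1$pos,
                    nlp1 = -log10(r1$p), nlp2 = -log10(r2$p),
                    r2_index = r2v, stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  structure(out, index_id = index_id, genes = genes, r2_ok = r2_ok,
            class = c("regional_plot_data", "data.frame"))
}

#' Write regional plot data as TSV
#' @param pd A `regional_plot_data`.
#' @param path Output path.
#' @export
write_plot_data <- function(pd, path) {
  data.table::fwrite(as.data.frame(pd), path, sep = "\t", na = ".",
                     quote = FALSE)
  invisible(path)
}

#' Minimal two-panel regional plot
#'
#' Renders stacked Manhattan panels (one per trait), points coloured by
#' r-squared to the index variant. Requires ggplot2.
#'
#' @param pd A `regional_plot_data`.
#' @param trait_names Panel labels.
#' @return A ggplot object.
#' @export
plot_regional <- function(pd, trait_names = c("trait 1", "trait 2")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("plot_regional requires the 'ggplot2' package")
  df <- as.data.frame(pd)
  long <- rbind(
    data.frame(pos = df$pos, nlp = df$nlp1, r2 = df$r2_index,
               trait = trait_names[1]),
    data.frame(pos = df$pos, nlp = df$nlp2, r2 = df$r2_index,
               trait = trait_names[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = pos / 1e6, y = nlp,
                                     colour = r2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(trait ~ ., scales = "free_y") +
    ggplot2::scale_colour_gradient(low = "navy", high = "red",
                                   limits = c(0, 1), name = "r²") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_bw()
}

#' Write a cohort as VCF plus a phenotype file
#'
#' Minimal VCFv4.2 with GT dosage encoding (0/0, 0/1, 1/1) and a
#' one-column phenotype text file beside it.
#'
#' @param cohort A `cohort`.
#' @param path VCF output path; phenotype goes to `<path>.pheno`.
#' @export
write_cohort_vcf <- function(cohort, path) {
  n <- nrow(cohort$genotypes)
  samples <- sprintf("S%05d", seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              "##source=dualcoloc",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  meta <- cohort$meta
  body <- vapply(seq_len(ncol(cohort$genotypes)), function(j) {
    paste(c(meta$chrom[j], meta$pos[j], meta$id[j], meta$ref[j],
            meta$alt[j], ".", "PASS", ".", "GT",
            gt_code[cohort$genotypes[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  writeLines(as.character(cohort$phenotype), paste0(path, ".pheno"))
  invisible(path)
}

#' Write a scenario truth record as TSV
#' @param scenario Output of [simulate_two_trait_scenario()].
#' @param path Output path.
#' @export
write_truth <- function(scenario, path) {
  data.table::fwrite(scenario$truth, path, sep = "\t", na = ".",
                     quote = FALSE)
  invisible(path)
}
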