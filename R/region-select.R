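# FDR-overlap variant selection and ~0.5 Mb analysis windows.
# Windows are seeded greedily at the variant with the smallest max(q1, q2),
# extend seed_pos +/- window_bp/2, absorb remaining overlap variants, and
# overlapping or abutting windows are merged (better seed kept).
# Coordinates are 1-based inclusive internally; BED output converts to
# 0-based half-open.

#' Variants significant in both traits
#'
#' @param q1,q2 Named q-value vectors (variant id -> q) from [bh_fdr()],
#'   on harmonized variant sets.
#' @param positions Named position vector (id -> bp) used for sorting.
#' @param threshold FDR threshold; strict `q < threshold` in BOTH traits.
#' @return Character vector of ids sorted by position.
#' @export
find_overlap_variants <- function(q1, q2, positions, threshold = 0.01) {
  shared <- intersect(names(q1), names(q2))
  hit <- shared[q1[shared] < threshold & q2[shared] < threshold]
  hit[order(positions[hit])]
}

#' Build analysis windows around overlap variants
#'
#' @param ids Overlap variant ids.
#' @param chrom,pos Named (by id) chromosome and position lookups covering
#'   `ids`.
#' @param qmax Named vector of `max(q1, q2)` per id; the smallest seeds
#'   each window.
#' @param window_bp Total window span (default 500000; seed +/-
#'   `window_bp/2`).
#' @return data.frame of regions: `chrom, start, end, seed_id,
#'   member_ids` (comma-joined), sorted by chrom then start; `start >= 1`.
#' @export
build_regions <- function(ids, chrom, pos, qmax, window_bp = 5e5) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), seed_id = character(),
                      member_ids = character(), stringsAsFactors = FALSE)
  if (!length(ids)) return(empty)
  half <- floor(window_bp / 2)
  df <- data.frame(id = ids, chrom = as.character(chrom[ids]),
                   pos = as.numeric(pos[ids]), qmax = as.numeric(qmax[ids]),
                   stringsAsFactors = FALSE)
  regions <- list()
  remaining <- df[order(df$pos), , drop = FALSE]
  while (nrow(remaining)) {
    s <- which.min(remaining$qmax)
    seed <- remaining[s, ]
    lo <- max(1, seed$pos - half + 1)  # span exactly window_bp inclusive
    hi <- seed$pos + half
    inside <- remaining$chrom == seed$chrom &
      remaining$pos >= lo & remaining$pos <= hi
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = seed$chrom, start = lo, end = hi, seed_id = seed$id,
      seed_q = seed$qmax,
      member_ids = paste(remaining$id[inside], collapse = ","),
      stringsAsFactors = FALSE)
    remaining <- remaining[!inside, , drop = FALSE]
  }
  reg <- do.call(rbind, regions)
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  # merge overlapping or abutting windows per chromosome, keep better seed
  merged <- list()
  for (ch in unique(reg$chrom)) {
    sub <- reg[reg$chrom == ch, , drop = FALSE]
    cur <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      nxt <- sub[i, ]
      if (nxt$start <= cur$end + 1) {
        cur$end <- max(cur$end, nxt$end)
        cur$member_ids <- paste(cur$member_ids, nxt$member_ids, sep = ",")
        if (nxt$seed_q < cur$seed_q) {
          cur$seed_id <- nxt$seed_id; cur$seed_q <- nxt$seed_q
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out$seed_q <- NULL
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write regions as BED (0-based half-open)
#'
#' Internal 1-based inclusive `[start, end]` becomes BED
#' `[start - 1, end)`.
#'
#' @param regions data.frame from [build_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = regions$seed_id)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive regions
#' @param path BED path.
#' @return data.frame with `chrom, start, end, seed_id` (1-based
#'   inclusive).
#' @export
read_regions_bed <- function(path) {
  bed <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(bed)[1:3] <- c("chrom", "start", "end")
  out <- data.frame(chrom = as.character(bed$chrom),
                    start = bed$start + 1L, end = bed$end,
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) out$seed_id <- bed[[4L]]
  out
}
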