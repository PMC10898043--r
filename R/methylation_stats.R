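#' Two-sided Fisher exact p value for a 2x2 table
#'
#' Convenience wrapper around [stats::fisher.test()] used by the DMR caller
#' and the peak-association test.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, c, b, d), 2)`.
#' @return The two-sided p value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))$p.value
}

#' Mean beta in tiling genomic windows
#'
#' Windows tile each chromosome from coordinate 1. A window's beta is the
#' unweighted mean of per-CpG betas at CpGs with at least `min_depth`
#' coverage; windows with no qualifying CpG are absent from the result
#' (missing, not zero), so genome-wide averages are not diluted.
#'
#' @param track A `cpg_track`.
#' @param window Window size in bp (default 100 kb).
#' @param min_depth Minimum per-CpG depth (default 1).
#' @return A data.frame with columns `chrom`, `win_start` (1-based),
#'   `win_end`, `n_cpgs`, `mean_beta`.
#' @export
window_betas <- function(track, window = 100000L, min_depth = 1L) {
  stopifnot(inherits(track, "cpg_track"))
  if (window < 1L) stop_param("'window' must be >= 1")
  t2 <- track[track$depth >= min_depth, , drop = FALSE]
  if (nrow(t2) == 0L) {
    return(data.frame(chrom = character(0), win_start = integer(0),
                      win_end = integer(0), n_cpgs = integer(0),
                      mean_beta = numeric(0)))
  }
  wi <- (t2$pos - 1L) %/% as.integer(window)
  key <- paste(t2$chrom, wi, sep = ":")
  mb <- tapply(t2$beta, key, mean)
  nc <- tapply(t2$beta, key, length)
  parts <- strsplit(names(mb), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    win_start = as.integer(vapply(parts, `[`, character(1), 2L)) *
      as.integer(window) + 1L,
    n_cpgs = as.integer(nc),
    mean_beta = as.numeric(mb),
    stringsAsFactors = FALSE
  )
  out$win_end <- out$win_start + as.integer(window) - 1L
  out <- out[order(out$chrom, out$win_start),
             c("chrom", "win_start", "win_end", "n_cpgs", "mean_beta")]
  rownames(out) <- NULL
  out
}

#' Per-CpG concordance between two coverage tracks
#'
#' Restricted to CpGs with at least `min_depth` coverage in both tracks:
#' Pearson correlation of the paired betas, and the discordant fraction --
#' the share of CpGs whose betas differ by more than 0.5, the conventional
#' definition of a switched methylation state.
#'
#' @param track_a,track_b `cpg_track` objects.
#' @param min_depth Minimum depth required in both tracks (default 1).
#' @param delta_cut Discordance cutoff on `|beta_a - beta_b|` (default 0.5,
#'   strict inequality).
#' @return A list of class `concordance_result`: `pearson_r` (`NA` when
#'   fewer than two shared CpGs or zero variance), `n_cpgs`,
#'   `discordant_fraction`.
#' @export
concordance <- function(track_a, track_b, min_depth = 1L, delta_cut = 0.5) {
  stopifnot(inherits(track_a, "cpg_track"), inherits(track_b, "cpg_track"))
  if (min_depth < 1L) stop_param("'min_depth' must be >= 1")
  a <- track_a[track_a$depth >= min_depth, c("chrom", "pos", "beta")]
  b <- track_b[track_b$depth >= min_depth, c("chrom", "pos", "beta")]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  n <- nrow(m)
  r <- NA_real_
  if (n >= 2L && stats::sd(m$beta_a) > 0 && stats::sd(m$beta_b) > 0) {
    r <- cor(m$beta_a, m$beta_b)
  }
  structure(
    list(pearson_r = r, n_cpgs = n,
         discordant_fraction = if (n > 0L)
           mean(abs(m$beta_a - m$beta_b) > delta_cut) else NA_real_),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> r = %s over %d CpGs; discordant (|dbeta|>0.5): %s\n",
              format(x$pearson_r, digits = 3), x$n_cpgs,
              format(x$discordant_fraction, digits = 3)))
  invisible(x)
}

# Candidate regions: maximal runs of consecutive CpGs with inter-CpG gap
# <= gap_max, greedily split so that each region spans <= max_region bp
# (the span includes the G of the last unit).
segment_regions <- function(chrom, pos, gap_max, max_region) {
  od <- order(chrom, pos)
  chrom <- chrom[od]; pos <- pos[od]
  newrun <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                diff(pos) > gap_max)
  run_id <- cumsum(newrun)
  regions <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    p <- pos[idx]
    start_i <- 1L
    for (j in seq_along(p)) {
      if (p[j] + 1L - p[start_i] + 1L > max_region) {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = chrom[idx[1]], start = p[start_i],
                     end = p[j - 1L] + 1L,
                     n_cpgs = j - start_i, stringsAsFactors = FALSE)
        start_i <- j
      }
    }
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = chrom[idx[1]], start = p[start_i],
                 end = p[length(p)] + 1L,
                 n_cpgs = length(p) - start_i + 1L,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, regions)
}

# Pooled (meth, unmeth) per region for one track.
region_counts <- function(track, regions_gr) {
  hits <- GenomicRanges::findOverlaps(track_positions_gr(track), regions_gr)
  meth <- integer(length(regions_gr)); unmeth <- integer(length(regions_gr))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    tmp <- rowsum(cbind(track$meth[qh], track$unmeth[qh]), sh)
    ridx <- as.integer(rownames(tmp))
    meth[ridx] <- tmp[, 1]; unmeth[ridx] <- tmp[, 2]
  }
  cbind(meth = meth, unmeth = unmeth)
}

#' Pooled beta per region
#'
#' @param track A `cpg_track`.
#' @param regions A `GRanges`.
#' @return Numeric vector of pooled `meth / (meth + unmeth)` per region
#'   (`NA` where uncovered).
#' @export
region_betas <- function(track, regions) {
  rc <- region_counts(track, regions)
  depth <- rc[, 1] + rc[, 2]
  ifelse(depth > 0L, rc[, 1] / depth, NA_real_)
}

#' Call differentially methylated regions
#'
#' Candidate regions are maximal runs of consecutive CpGs with inter-CpG
#' gap at most `gap_max`, split to spans of at most `max_region` bp. A
#' region is testable only when its pooled depth reaches `min_depth` in
#' every sample of both groups. Group betas are means of per-sample pooled
#' region betas; the p value is a two-sided Fisher exact test on the
#' pooled (methylated, unmethylated) counts of group A versus group B, and
#' q values are Benjamini-Hochberg across all tested regions. A DMR is
#' emitted when `p <= p_max` and `|delta_beta| >= delta_min` (the delta
#' cutoff is inclusive; set `delta_strict = TRUE` for a strict
#' inequality). Direction is `hyper` when group A exceeds group B.
#'
#' The printed threshold configurations in common use are
#' `(p_max = 1e-7, delta_min = 0.5)`, `(0.05, 0.2)` and `(0.05, 0.33)`.
#'
#' @param group_a,group_b Lists of `cpg_track` objects (one per sample).
#' @param max_region Maximum region span, bp (default 300).
#' @param gap_max Maximum inter-CpG gap within a region, bp (default 100).
#' @param min_depth Minimum pooled region depth per sample (default 10).
#' @param p_max,delta_min Emission thresholds.
#' @param delta_strict Use strict `>` for the delta cutoff.
#' @return A data.frame of class `dmr_set`: `chrom`, `start`, `end`,
#'   `n_cpgs`, `mean_beta_a`, `mean_beta_b`, `delta_beta`, `p_value`,
#'   `q_value`, `direction`; the attribute `n_tested` records how many
#'   regions entered testing.
#' @export
call_dmrs <- function(group_a, group_b, max_region = 300L, gap_max = 100L,
                      min_depth = 10L, p_max = 1e-7, delta_min = 0.5,
                      delta_strict = FALSE) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_param("both groups need at least one sample track")
  }
  stopifnot(all(vapply(c(group_a, group_b), inherits, logical(1),
                       "cpg_track")))
  all_tracks <- c(group_a, group_b)
  posdf <- unique(do.call(rbind, lapply(all_tracks,
                                        function(t) t[, c("chrom", "pos")])))
  if (nrow(posdf) == 0L) return(empty_dmr_set(0L))
  reg <- segment_regions(posdf$chrom, posdf$pos, gap_max, max_region)
  reg_gr <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start, reg$end))

  counts <- lapply(all_tracks, region_counts, regions_gr = reg_gr)
  depth_ok <- Reduce(`&`, lapply(counts, function(m)
    (m[, 1] + m[, 2]) >= min_depth))
  keep <- which(depth_ok)
  if (length(keep) == 0L) return(empty_dmr_set(0L))

  ia <- seq_along(group_a); ib <- length(group_a) + seq_along(group_b)
  beta_mat <- vapply(counts, function(m)
    m[keep, 1] / (m[keep, 1] + m[keep, 2]), numeric(length(keep)))
  beta_mat <- matrix(beta_mat, nrow = length(keep))
  mean_a <- rowMeans(beta_mat[, ia, drop = FALSE])
  mean_b <- rowMeans(beta_mat[, ib, drop = FALSE])

  pool <- function(idx, col) {
    Reduce(`+`, lapply(counts[idx], function(m) m[keep, col]))
  }
  ma <- pool(ia, 1L); ua <- pool(ia, 2L)
  mb <- pool(ib, 1L); ub <- pool(ib, 2L)
  p <- vapply(seq_along(keep), function(i)
    fisher_exact_p(ma[i], ua[i], mb[i], ub[i]), numeric(1))
  q <- p.adjust(p, method = "BH")

  delta <- mean_a - mean_b
  pass_delta <- if (delta_strict) abs(delta) > delta_min else
    abs(delta) >= delta_min
  sel <- which(p <= p_max & pass_delta)
  out <- data.frame(
    chrom = reg$chrom[keep][sel],
    start = reg$start[keep][sel],
    end = reg$end[keep][sel],
    n_cpgs = reg$n_cpgs[keep][sel],
    mean_beta_a = mean_a[sel],
    mean_beta_b = mean_b[sel],
    delta_beta = delta[sel],
    p_value = p[sel],
    q_value = q[sel],
    direction = ifelse(delta[sel] > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(keep)
  attr(out, "tested_p") <- p
  class(out) <- c("dmr_set", "data.frame")
  out
}

empty_dmr_set <- function(n_tested) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_cpgs = integer(0),
                    mean_beta_a = numeric(0), mean_beta_b = numeric(0),
                    delta_beta = numeric(0), p_value = numeric(0),
                    q_value = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_tested") <- n_tested
  attr(out, "tested_p") <- numeric(0)
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Export DMRs as BED6+
#'
#' Name column `hyper`/`hypo`, score 0, strand `.`; `delta_beta`, `p_value`
#' and `q_value` appended as extra columns.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- data.frame(dmrs$chrom, dmrs$start - 1L, dmrs$end, dmrs$direction,
                   0L, ".", signif(dmrs$delta_beta, 6),
                   signif(dmrs$p_value, 6), signif(dmrs$q_value, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Cell-specific differential promoter methylation
#'
#' For each TSS +/- `flank` region and each cell, compares that cell's
#' pooled counts against the pooled counts of all other cells (one versus
#' rest) with a two-sided Fisher exact test; Benjamini-Hochberg q values
#' are computed per cell across its tested regions. Regions pass into a
#' cell's `hyper` or `hypo` set at `q <= q_max` and
#' `|delta_beta| >= delta_min`.
#'
#' @param tracks Named list of `cpg_track` objects, one per cell (>= 2).
#' @param tss `GRanges` of width-1 TSS positions.
#' @param flank Half-width of the region around each TSS, bp (default
#'   4000).
#' @param min_depth Minimum pooled depth required on both sides of the
#'   comparison (default 10).
#' @param q_max,delta_min Emission thresholds (defaults 0.01 and 0.5).
#' @return A named list per cell, each with `hyper` and `hypo` (`GRanges`
#'   with `delta_beta`, `p_value`, `q_value` metadata), plus a `skipped`
#'   count of untestable region-cell pairs.
#' @export
differential_promoters <- function(tracks, tss, flank = 4000L,
                                   min_depth = 10L, q_max = 0.01,
                                   delta_min = 0.5) {
  if (length(tracks) < 2L) stop_param("need at least two cell tracks")
  if (is.null(names(tracks))) names(tracks) <- paste0("cell", seq_along(tracks))
  stopifnot(methods::is(tss, "GRanges"))
  centers <- BiocGenerics::start(tss)
  reg_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(centers - as.integer(flank), 1L),
                     centers + as.integer(flank))
  )
  counts <- lapply(tracks, region_counts, regions_gr = reg_gr)
  out <- list()
  skipped_total <- 0L
  for (cell in names(tracks)) {
    own <- counts[[cell]]
    rest <- Reduce(`+`, counts[setdiff(names(tracks), cell)])
    d_own <- own[, 1] + own[, 2]; d_rest <- rest[, 1] + rest[, 2]
    testable <- which(d_own >= min_depth & d_rest >= min_depth)
    skipped_total <- skipped_total + (length(reg_gr) - length(testable))
    if (length(testable) == 0L) {
      out[[cell]] <- list(hyper = reg_gr[0], hypo = reg_gr[0])
      next
    }
    p <- vapply(testable, function(i)
      fisher_exact_p(own[i, 1], own[i, 2], rest[i, 1], rest[i, 2]),
      numeric(1))
    q <- p.adjust(p, method = "BH")
    delta <- own[testable, 1] / d_own[testable] -
      rest[testable, 1] / d_rest[testable]
    sel <- q <= q_max & abs(delta) >= delta_min
    gr <- reg_gr[testable][sel]
    S4Vectors::mcols(gr)$delta_beta <- delta[sel]
    S4Vectors::mcols(gr)$p_value <- p[sel]
    S4Vectors::mcols(gr)$q_value <- q[sel]
    out[[cell]] <- list(hyper = gr[gr$delta_beta > 0],
                        hypo = gr[gr$delta_beta < 0])
  }
  out$skipped <- skipped_total
  out
}

#' Select hypomethylated regions from a track
#'
#' Regions whose pooled beta falls below `beta_max` (default 0.10, the
#' conventional "hypomethylated: beta < 10%" cutoff).
#'
#' @param track A `cpg_track`.
#' @param regions A `GRanges`.
#' @param beta_max Upper beta bound (strict).
#' @param min_depth Minimum pooled depth for a region to qualify.
#' @return The qualifying subset of `regions`.
#' @export
hypomethylated_regions <- function(track, regions, beta_max = 0.10,
                                   min_depth = 1L) {
  rc <- region_counts(track, regions)
  depth <- rc[, 1] + rc[, 2]
  beta <- ifelse(depth > 0L, rc[, 1] / depth, NA_real_)
  regions[!is.na(beta) & depth >= min_depth & beta < beta_max]
}

#' Association between cell-specific hypomethylation and ChIP peaks
#'
#' For each cell's specifically hypomethylated region set, counts how many
#' regions contain (overlap by >= 1 bp) a peak of that cell versus a peak
#' of the other cell, and tests the own-versus-other contrast with a
#' two-sided Fisher exact test -- small p means the cell's hypomethylation
#' co-locates preferentially with its own histone peaks. The `pct` matrix
#' reports, per region set (rows), the percentage containing each peak set
#' (columns).
#'
#' @param regions_1,regions_2 `GRanges`: regions specifically
#'   hypomethylated in cell 1 / cell 2.
#' @param peaks_1,peaks_2 `GRanges`: ChIP peaks of cell 1 / cell 2.
#' @return A list with `tables` (per cell, a 2x2 matrix of own/other peak
#'   containment), `pct` (2x2 percentage matrix regions x peaks) and
#'   `p_values` (named vector, `NA` for an empty region set).
#' @export
peak_association <- function(regions_1, regions_2, peaks_1, peaks_2) {
  ov <- function(r, p) IRanges::overlapsAny(r, p)
  cnt <- function(r, p) sum(ov(r, p))
  n1 <- length(regions_1); n2 <- length(regions_2)
  tab1 <- matrix(c(cnt(regions_1, peaks_1), n1 - cnt(regions_1, peaks_1),
                   cnt(regions_1, peaks_2), n1 - cnt(regions_1, peaks_2)),
                 nrow = 2L, byrow = TRUE,
                 dimnames = list(c("own_peak", "other_peak"),
                                 c("contains", "lacks")))
  tab2 <- matrix(c(cnt(regions_2, peaks_2), n2 - cnt(regions_2, peaks_2),
                   cnt(regions_2, peaks_1), n2 - cnt(regions_2, peaks_1)),
                 nrow = 2L, byrow = TRUE,
                 dimnames = list(c("own_peak", "other_peak"),
                                 c("contains", "lacks")))
  pct <- matrix(100 * c(
    if (n1) mean(ov(regions_1, peaks_1)) else NA_real_,
    if (n1) mean(ov(regions_1, peaks_2)) else NA_real_,
    if (n2) mean(ov(regions_2, peaks_1)) else NA_real_,
    if (n2) mean(ov(regions_2, peaks_2)) else NA_real_),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("cell1_regions", "cell2_regions"),
                    c("cell1_peaks", "cell2_peaks")))
  p1 <- if (n1 == 0L) NA_real_ else stats::fisher.test(tab1)$p.value
  p2 <- if (n2 == 0L) NA_real_ else stats::fisher.test(tab2)$p.value
  list(tables = list(cell1 = tab1, cell2 = tab2), pct = pct,
       p_values = c(cell1 = p1, cell2 = p2))
}
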