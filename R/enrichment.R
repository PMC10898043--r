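#' Accumulate per-CpG coverage from simulated molecules
#'
#' Because origin coordinates of simulated molecules are known, coverage is
#' accumulated directly (no alignment): each CpG unit overlapped by a
#' molecule's insert gains one unit of depth, counted as methylated or
#' unmethylated according to that molecule's drawn per-molecule state.
#'
#' @param molecules A `converted_molecules` object.
#' @return A data.frame of class `cpg_track` with columns `chrom`, `pos`
#'   (Watson C coordinate), `depth`, `meth`, `unmeth` and `beta`
#'   (`meth/depth`).
#' @export
accumulate_coverage <- function(molecules) {
  stopifnot(inherits(molecules, "converted_molecules"))
  n_units <- lengths(molecules$cpg_units)
  if (sum(n_units) == 0L) {
    return(new_cpg_track(character(0), integer(0), integer(0), integer(0)))
  }
  chrom <- rep(as.character(GenomicRanges::seqnames(molecules$fragments)),
               n_units)
  pos <- unlist(molecules$cpg_units, use.names = FALSE)
  meth <- unlist(molecules$cpg_meth, use.names = FALSE)
  key <- paste(chrom, pos, sep = ":")
  m <- rowsum(cbind(depth = 1L, meth = as.integer(meth)), key)
  parts <- strsplit(rownames(m), ":", fixed = TRUE)
  new_cpg_track(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    meth = as.integer(m[, "meth"]),
    unmeth = as.integer(m[, "depth"] - m[, "meth"])
  )
}

new_cpg_track <- function(chrom, pos, meth, unmeth) {
  out <- data.frame(chrom = chrom, pos = pos, depth = meth + unmeth,
                    meth = meth, unmeth = unmeth,
                    stringsAsFactors = FALSE)
  out$beta <- ifelse(out$depth > 0L, out$meth / out$depth, NA_real_)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_track", "data.frame")
  out
}

#' Build a CpG coverage track from counts
#'
#' @param chrom,pos,meth,unmeth Parallel vectors: chromosome, Watson C
#'   coordinate (1-based), methylated and unmethylated counts.
#' @return A `cpg_track` data.frame (see [accumulate_coverage()]).
#' @export
cpg_track <- function(chrom, pos, meth, unmeth) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(pos) == length(meth), length(meth) == length(unmeth),
            all(meth >= 0L), all(unmeth >= 0L))
  new_cpg_track(chrom, as.integer(pos), as.integer(meth),
                as.integer(unmeth))
}

#' Read and write bismark-style coverage files
#'
#' Tab-separated columns: chromosome, start (1-based), end (= start),
#' methylation percentage, methylated count, unmethylated count -- the
#' dialect emitted by bismark's coverage extractor.
#'
#' @param path File path.
#' @param track A `cpg_track`.
#' @return `read_bismark_cov()` returns a `cpg_track`.
#' @export
read_bismark_cov <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "pct",
                                 "meth", "unmeth"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric", "integer", "integer"))
  new_cpg_track(df$chrom, df$start, df$meth, df$unmeth)
}

#' @rdname read_bismark_cov
#' @export
write_bismark_cov <- function(track, path) {
  stopifnot(inherits(track, "cpg_track"))
  df <- data.frame(track$chrom, track$pos, track$pos,
                   ifelse(track$depth > 0, 100 * track$meth / track$depth, 0),
                   track$meth, track$unmeth)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_positions_gr <- function(track, width = 2L) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$pos, width = width))
}

#' Element capture at a combined-coverage threshold
#'
#' An element is captured when the combined coverage of its CpGs reaches
#' `threshold`. Combined coverage is the sum of per-CpG depths over all CpG
#' units inside the element (`rule = "sum"`, the default reading of
#' coverage "accumulated" across an element); `rule = "mean"` uses the mean
#' depth instead. An element containing no covered CpG is simply not
#' captured.
#'
#' @param track A `cpg_track`.
#' @param elements A `GRanges` of elements.
#' @param threshold Combined-coverage threshold (default 100).
#' @param rule `"sum"` or `"mean"`.
#' @return A logical vector along `elements`.
#' @export
element_captured <- function(track, elements, threshold = 100L,
                             rule = c("sum", "mean")) {
  rule <- match.arg(rule)
  if (threshold < 1L) stop_param("'threshold' must be >= 1")
  stopifnot(inherits(track, "cpg_track"), methods::is(elements, "GRanges"))
  if (nrow(track) == 0L) return(rep(FALSE, length(elements)))
  hits <- GenomicRanges::findOverlaps(track_positions_gr(track), elements)
  agg <- numeric(length(elements))
  cnt <- integer(length(elements))
  if (length(hits)) {
    d <- track$depth[S4Vectors::queryHits(hits)]
    sh <- S4Vectors::subjectHits(hits)
    tmp <- rowsum(d, sh)
    agg[as.integer(rownames(tmp))] <- tmp[, 1]
    tab <- table(sh)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  if (rule == "mean") {
    agg <- ifelse(cnt > 0L, agg / cnt, 0)
  }
  agg >= threshold
}

#' Downsampling saturation curve
#'
#' Counts captured elements as a function of sequenced bases. Molecules are
#' permuted once (per seed) and each grid point takes the shortest prefix
#' of that permutation whose cumulative insert length reaches the target,
#' including the molecule that crosses it; nested prefixes make the curve
#' exactly monotone. Targets beyond the total base count are truncated to
#' the full library and flagged.
#'
#' @param molecules A `converted_molecules` object.
#' @param elements A `GRanges` of elements.
#' @param depth_grid Increasing vector of target base counts.
#' @param threshold,rule Passed to [element_captured()].
#' @param seed Integer seed for the permutation.
#' @return A data.frame of class `saturation_curve` with columns `bases`
#'   (target), `bases_used`, `n_molecules`, `captured`, `truncated`.
#' @export
saturation_curve <- function(molecules, elements, depth_grid,
                             threshold = 100L, rule = c("sum", "mean"),
                             seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(inherits(molecules, "converted_molecules"))
  if (is.unsorted(depth_grid, strictly = TRUE)) {
    stop_param("'depth_grid' must be strictly increasing")
  }
  n <- length(molecules)
  widths <- BiocGenerics::width(molecules$fragments)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  csum <- cumsum(as.numeric(widths[perm]))
  total <- if (n) csum[n] else 0

  rows <- lapply(depth_grid, function(target) {
    truncated <- target > total
    if (target <= 0) {
      k <- 0L
    } else if (truncated) {
      k <- n
    } else {
      k <- which(csum >= target)[1]
    }
    cap <- if (k == 0L) 0L else sum(element_captured(
      accumulate_coverage(molecules[perm[seq_len(k)]]),
      elements, threshold = threshold, rule = rule))
    data.frame(bases = target, bases_used = if (k == 0L) 0 else csum[k],
               n_molecules = k, captured = as.integer(cap),
               truncated = truncated)
  })
  out <- do.call(rbind, rows)
  if (any(out$truncated)) {
    message("saturation_curve: grid truncated at total library size (",
            format(total, big.mark = ","), " bases)")
  }
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Fraction of molecules overlapping each element class
#'
#' A molecule counts toward a label when its insert overlaps any interval
#' of that label by at least one base; labels are not mutually exclusive.
#' With zero molecules the fractions are undefined (`NA`), not zero.
#'
#' @param molecules A `converted_molecules` object or `GRanges` of
#'   fragments.
#' @param annotations A named list of `GRanges` (e.g. island / shore /
#'   shelf / promoter).
#' @return A data.frame with columns `label`, `n_overlapping`, `fraction`.
#' @export
read_fraction_by_element <- function(molecules, annotations) {
  frags <- if (inherits(molecules, "converted_molecules"))
    molecules$fragments else molecules
  stopifnot(methods::is(frags, "GRanges"), is.list(annotations))
  n <- length(frags)
  rows <- lapply(names(annotations), function(lab) {
    k <- if (n == 0L) 0L else
      sum(IRanges::overlapsAny(frags, annotations[[lab]]))
    data.frame(label = lab, n_overlapping = as.integer(k),
               fraction = if (n == 0L) NA_real_ else k / n)
  })
  do.call(rbind, rows)
}

#' Fragment length histogram and mode
#'
#' @param molecules A `converted_molecules` object or `GRanges`.
#' @return A list with `histogram` (data.frame `length`, `count`) and
#'   `mode` (smallest length achieving the maximum count; `NA` when
#'   empty).
#' @export
fragment_length_stats <- function(molecules) {
  frags <- if (inherits(molecules, "converted_molecules"))
    molecules$fragments else molecules
  w <- BiocGenerics::width(frags)
  if (length(w) == 0L) {
    return(list(histogram = data.frame(length = integer(0),
                                       count = integer(0)),
                mode = NA_integer_))
  }
  tab <- table(w)
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab))
  list(histogram = hist,
       mode = hist$length[which.max(hist$count)])
}
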