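#' Restriction enzyme panels
#'
#' The built-in panels target AT-only palindromic recognition sites, which
#' appear in converted sequence wherever unmethylated C's have become T:
#' the 1-cut panel is MseI (TTAA); the 4-cut panel adds MluCI (AATT),
#' SspI (AATATT) and PsiI (TTATAA). Because every built-in site is its own
#' reverse complement, scanning the given strand suffices; custom
#' non-palindromic enzymes are scanned on both strands.
#'
#' @param panel `"one_cut"`, `"four_cut"`, or `"custom"`.
#' @param enzymes For `"custom"`: a named character vector of recognition
#'   strings (name = enzyme) over A/C/G/T, each at least 4 bp.
#' @return A list of class `enzyme_panel` with elements `name` and
#'   `enzymes` (named character vector of recognition strings).
#' @examples
#' enzyme_panel("four_cut")
#' @export
enzyme_panel <- function(panel = c("one_cut", "four_cut", "custom"),
                         enzymes = NULL) {
  panel <- match.arg(panel)
  if (panel == "one_cut") {
    enzymes <- c(MseI = "TTAA")
  } else if (panel == "four_cut") {
    enzymes <- c(MseI = "TTAA", MluCI = "AATT", SspI = "AATATT",
                 PsiI = "TTATAA")
  } else {
    if (is.null(enzymes) || is.null(names(enzymes)) ||
        any(names(enzymes) == "")) {
      stop_param("custom panels need a named character vector of sites")
    }
    enzymes <- toupper(enzymes)
    if (any(nchar(enzymes) < 4L) ||
        any(grepl("[^ACGT]", enzymes))) {
      stop_param("recognition strings must be >= 4 bp over A/C/G/T")
    }
  }
  structure(list(name = panel, enzymes = enzymes), class = "enzyme_panel")
}

#' @export
print.enzyme_panel <- function(x, ...) {
  cat(sprintf("<enzyme_panel> %s: %s\n", x$name,
              paste(sprintf("%s=%s", names(x$enzymes), x$enzymes),
                    collapse = ", ")))
  invisible(x)
}

is_palindromic <- function(site) {
  site == as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
}

#' Scan a sequence for recognition sites
#'
#' Reports every exact occurrence of every recognition string in the panel,
#' overlapping matches included. `N` never matches. For non-palindromic
#' recognition strings the reverse complement is scanned as well and
#' reported at the leftmost base of the match on the given sequence.
#'
#' @param sequence A single character string over A/C/G/T/N.
#' @param panel An [enzyme_panel()].
#' @return A data.frame with columns `pos` (1-based start of the match) and
#'   `enzyme`, sorted by position then enzyme name.
#' @examples
#' scan_sites("GTTAAC", enzyme_panel("one_cut"))
#' @export
scan_sites <- function(sequence, panel) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(panel, "enzyme_panel"))
  subj <- Biostrings::DNAString(sequence)
  out <- lapply(names(panel$enzymes), function(nm) {
    site <- panel$enzymes[[nm]]
    pats <- site
    if (!is_palindromic(site)) {
      pats <- unique(c(site, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(site)))))
    }
    pos <- unlist(lapply(pats, function(p) {
      BiocGenerics::start(Biostrings::matchPattern(p, subj, fixed = TRUE))
    }))
    if (length(pos) == 0L) return(NULL)
    data.frame(pos = as.integer(sort(unique(pos))), enzyme = nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), enzyme = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$pos, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Deterministic full-strand conversion used for site maps: every C becomes
# T except CpG C's protected under the methylation rule.
convert_strand <- function(bytes, protected_c_local) {
  cpos <- which(bytes == .RAW_C)
  bytes[cpos] <- .RAW_T
  if (length(protected_c_local)) {
    bytes[protected_c_local] <- .RAW_C
  }
  bytes
}

#' Map recognition sites in converted genome space
#'
#' Deterministically converts each strand of the genome (C to T, except
#' CpG cytosines deemed methylated under `methylation_rule`) and scans the
#' converted sequence for panel sites. Crick-strand sites are reported in
#' the Watson coordinate frame at the leftmost Watson base under the site.
#' Under `"all_unmethylated"` every CpG converts, giving the maximal site
#' set; under `"threshold"` CpGs with profile beta at or above
#' `beta_threshold` are protected, so methylation can block site creation.
#'
#' @param genome A genome as returned by [rrmp_genome()].
#' @param profile A [methylation_profile()] (may be `NULL` under
#'   `"all_unmethylated"`).
#' @param panel An [enzyme_panel()].
#' @param methylation_rule `"all_unmethylated"` or `"threshold"`.
#' @param beta_threshold Protection threshold for the `"threshold"` rule
#'   (default 0.5).
#' @return A data.frame of class `site_map` with columns `chrom`, `pos`
#'   (1-based leftmost Watson base), `strand` (`+` Watson / `-` Crick) and
#'   `enzyme`.
#' @export
converted_site_map <- function(genome, profile = NULL, panel,
                               methylation_rule = c("all_unmethylated",
                                                    "threshold"),
                               beta_threshold = 0.5) {
  methylation_rule <- match.arg(methylation_rule)
  stopifnot(inherits(panel, "enzyme_panel"))
  res <- list()
  for (cn in names(genome)) {
    seqc <- as.character(genome[[which(names(genome) == cn)]])
    b <- charToRaw(seqc)
    len <- length(b)
    prot_units <- integer(0)
    if (methylation_rule == "threshold" && !is.null(profile)) {
      p <- profile[profile$chrom == cn, , drop = FALSE]
      prot_units <- p$pos[p$beta >= beta_threshold]
    }
    # Watson: protected C is the unit coordinate itself
    wb <- convert_strand(b, prot_units)
    ws <- scan_sites(rawToChar(wb), panel)
    if (nrow(ws)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn, pos = ws$pos, strand = "+", enzyme = ws$enzyme,
        stringsAsFactors = FALSE)
    }
    # Crick: reverse complement, then protect the unit's G position
    # (genome coordinate u + 1 -> crick-local len - u)
    kb <- rev(.COMP[as.integer(b) + 1L])
    prot_local <- len - prot_units
    prot_local <- prot_local[prot_local >= 1L & prot_local <= len]
    kb <- convert_strand(kb, prot_local)
    ks <- scan_sites(rawToChar(kb), panel)
    if (nrow(ks)) {
      sl <- nchar(panel$enzymes[ks$enzyme])
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn, pos = len - ks$pos - sl + 2L, strand = "-",
        enzyme = ks$enzyme, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), pos = integer(0),
               strand = character(0), enzyme = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_map", "data.frame")
  out
}

#' Export a site map as BED6
#'
#' Enzyme name goes in the BED name column and the strand column carries
#' the site strand; coordinates convert to the BED 0-based half-open
#' dialect on export.
#'
#' @param site_map A `site_map` from [converted_site_map()].
#' @param panel The [enzyme_panel()] used (for site lengths).
#' @param path Output path.
#' @export
site_map_to_bed <- function(site_map, panel, path) {
  gr <- GenomicRanges::GRanges(
    site_map$chrom,
    IRanges::IRanges(site_map$pos,
                     width = nchar(panel$enzymes[site_map$enzyme])),
    strand = site_map$strand
  )
  S4Vectors::mcols(gr)$name <- site_map$enzyme
  write_bed(gr, path)
}

# TRUE for each sequence that contains at least one complete panel site.
has_site <- function(sequences, panel) {
  dss <- Biostrings::DNAStringSet(sequences)
  cut <- rep(FALSE, length(sequences))
  for (nm in names(panel$enzymes)) {
    site <- panel$enzymes[[nm]]
    pats <- site
    if (!is_palindromic(site)) {
      pats <- unique(c(site, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(site)))))
    }
    for (p in pats) {
      cut <- cut | Biostrings::vcountPattern(p, dss, fixed = TRUE) > 0L
    }
  }
  cut
}

#' Digest a converted library in silico
#'
#' A molecule is digested if and only if its post-conversion sequence
#' contains at least one complete recognition site of the panel (idealized
#' complete digestion: the repeated digestion-amplification of the wet
#' protocol is modeled as certainty). Retained molecules pass through
#' unmodified, so lengths and sequences are preserved exactly.
#'
#' @param molecules A `converted_molecules` object.
#' @param panel An [enzyme_panel()].
#' @return A list with `retained` and `digested` `converted_molecules`.
#' @export
digest_library <- function(molecules, panel) {
  stopifnot(inherits(molecules, "converted_molecules"),
            inherits(panel, "enzyme_panel"))
  cut <- has_site(molecules$sequence, panel)
  list(retained = molecules[!cut], digested = molecules[cut])
}

# mean G+C fraction of a set of sequences (mean over reads)
mean_gc <- function(sequences) {
  if (length(sequences) == 0L) return(NA_real_)
  dss <- Biostrings::DNAStringSet(sequences)
  mean(Biostrings::letterFrequency(dss, "GC", as.prob = TRUE)[, 1])
}

validate_fastq_lines <- function(lines) {
  if (length(lines) %% 4L != 0L) {
    stop_param("malformed FASTQ record %d: truncated file",
               length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    h <- lines[4L * i - 3L]; sq <- lines[4L * i - 2L]
    pl <- lines[4L * i - 1L]; ql <- lines[4L * i]
    if (!startsWith(h, "@") || !startsWith(pl, "+") ||
        nchar(sq) != nchar(ql) || nchar(sq) == 0L ||
        grepl("[^ACGTNacgtn]", sq)) {
      stop_param("malformed FASTQ record %d", i)
    }
  }
  n
}

#' Deplete AT-rich reads from converted FASTQ data
#'
#' Applies the digestion predicate of [digest_library()] to each read of an
#' already-converted FASTQ stream (external WGBS/EM-seq data or simulated
#' reads), as given and without strand inference: reads containing a
#' complete panel site are discarded. The summary quantifies the enrichment
#' this produces in G+C content.
#'
#' @param input Path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param panel An [enzyme_panel()].
#' @param output Optional path for the retained reads as FASTQ (records are
#'   passed through verbatim).
#' @return A list with `retained` (character vector of retained sequences)
#'   and `summary` (input count, retained count, mean G+C fraction of the
#'   input and of the retained reads).
#' @export
deplete_reads_insilico <- function(input, panel, output = NULL) {
  stopifnot(inherits(panel, "enzyme_panel"))
  from_file <- length(input) == 1L && file.exists(input) &&
    !grepl("^[ACGTNacgtn]+$", input)
  if (from_file) {
    lines <- readLines(input)
    validate_fastq_lines(lines)
    seqs <- toupper(lines[seq_along(lines) %% 4L == 2L])
  } else {
    seqs <- toupper(as.character(input))
    lines <- NULL
  }
  if (length(seqs) == 0L) {
    if (!is.null(output)) writeLines(character(0), output)
    return(list(retained = character(0),
                summary = list(input_count = 0L, retained_count = 0L,
                               cg_fraction_input = NA_real_,
                               cg_fraction_retained = NA_real_)))
  }
  cut <- has_site(seqs, panel)
  retained <- seqs[!cut]
  if (!is.null(output)) {
    if (!is.null(lines)) {
      keep_rec <- rep(!cut, each = 4L)
      writeLines(lines[keep_rec], output)
    } else {
      ids <- sprintf("@read_%07d", which(!cut))
      writeLines(as.vector(rbind(ids, retained, "+",
                                 vapply(nchar(retained),
                                        function(w) strrep("I", w),
                                        character(1)))), output)
    }
  }
  list(
    retained = retained,
    summary = list(
      input_count = length(seqs),
      retained_count = length(retained),
      cg_fraction_input = mean_gc(seqs),
      cg_fraction_retained = mean_gc(retained)
    )
  )
}

#' Coverage depth as a function of inter-site distance
#'
#' Every genomic position lying between two consecutive same-strand
#' recognition sites is annotated with the distance `d` separating those
#' sites (end of the upstream site to start of the downstream site), and
#' the mean depth of the retained library is computed per `d` bin. Long
#' inter-site intervals can host uncut molecules, so depth rises with `d`;
#' intervals shorter than the fragment length cannot retain any molecule
#' that covers them.
#'
#' @param site_map A `site_map` from [converted_site_map()].
#' @param retained A `GRanges` of retained fragments (or a
#'   `converted_molecules` object, whose fragments are used).
#' @param panel The [enzyme_panel()] used (for site lengths).
#' @param strand Which site strand to profile (`"+"` or `"-"`).
#' @param max_d Largest inter-site distance considered, bp.
#' @param bin Bin width for `d`, bp.
#' @return A data.frame with columns `d_lo`, `d_hi`, `n_positions`,
#'   `mean_depth`; zero rows when the strand has fewer than two sites.
#' @export
intersite_coverage_profile <- function(site_map, retained, panel,
                                       strand = "+", max_d = 1000L,
                                       bin = 50L) {
  if (inherits(retained, "converted_molecules")) {
    retained <- retained$fragments
  }
  stopifnot(inherits(panel, "enzyme_panel"))
  empty <- data.frame(d_lo = integer(0), d_hi = integer(0),
                      n_positions = integer(0), mean_depth = numeric(0))
  sm <- site_map[site_map$strand == strand, , drop = FALSE]
  if (nrow(sm) < 2L) return(empty)

  cov <- GenomicRanges::coverage(retained)
  rows <- list()
  for (cn in unique(sm$chrom)) {
    s <- sm[sm$chrom == cn, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (nrow(s) < 2L || !cn %in% names(cov)) next
    covc <- as.integer(cov[[cn]])
    upstream_end <- s$pos + nchar(panel$enzymes[s$enzyme]) - 1L
    for (i in seq_len(nrow(s) - 1L)) {
      gap_s <- upstream_end[i] + 1L
      gap_e <- s$pos[i + 1L] - 1L
      d <- gap_e - gap_s + 1L
      if (d < 1L || d > max_d) next
      rows[[length(rows) + 1L]] <- c(d, sum(covc[gap_s:gap_e]), d)
    }
  }
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  brk <- floor((m[, 1] - 1L) / bin)
  agg_sum <- tapply(m[, 2], brk, sum)
  agg_n <- tapply(m[, 3], brk, sum)
  b <- as.integer(names(agg_sum))
  out <- data.frame(d_lo = b * bin + 1L, d_hi = (b + 1L) * bin,
                    n_positions = as.integer(agg_n),
                    mean_depth = as.numeric(agg_sum) / as.numeric(agg_n))
  out[order(out$d_lo), , drop = FALSE]
}
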