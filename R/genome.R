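#' Build a validated reference genome
#'
#' A reference genome is a named [Biostrings::DNAStringSet] restricted to the
#' uppercase alphabet A/C/G/T/N. Coordinates throughout the package are
#' 1-based and closed (the native GenomicRanges convention); BED input and
#' output are converted at the file boundary.
#'
#' @param sequences A named character vector or `DNAStringSet`. Lowercase
#'   letters are converted to uppercase on load.
#' @return A `DNAStringSet` with unique names.
#' @examples
#' g <- rrmp_genome(c(chr1 = "ACGTACGT"))
#' @export
rrmp_genome <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  } else if (methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  } else {
    stop_param("'sequences' must be a named character vector or DNAStringSet")
  }
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_param("chromosome names must be present and unique")
  }
  if (any(Biostrings::width(sequences) < 1L)) {
    stop_param("every chromosome must have length >= 1")
  }
  bad <- Biostrings::letterFrequency(
    sequences, letters = "ACGTN", OR = 0
  )
  if (any(rowSums(bad) != Biostrings::width(sequences))) {
    stop_param("sequences may contain only A, C, G, T or N")
  }
  sequences
}

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that apply the package's genome
#' validation (uppercase, A/C/G/T/N only, unique names). Multi-record files
#' with wrapped lines are supported; record descriptions are truncated at the
#' first whitespace.
#'
#' @param path File path.
#' @param genome A genome as returned by [rrmp_genome()].
#' @return `read_fasta()` returns a validated `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  rrmp_genome(x)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(rrmp_genome(genome), path, width = 70L)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED3/BED6 input and output through [rtracklayer::import.bed()] and
#' [rtracklayer::export.bed()]. On import, the 0-based half-open BED
#' coordinates become 1-based closed `GRanges`; the reverse conversion
#' happens on export, so files round-trip exactly.
#'
#' @param path File path.
#' @param gr A `GRanges` (name/score/strand columns exported when present).
#' @return `read_bed()` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Locate CpG dinucleotides
#'
#' A CpG unit is identified by the coordinate of its Watson-strand C;
#' evidence on the Crick strand (the G position, one base right) is folded
#' onto that coordinate everywhere in the package.
#'
#' @param genome A genome as returned by [rrmp_genome()].
#' @return A data.frame with columns `chrom` and `pos` (1-based Watson C
#'   coordinates), sorted by chromosome then position.
#' @export
cpg_sites <- function(genome) {
  res <- lapply(seq_along(genome), function(i) {
    hits <- Biostrings::matchPattern("CG", genome[[i]], fixed = TRUE)
    data.frame(
      chrom = names(genome)[i],
      pos = BiocGenerics::start(hits),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Construct a methylation profile
#'
#' A methylation profile assigns a ground-truth beta value (fraction
#' methylated, in `[0, 1]`) to CpG units keyed by the Watson C coordinate.
#' Construction verifies that every keyed position is a C followed by a G on
#' the Watson strand of `genome`.
#'
#' @param genome A genome as returned by [rrmp_genome()].
#' @param chrom,pos,beta Parallel vectors: chromosome, 1-based Watson C
#'   coordinate, and beta value per CpG unit.
#' @return A data.frame of class `methylation_profile` with columns
#'   `chrom`, `pos`, `beta`.
#' @export
methylation_profile <- function(genome, chrom, pos, beta) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(beta))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop_param("beta values must lie in [0, 1]")
  }
  for (cn in unique(chrom)) {
    p <- pos[chrom == cn]
    if (!cn %in% names(genome)) stop_param("unknown chromosome '%s'", cn)
    len <- Biostrings::width(genome[names(genome) == cn])
    if (any(p < 1L | p + 1L > len)) {
      stop_param("CpG position out of bounds on '%s'", cn)
    }
    dinuc <- as.character(Biostrings::extractAt(
      genome[[which(names(genome) == cn)]],
      IRanges::IRanges(start = p, width = 2L)
    ))
    if (any(dinuc != "CG")) {
      stop_param("position without CpG dinucleotide on '%s'", cn)
    }
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos), beta = beta,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("methylation_profile", "data.frame")
  out
}

#' Simulate a genome with CpG-island architecture
#'
#' Generates a single-chromosome genome that alternates AT-rich spacers with
#' CpG-rich islands -- the architecture that restriction depletion of AT-rich
#' fragments exploits. Islands are drawn by per-base sampling with elevated
#' G+C probability plus forced CpG dinucleotide seeding at a fixed rate;
#' spacers use the background G+C. One TSS is placed at each island midpoint
#' (alternating strand), promoters are derived as 1 kb upstream / 500 bp
#' downstream of the TSS, and shores/shelves flank the islands. Ground-truth
#' betas are low inside islands and high outside, the canonical somatic
#' pattern.
#'
#' @param n_islands Number of islands.
#' @param island_len,spacer_len Length (bp) or `c(min, max)` range.
#' @param island_gc,background_gc G+C fraction inside islands / elsewhere;
#'   must satisfy `0 < background_gc < island_gc <= 1`.
#' @param cpg_seed_rate Forced CpG dinucleotides per island bp (default
#'   0.08, i.e. one seeded CpG every ~12 bp).
#' @param beta_island,beta_background Uniform ranges for ground-truth betas
#'   of CpGs inside/outside islands.
#' @param chrom Chromosome name.
#' @param seed Integer seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @return A list with elements `genome` (`DNAStringSet`), `annotation`
#'   (named list of `GRanges`: `cpg_island`, `cpg_shore`, `cpg_shelf`,
#'   `tss`, `promoter`) and `profile` (a [methylation_profile()]).
#' @export
simulate_genome <- function(n_islands,
                            island_len = c(800L, 1500L),
                            spacer_len = c(4000L, 8000L),
                            island_gc = 0.65,
                            background_gc = 0.25,
                            cpg_seed_rate = 0.08,
                            beta_island = c(0, 0.2),
                            beta_background = c(0.7, 1),
                            chrom = "chrSim",
                            seed = 1L) {
  n_islands <- check_count(n_islands, "n_islands")
  island_len <- check_range(island_len, "island_len")
  spacer_len <- check_range(spacer_len, "spacer_len")
  check_fraction(island_gc, "island_gc")
  check_fraction(background_gc, "background_gc")
  check_fraction(cpg_seed_rate, "cpg_seed_rate")
  if (background_gc <= 0 || island_gc <= background_gc) {
    stop_param("need 0 < background_gc < island_gc <= 1")
  }

  withr::with_seed(as.integer(seed), {
    ilen <- sample_range(n_islands, island_len)
    slen <- sample_range(n_islands + 1L, spacer_len)

    base_block <- function(len, gc) {
      sample(c("A", "C", "G", "T"), len, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }

    pieces <- character(2L * n_islands + 1L)
    island_start <- integer(n_islands)
    offset <- 0L
    for (i in seq_len(n_islands)) {
      pieces[2L * i - 1L] <- paste(base_block(slen[i], background_gc),
                                   collapse = "")
      offset <- offset + slen[i]
      island_start[i] <- offset + 1L
      blk <- base_block(ilen[i], island_gc)
      if (cpg_seed_rate > 0) {
        step <- max(2L, round(1 / cpg_seed_rate))
        at <- seq.int(1L, ilen[i] - 1L, by = step)
        blk[at] <- "C"
        blk[at + 1L] <- "G"
      }
      pieces[2L * i] <- paste(blk, collapse = "")
      offset <- offset + ilen[i]
    }
    pieces[2L * n_islands + 1L] <-
      paste(base_block(slen[n_islands + 1L], background_gc), collapse = "")

    genome <- rrmp_genome(stats::setNames(paste(pieces, collapse = ""), chrom))

    islands <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = island_start, width = ilen)
    )
    tss_pos <- island_start + ilen %/% 2L
    tss <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = tss_pos, width = 1L),
      strand = rep_len(c("+", "-"), n_islands)
    )
    promoter <- promoters_from_tss(tss, chrom_lengths = Biostrings::width(genome))
    flanks <- derive_shores_shelves(islands,
                                    chrom_lengths = Biostrings::width(genome))

    sites <- cpg_sites(genome)
    in_island <- IRanges::overlapsAny(
      GenomicRanges::GRanges(sites$chrom,
                             IRanges::IRanges(sites$pos, width = 2L)),
      islands
    )
    beta <- numeric(nrow(sites))
    beta[in_island] <- runif(sum(in_island), beta_island[1], beta_island[2])
    beta[!in_island] <- runif(sum(!in_island), beta_background[1],
                              beta_background[2])
    profile <- methylation_profile(genome, sites$chrom, sites$pos, beta)

    list(
      genome = genome,
      annotation = list(cpg_island = islands,
                        cpg_shore = flanks$cpg_shore,
                        cpg_shelf = flanks$cpg_shelf,
                        tss = tss,
                        promoter = promoter),
      profile = profile
    )
  })
}

#' Derive promoter intervals from TSS positions
#'
#' Promoters are defined as 1 kb upstream and 500 bp downstream of each
#' transcription start site, oriented by the TSS strand and clipped to
#' chromosome bounds.
#'
#' @param tss A `GRanges` of width-1 TSS positions with strand `+` or `-`.
#' @param upstream,downstream Extent in bp.
#' @param chrom_lengths Optional named (or parallel) integer vector of
#'   chromosome lengths used for clipping; unclipped when omitted and no
#'   `seqlengths` are set on `tss`.
#' @return A `GRanges` of promoter intervals, same order as `tss`.
#' @export
promoters_from_tss <- function(tss, upstream = 1000L, downstream = 500L,
                               chrom_lengths = NULL) {
  if (!methods::is(tss, "GRanges")) stop_param("'tss' must be a GRanges")
  if (any(BiocGenerics::width(tss) != 1L)) {
    stop_param("each TSS must be a single position")
  }
  if (any(as.character(BiocGenerics::strand(tss)) == "*")) {
    stop_param("every TSS needs a '+' or '-' strand")
  }
  # plus strand: [p - upstream, p + downstream) in 0-based terms;
  # minus strand: the coordinate mirror [p - downstream, p + upstream)
  p <- BiocGenerics::start(tss)
  plus <- as.character(BiocGenerics::strand(tss)) == "+"
  new_start <- ifelse(plus, p - upstream, p - downstream)
  new_end <- ifelse(plus, p + downstream - 1L, p + upstream - 1L)
  pr <- tss
  new_start <- pmax(new_start, 1L)
  if (!is.null(chrom_lengths)) {
    lens <- if (!is.null(names(chrom_lengths))) {
      as.integer(chrom_lengths[as.character(GenomicRanges::seqnames(pr))])
    } else {
      rep_len(as.integer(chrom_lengths), length(pr))
    }
    new_end <- pmin(new_end, lens)
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(pr),
                         IRanges::IRanges(new_start, new_end),
                         strand = BiocGenerics::strand(pr))
}

#' Derive CpG shores and shelves from islands
#'
#' Shores are the up-to-2-kb flanks on each side of an island; shelves are
#' the next 2 kb beyond the shores. Where two islands are close, the
#' intervening gap is split at its midpoint so that no base is assigned
#' twice; everything is clipped to chromosome bounds.
#'
#' @param islands A sorted, non-overlapping `GRanges` of CpG islands.
#' @param shore_width,shelf_width Flank widths in bp (defaults 2000).
#' @param chrom_lengths Chromosome length(s), named by chromosome or a
#'   single value for a single-chromosome genome.
#' @return A list with `GRanges` elements `cpg_shore` and `cpg_shelf`.
#' @export
derive_shores_shelves <- function(islands, shore_width = 2000L,
                                  shelf_width = 2000L,
                                  chrom_lengths = NULL) {
  if (!methods::is(islands, "GRanges")) stop_param("'islands' must be a GRanges")
  if (length(islands) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(cpg_shore = empty, cpg_shelf = empty))
  }
  od <- order(GenomicRanges::seqnames(islands), BiocGenerics::start(islands))
  islands <- islands[od]
  if (length(GenomicRanges::findOverlaps(islands, drop.self = TRUE)) > 0L) {
    stop_param("islands must be non-overlapping")
  }

  shores <- list(); shelves <- list()
  for (cn in unique(as.character(GenomicRanges::seqnames(islands)))) {
    isl <- islands[as.character(GenomicRanges::seqnames(islands)) == cn]
    s <- BiocGenerics::start(isl); e <- BiocGenerics::end(isl)
    n <- length(isl)
    len <- NA_integer_
    if (!is.null(chrom_lengths)) {
      len <- if (!is.null(names(chrom_lengths)))
        as.integer(chrom_lengths[[cn]]) else as.integer(chrom_lengths[1])
    }
    # flank limits: midpoint of the gap to the neighbouring island,
    # chromosome bounds at the ends
    left_lim <- c(1L, floor((e[-n] + s[-1]) / 2) + 1L)
    right_lim <- c(floor((e[-n] + s[-1]) / 2),
                   if (is.na(len)) e[n] + shore_width + shelf_width else len)
    for (i in seq_len(n)) {
      # left flank of island i: [shore | shelf] going outward from s[i]-1
      lo <- left_lim[i]
      sh_s <- max(lo, s[i] - shore_width); sh_e <- s[i] - 1L
      if (sh_s <= sh_e) shores[[length(shores) + 1L]] <-
        data.frame(chrom = cn, start = sh_s, end = sh_e)
      sf_s <- max(lo, s[i] - shore_width - shelf_width)
      sf_e <- s[i] - shore_width - 1L
      if (sf_s <= sf_e) shelves[[length(shelves) + 1L]] <-
        data.frame(chrom = cn, start = sf_s, end = sf_e)
      # right flank
      hi <- right_lim[i]
      sh_s <- e[i] + 1L; sh_e <- min(hi, e[i] + shore_width)
      if (sh_s <= sh_e) shores[[length(shores) + 1L]] <-
        data.frame(chrom = cn, start = sh_s, end = sh_e)
      sf_s <- e[i] + shore_width + 1L
      sf_e <- min(hi, e[i] + shore_width + shelf_width)
      if (sf_s <= sf_e) shelves[[length(shelves) + 1L]] <-
        data.frame(chrom = cn, start = sf_s, end = sf_e)
    }
  }
  to_gr <- function(lst) {
    if (length(lst) == 0L) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    BiocGenerics::sort(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end)))
  }
  list(cpg_shore = to_gr(shores), cpg_shelf = to_gr(shelves))
}
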