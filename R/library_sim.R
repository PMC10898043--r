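#' Simulate library fragments
#'
#' Draws library inserts from a genome. `cfdna` mode emulates plasma
#' cell-free DNA: a unimodal length distribution peaked at `mean_len`
#' (default 170 bp, the nucleosome-protected mode). `gdna` mode emulates
#' mechanically sheared genomic DNA with a broader distribution (default
#' mean 250 bp, sd 80). Start positions are uniform over the genome
#' (chromosomes weighted by length) and each molecule's origin strand is
#' Bernoulli(0.5): `+` denotes a Watson-strand original molecule, `-` Crick.
#'
#' @param genome A genome as returned by [rrmp_genome()].
#' @param mode `"cfdna"` or `"gdna"`.
#' @param mean_len Target modal length (cfdna) or mean length (gdna), bp.
#' @param n_fragments Number of molecules (>= 1).
#' @param sd_len Length spread; defaults 10 bp (cfdna, the sharp
#'   mono-nucleosomal peak) / 80 bp (gdna).
#' @param min_len Shortest admissible insert (default 30 bp).
#' @param seed Integer seed; fragment lists are reproducible per seed.
#' @return A `GRanges` with strand set to the origin strand and a
#'   `molecule_id` metadata column.
#' @export
fragment_genome <- function(genome, mode = c("cfdna", "gdna"),
                            mean_len = NULL, n_fragments = 1000L,
                            sd_len = NULL, min_len = 30L, seed = 1L) {
  mode <- match.arg(mode)
  n_fragments <- check_count(n_fragments, "n_fragments")
  if (is.null(mean_len)) mean_len <- if (mode == "cfdna") 170L else 250L
  if (is.null(sd_len)) sd_len <- if (mode == "cfdna") 10 else 80
  if (mean_len < 20) stop_param("'mean_len' must be >= 20")
  lens_chr <- Biostrings::width(genome)
  if (min_len > max(lens_chr)) {
    stop_param("no chromosome can hold a fragment of length %d", min_len)
  }

  withr::with_seed(as.integer(seed), {
    L <- pmax(min_len, round(rnorm(n_fragments, mean_len, sd_len)))
    L <- pmin(L, max(lens_chr))
    ci <- sample.int(length(genome), n_fragments, replace = TRUE,
                     prob = lens_chr)
    # resample chromosomes for fragments longer than the drawn chromosome
    bad <- L > lens_chr[ci]
    guard <- 0L
    while (any(bad)) {
      ci[bad] <- sample.int(length(genome), sum(bad), replace = TRUE,
                            prob = lens_chr)
      bad <- L > lens_chr[ci]
      guard <- guard + 1L
      if (guard > 100L) stop_param("cannot place fragments on this genome")
    }
    start <- integer(n_fragments)
    for (i in seq_along(genome)) {
      idx <- which(ci == i)
      if (length(idx)) {
        hi <- lens_chr[i] - L[idx] + 1L
        start[idx] <- pmin(floor(runif(length(idx), 1, hi + 1)), hi)
      }
    }
    strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
    gr <- GenomicRanges::GRanges(
      names(genome)[ci],
      IRanges::IRanges(start = start, width = L),
      strand = strand
    )
    S4Vectors::mcols(gr)$molecule_id <- sprintf("mol_%07d",
                                                seq_len(n_fragments))
    gr
  })
}

#' Conversion parameters
#'
#' Efficiencies of the enzymatic C-to-T conversion. `conversion_rate` is the
#' probability that an unmethylated C is converted to T; `protection_rate`
#' the probability that a methylated CpG C is protected (left as C). The
#' defaults of 1.0 model ideal chemistry; both are exposed because real
#' conversions are imperfect.
#'
#' @param conversion_rate,protection_rate Probabilities in `[0, 1]`.
#' @param seed Optional integer seed applied by [convert_molecules()].
#' @return A list of class `conversion_params`.
#' @export
conversion_params <- function(conversion_rate = 1.0, protection_rate = 1.0,
                              seed = NULL) {
  check_fraction(conversion_rate, "conversion_rate")
  check_fraction(protection_rate, "protection_rate")
  structure(list(conversion_rate = conversion_rate,
                 protection_rate = protection_rate, seed = seed),
            class = "conversion_params")
}

# raw byte codes
.RAW_C <- charToRaw("C"); .RAW_T <- charToRaw("T")
.COMP <- {
  m <- raw(256)
  m[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  m
}

#' Convert library molecules
#'
#' Applies strand-resolved C-to-T conversion to each fragment. The molecule
#' sequence is the insert in origin-strand orientation (for Crick-origin
#' molecules the reverse complement is taken first, then that strand's own
#' C's are converted). Each CpG unit overlapped by the insert receives one
#' per-molecule methylation state, drawn Bernoulli(beta) from the profile
#' and shared between the two strand positions of the unit. A methylated
#' CpG C is protected with probability `protection_rate`; any other C
#' converts to T with probability `conversion_rate`. Cytosines in non-CpG
#' (CH) context that remain unconverted are counted per molecule, the
#' signal used by the incomplete-conversion read filter.
#'
#' @param fragments A `GRanges` from [fragment_genome()].
#' @param genome The genome the fragments were drawn from.
#' @param profile A [methylation_profile()]; CpG units absent from the
#'   profile are treated as unmethylated.
#' @param params A [conversion_params()].
#' @return An object of class `converted_molecules`: the fragments, the
#'   post-conversion sequences, per-molecule CpG unit coordinates and drawn
#'   states, and the unconverted CH count.
#' @export
convert_molecules <- function(fragments, genome, profile = NULL,
                              params = conversion_params()) {
  stopifnot(methods::is(fragments, "GRanges"))
  n <- length(fragments)
  chroms <- as.character(GenomicRanges::seqnames(fragments))
  starts <- BiocGenerics::start(fragments)
  ends <- BiocGenerics::end(fragments)
  strands <- as.character(BiocGenerics::strand(fragments))
  if (any(!chroms %in% names(genome))) {
    stop_param("fragment chromosome missing from genome")
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(starts < 1L | ends > lens[chroms])) {
    stop_param("fragment outside chromosome bounds")
  }

  # per-chromosome byte caches and CpG lookups
  craw <- lapply(names(genome), function(cn)
    charToRaw(as.character(genome[[which(names(genome) == cn)]])))
  names(craw) <- names(genome)
  is_cpg <- lapply(names(genome), function(cn) {
    b <- craw[[cn]]
    v <- logical(length(b))
    if (length(b) >= 2L) {
      v[-length(b)] <- b[-length(b)] == .RAW_C & b[-1L] == charToRaw("G")
    }
    v
  })
  names(is_cpg) <- names(genome)
  beta_lookup <- lapply(names(genome), function(cn) {
    v <- numeric(length(craw[[cn]]))
    if (!is.null(profile)) {
      p <- profile[profile$chrom == cn, , drop = FALSE]
      v[p$pos] <- p$beta
    }
    v
  })
  names(beta_lookup) <- names(genome)

  run <- function() {
    seqs <- character(n)
    unit_list <- vector("list", n)
    meth_list <- vector("list", n)
    ch_count <- integer(n)
    conv <- params$conversion_rate
    prot <- params$protection_rate
    for (i in seq_len(n)) {
      cn <- chroms[i]; s <- starts[i]; e <- ends[i]
      b <- craw[[cn]][s:e]
      crick <- strands[i] == "-"
      if (crick) b <- rev(.COMP[as.integer(b) + 1L])
      w <- length(b)

      # CpG units overlapped by the insert (unit key = Watson C coordinate)
      cpgv <- is_cpg[[cn]]
      lo <- max(1L, s - 1L)
      cand <- lo:e
      units <- cand[cpgv[cand]]
      meth <- if (length(units))
        runif(length(units)) < beta_lookup[[cn]][units] else logical(0)

      cpos <- which(b == .RAW_C)
      if (length(cpos)) {
        # genome coordinate of each local C on the origin strand
        g <- if (crick) e - cpos + 1L else s + cpos - 1L
        # CpG context: Watson C at g (watson origin) / unit C at g-1 (crick)
        ucoord <- if (crick) g - 1L else g
        is_cpg_c <- ucoord >= 1L & cpgv[pmax(ucoord, 1L)]
        state <- rep(FALSE, length(cpos))
        hit <- match(ucoord[is_cpg_c], units)
        state[is_cpg_c] <- !is.na(hit) & meth[ifelse(is.na(hit), 1L, hit)]
        keep <- logical(length(cpos))
        # methylated CpG C: protected with prob prot
        mi <- which(state)
        keep[mi] <- if (prot >= 1) TRUE else runif(length(mi)) < prot
        # all other C (unmethylated CpG or CH): escapes conversion w.p. 1-conv
        oi <- which(!state)
        keep[oi] <- if (conv >= 1) FALSE else runif(length(oi)) >= conv
        b[cpos[!keep]] <- .RAW_T
        ch_count[i] <- sum(keep & !is_cpg_c)
      }
      seqs[i] <- rawToChar(b)
      unit_list[[i]] <- units
      meth_list[[i]] <- meth
    }
    list(seqs = seqs, units = unit_list, meth = meth_list, ch = ch_count)
  }

  res <- if (!is.null(params$seed)) {
    withr::with_seed(as.integer(params$seed), run())
  } else run()

  structure(
    list(fragments = fragments, sequence = res$seqs,
         cpg_units = res$units, cpg_meth = res$meth,
         unconverted_ch = res$ch),
    class = "converted_molecules"
  )
}

#' @export
length.converted_molecules <- function(x) length(x$fragments)

#' Subset converted molecules
#'
#' @param x A `converted_molecules` object.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.converted_molecules` <- function(x, i, ...) {
  structure(
    list(fragments = x$fragments[i], sequence = x$sequence[i],
         cpg_units = x$cpg_units[i], cpg_meth = x$cpg_meth[i],
         unconverted_ch = x$unconverted_ch[i]),
    class = "converted_molecules"
  )
}

#' @export
print.converted_molecules <- function(x, ...) {
  cat(sprintf("<converted_molecules> %d molecules, %d with unconverted CH\n",
              length(x), sum(x$unconverted_ch > 0L)))
  invisible(x)
}

#' Remove incompletely converted molecules
#'
#' Molecules whose retained non-CpG cytosine count exceeds `max_ch` are
#' treated as conversion failures and removed; a molecule with exactly
#' `max_ch` unconverted CH cytosines is retained. The default of 3 is the
#' standard "more than 3 CHs" bisulfite/EM-seq read filter.
#'
#' @param molecules A `converted_molecules` object.
#' @param max_ch Maximum tolerated unconverted CH cytosines (default 3).
#' @return A list with `retained` and `removed` `converted_molecules`.
#' @export
filter_non_conversion <- function(molecules, max_ch = 3L) {
  stopifnot(inherits(molecules, "converted_molecules"))
  keep <- molecules$unconverted_ch <= max_ch
  list(retained = molecules[keep], removed = molecules[!keep])
}

#' Export converted molecules as FASTQ
#'
#' Writes one record per molecule (molecule id as read name, constant
#' quality "I"). Files written here are read back bit-exactly by the
#' package's FASTQ-consuming functions.
#'
#' @param molecules A `converted_molecules` object.
#' @param path Output path.
#' @export
write_fastq <- function(molecules, path) {
  stopifnot(inherits(molecules, "converted_molecules"))
  ids <- S4Vectors::mcols(molecules$fragments)$molecule_id
  if (is.null(ids)) ids <- sprintf("mol_%07d", seq_along(molecules$sequence))
  qual <- vapply(nchar(molecules$sequence),
                 function(w) strrep("I", w), character(1))
  writeLines(
    as.vector(rbind(paste0("@", ids), molecules$sequence, "+", qual)),
    path
  )
  invisible(path)
}
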