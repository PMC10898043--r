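# Shared fixtures, all built in code at test time.

# Small island/AT-background genome used across modules.
std_sim <- function(seed = 1L, n_islands = 10L) {
  simulate_genome(n_islands = n_islands, seed = seed)
}

# Random raw sequence over ACGT (optionally with N).
random_seq <- function(len, seed = NULL, with_n = FALSE) {
  draw <- function() {
    alph <- c("A", "C", "G", "T")
    prob <- rep(0.25, 4)
    if (with_n) {
      alph <- c(alph, "N")
      prob <- c(rep(0.24, 4), 0.04)
    }
    paste(sample(alph, len, replace = TRUE, prob = prob), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Brute-force site scanner: compares every substring of every enzyme
# length against the recognition string.
oracle_scan <- function(sequence, panel) {
  out <- list()
  n <- nchar(sequence)
  for (nm in names(panel$enzymes)) {
    site <- panel$enzymes[[nm]]
    L <- nchar(site)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    subs <- substring(sequence, starts, starts + L - 1L)
    pos <- starts[subs == site]
    if (length(pos)) {
      out[[length(out) + 1L]] <- data.frame(pos = as.integer(pos),
                                            enzyme = nm,
                                            stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), enzyme = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$pos, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Position-by-position conversion oracle for one molecule, working directly
# on the genome string. states: named logical (names = Watson C coord).
oracle_convert <- function(genome_str, s, e, strand, states) {
  n <- nchar(genome_str)
  chars <- strsplit(substr(genome_str, s, e), "")[[1]]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    chars <- rev(unname(comp[chars]))
  }
  out <- chars
  for (i in seq_along(chars)) {
    if (chars[i] != "C") next
    g <- if (strand == "-") e - i + 1L else s + i - 1L
    unit <- if (strand == "-") g - 1L else g
    is_cpg <- unit >= 1L && unit < n &&
      substr(genome_str, unit, unit + 1L) == "CG"
    meth <- is_cpg && !is.null(states[[as.character(unit)]]) &&
      isTRUE(states[[as.character(unit)]])
    if (!meth) out[i] <- "T"
  }
  paste(out, collapse = "")
}

# Definitional two-sided Fisher exact p: enumerate the hypergeometric
# support and sum the probabilities of tables no more likely than the
# observed one (standard (1 + 1e-7) tie guard).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Genome with MseI sites at controlled spacings: C/G-only segments (which
# cannot form an AT-only site even after conversion) separated by TTAA.
gap_sweep_genome <- function(d_values, reps = 8L, seed = 1L) {
  gaps <- withr::with_seed(seed, sample(rep(d_values, each = reps)))
  segs <- withr::with_seed(seed + 1L, lapply(gaps, function(d)
    paste(sample(c("C", "G"), d, replace = TRUE), collapse = "")))
  body <- paste(unlist(segs), collapse = "TTAA")
  gstr <- paste0("TTAA", body, "TTAA")
  rrmp_genome(c(chrGap = gstr))
}

# One-group resampled track: binomial counts at the given depth per CpG.
resample_track <- function(profile, depth, seed) {
  withr::with_seed(seed, {
    meth <- rbinom(nrow(profile), depth, profile$beta)
    cpg_track(profile$chrom, profile$pos, meth, depth - meth)
  })
}
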