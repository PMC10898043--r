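test_that("scan_sites finds exact, overlapping matches and skips N", {
  one <- enzyme_panel("one_cut")
  four <- enzyme_panel("four_cut")

  # GTTAAC: TTAA at 0-based 1 (1-based 2)
  s1 <- scan_sites("GTTAAC", one)
  expect_equal(s1$pos, 2L)
  expect_equal(s1$enzyme, "MseI")

  # TTAATTAA: two MseI matches, 0-based {0, 4}
  s2 <- scan_sites("TTAATTAA", one)
  expect_equal(s2$pos, c(1L, 5L))

  # AATATT under the four-cut panel: SspI at 1 plus the MluCI occurrence
  s3 <- scan_sites("AATATT", four)
  expect_identical(s3, oracle_scan("AATATT", four))

  # N never matches
  expect_equal(nrow(scan_sites("TTNAA", one)), 0L)
  expect_equal(nrow(scan_sites("NNNNNN", four)), 0L)
})

test_that("scan_sites matches the all-substring oracle on random sequences", {
  panels <- list(enzyme_panel("one_cut"), enzyme_panel("four_cut"))
  for (seed in 1:25) {
    seqstr <- random_seq(2000, seed = seed, with_n = TRUE)
    for (panel in panels) {
      expect_identical(scan_sites(seqstr, panel), oracle_scan(seqstr, panel),
                       info = sprintf("seed %d panel %s", seed, panel$name))
    }
  }
})

test_that("non-palindromic custom enzymes are scanned on both strands", {
  pan <- enzyme_panel("custom", c(FakeI = "ACGT", AsymI = "AACCG"))
  # AsymI site on the reverse complement: CGGTT in the given sequence
  s <- scan_sites("TTCGGTTAA", pan)
  expect_true(any(s$enzyme == "AsymI" & s$pos == 3L))
  # palindromic member still reported once per occurrence
  s2 <- scan_sites("AACGTA", pan)
  expect_equal(s2$pos[s2$enzyme == "FakeI"], 2L)
})

test_that("conversion creates sites and methylation blocks them", {
  # GAATCGTT with unmethylated CpG at 0-based 4: watson converts to
  # GAATTGTT, creating MluCI AATT at 0-based 1
  g <- rrmp_genome(c(chr = "GAATCGTT"))
  prof0 <- methylation_profile(g, "chr", 5L, 0.0)
  four <- enzyme_panel("four_cut")
  sm0 <- converted_site_map(g, prof0, four, "threshold")
  w0 <- sm0[sm0$strand == "+", ]
  expect_true(any(w0$pos == 2L & w0$enzyme == "MluCI"))

  # beta 1 at that CpG: watson sequence unchanged, no watson site
  prof1 <- methylation_profile(g, "chr", 5L, 1.0)
  sm1 <- converted_site_map(g, prof1, four, "threshold")
  expect_equal(nrow(sm1[sm1$strand == "+", ]), 0L)
})

test_that("all_unmethylated site sets contain threshold-rule site sets", {
  four <- enzyme_panel("four_cut")
  for (seed in 1:10) {
    gstr <- random_seq(3000, seed = 100 + seed)
    g <- rrmp_genome(c(chr = gstr))
    sites <- cpg_sites(g)
    prof <- withr::with_seed(seed, methylation_profile(
      g, "chr", sites$pos, runif(nrow(sites))))
    sm_all <- converted_site_map(g, prof, four, "all_unmethylated")
    sm_thr <- converted_site_map(g, prof, four, "threshold")
    key_all <- with(sm_all, paste(chrom, pos, strand, enzyme))
    key_thr <- with(sm_thr, paste(chrom, pos, strand, enzyme))
    expect_true(all(key_thr %in% key_all), info = paste("seed", seed))
  }
})

test_that("converting more C's never removes an AT-only site", {
  # converted-sequence site set is a superset of the raw-sequence set
  four <- enzyme_panel("four_cut")
  for (seed in 1:10) {
    gstr <- random_seq(3000, seed = 200 + seed)
    raw_sites <- oracle_scan(gstr, four)
    conv <- chartr("C", "T", gstr)
    conv_sites <- scan_sites(conv, four)
    key_raw <- with(raw_sites, paste(pos, enzyme))
    key_conv <- with(conv_sites, paste(pos, enzyme))
    expect_true(all(key_raw %in% key_conv), info = paste("seed", seed))
  }
})

test_that("digestion removes molecules with sites, preserving the rest", {
  one <- enzyme_panel("one_cut")
  four <- enzyme_panel("four_cut")
  fr <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1, 9), c(8, 16)),
                               strand = "+")
  mol <- structure(list(
    fragments = fr,
    sequence = c("GGTTAAGG", "GCGCGCGC"),
    cpg_units = list(integer(0), integer(0)),
    cpg_meth = list(logical(0), logical(0)),
    unconverted_ch = c(0L, 0L)
  ), class = "converted_molecules")

  d1 <- digest_library(mol, one)
  expect_equal(d1$digested$sequence, "GGTTAAGG")
  expect_equal(d1$retained$sequence, "GCGCGCGC")
  d4 <- digest_library(mol, four)
  expect_equal(d4$retained$sequence, "GCGCGCGC")
})

test_that("four-cut retention is a subset of one-cut retention", {
  sim <- std_sim(seed = 9)
  fr <- fragment_genome(sim$genome, "cfdna", n_fragments = 2000, seed = 14)
  mol <- convert_molecules(fr, sim$genome, sim$profile,
                           conversion_params(seed = 15))
  r1 <- digest_library(mol, enzyme_panel("one_cut"))$retained
  r4 <- digest_library(mol, enzyme_panel("four_cut"))$retained
  id1 <- S4Vectors::mcols(r1$fragments)$molecule_id
  id4 <- S4Vectors::mcols(r4$fragments)$molecule_id
  expect_true(all(id4 %in% id1))
  # retained molecules are byte-identical to their input versions
  idx <- match(id4, S4Vectors::mcols(mol$fragments)$molecule_id)
  expect_identical(r4$sequence, mol$sequence[idx])
})

test_that("FASTQ depletion enriches G+C and reports counts", {
  one <- enzyme_panel("one_cut")
  res <- deplete_reads_insilico(c("TTAAT", "GCGCG"), one)
  expect_equal(res$retained, "GCGCG")
  expect_equal(res$summary$input_count, 2L)
  expect_equal(res$summary$retained_count, 1L)
  expect_equal(res$summary$cg_fraction_input, 0.5)
  expect_equal(res$summary$cg_fraction_retained, 1.0)

  # empty input
  res0 <- deplete_reads_insilico(character(0), one)
  expect_equal(res0$summary$input_count, 0L)
  expect_true(is.na(res0$summary$cg_fraction_input))

  # malformed FASTQ names the failing record
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-missing-at", "ACGT", "+",
               "IIII"), bad)
  expect_error(deplete_reads_insilico(bad, one), "record 2")
  unlink(bad)

  # simulated converted reads from a synthetic genome gain CG on depletion
  sim <- std_sim(seed = 10)
  fr <- fragment_genome(sim$genome, "cfdna", n_fragments = 1500, seed = 16)
  mol <- convert_molecules(fr, sim$genome, sim$profile,
                           conversion_params(seed = 17))
  res2 <- deplete_reads_insilico(mol$sequence, one)
  expect_gt(res2$summary$cg_fraction_retained,
            res2$summary$cg_fraction_input)
})

test_that("retained FASTQ records pass through verbatim", {
  one <- enzyme_panel("one_cut")
  fq <- tempfile(fileext = ".fastq")
  out <- tempfile(fileext = ".fastq")
  writeLines(c("@keep", "GCGCG", "+", "IIIII",
               "@cut", "TTAAT", "+", "IIIII"), fq)
  res <- deplete_reads_insilico(fq, one, output = out)
  expect_identical(readLines(out), c("@keep", "GCGCG", "+", "IIIII"))
  unlink(c(fq, out))
})

test_that("inter-site gaps shorter than the fragment length have zero depth", {
  # two MseI sites with a 50 bp gap; every 100-mer covering the gap must
  # contain a complete site, so no placement can be retained
  gap <- 50L
  left <- strrep("G", 120)
  right <- strrep("G", 120)
  gstr <- paste0(left, "TTAA", strrep("G", gap), "TTAA", right)
  g <- rrmp_genome(c(chr = gstr))
  one <- enzyme_panel("one_cut")
  glen <- nchar(gstr)

  # enumerate every 100-mer placement deterministically
  starts <- seq_len(glen - 100L + 1L)
  fr <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, width = 100),
                               strand = "+")
  S4Vectors::mcols(fr)$molecule_id <- as.character(starts)
  mol <- convert_molecules(fr, g, NULL, conversion_params(seed = 1))
  ret <- digest_library(mol, one)$retained
  sm <- converted_site_map(g, NULL, one, "all_unmethylated")
  prof_tab <- intersite_coverage_profile(sm, ret, one, strand = "+",
                                         max_d = 600, bin = 50)
  row50 <- prof_tab[prof_tab$d_lo == 1L, ]
  expect_equal(row50$mean_depth, 0)

  # a strand with fewer than two sites yields an empty table
  sm_plus_only <- sm[sm$strand == "+", , drop = FALSE]
  empty_tab <- intersite_coverage_profile(sm_plus_only, ret, one,
                                          strand = "-", max_d = 600,
                                          bin = 50)
  expect_equal(nrow(empty_tab), 0L)
})

test_that("mean retained depth rises with inter-site distance", {
  one <- enzyme_panel("one_cut")
  g <- gap_sweep_genome(seq(50L, 650L, by = 50L), reps = 8L, seed = 41)
  fr <- fragment_genome(g, "cfdna", n_fragments = 40000, mean_len = 100,
                        sd_len = 0, seed = 42)
  mol <- convert_molecules(fr, g, NULL, conversion_params(seed = 43))
  ret <- digest_library(mol, one)$retained
  sm <- converted_site_map(g, NULL, one, "all_unmethylated")
  tab <- intersite_coverage_profile(sm, ret, one, strand = "+",
                                    max_d = 700, bin = 100)
  expect_gte(nrow(tab), 6L)
  expect_true(all(diff(tab$mean_depth) >= 0))

  # deep inside the widest gaps, retained depth approaches the unfiltered
  # expectation (every placement covering such a position is retained)
  lambda <- length(fr) / sum(Biostrings::width(g))
  expected_depth <- lambda * 100
  sm_w <- sm[sm$strand == "+", ]
  cov <- as.integer(GenomicRanges::coverage(ret$fragments)[["chrGap"]])
  wide <- which(diff(sm_w$pos) > 600)
  interior <- unlist(lapply(wide, function(i) {
    (sm_w$pos[i] + 4L + 100L):(sm_w$pos[i + 1L] - 100L)
  }))
  expect_lt(abs(mean(cov[interior]) - expected_depth) / expected_depth, 0.1)
})

test_that("depth is depleted in the vicinity of cut sites", {
  one <- enzyme_panel("one_cut")
  g <- gap_sweep_genome(seq(100L, 800L, by = 100L), reps = 6L, seed = 51)
  fr <- fragment_genome(g, "cfdna", n_fragments = 20000, mean_len = 100,
                        sd_len = 0, seed = 52)
  mol <- convert_molecules(fr, g, NULL, conversion_params(seed = 53))
  ret <- digest_library(mol, one)$retained
  sm <- converted_site_map(g, NULL, one, "all_unmethylated")
  cov <- as.integer(GenomicRanges::coverage(ret$fragments)[["chrGap"]])
  glen <- length(cov)
  near <- logical(glen)
  frag_len <- 100L
  for (p in sm$pos) {
    lo <- max(1L, p - frag_len); hi <- min(glen, p + frag_len)
    near[lo:hi] <- TRUE
  }
  expect_lt(mean(cov[near]), mean(cov[!near]))
})
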