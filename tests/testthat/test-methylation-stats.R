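test_that("Fisher exact p agrees with hypergeometric enumeration", {
  # exhaustive over all small tables, random larger tables up to N = 200
  for (N in c(2:12)) {
    combos <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    combos <- combos[rowSums(combos) <= N, ]
    for (i in seq_len(nrow(combos))) {
      a <- combos$a[i]; b <- combos$b[i]; cc <- combos$c[i]
      d <- N - a - b - cc
      expect_equal(fisher_exact_p(a, b, cc, d),
                   oracle_fisher(a, b, cc, d), tolerance = 1e-10,
                   info = sprintf("table %d %d %d %d", a, b, cc, d))
    }
  }
  withr::with_seed(99, {
    for (rep in 1:400) {
      n <- sample(13:200, 1)
      cuts <- sort(sample(0:n, 3, replace = TRUE))
      a <- cuts[1]; b <- cuts[2] - cuts[1]; cc <- cuts[3] - cuts[2]
      d <- n - cuts[3]
      expect_equal(fisher_exact_p(a, b, cc, d),
                   oracle_fisher(a, b, cc, d), tolerance = 1e-10,
                   info = sprintf("table %d %d %d %d", a, b, cc, d))
    }
  })
})

test_that("window betas average qualifying CpGs and skip empty windows", {
  tr <- cpg_track("chr1", c(10L, 50L, 150L),
                  meth = c(2L, 4L, 10L), unmeth = c(8L, 6L, 0L))
  wb <- window_betas(tr, window = 100L)
  expect_equal(nrow(wb), 2L)
  expect_equal(wb$mean_beta[1], mean(c(0.2, 0.4)))
  expect_equal(wb$mean_beta[2], 1.0)

  # min_depth excludes shallow CpGs
  wb2 <- window_betas(tr, window = 100L, min_depth = 11L)
  expect_equal(nrow(wb2), 0L)

  # constant betas give constant windows
  tr3 <- cpg_track("chr1", seq(10L, 500L, by = 20L),
                   meth = rep(5L, 25), unmeth = rep(0L, 25))
  wb3 <- window_betas(tr3, window = 100L)
  expect_true(all(wb3$mean_beta == 1.0))
})

test_that("concordance reports r and the discordant fraction", {
  tr <- cpg_track("chr1", c(10L, 20L, 30L, 40L),
                  meth = c(0L, 3L, 7L, 10L), unmeth = c(10L, 7L, 3L, 0L))
  same <- concordance(tr, tr, min_depth = 1)
  expect_equal(same$pearson_r, 1.0)
  expect_equal(same$discordant_fraction, 0.0)
  expect_equal(same$n_cpgs, 4L)

  # anti-identical betas spanning [0,1] give r = -1
  tr_rev <- cpg_track("chr1", c(10L, 20L, 30L, 40L),
                      meth = c(10L, 7L, 3L, 0L), unmeth = c(0L, 3L, 7L, 10L))
  anti <- concordance(tr, tr_rev, min_depth = 1)
  expect_equal(anti$pearson_r, -1.0)
  expect_equal(anti$discordant_fraction, 0.5)  # |1-0| and |0.7-0.3|... only the extremes exceed 0.5

  # fewer than two shared CpGs: r missing, not zero
  tr_one <- cpg_track("chr1", 10L, meth = 5L, unmeth = 5L)
  expect_true(is.na(concordance(tr_one, tr_one)$pearson_r))

  # depth restriction applies to both tracks
  tr_deep <- cpg_track("chr1", c(10L, 20L), meth = c(50L, 1L),
                       unmeth = c(50L, 0L))
  res <- concordance(tr_deep, tr_deep, min_depth = 20)
  expect_equal(res$n_cpgs, 1L)
})

test_that("independent resamplings of one profile are highly concordant", {
  sim <- std_sim(seed = 18)
  expect_gte(nrow(sim$profile), 1000L)
  t1 <- resample_track(sim$profile, depth = 100L, seed = 71)
  t2 <- resample_track(sim$profile, depth = 100L, seed = 72)
  res <- concordance(t1, t2, min_depth = 20)
  expect_gte(res$n_cpgs, 1000L)
  expect_gt(res$pearson_r, 0.9)
  expect_lt(res$discordant_fraction, 0.01)
})

test_that("clear group differences are called as DMRs and nulls are not", {
  # one region, complete separation at depth 100 per sample
  ga <- list(cpg_track("chr1", c(100L, 130L), meth = c(50L, 50L),
                       unmeth = c(0L, 0L)))
  gb <- list(cpg_track("chr1", c(100L, 130L), meth = c(0L, 0L),
                       unmeth = c(50L, 50L)))
  dmrs <- call_dmrs(ga, gb, p_max = 1e-7, delta_min = 0.5)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$delta_beta, 1.0)
  expect_lt(dmrs$p_value, 1e-7)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$p_value,
               oracle_fisher(100, 0, 0, 100), tolerance = 1e-12)

  # identical groups: no DMR at any printed configuration
  for (cfg in list(c(1e-7, 0.5), c(0.05, 0.2), c(0.05, 0.33))) {
    expect_equal(nrow(call_dmrs(ga, ga, p_max = cfg[1],
                                delta_min = cfg[2])), 0L)
  }

  # empty group errors
  expect_error(call_dmrs(list(), gb), "group")
})

test_that("DMR regions respect the 300 bp span and the depth gate", {
  # CpGs spaced 80 bp apart: all gaps <= 100 so one run, split at 300 bp
  pos <- seq(100L, 900L, by = 80L)
  tr <- cpg_track("chr1", pos, meth = rep(5L, length(pos)),
                  unmeth = rep(5L, length(pos)))
  dmrs <- call_dmrs(list(tr), list(tr), p_max = 1, delta_min = 0)
  expect_gt(attr(dmrs, "n_tested"), 1L)
  expect_true(all(dmrs$end - dmrs$start + 1L <= 300L))

  # a sample below min_depth makes the region untestable
  shallow <- cpg_track("chr1", 100L, meth = 2L, unmeth = 2L)
  deep <- cpg_track("chr1", 100L, meth = 30L, unmeth = 30L)
  d2 <- call_dmrs(list(shallow), list(deep), min_depth = 10L,
                  p_max = 1, delta_min = 0)
  expect_equal(attr(d2, "n_tested"), 0L)
})

test_that("swapping groups negates delta and keeps p", {
  sim <- std_sim(seed = 19, n_islands = 5)
  t1 <- resample_track(sim$profile, depth = 60L, seed = 73)
  t2 <- resample_track(sim$profile, depth = 60L, seed = 74)
  mutate_beta <- function(pr) {
    pr$beta <- pmin(1, pr$beta + 0.3)
    pr
  }
  t3 <- resample_track(mutate_beta(sim$profile), depth = 60L, seed = 75)
  ab <- call_dmrs(list(t1), list(t3), p_max = 1, delta_min = 0)
  ba <- call_dmrs(list(t3), list(t1), p_max = 1, delta_min = 0)
  expect_equal(ab$delta_beta, -ba$delta_beta)
  expect_equal(ab$p_value, ba$p_value)
  flip <- c(hyper = "hypo", hypo = "hyper")
  nz <- ab$delta_beta != 0   # direction is arbitrary at delta exactly 0
  expect_equal(unname(flip[ab$direction[nz]]), ba$direction[nz])
})

test_that("null DMR false-positive rate is near the nominal 5%", {
  # 2000 independent regions x 5 seeds, both groups resampled from one
  # profile at depth 100
  rates <- vapply(1:5, function(seed) {
    withr::with_seed(1000 + seed, {
      n_regions <- 2000L
      beta <- runif(n_regions, 0.2, 0.8)
      pos <- seq(1L, by = 1000L, length.out = n_regions)
      mk <- function() {
        m <- rbinom(n_regions, 100L, beta)
        cpg_track("chr1", pos, meth = m, unmeth = 100L - m)
      }
      ga <- list(mk()); gb <- list(mk())
      dmrs <- call_dmrs(ga, gb, p_max = 1, delta_min = 0, min_depth = 10)
      mean(attr(dmrs, "tested_p") < 0.05)
    })
  }, numeric(1))
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("planted DMRs at delta 0.6 are recovered at the strictest config", {
  withr::with_seed(77, {
    n_null <- 400L; n_spike <- 50L
    pos_null <- seq(1L, by = 1000L, length.out = n_null)
    pos_spike <- seq(1000000L, by = 1000L, length.out = n_spike)
    beta_null <- runif(n_null, 0.1, 0.9)
    beta_a <- c(beta_null, rep(0.75, n_spike))
    beta_b <- c(beta_null, rep(0.15, n_spike))
    pos <- c(pos_null, pos_spike)
    mk <- function(beta) {
      m <- rbinom(length(beta), 200L, beta)
      cpg_track("chr1", pos, meth = m, unmeth = 200L - m)
    }
    dmrs <- call_dmrs(list(mk(beta_a)), list(mk(beta_b)),
                      p_max = 1e-7, delta_min = 0.5)
    hits <- dmrs$start %in% pos_spike
    recall <- sum(hits) / n_spike
    expect_gte(recall, 0.9)
    expect_equal(sum(!hits), 0L)
  })
})

test_that("cell-specific promoter methylation is detected one-vs-rest", {
  pos <- c(5000L, 5050L, 5100L)
  hi <- cpg_track("chr1", pos, meth = c(90L, 90L, 90L),
                  unmeth = c(10L, 10L, 10L))
  lo <- cpg_track("chr1", pos, meth = c(10L, 10L, 10L),
                  unmeth = c(90L, 90L, 90L))
  tracks <- list(a = hi, b = lo, c = lo, d = lo)
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5050, width = 1),
                                strand = "+")
  res <- differential_promoters(tracks, tss, flank = 4000, q_max = 0.01,
                                delta_min = 0.5)
  expect_equal(length(res$a$hyper), 1L)
  expect_equal(length(res$a$hypo), 0L)
  expect_equal(length(res$b$hyper), 0L)

  # identical cells yield empty sets
  res0 <- differential_promoters(list(a = lo, b = lo, c = lo), tss)
  expect_equal(length(res0$a$hyper) + length(res0$a$hypo), 0L)

  # BH q values are monotone along sorted p values
  p <- c(0.001, 0.01, 0.02, 0.5, 0.9)
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("peak association builds own-vs-other tables and Fisher p", {
  mk_gr <- function(starts) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 50))
  }
  # cell-1 regions: 8/10 contain an own-cell peak, 2/10 the other cell's
  r1 <- mk_gr(seq(1000, by = 1000, length.out = 10))
  p1 <- mk_gr(seq(1000, by = 1000, length.out = 8))
  r2 <- mk_gr(seq(101000, by = 1000, length.out = 10))
  p2 <- c(mk_gr(seq(9000, by = 1000, length.out = 2)),  # overlaps r1 #9,#10
          mk_gr(seq(101000, by = 1000, length.out = 9)))
  res <- peak_association(r1, r2, p1, p2)
  expect_equal(unname(res$tables$cell1[1, ]), c(8L, 2L))
  expect_equal(unname(res$tables$cell1[2, ]), c(2L, 8L))
  expect_equal(unname(res$p_values["cell1"]),
               oracle_fisher(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(unname(res$pct[1, ]), c(80, 20))
  expect_equal(unname(res$pct[2, ]), c(0, 90))

  # own and other containment balanced: no association
  p_bal <- mk_gr(seq(1000, by = 1000, length.out = 5))
  res_bal <- peak_association(r1, r1, p_bal, p_bal)
  expect_equal(unname(res_bal$p_values["cell1"]), 1.0)

  # empty region set: p missing for that cell
  res_e <- peak_association(r1[0], r2, p1, p2)
  expect_true(is.na(res_e$p_values["cell1"]))
  expect_false(is.na(res_e$p_values["cell2"]))
})

test_that("co-located hypomethylation and peaks give small p in simulation", {
  withr::with_seed(88, {
    sim <- simulate_genome(n_islands = 16, seed = 20)
    isl <- sim$annotation$cpg_island
    # cell 1 hypomethylated (and peaked) at odd islands, cell 2 at even
    own1 <- seq(1, 16, by = 2); own2 <- seq(2, 16, by = 2)
    prof1 <- sim$profile; prof2 <- sim$profile
    set_beta <- function(prof, regions, value) {
      gr <- GenomicRanges::GRanges(prof$chrom,
                                   IRanges::IRanges(prof$pos, width = 2))
      prof$beta[IRanges::overlapsAny(gr, regions)] <- value
      prof
    }
    prof1 <- set_beta(prof1, isl[own1], 0.02)
    prof1 <- set_beta(prof1, isl[own2], 0.85)
    prof2 <- set_beta(prof2, isl[own2], 0.02)
    prof2 <- set_beta(prof2, isl[own1], 0.85)
    t1 <- resample_track(prof1, depth = 80L, seed = 81)
    t2 <- resample_track(prof2, depth = 80L, seed = 82)
    hypo1 <- hypomethylated_regions(t1, isl, beta_max = 0.10)
    hypo2 <- hypomethylated_regions(t2, isl, beta_max = 0.10)
    # ChIP peaks co-locate with each cell's own hypomethylated islands
    peaks1 <- isl[own1]; peaks2 <- isl[own2]
    res <- peak_association(hypo1, hypo2, peaks1, peaks2)
    expect_lt(res$p_values["cell1"], 0.01)
    expect_lt(res$p_values["cell2"], 0.01)
    expect_gt(res$pct[1, 1], 90)
    expect_lt(res$pct[1, 2], 10)
  })
})
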