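#' Cohort design for the synthetic cfDNA simulator
#'
#' Describes a two-group plasma cohort: `n_bc` cancer (BC) and `n_nbc`
#' control (NBC) samples. Cancer samples are a mixture of the shared normal
#' methylome and a tumor methylome: at each informative CpG the BC mean
#' beta is shifted by `tumor_fraction * effect_delta` toward the tumor
#' state, reflecting that ctDNA contributes only a fraction of plasma
#' cfDNA. Inter-individual variation is Beta-distributed around the sample
#' mean with the given `concentration` (larger = tighter); observed counts
#' are binomial at a Poisson-distributed depth.
#'
#' @param n_bc,n_nbc Group sizes.
#' @param tumor_fraction Tumor fraction `f` in `[0, 1]`.
#' @param n_informative_cpgs Number of promoter CpGs carrying the planted
#'   effect (default 100).
#' @param effect_delta Planted full-tumor delta beta (default 0.5).
#' @param depth Mean sequencing depth per CpG (default 200).
#' @param concentration Beta-distribution concentration for
#'   inter-individual variation (default 10).
#' @param seed Integer seed.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_bc = 30L, n_nbc = 30L, tumor_fraction = 0.3,
                          n_informative_cpgs = 100L, effect_delta = 0.5,
                          depth = 200L, concentration = 10,
                          seed = 1L) {
  n_bc <- check_count(n_bc, "n_bc", min = 0L)
  n_nbc <- check_count(n_nbc, "n_nbc", min = 0L)
  check_fraction(tumor_fraction, "tumor_fraction")
  check_fraction(effect_delta, "effect_delta")
  n_informative_cpgs <- check_count(n_informative_cpgs,
                                    "n_informative_cpgs", min = 0L)
  depth <- check_count(depth, "depth")
  structure(list(n_bc = n_bc, n_nbc = n_nbc,
                 tumor_fraction = tumor_fraction,
                 n_informative_cpgs = n_informative_cpgs,
                 effect_delta = effect_delta, depth = depth,
                 concentration = concentration, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a two-group cfDNA methylation cohort
#'
#' NBC sample betas vary around the shared normal profile (the genome's
#' ground truth); BC samples are additionally shifted at the informative
#' CpGs by `tumor_fraction * effect_delta`, in the direction (hyper below
#' beta 0.5, hypo above) that keeps the tumor state inside `[0, 1]`.
#' Informative CpGs are drawn from CpGs within `tss_flank` of a TSS so
#' that the promoter-locality prefilter can find them. Deterministic per
#' design seed.
#'
#' @param design A [cohort_design()].
#' @param profile A [methylation_profile()] providing the normal methylome.
#' @param tss `GRanges` of TSS positions.
#' @param tss_flank Promoter window half-width used to pick informative
#'   CpGs (default 2000 bp).
#' @return A list of class `methyl_matrix`: `beta` and `depth` matrices
#'   (sites x samples), `sites` data.frame (`chrom`, `pos`, `autosome`),
#'   `labels` (factor BC/NBC) and `design`. The planted informative site
#'   indices are kept in the `informative` attribute for validation
#'   studies.
#' @export
simulate_cohort <- function(design, profile, tss, tss_flank = 2000L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(profile, "methylation_profile"),
            methods::is(tss, "GRanges"))
  n_sites <- nrow(profile)
  n <- design$n_bc + design$n_nbc
  if (n < 2L) stop_param("cohort needs at least two samples")

  centers <- BiocGenerics::start(tss)
  prom_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(centers - as.integer(tss_flank), 1L),
                     centers + as.integer(tss_flank)))
  site_gr <- GenomicRanges::GRanges(profile$chrom,
                                    IRanges::IRanges(profile$pos, width = 2L))
  in_prom <- which(IRanges::overlapsAny(site_gr, prom_gr))
  if (design$n_informative_cpgs > length(in_prom)) {
    stop_param("n_informative_cpgs (%d) exceeds available promoter CpGs (%d)",
               design$n_informative_cpgs, length(in_prom))
  }

  withr::with_seed(design$seed, {
    informative <- sort(sample(in_prom, design$n_informative_cpgs))
    mu <- pmin(pmax(profile$beta, 0.02), 0.98)
    dir <- ifelse(mu <= 0.5, 1, -1)
    mu_bc <- mu
    mu_bc[informative] <- pmin(pmax(
      mu[informative] + design$tumor_fraction * design$effect_delta *
        dir[informative], 0.02), 0.98)

    labels <- factor(rep(c("BC", "NBC"), c(design$n_bc, design$n_nbc)),
                     levels = c("NBC", "BC"))
    k <- design$concentration
    beta_m <- matrix(NA_real_, n_sites, n)
    depth_m <- matrix(0L, n_sites, n)
    for (j in seq_len(n)) {
      m <- if (labels[j] == "BC") mu_bc else mu
      true_beta <- rbeta(n_sites, m * k, (1 - m) * k)
      dp <- rpois(n_sites, design$depth)
      mc <- rbinom(n_sites, dp, true_beta)
      depth_m[, j] <- dp
      beta_m[, j] <- ifelse(dp > 0L, mc / dp, NA_real_)
    }
    colnames(beta_m) <- colnames(depth_m) <-
      sprintf("%s_%02d", as.character(labels), seq_len(n))
    structure(
      list(beta = beta_m, depth = depth_m,
           sites = data.frame(chrom = profile$chrom, pos = profile$pos,
                              autosome = TRUE, stringsAsFactors = FALSE),
           labels = labels, design = design),
      class = "methyl_matrix", informative = informative
    )
  })
}

#' Assemble a methylation matrix from components
#'
#' @param beta,depth Sites x samples matrices of beta values and depths.
#' @param sites A data.frame with columns `chrom`, `pos` and logical
#'   `autosome`.
#' @param labels Factor or character of per-sample labels (`BC` / `NBC`).
#' @return A `methyl_matrix`.
#' @export
methyl_matrix <- function(beta, depth, sites, labels) {
  stopifnot(is.matrix(beta), is.matrix(depth),
            all(dim(beta) == dim(depth)),
            nrow(beta) == nrow(sites), ncol(beta) == length(labels))
  if (!all(c("chrom", "pos", "autosome") %in% names(sites))) {
    stop_param("'sites' needs chrom, pos and autosome columns")
  }
  if (is.null(colnames(beta))) {
    colnames(beta) <- sprintf("sample_%02d", seq_len(ncol(beta)))
  }
  colnames(depth) <- colnames(beta)
  structure(list(beta = beta, depth = depth, sites = sites,
                 labels = factor(as.character(labels),
                                 levels = c("NBC", "BC"))),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d CpGs x %d samples (%s)\n",
              nrow(x$beta), ncol(x$beta),
              paste(sprintf("%s=%d", levels(x$labels),
                            tabulate(x$labels, nbins = nlevels(x$labels))),
                    collapse = ", ")))
  invisible(x)
}

subset_matrix <- function(mm, site_idx = NULL, sample_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(mm$beta))
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(mm$beta))
  structure(
    list(beta = mm$beta[site_idx, sample_idx, drop = FALSE],
         depth = mm$depth[site_idx, sample_idx, drop = FALSE],
         sites = mm$sites[site_idx, , drop = FALSE],
         labels = droplevels(mm$labels[sample_idx]),
         design = mm$design),
    class = "methyl_matrix"
  )
}

#' Cohort quality-control filter
#'
#' Two ordered steps. Sites: keep autosomal CpGs whose depth exceeds
#' `site_min_depth` in more than `site_sample_frac` of samples (both
#' strictly "more than", so a CpG deep enough in exactly 80% of samples is
#' dropped). Samples: among the kept sites, drop samples for which more
#' than `sample_missing_frac` of sites fall below `site_min_depth`.
#' Applying the filter to its own output changes nothing.
#'
#' @param mm A `methyl_matrix`.
#' @param site_min_depth Depth cutoff (default 100).
#' @param site_sample_frac Required fraction of samples per site (default
#'   0.8).
#' @param sample_missing_frac Tolerated fraction of shallow sites per
#'   sample (default 0.2).
#' @return A list with `matrix` (filtered `methyl_matrix`) and `report`
#'   (sites removed, samples excluded with reasons).
#' @export
qc_filter <- function(mm, site_min_depth = 100L, site_sample_frac = 0.8,
                      sample_missing_frac = 0.2) {
  stopifnot(inherits(mm, "methyl_matrix"))
  n_samples <- ncol(mm$depth)
  deep <- mm$depth > site_min_depth
  site_keep <- mm$sites$autosome &
    rowMeans(deep) > site_sample_frac
  kept_idx <- which(site_keep)
  if (length(kept_idx) == 0L) {
    stop_param("no site passes the depth filter")
  }
  shallow_frac <- colMeans(mm$depth[kept_idx, , drop = FALSE] <
                             site_min_depth)
  sample_keep <- shallow_frac <= sample_missing_frac
  if (!any(sample_keep)) stop_param("all samples excluded by QC")
  excluded <- colnames(mm$depth)[!sample_keep]
  list(
    matrix = subset_matrix(mm, kept_idx, which(sample_keep)),
    report = list(
      sites_total = nrow(mm$depth),
      sites_kept = length(kept_idx),
      samples_excluded = excluded,
      sample_shallow_fraction = shallow_frac
    )
  )
}

#' Promoter-locality and variance feature prefilter
#'
#' Keeps CpGs lying within `flank` bp of a TSS whose across-sample beta
#' variance (population variance, missing values excluded) is at least
#' `var_min`. The variance is computed on the full cohort, mirroring
#' common practice of defining one global feature set; note this is a mild
#' information leak relative to strictly in-fold filtering (see the
#' package vignette).
#'
#' @param mm A `methyl_matrix`.
#' @param tss `GRanges` of TSS positions.
#' @param flank Window half-width, bp (default 2000).
#' @param var_min Variance cutoff (default 0.009, inclusive).
#' @return The reduced `methyl_matrix`.
#' @export
feature_prefilter <- function(mm, tss, flank = 2000L, var_min = 0.009) {
  stopifnot(inherits(mm, "methyl_matrix"), methods::is(tss, "GRanges"))
  centers <- BiocGenerics::start(tss)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(centers - as.integer(flank), 1L),
                     centers + as.integer(flank)))
  site_gr <- GenomicRanges::GRanges(mm$sites$chrom,
                                    IRanges::IRanges(mm$sites$pos,
                                                     width = 2L))
  local <- IRanges::overlapsAny(site_gr, win)
  if (!any(local)) stop_param("no CpG lies within TSS +/- %d bp", flank)
  pop_var <- apply(mm$beta, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(0)
    mean((x - mean(x))^2)
  })
  keep <- which(local & pop_var >= var_min)
  if (length(keep) == 0L) {
    stop_param("no CpG passes the variance filter (var >= %g)", var_min)
  }
  subset_matrix(mm, keep, NULL)
}

# Row-wise means/variances via rowMeans arithmetic (fast inside the LOO
# loop); x must be NA-free.
row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  rowMeans((x - rowMeans(x))^2) * n / (n - 1L)
}

# Two-sided Welch t statistic per row between two column groups of the
# NA-free matrix x; rows with zero variance in both groups get t = 0.
welch_t_rows <- function(x, ga, gb) {
  xa <- x[, ga, drop = FALSE]; xb <- x[, gb, drop = FALSE]
  se2 <- row_var(xa) / length(ga) + row_var(xb) / length(gb)
  t <- (rowMeans(xa) - rowMeans(xb)) / sqrt(se2)
  t[!is.finite(t)] <- 0
  t
}

#' Leave-one-out logistic-regression classifier
#'
#' For each sample in turn, the remaining samples form the training fold.
#' Inside the fold: missing betas are imputed with the per-feature
#' training mean; features below the `var_min` across-sample variance on
#' the training fold are dropped (when `variance_in_fold = TRUE`, the
#' default -- fold-safe filtering; set it to `FALSE` when a global
#' [feature_prefilter()] set is to be used as-is); the remaining CpGs are
#' ranked by the absolute two-sided Welch t statistic between classes and
#' the top `n_features` enter an L2-regularized logistic regression
#' (ridge via \pkg{glmnet} at a fixed penalty, with balanced class
#' weights). The predicted probability of the held-out sample is its
#' tumor score. Feature selection is repeated inside every fold, so no
#' information from the held-out sample enters training.
#'
#' The default `n_features = 500` is deliberately weak selection: with
#' cohort-scale sample sizes, aggressively small panels (tens of CpGs)
#' make pooled leave-one-out scores unstable because each fold's model
#' concentrates on chance-separated CpGs; a broad ridge-regularized panel
#' keeps null-cohort AUC near 0.5 while leaving planted-signal recovery
#' intact (see the package vignette).
#'
#' @param mm A `methyl_matrix` (typically after [qc_filter()] and a
#'   locality [feature_prefilter()]).
#' @param n_features Features selected per fold (default 500; capped at
#'   the number available).
#' @param lambda Ridge penalty (default 0.05).
#' @param var_min In-fold variance threshold (default 0.009; ignored when
#'   `variance_in_fold = FALSE`).
#' @param variance_in_fold Apply the variance filter inside each training
#'   fold (default `TRUE`).
#' @param seed Integer seed (reserved for stochastic variants; the default
#'   path is deterministic).
#' @return A list of class `classifier_result`: per-sample `scores`,
#'   `labels`, `roc`, `auc`, `threshold` (Youden) and `predicted` labels
#'   at that threshold.
#' @export
loo_classify <- function(mm, n_features = 500L, lambda = 0.05,
                         var_min = 0.009, variance_in_fold = TRUE,
                         seed = 1L) {
  stopifnot(inherits(mm, "methyl_matrix"))
  y <- mm$labels
  if (nlevels(y) != 2L || any(table(y) < 3L)) {
    stop_param("need both classes with at least 3 samples each")
  }
  x <- mm$beta
  n <- ncol(x)
  n_features <- max(2L, as.integer(n_features))
  scores <- numeric(n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      ytr <- y[tr]
      if (length(unique(ytr)) < 2L) {
        stop_param("training fold %d has a single class", i)
      }
      xtr_all <- x[, tr, drop = FALSE]
      # impute missing betas with the training-fold feature mean
      if (anyNA(xtr_all)) {
        mu_row <- rowMeans(xtr_all, na.rm = TRUE)
        mu_row[is.nan(mu_row)] <- 0
        nas <- which(is.na(xtr_all), arr.ind = TRUE)
        xtr_all[nas] <- mu_row[nas[, 1L]]
      } else {
        mu_row <- rowMeans(xtr_all)
      }
      keep <- if (variance_in_fold) {
        which(rowMeans((xtr_all - rowMeans(xtr_all))^2) >= var_min)
      } else {
        seq_len(nrow(x))
      }
      if (length(keep) < 2L) {
        stop_param("fewer than 2 features pass the in-fold variance filter")
      }
      ga <- which(ytr == "BC"); gb <- which(ytr == "NBC")
      t_stat <- welch_t_rows(xtr_all[keep, , drop = FALSE], ga, gb)
      ord <- order(-abs(t_stat), seq_along(t_stat))
      sel <- keep[ord[seq_len(min(n_features, length(keep)))]]
      xtr <- t(xtr_all[sel, , drop = FALSE])
      xte <- x[sel, i]
      xte[is.na(xte)] <- mu_row[sel][is.na(xte)]
      # Balanced class weights: leaving one sample out shrinks its class
      # in the fold, which would otherwise bias every held-out score
      # against its own class (a pooled-LOO artifact).
      wt <- 0.5 / as.numeric(table(ytr)[as.character(ytr)])
      # glmnet warns about small classes; expected at cohort-study sizes
      fit <- suppressWarnings(
        glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = TRUE,
                       weights = wt * length(ytr)))
      scores[i] <- as.numeric(stats::predict(
        fit, newx = matrix(xte, nrow = 1L), type = "response"))
    }
  })
  names(scores) <- colnames(x)
  res <- roc_auc(scores, y)
  youden <- res$roc$tpr - res$roc$fpr
  thr <- res$roc$threshold[which.max(youden)]
  structure(
    list(scores = scores, labels = y, roc = res$roc, auc = res$auc,
         threshold = thr,
         predicted = factor(ifelse(scores >= thr, "BC", "NBC"),
                            levels = c("NBC", "BC"))),
    class = "classifier_result"
  )
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %d samples, AUC = %s, Youden threshold = %s\n",
              length(x$scores), format(x$auc, digits = 3),
              format(x$threshold, digits = 3)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC uses the rank (Mann-Whitney) formulation with ties contributing
#' one half; the ROC curve is a sweep over the observed score thresholds
#' (classifying `score >= threshold` as positive).
#'
#' @param scores Numeric scores, higher = more tumor-like.
#' @param labels Factor or character labels; `positive` names the tumor
#'   class.
#' @param positive Positive class label (default `"BC"`).
#' @return A list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc` (`NA` when a class is absent).
#' @export
roc_auc <- function(scores, labels, positive = "BC") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    return(list(roc = data.frame(threshold = numeric(0), fpr = numeric(0),
                                 tpr = numeric(0)),
                auc = NA_real_))
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  )
  list(roc = roc, auc = auc)
}

#' Read and write methylation matrices as TSV
#'
#' Beta and depth are sites x samples tables with `chrom` and `pos` as the
#' first two columns; labels are a two-column TSV (`sample`, `label`).
#'
#' @param beta_path,depth_path,labels_path File paths.
#' @param mm A `methyl_matrix`.
#' @param prefix Output path prefix; writes `<prefix>_beta.tsv`,
#'   `<prefix>_depth.tsv`, `<prefix>_labels.tsv`.
#' @return `read_methyl_matrix()` returns a `methyl_matrix`.
#' @export
read_methyl_matrix <- function(beta_path, depth_path, labels_path) {
  b <- read.table(beta_path, header = TRUE, sep = "\t",
                  check.names = FALSE)
  d <- read.table(depth_path, header = TRUE, sep = "\t",
                  check.names = FALSE)
  lab <- read.table(labels_path, header = TRUE, sep = "\t",
                    col.names = c("sample", "label"))
  samples <- setdiff(colnames(b), c("chrom", "pos"))
  stopifnot(identical(colnames(b), colnames(d)),
            setequal(lab$sample, samples))
  lab <- lab[match(samples, lab$sample), ]
  methyl_matrix(
    beta = as.matrix(b[, samples, drop = FALSE]),
    depth = as.matrix(d[, samples, drop = FALSE]),
    sites = data.frame(chrom = b$chrom, pos = b$pos, autosome = TRUE),
    labels = lab$label
  )
}

#' @rdname read_methyl_matrix
#' @export
write_methyl_matrix <- function(mm, prefix) {
  stopifnot(inherits(mm, "methyl_matrix"))
  bdf <- data.frame(chrom = mm$sites$chrom, pos = mm$sites$pos,
                    mm$beta, check.names = FALSE)
  ddf <- data.frame(chrom = mm$sites$chrom, pos = mm$sites$pos,
                    mm$depth, check.names = FALSE)
  write.table(bdf, paste0(prefix, "_beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ddf, paste0(prefix, "_depth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(mm$beta),
                         label = as.character(mm$labels)),
              paste0(prefix, "_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
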