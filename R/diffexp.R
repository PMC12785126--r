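#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the
#' ratio of the sample's count to the feature's geometric mean across
#' samples, computed over features with strictly positive counts in every
#' sample. Multiplying one sample's column by a constant multiplies its
#' size factor relative to every other sample's by that constant (the
#' geometric-mean reference itself rescales, so the absolute factors move
#' by `c^(1 - 1/m)` and `c^(-1/m)` respectively).
#'
#' @param counts Non-negative count matrix (features x samples).
#' @param pseudo_reference If `TRUE` and no feature has all-positive
#'   counts, fall back to a pseudo-reference computed from positive counts
#'   only; by default this situation is an error.
#' @return Named positive numeric vector, one entry per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      stop("no feature has positive counts in every sample; ",
           "set pseudo_reference = TRUE to use a positive-part reference")
    }
    log_gm <- apply(counts, 1, function(r) {
      pos <- r > 0
      if (!any(pos)) return(NA_real_)
      mean(log(r[pos]))
    })
    use <- is.finite(log_gm)
  } else {
    log_gm <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    counts <- counts[all_pos, , drop = FALSE]
    use <- rep(TRUE, nrow(counts))
  }
  s <- apply(counts[use, , drop = FALSE], 2, function(col) {
    r <- col / exp(log_gm[use])
    stats::median(r[col > 0 | !pseudo_reference])
  })
  if (any(!is.finite(s) | s <= 0)) stop("degenerate size factor estimate")
  s
}

#' Method-of-moments NB dispersion
#'
#' Per feature, pools the within-group variances of the normalized counts
#' and the grand mean, and returns
#' `alpha = max(0, (pooled_var - mean) / mean^2)`; features with zero mean
#' get `NA` (skipped downstream). This is the raw, unmoderated estimate;
#' see [moderate_dispersion()] for the trend-based moderation the pipeline
#' applies by default.
#'
#' @param norm_counts Normalized count matrix (counts divided by size
#'   factors), features x samples.
#' @param groups Factor or character vector of group labels per sample.
#' @return Named numeric vector of dispersions (`NA` for zero-mean
#'   features).
#' @export
estimate_dispersion <- function(norm_counts, groups) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(norm_counts))
  idx <- split(seq_along(groups), groups)
  df <- vapply(idx, function(i) max(0L, length(i) - 1L), integer(1))
  tot_df <- sum(df)
  if (tot_df == 0L) stop("need at least one group with >= 2 replicates")
  m <- rowMeans(norm_counts)
  ssq <- rowSums(matrix(vapply(idx, function(i) {
    x <- norm_counts[, i, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(norm_counts))), nrow = nrow(norm_counts)))
  v <- ssq / tot_df
  alpha <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  stats::setNames(alpha, rownames(norm_counts))
}

#' Moderate dispersions toward a mean-dispersion trend
#'
#' Fits the trend `alpha(mu) = a0 + a1 / mu` to the raw method-of-moments
#' estimates by least squares over features with positive estimates
#' (coefficients floored at 0; falls back to the median dispersion when
#' the fit degenerates), then combines each raw estimate with its fitted
#' trend value weighted by residual versus prior degrees of freedom:
#' `alpha_mod = (d_resid * alpha_raw + d_prior * alpha_trend) /
#' (d_resid + d_prior)`. With few replicates the raw estimate has very few
#' degrees of freedom, so the moderated value leans on the trend, which is
#' what keeps the Wald test calibrated at 2-3 replicates per group.
#'
#' @param alpha Raw dispersions from [estimate_dispersion()].
#' @param means Per-feature mean normalized counts.
#' @param resid_df Residual degrees of freedom of the raw estimates
#'   (`sum over groups of (n_g - 1)`).
#' @param prior_df Prior degrees of freedom given to the trend
#'   (default 20).
#' @return Named numeric vector of moderated dispersions (`NA` preserved).
#' @export
moderate_dispersion <- function(alpha, means, resid_df, prior_df = 20) {
  ok <- is.finite(alpha) & is.finite(means) & means > 0
  trend <- rep(NA_real_, length(alpha))
  fit_ok <- FALSE
  use <- ok & alpha > 0
  if (sum(use) >= 10) {
    co <- stats::coef(stats::lm(alpha[use] ~ I(1 / means[use])))
    if (all(is.finite(co))) {
      a0 <- max(0, co[1])
      a1 <- max(0, co[2])
      trend[ok] <- a0 + a1 / means[ok]
      fit_ok <- TRUE
    }
  }
  if (!fit_ok) trend[ok] <- stats::median(alpha[ok])
  out <- alpha
  out[ok] <- (resid_df * alpha[ok] + prior_df * trend[ok]) /
    (resid_df + prior_df)
  out
}

#' Define a two-group contrast
#'
#' @param name Contrast label, e.g. `"White_vs_Brown"`.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   names; fold changes are reported as a over b.
#' @return A list of class `de_contrast`.
#' @export
de_contrast <- function(name, group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1,
            length(intersect(group_a, group_b)) == 0)
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "de_contrast")
}

#' Negative-binomial Wald test for one contrast
#'
#' For each feature the log2 fold change is
#' `log2(mean_a + c0) - log2(mean_b + c0)` over normalized group means,
#' with a small-count offset `c0`. Its standard error comes from the delta
#' method applied to the NB variance `mu + alpha * mu^2` of each count
#' (evaluated at the estimated group means and scaled by the size
#' factors), and the p-value is two-sided normal. Features where both
#' groups have all-zero counts get `log2fc = 0`, `p = 1`.
#'
#' @param counts Raw count matrix (features x samples) with column names.
#' @param s Named size factors covering all samples in the contrast.
#' @param alpha Named per-feature dispersions (typically moderated).
#' @param contrast A [de_contrast()].
#' @param c0 Small-count offset on the normalized-count scale
#'   (default 0.5).
#' @return A data.frame `feature_id`, `base_mean`, `log2fc`, `se`, `p`.
#' @export
wald_test <- function(counts, s, alpha, contrast, c0 = 0.5) {
  counts <- as.matrix(counts)
  samp <- c(contrast$group_a, contrast$group_b)
  stopifnot(all(samp %in% colnames(counts)), all(samp %in% names(s)))
  norm <- sweep(counts[, samp, drop = FALSE], 2, s[samp], "/")
  a_idx <- match(contrast$group_a, samp)
  b_idx <- match(contrast$group_b, samp)
  qa <- rowMeans(norm[, a_idx, drop = FALSE])
  qb <- rowMeans(norm[, b_idx, drop = FALSE])
  al <- alpha[rownames(counts)]
  al[!is.finite(al)] <- 0

  group_var <- function(q, g_idx) {
    sg <- s[samp][g_idx]
    n <- length(g_idx)
    # Var(mean of K_j/s_j) with K_j ~ NB(mu = s_j q, alpha)
    vapply(seq_along(q), function(i) {
      mu <- sg * q[i]
      sum((mu + al[i] * mu^2) / sg^2) / n^2
    }, numeric(1))
  }
  va <- group_var(qa, a_idx)
  vb <- group_var(qb, b_idx)
  log2fc <- log2(qa + c0) - log2(qb + c0)
  se <- sqrt(va / ((qa + c0)^2) + vb / ((qb + c0)^2)) / log(2)
  zero_se <- !is.finite(se) | se == 0
  z <- ifelse(zero_se, 0, log2fc / se)
  p <- 2 * stats::pnorm(-abs(z))
  both_zero <- qa == 0 & qb == 0
  log2fc[both_zero] <- 0
  p[both_zero] <- 1
  se[both_zero] <- NA_real_
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2fc = log2fc, se = se, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`padj_(i) = min_{k >= i} m * p_(k) / k`, capped
#' at 1), delegated to `stats::p.adjust(method = "BH")` after validating
#' the inputs. `NA` entries are preserved and excluded from `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed features
#'
#' Both thresholds are strict: significance requires `padj < padj_max`
#' and `|log2fc| > lfc_min`; up means `log2fc > lfc_min`, down means
#' `log2fc < -lfc_min`. A feature at exactly `padj = padj_max` or
#' `|log2fc| = lfc_min` is not significant.
#'
#' @param results A data.frame with columns `feature_id`, `log2fc`,
#'   `padj`.
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @param lfc_min Absolute log2-fold-change threshold (default 1).
#' @return `results` with added columns `significant` and `direction`
#'   (`"up"`, `"down"`, or `""`).
#' @export
call_degs <- function(results, padj_max = 0.05, lfc_min = 1) {
  up <- !is.na(results$padj) & results$padj < padj_max &
    results$log2fc > lfc_min
  down <- !is.na(results$padj) & results$padj < padj_max &
    results$log2fc < -lfc_min
  results$significant <- up | down
  results$direction <- ifelse(up, "up", ifelse(down, "down", ""))
  results
}

#' Run the differential-expression pipeline for a set of contrasts
#'
#' Drops features with zero counts everywhere, computes size factors once
#' on the full matrix, estimates (and by default moderates) dispersions
#' per contrast from the contrast's samples, runs the Wald test, adjusts
#' p-values by BH within each contrast, and applies the significance rule.
#'
#' @param counts Raw count matrix (features x samples).
#' @param contrasts A list of [de_contrast()] objects.
#' @param padj_max,lfc_min Significance thresholds (strict; defaults 0.05
#'   and 1).
#' @param c0 Small-count offset passed to [wald_test()].
#' @param moderate If `TRUE` (default), moderate dispersions toward the
#'   mean-dispersion trend via [moderate_dispersion()].
#' @param prior_df Prior degrees of freedom for the moderation.
#' @param pseudo_reference Passed to [size_factors()].
#' @return Named list (one element per contrast) of [call_degs()] result
#'   data.frames with a `padj` column.
#' @export
run_diffexp <- function(counts, contrasts, padj_max = 0.05, lfc_min = 1,
                        c0 = 0.5, moderate = TRUE, prior_df = 20,
                        pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  s <- size_factors(counts, pseudo_reference = pseudo_reference)
  out <- list()
  for (ct in contrasts) {
    samp <- c(ct$group_a, ct$group_b)
    groups <- rep(c("a", "b"), c(length(ct$group_a), length(ct$group_b)))
    norm <- sweep(counts[, samp, drop = FALSE], 2, s[samp], "/")
    alpha <- estimate_dispersion(norm, groups)
    if (moderate) {
      resid_df <- sum(pmax(0L, table(groups) - 1L))
      alpha <- moderate_dispersion(alpha, rowMeans(norm), resid_df,
                                   prior_df = prior_df)
    }
    res <- wald_test(counts, s, alpha, ct, c0 = c0)
    res$padj <- bh_adjust(res$p)
    res <- call_degs(res, padj_max = padj_max, lfc_min = lfc_min)
    out[[ct$name]] <- res
  }
  out
}
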