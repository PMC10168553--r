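#' Sorensen-Dice coefficient of two binary masks
#'
#' `2|X ∩ Y| / (|X| + |Y|)`; 1 when both masks are empty (degenerate
#' inputs must not break cohort means), 0 for disjoint non-empty masks.
#'
#' @param X,Y binary masks ([LungMask] or 0/1 matrices) of equal shape.
#' @return overlap fraction in `[0, 1]`.
#' @export
sdc <- function(X, Y) {
  x <- as_pixels(X) != 0
  y <- as_pixels(Y) != 0
  if (!all(dim(x) == dim(y))) stop("mask shapes differ")
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0L) return(1)
  2 * sum(x & y) / (sx + sy)
}

#' Symmetric Hausdorff distance between mask boundaries, in mm
#'
#' The greatest boundary-to-boundary mismatch: the maximum over both
#' directed distances `sup_a inf_b d(a, b)` taken over boundary pixel
#' centres (pixels with a 4-neighbour outside the mask, or on the image
#' border), with Euclidean distance scaled by the pixel spacing.
#'
#' @param A,B non-empty binary masks of equal shape.
#' @param spacing_mm length-2 (row, col) pixel spacing in mm; defaults
#'   to the spacing recorded on `A` when it is a [LungMask].
#' @return distance in mm.
#' @export
hausdorff_mm <- function(A, B, spacing_mm = NULL) {
  a <- as_pixels(A); b <- as_pixels(B)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  if (sum(a != 0) == 0L || sum(b != 0) == 0L)
    stop("Hausdorff distance undefined for empty masks")
  if (is.null(spacing_mm))
    spacing_mm <- if (inherits(A, "LungMask")) A$spacing_mm else c(1, 1)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  hausdorff_cpp(matrix(as.integer(a != 0), nrow(a), ncol(a)),
                matrix(as.integer(b != 0), nrow(b), ncol(b)),
                spacing_mm[1], spacing_mm[2])
}

#' Welch's two-sample t-test
#'
#' `t = (x̄ - ȳ) / sqrt(s1²/n1 + s2²/n2)` with unbiased sample
#' variances, Welch–Satterthwaite degrees of freedom and a two-sided
#' p-value. Two constant samples with equal means give `t = 0, p = 1`.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param alpha_corrected significance level recorded on the result
#'   (e.g. a Bonferroni-corrected level).
#' @return a `TTestResult`: list with `t`, `df`, `p`, `alpha_corrected`.
#' @export
welch_t <- function(x, y, alpha_corrected = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample")
  res <- if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) list(t = 0, df = length(x) + length(y) - 2, p = 1)
    else list(t = sign(mean(x) - mean(y)) * Inf,
              df = length(x) + length(y) - 2, p = 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = unname(tt$p.value))
  }
  structure(c(res, list(alpha_corrected = alpha_corrected)),
            class = "TTestResult")
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g (alpha = %.3g)\n",
              x$t, x$df, x$p, x$alpha_corrected))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' `alpha / m`, truncated to three decimals for reporting (0.05 over
#' three comparisons is reported as 0.016). The exact quotient is kept
#' in the `"exact"` attribute.
#'
#' @param alpha family-wise level.
#' @param m number of comparisons (>= 1).
#' @return the reported corrected level.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  exact <- alpha / m
  reported <- floor(exact * 1000) / 1000
  attr(reported, "exact") <- exact
  reported
}

#' Score one predicted mask against ground truth
#'
#' @param pred,truth binary masks of equal shape.
#' @param spacing_mm pixel spacing for the Hausdorff distance.
#' @param id record identifier.
#' @param cohort,arm grouping labels carried into the record.
#' @return one-row `data.frame` (id, cohort, arm, sdc, hd_mm); `hd_mm`
#'   is `NA` when either mask is empty.
#' @export
eval_record <- function(pred, truth, spacing_mm = NULL, id = NA_character_,
                        cohort = NA_character_, arm = NA_character_) {
  s <- sdc(pred, truth)
  hd <- if (sum(as_pixels(pred)) > 0L && sum(as_pixels(truth)) > 0L)
    hausdorff_mm(pred, truth, spacing_mm %||%
                   (if (inherits(truth, "LungMask")) truth$spacing_mm else c(1, 1)))
  else NA_real_
  data.frame(id = id, cohort = cohort, arm = arm, sdc = s, hd_mm = hd,
             stringsAsFactors = FALSE)
}

#' Compare training arms on shared test cohorts
#'
#' Builds the per-cohort, per-arm summary (mean ± SD of the SDC in
#' percent and of the Hausdorff distance in mm) and the pairwise Welch
#' comparisons between arms within each cohort, flagged at the
#' Bonferroni-corrected level. Note the summary reports one HD mean per
#' arm (per-arm summaries, not per-comparison ones).
#'
#' @param records `data.frame` of per-image scores with columns `arm`,
#'   `cohort`, `sdc`, `hd_mm` (rows from [eval_record()]).
#' @param alpha family-wise significance level.
#' @return list with `summary` and `comparisons` data frames and the
#'   corrected level `alpha_corrected`.
#' @export
evaluate_arms <- function(records, alpha = 0.05) {
  stopifnot(all(c("arm", "cohort", "sdc", "hd_mm") %in% names(records)))
  arms <- unique(records$arm)
  cohorts <- unique(records$cohort)
  summ <- do.call(rbind, lapply(cohorts, function(co) {
    do.call(rbind, lapply(arms, function(a) {
      r <- records[records$arm == a & records$cohort == co, ]
      data.frame(cohort = co, arm = a, n = nrow(r),
                 sdc_mean_pct = mean(r$sdc) * 100,
                 sdc_sd_pct = stats::sd(r$sdc) * 100,
                 hd_mean_mm = mean(r$hd_mm, na.rm = TRUE),
                 hd_sd_mm = stats::sd(r$hd_mm, na.rm = TRUE),
                 hd_undefined = sum(is.na(r$hd_mm)),
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- if (length(arms) >= 2L) utils::combn(arms, 2L, simplify = FALSE)
           else list()
  alpha_c <- bonferroni(alpha, max(1L, length(pairs)))
  comp <- do.call(rbind, lapply(cohorts, function(co) {
    do.call(rbind, lapply(pairs, function(pr) {
      r1 <- records[records$arm == pr[1] & records$cohort == co, ]
      r2 <- records[records$arm == pr[2] & records$cohort == co, ]
      if (nrow(r1) < 2L || nrow(r2) < 2L) {
        warning("cohort ", co, " has fewer than 2 images; comparison skipped")
        return(NULL)
      }
      ts <- welch_t(r1$sdc, r2$sdc, alpha_c)
      h1 <- r1$hd_mm[!is.na(r1$hd_mm)]; h2 <- r2$hd_mm[!is.na(r2$hd_mm)]
      th <- if (length(h1) >= 2L && length(h2) >= 2L) welch_t(h1, h2, alpha_c)
            else list(t = NA_real_, p = NA_real_)
      data.frame(cohort = co, arm_a = pr[1], arm_b = pr[2],
                 sdc_t = ts$t, sdc_p = ts$p,
                 sdc_significant = ts$p < alpha_c,
                 hd_t = th$t, hd_p = th$p,
                 hd_significant = !is.na(th$p) & th$p < alpha_c,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, comparisons = comp, alpha_corrected = alpha_c)
}

#' Format an arm-comparison report as text
#'
#' @param report result of [evaluate_arms()].
#' @return character vector of report lines.
#' @export
format_arm_report <- function(report) {
  lines <- c("Arm comparison (per-arm HD means reported per arm)",
             sprintf("Bonferroni-corrected level: %.3f",
                     as.numeric(report$alpha_corrected)))
  for (co in unique(report$summary$cohort)) {
    lines <- c(lines, sprintf("Cohort: %s", co))
    s <- report$summary[report$summary$cohort == co, ]
    lines <- c(lines, sprintf(
      "  %-16s SDC %5.1f%% +/- %4.1f  HD %5.1f mm +/- %4.1f (n=%d)",
      s$arm, s$sdc_mean_pct, s$sdc_sd_pct, s$hd_mean_mm, s$hd_sd_mm, s$n))
    cmp <- report$comparisons[report$comparisons$cohort == co, , drop = FALSE]
    if (!is.null(cmp) && nrow(cmp))
      lines <- c(lines, sprintf(
        "  %s vs %s: p(SDC) = %.4g%s, p(HD) = %.4g%s",
        cmp$arm_a, cmp$arm_b, cmp$sdc_p,
        ifelse(cmp$sdc_significant, " *", ""),
        cmp$hd_p, ifelse(cmp$hd_significant, " *", "")))
  }
  lines
}
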