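test_that("Dice coefficient matches direct evaluation and conventions", {
  base <- matrix(0L, 40, 40)
  # |X| = 100, |Y| = 50, |X ∩ Y| = 25 -> SDC = 2*25/150 = 1/3
  X <- base; X[5:14, 5:14] <- 1L
  Y <- base; Y[5:9, 5:9] <- 1L; Y[20:24, 20:24] <- 1L
  expect_identical(sum(X), 100L); expect_identical(sum(Y), 50L)
  expect_identical(sum(X & Y), 25L)
  expect_equal(sdc(X, Y), 2 * 25 / 150)
  expect_equal(sdc(X, X), 1)
  Z <- base; Z[30:35, 30:35] <- 1L
  expect_equal(sdc(X, Z), 0)
  expect_equal(sdc(base, base), 1)  # empty-vs-empty convention
  expect_equal(sdc(X, Y), sdc(Y, X))
  expect_error(sdc(X, matrix(0L, 10, 10)), "shapes")
})

test_that("Hausdorff distance matches the double-loop oracle", {
  # two single pixels 5 px apart at 2 mm/px -> 10 mm
  A <- matrix(0L, 32, 32); A[10, 10] <- 1L
  B <- matrix(0L, 32, 32); B[10, 15] <- 1L
  expect_equal(hausdorff_mm(A, B, c(2, 2)), 10)
  expect_equal(hausdorff_mm(A, A, c(1, 1)), 0)
  expect_equal(hausdorff_mm(A, B, c(1, 1)), hausdorff_mm(B, A, c(1, 1)))
  expect_error(hausdorff_mm(A, matrix(0L, 32, 32), c(1, 1)), "empty")
  for (s in 1:10) {
    X <- random_blob_mask(32, seed = s)
    Y <- random_blob_mask(32, seed = s + 100)
    expect_lt(abs(hausdorff_mm(X, Y, c(1.7, 2.3)) -
                    hausdorff_oracle(X, Y, c(1.7, 2.3))), 1e-9)
  }
})

test_that("Welch t-test matches the closed-form statistic", {
  x <- c(1, 2, 3); y <- x + 10
  r <- welch_t(x, y)
  t_manual <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(r$t, t_manual)
  r2 <- welch_t(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(15, 0.5)
  ref <- t.test(a, b, var.equal = FALSE)
  r3 <- welch_t(a, b)
  expect_equal(r3$t, unname(ref$statistic))
  expect_equal(r3$df, unname(ref$parameter))
  expect_equal(r3$p, ref$p.value)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Bonferroni reporting truncates to three decimals", {
  expect_equal(as.numeric(bonferroni(0.05, 3)), 0.016)
  expect_equal(attr(bonferroni(0.05, 3), "exact"), 0.05 / 3)
  expect_equal(as.numeric(bonferroni(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni(0.06, 2)), 0.03)
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("arm evaluation reports per-cohort summaries and comparisons", {
  set.seed(3)
  mk <- function(arm, co, n, mu) data.frame(
    id = sprintf("%s_%s_%d", arm, co, 1:n), cohort = co, arm = arm,
    sdc = pmin(1, pmax(0, rnorm(n, mu, 0.03))),
    hd_mm = abs(rnorm(n, 8, 2)), stringsAsFactors = FALSE)
  rec <- rbind(mk("A", "with_cons", 10, 0.90), mk("A", "without_cons", 10, 0.92),
               mk("B", "with_cons", 10, 0.94), mk("B", "without_cons", 10, 0.93),
               mk("C", "with_cons", 10, 0.94), mk("C", "without_cons", 10, 0.93))
  rep3 <- evaluate_arms(rec)
  expect_identical(nrow(rep3$summary), 6L)       # 2 cohorts x 3 arms
  expect_identical(nrow(rep3$comparisons), 6L)   # 2 cohorts x 3 pairs
  expect_equal(as.numeric(rep3$alpha_corrected), 0.016)
  expect_true(all(c("sdc_p", "hd_p") %in% names(rep3$comparisons)))
  txt <- format_arm_report(rep3)
  expect_true(any(grepl("0.016", txt)))
  # one arm duplicated into two: all p-values 1
  dup <- rbind(mk("A", "with_cons", 10, 0.9))
  dup2 <- dup; dup2$arm <- "B"
  repd <- evaluate_arms(rbind(dup, dup2))
  expect_true(all(repd$comparisons$sdc_p == 1))
  # perfect predictions summarise to 100% / 0 mm
  perf <- data.frame(id = as.character(1:4), cohort = "with_cons", arm = "A",
                     sdc = 1, hd_mm = 0)
  reps <- evaluate_arms(perf)
  expect_equal(reps$summary$sdc_mean_pct, 100)
  expect_equal(reps$summary$hd_mean_mm, 0)
})

test_that("per-record scoring flags empty predictions", {
  truth <- generate_phantom(phantom_spec(seed = 12))$mask
  empty <- LungMask(matrix(0L, 64, 64), truth$spacing_mm)
  row <- eval_record(empty, truth, id = "x", cohort = "c", arm = "a")
  expect_equal(row$sdc, 0)
  expect_true(is.na(row$hd_mm))
  exact <- eval_record(truth, truth, id = "x", cohort = "c", arm = "a")
  expect_equal(exact$sdc, 1)
  expect_equal(exact$hd_mm, 0)
})
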