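test_that("slice categorisation follows the inclusive AP threshold", {
  expect_identical(categorize_slice("FLASH", 0), "FLASH")
  expect_identical(categorize_slice("FLASH", 40), "AP_FLASH")
  expect_identical(categorize_slice("bSSFP", -17), "AP_bSSFP")
  expect_identical(categorize_slice("bSSFP", 16.9), "bSSFP")
  expect_error(categorize_slice("SPGR", 0), "unknown sequence")
})

test_that("balancing factors reproduce the reference four-category table", {
  counts <- c(FLASH = 1371L, AP_FLASH = 21L, bSSFP = 256L, AP_bSSFP = 18L)
  plan <- compute_balancing_factors(counts, target = 4330)
  expect_identical(plan$factor, c(3L, 206L, 17L, 241L))
  expect_identical(plan$resulting, c(4113L, 4326L, 4352L, 4338L))
  expect_identical(attr(plan, "total"), 17129L)
  # balanced spread: most and least represented categories within 6%
  expect_lte(max(plan$resulting) / min(plan$resulting), 1.06)
  # degenerate and error cases
  eq <- compute_balancing_factors(c(a = 10L, b = 10L), 10)
  expect_identical(eq$factor, c(1L, 1L))
  expect_warning(compute_balancing_factors(c(a = 10L, b = 0L), 10), "zero-count")
  expect_error(compute_balancing_factors(c(a = 10L), 5), "target")
})

test_that("joint transforms preserve geometry contracts", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  label <- make_contour_label(ph$mask)
  ident <- transform_params(rescale_range = c(1, 1),
                            translate_px_range = c(0, 0),
                            rotate_deg_range = c(0, 0))
  out <- augment_pair(ph$image, label, ident, seed = 3)
  expect_equal(out$image$pixels, ph$image$pixels, tolerance = 1e-12)
  expect_identical(out$label$pixels, label$pixels)

  rnd <- transform_params()
  out2 <- augment_pair(ph$image, label, rnd, seed = 4)
  expect_identical(dim(out2$image$pixels), dim(ph$image$pixels))
  expect_true(all(out2$label$pixels %in% c(0L, 1L)))  # nearest neighbour
  expect_true(all(out2$image$pixels >= 0 & out2$image$pixels <= 1))
  expect_identical(out2, augment_pair(ph$image, label, rnd, seed = 4))
  tr <- out2$transform
  expect_gte(tr$scale, 0.3); expect_lte(tr$scale, 0.75)
  expect_true(abs(tr$tx) >= 10 && abs(tr$tx) <= 20)
  expect_true(abs(tr$ty) >= 10 && abs(tr$ty) <= 20)
})

test_that("transforming then contouring commutes with contouring then transforming", {
  # up to nearest-neighbour discretisation on a 1-px boundary band
  ph <- generate_phantom(phantom_spec(seed = 8))
  label <- make_contour_label(ph$mask)
  params <- transform_params(rescale_range = c(0.7, 0.75),
                             translate_px_range = c(0, 2),
                             rotate_deg_range = c(0, 20))
  tm <- augment_pair(ph$image, ph$mask, params, seed = 5)$label
  tl <- augment_pair(ph$image, label, params, seed = 5)$label
  contour_of_tm <- make_contour_label(tm)$pixels
  # disagreement confined to a thin discretisation band
  diff_px <- sum(contour_of_tm != tl$pixels)
  band_px <- sum(contour_of_tm | tl$pixels)
  expect_lt(diff_px / band_px, 0.35)
})

test_that("training sets match plan counts exactly in both modes", {
  recs <- make_labelled_cohort(8, seed = 41, ranges = list(ap_fraction = 0.25))
  counts <- category_counts(recs)
  plan <- compute_balancing_factors(counts, target = max(counts))
  bal <- build_training_set(recs, "balanced", plan = plan, seed = 1)
  expect_length(bal, sum(plan$resulting))
  by_cat <- table(vapply(bal, `[[`, "", "category"))
  expect_identical(as.integer(by_cat[plan$category]), plan$resulting)
  conv <- build_training_set(recs, "conventional", conv_copies = 3L, seed = 1)
  expect_length(conv, 8L * 4L)
  # factor-1 plan reproduces the input records
  plan1 <- compute_balancing_factors(counts, target = max(counts))
  plan1$factor[] <- 1L
  same <- build_training_set(recs, "balanced", plan = plan1, seed = 1)
  expect_length(same, length(recs))
  expect_identical(lapply(same, `[[`, "image"), lapply(recs, `[[`, "image"))
  # first copy is always the untransformed original
  expect_false(bal[[1]]$augmented)
  expect_identical(bal[[1]]$image, recs[[1]]$image)
  # missing category rejected
  plan_missing <- plan[plan$category != plan$category[1], ]
  expect_error(build_training_set(recs, "balanced", plan = plan_missing),
               "missing from plan")
})
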