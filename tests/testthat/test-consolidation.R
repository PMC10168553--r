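test_that("sampled regions are connected, in one lung, at the target area", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  params <- consolidation_params(area_fraction_range = c(0.1, 0.1))
  reg <- sample_region(ph$mask, params, seed = 5)
  lab <- label8_components(ph$mask$pixels)
  comp_id <- attr(reg, "lung_component")
  lung_area <- sum(lab == comp_id)
  expect_true(all(lab[reg == 1L] == comp_id))
  expect_lte(abs(sum(reg) - 0.1 * lung_area), 1)
  expect_identical(max(label8_components(reg)), 1L)  # connected
  # determinism
  expect_identical(reg, sample_region(ph$mask, params, seed = 5))
  # border placement: region meets the lung's 1-px inner boundary band
  inner <- erode_box_oracle(matrix(as.integer(lab == comp_id), nrow(lab),
                                   ncol(lab)), 1L)
  boundary_band <- (lab == comp_id) & inner == 0L
  expect_gt(sum(reg == 1L & boundary_band), 0L)
})

test_that("uniform fill spans the selected lung's intensity range", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  img <- ph$image$pixels
  lab <- label8_components(ph$mask$pixels)
  reg <- sample_region(ph$mask, consolidation_params(), seed = 9)
  comp <- matrix(as.integer(lab == attr(reg, "lung_component")),
                 nrow(lab), ncol(lab))
  lo <- min(img[comp == 1]); hi <- max(img[comp == 1])
  vals <- unlist(lapply(1:200, function(s)
    fill_region_uniform(img, comp, reg, seed = s)[reg == 1L]))
  expect_gte(min(vals), lo)
  expect_lte(max(vals), hi)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - (lo + hi) / 2), 3 * se + 1e-12)
})

test_that("insertion changes only lung pixels and respects intensity bounds", {
  # larger grid so the lungs have an interior beyond the filters' reach
  ph <- generate_phantom(phantom_spec(matrix_size = 96L, seed = 7))
  img <- ph$image$pixels
  m <- ph$mask$pixels
  reg <- sample_region(ph$mask, consolidation_params(), seed = 21)
  out <- insert_consolidation(ph$image, ph$mask, reg,
                              consolidation_params(), seed = 22)
  expect_identical(out$pixels[m == 0], img[m == 0])  # bit-identical outside
  lab <- label8_components(m)
  comp <- lab == attr(reg, "lung_component")
  lo <- min(img[comp]); hi <- max(img[comp])
  # deep inside the host lung (beyond the reach of the 10x10 median window
  # and the 5x5 blend, which mix in brighter body tissue at the margin) the
  # inserted intensities stay within the lung's own range
  interior <- erode_box_oracle(matrix(as.integer(comp), nrow(m), ncol(m)),
                               8L) == 1L
  expect_gte(min(out$pixels[interior]), lo - 0.02)
  expect_lte(max(out$pixels[interior]), hi + 0.02)
  # degenerate region: no-op
  zero <- matrix(0L, nrow(m), ncol(m))
  expect_identical(insert_consolidation(ph$image, ph$mask, zero)$pixels, img)
  # region outside the mask is rejected
  bad <- zero; bad[1, 1] <- 1L
  expect_error(insert_consolidation(ph$image, ph$mask, bad), "subset")
})

test_that("consolidating a dataset leaves labels and masks untouched", {
  recs <- make_labelled_cohort(4, seed = 31)
  out <- consolidate_dataset(recs, seed = 77)
  expect_length(out, 4L)
  for (i in seq_along(recs)) {
    expect_identical(out[[i]]$label, recs[[i]]$label)
    expect_identical(out[[i]]$mask, recs[[i]]$mask)
  }
  log <- attr(out, "consolidation_log")
  expect_identical(nrow(log), 4L)
  expect_identical(sum(log$consolidated), 4L)
  # determinism of the whole pass
  out2 <- consolidate_dataset(recs, seed = 77)
  expect_identical(lapply(out, `[[`, "image"), lapply(out2, `[[`, "image"))
  # consolidations actually brighten the host lung region
  changed <- vapply(seq_along(recs), function(i)
    sum(out[[i]]$image$pixels != recs[[i]]$image$pixels), 0)
  expect_true(all(changed > 0))
})
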