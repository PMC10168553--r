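test_that("phantom generation is deterministic and anatomically plausible", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  expect_identical(ph, generate_phantom(phantom_spec(seed = 1)))
  expect_s3_class(ph$image, "Image2D")
  expect_s3_class(ph$mask, "LungMask")
  expect_identical(dim(ph$image$pixels), dim(ph$mask$pixels))
  expect_identical(ph$image$spacing_mm, ph$mask$spacing_mm)
  # noise-free contrast: lung parenchyma darker than the rest of the slice
  ph0 <- generate_phantom(phantom_spec(seed = 3, noise_sd = 0))
  m <- ph0$mask$pixels
  expect_lt(mean(ph0$image$pixels[m == 1]), mean(ph0$image$pixels[m == 0]))
})

test_that("lung area shrinks away from the central slice", {
  areas <- vapply(c(0, 20, 40, 60), function(off)
    sum(generate_phantom(phantom_spec(slice_offset_mm = off,
                                      seed = 5))$mask$pixels), 0)
  expect_true(all(diff(areas) < 0))
  expect_gt(areas[1], areas[3])  # offset 0 strictly larger than offset 40
})

test_that("masks split into two lungs and stay dark across seeds", {
  for (s in 1:8) {
    for (off in c(0, 30, 55)) {
      ph <- generate_phantom(phantom_spec(slice_offset_mm = off, seed = s,
                                          noise_sd = 0.05))
      m <- ph$mask$pixels
      expect_equal(max(label8_components(m)), 2L)
      expect_lt(mean(ph$image$pixels[m == 1]), mean(ph$image$pixels[m == 0]))
      border <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
      expect_true(all(border == 0L))
    }
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(matrix_size = 16L), "matrix_size")
  expect_error(phantom_spec(slice_offset_mm = 100), "slice_offset_mm")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(sequence_kind = "SPIN_ECHO"))
})

test_that("cohort generation honours category fractions and determinism", {
  co <- generate_cohort(10, list(ap_fraction = 0.2), seed = 7)
  expect_length(co, 10L)
  meta <- attr(co, "meta")
  expect_identical(sum(abs(meta$slice_offset_mm) >= 17), 2L)
  expect_identical(attr(generate_cohort(10, list(ap_fraction = 0.2), seed = 7),
                        "meta"), meta)
  expect_length(generate_cohort(1, list(), seed = 2), 1L)
  expect_error(generate_cohort(0))
  expect_error(generate_cohort(5, list(lung_scale = c(0.9, 0.1))), "interval")
})

test_that("sequence kinds differ in body/lung contrast", {
  fl <- generate_phantom(phantom_spec(seed = 9, sequence_kind = "FLASH",
                                      noise_sd = 0))
  bs <- generate_phantom(phantom_spec(seed = 9, sequence_kind = "bSSFP",
                                      noise_sd = 0))
  contrast <- function(ph) {
    m <- ph$mask$pixels
    mean(ph$image$pixels[m == 0]) - mean(ph$image$pixels[m == 1])
  }
  expect_gt(contrast(bs), contrast(fl))
})
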