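test_that("thresholding follows the inclusive cutoff contract", {
  zero <- matrix(0, 40, 40)
  p <- postprocess_params(threshold = 6e-4, closing_radius_px = 0L)
  expect_identical(sum(threshold_contour(zero, p)), 0L)
  one <- zero; one[20, 20] <- 5e-4
  expect_identical(sum(threshold_contour(one, p)), 0L)  # below 0.06%
  one[20, 20] <- 6e-4
  expect_identical(sum(threshold_contour(one, p)), 1L)  # at the cutoff
  ring <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    r <- sqrt((i - 20)^2 + (j - 20)^2)
    if (r >= 8 && r < 9.5) ring[i, j] <- 1
  }
  expect_identical(threshold_contour(ring, p),
                   matrix(as.integer(ring > 0), 40, 40))
})

test_that("lowering the threshold never removes contour pixels", {
  set.seed(5)
  prob <- matrix(runif(64 * 64)^3, 64, 64)
  ths <- c(0.5, 0.2, 0.05, 0.01, 6e-4)
  prev <- NULL
  for (th in ths) {
    cur <- threshold_contour(prob, postprocess_params(threshold = th))
    if (!is.null(prev)) expect_true(all(cur[prev == 1L] == 1L))
    prev <- cur
  }
})

test_that("filling a closed ring matches the flood-fill oracle", {
  ring <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    r <- sqrt((i - 20.5)^2 + (j - 20.5)^2)
    if (r >= 9 && r < 10.5) ring[i, j] <- 1L
  }
  filled <- fill_contour(ring, postprocess_params())
  reached <- flood_fill_oracle(ring, c(1, 1))
  oracle <- matrix(as.integer(ring == 1L | !reached), 40, 40)
  expect_identical(filled$pixels, oracle)
  expect_true(all(filled$pixels[ring == 1L] == 1L))  # contour ⊆ fill
  # empty contour -> empty mask
  expect_identical(sum(fill_contour(matrix(0L, 40, 40))$pixels), 0L)
  # an unclosed arc encloses nothing and is flagged
  arc <- ring; arc[1:20, ] <- 0L
  out <- fill_contour(arc)
  expect_true(attr(out, "closure_failed"))
})

test_that("label fill round-trips phantom masks exactly", {
  for (s in c(1L, 6L, 13L)) {
    mask <- generate_phantom(phantom_spec(seed = s))$mask
    lab <- make_contour_label(mask)
    rec <- fill_contour(lab$pixels, postprocess_params(),
                        spacing_mm = mask$spacing_mm)
    expect_identical(rec$pixels, mask$pixels)
  }
})

test_that("component pruning keeps the largest lungs only", {
  m <- matrix(0L, 50, 50)
  m[5:20, 5:20] <- 1L    # big
  m[5:20, 30:45] <- 1L   # big
  m[40:42, 40:42] <- 1L  # speck
  lab <- make_contour_label(LungMask(m, c(1, 1)), 2L)
  filled <- fill_contour(lab$pixels, postprocess_params(keep_components = 2L))
  expect_identical(max(label8_components(filled$pixels)), 2L)
  expect_identical(sum(filled$pixels), sum(m) - 9L)
})
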