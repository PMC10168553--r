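test_that("contour label equals mask minus iterated box erosion", {
  for (side in c(12L, 30L)) {
    m <- matrix(0L, side + 10L, side + 10L)
    m[6:(5L + side), 6:(5L + side)] <- 1L
    lab <- make_contour_label(LungMask(m, c(1, 1)), width_px = 6L)
    oracle <- m - erode_box_oracle(m, 6L)
    expect_identical(lab$pixels, matrix(as.integer(oracle), nrow(m), ncol(m)))
  }
  # a 12 px square is emptied by 6 erosions: the label is the whole square
  m12 <- matrix(0L, 22, 22); m12[6:17, 6:17] <- 1L
  lab12 <- make_contour_label(LungMask(m12, c(1, 1)), 6L)
  expect_identical(lab12$pixels, m12)
  # a 30 px square keeps an 18 px core: band count 30^2 - 18^2 = 576
  m30 <- matrix(0L, 40, 40); m30[6:35, 6:35] <- 1L
  expect_identical(sum(make_contour_label(LungMask(m30, c(1, 1)), 6L)$pixels),
                   576L)
})

test_that("contour band is inner, closed and ring-like on phantom masks", {
  for (s in c(2L, 11L)) {
    mask <- generate_phantom(phantom_spec(seed = s))$mask
    lab <- make_contour_label(mask)
    expect_true(all(lab$pixels <= mask$pixels))  # label subset of mask
    # one closed ring per lung: as many band components as mask components
    expect_identical(max(label8_components(lab$pixels)),
                     max(label8_components(mask$pixels)))
  }
})

test_that("empty masks give empty labels and bad widths are rejected", {
  empty <- matrix(0L, 40, 40)
  expect_identical(sum(make_contour_label(LungMask(empty, c(1, 1)))$pixels), 0L)
  expect_error(make_contour_label(LungMask(empty, c(1, 1)), width_px = 0L),
               "width_px")
})

test_that("class map is a faithful round trip of the label", {
  lab <- make_contour_label(generate_phantom(phantom_spec(seed = 4))$mask)
  cm <- label_to_classmap(lab)
  expect_setequal(unique(as.vector(cm)), c(0L, 1L))
  expect_identical(sum(cm), sum(lab$pixels))
  expect_identical(label_to_classmap(classmap_to_label(cm)), cm)
  zero <- label_to_classmap(ContourLabel(matrix(0L, 40, 40)))
  expect_true(all(zero == 0L))
})
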