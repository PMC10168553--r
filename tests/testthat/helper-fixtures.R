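# Shared fixtures and independent oracles, built in code at test time.

# small labelled phantom records for training/evaluation fixtures
make_labelled_cohort <- function(n, seed = 1L, ranges = list()) {
  records <- generate_cohort(n, ranges, seed = seed)
  lapply(records, function(r) {
    r$label <- make_contour_label(r$mask)
    r
  })
}

# random connected-ish blob mask on an n x n grid (smoothed noise threshold);
# guaranteed non-empty and off the border
random_blob_mask <- function(n = 32L, seed = 1L, fill = 0.2) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  f <- as.matrix(EBImage::gblur(f, sigma = 2))
  m <- matrix(as.integer(f >= quantile(f, 1 - fill)), n, n)
  m[c(1L, n), ] <- 0L
  m[, c(1L, n)] <- 0L
  if (sum(m) == 0L) m[n %/% 2, n %/% 2] <- 1L
  m
}

# brute-force erosion with the 3x3 box, iterated; independent of EBImage
erode_box_oracle <- function(m, iterations) {
  H <- nrow(m); W <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- matrix(0L, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (m[i, j] == 0L) next
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W || m[ii, jj] == 0L) ok <- FALSE
      }
      if (ok) out[i, j] <- 1L
    }
    m <- out
  }
  m
}

# boundary pixels: foreground with a 4-neighbour outside the mask or on the
# image border (mirrors the metric definition, coded independently)
boundary_points_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pts <- NULL
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (m[i, j] == 0) next
    edge <- i == 1 || i == H || j == 1 || j == W
    if (!edge)
      edge <- m[i - 1, j] == 0 || m[i + 1, j] == 0 ||
        m[i, j - 1] == 0 || m[i, j + 1] == 0
    if (edge) pts <- rbind(pts, c(i, j))
  }
  pts
}

# O(nA * nB) double-loop symmetric Hausdorff oracle over boundary points
hausdorff_oracle <- function(A, B, spacing = c(1, 1)) {
  pa <- boundary_points_oracle(A)
  pb <- boundary_points_oracle(B)
  directed <- function(P, Q) {
    worst <- 0
    for (u in seq_len(nrow(P))) {
      best <- Inf
      for (v in seq_len(nrow(Q))) {
        d <- sqrt(((P[u, 1] - Q[v, 1]) * spacing[1])^2 +
                    ((P[u, 2] - Q[v, 2]) * spacing[2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# 4-connected flood fill from a seed through zero pixels; independent of the
# C++ border flood used by the package
flood_fill_oracle <- function(blocked, start) {
  H <- nrow(blocked); W <- ncol(blocked)
  reached <- matrix(FALSE, H, W)
  queue <- list(start)
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    i <- p[1]; j <- p[2]
    if (i < 1 || i > H || j < 1 || j > W) next
    if (reached[i, j] || blocked[i, j] != 0) next
    reached[i, j] <- TRUE
    queue <- c(queue, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  reached
}
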