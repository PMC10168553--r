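#' Training configuration for the contour U-Net
#'
#' Defaults follow the reference training recipe: binary cross entropy,
#' Adam with learning rate 0.001, batch size 64, up to 100 epochs with
#' early stopping at patience 10, 10% of the data carved for validation,
#' pixel accuracy as the monitored metric. `input_size`, `depth` and
#' `base_channels` set the spatial scale: 256/4/32 mirrors the
#' full-resolution network, 64/3/8 is the desk-scale default used
#' throughout the phantom experiments.
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^depth`.
#' @param depth number of resolution levels (encoder levels incl. the
#'   bottleneck); `depth - 1` poolings.
#' @param base_channels filters at the first level; doubled per level.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param val_fraction fraction of the dataset used for validation.
#' @param pos_weight optional weight on the contour class in the loss
#'   (1 = plain BCE, the default).
#' @param seed seed for weight initialisation, the validation split and
#'   batch shuffling.
#' @return a `TrainConfig` object.
#' @export
unet_config <- function(input_size = 64L, depth = 3L, base_channels = 8L,
                        learning_rate = 0.001, batch_size = 64L,
                        max_epochs = 100L, early_stop_patience = 10L,
                        val_fraction = 0.10, pos_weight = 1,
                        seed = 1L) {
  cfg <- structure(list(input_size = as.integer(input_size),
                        depth = as.integer(depth),
                        base_channels = as.integer(base_channels),
                        loss = "binary_crossentropy", optimizer = "adam",
                        learning_rate = learning_rate,
                        batch_size = as.integer(batch_size),
                        max_epochs = as.integer(max_epochs),
                        early_stop_patience = as.integer(early_stop_patience),
                        val_fraction = val_fraction,
                        metric = "accuracy",
                        pos_weight = pos_weight,
                        seed = as.integer(seed)),
                   class = "TrainConfig")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (cfg$early_stop_patience > cfg$max_epochs && cfg$max_epochs > 0)
    stop("patience must be <= max_epochs")
  if (cfg$input_size %% 2L^cfg$depth != 0L)
    stop("input_size must be divisible by 2^depth")
  cfg
}

new_conv <- function(cin, cout, k = 3L) {
  K <- cin * k * k
  # He initialisation for ReLU stacks
  list(W = matrix(rnorm(cout * K, sd = sqrt(2 / K)), cout, K),
       b = numeric(cout), kh = k, kw = k, cin = cin, cout = cout,
       pad = (k - 1L) %/% 2L)
}

#' Build a 2D U-Net model
#'
#' Encoder of `depth - 1` double-convolution blocks with 2x2 max
#' pooling, a double-convolution bottleneck, and a mirrored decoder
#' using nearest-neighbour upsampling, a channel-halving convolution and
#' skip concatenation. All hidden activations are ReLU; the final 1x1
#' convolution feeds a sigmoid, so the forward pass maps an
#' `input_size^2` image to a contour-probability map of the same size.
#'
#' @param config a [unet_config()].
#' @return a `unet_model` (list of layer parameters plus config).
#' @export
build_unet <- function(config = unet_config()) {
  d <- config$depth
  ch <- config$base_channels * 2L^(seq_len(d) - 1L)
  with_seed(derive_seed(config$seed, "init"), {
    layers <- list()
    cin <- 1L
    for (l in seq_len(d - 1L)) {
      layers[[sprintf("enc%d_conv1", l)]] <- new_conv(cin, ch[l])
      layers[[sprintf("enc%d_conv2", l)]] <- new_conv(ch[l], ch[l])
      cin <- ch[l]
    }
    layers[["bott_conv1"]] <- new_conv(cin, ch[d])
    layers[["bott_conv2"]] <- new_conv(ch[d], ch[d])
    for (l in rev(seq_len(d - 1L))) {
      layers[[sprintf("dec%d_up", l)]] <- new_conv(ch[l + 1L], ch[l])
      layers[[sprintf("dec%d_conv1", l)]] <- new_conv(2L * ch[l], ch[l])
      layers[[sprintf("dec%d_conv2", l)]] <- new_conv(ch[l], ch[l])
    }
    layers[["out"]] <- new_conv(ch[1], 1L, k = 1L)
    structure(list(config = config, layers = layers), class = "unet_model")
  })
}

conv_fwd_l <- function(layer, x)
  conv2d_fwd(x, dim(x), layer$W, layer$b, layer$kh, layer$kw, layer$pad)

conv_bwd_l <- function(layer, x, dy)
  conv2d_bwd(x, dim(x), layer$W, dy, layer$kh, layer$kw, layer$pad)

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(model, x, keep_cache = FALSE) {
  d <- model$config$depth
  L <- model$layers
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  conv_relu <- function(nm, a) {
    z <- conv_fwd_l(L[[nm]], a)
    y <- pmax(z, 0)
    if (keep_cache) cache[[nm]] <- list(x = a, y = y)
    y
  }
  skips <- vector("list", d - 1L)
  a <- x
  for (l in seq_len(d - 1L)) {
    a <- conv_relu(sprintf("enc%d_conv1", l), a)
    a <- conv_relu(sprintf("enc%d_conv2", l), a)
    skips[[l]] <- a
    mp <- maxpool2_fwd(a, dim(a))
    if (keep_cache) cache[[sprintf("pool%d", l)]] <-
      list(idx = mp$idx, xdim = dim(a))
    a <- mp$y
  }
  a <- conv_relu("bott_conv1", a)
  a <- conv_relu("bott_conv2", a)
  for (l in rev(seq_len(d - 1L))) {
    a <- upsample2_fwd(a, dim(a))
    a <- conv_relu(sprintf("dec%d_up", l), a)
    a <- cat_ch(skips[[l]], a)
    a <- conv_relu(sprintf("dec%d_conv1", l), a)
    a <- conv_relu(sprintf("dec%d_conv2", l), a)
  }
  if (keep_cache) cache[["out"]] <- list(x = a)
  z <- conv_fwd_l(L[["out"]], a)
  p <- 1 / (1 + exp(-z))
  list(p = p, cache = cache)
}

# mean (optionally class-weighted) binary cross entropy
bce_loss <- function(p, y, pos_weight = 1, eps = 1e-7) {
  w <- 1 + (pos_weight - 1) * y
  -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / length(p)
}

unet_backward <- function(model, cache, p, y) {
  d <- model$config$depth
  L <- model$layers
  pw <- model$config$pos_weight
  grads <- list()
  w <- 1 + (pw - 1) * y
  dz <- w * (p - y) / length(p)
  bw <- conv_bwd_l(L[["out"]], cache[["out"]]$x, dz)
  grads[["out"]] <- list(dW = bw$dW, db = bw$db)
  da <- bw$dx
  conv_relu_bwd <- function(nm, da) {
    cc <- cache[[nm]]
    dz <- da * (cc$y > 0)
    bw <- conv_bwd_l(L[[nm]], cc$x, dz)
    grads[[nm]] <<- list(dW = bw$dW, db = bw$db)
    bw$dx
  }
  dskips <- vector("list", d - 1L)
  for (l in seq_len(d - 1L)) {
    da <- conv_relu_bwd(sprintf("dec%d_conv2", l), da)
    da <- conv_relu_bwd(sprintf("dec%d_conv1", l), da)
    cl <- L[[sprintf("dec%d_up", l)]]$cout
    dims <- dim(da)
    dskips[[l]] <- da[, , seq_len(cl), , drop = FALSE]
    dup <- da[, , cl + seq_len(dims[3] - cl), , drop = FALSE]
    dup <- conv_relu_bwd(sprintf("dec%d_up", l), dup)
    da <- upsample2_bwd(dup, dim(dup))
  }
  da <- conv_relu_bwd("bott_conv2", da)
  da <- conv_relu_bwd("bott_conv1", da)
  for (l in rev(seq_len(d - 1L))) {
    pl <- cache[[sprintf("pool%d", l)]]
    da <- maxpool2_bwd(pl$idx, da, prod(pl$xdim))
    dim(da) <- pl$xdim
    da <- da + dskips[[l]]
    da <- conv_relu_bwd(sprintf("enc%d_conv2", l), da)
    da <- conv_relu_bwd(sprintf("enc%d_conv1", l), da)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]; l <- layers[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
    layers[[nm]] <- l
  }
  list(layers = layers, state = state)
}

# stack a list of H x W matrices into an (H, W, 1, N) array
stack_batch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(H, W, 1L, length(mats)))
}

#' Build a training dataset from labelled records
#'
#' @param records records with `image` and `label` elements.
#' @return list with `x` (images) and `y` (contour class maps), both
#'   `(H, W, 1, N)` arrays.
#' @export
records_to_dataset <- function(records) {
  x <- stack_batch(lapply(records, function(r) as_pixels(r$image)))
  y <- stack_batch(lapply(records, function(r)
    label_to_classmap(r$label) * 1.0))
  list(x = x, y = y)
}

eval_batched <- function(model, x, y, batch) {
  N <- dim(x)[4]
  loss <- 0; acc <- 0
  for (s in seq(1L, N, by = batch)) {
    ix <- s:min(N, s + batch - 1L)
    xb <- x[, , , ix, drop = FALSE]
    yb <- y[, , , ix, drop = FALSE]
    fw <- unet_forward(model, xb)
    loss <- loss + bce_loss(fw$p, yb, model$config$pos_weight) * length(ix)
    acc <- acc + mean((fw$p > 0.5) == (yb > 0.5)) * length(ix)
  }
  c(loss = loss / N, acc = acc / N)
}

#' Train a U-Net on (image, contour class map) pairs
#'
#' Minimises binary cross entropy with Adam. A validation split of
#' `val_fraction` is carved from the dataset after a seeded shuffle;
#' training stops at `max_epochs` or once validation loss has not
#' improved for `early_stop_patience` epochs, and the weights of the
#' best validation epoch are restored. Fully deterministic given the
#' config seed.
#'
#' @param model a [build_unet()] model.
#' @param dataset list with `x` and `y` arrays of shape `(H, W, 1, N)`
#'   (see [records_to_dataset()]).
#' @param config optional [unet_config()] overriding the model's.
#' @return list with `model` (trained) and `history` (`data.frame` with
#'   epoch, train_loss, val_loss, train_acc, val_acc).
#' @export
train_unet <- function(model, dataset, config = NULL) {
  cfg <- config %||% model$config
  empty_hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0), train_acc = numeric(0),
                           val_acc = numeric(0))
  N <- dim(dataset$x)[4]
  if (is.null(N) || N < 1L) stop("empty dataset")
  if (cfg$max_epochs == 0L)
    return(list(model = model, history = empty_hist))
  # seeded shuffle before carving the validation split
  ord <- with_seed(derive_seed(cfg$seed, "valsplit"), sample.int(N))
  n_val <- if (N >= 2L) max(1L, round(cfg$val_fraction * N)) else 0L
  val_ix <- if (n_val > 0L) ord[seq_len(n_val)] else integer(0)
  tr_ix <- setdiff(ord, val_ix)
  xt <- dataset$x[, , , tr_ix, drop = FALSE]
  yt <- dataset$y[, , , tr_ix, drop = FALSE]
  xv <- if (n_val > 0L) dataset$x[, , , val_ix, drop = FALSE]
  yv <- if (n_val > 0L) dataset$y[, , , val_ix, drop = FALSE]
  nt <- length(tr_ix)
  layers <- model$layers
  state <- adam_init(layers)
  batch <- min(cfg$batch_size, nt)
  hist <- empty_hist
  best_loss <- Inf
  best_layers <- layers
  wait <- 0L
  t_step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ep_ord <- with_seed(derive_seed(cfg$seed, "epoch", epoch), sample.int(nt))
    tr_loss <- 0; tr_acc <- 0
    for (s in seq(1L, nt, by = batch)) {
      ix <- ep_ord[s:min(nt, s + batch - 1L)]
      xb <- xt[, , , ix, drop = FALSE]
      yb <- yt[, , , ix, drop = FALSE]
      m <- structure(list(config = cfg, layers = layers), class = "unet_model")
      fw <- unet_forward(m, xb, keep_cache = TRUE)
      tr_loss <- tr_loss + bce_loss(fw$p, yb, cfg$pos_weight) * length(ix)
      tr_acc <- tr_acc + mean((fw$p > 0.5) == (yb > 0.5)) * length(ix)
      grads <- unet_backward(m, fw$cache, fw$p, yb)
      t_step <- t_step + 1L
      upd <- adam_step(layers, grads, state, cfg$learning_rate, t_step)
      layers <- upd$layers
      state <- upd$state
    }
    m <- structure(list(config = cfg, layers = layers), class = "unet_model")
    val <- if (n_val > 0L) eval_batched(m, xv, yv, batch)
           else c(loss = tr_loss / nt, acc = tr_acc / nt)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tr_loss / nt,
                                   val_loss = unname(val["loss"]),
                                   train_acc = tr_acc / nt,
                                   val_acc = unname(val["acc"])))
    if (val["loss"] < best_loss - 1e-7) {
      best_loss <- val["loss"]
      best_layers <- layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$layers <- best_layers
  list(model = model, history = hist)
}

#' Predict the contour probability map of one image
#'
#' Images whose grid differs from the configured input size are
#' bilinearly resampled to the network size and the resulting map is
#' resampled back, so the returned map always matches the input grid.
#'
#' @param model a trained `unet_model`.
#' @param image an [Image2D] or matrix.
#' @return a [ProbabilityMap].
#' @export
predict_unet <- function(model, image) {
  img <- as_pixels(image)
  sz <- model$config$input_size
  h0 <- nrow(img); w0 <- ncol(img)
  if (h0 != sz || w0 != sz)
    img <- as.matrix(EBImage::resize(img, w = sz, h = sz))
  x <- array(img, c(sz, sz, 1L, 1L))
  p <- unet_forward(model, x)$p[, , 1L, 1L]
  if (h0 != sz || w0 != sz)
    p <- as.matrix(EBImage::resize(p, w = h0, h = w0))
  ProbabilityMap(clip01(p))
}

#' Predict probability maps for a batch of records
#'
#' @param model a trained `unet_model`.
#' @param records list of records with an `image` element.
#' @return list of [ProbabilityMap] objects.
#' @export
predict_records <- function(model, records) {
  lapply(records, function(r) predict_unet(model, r$image))
}
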