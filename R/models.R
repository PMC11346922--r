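#' Encoder specification
#'
#' Two encoder families share one contract (images in, pooled feature
#' vector out): `resnet50_standard`, the standard-width ResNet-50 used at
#' clinical scale (2048-dim pooled features), and `small_cnn`, a four-block
#' strided conv net with global average pooling for desk-scale CPU runs
#' (accepts inputs down to 32x32). Grayscale B-scans are replicated across
#' the channel count the encoder expects.
#'
#' @param architecture `"small_cnn"` or `"resnet50_standard"`.
#' @param input_size `(height, width, channels)` of expected input.
#' @param channels per-block channel widths (`small_cnn` only).
#' @param initial_weights `"random"` or a path to a checkpoint written by
#'   [save_checkpoint()] (how an externally pre-trained encoder, e.g.
#'   ImageNet-initialized, is supplied).
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(architecture = c("small_cnn", "resnet50_standard"),
                         input_size = c(64, 64, 1),
                         channels = c(8, 16, 32, 64),
                         initial_weights = "random") {
  architecture <- match.arg(architecture)
  if (length(input_size) != 3L) stop_config("input_size must be (H, W, channels)")
  if (architecture == "small_cnn" && any(input_size[1:2] < 32))
    stop_config("small_cnn accepts inputs down to 32x32")
  if (architecture == "resnet50_standard") input_size[3] <- 3L
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 initial_weights = initial_weights),
            class = "encoder_spec")
}

build_small_cnn <- function(spec) {
  ch <- c(spec$input_size[3], spec$channels)
  layers <- list()
  for (k in seq_along(spec$channels)) {
    layers <- c(layers, list(layer_conv(ch[k], ch[k + 1], kernel = 3L,
                                        stride = 2L, pad = 1L),
                             layer_relu()))
  }
  c(layers, list(layer_gap()))
}

resnet_bottleneck <- function(in_ch, mid_ch, out_ch, stride) {
  main <- list(layer_conv(in_ch, mid_ch, kernel = 1L, stride = 1L, pad = 0L),
               layer_bn(mid_ch), layer_relu(),
               layer_conv(mid_ch, mid_ch, kernel = 3L, stride = stride, pad = 1L),
               layer_bn(mid_ch), layer_relu(),
               layer_conv(mid_ch, out_ch, kernel = 1L, stride = 1L, pad = 0L),
               layer_bn(out_ch))
  shortcut <- if (in_ch != out_ch || stride != 1L)
    list(layer_conv(in_ch, out_ch, kernel = 1L, stride = stride, pad = 0L),
         layer_bn(out_ch)) else list()
  layer_residual(main, shortcut)
}

build_resnet50 <- function(spec) {
  layers <- list(layer_conv(3L, 64L, kernel = 7L, stride = 2L, pad = 3L),
                 layer_bn(64L), layer_relu(),
                 layer_maxpool(size = 3L, stride = 2L))
  stages <- list(c(64, 256, 3, 1), c(128, 512, 4, 2),
                 c(256, 1024, 6, 2), c(512, 2048, 3, 2))
  in_ch <- 64L
  for (s in stages) {
    mid <- s[1]; out <- s[2]; reps <- s[3]; stride <- s[4]
    for (r in seq_len(reps)) {
      layers <- c(layers, list(resnet_bottleneck(in_ch, mid, out,
                                                 if (r == 1) stride else 1L)))
      in_ch <- out
    }
  }
  c(layers, list(layer_gap()))
}

#' Build an encoder with deterministic initialization
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed; the same seed gives identical initial
#'   parameters.
#' @return An object of class `rascl_encoder` with fields `spec`, `layers`,
#'   `feature_dim`, `n_params`.
#' @export
build_encoder <- function(spec, seed = 1) {
  if (!inherits(spec, "encoder_spec")) stop_config("spec must be an encoder_spec")
  layers <- with_seed(seed, switch(spec$architecture,
    small_cnn = build_small_cnn(spec),
    resnet50_standard = build_resnet50(spec)))
  feature_dim <- switch(spec$architecture,
                        small_cnn = spec$channels[length(spec$channels)],
                        resnet50_standard = 2048L)
  enc <- structure(list(spec = spec, layers = layers,
                        feature_dim = as.integer(feature_dim),
                        n_params = length(layers_param_vector(layers))),
                   class = "rascl_encoder")
  if (!identical(spec$initial_weights, "random")) {
    ck <- load_checkpoint(spec$initial_weights)
    enc <- set_encoder_params(enc, ck$params)
  }
  enc
}

#' @export
print.rascl_encoder <- function(x, ...) {
  cat(sprintf("<rascl_encoder %s: input %s, feature_dim %d, %d parameters>\n",
              x$spec$architecture, paste(x$spec$input_size, collapse = "x"),
              x$feature_dim, x$n_params))
  invisible(x)
}

encoder_params <- function(encoder) layers_param_vector(encoder$layers)

set_encoder_params <- function(encoder, v) {
  if (length(v) != encoder$n_params)
    stop_config("parameter vector has wrong length")
  encoder$layers <- layers_set_param_vector(encoder$layers, v)$layers
  encoder
}

# Stack a list of matrices (or a single matrix) into an (H, W, C, N) array,
# replicating grayscale to the encoder's channel count.
stack_images <- function(images, channels = 1L) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, dim = c(H, W, channels, length(images)))
  for (n in seq_along(images)) {
    for (c in seq_len(channels)) x[, , c, n] <- images[[n]]
  }
  x
}

encoder_forward <- function(encoder, images, train = FALSE) {
  x <- stack_images(images, encoder$spec$input_size[3])
  seq_forward(encoder$layers, x, train)
}

#' Encode images into pooled feature vectors
#' @param encoder a [build_encoder()] result.
#' @param images a matrix, list of matrices, or `(H, W, C, N)` array.
#' @return An `N x feature_dim` matrix.
#' @export
encode_features <- function(encoder, images)
  encoder_forward(encoder, images, train = FALSE)$out

#' MLP head specification
#'
#' The trunk is three fully connected layers of 512 nodes each (ReLU
#' between layers). In `projection` mode the final 512-dim layer is the
#' output; in `classifier` mode a fresh 2-way softmax layer consumes the
#' final 512-dim layer.
#'
#' @param mode `"projection"` or `"classifier"`.
#' @param hidden_width nodes per hidden layer (default 512).
#' @param hidden_layers number of hidden layers (default 3).
#' @param n_classes classifier output classes (default 2).
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(mode = c("projection", "classifier"),
                      hidden_width = 512L, hidden_layers = 3L,
                      n_classes = 2L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, hidden_width = as.integer(hidden_width),
                 hidden_layers = as.integer(hidden_layers),
                 n_classes = as.integer(n_classes)),
            class = "head_spec")
}

#' Build an MLP head
#' @param spec a [head_spec()].
#' @param feature_dim input feature dimension (the encoder's).
#' @param seed integer seed for deterministic initialization.
#' @return An object of class `rascl_head`.
#' @export
build_head <- function(spec, feature_dim, seed = 1) {
  dims <- c(feature_dim, rep(spec$hidden_width, spec$hidden_layers))
  if (spec$mode == "classifier") dims <- c(dims, spec$n_classes)
  with_seed(seed, {
    Ws <- list(); bs <- list()
    for (k in seq_len(length(dims) - 1L)) {
      Ws[[k]] <- matrix(rnorm(dims[k] * dims[k + 1], 0, sqrt(2 / dims[k])),
                        dims[k], dims[k + 1])
      bs[[k]] <- numeric(dims[k + 1])
    }
    structure(list(spec = spec, W = Ws, b = bs), class = "rascl_head")
  })
}

head_params <- function(head)
  unlist(c(lapply(head$W, as.numeric), lapply(head$b, as.numeric)))

set_head_params <- function(head, v) {
  off <- 0L
  for (k in seq_along(head$W)) {
    n <- length(head$W[[k]])
    head$W[[k]] <- matrix(v[(off + 1):(off + n)], nrow(head$W[[k]]),
                          ncol(head$W[[k]]))
    off <- off + n
  }
  for (k in seq_along(head$b)) {
    n <- length(head$b[[k]])
    head$b[[k]] <- v[(off + 1):(off + n)]
    off <- off + n
  }
  head
}

# Forward through the MLP. Hidden layers use ReLU; the final layer is
# linear (projection output or classifier logits).
head_forward <- function(head, X) {
  caches <- list()
  A <- X
  L <- length(head$W)
  for (k in seq_len(L)) {
    Z <- sweep(A %*% head$W[[k]], 2, head$b[[k]], "+")
    if (k < L) {
      caches[[k]] <- list(A = A, mask = Z > 0)
      A <- Z * (Z > 0)
    } else {
      caches[[k]] <- list(A = A)
      A <- Z
    }
  }
  list(out = A, caches = caches)
}

head_backward <- function(head, caches, dOut) {
  L <- length(head$W)
  dW <- vector("list", L); db <- vector("list", L)
  d <- dOut
  for (k in rev(seq_len(L))) {
    if (k < L) d <- d * caches[[k]]$mask
    dW[[k]] <- crossprod(caches[[k]]$A, d)
    db[[k]] <- colSums(d)
    d <- d %*% t(head$W[[k]])
  }
  list(dX = d, dW = dW, db = db)
}

head_grad_vector <- function(g)
  unlist(c(lapply(g$dW, as.numeric), lapply(g$db, as.numeric)))

#' Project images to the contrastive embedding space
#' @param encoder a [build_encoder()] result.
#' @param projection_head a `projection`-mode [build_head()] result.
#' @param images matrix, list of matrices, or `(H, W, C, N)` array.
#' @return An `N x hidden_width` matrix of projection vectors.
#' @export
project <- function(encoder, projection_head, images) {
  if (projection_head$spec$mode != "projection")
    stop_config("head is not in projection mode")
  feats <- encode_features(encoder, images)
  head_forward(projection_head, feats)$out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Classify images into per-class softmax scores
#' @param encoder a [build_encoder()] result.
#' @param classifier_head a `classifier`-mode [build_head()] result.
#' @param images matrix, list of matrices, or `(H, W, C, N)` array.
#' @return An `N x n_classes` matrix of scores in `[0, 1]` with rows
#'   summing to 1; columns named `control`, `FTMH` for the binary case.
#' @export
classify <- function(encoder, classifier_head, images) {
  if (classifier_head$spec$mode != "classifier")
    stop_config("head is not in classifier mode")
  feats <- encode_features(encoder, images)
  P <- softmax_rows(head_forward(classifier_head, feats)$out)
  if (ncol(P) == 2L) colnames(P) <- c("control", "FTMH")
  P
}

#' Save a model checkpoint
#'
#' Self-describing archive: specification, flat parameter vector(s) and
#' training history, written with `saveRDS`.
#'
#' @param object a list with at least `spec` and `params` (plus anything
#'   else worth keeping, e.g. `history`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return The stored list.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_format("no checkpoint at ", path)
  readRDS(path)
}
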