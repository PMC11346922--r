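#' Pre-training configuration
#'
#' Training schedule for contrastive pre-training. The clinical-scale
#' protocol is 800 epochs validated every 10; desk-scale runs use fewer
#' epochs with the same structure. The optimizer is Adam (no schedule).
#'
#' @param epochs training epochs (one epoch visits each eligible eye about
#'   once).
#' @param val_interval validate every this many epochs.
#' @param lr Adam learning rate (default 1e-3).
#' @param train_slices_per_eye anchors are restricted to this many slices
#'   centered on the fovea (default 3, the declared training slices);
#'   `NULL` allows anchors anywhere.
#' @return An object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 100, val_interval = 10, lr = 1e-3,
                            train_slices_per_eye = 3L) {
  check_number(epochs, "epochs", lower = 1)
  check_number(val_interval, "val_interval", lower = 1)
  check_number(lr, "lr", lower = 1e-12)
  structure(list(epochs = as.integer(epochs),
                 val_interval = as.integer(val_interval), lr = lr,
                 train_slices_per_eye =
                   if (is.null(train_slices_per_eye)) NULL
                   else as.integer(train_slices_per_eye)),
            class = "pretrain_config")
}

#' Fine-tuning configuration
#'
#' Supervised fine-tuning of the MLP with binary cross-entropy, the
#' encoder frozen (the baseline mode keeps it trainable). Up to
#' `max_slices_per_eye` B-scans per eye centered on the fovea enter the
#' training set.
#'
#' @param epochs fine-tuning epochs.
#' @param val_interval validate every this many epochs.
#' @param lr Adam learning rate (default 1e-4).
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient on
#'   the MLP (default 0); regularizes the 3x512 head, which otherwise
#'   overfits small fold-training sets within a few epochs.
#' @param batch_size minibatch size.
#' @param encoder_mode `"frozen"` or `"trainable"`.
#' @param max_slices_per_eye training B-scans per eye (default 3).
#' @param augment logical: augment training slices each epoch (disables
#'   the frozen-feature cache); evaluation is never augmented.
#' @return An object of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 100, val_interval = 10, lr = 1e-4,
                            weight_decay = 0, batch_size = 32L,
                            encoder_mode = c("frozen", "trainable"),
                            max_slices_per_eye = 3L, augment = FALSE) {
  encoder_mode <- match.arg(encoder_mode)
  check_number(epochs, "epochs", lower = 1)
  check_number(val_interval, "val_interval", lower = 1)
  check_number(lr, "lr", lower = 1e-12)
  check_number(weight_decay, "weight_decay", lower = 0)
  check_number(batch_size, "batch_size", lower = 1)
  structure(list(epochs = as.integer(epochs),
                 val_interval = as.integer(val_interval), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 encoder_mode = encoder_mode,
                 max_slices_per_eye = as.integer(max_slices_per_eye),
                 augment = isTRUE(augment)),
            class = "finetune_config")
}

#' Checkpoint selection: minimal validation loss over accuracy
#'
#' Returns the index of the history record minimizing
#' `val_loss / val_accuracy` (maximal accuracy and minimal loss jointly).
#' Records with zero accuracy are treated as infinitely bad; ties go to
#' the earliest epoch.
#'
#' @param history a `data.frame` with columns `epoch`, `val_loss`,
#'   `val_accuracy` (as produced by [pretrain()] / [finetune_fold()]).
#' @return Integer row index of the selected record.
#' @export
select_checkpoint <- function(history) {
  if (is.null(history) || nrow(history) == 0)
    stop_domain("empty training history")
  crit <- ifelse(history$val_accuracy > 0,
                 history$val_loss / history$val_accuracy, Inf)
  if (all(is.infinite(crit)))
    stop_domain("no history record has positive validation accuracy")
  which.min(crit)  # which.min takes the earliest minimum
}

# top-1 positive-retrieval accuracy: fraction of views whose nearest
# neighbor (cosine) among the other 2N-1 views is their positive partner
retrieval_accuracy <- function(projections) {
  U <- projections / sqrt(rowSums(projections^2))
  S <- tcrossprod(U)
  diag(S) <- -Inf
  M <- nrow(S)
  partner <- ifelse(seq_len(M) %% 2L == 1L, seq_len(M) + 1L, seq_len(M) - 1L)
  mean(max.col(S, ties.method = "first") == partner)
}

#' Contrastive pre-training of an encoder
#'
#' Each epoch draws `floor(n_train_eyes / batch_pairs)` batches of
#' augmented slice pairs (one pair per eye, eyes without replacement
#' within a batch) and minimizes the NT-Xent loss with Adam over encoder
#' plus projection head. Every `val_interval` epochs a fixed validation
#' batch (built once from the validation eyes) is scored for loss and
#' top-1 positive-retrieval accuracy; the returned encoder is the
#' checkpoint selected by [select_checkpoint()].
#'
#' @param train_volumes,train_manifest training eyes.
#' @param val_volumes,val_manifest validation eyes.
#' @param encoder a [build_encoder()] result (its weights are the
#'   starting point).
#' @param contrastive a [contrastive_config()].
#' @param augmentation an [augmentation_config()] whose `output_size`
#'   matches the encoder input.
#' @param config a [pretrain_config()].
#' @param seed integer seed; fixed seed and data give identical history.
#' @return A list of class `rascl_pretrain_fit`: `encoder` (at the
#'   selected checkpoint), `projection_head`, `history` (`data.frame`),
#'   `selected_epoch`.
#' @export
pretrain <- function(train_volumes, train_manifest, val_volumes, val_manifest,
                     encoder, contrastive, augmentation, config, seed = 1) {
  N <- contrastive$batch_pairs
  n_eligible <- length(unique(train_manifest$patient_id))
  if (n_eligible < 2 * N)
    stop_config("need at least 2 * batch_pairs = ", 2 * N,
                " training patients, have ", n_eligible)
  head0 <- build_head(head_spec("projection"), encoder$feature_dim,
                      seed = derive_seed(seed, "proj_head"))
  enc_par <- encoder_params(encoder)
  head_par <- head_params(head0)
  n_enc <- length(enc_par)
  params <- c(enc_par, head_par)
  opt <- adam_init(length(params), lr = config$lr)
  steps_per_epoch <- max(1L, n_eligible %/% N)
  # fixed validation batch, built once
  val_N <- min(N, length(unique(val_manifest$patient_id)))
  if (val_N < 2) stop_config("need at least 2 validation patients")
  val_contrastive <- contrastive
  val_contrastive$batch_pairs <- as.integer(val_N)
  val_batch <- with_seed(derive_seed(seed, "valbatch"), {
    build_pair_batch(val_manifest, val_volumes, val_contrastive, augmentation,
                     anchor_window = NULL)
  })
  history <- list()
  snapshots <- list()
  with_seed(derive_seed(seed, "pretrain"), {
    for (epoch in seq_len(config$epochs)) {
      epoch_losses <- numeric(steps_per_epoch)
      for (step in seq_len(steps_per_epoch)) {
        encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
        phead <- set_head_params(head0, params[(n_enc + 1):length(params)])
        window <- if (is.null(config$train_slices_per_eye)) NULL else
          training_slices(train_volumes[[1]], config$train_slices_per_eye)
        batch <- build_pair_batch(train_manifest, train_volumes, contrastive,
                                  augmentation, anchor_window = window)
        efwd <- seq_forward(encoder$layers, batch$views, train = TRUE)
        hfwd <- head_forward(phead, efwd$out)
        lg <- nt_xent_loss(hfwd$out, contrastive$temperature,
                           return_grad = TRUE)
        epoch_losses[step] <- lg$loss
        hb <- head_backward(phead, hfwd$caches, lg$grad)
        eb <- seq_backward(encoder$layers, efwd$caches, hb$dX)
        grads <- c(layers_grad_vector(encoder$layers, eb$grads),
                   head_grad_vector(hb))
        st <- adam_step(opt, params, grads)
        opt <- st$state
        params <- st$params
      }
      if (epoch %% config$val_interval == 0) {
        encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
        phead <- set_head_params(head0, params[(n_enc + 1):length(params)])
        vproj <- head_forward(phead,
                              seq_forward(encoder$layers, val_batch$views,
                                          train = FALSE)$out)$out
        vloss <- nt_xent_loss(vproj, contrastive$temperature)
        vacc <- retrieval_accuracy(vproj)
        history[[length(history) + 1L]] <-
          data.frame(epoch = epoch, train_loss = mean(epoch_losses),
                     val_loss = vloss, val_accuracy = vacc)
        snapshots[[length(snapshots) + 1L]] <- params
      }
    }
  })
  history <- do.call(rbind, history)
  sel <- select_checkpoint(history)
  params <- snapshots[[sel]]
  encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
  phead <- set_head_params(head0, params[(n_enc + 1):length(params)])
  structure(list(encoder = encoder, projection_head = phead,
                 history = history, selected_epoch = history$epoch[sel]),
            class = "rascl_pretrain_fit")
}

#' @export
print.rascl_pretrain_fit <- function(x, ...) {
  cat(sprintf("<rascl_pretrain_fit: %d validation points, selected epoch %d (val loss %.4f, retrieval acc %.3f)>\n",
              nrow(x$history), x$selected_epoch,
              x$history$val_loss[x$history$epoch == x$selected_epoch],
              x$history$val_accuracy[x$history$epoch == x$selected_epoch]))
  invisible(x)
}

# assemble (images, labels, eye_ids) for supervised fitting: up to
# max_slices foveal B-scans per eye; labels TRUE = FTMH
supervised_samples <- function(volumes, manifest, max_slices) {
  images <- list(); labels <- logical(0); eye_ids <- character(0)
  for (i in seq_len(nrow(manifest))) {
    vol <- volumes[[manifest$eye_id[i]]]
    for (s in training_slices(vol, max_slices)) {
      images[[length(images) + 1L]] <- vol$slices[[s]]
      labels <- c(labels, manifest$diagnosis[i] == "FTMH")
      eye_ids <- c(eye_ids, manifest$eye_id[i])
    }
  }
  list(images = images, labels = labels, eye_ids = eye_ids)
}

# binary cross-entropy on two-way softmax logits; labels TRUE = class 2
bce_softmax <- function(logits, labels, return_grad = FALSE) {
  P <- softmax_rows(logits)
  eps <- 1e-12
  target_col <- ifelse(labels, 2L, 1L)
  loss <- -mean(log(pmax(P[cbind(seq_len(nrow(P)), target_col)], eps)))
  if (!return_grad) return(loss)
  Tm <- matrix(0, nrow(P), ncol(P))
  Tm[cbind(seq_len(nrow(P)), target_col)] <- 1
  list(loss = loss, grad = (P - Tm) / nrow(P))
}

#' Fine-tune a classifier head on one cross-validation fold
#'
#' Trains the MLP (3 x 512 trunk plus a fresh 2-way softmax layer) with
#' binary cross-entropy on up to three foveal B-scans per eye. In
#' `"frozen"` mode the encoder is bit-identical before and after and its
#' features are computed once; in `"trainable"` mode (the
#' transfer-learning baseline) encoder weights are updated too. The best
#' epoch is chosen by [select_checkpoint()] on the fold-validation
#' history.
#'
#' @param encoder a [build_encoder()] result.
#' @param fold_train,fold_val lists with `volumes` and `manifest`.
#' @param config a [finetune_config()].
#' @param augmentation an [augmentation_config()] used when
#'   `config$augment` is `TRUE` (and for resizing if the image size
#'   differs from the encoder input).
#' @param init_trunk optional projection-mode [build_head()] result (the
#'   pre-trained MLP): its three 512-unit layers initialize the classifier
#'   trunk, so the fresh 2-way softmax layer consumes the pre-trained
#'   projection space and the whole MLP is tuned from there. `NULL` starts
#'   the MLP from random initialization.
#' @param seed integer seed.
#' @return A list of class `rascl_finetune_fit`: `head` (at the selected
#'   epoch), `encoder` (identical to the input in frozen mode), `history`,
#'   `selected_epoch`.
#' @export
finetune_fold <- function(encoder, fold_train, fold_val, config,
                          augmentation = NULL, init_trunk = NULL, seed = 1) {
  if (nrow(fold_train$manifest) == 0 || nrow(fold_val$manifest) == 0)
    stop_config("empty fold")
  frozen <- config$encoder_mode == "frozen"
  tr <- supervised_samples(fold_train$volumes, fold_train$manifest,
                           config$max_slices_per_eye)
  va <- supervised_samples(fold_val$volumes, fold_val$manifest,
                           config$max_slices_per_eye)
  head0 <- build_head(head_spec("classifier"), encoder$feature_dim,
                      seed = derive_seed(seed, "cls_head"))
  if (!is.null(init_trunk)) {
    n_trunk <- length(init_trunk$W)
    if (n_trunk >= length(head0$W))
      stop_config("init_trunk must have fewer layers than the classifier head")
    for (k in seq_len(n_trunk)) {
      if (!identical(dim(head0$W[[k]]), dim(init_trunk$W[[k]])))
        stop_config("init_trunk layer ", k, " has incompatible dimensions")
      head0$W[[k]] <- init_trunk$W[[k]]
      head0$b[[k]] <- init_trunk$b[[k]]
    }
  }
  head_par <- head_params(head0)
  n_enc <- if (frozen) 0L else encoder$n_params
  params <- if (frozen) head_par else c(encoder_params(encoder), head_par)
  opt <- adam_init(length(params), lr = config$lr,
                   weight_decay = config$weight_decay %||% 0)
  n_tr <- length(tr$images)
  feats_cache <- NULL
  if (frozen && !config$augment)
    feats_cache <- encode_features(encoder, tr$images)
  va_feats <- encode_features(encoder, va$images)
  history <- list(); snapshots <- list()
  with_seed(derive_seed(seed, "finetune"), {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_tr)
      losses <- c()
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        ix <- perm[start:min(start + config$batch_size - 1L, n_tr)]
        if (length(ix) < 2L) next
        hd <- set_head_params(head0, params[(n_enc + 1):length(params)])
        if (frozen) {
          X <- if (!is.null(feats_cache)) feats_cache[ix, , drop = FALSE]
          else {
            imgs <- lapply(tr$images[ix], augment_view, config = augmentation)
            encode_features(encoder, imgs)
          }
          hfwd <- head_forward(hd, X)
          lg <- bce_softmax(hfwd$out, tr$labels[ix], return_grad = TRUE)
          hb <- head_backward(hd, hfwd$caches, lg$grad)
          grads <- head_grad_vector(hb)
        } else {
          encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
          imgs <- if (config$augment)
            lapply(tr$images[ix], augment_view, config = augmentation)
          else tr$images[ix]
          efwd <- encoder_forward(encoder, imgs, train = TRUE)
          hfwd <- head_forward(hd, efwd$out)
          lg <- bce_softmax(hfwd$out, tr$labels[ix], return_grad = TRUE)
          hb <- head_backward(hd, hfwd$caches, lg$grad)
          eb <- seq_backward(encoder$layers, efwd$caches, hb$dX)
          grads <- c(layers_grad_vector(encoder$layers, eb$grads),
                     head_grad_vector(hb))
        }
        losses <- c(losses, lg$loss)
        st <- adam_step(opt, params, grads)
        opt <- st$state
        params <- st$params
      }
      if (epoch %% config$val_interval == 0) {
        hd <- set_head_params(head0, params[(n_enc + 1):length(params)])
        vX <- if (frozen) va_feats else {
          encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
          encode_features(encoder, va$images)
        }
        vlogits <- head_forward(hd, vX)$out
        vloss <- bce_softmax(vlogits, va$labels)
        vpred <- softmax_rows(vlogits)[, 2] >= 0.5
        history[[length(history) + 1L]] <-
          data.frame(epoch = epoch, train_loss = mean(losses),
                     val_loss = vloss, val_accuracy = mean(vpred == va$labels))
        snapshots[[length(snapshots) + 1L]] <- params
      }
    }
  })
  history <- do.call(rbind, history)
  sel <- select_checkpoint(history)
  params <- snapshots[[sel]]
  if (!frozen) encoder <- set_encoder_params(encoder, params[seq_len(n_enc)])
  hd <- set_head_params(head0, params[(n_enc + 1):length(params)])
  structure(list(head = hd, encoder = encoder, history = history,
                 selected_epoch = history$epoch[sel]),
            class = "rascl_finetune_fit")
}

#' Train the cross-validated classifier ensemble
#'
#' One [finetune_fold()] per fold, each holding its fold out for
#' validation and checkpoint selection; members are combined as an
#' equal-weight averaged ensemble.
#'
#' @param encoder a [build_encoder()] result (shared by all members in
#'   frozen mode).
#' @param volumes named list of training [bscan_volume()].
#' @param manifest training manifest.
#' @param fold_assignment named fold index per eye id (from
#'   [stratified_kfold()]).
#' @param config a [finetune_config()].
#' @param augmentation optional [augmentation_config()].
#' @param init_trunk optional pre-trained projection head passed to every
#'   [finetune_fold()].
#' @param seed integer seed.
#' @return An object of class `rascl_ensemble`: `encoder`, `heads` (one
#'   per fold), `fold_histories`, `k`.
#' @export
train_ensemble <- function(encoder, volumes, manifest, fold_assignment,
                           config, augmentation = NULL, init_trunk = NULL,
                           seed = 1) {
  folds <- sort(unique(fold_assignment))
  heads <- list(); histories <- list(); encoders <- list()
  for (m in seq_along(folds)) {
    f <- folds[m]
    val_ids <- names(fold_assignment)[fold_assignment == f]
    train_ids <- names(fold_assignment)[fold_assignment != f]
    fit <- finetune_fold(
      encoder,
      fold_train = list(volumes = volumes[train_ids],
                        manifest = manifest[manifest$eye_id %in% train_ids, ,
                                            drop = FALSE]),
      fold_val = list(volumes = volumes[val_ids],
                      manifest = manifest[manifest$eye_id %in% val_ids, ,
                                          drop = FALSE]),
      config = config, augmentation = augmentation,
      init_trunk = init_trunk, seed = derive_seed(seed, "fold", f))
    heads[[m]] <- fit$head
    histories[[m]] <- fit$history
    encoders[[m]] <- fit$encoder
  }
  structure(list(encoder = encoder, heads = heads,
                 member_encoders = if (config$encoder_mode == "trainable")
                   encoders else NULL,
                 fold_histories = histories, k = length(folds)),
            class = "rascl_ensemble")
}

#' @export
print.rascl_ensemble <- function(x, ...) {
  cat(sprintf("<rascl_ensemble: %d equal-weight members, %s encoder>\n",
              x$k, if (is.null(x$member_encoders)) "shared frozen"
                   else "per-member trainable"))
  invisible(x)
}

#' Ensemble prediction: averaged softmax, threshold 0.5
#'
#' The FTMH score is the arithmetic mean of the members' FTMH softmax
#' scores (equal weights); the label is FTMH iff the score is `>= 0.5`.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param images matrix, list of matrices, or `(H, W, C, N)` array.
#' @return A `data.frame` with `score` and `label` (logical, `TRUE` =
#'   FTMH).
#' @export
ensemble_predict <- function(ensemble, images) {
  scores <- matrix(0, 0, 0)
  for (m in seq_len(ensemble$k)) {
    enc <- if (is.null(ensemble$member_encoders)) ensemble$encoder
           else ensemble$member_encoders[[m]]
    P <- classify(enc, ensemble$heads[[m]], images)
    if (m == 1) scores <- matrix(0, nrow(P), ensemble$k)
    scores[, m] <- P[, 2]
  }
  score <- rowMeans(scores)
  data.frame(score = score, label = score >= 0.5)
}

#' @rdname ensemble_predict
#' @param object,newdata,... S3 `predict` interface: `newdata` as
#'   `images`.
#' @export
predict.rascl_ensemble <- function(object, newdata, ...)
  ensemble_predict(object, newdata)
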