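#' Contrastive pre-training configuration
#'
#' Positive pairs are two B-scans of one eye at most `max_offset` slices
#' apart; every scan from a different (unrelated) eye in the batch is a
#' negative. `temperature` is the NT-Xent softmax temperature (the value is
#' a choice of this implementation, defaulting to the region SimCLR-style
#' training works well in).
#'
#' @param max_offset maximum slice offset D for positive pairs (>= 1;
#'   default 2, i.e. up to 2 slices away on either side).
#' @param temperature NT-Xent temperature (> 0; default 0.5).
#' @param batch_pairs number of positive pairs N per batch (>= 2).
#' @param boundary one of `"clip"` (near volume edges the offset support is
#'   clipped to in-bounds indices and renormalized; default) or
#'   `"resample"` (rejection-resample the anchor until all offsets fit).
#' @return An object of class `contrastive_config`.
#' @export
contrastive_config <- function(max_offset = 2L, temperature = 0.5,
                               batch_pairs = 16L,
                               boundary = c("clip", "resample")) {
  boundary <- match.arg(boundary)
  check_number(max_offset, "max_offset", lower = 1)
  check_number(temperature, "temperature", lower = 1e-12)
  check_number(batch_pairs, "batch_pairs", lower = 2)
  structure(list(max_offset = as.integer(max_offset),
                 temperature = temperature,
                 batch_pairs = as.integer(batch_pairs),
                 boundary = boundary),
            class = "contrastive_config")
}

# offset support for an anchor in a volume of n slices: {a+d : 1<=|d|<=D}
# intersected with 1..n (anchor itself excluded by construction)
offset_support <- function(anchor, n, D) {
  s <- anchor + c(-(D:1), 1:D)
  s[s >= 1 & s <= n]
}

#' Sample positive pair indices within one eye
#'
#' The anchor is uniform over eligible slices; the neighbor is uniform over
#' in-bounds indices at distance 1..D on either side (never the anchor
#' itself). Near volume edges the support is clipped and renormalized
#' (`boundary = "clip"`), or anchors without full support are rejected and
#' redrawn (`"resample"`; with `n_slices <= 2 * D` every anchor is clipped,
#' in which case clipping is used regardless).
#'
#' @param volume a [bscan_volume()], or an integer slice count.
#' @param D maximum offset (>= 1).
#' @param n_draws number of pairs to draw.
#' @param anchor_window optional integer vector of eligible anchor slice
#'   indices (1-based), e.g. the declared training slices.
#' @param boundary `"clip"` or `"resample"`.
#' @return An `n_draws x 2` integer matrix with columns `anchor`,
#'   `neighbor` (1-based slice indices).
#' @export
sample_positive_pair <- function(volume, D = 2L, n_draws = 1L,
                                 anchor_window = NULL,
                                 boundary = "clip") {
  n <- if (inherits(volume, "bscan_volume")) n_slices(volume)
       else as.integer(volume)
  if (n < 2L) stop_domain("cannot sample a positive pair from a 1-slice volume")
  D <- as.integer(D)
  anchors_all <- if (is.null(anchor_window)) seq_len(n)
                 else intersect(as.integer(anchor_window), seq_len(n))
  if (!length(anchors_all)) stop_domain("empty anchor window")
  if (boundary == "resample") {
    full <- anchors_all[anchors_all - D >= 1 & anchors_all + D <= n]
    if (length(full)) anchors_all <- full
  }
  support <- lapply(seq_len(n), offset_support, n = n, D = D)
  anchors <- anchors_all[sample.int(length(anchors_all), n_draws, replace = TRUE)]
  neighbors <- vapply(anchors, function(a) {
    s <- support[[a]]
    s[sample.int(length(s), 1L)]
  }, integer(1))
  cbind(anchor = anchors, neighbor = neighbors)
}

#' Build a contrastive batch of augmented slice-pair views
#'
#' Draws `batch_pairs` eyes without replacement — at most one eye per
#' patient, so every cross-pair view in the batch comes from an unrelated
#' eye — samples a positive slice pair per eye, and augments the two views
#' independently.
#'
#' @param manifest manifest `data.frame` for the eligible eyes.
#' @param volumes named list of [bscan_volume()] keyed by eye id.
#' @param config a [contrastive_config()].
#' @param aug_config an [augmentation_config()].
#' @param anchor_window optional eligible anchor indices (1-based),
#'   applied per eye.
#' @return An object of class `slice_pair_batch`: list with `views` (an
#'   `(H, W, 1, 2N)` array where views `2k-1, 2k` are the k-th positive
#'   pair), `eye_ids` (length `2N`), `anchor_index` and `offset` (per
#'   pair).
#' @export
build_pair_batch <- function(manifest, volumes, config, aug_config,
                             anchor_window = NULL) {
  N <- config$batch_pairs
  eligible <- manifest[manifest$eye_id %in% names(volumes), , drop = FALSE]
  eligible <- eligible[vapply(eligible$eye_id,
                              function(id) n_slices(volumes[[id]]) >= 2L,
                              logical(1)), , drop = FALSE]
  patients <- unique(eligible$patient_id)
  if (length(patients) < N)
    stop_domain("need ", N, " eligible patients with >= 2 slices, have ",
                length(patients))
  chosen_pat <- sample(patients, N)
  eye_ids <- vapply(chosen_pat, function(p) {
    eyes <- eligible$eye_id[eligible$patient_id == p]
    if (length(eyes) == 1L) eyes else sample(eyes, 1L)
  }, character(1))
  first <- volumes[[eye_ids[1]]]$slices[[1]]
  H <- aug_config$output_size[1]; W <- aug_config$output_size[2]
  views <- array(0, dim = c(H, W, 1L, 2L * N))
  anchor_index <- integer(N); offset <- integer(N)
  batch_eye_ids <- character(2L * N)
  for (k in seq_len(N)) {
    vol <- volumes[[eye_ids[k]]]
    pair <- sample_positive_pair(vol, config$max_offset, 1L,
                                 anchor_window = anchor_window,
                                 boundary = config$boundary)
    anchor_index[k] <- pair[1, "anchor"]
    offset[k] <- pair[1, "neighbor"] - pair[1, "anchor"]
    views[, , 1L, 2L * k - 1L] <-
      augment_view(vol$slices[[pair[1, "anchor"]]], aug_config)
    views[, , 1L, 2L * k] <-
      augment_view(vol$slices[[pair[1, "neighbor"]]], aug_config)
    batch_eye_ids[c(2L * k - 1L, 2L * k)] <- eye_ids[k]
  }
  structure(list(views = views, eye_ids = batch_eye_ids,
                 anchor_index = anchor_index, offset = offset),
            class = "slice_pair_batch")
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For `2N` projections ordered so rows `2k-1, 2k` are a positive pair,
#' with cosine similarity `sim` and temperature `tau`:
#' `l(i, j) = -log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`,
#' and the loss is the mean of `l` over both directions of all `N` pairs.
#' Projections are L2-normalized internally, so the loss is invariant to a
#' positive rescaling of any single projection.
#'
#' @param projections a `2N x d` numeric matrix (`2N >= 4`, no zero rows).
#' @param tau temperature (> 0).
#' @param return_grad if `TRUE`, also return the gradient with respect to
#'   the (unnormalized) projections.
#' @return The scalar loss, or (with `return_grad`) a list with `loss` and
#'   `grad` (same shape as `projections`).
#' @export
nt_xent_loss <- function(projections, tau = 0.5, return_grad = FALSE) {
  Z <- as.matrix(projections)
  M <- nrow(Z)
  if (M < 4L || M %% 2L != 0L)
    stop_domain("projections must have 2N >= 4 rows")
  if (tau <= 0) stop_domain("temperature must be > 0")
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) stop_domain("zero-norm projection")
  U <- Z / norms
  S <- tcrossprod(U) / tau
  diag(S) <- -Inf
  partner <- ifelse(seq_len(M) %% 2L == 1L, seq_len(M) + 1L, seq_len(M) - 1L)
  # stable log-softmax per row
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  denom <- rowSums(E)
  logp <- (S - mx) - log(denom)
  loss <- -mean(logp[cbind(seq_len(M), partner)])
  if (!return_grad) return(loss)
  P <- E / denom
  Tm <- matrix(0, M, M)
  Tm[cbind(seq_len(M), partner)] <- 1
  G <- (P - Tm) / M          # dL/dS (rows are softmax rows)
  dU <- (G + t(G)) %*% U / tau
  # back through row-normalization u = z / ||z||
  dZ <- (dU - U * rowSums(dU * U)) / norms
  list(loss = loss, grad = dZ)
}
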