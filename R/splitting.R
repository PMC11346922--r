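#' Covariate balance objective of a fold assignment
#'
#' For each fold and each stratification feature, the objective adds
#' `|fold mean - overall mean| / scale + |fold SD - overall SD| / scale`,
#' with `scale` the overall SD of the feature (population SD, so that a
#' fold duplicating the overall distribution scores exactly zero). Sex is
#' encoded ordinally (F = 0, M = 1) before moments; diagnosis is encoded
#' as FTMH = 1 vs 0. The objective is >= 0, is 0 only when every fold
#' matches the overall moments exactly, and is invariant to fold
#' relabeling.
#'
#' @param assignment integer fold index (1-based) per manifest row.
#' @param manifest manifest `data.frame`.
#' @param features character vector among `"diagnosis"`, `"age"`, `"sex"`,
#'   `"preop_vision"`.
#' @return Scalar objective value.
#' @export
balance_objective <- function(assignment, manifest,
                              features = c("diagnosis", "age", "sex",
                                           "preop_vision")) {
  if (length(assignment) != nrow(manifest))
    stop_config("assignment must cover every manifest row")
  X <- encode_features_matrix(manifest, features)
  objective_on_matrix(assignment, X)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

objective_on_matrix <- function(assignment, X) {
  total <- 0
  folds <- unique(assignment)
  for (f in seq_len(ncol(X))) {
    v <- X[, f]
    mu <- mean(v)
    s <- pop_sd(v)
    scale <- if (is.na(s) || s == 0) 1 else s
    for (k in folds) {
      vk <- v[assignment == k]
      total <- total + abs(mean(vk) - mu) / scale +
        abs(pop_sd(vk) - s) / scale
    }
  }
  total
}

encode_features_matrix <- function(manifest, features) {
  cols <- lapply(features, function(f) {
    switch(f,
      diagnosis = as.numeric(manifest$diagnosis == "FTMH"),
      age = as.numeric(manifest$age),
      sex = as.numeric(manifest$sex == "M"),
      preop_vision = as.numeric(manifest$preop_vision),
      stop_config("unknown stratification feature: ", f))
  })
  do.call(cbind, cols)
}

#' Build replicate-level train/test split plans
#'
#' Each replicate holds out a class-exact test set (default 10 FTMH + 40
#' control eyes, about 15\% of the study cohort); test sets are pairwise
#' disjoint across replicates, and both eyes of a patient always fall on
#' the same side of the split.
#'
#' @param manifest cohort manifest `data.frame` (diagnoses FTMH/ERM).
#' @param n_replicates number of replicates (default 3).
#' @param test_counts named vector `c(FTMH = ..., control = ...)` of test
#'   eyes per class.
#' @param seed integer seed.
#' @return A list of `split_plan` objects, each with `replicate_id`,
#'   `test_eye_ids`, `train_eye_ids` and (initially `NULL`)
#'   `fold_assignment`.
#' @export
make_replicates <- function(manifest, n_replicates = 3,
                            test_counts = c(FTMH = 10, control = 40),
                            seed = 1) {
  stopifnot(all(c("FTMH", "control") %in% names(test_counts)))
  is_ftmh <- manifest$diagnosis == "FTMH"
  avail <- c(FTMH = sum(is_ftmh), control = sum(!is_ftmh))
  need <- n_replicates * test_counts
  for (cl in names(test_counts)) {
    if (need[[cl]] > avail[[cl]])
      stop_config("insufficient ", cl, " eyes: need ", need[[cl]],
                  " across replicates, have ", avail[[cl]])
  }
  with_seed(seed, {
    used <- character(0)
    plans <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      test_ids <- character(0)
      quota <- test_counts
      # patient-grouped greedy fill: visit patients in random order, take all
      # their eyes if they fit the remaining per-class quota
      pool <- manifest[!(manifest$eye_id %in% used), , drop = FALSE]
      pats <- sample(unique(pool$patient_id))
      for (p in pats) {
        eyes <- pool[pool$patient_id == p, , drop = FALSE]
        cls <- ifelse(eyes$diagnosis == "FTMH", "FTMH", "control")
        cnt <- table(factor(cls, levels = names(quota)))
        if (all(cnt <= quota)) {
          test_ids <- c(test_ids, eyes$eye_id)
          quota <- quota - as.numeric(cnt)
        }
        if (all(quota == 0)) break
      }
      if (!all(quota == 0))
        stop_config("could not assemble a class-exact test set for replicate ",
                    r, " (patient grouping left class quota unmet)")
      used <- c(used, test_ids)
      plans[[r]] <- structure(
        list(replicate_id = r,
             test_eye_ids = sort(test_ids),
             train_eye_ids = sort(setdiff(manifest$eye_id, test_ids)),
             fold_assignment = NULL),
        class = "split_plan")
    }
    plans
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan replicate %d: %d test eyes, %d train eyes%s>\n",
              x$replicate_id, length(x$test_eye_ids), length(x$train_eye_ids),
              if (is.null(x$fold_assignment)) ", folds unassigned"
              else sprintf(", %d folds", length(unique(x$fold_assignment)))))
  invisible(x)
}

# per-fold diagnosis counts within +-1 of exact proportionality (total/k)
fold_counts_ok <- function(assignment, is_ftmh, k) {
  for (cls in list(is_ftmh, !is_ftmh)) {
    cnt <- tabulate(assignment[cls], nbins = k)
    if (any(abs(cnt - sum(cls) / k) > 1)) return(FALSE)
  }
  TRUE
}

#' Covariate-balanced stratified k-fold assignment
#'
#' Partitions the training eyes into `k` folds, keeping both eyes of a
#' patient in one fold, holding per-fold diagnosis counts within one eye
#' of exact proportionality (hard constraint), and among assignments
#' satisfying it minimizing the [balance_objective()] over age, sex
#' (ordinal) and pre-operative vision by random-restart greedy pairwise
#' swaps of patient groups.
#'
#' @param manifest training-set manifest `data.frame`.
#' @param k number of folds (default 8).
#' @param features stratification features (diagnosis is always the
#'   primary, count-constrained feature).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 50).
#' @param n_swaps candidate swaps per restart (default 500).
#' @return Named integer vector: fold index (1..k) per eye id.
#' @export
stratified_kfold <- function(manifest, k = 8,
                             features = c("diagnosis", "age", "sex",
                                          "preop_vision"),
                             seed = 1, n_restarts = 50, n_swaps = 500) {
  if (k < 2) stop_config("k must be >= 2")
  groups <- split(seq_len(nrow(manifest)), manifest$patient_id)
  if (k > length(groups))
    stop_config("k = ", k, " exceeds the number of patient groups (",
                length(groups), ")")
  is_ftmh <- manifest$diagnosis == "FTMH"
  grp_class <- vapply(groups, function(ix) mean(is_ftmh[ix]) >= 0.5, logical(1))
  grp_size <- vapply(groups, length, integer(1))
  X <- encode_features_matrix(manifest, features)
  with_seed(seed, {
    best_assign <- NULL
    best_obj <- Inf
    for (rs in seq_len(n_restarts)) {
      assign_grp <- integer(length(groups))
      # deal each class's groups (bilateral first) to the emptiest fold
      for (cls in c(TRUE, FALSE)) {
        idx <- which(grp_class == cls)
        idx <- idx[order(-grp_size[idx], runif(length(idx)))]
        cnt <- numeric(k)
        for (g in idx) {
          f <- which.min(cnt + runif(k) * 1e-9)
          assign_grp[g] <- f
          cnt[f] <- cnt[f] + grp_size[g]
        }
      }
      assignment <- integer(nrow(manifest))
      for (g in seq_along(groups)) assignment[groups[[g]]] <- assign_grp[g]
      if (!fold_counts_ok(assignment, is_ftmh, k)) next
      obj <- objective_on_matrix(assignment, X)
      for (sw in seq_len(n_swaps)) {
        g1 <- sample.int(length(groups), 1L)
        g2 <- sample.int(length(groups), 1L)
        if (assign_grp[g1] == assign_grp[g2]) next
        cand_grp <- assign_grp
        cand_grp[c(g1, g2)] <- cand_grp[c(g2, g1)]
        cand <- assignment
        cand[groups[[g1]]] <- cand_grp[g1]
        cand[groups[[g2]]] <- cand_grp[g2]
        if (!fold_counts_ok(cand, is_ftmh, k)) next
        cand_obj <- objective_on_matrix(cand, X)
        if (cand_obj < obj) {
          assign_grp <- cand_grp
          assignment <- cand
          obj <- cand_obj
        }
      }
      if (obj < best_obj) {
        best_obj <- obj
        best_assign <- assignment
      }
    }
    if (is.null(best_assign))
      stop_config("no fold assignment satisfied the diagnosis count constraint")
    setNames(best_assign, manifest$eye_id)
  })
}

#' Attach an 8-fold assignment to each replicate's training set
#' @param plans list of `split_plan` from [make_replicates()].
#' @param manifest cohort manifest.
#' @param k folds (default 8).
#' @param seed integer seed.
#' @param ... passed to [stratified_kfold()].
#' @return The plans with `fold_assignment` filled in.
#' @export
assign_folds <- function(plans, manifest, k = 8, seed = 1, ...) {
  for (r in seq_along(plans)) {
    train_m <- manifest[manifest$eye_id %in% plans[[r]]$train_eye_ids, ,
                        drop = FALSE]
    plans[[r]]$fold_assignment <-
      stratified_kfold(train_m, k = k, seed = derive_seed(seed, "folds", r), ...)
  }
  plans
}
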