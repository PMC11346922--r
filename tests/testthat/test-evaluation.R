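# Confusion metrics, ROC/AUC against the Mann-Whitney oracle, challenge
# evaluation, saliency maps.

test_that("confusion counts follow the >= threshold rule", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 40))
  scores <- c(rep(0.9, 10), rep(0.1, 40))
  cc <- confusion_counts(labels, scores, 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 10, fp = 0, fn = 0, tn = 40))
  # boundary: everything at the threshold is predicted positive
  cc2 <- confusion_counts(c(TRUE, FALSE), c(0.5, 0.5), 0.5)
  expect_equal(cc2$tp + cc2$fp, 2)
  # empty input gives zero counts
  cc3 <- confusion_counts(logical(0), numeric(0))
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 0)
  expect_error(confusion_counts(c(TRUE), c(0.1, 0.2)), "equal length")
})

test_that("classification rates match hand arithmetic and flag 0/0", {
  m <- classification_metrics(confusion_counts(
    c(rep(TRUE, 10), rep(FALSE, 40)),
    c(rep(0.9, 10), rep(0.1, 40))))
  expect_equal(c(m$precision, m$sensitivity, m$specificity, m$f1),
               c(1, 1, 1, 1))
  m2 <- classification_metrics(structure(
    list(tp = 7, fp = 0, fn = 3, tn = 40), class = "confusion_counts"))
  expect_equal(m2$precision, 1)
  expect_equal(m2$sensitivity, 0.7)
  expect_equal(m2$f1, 14 / 17)
  m3 <- classification_metrics(structure(
    list(tp = 0, fp = 0, fn = 5, tn = 40), class = "confusion_counts"))
  expect_true("precision" %in% m3$degenerate)
  expect_equal(m3$sensitivity, 0)
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle with ties", {
  set.seed(31)
  for (r in 1:30) {
    n <- sample(6:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    # quantized scores force ties
    scores <- round(runif(n), 1)
    roc <- roc_curve_auc(labels, scores)
    expect_equal(roc$auc, auc_oracle(labels, scores), tolerance = 1e-10)
  }
})

test_that("AUC hits its trivial anchors and rejects one-class input", {
  expect_equal(roc_curve_auc(c(TRUE, TRUE, FALSE, FALSE),
                             c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_curve_auc(c(TRUE, FALSE, TRUE, FALSE),
                             rep(0.5, 4))$auc, 0.5)
  expect_error(roc_curve_auc(c(TRUE, TRUE), c(0.1, 0.2)), "both classes")
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (r in 1:10) {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 20, replace = TRUE))
    scores <- round(runif(22), 1)
    ours <- roc_curve_auc(labels, scores)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("replicate aggregation prints mean +- SD in table format", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 40))
  scores <- c(rep(0.9, 10), rep(0.1, 40))
  reps <- replicate(3, metrics_report(labels, scores), simplify = FALSE)
  agg <- aggregate_replicates(reps)
  f1_row <- agg[agg$metric == "f1_ftmh", ]
  expect_equal(f1_row$mean, 1)
  expect_equal(f1_row$sd, 0)
  expect_match(f1_row$formatted, "^1\\.000 . 0\\.000$")
})

test_that("per-class F1 treats each class as positive in turn", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  scores <- c(0.9, 0.8, 0.2, 0.6, 0.1, 0.1, 0.1)
  rep <- metrics_report(labels, scores)
  # FTMH: tp=2 fp=1 fn=1 tn=3
  expect_equal(rep$ftmh$precision, 2 / 3)
  expect_equal(rep$ftmh$sensitivity, 2 / 3)
  # control: tp=3 fp=1 fn=1 tn=2
  expect_equal(rep$control$precision, 3 / 4)
  expect_equal(rep$control$sensitivity, 3 / 4)
})

test_that("challenge evaluation scores FTMH-negative as correct", {
  ch <- tiny_cohort(n_ftmh = 3, n_erm = 9, seed = 41)
  plans <- make_replicates(ch$manifest, 1, c(FTMH = 1, control = 3), seed = 42)
  plans <- assign_folds(plans, ch$manifest, k = 2, seed = 42,
                        n_restarts = 2, n_swaps = 20)
  enc <- build_encoder(encoder_spec("small_cnn", c(32, 32, 1)), seed = 5)
  fc <- finetune_config(epochs = 4, val_interval = 2, lr = 1e-3)
  ens <- train_ensemble(enc, ch$volumes[plans[[1]]$train_eye_ids],
                        ch$manifest[ch$manifest$eye_id %in%
                                      plans[[1]]$train_eye_ids, ],
                        plans[[1]]$fold_assignment, fc, seed = 6)
  lam <- generate_challenge_set(cohort_config(n_lamellar = 3,
                                              image_height = 32,
                                              image_width = 32,
                                              n_slices = 5), seed = 43)
  res <- evaluate_challenge(ens, lam$volumes)
  expect_equal(res$accuracy, mean(!res$predictions$label))
  expect_equal(nrow(res$predictions), 3)
  expect_error(evaluate_challenge(ens, list()), "empty")
})

test_that("input-gradient saliency of a linear model is analytic", {
  # single 1x1-conv 'network': class logit = sum(w * image) per channel
  enc <- build_encoder(encoder_spec("small_cnn", c(32, 32, 1),
                                    channels = c(4)), seed = 8)
  head <- build_head(head_spec("classifier", hidden_layers = 1,
                               hidden_width = 4), 4, seed = 9)
  img <- matrix(runif(32 * 32), 32)
  s1 <- saliency_map(enc, head, img, target_class = 2, method = "input_grad")
  expect_equal(dim(s1), dim(img))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(max(s1), 1)
  # determinism
  s2 <- saliency_map(enc, head, img, target_class = 2, method = "input_grad")
  expect_identical(s1, s2)
  expect_error(saliency_map(enc, head, img, target_class = 5), "class")
})

test_that("grad-cam maps are input-sized, in [0,1], and flat for zero weights", {
  enc <- build_encoder(encoder_spec("small_cnn", c(32, 32, 1)), seed = 10)
  head <- build_head(head_spec("classifier"), enc$feature_dim, seed = 11)
  img <- matrix(runif(32 * 32), 32)
  g <- saliency_map(enc, head, img, target_class = 2, method = "gradcam")
  expect_equal(dim(g), dim(img))
  expect_true(all(g >= 0 & g <= 1))
  zero_head <- head
  for (k in seq_along(zero_head$W)) zero_head$W[[k]][] <- 0
  gz <- saliency_map(enc, zero_head, img, target_class = 2,
                     method = "gradcam")
  expect_true(all(gz == 0))
})
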