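# Positive-pair sampling law and the NT-Xent contrastive objective.

test_that("NT-Xent matches its closed forms", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  # two orthogonal pairs: every view has sim 1 to its partner, 0 to others
  expect_equal(nt_xent_loss(rbind(e1, e1, e2, e2), tau = 1),
               log(1 + 2 / exp(1)), tolerance = 1e-12)
  # all four projections identical: all similarities equal
  expect_equal(nt_xent_loss(rbind(e1, e1, e1, e1), tau = 1), log(3),
               tolerance = 1e-12)
})

test_that("NT-Xent equals the double-loop oracle on random batches", {
  set.seed(11)
  for (N in c(2, 3, 4)) {
    for (tau in c(0.1, 0.5, 1)) {
      for (r in 1:5) {
        Z <- matrix(rnorm(2 * N * 6), 2 * N)
        expect_equal(nt_xent_loss(Z, tau), ntxent_oracle(Z, tau),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("NT-Xent is scale-invariant per projection and symmetric", {
  set.seed(12)
  Z <- matrix(rnorm(8 * 5), 8)
  l0 <- nt_xent_loss(Z, 0.5)
  Z2 <- Z; Z2[3, ] <- 7.5 * Z2[3, ]
  expect_equal(nt_xent_loss(Z2, 0.5), l0, tolerance = 1e-12)
  # permuting whole pairs leaves the loss unchanged
  perm <- c(5, 6, 1, 2, 7, 8, 3, 4)
  expect_equal(nt_xent_loss(Z[perm, ], 0.5), l0, tolerance = 1e-12)
  # swapping the two views within a pair too
  swap <- c(2, 1, 3, 4, 5, 6, 7, 8)
  expect_equal(nt_xent_loss(Z[swap, ], 0.5), l0, tolerance = 1e-12)
})

test_that("raising a positive pair's similarity never increases the loss", {
  set.seed(13)
  Z <- matrix(rnorm(8 * 4), 8)
  l0 <- nt_xent_loss(Z, 0.5)
  # move view 2 toward its partner view 1
  Z2 <- Z
  u1 <- Z[1, ] / sqrt(sum(Z[1, ]^2))
  Z2[2, ] <- 0.5 * Z[2, ] / sqrt(sum(Z[2, ]^2)) + 0.5 * u1
  expect_lte(nt_xent_loss(Z2, 0.5), l0)
})

test_that("NT-Xent analytic gradient matches finite differences", {
  set.seed(14)
  Z <- matrix(rnorm(6 * 4), 6)
  g <- nt_xent_loss(Z, 0.3, return_grad = TRUE)$grad
  eps <- 1e-6
  for (i in sample(length(Z), 8)) {
    Zp <- Z; Zp[i] <- Zp[i] + eps
    Zm <- Z; Zm[i] <- Zm[i] - eps
    expect_equal(g[i], (nt_xent_loss(Zp, 0.3) - nt_xent_loss(Zm, 0.3)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("NT-Xent rejects degenerate inputs", {
  expect_error(nt_xent_loss(matrix(rnorm(2 * 3), 2), 0.5), "2N")
  expect_error(nt_xent_loss(rbind(c(1, 0), c(0, 0), c(0, 1), c(1, 1)), 0.5),
               "zero-norm")
  expect_error(nt_xent_loss(matrix(rnorm(4 * 3), 4), 0), "temperature")
})

test_that("gradient descent on a fixed batch strictly decreases the loss", {
  set.seed(15)
  X <- matrix(rnorm(8 * 10), 8)       # fixed inputs
  W <- matrix(rnorm(10 * 4, 0, 0.3), 10)  # linear projection model
  losses <- numeric(100)
  lr <- 0.05
  for (it in 1:100) {
    Z <- X %*% W
    lg <- nt_xent_loss(Z, 0.5, return_grad = TRUE)
    losses[it] <- lg$loss
    W <- W - lr * crossprod(X, lg$grad)
  }
  expect_lt(losses[100], losses[1])
  expect_true(all(diff(losses) < 1e-8))  # non-increasing throughout
})

test_that("positive-pair sampler never returns the anchor and stays in range", {
  vol_n <- 5
  draws <- sample_positive_pair(vol_n, D = 2, n_draws = 500)
  expect_true(all(draws[, "neighbor"] != draws[, "anchor"]))
  expect_true(all(abs(draws[, "neighbor"] - draws[, "anchor"]) <= 2))
  expect_true(all(draws >= 1 & draws <= vol_n))
  expect_error(sample_positive_pair(1, D = 2), "1-slice")
})

test_that("sampler offset law matches renormalized-uniform enumeration", {
  # anchor fixed via anchor_window; support enumerated under clipping
  set.seed(16)
  for (n in c(3, 5)) {
    for (D in c(1, 2)) {
      for (a in c(1, (n + 1) %/% 2)) {
        support <- setdiff(intersect(a + c(-(D:1), 1:D), seq_len(n)), a)
        draws <- sample_positive_pair(n, D = D, n_draws = 4000,
                                      anchor_window = a)
        obs <- table(factor(draws[, "neighbor"], levels = support))
        if (length(support) > 1) {
          p <- suppressWarnings(chisq.test(obs)$p.value)
          expect_gt(p, 0.001)
        }
        expect_setequal(unique(draws[, "neighbor"]), support)
      }
    }
  }
})

test_that("pair batches have correct structure and patient disjointness", {
  ch <- tiny_cohort(n_ftmh = 2, n_erm = 8, seed = 21)
  con <- contrastive_config(batch_pairs = 4)
  aug <- tiny_aug()
  set.seed(1)
  b <- build_pair_batch(ch$manifest, ch$volumes, con, aug)
  expect_equal(dim(b$views)[4], 8)
  ids <- b$eye_ids
  expect_equal(length(unique(ids)), 4)
  # views (2k-1, 2k) share an eye; all pairs distinct eyes
  expect_true(all(ids[c(1, 3, 5, 7)] == ids[c(2, 4, 6, 8)]))
  expect_true(all(abs(b$offset) >= 1 & abs(b$offset) <= con$max_offset))
  # at most one eye per patient in a batch
  pats <- ch$manifest$patient_id[match(unique(ids), ch$manifest$eye_id)]
  expect_equal(length(unique(pats)), 4)
  # a manifest where patients < batch_pairs errors
  two_pat <- ch$manifest[1:2, ]
  two_pat$patient_id <- "patX"
  expect_error(build_pair_batch(two_pat, ch$volumes[two_pat$eye_id],
                                contrastive_config(batch_pairs = 2), aug),
               "eligible")
  # determinism under a fixed seed
  set.seed(99); b1 <- build_pair_batch(ch$manifest, ch$volumes, con, aug)
  set.seed(99); b2 <- build_pair_batch(ch$manifest, ch$volumes, con, aug)
  expect_identical(b1, b2)
})
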