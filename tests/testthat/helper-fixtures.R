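# Small fixtures built in code, shared across test files.

tiny_cohort <- function(n_ftmh = 4, n_erm = 12, size = 32, n_slices = 5,
                        seed = 1, speckle = 0.3) {
  cfg <- cohort_config(n_ftmh = n_ftmh, n_erm = n_erm,
                       image_height = size, image_width = size,
                       n_slices = n_slices, speckle_sigma = speckle)
  generate_cohort(cfg, seed = seed)
}

tiny_aug <- function(size = 32)
  augmentation_config(noise_mu_range = c(-0.05, 0.075),
                      noise_var_range = c(0, 0.05),
                      crop_area_range = c(0.7, 1),
                      brightness_delta_range = c(-0.1, 0.1),
                      contrast_factor_range = c(0.9, 1.1),
                      output_size = c(size, size))

# independently coded double-loop NT-Xent oracle (kept deliberately naive)
ntxent_oracle <- function(Z, tau) {
  M <- nrow(Z)
  U <- Z
  for (i in seq_len(M)) U[i, ] <- Z[i, ] / sqrt(sum(Z[i, ]^2))
  sim <- function(i, j) sum(U[i, ] * U[j, ])
  partner <- function(i) if (i %% 2 == 1) i + 1 else i - 1
  total <- 0
  for (i in seq_len(M)) {
    denom <- 0
    for (k in seq_len(M)) if (k != i) denom <- denom + exp(sim(i, k) / tau)
    total <- total - log(exp(sim(i, partner(i)) / tau) / denom)
  }
  total / M
}

# brute-force Mann-Whitney U / (n+ * n-) with ties counted half
auc_oracle <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  u <- 0
  for (p in pos) for (n in neg) u <- u + (p > n) + 0.5 * (p == n)
  u / (length(pos) * length(neg))
}
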