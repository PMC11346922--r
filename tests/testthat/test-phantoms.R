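# Synthetic retina phantoms: lesion rendering, cohort statistics,
# within-eye coherence, class separability, reproducibility.

test_that("FTMH phantoms carry a full-thickness foveal defect", {
  p <- retina_phantom_params(64, 64, 7, "ftmh", lesion_width = 8,
                             speckle_sigma = 0)
  e <- generate_eye(p, seed = 3)
  vol <- e$volume
  img <- central_slice(vol)
  b <- vol$layer_bounds[[vol$central]]
  inner_mean <- vapply(seq_len(ncol(img)), function(j) {
    rows <- seq(ceiling(b$ilm[j]) + 1, floor(b$rpe[j]) - 1)
    mean(img[rows, j])
  }, numeric(1))
  dark <- which(inner_mean < 0.05)
  expect_gte(length(dark), 8)                      # >= lesion_width columns
  expect_true(all(diff(dark) == 1))                # contiguous band
  flank <- setdiff(seq_len(ncol(img)), dark)
  # flanking columns away from the pit keep layered signal
  flank <- flank[abs(flank - vol$fovea_col) > 12]
  expect_gt(mean(inner_mean[flank]), 0.3)
})

test_that("lamellar phantoms keep the RPE band under the defect", {
  p <- retina_phantom_params(64, 64, 7, "lamellar", lesion_width = 8,
                             speckle_sigma = 0)
  e <- generate_eye(p, seed = 4)
  vol <- e$volume
  img <- central_slice(vol)
  b <- vol$layer_bounds[[vol$central]]
  defect_cols <- (vol$fovea_col - 3):(vol$fovea_col + 3)
  rpe_intensity <- vapply(defect_cols, function(j)
    mean(img[ceiling(b$rpe[j]) + 0:2, j]), numeric(1))
  expect_true(all(rpe_intensity > 0.3))
  # but the inner half is removed
  inner <- vapply(defect_cols, function(j)
    mean(img[ceiling(b$ilm[j]) + 1:3, j]), numeric(1))
  expect_true(all(inner < 0.05))
})

test_that("noiseless control phantoms have unbroken layer bands", {
  p <- retina_phantom_params(64, 64, 5, "control_erm", speckle_sigma = 0)
  e <- generate_eye(p, seed = 5)
  vol <- e$volume
  img <- central_slice(vol)
  b <- vol$layer_bounds[[vol$central]]
  for (j in seq(4, 60, by = 4)) {
    rows <- seq(ceiling(b$ilm[j]) + 1, floor(b$rpe[j]) + 2)
    expect_gt(min(img[rows, j]), 0)  # no zero-intensity gap ILM..RPE
  }
  expect_true(all(img >= 0 & img <= 1))
})

test_that("generation is bit-reproducible and validates inputs", {
  p <- retina_phantom_params(48, 48, 5, "ftmh")
  e1 <- generate_eye(p, seed = 11)
  e2 <- generate_eye(p, seed = 11)
  expect_identical(e1$volume$slices, e2$volume$slices)
  expect_identical(e1$metadata, e2$metadata)
  expect_error(retina_phantom_params(10, 64), "image_height")
  expect_error(retina_phantom_params(64, 64, 2), "n_slices")
  expect_error(retina_phantom_params(64, 64, 5, "nonsense"))
})

test_that("cohorts honor requested class counts and demographics", {
  ch <- tiny_cohort(n_ftmh = 6, n_erm = 18, seed = 7)
  expect_equal(nrow(ch$manifest), 24)
  expect_equal(sum(ch$manifest$diagnosis == "FTMH"), 6)
  expect_equal(sum(ch$manifest$diagnosis == "ERM"), 18)
  expect_equal(length(ch$volumes), 24)
  expect_true(all(table(ch$manifest$patient_id) <= 2))
  # degenerate single-class config
  ch2 <- generate_cohort(cohort_config(n_ftmh = 2, n_erm = 0,
                                       image_height = 32, image_width = 32),
                         seed = 8)
  expect_equal(ch2$manifest$diagnosis, c("FTMH", "FTMH"))
  expect_error(cohort_config(n_ftmh = 0, n_erm = 0), "at least one eye")
})

test_that("cohort ages follow the configured class-conditional normals", {
  # CLT bound: mean of 1000 FTMH ages within 69.6 +- 3 * 6.4 / sqrt(1000)
  cfg <- cohort_config(n_ftmh = 1000, n_erm = 0, image_height = 32,
                       image_width = 32, n_slices = 3)
  set.seed(9)
  ages <- with(new.env(), {
    # draw demographics only (volumes would dominate runtime)
    ns <- asNamespace("rascl")
    replicate(1000, ns$sample_patient_demographics(cfg, "FTMH")$age)
  })
  expect_lt(abs(mean(ages) - 69.6), 3 * 6.4 / sqrt(1000) + 0.05)
})

test_that("challenge sets are all-lamellar with FTMH-negative truth", {
  cfg <- cohort_config(n_lamellar = 5, image_height = 32, image_width = 32)
  lam <- generate_challenge_set(cfg, seed = 10)
  expect_equal(nrow(lam$manifest), 5)
  expect_true(all(lam$manifest$diagnosis == "LAMELLAR"))
  one <- generate_challenge_set(cohort_config(n_lamellar = 1,
                                              image_height = 32,
                                              image_width = 32), seed = 11)
  expect_equal(nrow(one$manifest), 1)
})

test_that("adjacent slices within an eye correlate more than across eyes", {
  ch <- generate_cohort(cohort_config(n_ftmh = 0, n_erm = 50,
                                      image_height = 48, image_width = 48,
                                      speckle_sigma = 0), seed = 12)
  adj <- unlist(lapply(ch$volumes, function(v) {
    vapply(seq_len(n_slices(v) - 1), function(s)
      cor(as.vector(v$slices[[s]]), as.vector(v$slices[[s + 1]])),
      numeric(1))
  }))
  cs <- lapply(ch$volumes, central_slice)
  cross <- c()
  for (i in 1:20) for (j in (i + 1):21)
    cross <- c(cross, cor(as.vector(cs[[i]]), as.vector(cs[[j]])))
  tt <- t.test(adj, cross, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("a pixel-threshold oracle separates noiseless FTMH from control", {
  # full-depth low-intensity foveal column <=> FTMH
  has_hole <- function(vol) {
    img <- central_slice(vol)
    b <- vol$layer_bounds[[vol$central]]
    any(vapply(seq_len(ncol(img)), function(j) {
      rows <- seq(ceiling(b$ilm[j]) + 1, floor(b$rpe[j]) - 1)
      mean(img[rows, j]) < 0.05
    }, logical(1)))
  }
  ch <- generate_cohort(cohort_config(n_ftmh = 10, n_erm = 10,
                                      image_height = 48, image_width = 48,
                                      speckle_sigma = 0), seed = 13)
  pred <- vapply(ch$volumes, has_hole, logical(1))
  expect_equal(unname(pred), ch$manifest$diagnosis == "FTMH")
})
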