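test_that("image generation is deterministic and leaves the RNG alone", {
  p <- class_texture_params()
  a <- generate_image(p, size = 32, seed = 7)
  b <- generate_image(p, size = 32, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c_ <- generate_image(p, size = 32, seed = 8)
  expect_false(identical(a$pixels, c_$pixels))

  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_image(p, size = 32, seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("zero contrast and noise give a flat interior at base intensity", {
  p <- class_texture_params(base_intensity = 140, contrast = 0,
                            noise_sd = 0)
  img <- generate_image(p, size = 48, seed = 3)
  interior <- img$pixels[20:28, 20:28]  # well inside the support
  expect_true(all(interior == 140))
  # background outside the support decays to black
  expect_equal(img$pixels[1, 1], 0)
})

test_that("longer correlation lengths concentrate energy at coarse scales", {
  sd3 <- function(cl, seed) {
    p <- class_texture_params(correlation_length = cl, noise_sd = 0)
    extract_features(generate_image(p, size = 64, seed = seed),
                     wavelets = "db1")$db1dec3sd
  }
  seeds <- 1:20
  short <- vapply(seeds, function(s) sd3(1, 400 + s), numeric(1))
  long <- vapply(seeds, function(s) sd3(8, 400 + s), numeric(1))
  expect_gt(mean(long), mean(short))
})

test_that("default cohorts mirror the study arm sizes with low clipping", {
  co <- generate_cohort(cohort_config(seed = 11))
  expect_length(co$images, 22L)
  expect_identical(sum(co$labels$label), 7L)
  expect_identical(co$labels$label[1:7], rep(1L, 7))
  clip <- vapply(co$images, function(im) attr(im, "clip_fraction"),
                 numeric(1))
  expect_lt(max(clip), 0.01)
  # distinct subjects get distinct images
  expect_false(identical(co$images[[1]]$pixels, co$images[[2]]$pixels))
})

test_that("effect zero makes the classes exchangeable", {
  co <- generate_cohort(cohort_config(effect = 0, seed = 13))
  tab <- extract_cohort(co$images, co$labels$label,
                        wavelets = c("db1", "sym2"))
  obs <- abs(ttest_raw(tab$db1dec3mn[tab$label == 1],
                       tab$db1dec3mn[tab$label == 0])$t)
  # permutation distribution of |t| covers the observed value
  set.seed(17)
  perm <- replicate(199, {
    lab <- sample(tab$label)
    abs(ttest_raw(tab$db1dec3mn[lab == 1], tab$db1dec3mn[lab == 0])$t)
  })
  expect_gt(mean(perm >= obs), 0.05)
})

test_that("downstream accuracy is monotone in the effect size", {
  acc_at <- function(effect, seed) {
    tab <- generate_feature_cohort(cohort_config(effect = effect,
                                                 seed = seed))
    loocv(tab, features = c("db2dec2sd", "bior33dec1max",
                            "bior33dec3mn", "sym5dec2mn"))$metrics$accuracy
  }
  seeds <- 1:20
  a0 <- mean(vapply(seeds, function(s) acc_at(0, 900 + s), numeric(1)))
  a1 <- mean(vapply(seeds, function(s) acc_at(1, 900 + s), numeric(1)))
  a3 <- mean(vapply(seeds, function(s) acc_at(3, 900 + s), numeric(1)))
  expect_gte(a1 + 0.05, a0)  # sampling tolerance
  expect_gte(a3 + 0.05, a1)
  expect_gt(a3, a0 + 0.2)
  expect_gt(a3, 0.9)
})

test_that("feature cohorts are reproducible and plant the stated shift", {
  cfg <- cohort_config(effect = 3, seed = 19)
  t1 <- generate_feature_cohort(cfg)
  t2 <- generate_feature_cohort(cfg)
  expect_identical(t1, t2)
  expect_identical(dim(t1), c(22L, 122L))
  # planted features separate by ~3 within-class SDs; null features do not
  d <- mean(t1$db2dec2sd[t1$label == 1]) - mean(t1$db2dec2sd[t1$label == 0])
  expect_gt(d, 1.5)
  nulld <- mean(t1$db4dec2md[t1$label == 1]) -
    mean(t1$db4dec2md[t1$label == 0])
  expect_lt(abs(nulld), 1.5)
})

test_that("cohorts round-trip through image files and labels CSV", {
  co <- generate_cohort(cohort_config(n_pos = 3, n_neg = 3,
                                      image_size = 32, seed = 23))
  dir <- withr::local_tempdir()
  csv <- write_cohort(co, dir, format = "png")
  expect_true(file.exists(csv))
  back <- read_cohort(csv)
  expect_identical(back$labels$label, co$labels$label)
  for (i in seq_along(co$images)) {
    expect_equal(back$images[[i]]$pixels, co$images[[i]]$pixels,
                 ignore_attr = TRUE)
  }
})
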