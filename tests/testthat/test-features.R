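test_that("coefficient statistics match hand arithmetic", {
  s <- coefficient_stats(c(1, 2, 3, 4))
  expect_equal(s$mn, 2.5)
  expect_equal(s$md, 2.5)   # mean of the two central order statistics
  expect_equal(s$max, 4)
  expect_equal(s$sd, sd(1:4))

  const <- coefficient_stats(matrix(6, 3, 3))
  expect_equal(unlist(const), c(mn = 6, md = 6, max = 6, sd = 0))

  # the maximum is signed, not absolute
  expect_equal(coefficient_stats(c(-5, 0, 2))$max, 2)

  expect_error(coefficient_stats(7), "at least 2")
  expect_error(coefficient_stats(c(1, Inf)), "non-finite")
})

test_that("extraction emits exactly 12 variables per wavelet, 120 total", {
  set.seed(41)
  img <- gray_image(matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24),
                    subject_id = "a")
  fv <- extract_features(img)
  feats <- setdiff(names(fv), "subject_id")
  expect_length(feats, 120L)
  expect_identical(feats, feature_names())
  per_wavelet <- table(sub("dec[123](mn|md|max|sd)$", "", feats))
  expect_true(all(per_wavelet == 12L))
  expect_length(per_wavelet, 10L)
  expect_true(all(is.finite(unlist(fv[feats]))))
  # published variable spellings are produced verbatim
  expect_true(all(c("db2dec2sd", "bior33dec1max", "bior33dec3mn",
                    "sym5dec2mn") %in% feats))
})

test_that("constant images follow the Haar DC-gain ladder", {
  img <- gray_image(matrix(50, 32, 32))
  fv <- extract_features(img)
  expect_equal(fv$db1dec1mn, 100)
  expect_equal(fv$db1dec2mn, 200)
  expect_equal(fv$db1dec3mn, 400)
  sd_feats <- grep("sd$", names(fv), value = TRUE)
  expect_true(all(abs(unlist(fv[sd_feats])) < 1e-8))
})

test_that("near-uniform bright images scale like the published magnitudes", {
  # a bright, nearly flat tumor crop whose maximum pixel is 214:
  # with the 2D Haar DC gain of 2 per level the level-1/2 approximation
  # maxima sit near 2 x 214 = 428 and 4 x 214 = 856
  set.seed(43)
  px <- pmin(pmax(round(210 + matrix(rnorm(64 * 64, 0, 1.2), 64, 64)), 200),
             214)
  px[1, 1] <- 214
  fv <- extract_features(gray_image(px))
  expect_gt(fv$db1dec1max, 400)
  expect_lt(fv$db1dec1max, 440)
  expect_gt(fv$db1dec2max, 820)
  expect_lt(fv$db1dec2max, 880)
})

test_that("intensity shifts move approximation means by the DC gain", {
  set.seed(47)
  px <- matrix(sample(40:140, 32 * 32, replace = TRUE), 32, 32)
  f0 <- extract_features(gray_image(px))
  f1 <- extract_features(gray_image(px + 50))
  for (l in 1:3) {
    gain <- 2^l
    expect_equal(f1[[paste0("db1dec", l, "mn")]],
                 f0[[paste0("db1dec", l, "mn")]] + gain * 50)
    expect_equal(f1[[paste0("db1dec", l, "md")]],
                 f0[[paste0("db1dec", l, "md")]] + gain * 50)
    expect_equal(f1[[paste0("db1dec", l, "max")]],
                 f0[[paste0("db1dec", l, "max")]] + gain * 50)
    expect_equal(f1[[paste0("db1dec", l, "sd")]],
                 f0[[paste0("db1dec", l, "sd")]])
  }
})

test_that("feature extraction is bit-for-bit deterministic", {
  set.seed(53)
  img <- gray_image(matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20),
                    subject_id = "det")
  expect_identical(extract_features(img), extract_features(img))
})

test_that("detail-pooled mode is available and differs from approximation", {
  set.seed(59)
  img <- gray_image(matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24))
  fa <- extract_features(img, subband = "approximation")
  fd <- extract_features(img, subband = "detail")
  expect_identical(names(fa), names(fd))
  # detail subbands of a textured image centre near zero, approximations
  # near the DC-scaled intensity
  expect_gt(fa$db1dec1mn, 100)
  expect_lt(abs(fd$db1dec1mn), 20)
})

test_that("cohort extraction enforces alignment and identity integrity", {
  set.seed(61)
  imgs <- lapply(1:4, function(i) {
    gray_image(matrix(sample(0:255, 144, replace = TRUE), 12, 12),
               subject_id = paste0("s", i))
  })
  tab <- extract_cohort(imgs, c(1, 1, 0, 0))
  expect_identical(dim(tab), c(4L, 122L))
  expect_identical(tab$label, c(1L, 1L, 0L, 0L))

  expect_error(extract_cohort(list(), integer(0)), "empty")
  expect_error(extract_cohort(imgs, c(1, 0)), "align")
  imgs[[2]]$subject_id <- "s1"
  expect_error(extract_cohort(imgs, c(1, 1, 0, 0)), "duplicate")
})

test_that("feature tables round-trip through CSV at full precision", {
  tab <- generate_feature_cohort(cohort_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 0)
  header <- readLines(path, n = 1)
  expect_match(header, "^subject_id,label,db1dec1mn,")
})
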