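make_lda_table <- function(n_pos = 10, n_neg = 14, shift = c(2, 1),
                           seed = 101) {
  set.seed(seed)
  n <- n_pos + n_neg
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  X <- matrix(rnorm(n * length(shift)), n)
  X[label == 1L, ] <- sweep(X[label == 1L, , drop = FALSE], 2, shift, `+`)
  colnames(X) <- paste0("f", seq_along(shift))
  dplyr::bind_cols(tibble::tibble(subject_id = paste0("s", 1:n),
                                  label = label),
                   tibble::as_tibble(X))
}

test_that("one-feature discriminant matches the 1-D closed form", {
  # class means 0 and 1, common within-class sd s: coefficient 1/s and
  # score-mean separation 1/s
  s <- 0.5
  n_per <- 50
  set.seed(103)
  x <- c(rnorm(n_per, 1, s), rnorm(n_per, 0, s))
  # remove sampling noise so the closed form is exact
  x[1:n_per] <- 1 + s * scale(x[1:n_per])
  x[-(1:n_per)] <- 0 + s * scale(x[-(1:n_per)])
  tab <- tibble::tibble(subject_id = as.character(1:(2 * n_per)),
                        label = rep(c(1L, 0L), each = n_per), f = x)
  fit <- fit_lda(tab, "f")
  expect_equal(unname(fit$coefficients), 1 / s, tolerance = 1e-10)
  expect_equal(fit$score_mean_pos - fit$score_mean_neg, 1 / s,
               tolerance = 1e-10)
  # unstandardised convention: unit pooled within-class score variance,
  # zero weighted grand-mean score
  expect_equal(sd(fit$training$ds[tab$label == 1]), 1, tolerance = 1e-10)
  expect_equal(mean(fit$training$ds), 0, tolerance = 1e-10)
})

test_that("discriminant scores are invariant to affine feature maps", {
  tab <- make_lda_table(shift = c(2, 1, 0.5), seed = 107)
  feats <- c("f1", "f2", "f3")
  fit0 <- fit_lda(tab, feats)
  # invertible affine transform of the feature block
  A <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, 0, -0.7, 1.1), 3, 3)
  b <- c(10, -4, 2)
  X <- as.matrix(tab[feats]) %*% A
  X <- sweep(X, 2, b, `+`)
  tab2 <- tab
  tab2[feats] <- X
  fit1 <- fit_lda(tab2, feats)
  expect_equal(fit1$training$ds, fit0$training$ds, tolerance = 1e-8)
  expect_equal(fit1$cutoff, fit0$cutoff, tolerance = 1e-8)
})

test_that("discriminant direction agrees with the reference LDA", {
  tab <- make_lda_table(shift = c(1.5, -1), seed = 109)
  fit <- fit_lda(tab, c("f1", "f2"))
  ref <- MASS::lda(label ~ f1 + f2, data = tab)
  # same direction up to scale and sign
  ratio <- unname(fit$coefficients) / as.numeric(ref$scaling)
  expect_equal(ratio[1], ratio[2], tolerance = 1e-8)
  # identical ranking of subjects
  ref_scores <- as.numeric(predict(ref)$x)
  expect_equal(order(fit$training$ds),
               order(sign(ratio[1]) * ref_scores))
})

test_that("degenerate designs are rejected with named causes", {
  tab <- make_lda_table(seed = 113)
  tab$dup <- tab$f1
  expect_error(fit_lda(tab, c("f1", "dup")), "singular")
  expect_error(fit_lda(tab, c("f1", "f1")), "duplicate")
  expect_error(fit_lda(tab, "nope"), "nope")
  tiny <- tab[c(1, 11:24), ]  # one positive subject only
  expect_error(fit_lda(tiny, "f1"), "at least 2")
  small <- make_lda_table(n_pos = 3, n_neg = 3,
                          shift = c(2, 1, 0.5, 0.2), seed = 1)
  expect_error(fit_lda(small, paste0("f", 1:4)), "fewer than n - 2")
})

test_that("scoring is an affine map that names missing features", {
  m <- ds_reference_model()
  expect_equal(score(m, c(db2dec2sd = 0, bior33dec1max = 0,
                          bior33dec3mn = 0, sym5dec2mn = 0)),
               -541.1768021)
  # linearity in each feature
  base <- c(db2dec2sd = 100, bior33dec1max = 400, bior33dec3mn = 800,
            sym5dec2mn = 500)
  up <- base
  up["db2dec2sd"] <- 101
  expect_equal(score(m, up) - score(m, base), 0.2456044)
  expect_error(score(m, c(db2dec2sd = 1)), "sym5dec2mn")
})

test_that("the shipped reference model reproduces its worked example", {
  m <- ds_reference_model()
  expect_length(m$features, 4L)
  expect_equal(m$cutoff, -0.6299)
  present <- c(db2dec2sd = 191.107, bior33dec1max = 428.362,
               bior33dec3mn = 846.84, sym5dec2mn = 508.66)
  absent <- c(db2dec2sd = 165.39, bior33dec1max = 424.91,
              bior33dec3mn = 819.92, sym5dec2mn = 516.83)
  ds_p <- score(m, present)
  ds_a <- score(m, absent)
  expect_equal(ds_p, 6.0, tolerance = 0.01)
  expect_equal(ds_a, -6.0, tolerance = 0.01)
  expect_gt(ds_p, m$cutoff)
  expect_lt(ds_a, m$cutoff)
})

test_that("model serialisation preserves every digit", {
  m <- ds_reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_ds_model(m, path)
  back <- read_ds_model(path)
  expect_identical(back$features, m$features)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$constant, m$constant)
  expect_identical(back$cutoff, m$cutoff)

  tab <- make_lda_table(seed = 127)
  fit <- fit_lda(tab, c("f1", "f2"))
  write_ds_model(fit, path)
  rt <- read_ds_model(path)
  expect_identical(rt$coefficients, fit$coefficients)
  expect_identical(rt$cutoff, fit$cutoff)
})

test_that("tidy and glance expose the model in broom form", {
  m <- ds_reference_model()
  td <- tidy(m)
  expect_identical(td$term, c("(constant)", m$features))
  expect_equal(td$estimate[1], -541.1768021)
  gl <- glance(m)
  expect_identical(gl$n_features, 4L)
  expect_equal(gl$cutoff, -0.6299)
})
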