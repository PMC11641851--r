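test_that("all ten filter banks satisfy the standard tap invariants", {
  expected_taps <- c(db1 = 2, db2 = 4, db4 = 8, coif1 = 6, coif5 = 30,
                     bior22 = 6, bior33 = 8, sym2 = 4, sym3 = 6, sym5 = 10)
  for (w in wavetex_wavelets()) {
    fb <- filter_bank(w)
    expect_equal(sum(fb$dec_lo), sqrt(2), tolerance = 1e-10)
    expect_lt(abs(sum(fb$dec_hi)), 1e-10)
    expect_identical(length(fb$dec_lo), as.integer(expected_taps[[w]]))
    expect_identical(fb$orthogonal, !grepl("^bior", w))
    if (fb$orthogonal) {
      expect_equal(fb$rec_lo, rev(fb$dec_lo))
      expect_equal(fb$rec_hi, rev(fb$dec_hi))
    }
  }
})

test_that("wavelet identifiers accept aliases and reject unknown names", {
  expect_identical(filter_bank("bior2.2")$name, "bior22")
  expect_identical(filter_bank("sim5")$name, "sym5")
  expect_identical(filter_bank("sym5")$dec_lo, filter_bank("sim5")$dec_lo)
  expect_error(filter_bank("db3"), "db3")
  expect_error(filter_bank("morlet"), "unknown wavelet")
})

test_that("Haar transform matches its closed forms", {
  fb <- filter_bank("db1")
  expect_equal(fb$dec_lo, c(1, 1) / sqrt(2))
  expect_equal(sort(fb$dec_hi), sort(c(-1, 1) / sqrt(2)))

  # constant image: DC gain 2 in 2D, zero details
  sb <- dwt2_single_level(matrix(7, 8, 8), "db1")
  expect_equal(sb$cA, matrix(14, 4, 4))
  expect_equal(sb$cH, matrix(0, 4, 4))
  expect_equal(sb$cV, matrix(0, 4, 4))
  expect_equal(sb$cD, matrix(0, 4, 4))

  # 2x2 closed form: cA = (a + b + c + d) / 2
  m <- matrix(c(3, 5, 11, 2), 2, 2)
  sb2 <- dwt2_single_level(m, "db1")
  expect_equal(drop(sb2$cA), sum(m) / 2)
  # and the single-level pyramid inverts it exactly
  p <- wavedec2(m, "db1", 1)
  expect_equal(waverec2(p, "db1"), m, tolerance = 1e-12)
})

test_that("subband dimensions follow the reference convention", {
  for (w in c("db1", "db2", "coif1", "bior33")) {
    fl <- length(filter_bank(w)$dec_lo)
    for (n in c(11L, 16L, 33L)) {
      if (n < fl) next
      sb <- dwt2_single_level(random_image_matrix(n, n + 3), w)
      expect_identical(dim(sb$cA),
                       c((n + fl - 1L) %/% 2L, (n + 3L + fl - 1L) %/% 2L))
      expect_identical(dim(sb$cH), dim(sb$cA))
      expect_identical(dim(sb$cV), dim(sb$cA))
      expect_identical(dim(sb$cD), dim(sb$cA))
    }
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(dwt2_single_level(matrix(1, 1, 8), "db1"), "degenerate")
  expect_error(dwt2_single_level(matrix(NA_real_, 4, 4), "db1"),
               "non-finite")
})

test_that("filters longer than the image still match the reference", {
  set.seed(97)
  cases <- list(
    list(x = random_image_matrix(8), wavelet = "coif5", levels = 2L),
    list(x = random_image_matrix(12, 9), wavelet = "coif5", levels = 1L),
    list(x = random_image_matrix(6), wavelet = "sym5", levels = 1L))
  oracle <- pywt_dwt2_batch(cases)
  for (i in seq_along(cases)) {
    p <- wavedec2(cases[[i]]$x, cases[[i]]$wavelet, cases[[i]]$levels)
    for (lev in seq_len(cases[[i]]$levels)) {
      for (b in c("cA", "cH", "cV", "cD")) {
        expect_lt(max(abs(p$levels[[lev]][[b]] - oracle[[i]][[lev]][[b]])),
                  1e-10)
      }
    }
  }
})

test_that("multilevel decomposition chains approximations", {
  # constant image: approximation mean doubles per level
  p <- wavedec2(matrix(5, 32, 32), "db1", 3)
  expect_equal(mean(p$levels[[1]]$cA), 10)
  expect_equal(mean(p$levels[[2]]$cA), 20)
  expect_equal(mean(p$levels[[3]]$cA), 40)

  # L = 1 is exactly the single-level transform
  set.seed(11)
  x <- random_image_matrix(16)
  p1 <- wavedec2(x, "sym3", 1)
  sb <- dwt2_single_level(x, "sym3")
  expect_equal(p1$levels[[1]]$cA, sb$cA)
  expect_equal(p1$levels[[1]]$cD, sb$cD)

  # excessive depth names the feasible maximum
  lmax <- max_wavedec_level(c(16, 16), "db2")
  expect_error(wavedec2(x, "db2", lmax + 1),
               paste0("maximum feasible level is ", lmax))
})

test_that("every wavelet reconstructs random images perfectly", {
  set.seed(21)
  for (w in wavetex_wavelets()) {
    for (n in c(17, 64)) {
      x <- random_image_matrix(n)
      L <- min(3L, max_wavedec_level(c(n, n), w))
      p <- wavedec2(x, w, L)
      expect_lt(max(abs(waverec2(p, w) - x)), 1e-8)
    }
  }
})

test_that("reconstruction guards against wavelet mismatch and inverts zero", {
  set.seed(5)
  p <- wavedec2(random_image_matrix(16), "db2", 2)
  expect_error(waverec2(p, "db4"), "db4")
  for (k in seq_along(p$levels)) {
    for (b in c("cA", "cH", "cV", "cD")) p$levels[[k]][[b]][] <- 0
  }
  expect_equal(waverec2(p, "db2"), matrix(0, 16, 16))
})

test_that("coefficients equal the reference DWT implementation", {
  set.seed(31)
  cases <- c(
    # every wavelet twice: one even-sized and one odd-sized image
    lapply(wavetex_wavelets(), function(w) {
      list(x = random_image_matrix(32), wavelet = w, levels = 1L)
    }),
    lapply(wavetex_wavelets(), function(w) {
      list(x = random_image_matrix(31, 29), wavelet = w, levels = 1L)
    }),
    # multilevel agreement
    list(list(x = random_image_matrix(32), wavelet = "db2", levels = 3L),
         list(x = random_image_matrix(40), wavelet = "sym5", levels = 2L))
  )
  oracle <- pywt_dwt2_batch(cases)
  for (i in seq_along(cases)) {
    p <- wavedec2(cases[[i]]$x, cases[[i]]$wavelet, cases[[i]]$levels)
    for (lev in seq_len(cases[[i]]$levels)) {
      for (b in c("cA", "cH", "cV", "cD")) {
        expect_lt(max(abs(p$levels[[lev]][[b]] - oracle[[i]][[lev]][[b]])),
                  1e-10,
                  label = sprintf("case %d %s L%d %s deviation", i,
                                  cases[[i]]$wavelet, lev, b))
      }
    }
  }
})
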