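# Independent reference oracle for the 2D DWT: the PyWavelets library,
# driven through one batched python process per test run.
#
# Each case is list(x = matrix, wavelet = "db2", levels = 2).  Returns a
# list (per case) of lists (per level) with matrices cA, cH, cV, cD
# computed by the reference implementation in symmetric mode.

pywt_dwt2_batch <- function(cases) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  manifest <- file.path(dir, "manifest.csv")
  rows <- lapply(seq_along(cases), function(i) {
    xp <- file.path(dir, sprintf("x%03d.csv", i))
    utils::write.table(cases[[i]]$x, xp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    data.frame(id = i, path = xp, wavelet = cases[[i]]$wavelet,
               levels = cases[[i]]$levels %||% 1L)
  })
  utils::write.table(do.call(rbind, rows), manifest, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, csv, numpy as np, pywt",
    "mani = list(csv.DictReader(open(sys.argv[1])))",
    "outdir = sys.argv[2]",
    "for row in mani:",
    "    x = np.loadtxt(row['path'], delimiter=',', ndmin=2)",
    "    w = row['wavelet'].replace('bior22','bior2.2').replace('bior33','bior3.3')",
    "    cur = x",
    "    for lev in range(1, int(row['levels']) + 1):",
    "        cA, (cH, cV, cD) = pywt.dwt2(cur, w, mode='symmetric')",
    "        for name, m in [('cA',cA),('cH',cH),('cV',cV),('cD',cD)]:",
    "            np.savetxt(f\"{outdir}/o{int(row['id']):03d}_L{lev}_{name}.csv\",",
    "                       np.atleast_2d(m), delimiter=',', fmt='%.17g')",
    "        cur = cA"
  ), script)
  status <- system2("python", c(script, manifest, dir),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference DWT oracle process failed")
  lapply(seq_along(cases), function(i) {
    lapply(seq_len(cases[[i]]$levels %||% 1L), function(lev) {
      out <- lapply(c("cA", "cH", "cV", "cD"), function(b) {
        as.matrix(utils::read.table(
          file.path(dir, sprintf("o%03d_L%d_%s.csv", i, lev, b)),
          sep = ","))
      })
      names(out) <- c("cA", "cH", "cV", "cD")
      out
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random test image helper (deterministic under the test seed).
random_image_matrix <- function(nr, nc = nr) {
  matrix(stats::runif(nr * nc, 0, 255), nr, nc)
}
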