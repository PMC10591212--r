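# Spectrum IO, baseline/smoothing contract and S/N peak picking.

test_that("peak-list files parse with headers, commas and round-trip", {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(c("1000.1 5", "1000.2 7", "1000.3 4"), f)
  s <- read_spectrum(f)
  expect_length(s$mz, 3)
  writeLines(c("m/z intensity", "1000.1,5", "1000.2,7"), f)
  s2 <- read_spectrum(f)
  expect_equal(s2$intensity, c(5, 7))
  writeLines(c("1000.1 5", "1000.2 -7"), f)
  expect_error(read_spectrum(f), "negative intensity")
  writeLines(c("1000.2 5", "1000.1 7"), f)
  expect_warning(s3 <- read_spectrum(f), "sorting")
  expect_equal(s3$mz, c(1000.1, 1000.2))
  # write -> read equality to 6 significant digits
  sp <- gaussian_spectrum(1000, 50)
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$mz, sp$mz, tolerance = 1e-6)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)
})

test_that("mzML dialect reads via mzR", {
  # minimal valid mzML with one spectrum, little-endian 64-bit arrays
  enc <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                   endian = "little"))
  mz <- c(1000.1, 1000.2, 1000.3); it <- c(5, 7, 4)
  f <- tempfile(fileext = ".mzML")
  on.exit(unlink(f))
  writeLines(sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://purl.obolibrary.org/obo/ms.owl"/></cvList>
  <run id="r">
    <spectrumList count="1">
      <spectrum index="0" id="scan=1" defaultArrayLength="3">
        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>', nchar(enc(mz)), enc(mz), nchar(enc(it)), enc(it)), f)
  s <- read_spectrum(f, dialect = "mzml")
  expect_equal(s$mz, mz, tolerance = 1e-9)
  expect_equal(s$intensity, it, tolerance = 1e-9)
})

test_that("baseline subtraction zeroes flat spectra, keeps zeros zero", {
  mz <- seq(1000, 1100, by = 0.1)
  flat <- maldi_spectrum(mz, rep(25, length(mz)), centroided = FALSE)
  out <- preprocess_spectrum(flat)
  expect_lt(max(out$intensity), 1e-9)
  zero <- maldi_spectrum(mz, rep(0, length(mz)), centroided = FALSE)
  expect_equal(preprocess_spectrum(zero)$intensity, zero$intensity)
  tiny <- maldi_spectrum(mz[1:3], c(0, 1, 0), centroided = FALSE)
  expect_error(preprocess_spectrum(tiny, preprocess_params(smooth_points = 7)),
               "larger than spectrum")
})

test_that("a Gaussian on an exponential baseline keeps its apex", {
  mz <- seq(1000, 1400, by = 0.1)
  base <- 40 * exp(-(mz - 1000) / 150)
  sig <- 0.35 / 2.354820045
  y <- base + 100 * exp(-0.5 * ((mz - 1200.17) / sig)^2)
  s <- maldi_spectrum(mz, y, centroided = FALSE)
  pk <- pick_peaks(preprocess_spectrum(s), preprocess_params(snr = 3))
  expect_gte(nrow(pk), 1L)
  apex <- pk$mz[which.max(pk$intensity)]
  expect_lt(abs(apex - 1200.17), 0.05)
})

test_that("peak picking: detection, sub-threshold rejection, refinement", {
  set.seed(10)
  mz <- seq(1000, 1200, by = 0.1)
  noise <- stats::rnorm(length(mz), 50, 1)  # sigma = 1 around a pedestal
  sig <- 0.35 / 2.354820045
  y <- noise + 10 * exp(-0.5 * ((mz - 1100.13) / sig)^2)  # 10 sigma peak
  s <- maldi_spectrum(mz, y, centroided = FALSE)
  pk <- pick_peaks(s, preprocess_params(snr = 3))
  hit <- pk[abs(pk$mz - 1100.13) < 0.1, ]
  expect_equal(nrow(hit), 1L)
  # 2 sigma peak is not reported at threshold 3
  y2 <- noise + 2 * exp(-0.5 * ((mz - 1100.13) / sig)^2)
  s2 <- maldi_spectrum(mz, y2, centroided = FALSE)
  pk2 <- pick_peaks(s2, preprocess_params(snr = 3))
  expect_equal(nrow(pk2[abs(pk2$mz - 1100.13) < 0.05 & pk2$snr >= 3, ]), 0L)
  # noise-only false positives bounded by the 3-sigma tail probability
  s3 <- maldi_spectrum(mz, noise, centroided = FALSE)
  fp <- nrow(pick_peaks(s3, preprocess_params(snr = 3)))
  n <- length(mz)
  bound <- n * stats::pnorm(3, lower.tail = FALSE) +
    4 * sqrt(n * stats::pnorm(3, lower.tail = FALSE))
  expect_lte(fp, ceiling(bound))
})

test_that("apex refinement recovers a Gaussian centre at 3 pts per FWHM", {
  fwhm <- 0.3
  for (offset in c(0, 0.03, 0.07)) {
    s <- gaussian_spectrum(1000.5 + offset, 80, fwhm = fwhm,
                           mz = seq(995, 1005, by = fwhm / 3))
    pk <- pick_peaks(s, preprocess_params(snr = 3))
    expect_equal(nrow(pk), 1L)
    expect_lt(abs(pk$mz - (1000.5 + offset)), 0.05)
  }
})

test_that("peak count is non-increasing in the S/N threshold", {
  set.seed(11)
  mz <- seq(1000, 1300, by = 0.1)
  y <- stats::rnorm(length(mz), 30, 1)
  sig <- 0.35 / 2.354820045
  for (c0 in seq(1010, 1290, by = 20))
    y <- y + stats::runif(1, 2, 12) * exp(-0.5 * ((mz - c0) / sig)^2)
  s <- maldi_spectrum(mz, y, centroided = FALSE)
  counts <- vapply(c(3, 3.5, 4, 4.5, 5), function(thr)
    nrow(pick_peaks(s, preprocess_params(snr = thr))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("preprocess + pick commute with a global m/z shift", {
  set.seed(12)
  mz <- seq(1000, 1200, by = 0.1)
  sig <- 0.35 / 2.354820045
  y <- 20 * exp(-(mz - 1000) / 100) + stats::rnorm(length(mz), 10, 0.5)
  for (c0 in c(1050.12, 1120.4, 1180.77))
    y <- y + 50 * exp(-0.5 * ((mz - c0) / sig)^2)
  y <- pmax(y, 0)
  delta <- 7.3
  s <- maldi_spectrum(mz, y, centroided = FALSE)
  s_shift <- maldi_spectrum(mz + delta, y, centroided = FALSE)
  p <- preprocess_params(snr = 3)
  pk <- pick_peaks(preprocess_spectrum(s, p), p)
  pk_shift <- pick_peaks(preprocess_spectrum(s_shift, p), p)
  expect_equal(nrow(pk), nrow(pk_shift))
  expect_equal(pk_shift$mz, pk$mz + delta, tolerance = 1e-8)
  expect_equal(pk_shift$snr, pk$snr, tolerance = 1e-8)
})

test_that("centroided input bypasses profile-mode processing", {
  set.seed(13)
  mz <- seq(1000, 1145, by = 5)
  it <- stats::rnorm(length(mz), 5, 0.3)
  it[11] <- 80  # one real peak over a low centroid floor
  s <- maldi_spectrum(mz, pmax(it, 0))
  expect_true(s$centroided)
  expect_identical(preprocess_spectrum(s), s)
  pk <- pick_peaks(s, preprocess_params(snr = 3))
  expect_true(mz[11] %in% pk$mz)
  expect_equal(nrow(pk[pk$intensity > 50, ]), 1L)
})
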