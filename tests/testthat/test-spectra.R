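test_that("MGF round trip parses records, sorts peaks, skips bad records", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=rec1",
    "PEPMASS=301.1412",
    "STRUCTUREKEY=AAAA",
    "ADDUCT=[M+H]+",
    "COLLISIONENERGY=20",
    "INSTRUMENT=orbitrap",
    "200.1 5.0",
    "100.05 10.0",       # out of order on purpose
    "150.2 1.0",
    "END IONS",
    "",
    "BEGIN IONS",        # no precursor: must be skipped with a warning
    "TITLE=rec2",
    "100.0 1.0",
    "END IONS"), path)
  expect_warning(sp <- read_spectra(path, "mgf"), "no precursor")
  expect_length(sp, 1)
  s <- sp[[1]]
  expect_equal(s$mz, c(100.05, 150.2, 200.1))
  expect_equal(s$intensity, c(10, 1, 5))
  expect_equal(s$precursor_mz, 301.1412)
  expect_equal(s$structure_key, "AAAA")
  expect_equal(s$collision_energy, "20")

  # writer round trip
  out <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, out)
  sp2 <- read_spectra(out, "mgf")
  expect_equal(sp2[[1]]$mz, s$mz)
  expect_equal(sp2[[1]]$structure_key, "AAAA")

  # empty file -> empty list; malformed peak line -> error with line number
  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(), empty)
  expect_length(read_spectra(empty, "mgf"), 0)
  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "TITLE=x", "oops", "END IONS"),
             bad)
  expect_error(read_spectra(bad, "mgf"), "line 4")
})

test_that("MSP dialect parses NIST-style records", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "Name: compound one",
    "InChIKey: ABCDEFGHIJKLMN-UHFFFAOYSA-N",
    "PrecursorMZ: 180.05",
    "Precursor_type: [M+H]+",
    "Num Peaks: 2",
    "80.9 100",
    "120.4 50",
    "",
    "Name: compound two",
    "InChIKey: ZZZZZZZZZZZZZZ-UHFFFAOYSA-N",
    "PrecursorMZ: 250.1",
    "Num Peaks: 1",
    "99.0 10"), path)
  sp <- read_spectra(path, "msp")
  expect_length(sp, 2)
  expect_equal(sp[[1]]$structure_key, "ABCDEFGHIJKLMN")  # 2D block only
  expect_equal(sp[[1]]$adduct, "[M+H]+")
  expect_equal(sp[[2]]$mz, 99)
})

test_that("merge_spectra groups by structure/instrument/adduct and merges close peaks", {
  mk <- function(key, instr, mz, int, id) {
    s <- toy_spectrum(mz, int, precursor = 300, key = key, id = id,
                      instrument = instr)
    s
  }
  sp <- list(mk("A", "qtof", c(100.0000, 150), c(1, 0.5), "a1"),
             mk("A", "qtof", c(100.0005, 170), c(0.8, 0.2), "a2"),
             mk("A", "orbi", c(120), c(1), "a3"),
             mk("B", "qtof", c(130), c(1), "b1"))
  rec <- merge_spectra(sp)
  expect_length(rec, 3)   # (A,qtof), (A,orbi), (B,qtof)
  a_qtof <- rec[[which(vapply(rec, function(r)
    r$structure_key == "A" && r$spectrum$instrument == "qtof", logical(1)))]]
  expect_equal(a_qtof$n_merged, 2L)
  # 100.0000 and 100.0005 are 5 ppm apart -> one merged peak at the
  # intensity-weighted mean with max intensity
  expect_equal(length(a_qtof$spectrum$mz), 3)
  expect_equal(a_qtof$spectrum$mz[1],
               (100.0000 * 1 + 100.0005 * 0.8) / 1.8, tolerance = 1e-10)
  expect_equal(a_qtof$spectrum$intensity[1], 1)

  # single-record group is returned unchanged (idempotence)
  solo <- merge_spectra(sp[4])
  expect_equal(solo[[1]]$spectrum$mz, sp[[4]]$mz)
  expect_equal(solo[[1]]$n_merged, 1L)

  # conflicting precursors in one group -> error
  sp_bad <- list(mk("C", "qtof", 100, 1, "c1"), mk("C", "qtof", 100, 1, "c2"))
  sp_bad[[2]]$precursor_mz <- 310
  expect_error(merge_spectra(sp_bad), "precursor")
})

test_that("peaks just outside / inside 10 ppm tolerance merge correctly", {
  # 100.0000 vs 100.0010 is 10 ppm: merged under the agglomerative rule
  s1 <- toy_spectrum(c(100.0000), 1, precursor = 300, key = "D", id = "d1")
  s2 <- toy_spectrum(c(100.0010), 1, precursor = 300, key = "D", id = "d2")
  rec <- merge_spectra(list(s1, s2), ppm = 10)
  expect_length(rec[[1]]$spectrum$mz, 1)
  # 100.0000 vs 100.0050 is 50 ppm: stays two peaks
  s3 <- toy_spectrum(c(100.0050), 1, precursor = 300, key = "D", id = "d3")
  rec2 <- merge_spectra(list(s1, s3), ppm = 10)
  expect_length(rec2[[1]]$spectrum$mz, 2)
})

test_that("sample weights are 1/sqrt(count), decreasing, in (0,1]", {
  w <- compute_sample_weights(c(a = 1, b = 4, c = 85))
  expect_equal(unname(w["a"]), 1)
  expect_equal(unname(w["b"]), 0.5)
  expect_equal(unname(w["c"]), 1 / sqrt(85))   # ~0.108465
  expect_equal(unname(w["c"]), 0.108465, tolerance = 1e-5)
  counts <- 1:50
  ww <- compute_sample_weights(counts)
  expect_true(all(diff(ww) < 0))
  expect_true(all(ww > 0 & ww <= 1))
  expect_error(compute_sample_weights(c(x = 0)), ">= 1")
})

test_that("select_labels keeps only labels with enough positive structures", {
  m <- cbind(L1 = c(rep(1, 25), rep(0, 5)),
             L2 = c(rep(1, 19), rep(0, 11)),
             L3 = c(rep(1, 20), rep(0, 10)))
  rownames(m) <- sprintf("S%02d", 1:30)
  fp <- fingerprint_matrix(m)
  sel <- select_labels(fp, 20)
  expect_equal(sel$labels, c("L1", "L3"))
  expect_equal(unname(sel$positive_counts), c(25, 20))
  all_zero <- fingerprint_matrix(matrix(0L, 5, 2))
  expect_error(select_labels(all_zero, 1), "no labels")
})

test_that("binned features follow the two-axis sqrt-intensity contract", {
  s <- toy_spectrum(c(100.0001, 100.0049, 150.05), c(1, 0.5, 0.25),
                    precursor = 300.10)
  v <- bin_spectrum_features(s, bin_width = 0.005, max_mass = 400)
  nbins <- ceiling(400 / 0.005)
  expect_equal(length(v), 2 * nbins)
  dv <- as.numeric(v)
  # peaks at 100.0001 and 100.0049 share bin floor(100.0001/0.005) = 20000;
  # collision keeps the max sqrt intensity (= 1)
  expect_equal(dv[20000 + 1], 1)
  # sqrt intensity: 0.25 -> 0.5 on the raw axis at floor(150.05/0.005)
  expect_equal(dv[floor(150.05 / 0.005) + 1], 0.5)
  # precursor-difference axis: 300.10 - 150.05 = 150.05
  expect_equal(dv[nbins + floor((300.10 - 150.05) / 0.005) + 1], 0.5)
  # one-peak spectrum yields exactly two nonzero features
  s1 <- toy_spectrum(120.5, 1, precursor = 250)
  expect_equal(length(as(bin_spectrum_features(s1, 0.005, 400), "sparseVector")@x), 2)
  # peak above max_mass dropped with warning
  s2 <- toy_spectrum(c(100, 500), c(1, 1), precursor = 600)
  expect_warning(bin_spectrum_features(s2, 0.005, 400), "dropped")
})

test_that("formula features normalize by training std and drop constants", {
  f <- c(C = 6, H = 12, O = 6)
  v <- formula_feature_vector(f, c("C", "H", "O"), c(C = 1, H = 1, O = 1))
  expect_equal(unname(v), c(6, 12, 6))
  v2 <- formula_feature_vector(c(C = 6), c("C", "H"), c(C = 3, H = 2))
  expect_equal(unname(v2), c(2, 0))
  # zero-std element dropped
  v3 <- formula_feature_vector(c(C = 6, N = 1), c("C", "N"), c(C = 3, N = 0))
  expect_equal(names(v3), "C")
  expect_error(formula_feature_vector(c(Se = 1), c("C"), c(C = 1)),
               "Se")
  st <- formula_feature_stats(list(c(C = 2, H = 6), c(C = 4, H = 2)))
  expect_equal(st$element_order, c("C", "H"))
  expect_equal(unname(st$stds["C"]), stats::sd(c(2, 4)))
})

test_that("remove_noise_peaks applies intensity floor and peak cap", {
  s <- toy_spectrum(seq(50, 50 + 0.9, by = 0.1) + 0:9 * 10,
                    c(1, rep(0.5, 5), rep(0.0005, 4)), precursor = 300)
  cleaned <- remove_noise_peaks(s, min_rel_intensity = 0.001)
  expect_equal(length(cleaned$mz), 6)
  capped <- remove_noise_peaks(s, min_rel_intensity = 0, max_peaks = 3)
  expect_equal(length(capped$mz), 3)
  expect_true(max(s$intensity) %in% capped$intensity)
})

test_that("simulate_noise respects its contracts", {
  s <- toy_spectrum(seq(60, 240, by = 20), runif(10, 0.1, 1), precursor = 300)
  pool <- c(77.7, 88.8, 99.9)

  # all params zero -> identity
  out0 <- simulate_noise(s, pool, drop_fraction = 0, intensity_jitter_sd = 0,
                         n_noise_peaks = 0, seed = 5)
  expect_equal(out0$mz, s$mz)
  expect_equal(out0$intensity, s$intensity)

  # exact noise-peak count, and every added mass comes from the pool
  out1 <- simulate_noise(s, pool, drop_fraction = 0, intensity_jitter_sd = 0,
                         n_noise_peaks = 5, seed = 5)
  expect_equal(length(out1$mz), length(s$mz) + 5)
  added <- setdiff(out1$mz, s$mz)
  expect_true(all(added %in% pool))

  # drop fraction removes floor(f * n), never the base peak
  out2 <- simulate_noise(s, pool, drop_fraction = 0.3, intensity_jitter_sd = 0,
                         n_noise_peaks = 0, seed = 5)
  expect_equal(length(out2$mz), 10 - 3)
  expect_true(s$mz[which.max(s$intensity)] %in% out2$mz)

  # bit-reproducible under a fixed seed; different seeds differ
  outa <- simulate_noise(s, pool, seed = 11)
  outb <- simulate_noise(s, pool, seed = 11)
  outc <- simulate_noise(s, pool, seed = 12)
  expect_identical(outa, outb)
  expect_false(identical(outa$mz, outc$mz) && identical(outa$intensity, outc$intensity))

  expect_error(simulate_noise(s, pool, drop_fraction = 1, seed = 1), "drop_fraction")
  expect_error(simulate_noise(s, numeric(), n_noise_peaks = 3, seed = 1),
               "peak_pool")
})
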