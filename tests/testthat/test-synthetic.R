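test_that("band wavelengths are evenly spaced over the acquisition range", {
  p <- sim_params()
  wl <- band_wavelengths(p)
  expect_length(wl, 16)
  expect_equal(unique(round(diff(wl), 10)), 9.375)   # 150 nm / 16 bands
  expect_equal(unique(diff(band_wavelengths(
    sim_params(wavelength_start = 0, wavelength_end = 100, n_bands = 2)))), 50)
  expect_equal(unique(round(diff(band_wavelengths(
    sim_params(n_bands = 4))), 10)), 37.5)
  expect_error(sim_params(n_bands = 1), "n_bands")
  expect_error(sim_params(wavelength_start = 650, wavelength_end = 500),
               "wavelength")
})

test_that("sample generation is seeded-deterministic and validates inputs", {
  p <- small_params()
  s1 <- generate_sample("IN", p, seed = 11)
  s2 <- generate_sample("IN", p, seed = 11)
  expect_identical(s1$volume, s2$volume)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_sample("IN", p, seed = 12)
  expect_false(identical(s1$volume, s3$volume))

  expect_equal(dim(s1$volume), c(48L, 48L, 8L))
  expect_gt(sum(s1$mask), 0)
  frac <- sum(s1$mask) / length(s1$mask)
  expect_gt(frac, 0.1); expect_lt(frac, 0.7)

  expect_error(generate_sample("XX", p), "unknown tissue class")
  expect_error(generate_sample("CA", sim_params(width = 4, height = 4)),
               "degenerate")
})

test_that("cohorts use per-sample derived seeds and the default 39-patient split", {
  p <- small_params()
  co <- generate_cohort(params = p, seed = 5)
  expect_length(co, 39)
  expect_equal(as.vector(table(factor(sapply(co, `[[`, "label"),
                                      levels = tissue_classes()))),
               c(9, 10, 9, 11))
  co2 <- generate_cohort(params = p, seed = 5)
  expect_identical(lapply(co, `[[`, "volume"), lapply(co2, `[[`, "volume"))

  one <- generate_cohort(counts = c(ST = 0, BH = 0, IN = 0, CA = 1),
                         params = p, seed = 2)
  expect_length(one, 1)
  expect_equal(one[[1]]$label, "CA")
  expect_error(generate_cohort(counts = c(-1, 1, 1, 1), params = p),
               "counts")
})

test_that("effect_scale = 0 collapses the classes onto one texture distribution", {
  p0 <- small_params(effect_scale = 0)
  # identical seeds differ only through the label-independent draws, so the
  # per-class parameter sets coincide and class means agree within noise
  f <- function(lab, base) rowMeans(sapply(1:12, function(s) {
    sm <- generate_sample(lab, p0, seed = base + s)
    extract_feature_vector(sm$volume, sm$mask)
  }))
  fst <- f("ST", 9000); fca <- f("CA", 9050)
  # z-scale the gap by the spread of the CA replicate means
  sds <- apply(sapply(1:12, function(s) {
    sm <- generate_sample("CA", p0, seed = 9100 + s)
    extract_feature_vector(sm$volume, sm$mask)
  }), 1, sd)
  expect_lt(median(abs(fst - fca) / (sds * sqrt(2 / 12))), 4)
})

test_that("under the null generator a per-feature t-test rejects at its nominal rate", {
  p0 <- small_params(effect_scale = 0)
  n_cohorts <- 200
  reject <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    co <- generate_cohort(counts = c(ST = 0, BH = 5, IN = 0, CA = 5),
                          params = p0, seed = 50000 + 100 * i)
    ft <- extract_features(co)
    x <- ft$variance_LHL[ft$label == "BH"]
    y <- ft$variance_LHL[ft$label == "CA"]
    reject[i] <- t.test(x, y)$p.value < 0.05
  }
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.08)
})

test_that("planted carcinoma texture separates from hyperplasia in detail-band variance", {
  pd <- sim_params()
  fmat <- function(lab, base) sapply(1:20, function(s) {
    sm <- generate_sample(lab, pd, seed = base + s)
    extract_feature_vector(sm$volume, sm$mask)
  })
  fca <- fmat("CA", 500); fbh <- fmat("BH", 500)
  gap <- abs(mean(fca["variance_LHL", ]) - mean(fbh["variance_LHL", ]))
  pooled <- sqrt((var(fca["variance_LHL", ]) + var(fbh["variance_LHL", ])) / 2)
  expect_gt(gap / pooled, 2)
})
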