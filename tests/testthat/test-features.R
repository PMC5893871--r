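test_that("volume normalization fixes global SD at one and rejects constants", {
  set.seed(3)
  v <- array(rnorm(6 * 6 * 4, 5, 3), c(6, 6, 4))
  n1 <- normalize_volume(v)
  expect_equal(sd(as.numeric(n1)), 1, tolerance = 1e-12)
  expect_equal(normalize_volume(10 * v), 10 * v / sd(as.numeric(10 * v)),
               tolerance = 1e-12)
  # scale invariance up to the common factor: same normalized *SD*, and
  # scaling preserves the normalized volume exactly
  expect_equal(normalize_volume(3.7 * v), normalize_volume(v),
               tolerance = 1e-12)
  expect_error(normalize_volume(array(2, c(4, 4, 4))), "constant")
})

test_that("variance quantifier follows the 1/N mean-squared-deviation convention", {
  expect_equal(variance_feature(c(1, 2, 3, 4)), 1.25)
  expect_equal(variance_feature(rep(7, 10)), 0)
  set.seed(9)
  v <- rnorm(100)
  expect_equal(variance_feature(v + 1000), variance_feature(v),
               tolerance = 1e-6)
  # brute-force two-pass oracle
  two_pass <- function(x) { m <- sum(x) / length(x)
    s <- 0; for (xi in x) s <- s + (xi - m)^2; s / length(x) }
  expect_equal(variance_feature(v), two_pass(v), tolerance = 1e-12)
  expect_equal(variance_feature(v, convention = "raw"),
               100 * variance_feature(v), tolerance = 1e-12)
  expect_error(variance_feature(numeric(0)), "empty")
})

test_that("entropy and energy match hand-derivable histogram values", {
  # constant sub-band: one occupied bin
  expect_equal(entropy_feature(rep(2.5, 50)), 0)
  expect_equal(energy_feature(rep(2.5, 50)), 1)
  # two equally occupied bins
  two_bins <- rep(c(0, 1), each = 32)
  expect_equal(entropy_feature(two_bins), 1)
  expect_equal(energy_feature(two_bins), 0.5)
  # 256 equally occupied bins: bin centers, one value per bin
  u <- (seq_len(256) - 0.5) / 256
  expect_equal(entropy_feature(u), 8, tolerance = 1e-12)
  expect_equal(energy_feature(u), 1 / 256, tolerance = 1e-12)
  expect_error(entropy_feature(numeric(0)), "empty")
})

test_that("histogram quantifiers are affine-invariant and bounded", {
  set.seed(21)
  for (rep in 1:5) {
    v <- rnorm(500)
    a <- runif(1, 0.5, 4) * sample(c(-1, 1), 1)
    b <- runif(1, -10, 10)
    expect_equal(entropy_feature(a * v + b), entropy_feature(v),
                 tolerance = 1e-10)
    expect_equal(energy_feature(a * v + b), energy_feature(v),
                 tolerance = 1e-10)
    expect_lte(entropy_feature(v), log2(256))
    expect_gte(energy_feature(v), 1 / 256)
    # permuting the voxel set leaves set-valued quantifiers unchanged
    p <- sample(v)
    expect_equal(entropy_feature(p), entropy_feature(v))
    expect_equal(variance_feature(p), variance_feature(v),
                 tolerance = 1e-12)
  }
  # energy == 1 iff entropy == 0 over assorted histograms
  for (v in list(rep(1, 9), c(rep(0, 5), 1e-9), rnorm(40))) {
    expect_equal(energy_feature(v) == 1, entropy_feature(v) == 0)
  }
})

test_that("a sample yields exactly 24 finite named features, deterministically", {
  s <- generate_sample("CA", small_params(), seed = 4)
  fv <- extract_feature_vector(s$volume, s$mask)
  expect_length(fv, 24)
  expect_true(all(is.finite(fv)))
  expect_setequal(
    names(fv),
    as.vector(outer(c("variance", "entropy", "energy"),
                    c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH"),
                    paste, sep = "_")))
  fv2 <- extract_feature_vector(s$volume, s$mask)
  expect_identical(fv, fv2)
  # constant volume fails at the normalization guard
  expect_error(extract_feature_vector(array(1, dim(s$volume)), s$mask),
               "constant")
  # empty ROI is refused
  expect_error(extract_feature_vector(s$volume, s$mask * 0), "empty")
})

test_that("feature extraction handles odd ROI bounding boxes via padding", {
  s <- generate_sample("BH", small_params(), seed = 6)
  # force an odd bounding box by clipping the mask to odd extents
  m <- s$mask
  m[1:11, ] <- 0; m[, 1:11] <- 0
  if (sum(m) > 20) {
    fv <- extract_feature_vector(s$volume, m)
    expect_length(fv, 24)
    expect_true(all(is.finite(fv)))
  }
})

test_that("z-scoring gives zero-mean unit-population-SD columns", {
  tab <- structure(
    data.frame(sample_id = c("a", "b", "c"), label = c("ST", "BH", "CA"),
               f1 = c(1, 2, 3), f2 = c(10, 10, 10)),
    class = c("feature_table", "data.frame"), normalization = "raw")
  expect_warning(z <- zscore_table(tab), "constant")
  expect_equal(z$f1, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(z$f1[1], -1.2247, tolerance = 1e-4)
  expect_equal(z$f2, c(0, 0, 0))
  expect_equal(mean(z$f1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z$f1 - mean(z$f1))^2)), 1, tolerance = 1e-12)
  expect_error(zscore_table(tab[1, ]), "at least 2")
})
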