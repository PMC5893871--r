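#' Normalize a volume by its global standard deviation
#'
#' Divides every voxel by the standard deviation of the whole volume, so the
#' normalized volume has global SD 1. This suppresses acquisition-level
#' intensity scale differences between samples before texture extraction.
#'
#' @param vol numeric array.
#' @return array of the same shape with global SD 1.
#' @export
normalize_volume <- function(vol) {
  s <- stats::sd(as.numeric(vol))
  if (!is.finite(s) || s <= 0)
    stop("constant volume: global SD is zero, cannot normalize")
  vol / s
}

#' Histogram specification for entropy/energy quantifiers
#'
#' @param n_bins number of equal-width intervals (default 256). The value
#'   range is the min-max of the ROI voxels of each sub-band; the maximum
#'   value is placed in the last bin, and a degenerate range (min == max)
#'   collapses to a single occupied bin.
#' @return object of class \code{histogram_spec}.
#' @export
histogram_spec <- function(n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2) stop("n_bins must be >= 2")
  structure(list(n_bins = n_bins), class = "histogram_spec")
}

# Bin probabilities over equal-width bins spanning the value range.
bin_probs <- function(v, spec) {
  if (length(v) == 0) stop("empty ROI: no sub-band voxels to quantify")
  rng <- range(v)
  if (rng[1] == rng[2]) return(1)           # single occupied bin
  k <- floor((v - rng[1]) / (rng[2] - rng[1]) * spec$n_bins) + 1L
  k[k > spec$n_bins] <- spec$n_bins         # v == max goes to the last bin
  p <- tabulate(k, nbins = spec$n_bins) / length(v)
  p[p > 0]
}

#' Texture variance of sub-band values within the ROI
#'
#' Mean squared deviation from the arithmetic mean (population, 1/N
#' convention). \code{convention = "raw"} returns the un-normalized sum of
#' squared deviations instead.
#'
#' @param v numeric vector of ROI voxel values of one sub-band.
#' @param convention "mean" (default) or "raw".
#' @return scalar.
#' @export
variance_feature <- function(v, convention = c("mean", "raw")) {
  convention <- match.arg(convention)
  if (length(v) == 0) stop("empty ROI: no sub-band voxels to quantify")
  ss <- sum((v - mean(v))^2)
  if (convention == "raw") ss else ss / length(v)
}

#' Texture entropy of sub-band values within the ROI
#'
#' Shannon entropy in bits of the 256-bin (by default) equal-width histogram
#' of the values: \eqn{-\sum_k p_k \log_2 p_k} with \eqn{0 \log 0 := 0}.
#' Zero for a constant sub-band, \eqn{\log_2 n_{bins}} for a uniform one.
#'
#' @inheritParams variance_feature
#' @param spec a [histogram_spec()].
#' @return scalar in \eqn{[0, \log_2 n_{bins}]}.
#' @export
entropy_feature <- function(v, spec = histogram_spec()) {
  p <- bin_probs(v, spec)
  -sum(p * log2(p))
}

#' Texture energy (uniformity) of sub-band values within the ROI
#'
#' \eqn{\sum_k p_k^2} over the same histogram as [entropy_feature()]; equals 1
#' iff all values fall in one bin and \eqn{1/n_{bins}} for a uniform histogram.
#'
#' @inheritParams entropy_feature
#' @return scalar in (0, 1].
#' @export
energy_feature <- function(v, spec = histogram_spec()) {
  p <- bin_probs(v, spec)
  sum(p^2)
}

# Crop volume+mask to the mask bounding box, zero voxels outside the ROI and
# pad (edge-replicating the volume, zero-extending the mask) so both spatial
# dims are even and >= 4. Returns list(vol, mask).
crop_to_roi <- function(vol, mask) {
  if (!all(dim(vol)[1:2] == dim(mask)))
    stop("mask dimensions must match the volume's spatial dimensions")
  m <- mask > 0
  if (!any(m)) stop("empty ROI mask")
  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  v <- vol[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  mk <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  v <- v * as.numeric(rep(mk, dim(v)[3]))          # zero outside the ROI
  pad_axis <- function(v, mk, axis) {
    n <- dim(v)[axis]
    need <- max(4L - n, n %% 2L)
    while (need > 0) {
      if (axis == 1) {
        v <- abind3(v, v[n, , , drop = FALSE], axis = 1)
        mk <- rbind(mk, rep(FALSE, ncol(mk)))
      } else {
        v <- abind3(v, v[, n, , drop = FALSE], axis = 2)
        mk <- cbind(mk, rep(FALSE, nrow(mk)))
      }
      n <- n + 1L
      need <- max(4L - n, n %% 2L)
    }
    list(v = v, mk = mk)
  }
  p <- pad_axis(v, mk, 1)
  p <- pad_axis(p$v, p$mk, 2)
  list(vol = p$v, mask = p$mk)
}

# minimal bind along spatial axes of a 3D array
abind3 <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  if (axis == 1) out <- array(0, c(da[1] + db[1], da[2], da[3]))
  else out <- array(0, c(da[1], da[2] + db[2], da[3]))
  if (axis == 1) { out[seq_len(da[1]), , ] <- a; out[da[1] + seq_len(db[1]), , ] <- b }
  else { out[, seq_len(da[2]), ] <- a; out[, da[2] + seq_len(db[2]), ] <- b }
  out
}

feature_names <- function() {
  as.vector(t(outer(c("variance", "entropy", "energy"), octant_keys(),
                    paste, sep = "_")))
}

#' Extract the 24-feature texture vector of one sample
#'
#' Pipeline for a single multispectral volume and its ROI mask: normalize the
#' volume to unit global SD, crop to the ROI bounding box and zero voxels
#' outside the region, decompose with the single-level db2 3D wavelet
#' transform, and summarize each of the eight octant sub-bands (restricted to
#' the ROI support on the decimated grid) with the variance, entropy and
#' energy quantifiers.
#'
#' @param vol numeric 3D array (x, y, spectral band); even band count.
#' @param mask binary 2D matrix matching the spatial dimensions.
#' @param bank wavelet \code{filter_bank} (default db2).
#' @param spec a [histogram_spec()].
#' @param variance_convention passed to [variance_feature()].
#' @return named numeric vector of 24 features, keyed
#'   \code{<quantifier>_<octant>}.
#' @export
extract_feature_vector <- function(vol, mask, bank = db2_filters(),
                                   spec = histogram_spec(),
                                   variance_convention = "mean") {
  vol <- normalize_volume(vol)
  cr <- crop_to_roi(vol, mask)
  nz <- dim(cr$vol)[3]
  if (nz %% 2 != 0 || nz < 4)
    stop("spectral extent must be even and >= 4")
  sb <- dwt3d(cr$vol, bank)
  dm <- decimate_mask(cr$mask, nz)
  if (!any(dm)) stop("empty decimated ROI mask")
  out <- numeric(0)
  for (k in octant_keys()) {
    v <- sb[[k]][dm]
    out[paste0("variance_", k)] <- variance_feature(v, variance_convention)
    out[paste0("entropy_", k)]  <- entropy_feature(v, spec)
    out[paste0("energy_", k)]   <- energy_feature(v, spec)
  }
  out[feature_names()]
}

#' Extract a feature table from a cohort of labeled samples
#'
#' @param cohort list of labeled samples as produced by [generate_cohort()]
#'   (each with \code{volume}, \code{mask}, \code{label}, \code{sample_id}).
#' @inheritParams extract_feature_vector
#' @return a \code{feature_table}: data.frame with \code{sample_id},
#'   \code{label} and 24 feature columns; attribute
#'   \code{normalization = "raw"}.
#' @export
extract_features <- function(cohort, bank = db2_filters(),
                             spec = histogram_spec(),
                             variance_convention = "mean") {
  rows <- lapply(cohort, function(s) {
    fv <- extract_feature_vector(s$volume, s$mask, bank, spec,
                                 variance_convention)
    data.frame(sample_id = s$sample_id, label = s$label,
               as.list(fv), check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, normalization = "raw", class = c("feature_table",
                                                  "data.frame"))
}

#' Z-score normalize feature columns across samples
#'
#' Each feature column is mapped to \eqn{(r - mean)/\sigma} with the
#' population (1/n) standard deviation taken across samples. A zero-SD column
#' is set to all zeros with a warning.
#'
#' @param table a \code{feature_table} (>= 2 rows).
#' @return the table with transformed feature columns and
#'   \code{normalization = "zscored"}.
#' @export
zscore_table <- function(table) {
  if (nrow(table) < 2) stop("z-scoring needs at least 2 samples")
  cols <- setdiff(names(table), c("sample_id", "label"))
  for (cn in cols) {
    r <- table[[cn]]
    mu <- mean(r)
    sg <- sqrt(mean((r - mu)^2))
    if (sg == 0) {
      warning("feature '", cn, "' is constant across samples; set to zeros")
      table[[cn]] <- rep(0, length(r))
    } else {
      table[[cn]] <- (r - mu) / sg
    }
  }
  attr(table, "normalization") <- "zscored"
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Texture feature table: %d samples x %d features (%s)\n",
              nrow(x), ncol(x) - 2L, attr(x, "normalization")))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$label)),
                                  table(x$label)), collapse = ", "), "\n")
  NextMethod()
}
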