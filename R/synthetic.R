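#' Tissue classes of the colorectal grading problem
#'
#' Stroma (ST), benign hyperplasia (BH), intraepithelial neoplasia (IN) and
#' carcinoma (CA).
#' @export
tissue_classes <- function() c("ST", "BH", "IN", "CA")

#' Simulation parameters for synthetic multispectral histology volumes
#'
#' Controls the synthetic generator that emulates 16-band multispectral
#' whole-slide stacks (500-650 nm) with class-distinct spatial-frequency
#' texture. Class differences are expressed as offsets from a shared baseline
#' and scaled by \code{effect_scale}: at \code{effect_scale = 0} all four
#' classes are drawn from one texture distribution (a null generator), at 1
#' they are separated by the frozen default offsets.
#'
#' @param width,height frame size in pixels (defaults 128; the full-scale
#'   acquisition frame is 512).
#' @param n_bands number of spectral bands (default 16, even, >= 2).
#' @param wavelength_start,wavelength_end spectral range in nm (500, 650).
#' @param blob_density nuclei blobs per 1000 px^2 inside the lesion (baseline).
#' @param blob_radius_mean,blob_radius_sd blob radius distribution, pixels.
#' @param blob_contrast blob amplitude relative to the tissue base intensity.
#' @param background_correlation_length Gaussian correlation length (pixels)
#'   of the smooth tissue background field.
#' @param spectral_slope fractional intensity change across the band range.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param effect_scale multiplier (>= 0) on the class-specific offsets.
#' @param seed integer seed recorded with the parameters.
#' @return object of class \code{sim_params}.
#' @export
sim_params <- function(width = 128L, height = 128L, n_bands = 16L,
                       wavelength_start = 500, wavelength_end = 650,
                       blob_density = 5, blob_radius_mean = 3,
                       blob_radius_sd = 0.7, blob_contrast = 0.9,
                       background_correlation_length = 5,
                       spectral_slope = 0.15, noise_sd = 0.03,
                       effect_scale = 1, seed = 1L) {
  if (width <= 0 || height <= 0) stop("frame dimensions must be positive")
  if (n_bands < 2) stop("n_bands must be >= 2")
  if (wavelength_end <= wavelength_start)
    stop("wavelength_end must exceed wavelength_start")
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_bands = as.integer(n_bands),
                 wavelength_start = wavelength_start,
                 wavelength_end = wavelength_end,
                 blob_density = blob_density,
                 blob_radius_mean = blob_radius_mean,
                 blob_radius_sd = blob_radius_sd,
                 blob_contrast = blob_contrast,
                 background_correlation_length = background_correlation_length,
                 spectral_slope = spectral_slope,
                 noise_sd = noise_sd,
                 effect_scale = effect_scale, seed = as.integer(seed)),
            class = "sim_params")
}

#' Band-center wavelengths of the simulated acquisition
#'
#' Evenly spaced band centers: spacing is
#' \code{(wavelength_end - wavelength_start)/n_bands}, constant across
#' successive bands (9.375 nm for the default 16 bands over 500-650 nm).
#'
#' @param params a [sim_params()].
#' @return numeric vector of \code{n_bands} wavelengths in nm.
#' @export
band_wavelengths <- function(params) {
  if (params$n_bands < 2) stop("n_bands must be >= 2")
  step <- (params$wavelength_end - params$wavelength_start) / params$n_bands
  params$wavelength_start + step * (seq_len(params$n_bands) - 0.5)
}

# Frozen per-class offsets from the shared baseline, applied as
# baseline + effect_scale * offset. Chosen once so that carcinoma has dense,
# small, high-contrast nuclei and rough short-range background while stroma is
# smooth and sparse; intermediate grades interpolate. Documented in the
# methods vignette.
class_offsets <- function() {
  list(
    ST = list(blob_density = -4.5, blob_radius_mean =  3.0,
              blob_contrast = -0.70, background_correlation_length =  7.0,
              spectral_slope = -0.12),
    BH = list(blob_density = -1.0, blob_radius_mean =  0.8,
              blob_contrast = -0.30, background_correlation_length =  1.5,
              spectral_slope = -0.04),
    IN = list(blob_density =  2.0, blob_radius_mean = -0.8,
              blob_contrast =  0.30, background_correlation_length = -2.0,
              spectral_slope =  0.06),
    CA = list(blob_density =  7.0, blob_radius_mean = -1.8,
              blob_contrast =  0.80, background_correlation_length = -3.5,
              spectral_slope =  0.18)
  )
}

effective_params <- function(label, params) {
  off <- class_offsets()[[label]]
  p <- params
  for (nm in names(off))
    p[[nm]] <- params[[nm]] + params$effect_scale * off[[nm]]
  p$blob_density <- max(p$blob_density, 0.2)
  p$blob_radius_mean <- max(p$blob_radius_mean, 1)
  p$background_correlation_length <-
    max(p$background_correlation_length, 0.8)
  p
}

# Stationary Gaussian random field via FFT filtering of white noise with a
# Gaussian kernel of the given correlation length; unit variance output.
gaussian_field <- function(w, h, corr_len) {
  z <- matrix(stats::rnorm(w * h), w, h)
  fx <- c(0:(w %/% 2), -((ceiling(w / 2) - 1):1)) / w
  fy <- c(0:(h %/% 2), -((ceiling(h / 2) - 1):1)) / h
  filt <- exp(-2 * pi^2 * corr_len^2 *
                (outer(fx^2, rep(1, h)) + outer(rep(1, w), fy^2)))
  f <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (w * h)
  s <- stats::sd(as.numeric(f))
  if (s > 0) f / s else f
}

# Smoothed star-convex polygon mask occupying roughly 20-60% of the frame.
star_mask <- function(w, h) {
  cx <- w * stats::runif(1, 0.4, 0.6)
  cy <- h * stats::runif(1, 0.4, 0.6)
  n_arm <- 12L
  base_r <- min(w, h) * stats::runif(1, 0.27, 0.42)
  radii <- base_r * stats::runif(n_arm, 0.65, 1.35)
  # periodic smoothing of arm radii
  radii <- (radii + radii[c(2:n_arm, 1)] + radii[c(n_arm, 1:(n_arm - 1))]) / 3
  ang <- seq(0, 2 * pi, length.out = n_arm + 1)[-(n_arm + 1)]
  px <- rep(seq_len(w), h); py <- rep(seq_len(h), each = w)
  theta <- atan2(py - cy, px - cx) %% (2 * pi)
  rr <- sqrt((px - cx)^2 + (py - cy)^2)
  # linear interpolation of the boundary radius around the circle
  i0 <- findInterval(theta, ang)
  i0[i0 == 0] <- n_arm
  i1 <- i0 %% n_arm + 1L
  t0 <- (theta - ang[i0]) / (2 * pi / n_arm)
  rbound <- radii[i0] * (1 - t0) + radii[i1] * t0
  matrix(as.integer(rr <= rbound), w, h)
}

# Elliptical Gaussian "nuclei" blobs added inside the mask.
add_blobs <- function(field, mask, density, r_mean, r_sd, contrast) {
  w <- nrow(field); h <- ncol(field)
  n_area <- sum(mask)
  n_blob <- stats::rpois(1, density * n_area / 1000)
  if (n_blob == 0) return(field)
  idx <- which(mask > 0)
  pick <- idx[sample.int(length(idx), n_blob, replace = TRUE)]
  bx <- (pick - 1) %% w + 1
  by <- (pick - 1) %/% w + 1
  for (b in seq_len(n_blob)) {
    r <- max(stats::rnorm(1, r_mean, r_sd), 0.8)
    ecc <- stats::runif(1, 0.6, 1)
    amp <- contrast * stats::runif(1, 0.7, 1.3) * sample(c(-1, 1), 1)
    ext <- ceiling(3 * r)
    xs <- max(1, bx[b] - ext):min(w, bx[b] + ext)
    ys <- max(1, by[b] - ext):min(h, by[b] + ext)
    dx2 <- (xs - bx[b])^2
    dy2 <- ((ys - by[b]) / ecc)^2
    g <- exp(-(outer(dx2, rep(1, length(ys))) +
                 outer(rep(1, length(xs)), dy2)) / (2 * r^2))
    field[xs, ys] <- field[xs, ys] + amp * g
  }
  field
}

#' Generate one labeled synthetic multispectral sample
#'
#' Builds a (width, height, n_bands) volume: inside a smoothed star-convex
#' lesion mask, a correlated tissue background plus elliptical nuclei blobs
#' with class-specific density/size/contrast; outside, a dimmer smooth
#' background. The spectral axis is modulated by a class-specific monotone
#' attenuation profile plus a band-to-band texture ripple, and i.i.d. Gaussian
#' noise is added. Identical (label, params, seed) reproduce the volume
#' bit-for-bit.
#'
#' @param label one of [tissue_classes()].
#' @param params a [sim_params()].
#' @param seed integer seed for this sample.
#' @return a \code{labeled_sample}: list with \code{volume} (array),
#'   \code{mask} (0/1 matrix), \code{label}, \code{sample_id} and
#'   \code{wavelengths}.
#' @export
generate_sample <- function(label, params = sim_params(),
                            seed = params$seed) {
  if (!label %in% tissue_classes())
    stop("unknown tissue class '", label, "'; expected one of ",
         paste(tissue_classes(), collapse = ", "))
  if (params$width < 8 || params$height < 8 || params$n_bands < 2)
    stop("degenerate volume dimensions")
  p <- effective_params(label, params)
  w <- p$width; h <- p$height; nb <- p$n_bands
  set.seed(as.integer(seed))
  mask <- star_mask(w, h)

  bg_out <- 0.30 + 0.05 * gaussian_field(w, h, 8)
  tissue <- 0.65 + 0.18 * gaussian_field(w, h, p$background_correlation_length)
  tissue <- add_blobs(tissue, mask, p$blob_density, p$blob_radius_mean,
                      p$blob_radius_sd, p$blob_contrast)
  plane <- ifelse(mask > 0, tissue, bg_out)

  # spectral modulation: monotone attenuation across bands plus a band ripple
  # whose roughness tracks the class (puts class signal in spectral-detail
  # octants as well)
  t_band <- (seq_len(nb) - 1) / (nb - 1)
  atten <- 1 + p$spectral_slope * (t_band - 0.5)
  ripple_sd <- max(0.005, 0.02 + 0.25 * (p$spectral_slope - 0.15))
  ripple <- 1 + stats::rnorm(nb, 0, ripple_sd)
  vol <- array(0, c(w, h, nb))
  for (b in seq_len(nb)) {
    band_field <- 1 + 0.05 * gaussian_field(w, h,
                                            p$background_correlation_length)
    vol[, , b] <- plane * atten[b] * ripple[b] * band_field +
      stats::rnorm(w * h, 0, p$noise_sd)
  }
  structure(list(volume = vol, mask = mask, label = label,
                 sample_id = sprintf("%s_seed%d", label, as.integer(seed)),
                 wavelengths = band_wavelengths(params)),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("Synthetic multispectral sample %s (class %s): %d x %d x %d, ROI %d px\n",
              x$sample_id, x$label, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Generate a labeled cohort of synthetic samples
#'
#' Per-sample seeds are derived as \code{seed + index}, so cohorts are
#' reproducible while samples stay independent. The default class counts
#' mirror a 39-patient colorectal cohort (ST 9, BH 10, IN 9, CA 11).
#'
#' @param counts named or positional integer vector of per-class sample counts
#'   in the order ST, BH, IN, CA.
#' @param params a [sim_params()].
#' @param seed integer cohort seed.
#' @return list of \code{labeled_sample} objects.
#' @export
generate_cohort <- function(counts = c(ST = 9, BH = 10, IN = 9, CA = 11),
                            params = sim_params(), seed = params$seed) {
  if (is.null(names(counts))) names(counts) <- tissue_classes()
  if (any(counts < 0)) stop("class counts must be >= 0")
  labels <- rep(names(counts), counts)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    out[[i]] <- generate_sample(labels[i], params, seed = seed + i)
    out[[i]]$sample_id <- sprintf("S%02d_%s", i, labels[i])
  }
  out
}
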