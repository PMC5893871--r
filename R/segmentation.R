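#' Mean image across spectral bands
#'
#' @param vol 3D array (x, y, band).
#' @return 2D matrix of band-averaged intensities.
#' @export
band_mean <- function(vol) {
  if (length(dim(vol)) != 3) stop("expected a 3D volume")
  apply(vol, c(1, 2), mean)
}

# Block-mean down-sampling by an integer factor; trailing rows/columns that do
# not fill a block are dropped.
block_mean <- function(img, factor) {
  w <- nrow(img) %/% factor * factor
  h <- ncol(img) %/% factor * factor
  img <- img[seq_len(w), seq_len(h), drop = FALSE]
  out <- matrix(0, w %/% factor, h %/% factor)
  for (i in seq_len(factor)) for (j in seq_len(factor))
    out <- out + img[seq(i, w, factor), seq(j, h, factor), drop = FALSE]
  out / factor^2
}

# Two-phase region-competition sweep loop: each pixel joins the phase with
# the higher Gaussian likelihood (phase mean and SD re-estimated every
# sweep), followed by 3x3 majority smoothing as the curvature/regularization
# step. Modelling per-phase variance keeps the wide-variance tissue phase
# from shedding its own intensity dips to the narrow background phase; each
# SD is floored at a tenth of the global image SD so a perfectly flat phase
# cannot claim an unbounded halo. Stops when the mask changes by less than
# tol (fraction of pixels) or at max_iter.
acwe_iterate <- function(img, u, tol, max_iter) {
  floor_sd <- 0.1 * stats::sd(as.numeric(img))
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    inside <- u > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside]); c2 <- mean(img[!inside])
    s1 <- max(stats::sd(img[inside]), floor_sd, na.rm = TRUE)
    s2 <- max(stats::sd(img[!inside]), floor_sd, na.rm = TRUE)
    d1 <- (img - c1)^2 / (2 * s1^2) + log(s1)
    d2 <- (img - c2)^2 / (2 * s2^2) + log(s2)
    u_new <- majority3((d1 < d2) * 1)
    changed <- mean(u_new != u)
    u <- u_new
    if (changed < tol) break
  }
  list(u = u, iterations = iters)
}

# One sweep of 3x3 majority smoothing used as the curvature/regularization
# step of the morphological two-phase contour.
majority3 <- function(u) {
  w <- nrow(u); h <- ncol(u)
  p <- matrix(0, w + 2, h + 2)
  p[2:(w + 1), 2:(h + 1)] <- u
  # replicate borders
  p[1, ] <- p[2, ]; p[w + 2, ] <- p[w + 1, ]
  p[, 1] <- p[, 2]; p[, h + 2] <- p[, h + 1]
  s <- matrix(0, w, h)
  for (di in 0:2) for (dj in 0:2)
    s <- s + p[(1 + di):(w + di), (1 + dj):(h + dj)]
  (s >= 5) * 1
}

#' Semi-automatic region detection by a region-based active contour
#'
#' Emulates the semi-automatic lesion detection stage: the image is block-mean
#' down-sampled by \code{downsample} in each spatial dimension, a two-phase
#' region-based contour (a morphological Chan-Vese variant with per-phase
#' Gaussian statistics, so a textured region does not shed its intensity dips
#' to a uniform background) evolves from a full-frame rectangular
#' initialization, iterations stop automatically when
#' the mask changes by less than \code{tol} (fraction of pixels) between
#' sweeps or at \code{max_iter}, and the converged mask is up-sampled back to
#' the original resolution (nearest neighbour), refined by a short
#' full-resolution pass of the same evolution on a lightly blurred image so
#' the boundary is neither locked to the coarse block grid nor perforated by
#' within-tissue texture, closed with a 3x3 morphological closing,
#' hole-filled and split into connected components. The phase overlapping the
#' image border most is taken as background. All detected regions are
#' returned so a pathologist (or [select_regions()]) can choose which to
#' analyse.
#'
#' @param image 2D matrix (e.g. [band_mean()] of a volume), at least 16 x 16.
#' @param downsample integer spatial down-sampling factor (default 8).
#' @param tol relative mask-change stopping threshold (default 1e-3).
#' @param max_iter iteration cap (default 500).
#' @param min_region_px connected components smaller than this many pixels at
#'   full resolution are dropped (default 50).
#' @param refine_blur_sigma Gaussian blur SD (pixels) applied to the image for
#'   the full-resolution refinement pass; 0 disables blurring (default 2).
#' @return object of class \code{segmentation}: list with \code{labels}
#'   (integer matrix, 0 background, 1..K region ids), \code{n_regions} and
#'   \code{iterations}.
#' @export
segment <- function(image, downsample = 8L, tol = 1e-3, max_iter = 500L,
                    min_region_px = 50L, refine_blur_sigma = 2) {
  if (length(dim(image)) != 2 || any(dim(image) < 16))
    stop("segment expects a 2D image of at least 16 x 16 pixels")
  d0 <- dim(image)
  if (stats::sd(as.numeric(image)) == 0)
    return(structure(list(labels = matrix(0L, d0[1], d0[2]),
                          n_regions = 0L, iterations = 0L),
                     class = "segmentation"))
  small <- block_mean(image, downsample)
  w <- nrow(small); h <- ncol(small)
  # rectangular initialization on the image extreme: everything inside a
  # one-pixel frame starts as foreground
  u <- matrix(0, w, h)
  u[2:(w - 1), 2:(h - 1)] <- 1
  coarse <- acwe_iterate(small, u, tol, max_iter)
  u <- coarse$u
  iters <- coarse$iterations
  # decide which phase is the object: the phase that dominates the image
  # border is background
  border <- c(u[1, ], u[w, ], u[, 1], u[, h])
  fg <- if (mean(border) > 0.5) 1 - u else u
  if (!any(fg > 0))
    return(structure(list(labels = matrix(0L, d0[1], d0[2]),
                          n_regions = 0L, iterations = iters),
                     class = "segmentation"))
  # nearest-neighbour up-sampling to the original frame, then a short
  # full-resolution refinement of the contour so the boundary is not locked
  # to the coarse block grid
  ii <- pmin(ceiling(seq_len(d0[1]) / downsample), w)
  jj <- pmin(ceiling(seq_len(d0[2]) / downsample), h)
  full <- matrix(fg[ii, jj], d0[1], d0[2])
  smoothed <- if (refine_blur_sigma > 0)
    as.matrix(EBImage::imageData(EBImage::gblur(image,
                                                sigma = refine_blur_sigma)))
  else image
  refined <- acwe_iterate(smoothed, full, tol, min(max_iter, 100L))
  iters <- iters + refined$iterations
  full <- refined$u
  border <- c(full[1, ], full[d0[1], ], full[, 1], full[, d0[2]])
  if (mean(border) > 0.5) full <- 1 - full
  closed <- EBImage::fillHull(
    EBImage::closing(full, EBImage::makeBrush(3, shape = "box")))
  lab <- EBImage::bwlabel(closed)
  # drop speckle components and relabel 1..K by decreasing size
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_region_px)
  out <- matrix(0L, d0[1], d0[2])
  keep <- keep[order(-sizes[keep])]
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  structure(list(labels = out, n_regions = length(keep),
                 iterations = iters),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Active-contour segmentation: %d region(s) after %d iteration(s)\n",
              x$n_regions, x$iterations))
  if (x$n_regions > 0) {
    sz <- tabulate(x$labels[x$labels > 0], nbins = x$n_regions)
    cat("  region sizes (px):", paste(sz, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select detected regions into a single ROI mask
#'
#' Stands in for the pathologist's choice of which detected regions enter the
#' texture analysis.
#'
#' @param result a \code{segmentation} from [segment()].
#' @param region_ids integer ids of the regions to keep; an empty selection
#'   yields an empty (all-zero) mask.
#' @return binary 0/1 matrix of the union of the selected regions.
#' @export
select_regions <- function(result, region_ids) {
  valid <- seq_len(result$n_regions)
  bad <- setdiff(region_ids, valid)
  if (length(bad) > 0)
    stop("unknown region id(s) ", paste(bad, collapse = ", "),
         "; valid ids: ", if (length(valid)) paste(valid, collapse = ", ")
         else "(none)")
  (matrix(result$labels %in% region_ids,
          nrow(result$labels), ncol(result$labels))) * 1
}

#' Segmentation agreement metrics (Jaccard, Dice, FPR, FNR)
#'
#' With A the ground-truth region and B the predicted region:
#' JSC = |A n B| / |A u B|, DSC = 2|A n B| / (|A| + |B|),
#' FPR = |B \\ A| / |complement of A|, FNR = |A \\ B| / |A|.
#'
#' @param truth,pred binary masks of equal dimensions; \code{truth} non-empty.
#' @return object of class \code{similarity_metrics} with elements \code{jsc},
#'   \code{dsc}, \code{fpr}, \code{fnr}.
#' @export
similarity_metrics <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred)))
    stop("truth and pred masks must have identical dimensions")
  a <- truth > 0; b <- pred > 0
  na <- sum(a)
  if (na == 0) stop("ground-truth mask is empty")
  inter <- sum(a & b)
  uni <- sum(a | b)
  ncomp <- sum(!a)
  structure(list(
    jsc = inter / uni,
    dsc = 2 * inter / (na + sum(b)),
    fpr = if (ncomp > 0) sum(b & !a) / ncomp else NA_real_,
    fnr = sum(a & !b) / na
  ), class = "similarity_metrics")
}

#' @export
print.similarity_metrics <- function(x, ...) {
  cat(sprintf("JSC %.4f | DSC %.4f | FPR %.4f | FNR %.4f\n",
              x$jsc, x$dsc, x$fpr, x$fnr))
  invisible(x)
}
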