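#' Daubechies-2 analysis/synthesis filter bank
#'
#' Returns the 4-tap orthonormal Daubechies-2 (db2) filter pair used for the
#' single-level 3D decomposition. The decomposition low-pass is
#' \eqn{g = (1+\sqrt3,\ 3+\sqrt3,\ 3-\sqrt3,\ 1-\sqrt3)/(4\sqrt2)} and the
#' high-pass is its alternating flip (quadrature mirror), so that
#' \eqn{\sum g = \sqrt2}, \eqn{\sum h = 0} and \eqn{\sum g^2 = 1}.
#'
#' @return An object of class \code{filter_bank}: a list with components
#'   \code{dec_low}, \code{dec_high}, \code{rec_low}, \code{rec_high} and
#'   \code{name}.
#' @examples
#' fb <- db2_filters()
#' sum(fb$dec_low)   # sqrt(2)
#' sum(fb$dec_high)  # 0
#' @export
db2_filters <- function() {
  s3 <- sqrt(3)
  g <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  # alternating flip: h[k] = (-1)^(k-1) g[L-k+1]
  h <- rev(g) * c(1, -1, 1, -1)
  structure(list(dec_low = g, dec_high = h,
                 rec_low = rev(g), rec_high = rev(h),
                 name = "db2"),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("Orthonormal wavelet filter bank:", x$name,
      sprintf("(%d taps)\n", length(x$dec_low)))
  cat("  dec_low :", format(x$dec_low, digits = 6), "\n")
  cat("  dec_high:", format(x$dec_high, digits = 6), "\n")
  invisible(x)
}

# Periodized orthogonal analysis matrix for signal length n: the first n/2
# rows carry even shifts of the low-pass, the rest even shifts of the
# high-pass. Orthogonality of the db2 pair makes W an orthogonal matrix, so
# synthesis is t(W) and Parseval holds exactly.
analysis_matrix <- function(n, bank) {
  if (n %% 2 != 0 || n < 4)
    stop("signal length must be even and >= 4, got ", n)
  g <- bank$dec_low; h <- bank$dec_high
  L <- length(g)
  W <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    idx <- ((2L * (i - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (k in seq_len(L)) {
      W[i, idx[k]] <- W[i, idx[k]] + g[k]
      W[i + n / 2, idx[k]] <- W[i + n / 2, idx[k]] + h[k]
    }
  }
  W
}

#' Single-level 1D discrete wavelet transform (periodized)
#'
#' Convolve-and-decimate by two with periodic boundary handling; each output
#' half has length \code{length(x)/2}.
#'
#' @param x numeric vector of even length >= 4.
#' @param bank a \code{filter_bank}, e.g. \code{db2_filters()}.
#' @return list with numeric vectors \code{approx} and \code{detail}.
#' @seealso [idwt1d()], [dwt3d()]
#' @export
dwt1d <- function(x, bank = db2_filters()) {
  n <- length(x)
  if (n %% 2 != 0 || n < 4)
    stop("dwt1d needs an even-length signal of length >= 4")
  y <- analysis_matrix(n, bank) %*% x
  list(approx = y[seq_len(n / 2)], detail = y[n / 2 + seq_len(n / 2)])
}

#' Inverse of [dwt1d()]
#'
#' @param approx,detail equal-length coefficient vectors.
#' @param bank a \code{filter_bank}.
#' @return reconstructed numeric vector of length \code{2 * length(approx)}.
#' @export
idwt1d <- function(approx, detail, bank = db2_filters()) {
  if (length(approx) != length(detail))
    stop("approx and detail must have equal length")
  n <- 2L * length(approx)
  as.numeric(t(analysis_matrix(n, bank)) %*% c(approx, detail))
}

# Apply the analysis (or synthesis, transpose = TRUE) operator along one axis
# of a 3D array by unfolding that axis to the rows of a matrix.
apply_axis <- function(vol, axis, bank, transpose = FALSE) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(vol, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], dm[2] * dm[3])
  W <- analysis_matrix(dm[1], bank)
  out <- if (transpose) t(W) %*% m else W %*% m
  dim(out) <- dm
  aperm(out, order(perm))
}

octant_keys <- function() c("LLL", "HLL", "LHL", "HHL",
                            "LLH", "HLH", "LHH", "HHH")

#' Single-level 3D discrete wavelet transform into octant sub-bands
#'
#' Applies the periodized 1D transform independently along the x and y image
#' axes and then along the spectral z axis (the 2D + 1D scheme), splitting the
#' volume into the eight octant sub-bands LLL, HLL, LHL, HHL, LLH, HLH, LHH,
#' HHH. Letter i of an octant key names the filter (L = low, H = high)
#' applied on axis i in the order (x, y, z). The transform is separable: any
#' axis ordering yields the same coefficients.
#'
#' @param vol numeric 3D array; every dimension even and >= 4.
#' @param bank a \code{filter_bank} (default db2).
#' @return An object of class \code{subband_set}: a list of eight sub-volumes
#'   of dimension \code{dim(vol)/2} keyed by octant, with attributes
#'   \code{filter} and \code{boundary}.
#' @examples
#' v <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
#' sb <- dwt3d(v)
#' sum(sapply(sb, function(b) sum(b^2))) - sum(v^2)  # ~0: Parseval
#' @export
dwt3d <- function(vol, bank = db2_filters()) {
  if (length(dim(vol)) != 3)
    stop("dwt3d expects a 3D array")
  d <- dim(vol)
  if (any(d %% 2 != 0) || any(d < 4))
    stop("all three dimensions must be even and >= 4; got ",
         paste(d, collapse = " x "))
  w <- vol
  for (ax in 1:3) w <- apply_axis(w, ax, bank)
  h <- d %/% 2L
  pick <- function(cx, cy, cz) {
    ix <- if (cx == "L") seq_len(h[1]) else h[1] + seq_len(h[1])
    iy <- if (cy == "L") seq_len(h[2]) else h[2] + seq_len(h[2])
    iz <- if (cz == "L") seq_len(h[3]) else h[3] + seq_len(h[3])
    w[ix, iy, iz, drop = FALSE]
  }
  keys <- octant_keys()
  sb <- lapply(keys, function(k) {
    p <- strsplit(k, "")[[1]]
    pick(p[1], p[2], p[3])
  })
  names(sb) <- keys
  structure(sb, class = "subband_set", filter = bank$name,
            boundary = "periodization", original_dim = d)
}

#' @export
print.subband_set <- function(x, ...) {
  d <- dim(x[[1]])
  cat("Octant sub-band set (single-level 3D DWT)\n")
  cat("  filter:", attr(x, "filter"), "| boundary:", attr(x, "boundary"), "\n")
  cat("  8 octants of", paste(d, collapse = " x "), "coefficients:",
      paste(names(x), collapse = " "), "\n")
  invisible(x)
}

#' Inverse single-level 3D wavelet transform
#'
#' Reassembles the eight octants and inverts the three 1D passes; with the
#' orthonormal periodized bank the reconstruction is exact to round-off.
#'
#' @param subbands a \code{subband_set} from [dwt3d()].
#' @param bank a \code{filter_bank}; must match the analysis bank.
#' @return numeric 3D array of the original dimensions.
#' @export
idwt3d <- function(subbands, bank = db2_filters()) {
  keys <- octant_keys()
  if (!all(keys %in% names(subbands)))
    stop("subband_set must contain all eight octants")
  dims <- lapply(subbands[keys], dim)
  if (any(vapply(dims, length, 1L) != 3) ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("octant shapes are inconsistent")
  h <- dims[[1]]
  d <- 2L * h
  w <- array(0, d)
  for (k in keys) {
    p <- strsplit(k, "")[[1]]
    ix <- if (p[1] == "L") seq_len(h[1]) else h[1] + seq_len(h[1])
    iy <- if (p[2] == "L") seq_len(h[2]) else h[2] + seq_len(h[2])
    iz <- if (p[3] == "L") seq_len(h[3]) else h[3] + seq_len(h[3])
    w[ix, iy, iz] <- subbands[[k]]
  }
  for (ax in 3:1) w <- apply_axis(w, ax, bank, transpose = TRUE)
  w
}

#' Decimate a 2D ROI mask onto the octant sub-band grid
#'
#' Texture quantifiers are evaluated only on sub-band voxels whose parent
#' voxels intersect the segmented region. The 2D mask is replicated across the
#' spectral extent, and each 2 x 2 x 2 parent cell maps to one sub-band voxel,
#' included iff any parent voxel lies in the ROI.
#'
#' @param mask binary 2D matrix (0/1 or logical) with even dimensions.
#' @param z_extent even number of spectral bands of the parent volume.
#' @return logical 3D array of dimension \code{c(dim(mask)/2, z_extent/2)}.
#' @export
decimate_mask <- function(mask, z_extent) {
  if (length(dim(mask)) != 2) stop("mask must be a 2D matrix")
  d <- dim(mask)
  if (any(d %% 2 != 0) || z_extent %% 2 != 0)
    stop("mask dimensions and z_extent must be even")
  m <- mask > 0
  hx <- d[1] %/% 2L; hy <- d[2] %/% 2L
  m2 <- m[seq(1, d[1], 2), seq(1, d[2], 2), drop = FALSE] |
        m[seq(2, d[1], 2), seq(1, d[2], 2), drop = FALSE] |
        m[seq(1, d[1], 2), seq(2, d[2], 2), drop = FALSE] |
        m[seq(2, d[1], 2), seq(2, d[2], 2), drop = FALSE]
  array(rep(m2, z_extent %/% 2L), c(hx, hy, z_extent %/% 2L))
}
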