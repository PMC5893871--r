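#' Read a multispectral volume from a multi-page TIFF
#'
#' Pages are stacked along the spectral axis in page order (assumed
#' wavelength-ascending; set \code{reverse_bands} if the stack was written
#' red-to-blue). Intensities are returned as reals on the scale stored in the
#' file.
#'
#' @param path TIFF file with >= 2 grayscale pages of identical dimensions.
#' @param reverse_bands reverse the spectral page order.
#' @return numeric 3D array (x, y, band).
#' @export
read_volume <- function(path, reverse_bands = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("'", path, "' is not a multispectral stack (needs >= 2 pages)")
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    pages <- lapply(pages, function(p) if (length(dim(p)) > 2) p[, , 1] else p)
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE)))
    stop("mixed page dimensions in '", path, "'")
  if (reverse_bands) pages <- rev(pages)
  vol <- array(0, c(d1[1], d1[2], length(pages)))
  for (b in seq_along(pages)) vol[, , b] <- pages[[b]]
  vol
}

#' Write a multispectral volume as a 16-bit multi-page TIFF
#'
#' Intensities are min-max scaled to [0, 1] for storage (16-bit grayscale,
#' one page per band); [read_volume()] round-trips the stored values exactly.
#'
#' @param vol numeric 3D array.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  rng <- range(vol)
  sc <- if (rng[2] > rng[1]) (vol - rng[1]) / (rng[2] - rng[1]) else vol * 0
  # quantize to the 16-bit grid so a write/read round trip is bit-exact
  sc <- round(sc * 65535) / 65535
  pages <- lapply(seq_len(dim(vol)[3]), function(b) sc[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary ROI mask from a PNG or TIFF image
#'
#' @param path single-channel image; any value above half range counts as
#'   in-region.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) > 2) img <- img[, , 1]
  (img > 0.5) * 1L
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path output file ending in .png.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Write a cohort of synthetic samples to disk
#'
#' Writes each sample's volume as a multi-page TIFF and its ground-truth mask
#' as a PNG, plus a manifest CSV with columns sample_id, label, volume_path,
#' mask_path.
#'
#' @param cohort list of labeled samples from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    vp <- file.path(dir, paste0(s$sample_id, ".tiff"))
    mp <- file.path(dir, paste0(s$sample_id, "_mask.png"))
    write_volume(s$volume, vp)
    write_mask(s$mask, mp)
    data.frame(sample_id = s$sample_id, label = s$label,
               volume_path = vp, mask_path = mp)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read and validate a sample manifest
#'
#' @param path manifest CSV with columns sample_id, label, volume_path,
#'   mask_path (mask_path may be empty if segmentation is enabled).
#' @return data.frame of the validated manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "volume_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest")
  bad <- setdiff(unique(m$label), tissue_classes())
  if (length(bad) > 0)
    stop("unknown label(s) in manifest: ", paste(bad, collapse = ", "))
  missing <- m$volume_path[!file.exists(m$volume_path)]
  if (length(missing) > 0)
    stop("missing volume file(s): ", paste(missing, collapse = ", "))
  m
}

#' Run the full texture-analysis pipeline over a manifest
#'
#' For every sample: read the volume, take the provided mask (or detect one
#' with [segment()] on the band-mean image when \code{segment_missing} is
#' TRUE, selecting all detected regions), extract the 24 texture features,
#' z-score across samples, run the univariate ANOVA/Holm report and the
#' cross-validated random-forest evaluation. Artifacts are written under
#' \code{out_dir}: \code{features.csv}, \code{stats_report.json},
#' \code{cv_report.json} and \code{provenance.json}.
#'
#' @param manifest data.frame from [read_manifest()] or a path to one.
#' @param out_dir output directory.
#' @param seed integer seed for fold assignment and forests.
#' @param alpha familywise significance level of the univariate report.
#' @param k,n_trees cross-validation folds and forest size.
#' @param segment_missing detect an ROI when mask_path is absent/empty.
#' @return list with \code{features} (z-scored table), \code{stats}
#'   (\code{stats_report}) and \code{cv} (\code{cv_report}), invisibly.
#' @export
run_pipeline <- function(manifest, out_dir, seed = 1L, alpha = 0.01,
                         k = 5L, n_trees = 100L, segment_missing = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    vol <- tryCatch(read_volume(manifest$volume_path[i]),
                    error = function(e) stop("sample '", sid,
                                             "' at stage read: ",
                                             conditionMessage(e)))
    mp <- if ("mask_path" %in% names(manifest)) manifest$mask_path[i] else ""
    if (!is.na(mp) && nzchar(mp) && file.exists(mp)) {
      mask <- read_mask(mp)
    } else if (segment_missing) {
      sr <- segment(band_mean(vol))
      if (sr$n_regions == 0)
        stop("sample '", sid, "' at stage segment: no region detected")
      mask <- select_regions(sr, seq_len(sr$n_regions))
      message("sample '", sid, "': mask detected by active contour (",
              sr$n_regions, " region(s))")
    } else {
      stop("sample '", sid, "' has no mask and segmentation is disabled")
    }
    cohort[[i]] <- list(volume = vol, mask = mask,
                        label = manifest$label[i], sample_id = sid)
  }
  features <- tryCatch(extract_features(cohort),
                       error = function(e) stop("stage extract: ",
                                                conditionMessage(e)))
  z <- zscore_table(features)
  stats_rep <- significance_report(z, alpha = alpha)
  cv_rep <- train_eval_cv(z, k = k, n_trees = n_trees, seed = seed)

  utils::write.csv(cbind(as.data.frame(z)[1:2],
                         round(as.data.frame(z)[-(1:2)], 10)),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(alpha = alpha, m = attr(stats_rep, "m"),
         n_significant = sum(stats_rep$significant),
         features = as.data.frame(stats_rep)),
    file.path(out_dir, "stats_report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(
    list(k = cv_rep$k, n_trees = cv_rep$n_trees, seed = cv_rep$seed,
         mean = as.list(round(cv_rep$mean, 10)),
         sd = as.list(round(cv_rep$sd, 10)),
         auc_mean = as.list(round(cv_rep$auc_mean, 10)),
         fold_metrics = as.data.frame(round(cv_rep$fold_metrics, 10))),
    file.path(out_dir, "cv_report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(
    list(seed = seed, alpha = alpha, k = k, n_trees = n_trees,
         n_samples = nrow(manifest),
         filter = "db2", boundary = "periodization", n_bins = 256,
         variance_convention = "mean", zscore = "population",
         package_version = as.character(utils::packageVersion("octantex"))),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = z, stats = stats_rep, cv = cv_rep))
}
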