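#' Read a single-channel grayscale image
#'
#' Reads 8/16-bit grayscale TIFF (or PNG) into a [gray_image()], keeping the
#' native integer intensity scale for TIFF. Multi-channel images are
#' rejected: extract one channel upstream (e.g. `img[, , 1]`) and save it as
#' single-channel.
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @param pixel_size pixel size in nm recorded on the image (metadata only).
#' @return a [gray_image()].
#' @export
read_image <- function(path, pixel_size = 32.27) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  m <- if (is_png) png::readPNG(path) else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 1L) {
      m <- m[, , 1]
    } else {
      stop(sprintf(
        "%s has %d channels; extract a single channel (e.g. img[, , 1]) and save it as grayscale",
        path, dim(m)[3]), call. = FALSE)
    }
  }
  if (!is.matrix(m)) stop("unreadable image data in ", path, call. = FALSE)
  gray_image(m, pixel_size = pixel_size)
}

#' Write a grayscale image to TIFF
#'
#' Writes integer intensities as 8- or 16-bit grayscale TIFF. Intensities
#' must fit the requested bit depth; 16-bit data round-trips bit-exactly
#' through [read_image()].
#'
#' @param img a [gray_image()].
#' @param path output path.
#' @param bits 8 or 16.
#' @export
write_image <- function(img, path, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  m <- img_matrix(as_gray_image(img))
  top <- 2^bits - 1
  if (max(m) > top) {
    stop(sprintf("intensities exceed %d-bit range (max %.4g)", bits, max(m)),
         call. = FALSE)
  }
  tiff::writeTIFF(round(m) / top, path, bits.per.sample = bits)
  invisible(path)
}

#' Export a power spectrum
#'
#' `spectrum_to_csv()` writes the centered magnitude grid with its integer
#' frequency indices as row/column names. `write_spectrum_tiff()` writes a
#' 32-bit float TIFF of the magnitudes scaled to \[0, 1\]
#' (`log1p`-compressed when `log = TRUE`, the usual display transform).
#'
#' @param ps a `power_spectrum`.
#' @param path output path.
#' @param log write log1p-compressed magnitudes (TIFF only).
#' @export
spectrum_to_csv <- function(ps, path) {
  stopifnot(inherits(ps, "power_spectrum"))
  m <- ps$magnitudes
  dimnames(m) <- list(v = centered_freq(ps$n), u = centered_freq(ps$n))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname spectrum_to_csv
#' @export
write_spectrum_tiff <- function(ps, path, log = TRUE) {
  stopifnot(inherits(ps, "power_spectrum"))
  m <- ps$magnitudes
  if (log) m <- log1p(m)
  if (max(m) > 0) m <- m / max(m)
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}

#' Extract a square ROI
#'
#' Copies a `size` x `size` region with 0-based, half-open indexing: the ROI
#' covers columns `[x, x + size)` and rows `[y, y + size)` of the source.
#'
#' @param img a [gray_image()].
#' @param top_left numeric `c(x, y)`: 0-based column/row of the ROI's
#'   top-left pixel.
#' @param size ROI side length in pixels (default 128).
#' @return a [gray_image()].
#' @export
extract_square_roi <- function(img, top_left = c(0, 0), size = 128L) {
  m <- as.matrix(img)
  size <- as.integer(size)
  x <- as.integer(top_left[1]); y <- as.integer(top_left[2])
  if (x < 0 || y < 0 || x + size > ncol(m) || y + size > nrow(m)) {
    stop(sprintf(
      "ROI [%d, %d) x [%d, %d) exceeds the %d x %d image; largest corner for size %d is (%d, %d)",
      x, x + size, y, y + size, ncol(m), nrow(m), size,
      max(ncol(m) - size, 0), max(nrow(m) - size, 0)), call. = FALSE)
  }
  gray_image(m[(y + 1):(y + size), (x + 1):(x + size)],
             pixel_size = attr(img, "pixel_size") %||% 32.27)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with the reference
#' protocol's values as defaults: scoring band (1/4, 1/16), ROI side 128 px,
#' mean-fill circular cutout, normalized band score, population-sd CV,
#' trace length 180 samples.
#'
#' @param band_outer,band_inner scoring-band side fractions.
#' @param roi_size square ROI side in pixels.
#' @param fill circular-window fill strategy.
#' @param score_flavor `"normalized"` or `"raw"` band score.
#' @param sd_convention `"population"` or `"sample"` CV.
#' @param trace_length membrane trace length in samples.
#' @param seed optional integer seed echoed into outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(band_outer = 1 / 4, band_inner = 1 / 16,
                       roi_size = 128L, fill = c("mean", "zero"),
                       score_flavor = c("normalized", "raw"),
                       sd_convention = c("population", "sample"),
                       trace_length = 180L, seed = NULL) {
  cfg <- list(band = band_spec(band_outer, band_inner),
              roi_size = as.integer(roi_size),
              fill = match.arg(fill),
              score_flavor = match.arg(score_flavor),
              sd_convention = match.arg(sd_convention),
              trace_length = as.integer(trace_length),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> band (%g, %g), roi %d px, fill %s, score %s, sd %s, trace %d\n",
    x$band$f_outer, x$band$f_inner, x$roi_size, x$fill, x$score_flavor,
    x$sd_convention, x$trace_length))
  invisible(x)
}

#' Read an ROI manifest
#'
#' A manifest is a CSV with columns `subject_id`, `roi_id`, `image_path`,
#' `roi_kind` (`"square"` or `"polyline"`) and `roi_payload` — for square
#' ROIs either empty (use the whole image) or `"x,y"` (0-based top-left
#' corner, side from the config); for polyline ROIs the path of a trace
#' CSV/JSON file. Relative paths resolve against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with validated columns; duplicate `roi_id`s or missing
#'   files are an error.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject_id", "roi_id", "image_path", "roi_kind", "roi_payload")
  miss <- setdiff(need, names(mf))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mf$roi_id)) {
    stop("duplicate roi_id in manifest", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  mf$image_path <- resolve(mf$image_path)
  gone <- !file.exists(mf$image_path)
  if (any(gone)) {
    stop("missing image file(s): ",
         paste(mf$image_path[gone], collapse = ", "), call. = FALSE)
  }
  poly <- mf$roi_kind == "polyline"
  mf$roi_payload[poly] <- resolve(mf$roi_payload[poly])
  mf
}

#' Run a metric over a manifest
#'
#' Applies one metric (`"footprocess"`, `"mito"` or `"membrane"`) to every
#' manifest row. Per-row failures are caught, recorded and reported; the
#' remaining rows still complete. Per-subject means are appended as in the
#' batch functions.
#'
#' @param manifest data.frame from [read_roi_manifest()] (or of the same
#'   shape).
#' @param metric which metric to run.
#' @param config a [run_config()].
#' @return list with `results` (data.frame), `failures` (data.frame of
#'   `roi_id`, `error`) and `config`.
#' @export
run_pipeline <- function(manifest, metric = c("footprocess", "mito", "membrane"),
                         config = run_config()) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  ok <- logical(nrow(manifest))
  errs <- character(nrow(manifest))
  items <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- read_image(row$image_path)
      if (metric %in% c("footprocess", "mito")) {
        if (nzchar(row$roi_payload %||% "") && !is.na(row$roi_payload)) {
          corner <- as.numeric(strsplit(row$roi_payload, ",")[[1]])
          img <- extract_square_roi(img, corner, config$roi_size)
        }
        if (metric == "footprocess") {
          s <- band_power_score(img, config$band, roi_id = row$roi_id)
          data.frame(roi_id = row$roi_id, subject = row$subject_id,
                     level = "roi", value = if (config$score_flavor == "raw")
                       s$score_raw else s$score_normalized,
                     stringsAsFactors = FALSE)
        } else {
          d <- damage_index(img, fill = config$fill)
          data.frame(roi_id = row$roi_id, subject = row$subject_id,
                     level = "roi", value = d$damage_index,
                     stringsAsFactors = FALSE)
        }
      } else {
        roi <- read_polyline(row$roi_payload, config$trace_length)
        tr <- extract_trace(img, roi)
        data.frame(roi_id = row$roi_id, subject = row$subject_id,
                   level = "roi",
                   value = trace_cv(tr, config$sd_convention)$cv,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errs[i] <- res
    } else {
      ok[i] <- TRUE
      items[[i]] <- res
    }
  }
  rows <- do.call(rbind, items[ok])
  agg <- if (!is.null(rows)) {
    do.call(rbind, lapply(unique(rows$subject), function(s) {
      data.frame(roi_id = NA_character_, subject = s, level = "subject",
                 value = mean(rows$value[rows$subject == s]),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  list(results = rbind(rows, agg),
       failures = data.frame(roi_id = manifest$roi_id[!ok],
                             error = errs[!ok], stringsAsFactors = FALSE),
       config = config)
}
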