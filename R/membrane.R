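#' Polyline ROI for membrane tracing
#'
#' An ordered list of (x, y) subpixel vertices tracing a capillary wall in
#' image coordinates (0-based, x = column, y = row, origin top-left),
#' together with the number of samples the trace is linearized to.
#'
#' @param vertices two-column numeric matrix (or data.frame with columns
#'   `x`, `y`) of at least 2 vertices; consecutive vertices must not
#'   coincide.
#' @param target_length number of resampled intensities (default 180, the
#'   1 x 180 pixel trace of the reference protocol).
#' @return a `polyline_roi`.
#' @export
polyline_roi <- function(vertices, target_length = 180L) {
  if (is.data.frame(vertices)) {
    if (!all(c("x", "y") %in% names(vertices))) {
      stop("vertex data.frame needs columns `x` and `y`", call. = FALSE)
    }
    vertices <- cbind(vertices$x, vertices$y)
  }
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L) {
    stop("`vertices` must be an m x 2 matrix with m >= 2", call. = FALSE)
  }
  if (!all(is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  seglen <- sqrt(rowSums(diff(vertices)^2))
  if (any(seglen == 0)) {
    stop("consecutive vertices must not coincide", call. = FALSE)
  }
  target_length <- as.integer(target_length)
  if (target_length < 2L) stop("`target_length` must be >= 2", call. = FALSE)
  structure(list(vertices = unname(vertices), target_length = target_length),
            class = "polyline_roi")
}

#' Read a polyline ROI from CSV or JSON
#'
#' CSV must have a header with columns `x`, `y`; JSON must be a list of
#' \[x, y\] pairs. Coordinates are 0-based with x = column.
#'
#' @param path file path (`.csv` or `.json`).
#' @param target_length see [polyline_roi()].
#' @return a `polyline_roi`.
#' @export
read_polyline <- function(path, target_length = 180L) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- jsonlite::fromJSON(path)
    if (is.list(v)) v <- do.call(rbind, v)
  } else {
    v <- utils::read.csv(path)
  }
  polyline_roi(v, target_length = target_length)
}

#' @export
print.polyline_roi <- function(x, ...) {
  cat(sprintf("<polyline_roi> %d vertices, arc length %.2f px, %d samples\n",
              nrow(x$vertices), sum(sqrt(rowSums(diff(x$vertices)^2))),
              x$target_length))
  invisible(x)
}

#' Linearize a membrane trace
#'
#' Resamples the polyline at `target_length` equally spaced arc-length
#' positions (endpoints included) and reads the image intensity at each
#' subpixel position — bilinear interpolation by default, which is exact on
#' affine intensity ramps; nearest-neighbour is available. Traces whose arc
#' length is below `target_length` pixels are upsampled, with a warning.
#'
#' @param img a [gray_image()] (any rectangular size).
#' @param roi a [polyline_roi()]; every vertex must lie inside the image.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return a `trace_profile`: list with `values` (length `target_length`) and
#'   `source_roi`.
#' @export
extract_trace <- function(img, roi, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  m <- img_matrix(as_gray_image(as.matrix(img)))
  stopifnot(inherits(roi, "polyline_roi"))
  v <- roi$vertices
  w <- ncol(m); h <- nrow(m)
  bad <- which(v[, 1] < 0 | v[, 1] > w - 1 | v[, 2] < 0 | v[, 2] > h - 1)
  if (length(bad)) {
    stop(sprintf("vertex %d at (%.2f, %.2f) lies outside the %d x %d image",
                 bad[1], v[bad[1], 1], v[bad[1], 2], w, h), call. = FALSE)
  }
  seglen <- sqrt(rowSums(diff(v)^2))
  total <- sum(seglen)
  L <- roi$target_length
  if (total < L) {
    warning(sprintf("arc length %.1f px below %d samples; trace is upsampled",
                    total, L))
  }
  s <- seq(0, total, length.out = L)
  cum <- c(0, cumsum(seglen))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(v) - 1L)
  t01 <- (s - cum[seg]) / seglen[seg]
  px <- v[seg, 1] + t01 * (v[seg + 1L, 1] - v[seg, 1])
  py <- v[seg, 2] + t01 * (v[seg + 1L, 2] - v[seg, 2])
  vals <- if (method == "bilinear") bilinear_at(m, px, py) else {
    m[cbind(pmin(pmax(round(py), 0), h - 1) + 1,
            pmin(pmax(round(px), 0), w - 1) + 1)]
  }
  structure(list(values = vals, source_roi = roi), class = "trace_profile")
}

#' @export
print.trace_profile <- function(x, ...) {
  cat(sprintf("<trace_profile> %d samples, mean %.4g, range [%.4g, %.4g]\n",
              length(x$values), mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.trace_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1, x$values, type = "l",
                 xlab = "sample", ylab = "intensity", ...)
  invisible(x)
}

#' Coefficient of variation of a linearized trace
#'
#' CV = population standard deviation / mean of the trace intensities. The
#' population convention (divisor n) is the default because the resampled
#' trace is the full traced object, not a sample from a larger one; the
#' sample convention (divisor n - 1) is available. Higher CV = more
#' irregular membrane signal.
#'
#' @param profile a `trace_profile` (or bare numeric vector).
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return a `trace_stats` list: `mean`, `sd`, `cv`, `n`, `sd_convention`.
#' @export
trace_cv <- function(profile, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  v <- if (inherits(profile, "trace_profile")) profile$values else as.numeric(profile)
  n <- length(v)
  if (n < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  mu <- mean(v)
  if (mu <= 0) {
    stop("CV undefined: trace mean must be positive", call. = FALSE)
  }
  ss <- sum((v - mu)^2)
  s <- sqrt(ss / if (sd_convention == "population") n else n - 1L)
  structure(list(mean = mu, sd = s, cv = s / mu, n = n,
                 sd_convention = sd_convention),
            class = "trace_stats")
}

#' @export
print.trace_stats <- function(x, ...) {
  cat(sprintf("<trace_stats> CV %.4f (mean %.4g, %s sd %.4g, n = %d)\n",
              x$cv, x$mean, x$sd_convention, x$sd, x$n))
  invisible(x)
}

#' CV for a batch of traces with per-subject aggregation
#'
#' Accepts ready-made traces, or images paired with polyline ROIs (extracted
#' with [extract_trace()]). One row per trace plus one mean-CV row per
#' subject (at least 6 traces per patient in the reference protocol).
#'
#' @param traces list of `trace_profile` (or numeric vectors). Alternatively
#'   supply `images` and `rois` of equal length.
#' @param subjects subject label per trace (single value recycled).
#' @param images,rois optional parallel lists used when `traces` is missing.
#' @param sd_convention see [trace_cv()].
#' @param trace_ids optional labels.
#' @return data.frame with columns `trace_id`, `subject`, `level`, `mean`,
#'   `sd`, `cv`.
#' @export
cv_batch <- function(traces = NULL, subjects = "subject_1", images = NULL,
                     rois = NULL, sd_convention = c("population", "sample"),
                     trace_ids = NULL) {
  sd_convention <- match.arg(sd_convention)
  if (is.null(traces)) {
    if (is.null(images) || is.null(rois) || length(images) != length(rois)) {
      stop("supply `traces`, or `images` and `rois` of equal length",
           call. = FALSE)
    }
    traces <- mapply(extract_trace, images, rois, SIMPLIFY = FALSE)
  }
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  k <- length(traces)
  subjects <- rep_len(as.character(subjects), k)
  if (is.null(trace_ids)) trace_ids <- paste0("trace_", seq_len(k))
  st <- lapply(traces, trace_cv, sd_convention = sd_convention)
  rows <- data.frame(
    trace_id = trace_ids,
    subject = subjects,
    level = "trace",
    mean = vapply(st, `[[`, numeric(1), "mean"),
    sd = vapply(st, `[[`, numeric(1), "sd"),
    cv = vapply(st, `[[`, numeric(1), "cv"),
    stringsAsFactors = FALSE
  )
  agg <- do.call(rbind, lapply(unique(subjects), function(s) {
    sel <- rows$subject == s
    data.frame(trace_id = NA_character_, subject = s, level = "subject",
               mean = mean(rows$mean[sel]), sd = NA_real_,
               cv = mean(rows$cv[sel]), stringsAsFactors = FALSE)
  }))
  rbind(rows, agg)
}

# ---- internal ----------------------------------------------------------

# bilinear interpolation at 0-based subpixel (x, y); coordinates clamped to
# the valid cell range so exact-boundary points read the edge pixel
bilinear_at <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
}
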