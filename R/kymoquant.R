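#' Kymograph container
#'
#' A space-time intensity image along a line traced across a junction:
#' rows are frames (time), columns are positions along the line.
#'
#' @param intensity Numeric matrix, time in rows, position in columns;
#'   non-negative.
#' @param pixel_size Length per pixel.
#' @param frame_interval Time per frame (row).
#' @param junction_x Reference (junction) position per frame, in length
#'   units from the first pixel; scalar or one value per frame.  Defaults to
#'   the centre of the line.
#' @param times Optional frame time stamps (default `0, dt, 2 dt, ...`).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_size = 1, frame_interval = 1,
                      junction_x = NULL, times = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) {
    stop("kymograph intensities must be non-negative", call. = FALSE)
  }
  nt <- nrow(intensity)
  extent <- ncol(intensity) * pixel_size
  if (is.null(junction_x)) junction_x <- extent / 2
  junction_x <- rep_len(junction_x, nt)
  if (any(junction_x < 0 | junction_x > extent)) {
    stop("`junction_x` must lie within the line extent", call. = FALSE)
  }
  if (is.null(times)) times <- (seq_len(nt) - 1) * frame_interval
  structure(
    list(
      intensity = intensity, pixel_size = pixel_size,
      frame_interval = frame_interval, junction_x = junction_x,
      times = times
    ),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d frames x %d pixels (%.3g length/px, %.3g time/frame)\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$frame_interval
  ))
  invisible(x)
}

#' Background level estimate for a kymograph
#'
#' Median of the 10 percent lowest-intensity pixels plus three times their
#' standard deviation — a simple "above background" threshold when no
#' explicit background is supplied.
#'
#' @param kymo A [kymograph()].
#' @return A scalar background level.
#' @export
estimate_background <- function(kymo) {
  v <- sort(as.vector(kymo$intensity))
  low <- v[seq_len(max(1L, floor(length(v) * 0.1)))]
  stats::median(low) + 3 * stats::sd(low)
}

#' Quantify zone width and intensity from a kymograph
#'
#' The Fig-7-style quantification: per frame the line is re-centred at the
#' junction position (X = 0), the zone is the maximal contiguous run of
#' above-background pixels containing X = 0, its width is the run length
#' times the pixel size, its intensity the mean over the run; both series
#' are normalized to their values at the first frame.  If the zone at the
#' first frame is empty an error is raised; an empty zone at a later frame
#' contributes width 0 and intensity 0.
#'
#' @param kymo A [kymograph()].
#' @param background Intensity threshold; if `NULL`, estimated with
#'   [estimate_background()].
#' @param temporal_median If `TRUE`, apply a 3-frame running median along
#'   time before thresholding (default off).
#' @return A tibble with columns `time`, `width`, `intensity`, `width_norm`,
#'   `intensity_norm`.
#' @export
quantify_kymograph <- function(kymo, background = NULL,
                               temporal_median = FALSE) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(background)) background <- estimate_background(kymo)
  if (background < 0) stop("background must be non-negative", call. = FALSE)
  img <- kymo$intensity
  if (temporal_median && nrow(img) >= 3) {
    img <- apply(img, 2, function(col) stats::runmed(col, 3))
  }
  nt <- nrow(img)
  np <- ncol(img)
  res <- vapply(seq_len(nt), function(i) {
    jpix <- min(max(1L, round(kymo$junction_x[i] / kymo$pixel_size + 0.5)), np)
    above <- img[i, ] > background
    if (!above[jpix]) {
      return(c(0, 0))
    }
    lo <- jpix
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- jpix
    while (hi < np && above[hi + 1]) hi <- hi + 1
    c((hi - lo + 1) * kymo$pixel_size, mean(img[i, lo:hi]))
  }, numeric(2))
  width <- res[1, ]
  intensity <- res[2, ]
  if (width[1] == 0) {
    stop("empty zone at t = 0: nothing to normalize to", call. = FALSE)
  }
  tibble::tibble(
    time = kymo$times,
    width = width, intensity = intensity,
    width_norm = width / width[1],
    intensity_norm = intensity / intensity[1]
  )
}

#' Synthetic kymograph generator
#'
#' Generates a Gaussian-ridge kymograph with prescribed width and peak
#' profiles plus seeded Gaussian noise, for testing the quantification
#' against known ground truth.  The ground-truth profiles are carried in
#' the attributes.
#'
#' @param width_fn Function of time giving the ridge standard deviation
#'   (length units); must be positive over the span.
#' @param peak_fn Function of time giving the peak intensity; positive.
#' @param noise_sd Gaussian noise standard deviation (intensities are
#'   clamped at zero).
#' @param seed Integer seed; the generator is deterministic given the seed
#'   and does not disturb the session RNG state.
#' @param n_frames,n_pixels Geometry of the image.
#' @param pixel_size,frame_interval Calibration.
#' @param center Ridge centre in length units (default: line centre);
#'   scalar or per-frame vector, also used as `junction_x`.
#' @return A [kymograph()] with attributes `width_truth`, `peak_truth`.
#' @export
synth_kymograph <- function(width_fn, peak_fn, noise_sd = 0, seed = 1,
                            n_frames = 60, n_pixels = 128, pixel_size = 1,
                            frame_interval = 1, center = NULL) {
  times <- (seq_len(n_frames) - 1) * frame_interval
  xpix <- (seq_len(n_pixels) - 0.5) * pixel_size
  extent <- n_pixels * pixel_size
  if (is.null(center)) center <- extent / 2
  center <- rep_len(center, n_frames)
  sig <- vapply(times, width_fn, numeric(1))
  pk <- vapply(times, peak_fn, numeric(1))
  if (any(sig <= 0) || any(pk <= 0)) {
    stop("width_fn and peak_fn must be positive over the time span", call. = FALSE)
  }
  img <- t(vapply(
    seq_len(n_frames),
    function(i) pk[i] * exp(-(xpix - center[i])^2 / (2 * sig[i]^2)),
    numeric(n_pixels)
  ))
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd), nrow = n_frames)
    img[img < 0] <- 0
  }
  out <- kymograph(img,
    pixel_size = pixel_size, frame_interval = frame_interval,
    junction_x = center, times = times
  )
  attr(out, "width_truth") <- sig
  attr(out, "peak_truth") <- pk
  out
}

#' Convert a simulation record to a kymograph
#'
#' Maps the RhoA space-time field to an intensity image with the junction
#' reference at the zone centroid of the first frame, bridging simulation
#' output to the imaging-style quantification.
#'
#' @param rec A `spacetime_record`.
#' @return A [kymograph()].
#' @export
record_to_kymograph <- function(rec) {
  stopifnot(inherits(rec, "spacetime_record"))
  if (length(rec$times) == 0) stop("empty record", call. = FALSE)
  r0 <- rec$rho_xt[1, ]
  centroid <- if (sum(r0) > 0) sum(rec$x * r0) / sum(r0) else rec$grid$length / 2
  kymograph(rec$rho_xt,
    pixel_size = rec$grid$dx,
    frame_interval = if (length(rec$times) > 1) diff(rec$times)[1] else 1,
    junction_x = centroid, times = rec$times
  )
}

#' Read a kymograph from a single-channel TIFF stack or matrix CSV
#'
#' @param path File path; `.tif`/`.tiff` are read with the tiff package
#'   (rows = time), anything else as a headerless numeric CSV matrix.
#' @param ... Calibration arguments passed to [kymograph()].
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path, ...) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF kymographs requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path, all = FALSE)
    if (length(dim(img)) == 3) img <- img[, , 1]
  } else {
    img <- as.matrix(utils::read.csv(path, header = FALSE))
  }
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  kymograph(img, ...)
}

#' Write a quantification series as CSV
#'
#' @param qs A [quantify_kymograph()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_quant_csv <- function(qs, path) {
  utils::write.csv(qs, path, row.names = FALSE)
  invisible(path)
}
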