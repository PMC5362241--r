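trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Zone width and edge positions over time
#'
#' The width of the contractile zone is defined as the integral of the RhoA
#' concentration over the whole domain (trapezoidal rule).  Because the
#' high-state plateau concentration is close to 1 for small `kappa`, this
#' integral closely tracks the geometric extent of the zone.  Edge positions
#' (outermost crossings of half the record maximum) are attached for
#' boundary-contact detection.
#'
#' @param rec A `spacetime_record`.
#' @return A `zone_trace`: tibble with columns `time`, `width`, `edge_lo`,
#'   `edge_hi`, carrying the grid as attribute.
#' @export
zone_width_series <- function(rec) {
  stopifnot(inherits(rec, "spacetime_record"))
  if (length(rec$times) == 0) stop("empty record", call. = FALSE)
  x <- rec$x
  width <- apply(rec$rho_xt, 1, function(r) trapz(x, r))
  thr <- 0.5 * max(rec$rho_xt)
  edges <- t(apply(rec$rho_xt, 1, function(r) {
    idx <- which(r > thr)
    if (!length(idx)) c(NA_real_, NA_real_) else range(x[idx])
  }))
  out <- tibble::tibble(
    time = rec$times, width = width,
    edge_lo = edges[, 1], edge_hi = edges[, 2]
  )
  structure(out,
    grid = rec$grid, aborted = rec$aborted,
    class = c("zone_trace", class(out))
  )
}

#' Front propagation speed from a width trace
#'
#' For a bidirectionally expanding zone the width (RhoA integral) grows at
#' `2 * c_high * speed`: two fronts move outward, each adding plateau
#' concentration `c_high` per unit length.  The speed is the least-squares
#' slope of width versus time over the late-time window, divided by
#' `2 * c_high`.  The default window is the second half of the trace,
#' excluding any frames after boundary contact.
#'
#' @param trace A [zone_width_series()] result.
#' @param c_high Plateau concentration of the contractile state (from
#'   [high_state()] / [find_fixed_points()]).
#' @param margin Boundary margin (length units) used to drop post-contact
#'   frames.
#' @return The front speed (length per time).
#' @export
front_speed <- function(trace, c_high, margin = 2) {
  stopifnot(inherits(trace, "zone_trace"), c_high > 0)
  g <- attr(trace, "grid")
  ok <- rep(TRUE, nrow(trace))
  if (!is.null(g)) {
    contact <- !is.na(trace$edge_lo) &
      (trace$edge_lo < margin | trace$edge_hi > g$length - margin)
    if (any(contact)) ok[seq(min(which(contact)), nrow(trace))] <- FALSE
  }
  t_mid <- (min(trace$time) + max(trace$time[ok])) / 2
  win <- ok & trace$time >= t_mid
  if (sum(win) < 10) {
    stop("fitting window has fewer than 10 frames", call. = FALSE)
  }
  slope <- stats::coef(stats::lm(width ~ time, data = trace[win, ]))[["time"]]
  slope / (2 * c_high)
}

#' Stationarity verdict for a zone trace
#'
#' A zone is stationary when the relative change of its width over the
#' trailing window is below `rel_tol` *and* the zone edges have stayed clear
#' of the domain boundaries.  A front that touches the boundary margin gives
#' the verdict `"censored"` (the run cannot distinguish a slow front from a
#' pinned zone), never `"stationary"`.
#'
#' @param trace A [zone_width_series()] result.
#' @param rel_tol Relative width-change tolerance over the window.
#' @param window Trailing window length in time units.
#' @param margin Boundary margin in length units.
#' @return A one-row tibble with `verdict` (`"stationary"`, `"propagating"`
#'   or `"censored"`), `is_stationary`, `stationary_width` (trailing-window
#'   mean; `NA` unless stationary) and `rel_change`.
#' @export
detect_stationary <- function(trace, rel_tol = 1e-3, window = 20, margin = 2) {
  stopifnot(inherits(trace, "zone_trace"))
  t_max <- max(trace$time)
  if (t_max - min(trace$time) < 2 * window) {
    stop("trace must span at least twice the stationarity window", call. = FALSE)
  }
  tail_i <- trace$time >= t_max - window
  w <- trace$width[tail_i]
  contact <- !is.na(trace$edge_lo[tail_i]) &
    (trace$edge_lo[tail_i] < margin |
      trace$edge_hi[tail_i] > attr(trace, "grid")$length - margin)
  censored <- any(contact) || isTRUE(attr(trace, "aborted"))
  rel_change <- (max(w) - min(w)) / max(mean(w), .Machine$double.eps)
  verdict <- if (censored) {
    "censored"
  } else if (rel_change < rel_tol) {
    "stationary"
  } else {
    "propagating"
  }
  tibble::tibble(
    verdict = verdict,
    is_stationary = verdict == "stationary",
    stationary_width = if (verdict == "stationary") mean(w) else NA_real_,
    rel_change = rel_change
  )
}

#' Geometric extent of a zone at a fractional threshold
#'
#' Length between the outermost crossings of `frac * max(field)`; a
#' cross-check for the integral width measure.
#'
#' @param field Concentration field.
#' @param x Cell-centre coordinates.
#' @param frac Fraction of the field maximum (default half-maximum).
#' @return The extent in length units (0 if the field is empty).
#' @export
zone_extent <- function(field, x, frac = 0.5) {
  thr <- frac * max(field)
  if (max(field) <= 0) {
    return(0)
  }
  idx <- which(field > thr)
  if (!length(idx)) {
    return(0)
  }
  diff(range(x[idx])) + (x[2] - x[1])
}

#' Local maxima with prominence
#'
#' Counts interior peaks of a 1D field whose topographic prominence exceeds
#' a threshold.  A peak is a run of equal values strictly above both
#' neighbouring runs (plateaus count once; the domain edges are never
#' peaks).  Its two flanking bases are the lowest values encountered walking
#' outward until strictly higher terrain or the domain edge; the prominence
#' is the height above the higher base, so the tallest crest of an isolated
#' zone carries the zone's full height while secondary ripples carry only
#' their local relief.
#'
#' @param y Field values.
#' @param min_prominence Prominence threshold.
#' @return Integer count of prominent peaks.
#' @export
peak_count <- function(y, min_prominence) {
  r <- rle(y)
  vals <- r$values
  k <- length(vals)
  if (k < 3) {
    return(0L)
  }
  count <- 0L
  for (i in 2:(k - 1)) {
    if (!(vals[i] > vals[i - 1] && vals[i] > vals[i + 1])) next
    base_l <- vals[i]
    j <- i - 1
    while (j >= 1 && vals[j] <= vals[i]) {
      base_l <- min(base_l, vals[j])
      j <- j - 1
    }
    base_r <- vals[i]
    j <- i + 1
    while (j <= k && vals[j] <= vals[i]) {
      base_r <- min(base_r, vals[j])
      j <- j + 1
    }
    if (vals[i] - max(base_l, base_r) >= min_prominence) count <- count + 1L
  }
  count
}

#' Count myosin clusters in a record frame
#'
#' In the propagating regime at intermediate Peclet numbers the advected
#' contractile component condenses into a periodic pattern of high-
#' concentration clusters behind the front while the non-advected component
#' stays uniform.  Counts local maxima of the chosen species' field with
#' prominence above the threshold.
#'
#' @param rec A `spacetime_record`.
#' @param frame Frame index.
#' @param min_prominence Prominence threshold (concentration units).
#' @param species `"m"` (default) or `"rho"`.
#' @return Integer cluster count.
#' @export
cluster_count <- function(rec, frame, min_prominence, species = c("m", "rho")) {
  stopifnot(inherits(rec, "spacetime_record"))
  species <- match.arg(species)
  if (frame < 1 || frame > length(rec$times)) {
    stop("frame index out of range", call. = FALSE)
  }
  y <- if (species == "m") rec$m_xt[frame, ] else rec$rho_xt[frame, ]
  peak_count(y, min_prominence)
}

#' Export a zone trace as CSV
#'
#' @param trace A [zone_width_series()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_zone_trace_csv <- function(trace, path) {
  utils::write.csv(
    tibble::as_tibble(trace)[, c("time", "width")], path,
    row.names = FALSE
  )
  invisible(path)
}
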