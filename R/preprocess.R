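#' @useDynLib oxydyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

CHANNEL_NAMES <- c("HR", "VE", "BF", "Hacc", "CAD", "VO2")
FEATURE_ORDER <- c("HR", "dHR", "VE", "BF", "Hacc", "CAD")
SEGMENT_LABELS <- c("PRTS1", "PRTS2", "ADL", "REST")

#' Construct a raw sensor channel
#'
#' A single recorded channel with its own (possibly non-uniform) timestamps,
#' e.g. breath-by-breath VO2 or beat-derived heart rate.
#'
#' @param name Channel identifier, one of `"HR"`, `"VE"`, `"BF"`, `"Hacc"`,
#'   `"CAD"`, `"VO2"`.
#' @param timestamps Seconds from recording start, strictly increasing.
#' @param values Channel values, finite, same length as `timestamps`.
#' @return A `raw_channel` object.
#' @export
raw_channel <- function(name, timestamps, values) {
  if (!name %in% CHANNEL_NAMES) {
    stop("unknown channel name '", name, "'; expected one of ",
         paste(CHANNEL_NAMES, collapse = ", "))
  }
  if (length(timestamps) != length(values)) stop("timestamps/values length mismatch in ", name)
  if (length(timestamps) < 2L) stop("channel ", name, " needs at least 2 samples")
  if (any(diff(timestamps) <= 0)) stop("timestamps not strictly increasing in channel ", name)
  if (!all(is.finite(values))) stop("non-finite values in channel ", name)
  structure(list(name = name, timestamps = as.numeric(timestamps),
                 values = as.numeric(values)),
            class = "raw_channel")
}

#' Load a participant's channel recordings and segment annotations
#'
#' Reads either one wide CSV (`time_s, HR, VE, BF, Hacc, CAD, VO2`) or one
#' two-column CSV (`time_s, value`) per channel, plus a segment annotation CSV
#' (`label, start_s, end_s`, half-open intervals).
#'
#' @param paths Named character vector of file paths. Either a single element
#'   named `"wide"`, or one element per channel named by channel.
#' @param annotation Path to the segment annotation CSV, or `NULL`.
#' @return List with `channels` (named list of `raw_channel`) and `segments`
#'   (data frame `label, start_s, end_s`).
#' @export
load_participant <- function(paths, annotation = NULL) {
  channels <- list()
  if (identical(names(paths), "wide")) {
    wide <- utils::read.csv(paths[["wide"]])
    if (!"time_s" %in% names(wide)) stop("wide CSV must contain a time_s column")
    present <- intersect(CHANNEL_NAMES, names(wide))
    missing <- setdiff(CHANNEL_NAMES, names(wide))
    if (length(missing)) {
      stop("wide CSV missing channels: ", paste(missing, collapse = ", "))
    }
    for (nm in present) {
      channels[[nm]] <- raw_channel(nm, wide$time_s, wide[[nm]])
    }
  } else {
    for (nm in names(paths)) {
      d <- utils::read.csv(paths[[nm]])
      if (!all(c("time_s", "value") %in% names(d))) {
        stop("channel file for ", nm, " must have columns time_s, value")
      }
      channels[[nm]] <- raw_channel(nm, d$time_s, d$value)
    }
  }
  segments <- NULL
  if (!is.null(annotation)) {
    segments <- utils::read.csv(annotation)
    if (!all(c("label", "start_s", "end_s") %in% names(segments))) {
      stop("annotation CSV must have columns label, start_s, end_s")
    }
    segments <- validate_segments(segments)
  }
  list(channels = channels, segments = segments)
}

validate_segments <- function(segments) {
  bad <- setdiff(segments$label, SEGMENT_LABELS)
  if (length(bad)) stop("unknown segment labels: ", paste(bad, collapse = ", "))
  if (any(segments$end_s <= segments$start_s)) stop("segment end_s must exceed start_s")
  o <- order(segments$start_s)
  s <- segments[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s$start_s[-1L] < s$end_s[-nrow(s)])) {
    stop("segment intervals overlap")
  }
  segments
}

#' Synchronize channels onto a common 1-Hz grid
#'
#' Linearly interpolates every channel onto the integer-second grid of the
#' overlapping time window. No extrapolation: the frame is trimmed to the
#' intersection of the channels' supports.
#'
#' @param channels Named list of `raw_channel` objects.
#' @param segments Optional segment annotation data frame, carried through
#'   (clipped to the frame window).
#' @return A `sensor_frame`: list with `time` (integer seconds), `channels`
#'   (named list of numeric vectors) and `segments`.
#' @export
synchronize_resample <- function(channels, segments = NULL) {
  stopifnot(length(channels) >= 1L)
  t_start <- max(vapply(channels, function(ch) ch$timestamps[1L], 0))
  t_end <- min(vapply(channels, function(ch) utils::tail(ch$timestamps, 1L), 0))
  t0 <- ceiling(t_start)
  t1 <- floor(t_end)
  if (t1 - t0 < 1) stop("overlapping window shorter than 2 s")
  grid <- seq(t0, t1)
  out <- lapply(channels, function(ch) {
    stats::approx(ch$timestamps, ch$values, xout = grid, method = "linear")$y
  })
  names(out) <- vapply(channels, `[[`, "", "name")
  if (!is.null(segments)) {
    segments <- validate_segments(segments)
    segments$start_s <- pmax(segments$start_s, t0)
    segments$end_s <- pmin(segments$end_s, t1 + 1)
    segments <- segments[segments$end_s > segments$start_s, , drop = FALSE]
  }
  structure(list(time = grid, channels = out, segments = segments),
            class = "sensor_frame")
}

#' One-second lagged heart-rate difference
#'
#' `dHR[t] = HR[t] - HR[t-1]` on the 1-Hz grid; the first element, which has
#' no predecessor, is set to 0 so channel alignment is preserved.
#'
#' @param hr Numeric 1-Hz heart-rate series.
#' @return Numeric series of the same length.
#' @export
delta_hr <- function(hr) {
  if (length(hr) == 0L) stop("empty series")
  c(0, diff(hr))
}

#' Zero-phase low-pass filter at 0.01 Hz
#'
#' 4th-order Butterworth applied forward and backward (zero phase) at 1-Hz
#' sampling, so the slow aerobic dynamics pass undistorted in time while
#' frequencies above the cutoff - where circulatory distortions introduce
#' non-linearities - are strongly attenuated. The series is extended by odd
#' (point-mirrored) reflection of 300 samples at each end before filtering to
#' suppress startup transients over the ~100-s characteristic period of the
#' cutoff.
#'
#' @param series Numeric 1-Hz series.
#' @param cutoff Cutoff frequency in Hz (default 0.01).
#' @param order Butterworth order per pass (default 4).
#' @return Filtered series, same length as the input.
#' @export
lowpass_001 <- function(series, cutoff = 0.01, order = 4L) {
  n <- length(series)
  if (n < 6L * order) stop("series too short for stable zero-phase filtering")
  bf <- signal::butter(order, 2 * cutoff, type = "low")
  pad <- min(300L, n - 1L)
  # filter the deviations from the mean: DC passes exactly and the narrow-band
  # IIR stays well conditioned
  mu <- mean(series)
  s <- series - mu
  head_ref <- 2 * s[1L] - s[(pad + 1L):2L]
  tail_ref <- 2 * s[n] - s[(n - 1L):(n - pad)]
  x <- c(head_ref, s, tail_ref)
  y <- signal::filter(bf, x)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)] + mu
}

#' Restrict a frame's sample indices to annotated segments
#'
#' @param frame A `sensor_frame`.
#' @param labels Segment labels to keep.
#' @return Integer vector of row indices into the frame's time grid.
#' @export
segment_indices <- function(frame, labels) {
  stopifnot(inherits(frame, "sensor_frame"))
  if (is.null(frame$segments)) stop("frame has no segment annotations")
  seg <- frame$segments[frame$segments$label %in% labels, , drop = FALSE]
  if (nrow(seg) == 0L) stop("no segments with labels: ", paste(labels, collapse = ", "))
  idx <- integer(0)
  for (i in seq_len(nrow(seg))) {
    keep <- which(frame$time >= seg$start_s[i] & frame$time < seg$end_s[i])
    idx <- c(idx, keep)
  }
  sort(unique(idx))
}

#' Build the model feature matrix from a sensor frame
#'
#' Assembles the fixed-order predictor columns (HR, dHR, VE, BF, Hacc, CAD).
#' With `filter = TRUE` every feature column and the VO2 target are low-pass
#' filtered at 0.01 Hz; the raw (unfiltered) VO2 is always kept alongside as
#' the validation reference.
#'
#' @param frame A `sensor_frame` containing all six channels.
#' @param segments Optional segment labels to restrict rows to.
#' @param filter Apply the 0.01-Hz zero-phase low-pass? Default `TRUE`.
#' @return List with `X` (numeric matrix, columns `HR, dHR, VE, BF, Hacc,
#'   CAD`), `y` (filtered VO2 target), `y_raw` (unfiltered VO2), `time`.
#' @export
build_feature_matrix <- function(frame, segments = NULL, filter = TRUE) {
  stopifnot(inherits(frame, "sensor_frame"))
  need <- c("HR", "VE", "BF", "Hacc", "CAD", "VO2")
  missing <- setdiff(need, names(frame$channels))
  if (length(missing)) stop("frame missing channels: ", paste(missing, collapse = ", "))

  ch <- frame$channels
  ch$dHR <- delta_hr(ch$HR)
  y_raw <- ch$VO2
  if (filter) {
    for (nm in c(FEATURE_ORDER, "VO2")) ch[[nm]] <- lowpass_001(ch[[nm]])
  }
  X <- do.call(cbind, ch[FEATURE_ORDER])
  colnames(X) <- FEATURE_ORDER
  y <- ch$VO2

  bad <- which(!stats::complete.cases(X) | !is.finite(y))
  if (length(bad)) stop("non-finite feature/target values at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))

  keep <- seq_along(y)
  if (!is.null(segments)) keep <- segment_indices(frame, segments)
  list(X = X[keep, , drop = FALSE], y = y[keep], y_raw = y_raw[keep],
       time = frame$time[keep])
}
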