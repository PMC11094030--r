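#' Read single-particle trajectories from TRXYT or CSV
#'
#' TRXYT is the whitespace-separated, headerless format used by
#' localization-clustering tools: one detection per line as
#' \code{trajectory-id x[um] y[um] t[s]}. The CSV dialect carries a header
#' with columns \code{id,x,y,t}. Detections are grouped by id and sorted
#' by time; malformed lines are skipped with a warning naming their line
#' numbers; non-monotonic time within a trajectory is an error naming the
#' offending id.
#'
#' @param path file path.
#' @param format \code{"trxyt"} or \code{"csv"}.
#' @param frameTime frame interval in seconds used to reconstruct frame
#'   indices (frame = round(t/frameTime)).
#' @param roiArea region-of-interest area, um^2; if \code{NULL}, the
#'   bounding-box area of the detections is used.
#' @param duration acquisition duration, seconds; if \code{NULL}, the
#'   largest detection time.
#' @return a \code{\link{TrackSet}}.
#' @export
readTracks <- function(path, format = c("trxyt", "csv"), frameTime = 0.02,
                       roiArea = NULL, duration = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  start <- 1L
  if (format == "csv" && length(lines) > 0) start <- 2L
  if (length(lines) < start) {
    det <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      frame = integer(), t = numeric())
  } else {
    body <- lines[start:length(lines)]
    lineNo <- seq_along(body) + start - 1L
    nonEmpty <- nzchar(trimws(body))
    body <- body[nonEmpty]; lineNo <- lineNo[nonEmpty]
    parts <- if (format == "trxyt") strsplit(trimws(body), "[[:space:]]+")
             else strsplit(body, ",")
    ok <- vapply(parts, function(p) {
      length(p) >= 4 && !anyNA(suppressWarnings(as.numeric(p[1:4])))
    }, logical(1))
    if (any(!ok))
      warning("skipped ", sum(!ok), " malformed line(s): ",
              paste(utils::head(lineNo[!ok], 10), collapse = ", "))
    m <- matrix(as.numeric(unlist(lapply(parts[ok], `[`, 1:4))),
                ncol = 4, byrow = TRUE)
    det <- data.frame(id = m[, 1], x = m[, 2], y = m[, 3],
                      t = m[, 4])
    # within-id time must already increase in file order; sorting would
    # silently repair corrupt tracks
    badId <- vapply(split(det$t, det$id), function(tt) any(diff(tt) <= 0),
                    logical(1))
    if (any(badId))
      stop("non-monotonic time within trajectory id(s): ",
           paste(utils::head(names(badId)[badId], 5), collapse = ", "))
    det <- det[order(det$id, det$t), , drop = FALSE]
    det$frame <- as.integer(round(det$t / frameTime))
    det <- det[, c("id", "x", "y", "frame", "t")]
    rownames(det) <- NULL
  }
  if (is.null(roiArea)) {
    roiArea <- if (nrow(det) > 1)
      max(diff(range(det$x)) * diff(range(det$y)), .Machine$double.eps)
    else 1
  }
  if (is.null(duration)) duration <- if (nrow(det)) max(det$t) else 0
  methods::new("TrackSet", detections = det, frameTime = frameTime,
               duration = duration, roiArea = roiArea, metadata = list())
}

#' Write a TrackSet to TRXYT or CSV
#'
#' @param ts a \code{\link{TrackSet}}.
#' @param path output file path.
#' @param format \code{"trxyt"} (whitespace-separated, no header) or
#'   \code{"csv"} (header \code{id,x,y,t}).
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(ts, path, format = c("trxyt", "csv")) {
  format <- match.arg(format)
  d <- detections(ts)
  out <- data.frame(id = d$id, x = d$x, y = d$y, t = d$t)
  if (format == "trxyt") {
    utils::write.table(format(out, digits = 12, trim = TRUE, scientific = FALSE),
                       path, sep = " ", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.csv(format(out, digits = 12, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Filter trajectories by length and flag over-dense acquisitions
#'
#' Retains trajectories with \code{minLen <= length <= maxLen} detections
#' (tracks shorter than 8 frames are excluded by default, the standard
#' background screen for sptPALM tracking). If the retained trajectory
#' density exceeds \code{densityLimit} (high detection densities induce
#' mistracking) the whole set is flagged in \code{metadata$densityFlag},
#' with a warning, and rejected with an error when \code{reject = TRUE}.
#'
#' @param ts a \code{\link{TrackSet}}.
#' @param minLen minimum detections per trajectory (>= 2).
#' @param maxLen maximum detections per trajectory.
#' @param densityLimit trajectory density limit, trajectories per um^2.
#' @param reject if \code{TRUE}, error when the density limit is exceeded.
#' @return the filtered \code{\link{TrackSet}}.
#' @export
filterTracks <- function(ts, minLen = 8, maxLen = Inf, densityLimit = 50,
                         reject = FALSE) {
  if (minLen < 2) stop("minLen must be >= 2")
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  len <- trackLengths(ts)
  keepIds <- names(len)[len >= minLen & len <= maxLen]
  d <- detections(ts)
  d <- d[as.character(d$id) %in% keepIds, , drop = FALSE]
  rownames(d) <- NULL
  out <- methods::new("TrackSet", detections = d, frameTime = ts@frameTime,
                      duration = ts@duration, roiArea = ts@roiArea,
                      metadata = ts@metadata)
  dens <- length(keepIds) / ts@roiArea
  if (dens > densityLimit) {
    out@metadata$densityFlag <- TRUE
    if (reject)
      stop(sprintf("trajectory density %.1f/um^2 exceeds limit %.1f/um^2",
                   dens, densityLimit))
    warning(sprintf("trajectory density %.1f/um^2 exceeds limit %.1f/um^2; set flagged",
                    dens, densityLimit))
  } else {
    out@metadata$densityFlag <- FALSE
  }
  out
}
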