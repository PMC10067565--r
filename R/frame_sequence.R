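#' Construct a FrameSequence
#'
#' @param frames numeric matrix, frames in rows, pixels in columns.
#' @param frameRate acquisition rate, Hz.
#' @param t0 timestamp of the first frame, seconds.
#' @param events event data.frame with columns \code{time}, \code{kind} and
#'   optionally \code{payload} (list column); may be \code{NULL}.
#' @param metadata named list.
#' @return a validated \code{\linkS4class{FrameSequence}}.
#' @export
frameSequence <- function(frames, frameRate, t0 = 0, events = NULL,
                          metadata = list()) {
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  events <- normalizeEvents(events)
  times <- t0 + (0:(nrow(frames) - 1)) / frameRate
  new("FrameSequence", frames = frames, frameRate = frameRate,
      times = times, events = events, metadata = metadata)
}

normalizeEvents <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    ev <- data.frame(time = numeric(0), kind = character(0))
    ev$payload <- list()
    return(ev)
  }
  if (!all(c("time", "kind") %in% names(events)))
    stop("events must have columns 'time' and 'kind'")
  ev <- data.frame(time = as.numeric(events$time),
                   kind = as.character(events$kind),
                   stringsAsFactors = FALSE)
  ev$payload <- if ("payload" %in% names(events)) events$payload
  else replicate(nrow(ev), list(), simplify = FALSE)
  ev[order(ev$time), , drop = FALSE]
}

#' @describeIn frameSequence the frame matrix (frames x pixels).
#' @param seq a \code{\linkS4class{FrameSequence}}.
#' @export
frameMatrix <- function(seq) seq@frames

#' @describeIn frameSequence acquisition rate in Hz.
#' @export
frameRate <- function(seq) seq@frameRate

#' @describeIn frameSequence frame timestamps in seconds.
#' @export
frameTimes <- function(seq) seq@times

#' @describeIn frameSequence the ordered event log.
#' @export
eitEvents <- function(seq) seq@events

#' @describeIn frameSequence the metadata list.
#' @export
seqMetadata <- function(seq) seq@metadata

#' @describeIn frameSequence number of frames.
#' @export
nFrames <- function(seq) nrow(seq@frames)

setMethod("show", "FrameSequence", function(object) {
  cat("FrameSequence:", nrow(object@frames), "frames x",
      ncol(object@frames), "pixels at", object@frameRate, "Hz (",
      sprintf("%.1f", nrow(object@frames) / object@frameRate), "s )\n")
  if (nrow(object@events)) {
    cat("  events:\n")
    ev <- object@events
    for (i in seq_len(nrow(ev)))
      cat(sprintf("    %8.2f s  %s\n", ev$time[i], ev$kind[i]))
  } else cat("  events: none\n")
})

.FRAMES_FORMAT <- "eit-frames-v1"

#' Write / read a FrameSequence container
#'
#' The container is a directory holding \code{frames.bin} (little-endian
#' float64: first the T frame timestamps, then the T x P frame matrix
#' row-major, frame by frame) and \code{meta.json} (format tag, frame rate,
#' dimensions, event log and metadata). Writing then reading is the identity
#' for frame values (binary doubles) and preserves events and metadata.
#'
#' @param seq a \code{\linkS4class{FrameSequence}}.
#' @param path container directory (created by \code{writeFrameSequence}).
#' @return \code{readFrameSequence} returns a
#'   \code{\linkS4class{FrameSequence}}; \code{writeFrameSequence} returns
#'   \code{path} invisibly.
#' @export
writeFrameSequence <- function(seq, path) {
  validObject(seq)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ev <- seq@events
  evList <- lapply(seq_len(nrow(ev)), function(i)
    list(time = ev$time[i], kind = ev$kind[i], payload = ev$payload[[i]]))
  meta <- list(format = .FRAMES_FORMAT, frame_rate = seq@frameRate,
               n_frames = nrow(seq@frames), n_pixels = ncol(seq@frames),
               byte_order = "little", events = evList,
               metadata = seq@metadata)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "frames.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(seq@times), con, size = 8, endian = "little")
  writeBin(as.numeric(t(seq@frames)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeFrameSequence
#' @export
readFrameSequence <- function(path) {
  metaPath <- file.path(path, "meta.json")
  binPath <- file.path(path, "frames.bin")
  if (!file.exists(metaPath) || !file.exists(binPath))
    stop("not a FrameSequence container (missing meta.json or frames.bin): ",
         path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = FALSE)
  if (!identical(meta$format, .FRAMES_FORMAT))
    stop("unrecognized container format tag: ", meta$format %||% "<missing>")
  nT <- meta$n_frames; nP <- meta$n_pixels
  vals <- readBin(binPath, "double", n = nT * (nP + 1L) + 1L, size = 8,
                  endian = "little")
  if (length(vals) != nT * (nP + 1L))
    stop("frame payload length mismatch: expected ", nT * (nP + 1L),
         " doubles, found ", length(vals))
  times <- vals[seq_len(nT)]
  frames <- matrix(vals[-seq_len(nT)], nrow = nT, ncol = nP, byrow = TRUE)
  evList <- meta$events
  ev <- data.frame(
    time = vapply(evList, function(e) as.numeric(e$time), numeric(1)),
    kind = vapply(evList, function(e) as.character(e$kind), character(1)),
    stringsAsFactors = FALSE)
  ev$payload <- lapply(evList, function(e) e$payload %||% list())
  if (nrow(ev) > 1L && is.unsorted(ev$time))
    stop("malformed container: events are not time-sorted")
  md <- lapply(meta$metadata, function(x) if (is.list(x)) x else x)
  obj <- new("FrameSequence", frames = frames, frameRate = meta$frame_rate,
             times = times, events = normalizeEvents(ev),
             metadata = as.list(md))
  validObject(obj)
  obj
}

#' Delimited-text export of a FrameSequence
#'
#' Writes \code{frames.csv} (time column plus one column per pixel) and
#' \code{events.csv} for interoperability with other tools. Intended for
#' short sequences; the binary container is the primary format.
#'
#' @param seq a \code{\linkS4class{FrameSequence}}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
exportFrameCsv <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(time = seq@times, seq@frames)
  names(df) <- c("time", paste0("px", seq_len(ncol(seq@frames)) - 1L))
  utils::write.csv(df, file.path(dir, "frames.csv"), row.names = FALSE)
  ev <- seq@events
  utils::write.csv(data.frame(time = ev$time, kind = ev$kind),
                   file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}
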