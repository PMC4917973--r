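# Pipeline orchestration: segmentation -> centerline -> head endpoints ->
# head direction per frame, then gated global association across frames.

#' Detect fish heads in one frame
#'
#' Runs the full single-frame detection chain: background differencing and
#' mask cleaning, fast-marching centerline extraction and thinning,
#' endpoint filtering, inscribed-circle width measurement, head
#' classification, and Hessian direction estimation.
#'
#' @param frame numeric matrix (gray levels 0-255).
#' @param bg background matrix from \code{\link{computeBackground}}.
#' @param config a \code{\link{FishTrackConfig-class}}.
#' @param frameIndex 0-based index recorded in the detections.
#' @return data.frame of head detections (\code{frame}, \code{x}, \code{y},
#'   \code{width}, \code{theta_deg}, \code{component}).
#' @export
detectFrame <- function(frame, bg, config, frameIndex = 0L) {
  mask <- cleanMask(segmentFrame(frame, bg, config@tG),
                    config@minBlobArea, config@medianKernel)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      width = numeric(0), theta_deg = numeric(0),
                      component = integer(0))
  if (!any(mask)) return(empty)
  field <- propagateArrivalTimes(parameterizeBoundary(mask))
  cl <- pruneSpurs(thinCenterline(extractCenterline(field, config@tU)))
  if (!any(cl)) return(empty)
  graph <- buildSkeletonGraph(cl, field$labels)
  eps <- filterEndpoints(graph, config@tL)
  if (nrow(eps) == 0) return(empty)
  eps <- measureEndpointWidths(eps, mask)
  heads <- classifyHeads(eps, config@tW, frameIndex)
  estimateHeadDirections(heads, frame, graph, config@scales,
                         config@anisotropyMin, config@darkFish)
}

#' Detect fish heads in a frame sequence
#'
#' @param frames list of frame matrices, or a
#'   \code{\link{FishBenchmark-class}}.
#' @param config a \code{\link{FishTrackConfig-class}}.
#' @param verbose print a progress line every 100 frames.
#' @return detection data.frame over all frames.
#' @export
detectFish <- function(frames, config, verbose = FALSE) {
  if (is(frames, "FishBenchmark")) frames <- benchFrames(frames)
  if (!length(frames)) stop("no frames to process")
  n <- min(config@nBackgroundFrames, length(frames))
  bg <- computeBackground(frames, n)
  dets <- vector("list", length(frames))
  for (f in seq_along(frames) - 1L) {
    dets[[f + 1L]] <- detectFrame(frames[[f + 1L]], bg, config, f)
    if (verbose && f %% 100 == 0)
      message(sprintf("frame %d: %d detections", f, nrow(dets[[f + 1L]])))
  }
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}

#' Run the full detection and tracking pipeline
#'
#' Detects heads in every frame and associates them across frames into N
#' persistent trajectories. Optionally writes the detection CSV, the
#' trajectory CSV and a run log.
#'
#' @param frames list of frame matrices, a \code{\link{FishBenchmark-class}},
#'   or a path readable by \code{\link{readFrames}}.
#' @param config a \code{\link{FishTrackConfig-class}}.
#' @param outDir when non-NULL, \code{detections.csv},
#'   \code{trajectories.csv} and \code{run_log.txt} are written there.
#' @param verbose print progress.
#' @return list: \code{detections} (data.frame), \code{tracks}
#'   (\code{\link{TrackSet-class}}), \code{log} (list with per-frame
#'   detection counts, propagation events, and the count of
#'   degenerate-direction detections).
#' @export
runPipeline <- function(frames, config, outDir = NULL, verbose = FALSE) {
  if (is.character(frames)) frames <- readFrames(frames)
  if (is(frames, "FishBenchmark")) frames <- benchFrames(frames)
  if (!length(frames)) stop("no frames to process")
  detections <- detectFish(frames, config, verbose)
  tracks <- trackFish(detections, length(frames), config@nFish,
                      config@omega, config@pcMax, config@dcMax, config@tO)
  st <- tracks@states
  prop <- st[st$status == "propagated", , drop = FALSE]
  counts <- vapply(seq_along(frames) - 1L,
                   function(f) sum(detections$frame == f), integer(1))
  log <- list(
    perFrameDetections = counts,
    propagationEvents = nrow(prop),
    propagationFrames = unique(prop$frame),
    degenerateDirections = sum(is.na(detections$theta_deg)),
    startFrame = tracks@startFrame)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeDetections(detections, file.path(outDir, "detections.csv"))
    writeTracks(tracks, file.path(outDir, "trajectories.csv"))
    writeLines(c(
      sprintf("frames: %d", length(frames)),
      sprintf("start frame: %d", log$startFrame),
      sprintf("propagation events: %d", log$propagationEvents),
      sprintf("degenerate directions: %d", log$degenerateDirections),
      sprintf("mean detections/frame: %.2f", mean(counts))),
      file.path(outDir, "run_log.txt"))
  }
  list(detections = detections, tracks = tracks, log = log)
}
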