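#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fishHeadTracker, .registration = TRUE
NULL

#' Pipeline configuration
#'
#' Holds every tunable parameter of the detection and tracking pipeline.
#' Two named profiles are shipped: \code{"D1"} (20 fish, strong lighting)
#' and \code{"D2"} (40 fish, ordinary lighting), plus a \code{"synthetic"}
#' profile matched to the geometry of the built-in fish renderer.
#'
#' @slot tG intensity threshold (gray levels) on the background difference.
#' @slot nBackgroundFrames number of initial frames in the median background.
#' @slot minBlobArea smallest foreground component kept (pixels).
#' @slot medianKernel odd side length of the binary median smoothing window.
#' @slot tU arrival-time-difference threshold for centerline pruning
#'   (boundary pixels); must exceed 2.
#' @slot tL branch length threshold for endpoint filtering (pixels).
#' @slot tW endpoint width threshold separating head from tail (pixels).
#' @slot scales Hessian analysis scales (pixels), strictly increasing.
#' @slot anisotropyMin minimum |lambda1|/|lambda2| eigenvalue ratio below
#'   which a head patch is treated as isotropic (direction unavailable).
#' @slot omega weight of the position term in the association cost, in [0,1].
#' @slot pcMax maximum per-frame position change used to normalize the cost.
#' @slot dcMax maximum per-frame direction change (degrees).
#' @slot tO gating distance: pairs farther apart are never associated (px).
#' @slot nFish fixed number of fish N.
#' @slot darkFish logical; TRUE when fish are darker than the background.
#' @export
setClass("FishTrackConfig",
  representation(
    tG = "numeric", nBackgroundFrames = "numeric", minBlobArea = "numeric",
    medianKernel = "numeric", tU = "numeric", tL = "numeric", tW = "numeric",
    scales = "numeric", anisotropyMin = "numeric", omega = "numeric",
    pcMax = "numeric", dcMax = "numeric", tO = "numeric", nFish = "numeric",
    darkFish = "logical"
  )
)

setValidity("FishTrackConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(length(object@tG) == 1 && object@tG >= 0, "tG must be >= 0")
  chk(object@nBackgroundFrames >= 1, "nBackgroundFrames must be >= 1")
  chk(object@minBlobArea >= 0, "minBlobArea must be >= 0")
  chk(object@medianKernel >= 1 && object@medianKernel %% 2 == 1,
      "medianKernel must be odd and >= 1")
  chk(object@tU > 2, "tU must be > 2")
  chk(object@tL >= 0, "tL must be >= 0")
  chk(object@tW > 0, "tW must be > 0")
  chk(length(object@scales) >= 1 && all(object@scales > 0) &&
        !is.unsorted(object@scales, strictly = TRUE),
      "scales must be non-empty, positive, strictly increasing")
  chk(object@anisotropyMin >= 1, "anisotropyMin must be >= 1")
  chk(object@omega >= 0 && object@omega <= 1, "omega must be in [0, 1]")
  chk(object@pcMax > 0, "pcMax must be > 0")
  chk(object@dcMax > 0, "dcMax must be > 0")
  chk(object@tO > 0, "tO must be > 0")
  chk(object@nFish >= 1, "nFish must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Skeleton graph of a pruned centerline
#'
#' Centerline pixels organized into endpoints (one 8-connected skeleton
#' neighbor), junctions (three or more) and branches (maximal simple paths
#' between node pixels). Coordinates are 0-based (x = column, y = row).
#'
#' @slot pixels integer matrix with columns \code{x}, \code{y}, \code{component}.
#' @slot endpoints integer matrix, columns \code{x}, \code{y}, \code{component}.
#' @slot junctions integer matrix, columns \code{x}, \code{y}, \code{component}.
#' @slot branches list; each element a list with \code{path} (n x 2 matrix of
#'   x, y along the branch), \code{length} (pixel count), \code{geodesic}
#'   (arc length, diagonal steps weighted sqrt(2)) and \code{component}.
#' @slot dim image dimensions c(nrow, ncol).
#' @export
setClass("SkeletonGraph",
  representation(pixels = "matrix", endpoints = "matrix",
                 junctions = "matrix", branches = "list", dim = "integer")
)

setValidity("SkeletonGraph", function(object) {
  if (nrow(object@endpoints) + nrow(object@junctions) > 0 &&
      nrow(object@pixels) == 0)
    return("endpoints/junctions present without pixels")
  TRUE
})

#' A set of persistent fish tracks
#'
#' After initialization every frame carries exactly N states, one per fish;
#' a state is \code{detected} when a head detection was associated to the
#' track in that frame and \code{propagated} (copied unchanged from the
#' previous frame) when its fish had no usable detection, e.g. during
#' occlusion.
#'
#' @slot states data.frame with columns \code{frame}, \code{track_id},
#'   \code{x}, \code{y}, \code{theta_deg}, \code{status}.
#' @slot nTracks fixed number of fish N.
#' @slot startFrame frame index at which tracking was initialized.
#' @export
setClass("TrackSet",
  representation(states = "data.frame", nTracks = "integer",
                 startFrame = "integer")
)

setValidity("TrackSet", function(object) {
  st <- object@states
  need <- c("frame", "track_id", "x", "y", "theta_deg", "status")
  if (!all(need %in% names(st)))
    return(paste("states must have columns", paste(need, collapse = ", ")))
  if (nrow(st)) {
    per <- table(st$frame)
    if (any(per != object@nTracks))
      return("every frame must carry exactly nTracks states")
    if (!all(st$status %in% c("detected", "propagated")))
      return("status must be detected or propagated")
  }
  TRUE
})

#' A synthetic fish-swimming benchmark sequence
#'
#' Frames plus exact per-frame ground truth, regenerated bit-exactly from
#' the stored seed and parameters.
#'
#' @slot frames list of 2-D numeric matrices (gray levels 0-255).
#' @slot groundTruth data.frame with columns \code{frame}, \code{fish_id},
#'   \code{x}, \code{y}, \code{theta_deg}, \code{occluded}.
#' @slot seed integer seed the sequence was generated from.
#' @slot params list of generator parameters (fish geometry, motion model,
#'   arena, noise).
#' @export
setClass("FishBenchmark",
  representation(frames = "list", groundTruth = "data.frame",
                 seed = "integer", params = "list")
)

setValidity("FishBenchmark", function(object) {
  gt <- object@groundTruth
  need <- c("frame", "fish_id", "x", "y", "theta_deg", "occluded")
  if (!all(need %in% names(gt)))
    return(paste("groundTruth must have columns", paste(need, collapse = ", ")))
  if (length(object@frames) && nrow(gt) &&
      max(gt$frame) >= length(object@frames))
    return("groundTruth refers to frames beyond the sequence")
  TRUE
})

#' @describeIn FishTrackConfig-class compact display
#' @param object a \code{FishTrackConfig}
#' @export
setMethod("show", "FishTrackConfig", function(object) {
  cat("FishTrackConfig\n")
  cat(sprintf("  segmentation: tG=%g, background frames=%d, minBlobArea=%g, medianKernel=%d\n",
              object@tG, as.integer(object@nBackgroundFrames),
              object@minBlobArea, as.integer(object@medianKernel)))
  cat(sprintf("  centerline:   tU=%g\n", object@tU))
  cat(sprintf("  head:         tL=%g, tW=%g, scales={%s}, anisotropyMin=%g\n",
              object@tL, object@tW, paste(object@scales, collapse = ","),
              object@anisotropyMin))
  cat(sprintf("  tracking:     omega=%g, pcMax=%g, dcMax=%g, tO=%g, N=%d\n",
              object@omega, object@pcMax, object@dcMax, object@tO,
              as.integer(object@nFish)))
  cat(sprintf("  polarity:     %s\n",
              if (object@darkFish) "dark fish on light background"
              else "light fish on dark background"))
})

#' @describeIn SkeletonGraph-class compact display
#' @param object a \code{SkeletonGraph}
#' @export
setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d pixels, %d endpoints, %d junctions, %d branches\n",
              nrow(object@pixels), nrow(object@endpoints),
              nrow(object@junctions), length(object@branches)))
})

#' @describeIn TrackSet-class compact display
#' @param object a \code{TrackSet}
#' @export
setMethod("show", "TrackSet", function(object) {
  st <- object@states
  nf <- length(unique(st$frame))
  cat(sprintf("TrackSet: %d tracks x %d frames (start frame %d); %d propagated states\n",
              object@nTracks, nf, object@startFrame,
              sum(st$status == "propagated")))
})

#' @describeIn FishBenchmark-class compact display
#' @param object a \code{FishBenchmark}
#' @export
setMethod("show", "FishBenchmark", function(object) {
  gt <- object@groundTruth
  cat(sprintf("FishBenchmark: %d frames (%dx%d), %d fish, %d occluded target-frames, seed %d\n",
              length(object@frames),
              if (length(object@frames)) nrow(object@frames[[1]]) else 0L,
              if (length(object@frames)) ncol(object@frames[[1]]) else 0L,
              length(unique(gt$fish_id)), sum(gt$occluded), object@seed))
})

#' Accessors
#'
#' @param x a \code{TrackSet} or \code{FishBenchmark}
#' @return \code{trackStates}: the per-frame state table; \code{nTracks}:
#'   the fixed fish count; \code{benchFrames}: the list of frame matrices;
#'   \code{groundTruth}: the ground-truth table.
#' @name accessors
NULL

#' @rdname accessors
#' @export
trackStates <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@states
}

#' @rdname accessors
#' @export
nTracks <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@nTracks
}

#' @rdname accessors
#' @export
benchFrames <- function(x) {
  stopifnot(is(x, "FishBenchmark"))
  x@frames
}

#' @rdname accessors
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "FishBenchmark"))
  x@groundTruth
}

#' @rdname accessors
#' @export
skeletonPixels <- function(x) {
  stopifnot(is(x, "SkeletonGraph"))
  x@pixels
}

#' @rdname accessors
#' @export
skeletonEndpoints <- function(x) {
  stopifnot(is(x, "SkeletonGraph"))
  x@endpoints
}

#' @rdname accessors
#' @export
skeletonJunctions <- function(x) {
  stopifnot(is(x, "SkeletonGraph"))
  x@junctions
}

#' @rdname accessors
#' @export
skeletonBranches <- function(x) {
  stopifnot(is(x, "SkeletonGraph"))
  x@branches
}
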