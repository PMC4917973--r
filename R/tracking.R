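# Frame-to-frame data association. The cost of linking track i to
# detection j mixes normalized position and direction change,
#   cv_ij = omega * pc_ij / pc_max + (1 - omega) * dc_ij / dc_max,
# pairs farther apart than the gating distance tO are forbidden, and the
# minimum-total-cost one-to-one matching is found with the Hungarian
# algorithm. Unmatched tracks are propagated unchanged (occlusion), surplus
# detections are dropped, so the population size N is conserved.

#' Position change between a track state and a detection
#'
#' @param a,b length-2 numeric vectors (x, y) or rows with \code{x}, \code{y}.
#' @return Euclidean distance in pixels.
#' @export
positionChange <- function(a, b) {
  sqrt((as.numeric(a[["x"]]) - as.numeric(b[["x"]]))^2 +
       (as.numeric(a[["y"]]) - as.numeric(b[["y"]]))^2)
}

#' Direction change between two headings
#'
#' @param thetaA,thetaB angles in degrees in [0, 360).
#' @return smallest absolute angular difference, in [0, 180].
#' @export
directionChange <- function(thetaA, thetaB) {
  d <- abs(thetaA - thetaB) %% 360
  pmin(d, 360 - d)
}

#' Association cost of a position/direction change pair
#'
#' @param pc position change (px).
#' @param dc direction change (deg).
#' @param omega position weight in [0, 1].
#' @param pcMax,dcMax normalizing maximum changes.
#' @return the cost value; 0 for a perfectly still target, 1 when both
#'   changes reach their maxima. Values above 1 are possible when
#'   \code{pc > pcMax}; exclusion of implausible pairs is the gate's job,
#'   not the cost's.
#' @export
costValue <- function(pc, dc, omega, pcMax, dcMax) {
  stopifnot(pc >= 0, dc >= 0)
  omega * (pc / pcMax) + (1 - omega) * (dc / dcMax)
}

#' Gated cost matrix between previous tracks and current detections
#'
#' Entry (i, j) is the association cost when the Euclidean distance between
#' track i and detection j is below the maximum occlusion distance
#' \code{tO}, and +Inf otherwise. Detections without a usable direction
#' (degenerate Hessian, \code{theta_deg = NA}) contribute an uninformative
#' direction term of dcMax / 2.
#'
#' @param prev data.frame of track states (\code{x}, \code{y},
#'   \code{theta_deg}).
#' @param curr data.frame of detections (\code{x}, \code{y},
#'   \code{theta_deg}).
#' @param omega,pcMax,dcMax,tO tracking parameters.
#' @return numeric n x m matrix with +Inf on gated entries.
#' @export
buildCostMatrix <- function(prev, curr, omega, pcMax, dcMax, tO) {
  n <- nrow(prev); m <- nrow(curr)
  A <- matrix(Inf, n, m)
  if (n == 0 || m == 0) return(A)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pc <- sqrt((prev$x[i] - curr$x[j])^2 + (prev$y[i] - curr$y[j])^2)
    if (pc >= tO) next
    dc <- if (is.na(curr$theta_deg[j]) || is.na(prev$theta_deg[i]))
      dcMax / 2 else directionChange(prev$theta_deg[i], curr$theta_deg[j])
    A[i, j] <- costValue(pc, dc, omega, pcMax, dcMax)
  }
  A
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) on a square
# matrix of finite costs. Returns, for each row, the assigned column.
.hungarianSquare <- function(C) {
  n <- nrow(C)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- C[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Minimum-cost assignment with gating
#'
#' Solves the global data-association problem: a one-to-one matching of
#' rows (previous-frame tracks) to columns (current detections) minimizing
#' total cost, covering min(n, m) pairs, never using a gated (+Inf) entry.
#' Internally, gated entries become a finite BIG constant and the matrix is
#' padded square with BIG dummies; matches through BIG entries are reported
#' as unmatched. Ties between equal-cost assignments resolve
#' deterministically (lowest row index first).
#'
#' @param A numeric cost matrix, entries in [0, Inf].
#' @return list with \code{pairs} (two-column matrix of matched row and
#'   column indices), \code{cost} (total over matched pairs),
#'   \code{unmatchedRows}, \code{unmatchedCols}.
#' @export
solveAssignment <- function(A) {
  n <- nrow(A); m <- ncol(A)
  if (n == 0 || m == 0)
    return(list(pairs = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("row", "col"))),
                cost = 0, unmatchedRows = seq_len(n),
                unmatchedCols = seq_len(m)))
  finite <- A[is.finite(A)]
  big <- if (length(finite)) max(n, m) * max(finite) + 1 else 1
  k <- max(n, m)
  C <- matrix(big, k, k)
  Af <- A
  Af[!is.finite(Af)] <- big
  C[seq_len(n), seq_len(m)] <- Af
  assign <- .hungarianSquare(C)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    j <- assign[i]
    if (j >= 1 && j <= m && is.finite(A[i, j]))
      pairs <- rbind(pairs, c(i, j))
  }
  colnames(pairs) <- c("row", "col")
  list(pairs = pairs,
       cost = if (nrow(pairs)) sum(A[pairs]) else 0,
       unmatchedRows = setdiff(seq_len(n), pairs[, "row"]),
       unmatchedCols = setdiff(seq_len(m), pairs[, "col"]))
}

#' Initialize tracks at the first frame with exactly N detections
#'
#' Scans detection frames in order and starts tracking at the first frame
#' whose detection count equals \code{N}, assigning track ids 1..N in
#' detection order. Fails explicitly when no frame reaches N detections.
#'
#' @param detections data.frame of all detections (\code{frame}, \code{x},
#'   \code{y}, \code{theta_deg}).
#' @param N fixed number of fish.
#' @return list with \code{startFrame} and \code{states} (the initial
#'   track-state data.frame).
#' @export
initializeTracks <- function(detections, N) {
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    d <- detections[detections$frame == f, , drop = FALSE]
    if (nrow(d) == N) {
      return(list(
        startFrame = as.integer(f),
        states = data.frame(frame = as.integer(f),
                            track_id = seq_len(N),
                            x = d$x, y = d$y, theta_deg = d$theta_deg,
                            status = "detected")))
    }
  }
  stop("initialization failure: no frame with exactly N = ", N,
       " detections")
}

#' Advance tracks by one frame
#'
#' Associates the previous frame's N track states with the current frame's
#' detections by gated minimum-cost assignment. Matched tracks take the
#' detection's position and direction (status \code{detected}); unmatched
#' tracks -- occluded fish, or fish whose every pairing was gated -- keep
#' their previous state unchanged (status \code{propagated}); surplus
#' detections are dropped. Every frame therefore ends with exactly N
#' states.
#'
#' @param prev data.frame of the previous frame's N states.
#' @param detections data.frame of the current frame's detections.
#' @param frame current frame index.
#' @param omega,pcMax,dcMax,tO tracking parameters.
#' @return data.frame of the current frame's N states.
#' @export
stepTracks <- function(prev, detections, frame, omega, pcMax, dcMax, tO) {
  N <- nrow(prev)
  out <- prev
  out$frame <- as.integer(frame)
  out$status <- "propagated"
  if (nrow(detections) > 0) {
    A <- buildCostMatrix(prev, detections, omega, pcMax, dcMax, tO)
    sol <- solveAssignment(A)
    if (nrow(sol$pairs)) {
      i <- sol$pairs[, "row"]; j <- sol$pairs[, "col"]
      out$x[i] <- detections$x[j]
      out$y[i] <- detections$y[j]
      # a detection with no usable direction keeps the track's previous one
      nd <- !is.na(detections$theta_deg[j])
      out$theta_deg[i[nd]] <- detections$theta_deg[j[nd]]
      out$status[i] <- "detected"
    }
  }
  out
}

#' Track fish across a detection sequence
#'
#' Runs initialization (forward scan for a frame with exactly N
#' detections), then per-frame gated global association. Frames before the
#' initialization frame carry no states.
#'
#' @param detections data.frame of detections for frames 0..F-1.
#' @param nFrames total number of frames in the sequence.
#' @param N fixed number of fish.
#' @param omega,pcMax,dcMax,tO tracking parameters.
#' @return a \code{\link{TrackSet-class}}.
#' @export
trackFish <- function(detections, nFrames, N, omega, pcMax, dcMax, tO) {
  init <- initializeTracks(detections, N)
  states <- vector("list", nFrames)
  states[[init$startFrame + 1L]] <- init$states
  prev <- init$states
  f <- init$startFrame + 1L
  while (f < nFrames) {
    d <- detections[detections$frame == f, , drop = FALSE]
    cur <- stepTracks(prev, d, f, omega, pcMax, dcMax, tO)
    states[[f + 1L]] <- cur
    prev <- cur
    f <- f + 1L
  }
  st <- do.call(rbind, states[!vapply(states, is.null, logical(1))])
  rownames(st) <- NULL
  new("TrackSet", states = st, nTracks = as.integer(N),
      startFrame = init$startFrame)
}
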