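# Detection and tracking evaluation against ground truth: average correct /
# error / occlusion detection rates, average direction error, and the
# mostly-tracked / partially-tracked / identity-switch trajectory criteria.

# deterministic greedy one-to-one matching: repeatedly take the globally
# closest (detection, truth) pair under the radius; ties broken by row
# order of the distance table
.greedyMatch <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  if (na == 0 || nb == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b"))))
  D <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  D <- sqrt(D)
  D[D >= radius] <- Inf
  pairs <- matrix(integer(0), 0, 2)
  while (any(is.finite(D))) {
    k <- which.min(D)  # first minimum in column-major order: deterministic
    i <- ((k - 1) %% na) + 1
    j <- ((k - 1) %/% na) + 1
    pairs <- rbind(pairs, c(i, j))
    D[i, ] <- Inf
    D[, j] <- Inf
  }
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Score detections against ground truth
#'
#' Per frame, detections are matched one-to-one to ground-truth targets
#' within \code{matchRadius} (greedy nearest, deterministic). A matched
#' detection is correct; an unmatched detection is an error. Rates are
#' averaged over frames: ACDR = mean fraction of targets correctly
#' detected, AEDR = mean ratio of error detections to targets, AODR = the
#' correct-detection rate over targets flagged occluded (pooled over all
#' frames), and ADE = the mean smallest angular difference between detected
#' and true heading over correct detections with a usable direction.
#'
#' @param detections data.frame with \code{frame}, \code{x}, \code{y},
#'   \code{theta_deg}.
#' @param gt ground truth data.frame with \code{frame}, \code{fish_id},
#'   \code{x}, \code{y}, \code{theta_deg}, \code{occluded}.
#' @param matchRadius matching radius in pixels.
#' @return list: \code{acdr}, \code{aedr}, \code{aodr} (NA when the truth
#'   has no occlusions), \code{ade} (degrees), \code{nOcclusions} (occluded
#'   target-frames in the truth).
#' @export
scoreDetections <- function(detections, gt, matchRadius) {
  if (nrow(gt) == 0) stop("ground truth is empty")
  stopifnot(matchRadius > 0)
  frames <- sort(unique(gt$frame))
  cdr <- edr <- numeric(length(frames))
  occTotal <- 0L; occDetected <- 0L
  angErr <- numeric(0)
  for (k in seq_along(frames)) {
    f <- frames[k]
    g <- gt[gt$frame == f, , drop = FALSE]
    d <- detections[detections$frame == f, , drop = FALSE]
    pr <- .greedyMatch(d$x, d$y, g$x, g$y, matchRadius)
    nCorrect <- nrow(pr)
    cdr[k] <- nCorrect / nrow(g)
    edr[k] <- (nrow(d) - nCorrect) / nrow(g)
    occ <- which(g$occluded)
    occTotal <- occTotal + length(occ)
    occDetected <- occDetected + sum(pr[, "b"] %in% occ)
    if (nCorrect > 0) {
      th <- detections$theta_deg[detections$frame == f][pr[, "a"]]
      tt <- g$theta_deg[pr[, "b"]]
      okA <- !is.na(th)
      if (any(okA)) angErr <- c(angErr, directionChange(th[okA], tt[okA]))
    }
  }
  list(acdr = mean(cdr),
       aedr = mean(edr),
       aodr = if (occTotal > 0) occDetected / occTotal else NA_real_,
       ade = if (length(angErr)) mean(angErr) else NA_real_,
       nOcclusions = occTotal)
}

#' Score tracking against ground-truth trajectories
#'
#' Per frame, track states are matched one-to-one to ground-truth fish
#' within \code{matchRadius} (greedy nearest). A fish's owner id is the
#' track id currently matched to it; the owner updates whenever the match
#' switches to a different track. Coverage of a trajectory is the fraction
#' of its frames in which it has a matched track; MTT counts trajectories
#' with coverage > 0.8, PTT those in [0.2, 0.8], and TIS the total number
#' of owner-id change events summed over all trajectories.
#'
#' @param tracks a \code{\link{TrackSet-class}} or its states data.frame.
#' @param gt ground truth data.frame (see \code{\link{scoreDetections}}).
#' @param matchRadius matching radius in pixels.
#' @return list: \code{mtt}, \code{ptt}, \code{tis}, \code{gtCount},
#'   \code{coverage} (named by fish id).
#' @export
scoreTracking <- function(tracks, gt, matchRadius) {
  st <- if (is(tracks, "TrackSet")) tracks@states else tracks
  fish <- sort(unique(gt$fish_id))
  frames <- sort(unique(gt$frame))
  owner <- stats::setNames(rep(NA_integer_, length(fish)), fish)
  switches <- stats::setNames(rep(0L, length(fish)), fish)
  matchedFrames <- stats::setNames(rep(0L, length(fish)), fish)
  totalFrames <- stats::setNames(rep(0L, length(fish)), fish)
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    tt <- st[st$frame == f, , drop = FALSE]
    totalFrames[as.character(g$fish_id)] <-
      totalFrames[as.character(g$fish_id)] + 1L
    if (nrow(tt) == 0) next
    pr <- .greedyMatch(tt$x, tt$y, g$x, g$y, matchRadius)
    if (nrow(pr) == 0) next
    for (r in seq_len(nrow(pr))) {
      fid <- as.character(g$fish_id[pr[r, "b"]])
      tid <- tt$track_id[pr[r, "a"]]
      matchedFrames[fid] <- matchedFrames[fid] + 1L
      if (!is.na(owner[fid]) && owner[fid] != tid)
        switches[fid] <- switches[fid] + 1L
      owner[fid] <- tid
    }
  }
  coverage <- matchedFrames / pmax(totalFrames, 1L)
  list(mtt = sum(coverage > 0.8),
       ptt = sum(coverage >= 0.2 & coverage <= 0.8),
       tis = sum(switches),
       gtCount = length(fish),
       coverage = coverage)
}
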