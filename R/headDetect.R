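# Head endpoint determination: endpoints far enough (along the skeleton)
# from the nearest junction are head/tail candidates; the largest inscribed
# circle at the endpoint measures local body width, and the wider-than-tW
# endpoints are fish heads.

# geodesic (arc-length, sqrt(2) diagonals) distance from one endpoint to the
# nearest junction pixel along the skeleton; Inf when its component has none
.distToJunction <- function(graph, endpoint) {
  px <- graph@pixels
  if (nrow(graph@junctions) == 0) return(Inf)
  comp <- endpoint[["component"]]
  inComp <- px[, "component"] == comp
  jct <- graph@junctions
  jctComp <- jct[jct[, "component"] == comp, , drop = FALSE]
  if (nrow(jctComp) == 0) return(Inf)
  pts <- px[inComp, , drop = FALSE]
  keyOf <- function(x, y) paste(x, y)
  idxOf <- new.env(hash = TRUE)
  for (t in seq_len(nrow(pts)))
    assign(keyOf(pts[t, "x"], pts[t, "y"]), t, envir = idxOf)
  n <- nrow(pts)
  dist <- rep(Inf, n)
  src <- get(keyOf(endpoint[["x"]], endpoint[["y"]]), envir = idxOf)
  dist[src] <- 0
  visited <- rep(FALSE, n)
  isJ <- rep(FALSE, n)
  for (t in seq_len(nrow(jctComp))) {
    k <- keyOf(jctComp[t, "x"], jctComp[t, "y"])
    if (exists(k, envir = idxOf)) isJ[get(k, envir = idxOf)] <- TRUE
  }
  # Dijkstra over the (small) per-component skeleton
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) return(Inf)
    cur <- cand[which.min(dist[cand])]
    if (isJ[cur]) return(dist[cur])
    visited[cur] <- TRUE
    cx <- pts[cur, "x"]; cy <- pts[cur, "y"]
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      k <- keyOf(cx + dx, cy + dy)
      if (!exists(k, envir = idxOf)) next
      j <- get(k, envir = idxOf)
      w <- if (dx != 0 && dy != 0) sqrt(2) else 1
      if (dist[cur] + w < dist[j]) dist[j] <- dist[cur] + w
    }
  }
}

#' Filter skeleton endpoints by branch length
#'
#' Keeps endpoints whose along-skeleton (geodesic) distance to the nearest
#' junction exceeds \code{tL}; endpoints on junction-free skeletons (simple
#' curves) are always kept. Short spur endpoints produced by occlusion
#' burrs are removed.
#'
#' @param graph a \code{\link{SkeletonGraph-class}}.
#' @param tL branch length threshold in pixels.
#' @return data.frame with columns \code{x}, \code{y}, \code{component},
#'   \code{branch_length} (geodesic pixels, \code{Inf} when the component
#'   has no junction).
#' @export
filterEndpoints <- function(graph, tL) {
  ep <- graph@endpoints
  out <- data.frame(x = integer(0), y = integer(0), component = integer(0),
                    branch_length = numeric(0))
  if (nrow(ep) == 0) return(out)
  bl <- vapply(seq_len(nrow(ep)), function(t)
    .distToJunction(graph, ep[t, ]), numeric(1))
  keep <- bl > tL
  data.frame(x = ep[keep, "x"], y = ep[keep, "y"],
             component = ep[keep, "component"], branch_length = bl[keep])
}

#' Largest-inscribed-circle width at an endpoint
#'
#' The minimum Euclidean distance from the endpoint to the region edge is
#' the inscribed circle's radius; twice that distance approximates the
#' local body width. Computed exactly by an expanding-window search for the
#' nearest background pixel (pixels outside the image count as background).
#'
#' @param endpoint length-2 vector or 1-row data.frame with \code{x},
#'   \code{y} (0-based pixel).
#' @param mask logical matrix of the moving region.
#' @return width in pixels (2 x distance to the nearest background pixel).
#' @export
measureEndpointWidth <- function(endpoint, mask) {
  if (all(c("x", "y") %in% names(endpoint))) {
    x <- as.numeric(endpoint[["x"]]); y <- as.numeric(endpoint[["y"]])
  } else {
    x <- as.numeric(endpoint[[1]]); y <- as.numeric(endpoint[[2]])
  }
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- as.integer(y) + 1L; c0 <- as.integer(x) + 1L
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc || !mask[r0, c0])
    stop("endpoint is not a foreground pixel")
  best <- Inf
  rad <- 1L
  repeat {
    rlo <- max(1L, r0 - rad); rhi <- min(nr, r0 + rad)
    clo <- max(1L, c0 - rad); chi <- min(nc, c0 + rad)
    sub <- mask[rlo:rhi, clo:chi, drop = FALSE]
    bgIdx <- which(!sub)
    if (length(bgIdx)) {
      br <- ((bgIdx - 1L) %% nrow(sub)) + rlo
      bc <- ((bgIdx - 1L) %/% nrow(sub)) + clo
      best <- min(best, sqrt((br - r0)^2 + (bc - c0)^2))
    }
    # image border counts as background
    borderD <- Inf
    if (r0 - rad < 1L || r0 + rad > nr || c0 - rad < 1L || c0 + rad > nc)
      borderD <- min(r0, nr - r0 + 1L, c0, nc - c0 + 1L)
    best <- min(best, borderD)
    if (is.finite(best) && best <= rad) break
    rad <- rad * 2L
    if (rad > max(nr, nc)) break
  }
  2 * best
}

#' Classify head endpoints by width
#'
#' Endpoints whose measured width strictly exceeds \code{tW} are emitted as
#' head detections (the head region is wider than the tail). When one
#' component yields several super-threshold endpoints -- two overlapping
#' fish, for instance -- all are emitted; disambiguation is the tracker's
#' job.
#'
#' @param endpoints data.frame from \code{\link{filterEndpoints}} with an
#'   added \code{width} column (see \code{\link{measureEndpointWidth}}).
#' @param tW width threshold in pixels.
#' @param frame frame index recorded in the detections.
#' @return data.frame of head detections: \code{frame}, \code{x}, \code{y},
#'   \code{width}, \code{theta_deg} (NA until direction estimation),
#'   \code{component}.
#' @export
classifyHeads <- function(endpoints, tW, frame = 0L) {
  stopifnot(tW > 0)
  keep <- if (nrow(endpoints) == 0 || !"width" %in% names(endpoints))
    logical(0) else endpoints$width > tW
  data.frame(frame = rep(as.integer(frame), sum(keep)),
             x = as.numeric(endpoints$x[keep]),
             y = as.numeric(endpoints$y[keep]),
             width = endpoints$width[keep],
             theta_deg = rep(NA_real_, sum(keep)),
             component = as.integer(endpoints$component[keep]))
}

#' Measure widths for a table of endpoints
#'
#' @param endpoints data.frame with \code{x}, \code{y} columns.
#' @param mask logical moving-region mask.
#' @return the data.frame with a \code{width} column appended.
#' @export
measureEndpointWidths <- function(endpoints, mask) {
  if (nrow(endpoints) == 0) {
    endpoints$width <- numeric(0)
    return(endpoints)
  }
  endpoints$width <- vapply(seq_len(nrow(endpoints)), function(t)
    measureEndpointWidth(endpoints[t, ], mask), numeric(1))
  endpoints
}
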