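# Centerline extraction by augmented fast marching: the region boundary is
# parameterized with monotonically increasing arrival values U, U is
# propagated inward so every interior pixel carries the U of its nearest
# boundary point, and centerline pixels are those where neighboring U
# values differ by more than a pruning threshold tU (wrap-corrected for the
# seam where the boundary parameter jumps from L back to 1).

# clockwise Moore neighborhood with x right / y down: E, SE, S, SW, W, NW, N, NE
.mooreDx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.mooreDy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

# Trace the outer contour of one component (given as a logical matrix) by
# Moore-neighbor following, clockwise, from the lexicographically smallest
# (x, y) boundary pixel. Returns the ordered (x, y) contour with possible
# revisits on 1-px-wide protrusions.
.traceContour <- function(inComp, start) {
  nr <- nrow(inComp); nc <- ncol(inComp)
  inside <- function(x, y) x >= 0L && x < nc && y >= 0L && y < nr &&
    inComp[y + 1L, x + 1L]
  cx <- start[1]; cy <- start[2]
  # west neighbor of the start is outside the component by minimality of x
  bdir <- 5L  # index into .moore* of the backtrack direction (W)
  path <- matrix(NA_integer_, 4L * sum(inComp) + 8L, 2L)
  path[1, ] <- c(cx, cy)
  np <- 1L
  first <- NULL  # state (pixel, backtrack) after the first move; the trace
                 # is periodic, so its recurrence marks one full loop
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- ((bdir - 1L + k - 1L) %% 8L) + 1L  # clockwise from the backtrack
      nx <- cx + .mooreDx[d]; ny <- cy + .mooreDy[d]
      if (inside(nx, ny)) {
        # new backtrack: the previously examined (background) neighbor,
        # expressed relative to the new current pixel
        pd <- ((d - 2L) %% 8L) + 1L
        px <- cx + .mooreDx[pd]; py <- cy + .mooreDy[pd]
        nb <- which(.mooreDx == px - nx & .mooreDy == py - ny)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (!is.null(first) &&
        nx == first[1] && ny == first[2] && nb == first[3]) break
    if (is.null(first)) first <- c(nx, ny, nb)
    cx <- nx; cy <- ny; bdir <- nb
    np <- np + 1L
    if (np > nrow(path)) { np <- np - 1L; break }  # safety net
    path[np, ] <- c(cx, cy)
  }
  path[seq_len(np), , drop = FALSE]
}

#' Parameterize region boundaries with arrival values
#'
#' For each connected foreground component the outer boundary is traversed
#' by clockwise Moore-neighbor contour following, starting at the
#' lexicographically smallest (x, y) boundary pixel, and its pixels are
#' assigned U = 1, 2, ..., L in traversal order (first visit wins on 1-px
#' protrusions), where L is the component's boundary length.
#'
#' @param mask logical matrix; components should be hole-free (see
#'   \code{\link{cleanMask}}).
#' @return an \code{arrivalField} list with elements \code{U} (numeric
#'   matrix; boundary parameter on boundary pixels, NA elsewhere),
#'   \code{boundary} (logical matrix), \code{labels} (integer component
#'   labels), \code{boundaryLength} (named numeric, per component) and
#'   \code{propagated = FALSE}.
#' @export
parameterizeBoundary <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  U <- matrix(NA_real_, nr, nc)
  bnd <- matrix(FALSE, nr, nc)
  labels <- matrix(0L, nr, nc)
  L <- numeric(0)
  if (any(mask)) {
    labels <- matrix(as.integer(EBImage::bwlabel(
      matrix(as.integer(mask), nr, nc))), nr, nc)
    ncomp <- max(labels)
    L <- numeric(ncomp)
    for (comp in seq_len(ncomp)) {
      inComp <- labels == comp
      idx <- which(inComp)
      rows <- ((idx - 1L) %% nr) + 1L
      cols <- ((idx - 1L) %/% nr) + 1L
      xs <- cols - 1L; ys <- rows - 1L
      if (length(idx) == 1L) {
        U[idx] <- 1; bnd[idx] <- TRUE; L[comp] <- 1
        next
      }
      ord <- order(xs, ys)
      start <- c(xs[ord[1]], ys[ord[1]])
      ctr <- .traceContour(inComp, start)
      seen <- !duplicated(ctr)
      uniq <- ctr[seen, , drop = FALSE]
      L[comp] <- nrow(uniq)
      U[cbind(uniq[, 2] + 1L, uniq[, 1] + 1L)] <- seq_len(nrow(uniq))
      bnd[cbind(uniq[, 2] + 1L, uniq[, 1] + 1L)] <- TRUE
    }
    names(L) <- as.character(seq_len(ncomp))
  }
  structure(list(U = U, boundary = bnd, labels = labels,
                 boundaryLength = L, propagated = FALSE),
            class = "arrivalField")
}

#' Propagate boundary arrival values inward
#'
#' Fast-marching propagation (4-connected first-order upwind scheme) from
#' the parameterized boundary into the component interior; each interior
#' pixel inherits the U of the upwind neighbor that last improved its
#' arrival time, so U is consistent with the nearest boundary point. Ties
#' in the marching front are resolved by first arrival (insertion order),
#' making the result deterministic.
#'
#' @param field an \code{arrivalField} from \code{\link{parameterizeBoundary}}.
#' @return the field with \code{U} filled over all foreground pixels, an
#'   added \code{T} matrix of arrival times (distance to the boundary) and
#'   \code{propagated = TRUE}.
#' @export
propagateArrivalTimes <- function(field) {
  stopifnot(inherits(field, "arrivalField"))
  if (field$propagated) return(field)
  mask <- field$labels > 0L
  if (!any(mask)) {
    field$T <- matrix(NA_real_, nrow(field$U), ncol(field$U))
    field$propagated <- TRUE
    return(field)
  }
  U0 <- field$U
  U0[is.na(U0)] <- 0
  res <- .fmmPropagate(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                       U0,
                       matrix(as.integer(field$boundary), nrow(mask), ncol(mask)))
  U <- res$U
  U[!mask] <- NA_real_
  field$U <- U
  field$T <- res$T
  field$propagated <- TRUE
  field
}

#' Extract the pruned centerline from an arrival field
#'
#' A foreground pixel (x, y) belongs to the centerline when
#' max(|ux|, |uy|) > tU, with ux = U(x+1, y) - U(x, y) and
#' uy = U(x, y+1) - U(x, y). Each absolute difference d is first
#' wrap-corrected to min(d, L - d), L being the component's boundary
#' length, which removes the spurious seam where the boundary parameter
#' jumps from L back to 1. Differences across components or into the
#' background are ignored.
#'
#' @param field a propagated \code{arrivalField}.
#' @param tU pruning threshold, in boundary pixels; larger values prune
#'   side branches more aggressively.
#' @return logical matrix of centerline pixels (possibly 2 px thick; see
#'   \code{\link{thinCenterline}}).
#' @export
extractCenterline <- function(field, tU) {
  stopifnot(inherits(field, "arrivalField"), isTRUE(field$propagated), tU > 2)
  U <- field$U; lab <- field$labels
  nr <- nrow(U); nc <- ncol(U)
  if (!any(lab > 0L)) return(matrix(FALSE, nr, nc))
  Lmap <- matrix(0, nr, nc)
  pos <- lab > 0L
  Lmap[pos] <- field$boundaryLength[lab[pos]]

  wrapAbs <- function(d, L) pmin(abs(d), L - abs(d))

  cl <- matrix(FALSE, nr, nc)
  # x-difference: neighbor one column right, same component
  dx <- matrix(0, nr, nc)
  ok <- matrix(FALSE, nr, nc)
  ok[, -nc] <- lab[, -nc] > 0L & lab[, -1] == lab[, -nc]
  dx[, -nc][ok[, -nc]] <- (U[, -1] - U[, -nc])[ok[, -nc]]
  ux <- matrix(0, nr, nc)
  ux[ok] <- wrapAbs(dx[ok], Lmap[ok])
  # y-difference: neighbor one row down, same component
  dy <- matrix(0, nr, nc)
  ok2 <- matrix(FALSE, nr, nc)
  ok2[-nr, ] <- lab[-nr, ] > 0L & lab[-1, ] == lab[-nr, ]
  dy[-nr, ][ok2[-nr, ]] <- (U[-1, ] - U[-nr, ])[ok2[-nr, ]]
  uy <- matrix(0, nr, nc)
  uy[ok2] <- wrapAbs(dy[ok2], Lmap[ok2])

  cl[pos] <- pmax(ux[pos], uy[pos]) > tU
  cl
}

#' Thin a centerline to unit width
#'
#' The raw arrival-time-difference detector can produce a 2-px-thick ridge;
#' morphological (Zhang-Suen) thinning reduces it to an 8-connected curve
#' of unit width, as required for endpoint and junction counting.
#'
#' @param centerline logical matrix.
#' @return logical matrix of the thinned centerline.
#' @export
thinCenterline <- function(centerline) {
  stopifnot(is.logical(centerline))
  m <- .thinMask(matrix(as.integer(centerline), nrow(centerline),
                        ncol(centerline)))
  m > 0L
}

#' Remove tiny spurs left by thinning
#'
#' Deletes endpoint-to-junction branches of at most \code{minSpur} pixels
#' (excluding the junction pixel) and repeats once; unit-width thinning of
#' a 2-px ridge can leave 1-2 px forks at line ends, which would otherwise
#' read as junctions and defeat endpoint analysis. Real side branches are
#' far longer and are handled by the branch-length filter instead.
#'
#' @param centerline logical matrix, thinned to unit width.
#' @param minSpur maximum spur length to remove, in pixels.
#' @return logical matrix.
#' @export
pruneSpurs <- function(centerline, minSpur = 3) {
  out <- centerline
  for (pass in 1:2) {
    g <- buildSkeletonGraph(out)
    if (nrow(g@junctions) == 0) return(out)
    jset <- paste(g@junctions[, "x"], g@junctions[, "y"])
    changed <- FALSE
    for (br in g@branches) {
      p <- br$path
      n <- nrow(p)
      if (n < 2 || n > minSpur + 1L) next
      endA <- paste(p[1, "x"], p[1, "y"])
      endB <- paste(p[n, "x"], p[n, "y"])
      aJ <- endA %in% jset; bJ <- endB %in% jset
      if (aJ == bJ) next  # spur = endpoint on one side, junction on other
      drop <- if (aJ) p[-1, , drop = FALSE] else p[-n, , drop = FALSE]
      out[cbind(drop[, "y"] + 1L, drop[, "x"] + 1L)] <- FALSE
      changed <- TRUE
    }
    if (!changed) return(out)
  }
  out
}

#' Organize a thinned centerline into a skeleton graph
#'
#' Endpoints are skeleton pixels with exactly one 8-connected skeleton
#' neighbor (isolated pixels count as endpoints), junctions have three or
#' more, and branches are maximal simple paths between node pixels.
#'
#' @param centerline logical matrix, thinned to unit width.
#' @param labels optional integer matrix of component labels to attach to
#'   pixels (defaults to the skeleton's own 8-connected components).
#' @return a \code{\link{SkeletonGraph-class}} object.
#' @export
buildSkeletonGraph <- function(centerline, labels = NULL) {
  stopifnot(is.logical(centerline))
  nr <- nrow(centerline); nc <- ncol(centerline)
  emptyMat <- matrix(integer(0), 0, 3,
                     dimnames = list(NULL, c("x", "y", "component")))
  if (!any(centerline))
    return(new("SkeletonGraph", pixels = emptyMat, endpoints = emptyMat,
               junctions = emptyMat, branches = list(),
               dim = c(nr, nc)))

  idx <- which(centerline)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  if (is.null(labels)) {
    pad <- matrix(0L, nr, nc)
    pad[centerline] <- 1L
    # 8-connected labelling by dilating each 4-labelled piece is overkill;
    # a simple union over diagonal adjacencies via repeated bwlabel merge:
    lab4 <- matrix(as.integer(EBImage::bwlabel(pad)), nr, nc)
    labels <- .merge8(lab4, rows, cols, nr, nc)
  }
  comp <- labels[idx]

  S <- centerline
  deg <- integer(length(idx))
  key <- function(r, c) (c - 1L) * nr + r
  pixIndex <- new.env(hash = TRUE)
  for (t in seq_along(idx)) assign(as.character(idx[t]), t, envir = pixIndex)

  nbrList <- vector("list", length(idx))
  for (t in seq_along(idx)) {
    r <- rows[t]; c <- cols[t]
    nb <- integer(0)
    for (drr in -1:1) for (dcc in -1:1) {
      if (drr == 0 && dcc == 0) next
      rr <- r + drr; cc <- c + dcc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (S[rr, cc]) nb <- c(nb, key(rr, cc))
    }
    nbrList[[t]] <- nb
    deg[t] <- length(nb)
  }

  isEnd <- deg <= 1L
  isJct <- deg >= 3L
  isNode <- isEnd | isJct

  mk <- function(sel) {
    m <- cbind(x = cols[sel] - 1L, y = rows[sel] - 1L,
               component = comp[sel])
    storage.mode(m) <- "integer"
    m
  }

  # branch tracing between node pixels
  branches <- list()
  visitedEdge <- new.env(hash = TRUE)
  edgeKey <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  t2i <- function(k) get(as.character(k), envir = pixIndex)
  for (t in which(isNode)) {
    for (nb in nbrList[[t]]) {
      ek <- edgeKey(idx[t], nb)
      if (exists(ek, envir = visitedEdge)) next
      assign(ek, TRUE, envir = visitedEdge)
      path <- c(idx[t], nb)
      prev <- idx[t]; cur <- nb
      while (!isNode[t2i(cur)]) {
        nxt <- setdiff(nbrList[[t2i(cur)]], prev)
        if (length(nxt) == 0L) break
        nxt <- nxt[1]
        assign(edgeKey(cur, nxt), TRUE, envir = visitedEdge)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      pr <- ((path - 1L) %% nr) + 1L
      pc <- ((path - 1L) %/% nr) + 1L
      steps <- sqrt(diff(pr)^2 + diff(pc)^2)
      branches[[length(branches) + 1L]] <- list(
        path = cbind(x = pc - 1L, y = pr - 1L),
        length = length(path),
        geodesic = sum(steps),
        component = comp[t2i(path[1])])
    }
  }

  new("SkeletonGraph",
      pixels = mk(rep(TRUE, length(idx))),
      endpoints = mk(isEnd),
      junctions = mk(isJct),
      branches = branches,
      dim = c(nr, nc))
}

# merge 4-connected labels across diagonal adjacencies (union-find)
.merge8 <- function(lab4, rows, cols, nr, nc) {
  n <- max(lab4)
  if (n <= 1) return(lab4)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (t in seq_along(rows)) {
    r <- rows[t]; c <- cols[t]; a <- lab4[r, c]
    for (d in list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      b <- lab4[rr, cc]
      if (b > 0L && b != a) union(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab4
  out[lab4 > 0L] <- remap[lab4[lab4 > 0L]]
  out
}

#' Skeletonize a cleaned mask
#'
#' Convenience wrapper running boundary parameterization, fast-marching
#' propagation, centerline extraction at \code{tU} and thinning, returning
#' the skeleton graph.
#'
#' @inheritParams parameterizeBoundary
#' @inheritParams extractCenterline
#' @return a \code{\link{SkeletonGraph-class}} object.
#' @export
skeletonize <- function(mask, tU) {
  field <- propagateArrivalTimes(parameterizeBoundary(mask))
  cl <- pruneSpurs(thinCenterline(extractCenterline(field, tU)))
  buildSkeletonGraph(cl, field$labels)
}
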