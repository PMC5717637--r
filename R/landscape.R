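#' Connectivity network over sampling localities
#'
#' Builds the Delaunay triangulation of the unique locality centroids
#' (empty-circumcircle rule) and returns its edges.  Individuals are
#' aggregated into localities; they contribute later through the averaged
#' inter-locality genetic distances.  Degenerate inputs fall back: two
#' localities give the single edge, collinear localities a path graph
#' along their axis of variation.
#'
#' @param gs geographic sample data.frame (see \code{\link{readCoords}}).
#' @return list with \code{localities} (data.frame locality, x, y) and
#'   \code{edges} (data.frame from, to, length) over locality names.
#' @export
connectivityNetwork <- function(gs) {
  loc <- unique(gs[, c("locality", "x", "y")])
  agg <- aggregate(cbind(x, y) ~ locality, data = gs, FUN = mean)
  nl <- nrow(agg)
  if (nl < 2L) stop("need at least 2 localities for a connectivity network")
  xy <- as.matrix(agg[, c("x", "y")])
  if (nl == 2L) {
    e <- data.frame(from = 1L, to = 2L)
  } else if (.allCollinear(xy)) {
    ord <- order(xy %*% prcomp(xy)$rotation[, 1])
    e <- data.frame(from = ord[-nl], to = ord[-1])
  } else {
    e <- .delaunayEdges(xy)
  }
  len <- sqrt((xy[e$from, 1] - xy[e$to, 1])^2 +
              (xy[e$from, 2] - xy[e$to, 2])^2)
  list(localities = agg,
       edges = data.frame(from = agg$locality[e$from],
                          to = agg$locality[e$to], length = len))
}

.allCollinear <- function(xy) {
  if (nrow(xy) < 3) return(TRUE)
  xc <- sweep(xy, 2, colMeans(xy))
  sv <- svd(xc)$d
  sv[2] < 1e-9 * max(sv[1], 1e-12)
}

# Delaunay edges by the empty-circumcircle triangle test: a triangle
# belongs to the triangulation iff no other point lies strictly inside its
# circumcircle.  O(n^4); locality counts are small.
.delaunayEdges <- function(xy) {
  n <- nrow(xy)
  edges <- matrix(0L, 0, 2)
  for (tri in asplit(combn(n, 3), 2)) {
    cc <- .circumcircle(xy[tri[1], ], xy[tri[2], ], xy[tri[3], ])
    if (is.null(cc)) next                       # collinear triple
    others <- setdiff(seq_len(n), tri)
    dd <- sqrt((xy[others, 1] - cc$cx)^2 + (xy[others, 2] - cc$cy)^2)
    if (all(dd >= cc$r * (1 - 1e-12))) {
      edges <- rbind(edges, rbind(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)]))
    }
  }
  if (nrow(edges) == 0L) {                      # numerically degenerate
    ord <- order(xy %*% prcomp(xy)$rotation[, 1])
    return(data.frame(from = ord[-n], to = ord[-1]))
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  data.frame(from = edges[, 1], to = edges[, 2])
}

.circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12 * max(abs(c(ax, ay, bx, by, cx, cy, 1)))) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Genetic distances at connectivity-edge midpoints
#'
#' Assigns to the midpoint of every connectivity edge the mean pairwise
#' p-distance over all inter-locality individual pairs spanning that edge
#' (Z_i at X_i, Y_i).  In \code{"residual"} mode Z is replaced by the
#' residuals of a simple linear regression of Z on straight-line edge
#' length, removing isolation-by-distance before interpolation.
#'
#' @param net result of \code{\link{connectivityNetwork}}.
#' @param gs geographic sample data.frame (sample, x, y, locality).
#' @param dm distance list from \code{\link{pairwisePDistance}} over the
#'   individuals (ids must match \code{gs$sample}).
#' @param mode "raw" or "residual".
#' @return data.frame with columns x, y, z, from, to, length (one row per
#'   connectivity edge).
#' @export
midpointDistances <- function(net, gs, dm, mode = c("raw", "residual")) {
  mode <- match.arg(mode)
  byloc <- split(gs$sample, gs$locality)
  seqd <- dm$d
  have <- vapply(byloc, function(s) any(s %in% rownames(seqd)), TRUE)
  used <- unique(c(net$edges$from, net$edges$to))
  missingLoc <- used[!have[used]]
  if (length(missingLoc))
    stop("locality without sequence data: ",
         paste(missingLoc, collapse = ", "))
  agg <- net$localities
  rownames(agg) <- agg$locality
  z <- mapply(function(a, b) {
    ia <- intersect(byloc[[a]], rownames(seqd))
    ib <- intersect(byloc[[b]], rownames(seqd))
    mean(seqd[ia, ib, drop = FALSE])
  }, net$edges$from, net$edges$to)
  mx <- (agg[net$edges$from, "x"] + agg[net$edges$to, "x"]) / 2
  my <- (agg[net$edges$from, "y"] + agg[net$edges$to, "y"]) / 2
  if (mode == "residual")
    z <- resid(lm(z ~ net$edges$length))
  data.frame(x = mx, y = my, z = as.numeric(z),
             from = net$edges$from, to = net$edges$to,
             length = net$edges$length, row.names = NULL)
}

#' Inverse-distance-weighted genetic landscape surface
#'
#' Interpolates the midpoint values onto a uniform nx x ny grid spanning
#' the midpoint bounding box expanded by 2.5% per side.  A node's value is
#' the weighted mean of all midpoint values with weights 1/d^a; a node
#' coinciding with a midpoint takes that midpoint's value exactly.  In raw
#' mode every node value lies between min(Z) and max(Z) (convex
#' combination).
#'
#' @param mp midpoint data.frame from \code{\link{midpointDistances}}.
#' @param nx,ny grid dimensions (>= 2).
#' @param a distance weighting exponent (> 0); 1 is the conventional
#'   default.
#' @return A \code{\link{LandscapeGrid}}.
#' @export
interpolateSurface <- function(mp, nx = 50, ny = 50, a = 1) {
  if (nrow(mp) < 1) stop("need at least one midpoint")
  if (a <= 0) stop("weighting exponent a must be > 0")
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2")
  pad <- function(r) {
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 1)
    r + c(-1, 1) * 0.025 * span
  }
  rx <- pad(range(mp$x)); ry <- pad(range(mp$y))
  gx <- seq(rx[1], rx[2], length.out = nx)
  gy <- seq(ry[1], ry[2], length.out = ny)
  vals <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    d <- sqrt((mp$x - gx[i])^2 + (mp$y - gy[j])^2)
    hit <- which(d < 1e-12)
    if (length(hit)) {
      vals[i, j] <- mean(mp$z[hit])
    } else {
      w <- 1 / d^a
      vals[i, j] <- sum(w * mp$z) / sum(w)
    }
  }
  new("LandscapeGrid", x = gx, y = gy, values = vals, a = a,
      midpoints = mp[, c("x", "y", "z")])
}

#' Long-format export of a landscape grid
#'
#' @param grid a \code{\link{LandscapeGrid}}.
#' @return data.frame with columns x, y, value (one row per node).
#' @export
gridToTable <- function(grid) {
  data.frame(x = rep(grid@x, times = length(grid@y)),
             y = rep(grid@y, each = length(grid@x)),
             value = as.vector(grid@values))
}

#' @importFrom stats aggregate
NULL
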