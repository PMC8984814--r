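# Face-face interpenetration tests.
#
# Faces are triangulated into their facelets (face centre, node i, node i+1)
# and facelet pairs from different faces are tested with the Moller
# triangle-triangle algorithm.  Pairs whose triangles share a cage node are
# skipped: contact along shared edges and at hole corners is structural, not
# interpenetration.

#' Triangle-triangle intersection test
#'
#' Robust Moller interval test, including the coplanar case; triangles that
#' merely touch count as intersecting (closed triangles).
#'
#' @param t1,t2 3 x 3 numeric matrices, one vertex per row.
#' @return `TRUE` if the closed triangles share at least one point.
#' @export
#' @examples
#' a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' b <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
#' triangles_intersect(a, b)  # FALSE: parallel planes
triangles_intersect <- function(t1, t2) {
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  stopifnot(all(dim(t1) == c(3, 3)), all(dim(t2) == c(3, 3)))
  for (tt in list(t1, t2)) {
    e1 <- tt[2, ] - tt[1, ]; e2 <- tt[3, ] - tt[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(n^2)) < 1e-12)
      stop("degenerate input: triangle with (near-)zero area")
  }
  pc_tri_tri_cpp(t1, t2)
}

#' Self-intersection test for a cage geometry
#'
#' @param geometry A `pcage_geometry`.
#' @return Logical; attribute `"pairs"` is a two-column matrix of offending
#'   face pairs (empty when there is no interpenetration).
#' @export
cage_self_intersects <- function(geometry) {
  res <- pc_cage_intersections_cpp(geometry$coords, geometry$topology$faces)
  pairs <- unique(cbind(res$face1, res$face2))
  structure(isTRUE(res$intersects), pairs = pairs)
}
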