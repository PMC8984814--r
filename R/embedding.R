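# Initial 3-D embedding of a p-cage topology.
#
# Each face starts as a regular unit-edge P-gon placed on its hole-polyhedron
# vertex at radius R, facing outward, rotated so that its shared edges point
# towards the neighbour faces.  A mechanical relaxation of semi-rigid faces
# joined by zero-rest-length springs at the shared-edge node copies then
# pulls the copies together (alternating rigid Kabsch fits of each regular
# face to the current node-class means); the copies are finally merged by
# averaging, which deforms the faces slightly and yields the starting
# geometry for the Metropolis optimization.

.kabsch_fit <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cd - as.vector(R %*% cs))
}

.apply_rigid <- function(pts, fit) {
  sweep(pts %*% t(fit$R), 2, fit$t, `+`)
}

#' Initial embedding of a p-cage
#'
#' @param topology A `pcage_topology` from [build_topology()].
#' @param solid Optional pre-built `pcage_solid`.
#' @param seed Optional integer; seeds a small jitter of the initial face
#'   placement (useful to restart a failed relaxation).
#' @param iters Maximum relaxation iterations.
#' @param tol Convergence tolerance on the shared-node gap change.
#' @return An object of class `pcage_geometry`: the topology plus `coords`
#'   (NN x 3 matrix, edge lengths near 1).
#' @export
initial_embedding <- function(topology, solid = NULL, seed = NULL,
                              iters = 400L, tol = 1e-9) {
  if (is.null(solid)) solid <- build_solid(topology$symbol)
  P <- topology$P; N <- topology$N
  rP <- 1 / (2 * sin(pi / P))  # circumradius of the unit-edge P-gon
  dmin <- min(stats::dist(solid$vertices))
  R <- 2 * rP / dmin
  if (!is.null(seed)) set.seed(seed)
  jitter <- if (is.null(seed)) 0 else 1e-3

  # per-face local copies, P x 3 each
  copies <- vector("list", N)
  ref <- cbind(rP * cos(2 * pi * (0:(P - 1)) / P),
               rP * sin(2 * pi * (0:(P - 1)) / P), 0)
  for (v in seq_len(N)) {
    nrm <- solid$vertices[v, ]
    B <- tangent_basis(nrm)
    ctr <- R * nrm
    # phase aligning shared-edge midpoints with the neighbour directions
    sh <- which(topology$slot_kind[v, ] == "S")
    z <- 0
    for (j in sh) {
      e <- topology$slot_ref[v, j]
      other <- setdiff(solid$edges[e, ], v)
      rel <- solid$vertices[other, ] - nrm
      psi <- atan2(sum(rel * B[, 2]), sum(rel * B[, 1]))
      z <- z + exp(1i * (psi - 2 * pi * (j - 0.5) / P))
    }
    phi0 <- Arg(z)
    ang <- phi0 + 2 * pi * (0:(P - 1)) / P
    pts <- sweep(rP * (cos(ang) %o% B[, 1] + sin(ang) %o% B[, 2]), 2, ctr, `+`)
    if (jitter > 0) pts <- pts + matrix(stats::rnorm(3 * P, sd = jitter), P, 3)
    copies[[v]] <- pts
  }

  # rigid consensus relaxation
  fidx <- topology$faces
  gap_prev <- Inf
  for (it in seq_len(iters)) {
    targets <- matrix(0, topology$NN, 3)
    counts <- numeric(topology$NN)
    for (v in seq_len(N)) {
      ids <- fidx[v, ]
      targets[ids, ] <- targets[ids, ] + copies[[v]]
      counts[ids] <- counts[ids] + 1
    }
    targets <- targets / counts
    gap <- 0
    for (v in seq_len(N)) {
      dst <- targets[fidx[v, ], ]
      gap <- max(gap, max(abs(copies[[v]] - dst)))
      fit <- .kabsch_fit(ref, dst)
      copies[[v]] <- .apply_rigid(ref, fit)
    }
    if (abs(gap_prev - gap) < tol) break
    gap_prev <- gap
  }
  if (!is.finite(gap_prev)) stop("embedding failure: relaxation did not run")

  # merge copies: average per node class (faces become slightly deformed)
  coords <- matrix(0, topology$NN, 3)
  counts <- numeric(topology$NN)
  for (v in seq_len(N)) {
    ids <- fidx[v, ]
    coords[ids, ] <- coords[ids, ] + copies[[v]]
    counts[ids] <- counts[ids] + 1
  }
  coords <- coords / counts
  pcage_geometry(topology, coords)
}

#' Construct a p-cage geometry from a topology and node coordinates
#'
#' @param topology A `pcage_topology`.
#' @param coords NN x 3 numeric matrix of node positions.
#' @return An object of class `pcage_geometry`.
#' @export
pcage_geometry <- function(topology, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == topology$NN, ncol(coords) == 3)
  structure(list(topology = topology, coords = coords),
            class = "pcage_geometry")
}

#' @export
print.pcage_geometry <- function(x, ...) {
  m <- cage_metrics(x)
  cat(sprintf("<pcage_geometry> %s: NN=%d nodes, delta_l=%.3g delta_a=%.3g\n",
              x$topology$name, x$topology$NN, m$delta_l, m$delta_a))
  invisible(x)
}

# ---- per-face geometric quantities (reference implementations in R) -------

.face_nodes <- function(geometry, f) {
  geometry$coords[geometry$topology$faces[f, ], , drop = FALSE]
}

#' Geometric quantities of one face
#'
#' Corner angles, centre, facelet normals, area vector and unit normal of
#' face `f`, together with the cage centre.  The angle computed from edges
#' `s_i` and `s_(i+1)` is stored at position `(i %% P) + 1`.
#'
#' @param geometry A `pcage_geometry`.
#' @param f Face index.
#' @return A list with `angles` (length P, radians), `lengths`, `centre`,
#'   `cage_centre`, `facelet_normals` (P x 3), `area_vector`, `unit_normal`.
#' @export
face_geometry <- function(geometry, f) {
  pts <- .face_nodes(geometry, f)
  P <- nrow(pts)
  nxt <- c(2:P, 1)
  s <- pts[nxt, ] - pts
  len <- sqrt(rowSums(s^2))
  if (any(len == 0)) stop("degenerate edge in face ", f)
  cosang <- -rowSums(s * s[nxt, ]) / (len * len[nxt])
  cosang <- pmin(1, pmax(-1, cosang))
  ang_raw <- acos(cosang)       # angle from s_i, s_(i+1)
  angles <- ang_raw[c(P, 1:(P - 1))]  # stored at node (i+1) %% P
  angles <- ang_raw[]
  angles <- ang_raw
  angles <- angles[c(P, 1:(P - 1))]
  ctr <- colMeans(pts)
  nu <- sweep(pts, 2, ctr)
  w <- 0.5 * cbind(
    nu[, 2] * nu[nxt, 3] - nu[, 3] * nu[nxt, 2],
    nu[, 3] * nu[nxt, 1] - nu[, 1] * nu[nxt, 3],
    nu[, 1] * nu[nxt, 2] - nu[, 2] * nu[nxt, 1]
  )
  W <- colSums(w)
  Wn <- sqrt(sum(W^2))
  if (Wn == 0) stop("degenerate face ", f, ": zero area vector")
  list(angles = angles, lengths = len, centre = ctr,
       cage_centre = colMeans(geometry$coords),
       facelet_normals = w, area_vector = W, unit_normal = W / Wn)
}

#' Corner angles of one face
#'
#' @inheritParams face_geometry
#' @return Numeric vector of P corner angles in radians.
#' @export
face_angles <- function(geometry, f) face_geometry(geometry, f)$angles

#' Centre of the cage (mean of all nodes, each counted once)
#'
#' @param geometry A `pcage_geometry`.
#' @return Length-3 numeric vector.
#' @export
cage_centre <- function(geometry) colMeans(geometry$coords)
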