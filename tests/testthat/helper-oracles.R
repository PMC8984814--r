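# Shared helpers: brute-force enumeration oracle, independent geometric
# oracles, and small fixture builders.

# All ordered compositions of m into k positive parts.
compositions_of <- function(m, k) {
  if (k == 1L) return(matrix(m, 1, 1))
  if (m < k) return(matrix(integer(0), 0, k))
  do.call(rbind, lapply(seq_len(m - k + 1L), function(first) {
    cbind(first, compositions_of(m - first, k - 1L), deparse.level = 0)
  }))
}

# Exhaustive enumeration of connectivity-invariant labelings: every
# combination of per-vertex compositions is tested directly against the
# definition (label-preserving subgroup transitive on vertices), then
# reduced to one representative per rotation orbit.  Only feasible for the
# small solids; completely independent of the subgroup-orbit algorithm.
brute_force_labelings <- function(symbol, P) {
  solid <- build_solid(symbol)
  group <- rotation_group(solid)
  V <- solid$V; Eh <- solid$Eh
  comps <- compositions_of(P - Eh, Eh)
  nc <- nrow(comps)
  if (nc == 0) return(character(0))
  found <- new.env(parent = emptyenv())
  reps <- character(0)
  idx <- rep(1L, V)
  repeat {
    labels <- as.integer(t(comps[idx, , drop = FALSE]))
    key <- paste(labels, collapse = ",")
    if (is.null(found[[key]])) {
      stab <- which(vapply(seq_len(group$order), function(i) {
        all(labels[group$cperm[i, ]] == labels)
      }, TRUE))
      ok <- length(stab) > 0 &&
        length(unique(pcage:::.perm_orbits(group$vperm[stab, , drop = FALSE], V))) == 1L
      if (ok) {
        orbit <- vapply(seq_len(group$order), function(i) {
          paste(labels[group$cperm[i, ]], collapse = ",")
        }, "")
        for (k in unique(orbit)) found[[k]] <- "member"
        found[[key]] <- "rep"
        reps <- c(reps, min(orbit))
      } else {
        found[[key]] <- "no"
      }
    }
    # next combination
    pos <- 1L
    while (pos <= V) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= nc) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > V) break
  }
  sort(unique(reps))
}

# Canonical orbit key of a labeling (smallest label vector over the group).
orbit_key <- function(labels, group) {
  min(vapply(seq_len(group$order), function(i) {
    paste(labels[group$cperm[i, ]], collapse = ",")
  }, ""))
}

# Independent segment/triangle intersection oracle (sign tests + clipping),
# structured differently from the Moller interval test.
oracle_tri_tri <- function(t1, t2, eps = 1e-9) {
  seg_tri <- function(p, q, tri) {
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    dp <- sum(n * (p - tri[1, ])); dq <- sum(n * (q - tri[1, ]))
    if (abs(dp) < eps && abs(dq) < eps) {
      # coplanar segment: sample densely
      ts <- seq(0, 1, length.out = 41)
      return(any(vapply(ts, function(t) {
        point_in_tri(p + t * (q - p), tri, eps)
      }, TRUE)))
    }
    if (dp * dq > 0) return(FALSE)
    t <- dp / (dp - dq)
    x <- p + t * (q - p)
    point_in_tri(x, tri, eps)
  }
  point_in_tri <- function(x, tri, eps) {
    v0 <- tri[3, ] - tri[1, ]; v1 <- tri[2, ] - tri[1, ]; v2 <- x - tri[1, ]
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    if (abs(den) < 1e-14) return(FALSE)
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    u >= -eps && v >= -eps && u + v <= 1 + eps
  }
  pracma_cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  edges <- function(tt) list(tt[1:2, ], tt[2:3, ], tt[c(3, 1), ])
  for (e in edges(t1)) if (seg_tri(e[1, ], e[2, ], t2)) return(TRUE)
  for (e in edges(t2)) if (seg_tri(e[1, ], e[2, ], t1)) return(TRUE)
  FALSE
}

# Single-face geometry (no shared edges) from a P x 3 coordinate matrix.
single_face_geometry <- function(pts) {
  topo <- structure(list(
    symbol = NA_character_, name = "single", N = 1L, P = nrow(pts),
    NN = nrow(pts), E = 0L,
    faces = matrix(seq_len(nrow(pts)), 1),
    slot_kind = matrix("H", 1, nrow(pts)), slot_ref = NULL,
    shared_edges = matrix(integer(0), 0, 4,
                          dimnames = list(NULL, c("f1", "s1", "f2", "s2"))),
    holes = list()
  ), class = "pcage_topology")
  pcage_geometry(topo, pts)
}

# Two unit squares sharing an edge, folded by `dihedral` (pi = coplanar,
# < pi bends away from `centre_side`).
roof_geometry <- function(dihedral = pi * 0.8) {
  # shared edge along y axis from (0,0,0) to (0,1,0)
  a <- dihedral / 2
  # faces tilted symmetrically about the xz plane
  p1 <- rbind(c(0, 0, 0), c(0, 1, 0),
              c(-sin(a), 1, cos(a)), c(-sin(a), 0, cos(a)))
  p2 <- rbind(c(0, 1, 0), c(0, 0, 0),
              c(sin(a), 0, cos(a)), c(sin(a), 1, cos(a)))
  geometry_from_polygons(list(p1, p2))
}

regular_polygon <- function(P, L = 1) {
  r <- L / (2 * sin(pi / P))
  ang <- 2 * pi * (0:(P - 1)) / P
  cbind(r * cos(ang), r * sin(ang), 0)
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3))
}

apply_rigid <- function(coords, rm) {
  sweep(coords %*% t(rm$R), 2, rm$t, `+`)
}
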