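# Construction of the convex uniform solids used as hole-polyhedra.
#
# A hole-polyhedron is the dual of a p-cage: its vertices carry the p-cage
# faces, its edges the shared face edges, and its faces the holes.  The
# eligible solids are the vertex-transitive convex polyhedra whose vertex
# transitivity does not require a reflection: prisms and antiprisms, the
# Platonic solids, and 11 of the 13 Archimedean solids (the truncated
# cuboctahedron and truncated icosidodecahedron are excluded).

PHI <- (1 + sqrt(5)) / 2

.pcage_solid_table <- tibble::tribble(
  ~symbol, ~solid,                  ~family,
  "tp",    "triangular prism",      "prism",
  "pp",    "pentagonal prism",      "prism",
  "hp",    "hexagonal prism",       "prism",
  "7p",    "heptagonal prism",      "prism",
  "8p",    "octagonal prism",       "prism",
  "9p",    "nonagonal prism",       "prism",
  "10p",   "decagonal prism",       "prism",
  "ta",    "triangular antiprism",  "antiprism",
  "sa",    "square antiprism",      "antiprism",
  "pa",    "pentagonal antiprism",  "antiprism",
  "ha",    "hexagonal antiprism",   "antiprism",
  "7a",    "heptagonal antiprism",  "antiprism",
  "8a",    "octagonal antiprism",   "antiprism",
  "9a",    "nonagonal antiprism",   "antiprism",
  "10a",   "decagonal antiprism",   "antiprism",
  "Pte",   "tetrahedron",           "platonic",
  "Pcu",   "cube",                  "platonic",
  "Poc",   "octahedron",            "platonic",
  "Pdo",   "dodecahedron",          "platonic",
  "Pic",   "icosahedron",           "platonic",
  "Att",   "truncated tetrahedron", "archimedean",
  "Atc",   "truncated cube",        "archimedean",
  "Ato",   "truncated octahedron",  "archimedean",
  "Atd",   "truncated dodecahedron","archimedean",
  "Ati",   "truncated icosahedron", "archimedean",
  "Asc",   "snub cube",             "archimedean",
  "Asd",   "snub dodecahedron",     "archimedean",
  "Aco",   "cuboctahedron",         "archimedean",
  "Arco",  "rhombicuboctahedron",   "archimedean",
  "Arcd",  "rhombicosidodecahedron","archimedean",
  "Aid",   "icosidodecahedron",     "archimedean"
)

.excluded_solids <- c("Atco", "Atid")

#' Supported hole-polyhedra
#'
#' Lists the convex uniform solids that can act as the hole-polyhedron of a
#' connectivity-invariant p-cage, one row per solid symbol.
#'
#' @return A tibble with columns `symbol`, `solid`, `family`, and the counts
#'   `V`, `E`, `F`, `Eh` (vertices, edges, faces, vertex degree).
#' @export
#' @examples
#' pcage_solids()
pcage_solids <- function() {
  info <- purrr::map(.pcage_solid_table$symbol, function(s) {
    hp <- build_solid(s)
    tibble::tibble(V = hp$V, E = hp$E, F = hp$F, Eh = hp$Eh)
  })
  dplyr::bind_cols(.pcage_solid_table, dplyr::bind_rows(info))
}

# ---- geometric helpers -----------------------------------------------------

vnorm <- function(x) sqrt(sum(x^2))

unitize_rows <- function(m) m / sqrt(rowSums(m^2))

# Newell normal of a (possibly slightly non-planar) polygon.
newell_normal <- function(pts) {
  k <- nrow(pts)
  nxt <- c(2:k, 1)
  n <- c(
    sum((pts[, 2] - pts[nxt, 2]) * (pts[, 3] + pts[nxt, 3])),
    sum((pts[, 3] - pts[nxt, 3]) * (pts[, 1] + pts[nxt, 1])),
    sum((pts[, 1] - pts[nxt, 1]) * (pts[, 2] + pts[nxt, 2]))
  )
  n
}

# Orient every face anticlockwise as seen from outside a convex solid
# centred at the origin (outward Newell normal).
orient_faces_outward <- function(verts, faces) {
  lapply(faces, function(f) {
    n <- newell_normal(verts[f, , drop = FALSE])
    if (sum(n * colMeans(verts[f, , drop = FALSE])) < 0) rev(f) else f
  })
}

# Any unit vector -> a right-handed orthonormal tangent basis (e1, e2, n).
tangent_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / vnorm(e1)
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  cbind(e1, e2)
}

# Given face normals, pick for each normal the k closest vertices and order
# them anticlockwise; used for the Platonic solids.
faces_from_normals <- function(verts, normals, k) {
  lapply(seq_len(nrow(normals)), function(i) {
    n <- normals[i, ] / vnorm(normals[i, ])
    d <- drop(verts %*% n)
    sel <- order(d, decreasing = TRUE)[seq_len(k)]
    ctr <- colMeans(verts[sel, , drop = FALSE])
    rel <- sweep(verts[sel, , drop = FALSE], 2, ctr)
    B <- tangent_basis(n)
    uv <- rel %*% B
    sel[order(atan2(uv[, 2], uv[, 1]))]
  })
}

# ---- seed coordinate constructions ----------------------------------------

.platonic_raw <- function(symbol) {
  cyc <- function(m) rbind(m, m[, c(2, 3, 1)], m[, c(3, 1, 2)])
  signs <- function(base, pattern) {
    out <- NULL
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      v <- base * c(s1, s2, s3)
      out <- rbind(out, v)
    }
    unique(round(out, 12))
  }
  switch(symbol,
    Pte = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      list(verts = v, normals = -v, k = 3)
    },
    Pcu = {
      v <- signs(c(1, 1, 1))
      n <- rbind(diag(3), -diag(3))
      list(verts = v, normals = n, k = 4)
    },
    Poc = {
      v <- rbind(diag(3), -diag(3))
      n <- signs(c(1, 1, 1))
      list(verts = v, normals = n, k = 3)
    },
    Pdo = {
      v <- rbind(signs(c(1, 1, 1)), cyc(signs(c(0, 1 / PHI, PHI))))
      v <- unique(round(v, 10))
      n <- unique(round(cyc(signs(c(0, PHI, 1))), 10))
      list(verts = v, normals = n, k = 5)
    },
    Pic = {
      v <- unique(round(cyc(signs(c(0, 1, PHI))), 10))
      n <- unique(round(rbind(signs(c(1, 1, 1)), cyc(signs(c(1 / PHI, 0, PHI)))), 10))
      list(verts = v, normals = n, k = 3)
    }
  )
}

.build_platonic <- function(symbol) {
  raw <- .platonic_raw(symbol)
  verts <- unitize_rows(raw$verts)
  faces <- faces_from_normals(verts, raw$normals, raw$k)
  list(verts = verts, faces = orient_faces_outward(verts, faces), base_faces = integer(0))
}

.build_prism <- function(n) {
  # circumradius r and half-height h with square side faces, on the unit sphere
  r <- 1 / sqrt(1 + sin(pi / n)^2)
  h <- r * sin(pi / n)
  ang <- 2 * pi * (0:(n - 1)) / n
  top <- cbind(r * cos(ang), r * sin(ang), h)
  bot <- cbind(r * cos(ang), r * sin(ang), -h)
  verts <- rbind(top, bot)
  nxt <- c(2:n, 1)
  faces <- c(
    list(1:n, rev(n + (1:n))),
    lapply(1:n, function(i) c(i, n + i, n + nxt[i], nxt[i]))
  )
  list(verts = unitize_rows(verts),
       faces = orient_faces_outward(unitize_rows(verts), faces),
       base_faces = 1:2)
}

.build_antiprism <- function(n) {
  # half-height for equilateral side triangles: 4h^2 = edge^2 - 2r^2(1 - cos(pi/n))
  ang_t <- 2 * pi * (0:(n - 1)) / n
  ang_b <- ang_t + pi / n
  r <- 1
  edge <- 2 * r * sin(pi / n)
  h2 <- (edge^2 - 2 * r^2 * (1 - cos(pi / n))) / 4
  h <- sqrt(max(h2, 0.05))
  top <- cbind(r * cos(ang_t), r * sin(ang_t), h)
  bot <- cbind(r * cos(ang_b), r * sin(ang_b), -h)
  verts <- rbind(top, bot)
  nxt <- c(2:n, 1)
  tri1 <- lapply(1:n, function(i) c(i, n + i, nxt[i]))
  tri2 <- lapply(1:n, function(i) c(n + i, n + nxt[i], nxt[i]))
  faces <- c(list(1:n, rev(n + (1:n))), tri1, tri2)
  v <- unitize_rows(verts)
  list(verts = v, faces = orient_faces_outward(v, faces), base_faces = 1:2)
}

# ---- combinatorial operations on a seed solid ------------------------------

# Faces of each vertex ordered anticlockwise from outside, plus the incident
# edge between consecutive faces of the cycle (edge i lies between faces
# i-1 and i of the cycle).
.seed_incidence <- function(verts, faces) {
  V <- nrow(verts)
  fctr <- do.call(rbind, lapply(faces, function(f) colMeans(verts[f, , drop = FALSE])))
  vface <- vector("list", V)
  for (fi in seq_along(faces)) for (v in faces[[fi]]) vface[[v]] <- c(vface[[v]], fi)
  cycles <- vector("list", V)
  for (v in seq_len(V)) {
    fs <- vface[[v]]
    dir <- verts[v, ]
    B <- tangent_basis(dir / vnorm(dir))
    rel <- sweep(fctr[fs, , drop = FALSE], 2, verts[v, ]) %*% B
    cycles[[v]] <- fs[order(atan2(rel[, 2], rel[, 1]))]
  }
  cycles
}

.op_truncate <- function(seed, t = 1/3) {
  verts <- seed$verts; faces <- seed$faces
  # new vertex for each (vertex, directed-edge-neighbour) pair
  key <- new.env(parent = emptyenv())
  coords <- list(); cnt <- 0L
  vid <- function(v, u) {
    k <- paste(v, u)
    if (is.null(key[[k]])) {
      cnt <<- cnt + 1L
      key[[k]] <- cnt
      coords[[cnt]] <<- (1 - t) * verts[v, ] + t * verts[u, ]
    }
    key[[k]]
  }
  newfaces <- list()
  for (f in faces) {
    k <- length(f); nxt <- c(2:k, 1)
    cyc <- integer(0)
    for (i in seq_len(k)) {
      v <- f[i]; u <- f[nxt[i]]
      cyc <- c(cyc, vid(v, u), vid(u, v))
    }
    newfaces[[length(newfaces) + 1L]] <- cyc
  }
  cycles <- .seed_incidence(verts, faces)
  # vertex figure: neighbours of v ordered anticlockwise
  nbr <- .vertex_neighbours_acw(verts, faces)
  for (v in seq_len(nrow(verts))) {
    newfaces[[length(newfaces) + 1L]] <- vapply(nbr[[v]], function(u) vid(v, u), 1L)
  }
  vm <- do.call(rbind, coords)
  list(verts = unitize_rows(vm), faces = orient_faces_outward(unitize_rows(vm), newfaces),
       base_faces = integer(0))
}

# Neighbours of each vertex ordered anticlockwise from outside.
.vertex_neighbours_acw <- function(verts, faces) {
  V <- nrow(verts)
  nb <- vector("list", V)
  for (f in faces) {
    k <- length(f); nxt <- c(2:k, 1)
    for (i in seq_len(k)) nb[[f[i]]] <- union(nb[[f[i]]], c(f[nxt[i]], f[c(k, 1:(k - 1))[i]]))
  }
  for (v in seq_len(V)) {
    us <- nb[[v]]
    dir <- verts[v, ] / vnorm(verts[v, ])
    B <- tangent_basis(dir)
    rel <- sweep(verts[us, , drop = FALSE], 2, verts[v, ]) %*% B
    nb[[v]] <- us[order(atan2(rel[, 2], rel[, 1]))]
  }
  nb
}

.op_rectify <- function(seed) {
  verts <- seed$verts; faces <- seed$faces
  ekey <- new.env(parent = emptyenv()); coords <- list(); cnt <- 0L
  eid <- function(u, v) {
    k <- paste(min(u, v), max(u, v))
    if (is.null(ekey[[k]])) {
      cnt <<- cnt + 1L; ekey[[k]] <- cnt
      coords[[cnt]] <<- (verts[u, ] + verts[v, ]) / 2
    }
    ekey[[k]]
  }
  newfaces <- list()
  for (f in faces) {
    k <- length(f); nxt <- c(2:k, 1)
    newfaces[[length(newfaces) + 1L]] <-
      vapply(seq_len(k), function(i) eid(f[i], f[nxt[i]]), 1L)
  }
  nbr <- .vertex_neighbours_acw(verts, faces)
  for (v in seq_len(nrow(verts))) {
    newfaces[[length(newfaces) + 1L]] <- vapply(nbr[[v]], function(u) eid(v, u), 1L)
  }
  vm <- unitize_rows(do.call(rbind, coords))
  list(verts = vm, faces = orient_faces_outward(vm, newfaces), base_faces = integer(0))
}

# Cantellation (expansion): one new vertex per (vertex, face) flag.
# With `snub = TRUE` the edge squares are split into two triangles along a
# fixed diagonal, giving one chirality of the snub solid.
.op_cantellate <- function(seed, snub = FALSE, rho = 0.55, twist = 0.25) {
  verts <- seed$verts; faces <- seed$faces
  fctr <- do.call(rbind, lapply(faces, function(f) colMeans(verts[f, , drop = FALSE])))
  key <- new.env(parent = emptyenv()); coords <- list(); cnt <- 0L
  fid <- function(v, f) {
    k <- paste(v, f)
    if (is.null(key[[k]])) {
      cnt <<- cnt + 1L; key[[k]] <- cnt
      c0 <- fctr[f, ] / vnorm(fctr[f, ])
      rel <- verts[v, ] - sum(verts[v, ] * c0) * c0
      if (snub) {
        # rotate rel about the face normal by `twist`
        e1 <- rel / vnorm(rel)
        e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
                c0[3] * e1[1] - c0[1] * e1[3],
                c0[1] * e1[2] - c0[2] * e1[1])
        rel <- vnorm(rel) * (cos(twist) * e1 + sin(twist) * e2)
      }
      coords[[cnt]] <<- c0 + rho * rel
    }
    key[[k]]
  }
  newfaces <- list()
  for (f0 in seq_along(faces)) {
    f <- faces[[f0]]
    newfaces[[length(newfaces) + 1L]] <- vapply(f, function(v) fid(v, f0), 1L)
  }
  cycles <- .seed_incidence(verts, faces)
  for (v in seq_len(nrow(verts))) {
    newfaces[[length(newfaces) + 1L]] <- vapply(cycles[[v]], function(f0) fid(v, f0), 1L)
  }
  # directed edge u->v with face f on its left; g the face on the right
  left <- new.env(parent = emptyenv())
  for (f0 in seq_along(faces)) {
    f <- faces[[f0]]; k <- length(f); nxt <- c(2:k, 1)
    for (i in seq_len(k)) left[[paste(f[i], f[nxt[i]])]] <- f0
  }
  done <- new.env(parent = emptyenv())
  for (f0 in seq_along(faces)) {
    f <- faces[[f0]]; k <- length(f); nxt <- c(2:k, 1)
    for (i in seq_len(k)) {
      u <- f[i]; v <- f[nxt[i]]
      ek <- paste(min(u, v), max(u, v))
      if (!is.null(done[[ek]])) next
      done[[ek]] <- TRUE
      fl <- left[[paste(u, v)]]; fr <- left[[paste(v, u)]]
      quad <- c(fid(u, fl), fid(v, fl), fid(v, fr), fid(u, fr))
      if (snub) {
        newfaces[[length(newfaces) + 1L]] <- quad[c(1, 2, 4)]
        newfaces[[length(newfaces) + 1L]] <- quad[c(2, 3, 4)]
      } else {
        newfaces[[length(newfaces) + 1L]] <- quad
      }
    }
  }
  vm <- unitize_rows(do.call(rbind, coords))
  list(verts = vm, faces = orient_faces_outward(vm, newfaces), base_faces = integer(0))
}

# ---- assembly and validation ----------------------------------------------

.finish_solid <- function(symbol, raw, family, name) {
  verts <- unitize_rows(raw$verts)
  dimnames(verts) <- NULL
  faces <- raw$faces
  V <- nrow(verts); F <- length(faces)
  ekey <- new.env(parent = emptyenv()); edges <- list()
  for (f in faces) {
    k <- length(f); nxt <- c(2:k, 1)
    for (i in seq_len(k)) {
      u <- f[i]; v <- f[nxt[i]]
      kk <- paste(min(u, v), max(u, v))
      if (is.null(ekey[[kk]])) {
        edges[[length(edges) + 1L]] <- c(min(u, v), max(u, v))
        ekey[[kk]] <- length(edges)
      }
    }
  }
  edges <- do.call(rbind, edges)
  E <- nrow(edges)
  deg <- tabulate(c(edges), V)
  if (length(unique(deg)) != 1L)
    stop("solid is not regular-degree; construction error for ", symbol)
  Eh <- deg[1]
  cycles <- .seed_incidence(verts, faces)
  # edge between consecutive faces of each vertex cycle
  eid_of <- function(u, v) ekey[[paste(min(u, v), max(u, v))]]
  edge_cycles <- vector("list", V)
  for (v in seq_len(V)) {
    fs <- cycles[[v]]
    m <- length(fs)
    ec <- integer(m)
    for (i in seq_len(m)) {
      fprev <- faces[[fs[[if (i == 1) m else i - 1]]]]
      fcur <- faces[[fs[[i]]]]
      shared <- intersect(fprev, fcur)
      shared <- shared[shared != v]
      cand <- shared[vapply(shared, function(u) !is.null(ekey[[paste(min(u, v), max(u, v))]]), TRUE)]
      if (length(cand) != 1L)
        stop("vertex cycle inconsistency at vertex ", v, " of ", symbol)
      ec[i] <- eid_of(v, cand)
    }
    edge_cycles[[v]] <- ec
  }
  solid <- structure(list(
    symbol = symbol, solid = name, family = family,
    vertices = verts, faces = faces, edges = edges,
    V = V, E = E, F = F, Eh = Eh,
    vertex_cycles = cycles, edge_cycles = edge_cycles,
    base_faces = raw$base_faces
  ), class = "pcage_solid")
  solid$a_faces <- .a_face_class(solid)
  solid
}

# Faces eligible to carry the first label 'a' of a corner labeling:
# the base polygons for (anti)prisms, the smallest faces for Archimedean
# solids (square for the snub cube, pentagon for the snub dodecahedron),
# any face for the Platonic solids.
.a_face_class <- function(solid) {
  sizes <- lengths(solid$faces)
  switch(solid$family,
    prism = solid$base_faces,
    antiprism = solid$base_faces,
    platonic = seq_len(solid$F),
    archimedean = {
      target <- switch(solid$symbol, Asc = 4L, Asd = 5L, min(sizes))
      which(sizes == target)
    }
  )
}

.solid_cache <- new.env(parent = emptyenv())

#' Build a hole-polyhedron
#'
#' Constructs one of the supported convex uniform solids as an oriented
#' combinatorial polyhedron with unit-circumsphere coordinates.  Faces are
#' stored as cyclic vertex lists running anticlockwise seen from outside,
#' and each vertex carries the anticlockwise cyclic order of its incident
#' faces (its corners).
#'
#' @param symbol Solid symbol, e.g. `"Pic"` (icosahedron), `"Asc"` (snub
#'   cube), `"7p"` (heptagonal prism), `"ta"` (triangular antiprism).  See
#'   [pcage_solids()] for the full table.
#' @return An object of class `pcage_solid`.
#' @export
#' @examples
#' hp <- build_solid("Pic")
#' c(hp$V, hp$E, hp$F, hp$Eh)
build_solid <- function(symbol) {
  if (symbol %in% .excluded_solids)
    stop("reflection-only vertex transitivity: '", symbol,
         "' cannot generate connectivity-invariant p-cages", call. = FALSE)
  row <- .pcage_solid_table[.pcage_solid_table$symbol == symbol, ]
  if (nrow(row) == 0L)
    stop("unsupported solid: '", symbol, "'", call. = FALSE)
  if (!is.null(.solid_cache[[symbol]])) return(.solid_cache[[symbol]])
  family <- row$family
  raw <- switch(family,
    prism = .build_prism(.prism_n(symbol)),
    antiprism = .build_antiprism(.prism_n(symbol)),
    platonic = .build_platonic(symbol),
    archimedean = switch(symbol,
      Att = .op_truncate(.build_platonic("Pte")),
      Atc = .op_truncate(.build_platonic("Pcu")),
      Ato = .op_truncate(.build_platonic("Poc")),
      Atd = .op_truncate(.build_platonic("Pdo")),
      Ati = .op_truncate(.build_platonic("Pic")),
      Aco = .op_rectify(.build_platonic("Pcu")),
      Aid = .op_rectify(.build_platonic("Pic")),
      Arco = .op_cantellate(.build_platonic("Pcu")),
      Arcd = .op_cantellate(.build_platonic("Pdo")),
      Asc = .op_cantellate(.build_platonic("Pcu"), snub = TRUE),
      Asd = .op_cantellate(.build_platonic("Pdo"), snub = TRUE)
    )
  )
  out <- .finish_solid(symbol, raw, family, row$solid)
  .solid_cache[[symbol]] <- out
  out
}

.prism_n <- function(symbol) {
  base <- sub("[pa]$", "", symbol)
  switch(base, t = 3L, s = 4L, p = 5L, h = 6L, as.integer(base))
}

#' @export
print.pcage_solid <- function(x, ...) {
  cat(sprintf("<pcage_solid> %s (%s): V=%d E=%d F=%d Eh=%d\n",
              x$symbol, x$solid, x$V, x$E, x$F, x$Eh))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hole-polyhedron
#'
#' @param x A `pcage_solid`.
#' @param ... Unused.
#' @return A tibble with one row per face: face id, size, and vertex cycle.
#' @method tidy pcage_solid
#' @export
tidy.pcage_solid <- function(x, ...) {
  tibble::tibble(
    symbol = x$symbol,
    face = seq_len(x$F),
    size = lengths(x$faces),
    vertices = lapply(x$faces, identity)
  )
}

# ---- combinatorial automorphisms ------------------------------------------

# Rotation-system representation: one directed edge per (face, position).
.rotation_system <- function(solid) {
  from <- integer(0); to <- integer(0); fc <- integer(0)
  for (fi in seq_along(solid$faces)) {
    f <- solid$faces[[fi]]
    k <- length(f); nxt <- c(2:k, 1)
    from <- c(from, f); to <- c(to, f[nxt]); fc <- c(fc, rep(fi, k))
  }
  nd <- length(from)
  key <- paste(from, to)
  idx <- seq_len(nd)
  names(idx) <- key
  if (anyDuplicated(key))
    stop("inconsistent face orientation: some directed edge appears twice")
  nxt <- integer(nd); prv <- integer(nd); rv <- integer(nd)
  pos <- 0L
  for (fi in seq_along(solid$faces)) {
    k <- length(solid$faces[[fi]])
    ids <- pos + seq_len(k)
    nxt[ids] <- pos + c(2:k, 1)
    prv[ids] <- pos + c(k, 1:(k - 1))
    pos <- pos + k
  }
  rv <- unname(idx[paste(to, from)])
  if (anyNA(rv))
    stop("open surface: some edge lacks its reverse")
  list(from = from, to = to, face = fc, nxt = nxt, prv = prv, rev = rv, n = nd)
}

# Try to extend the flag map d0 -> img to a full automorphism.
.propagate_map <- function(rs, img, reversing) {
  m <- integer(rs$n)
  m[1L] <- img
  stack <- 1L
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    y <- m[x]
    steps <- if (!reversing) {
      list(c(rs$nxt[x], rs$nxt[y]), c(rs$rev[x], rs$rev[y]))
    } else {
      # a reflection maps the left face of u->v to the right face of its
      # image, so the in-face successor maps through the reversed cycle
      list(c(rs$nxt[x], rs$rev[rs$prv[rs$rev[y]]]), c(rs$rev[x], rs$rev[y]))
    }
    for (s in steps) {
      a <- s[1]; b <- s[2]
      if (m[a] == 0L) {
        m[a] <- b
        stack <- c(stack, a)
      } else if (m[a] != b) return(NULL)
    }
  }
  if (anyDuplicated(m)) return(NULL)
  m
}

.derive_perms <- function(solid, rs, m, reversing) {
  V <- solid$V
  vperm <- integer(V)
  vp <- rs$from[m]
  ok <- TRUE
  for (i in seq_len(rs$n)) {
    v <- rs$from[i]
    if (vperm[v] == 0L) vperm[v] <- vp[i]
    else if (vperm[v] != vp[i]) { ok <- FALSE; break }
  }
  if (!ok || anyDuplicated(vperm)) return(NULL)
  fperm <- integer(solid$F)
  fp <- if (reversing) rs$face[rs$rev[m]] else rs$face[m]
  for (i in seq_len(rs$n)) {
    f <- rs$face[i]
    if (fperm[f] == 0L) fperm[f] <- fp[i]
    else if (fperm[f] != fp[i]) { ok <- FALSE; break }
  }
  if (!ok || anyDuplicated(fperm)) return(NULL)
  list(vperm = vperm, fperm = fperm)
}

# Corner ids: corner (v, i) = i-th face of vertex v's anticlockwise cycle,
# numbered (v-1)*Eh + i.
.corner_index <- function(solid) {
  ci <- matrix(NA_integer_, solid$V, solid$F)
  for (v in seq_len(solid$V)) {
    fs <- solid$vertex_cycles[[v]]
    ci[v, fs] <- (v - 1L) * solid$Eh + seq_along(fs)
  }
  ci
}

.automorphisms <- function(solid, include_reversing) {
  rs <- .rotation_system(solid)
  vperms <- list(); fperms <- list(); revflag <- logical(0)
  for (reversing in if (include_reversing) c(FALSE, TRUE) else FALSE) {
    for (img in seq_len(rs$n)) {
      m <- .propagate_map(rs, img, reversing)
      if (is.null(m)) next
      p <- .derive_perms(solid, rs, m, reversing)
      if (is.null(p)) next
      vperms[[length(vperms) + 1L]] <- p$vperm
      fperms[[length(fperms) + 1L]] <- p$fperm
      revflag <- c(revflag, reversing)
    }
  }
  vperm <- do.call(rbind, vperms)
  fperm <- do.call(rbind, fperms)
  # prisms and antiprisms use their dihedral symmetry convention: keep only
  # automorphisms preserving the pair of base faces (this restricts the
  # triangular antiprism to the antiprism group rather than the full
  # octahedral group it is combinatorially entitled to)
  if (solid$family %in% c("prism", "antiprism")) {
    keep <- vapply(seq_len(nrow(vperm)), function(i)
      setequal(fperm[i, solid$base_faces], solid$base_faces), TRUE)
    vperm <- vperm[keep, , drop = FALSE]
    fperm <- fperm[keep, , drop = FALSE]
    revflag <- revflag[keep]
  }
  ci <- .corner_index(solid)
  C <- solid$V * solid$Eh
  cperm <- matrix(NA_integer_, nrow(vperm), C)
  cv <- rep(seq_len(solid$V), each = solid$Eh)
  cf <- unlist(solid$vertex_cycles)
  for (i in seq_len(nrow(vperm))) {
    cperm[i, ] <- ci[cbind(vperm[i, cv], fperm[i, cf])]
  }
  structure(list(
    symbol = solid$symbol,
    order = nrow(vperm),
    vperm = vperm, fperm = fperm, cperm = cperm,
    reversing = revflag,
    corner_vertex = cv, corner_face = cf
  ), class = "pcage_group")
}

.group_cache <- new.env(parent = emptyenv())

#' Rotation group of a hole-polyhedron
#'
#' Computes the group of orientation-preserving combinatorial automorphisms
#' of the solid (reflections are excluded, as connectivity invariance via a
#' reflection is not considered).  Elements act on vertices, faces, and
#' corners, where a corner is an ordered (vertex, incident face) pair.
#'
#' For prisms and antiprisms the group is the dihedral rotation group of
#' order 2n that preserves the base-face pair; in particular the triangular
#' antiprism `"ta"` keeps its antiprism convention (order 6) rather than the
#' octahedral symmetry of its graph.
#'
#' @param solid A `pcage_solid` from [build_solid()].
#' @return An object of class `pcage_group` with fields `order`, `vperm`,
#'   `fperm`, `cperm` (one permutation per row) and `reversing` (all `FALSE`).
#' @export
#' @examples
#' rotation_group(build_solid("Pte"))$order  # 12
rotation_group <- function(solid) {
  key <- paste0(solid$symbol, "_rot")
  if (!is.null(.group_cache[[key]])) return(.group_cache[[key]])
  g <- full_automorphisms(solid)
  keep <- !g$reversing
  out <- structure(list(
    symbol = g$symbol, order = sum(keep),
    vperm = g$vperm[keep, , drop = FALSE],
    fperm = g$fperm[keep, , drop = FALSE],
    cperm = g$cperm[keep, , drop = FALSE],
    reversing = g$reversing[keep],
    corner_vertex = g$corner_vertex, corner_face = g$corner_face
  ), class = "pcage_group")
  .group_cache[[key]] <- out
  out
}

#' Full automorphism group, including orientation-reversing elements
#'
#' Like [rotation_group()] but also returns the combinatorial reflections,
#' flagged in the `reversing` field.  Used to identify chiral pairs of
#' corner labelings.
#'
#' @inheritParams rotation_group
#' @return A `pcage_group`; `reversing` marks orientation-reversing elements.
#' @export
full_automorphisms <- function(solid) {
  key <- paste0(solid$symbol, "_full")
  if (!is.null(.group_cache[[key]])) return(.group_cache[[key]])
  out <- .automorphisms(solid, include_reversing = TRUE)
  .group_cache[[key]] <- out
  out
}

#' @export
print.pcage_group <- function(x, ...) {
  cat(sprintf("<pcage_group> %s: order %d (%d orientation-reversing)\n",
              x$symbol, x$order, sum(x$reversing)))
  invisible(x)
}

# Orbits of a set of permutations (rows of `perm`) on 1..n.
.perm_orbits <- function(perm, n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(perm))) {
    for (i in seq_len(n)) {
      a <- find(i); b <- find(perm[r, i])
      if (a != b) parent[a] <- b
    }
  }
  as.integer(vapply(seq_len(n), find, numeric(1)))
}

# Is the group (or subgroup given by element rows) transitive on vertices?
.vertex_transitive <- function(group, rows = seq_len(group$order)) {
  orb <- .perm_orbits(group$vperm[rows, , drop = FALSE], ncol(group$vperm))
  length(unique(orb)) == 1L
}
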