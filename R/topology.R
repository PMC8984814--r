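# From a corner labeling to the p-cage incidence structure.
#
# Each hole-polyhedron vertex carries one P-gonal face of the p-cage.  Going
# anticlockwise around the vertex, the face alternates an edge shared with
# the neighbour face across each incident solid edge with a run of a_i hole
# edges on the hole behind each incident solid face.  Nodes (face vertices)
# shared between two faces are identified, giving NN = N*P - 2*E distinct
# nodes; the leftover free edges trace out one boundary cycle per solid face,
# the holes.

#' Build the p-cage topology for a corner labeling
#'
#' @param labeling A labeling (one-row slice of a `pcage_labelings` tibble,
#'   or a list with `symbol`, `P`, `labels`).
#' @param solid Optional pre-built `pcage_solid`.
#' @return An object of class `pcage_topology`: fields `symbol`, `name`, `N`,
#'   `P`, `NN`, `faces` (N x P matrix of node ids, each row anticlockwise
#'   seen from outside), `slot_kind` (N x P, `"S"` shared / `"H"` hole),
#'   `shared_edges` (matrix with columns `f1, s1, f2, s2`, one row per shared
#'   edge), and `holes` (list with `face`, `Q`, `q`, `nodes` per hole).
#' @export
#' @examples
#' lab <- enumerate_distributions("Pic", 10)
#' topo <- build_topology(lab[1, ])
#' c(topo$N, topo$NN, length(topo$holes))
build_topology <- function(labeling, solid = NULL) {
  lab <- .as_labeling(labeling)
  if (is.null(solid)) solid <- build_solid(lab$symbol)
  P <- as.integer(lab$P)
  labels <- lab$labels
  Eh <- solid$Eh
  N <- solid$V
  stopifnot(length(labels) == N * Eh, all(labels >= 1L))

  slot_kind <- matrix("", N, P)
  slot_ref <- matrix(NA_integer_, N, P)  # solid edge id (shared) or face id (hole)
  for (v in seq_len(N)) {
    fs <- solid$vertex_cycles[[v]]
    ec <- solid$edge_cycles[[v]]
    j <- 0L
    for (i in seq_len(Eh)) {
      j <- j + 1L
      slot_kind[v, j] <- "S"; slot_ref[v, j] <- ec[i]
      ai <- labels[(v - 1L) * Eh + i]
      for (k in seq_len(ai)) {
        j <- j + 1L
        slot_kind[v, j] <- "H"; slot_ref[v, j] <- fs[i]
      }
    }
    if (j != P) stop("labeling does not satisfy Eh + sum(a_i) = P at vertex ", v)
  }

  # union-find over face-slot node copies
  nid <- function(f, j) (f - 1L) * P + ((j - 1L) %% P) + 1L
  parent <- seq_len(N * P)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  # locate the shared slot of each face for every solid edge
  edge_slots <- vector("list", solid$E)
  for (v in seq_len(N)) for (j in seq_len(P)) {
    if (slot_kind[v, j] == "S") {
      e <- slot_ref[v, j]
      edge_slots[[e]] <- rbind(edge_slots[[e]], c(v, j))
    }
  }
  shared <- NULL
  for (e in seq_len(solid$E)) {
    es <- edge_slots[[e]]
    if (is.null(es) || nrow(es) != 2L)
      stop("non-orientable assembly: solid edge ", e, " not shared by two faces")
    f1 <- es[1, 1]; s1 <- es[1, 2]; f2 <- es[2, 1]; s2 <- es[2, 2]
    # the two faces traverse the shared edge in opposite directions
    unite(nid(f1, s1), nid(f2, s2 + 1L))
    unite(nid(f1, s1 + 1L), nid(f2, s2))
    shared <- rbind(shared, c(f1, s1, f2, s2))
  }
  roots <- vapply(seq_len(N * P), find, numeric(1))
  node_id <- match(roots, unique(roots))
  NN <- length(unique(roots))
  if (NN != N * P - 2L * solid$E)
    stop("node count mismatch: got ", NN, ", expected ", N * P - 2L * solid$E)
  faces <- matrix(node_id, N, P, byrow = TRUE)

  # hole boundaries: trace the free (hole) slots of each solid face
  holes <- vector("list", solid$F)
  for (fi in seq_len(solid$F)) {
    idx <- which(slot_kind == "H" & slot_ref == fi)  # column-major index
    vs <- ((idx - 1L) %% N) + 1L
    js <- ((idx - 1L) %/% N) + 1L
    starts <- faces[cbind(vs, js)]
    ends <- faces[cbind(vs, (js %% P) + 1L)]
    m <- length(starts)
    nxt <- match(ends, starts)
    if (anyNA(nxt)) stop("hole boundary of solid face ", fi, " does not close")
    cyc <- integer(m); cur <- 1L
    for (k in seq_len(m)) {
      cyc[k] <- cur
      cur <- nxt[cur]
    }
    if (cur != 1L || anyDuplicated(cyc))
      stop("hole boundary of solid face ", fi, " is not a single cycle")
    ci <- .corner_index(solid)
    q <- unname(labels[ci[cbind(solid$faces[[fi]], fi)]])
    holes[[fi]] <- list(face = fi, Q = length(solid$faces[[fi]]), q = q,
                        nodes = starts[cyc])
  }

  structure(list(
    symbol = lab$symbol,
    name = if (!is.null(lab$name)) lab$name else canonical_name(lab),
    N = N, P = P, NN = NN, E = solid$E,
    faces = faces, slot_kind = slot_kind, slot_ref = slot_ref,
    shared_edges = `colnames<-`(shared, c("f1", "s1", "f2", "s2")),
    holes = holes
  ), class = "pcage_topology")
}

#' @export
print.pcage_topology <- function(x, ...) {
  qlen <- table(vapply(x$holes, function(h) sum(h$q), 1))
  cat(sprintf("<pcage_topology> %s: N=%d faces of P=%d edges, NN=%d nodes, %d holes (%s)\n",
              x$name, x$N, x$P, x$NN, length(x$holes),
              paste(names(qlen), qlen, sep = "-edge x", collapse = ", ")))
  invisible(x)
}

#' Tidy a p-cage topology
#'
#' @param x A `pcage_topology`.
#' @param ... Unused.
#' @return A tibble with one row per hole: hole id, `Q`, `q`, boundary length.
#' @method tidy pcage_topology
#' @export
tidy.pcage_topology <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    hole = seq_along(x$holes),
    Q = vapply(x$holes, `[[`, 1L, "Q"),
    q = lapply(x$holes, `[[`, "q"),
    boundary = vapply(x$holes, function(h) length(h$nodes), 1L)
  )
}
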