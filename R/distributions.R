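# Enumeration of connectivity-invariant hole-edge distributions.
#
# A corner labeling assigns to every (vertex, incident-face) corner of the
# hole-polyhedron the number a_i >= 1 of edges the p-cage face at that vertex
# contributes to the hole behind that corner, with Eh + sum(a_i) = P at every
# vertex.  The labeling is connectivity-invariant when the subgroup of the
# rotation group that preserves it is still transitive on vertices.  Such a
# labeling is exactly one that is constant on the corner orbits of some
# vertex-transitive subgroup, which is how the enumeration proceeds.

# ---- group algebra ---------------------------------------------------------

.perm_key <- function(p) paste(p, collapse = ",")

# Multiplication table of a pcage_group: mt[i, j] = index of g_i o g_j.
.group_mult_table <- function(group) {
  n <- group$order
  keys <- apply(group$vperm, 1, .perm_key)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(n)) lookup[[keys[i]]] <- i
  mt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    gi <- group$vperm[i, ]
    for (j in seq_len(n)) {
      mt[i, j] <- lookup[[.perm_key(gi[group$vperm[j, ]])]]
    }
  }
  if (anyNA(mt)) stop("group not closed under composition")
  mt
}

.subgroup_closure <- function(mt, gens) {
  elems <- sort(unique(c(.group_identity(mt), gens)))
  repeat {
    prod <- unique(as.vector(mt[elems, elems]))
    new <- union(elems, prod)
    if (length(new) == length(elems)) return(sort(elems))
    elems <- sort(new)
  }
}

.group_identity <- function(mt) {
  n <- nrow(mt)
  for (i in seq_len(n)) if (all(mt[i, ] == seq_len(n))) return(i)
  stop("no identity element")
}

# All subgroups of the group, as sorted element-index vectors.
.all_subgroups <- function(mt) {
  n <- nrow(mt)
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(s) {
    k <- .perm_key(s)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      out[[length(out) + 1L]] <<- s
      TRUE
    } else FALSE
  }
  queue <- list()
  add(.subgroup_closure(mt, integer(0)))
  for (x in seq_len(n)) {
    s <- .subgroup_closure(mt, x)
    if (add(s)) queue[[length(queue) + 1L]] <- s
  }
  while (length(queue)) {
    s <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    if (length(s) == n) next
    for (x in setdiff(seq_len(n), s)) {
      t <- .subgroup_closure(mt, c(s, x))
      if (add(t)) queue[[length(queue) + 1L]] <- t
    }
  }
  out
}

.subgroup_cache <- new.env(parent = emptyenv())

# Vertex-transitive subgroups of the rotation group of a solid.
.vertex_transitive_subgroups <- function(solid, group) {
  key <- solid$symbol
  if (!is.null(.subgroup_cache[[key]])) return(.subgroup_cache[[key]])
  mt <- .group_mult_table(group)
  subs <- .all_subgroups(mt)
  keep <- purrr::keep(subs, function(s) {
    length(s) >= solid$V && .vertex_transitive(group, s)
  })
  .subgroup_cache[[key]] <- keep
  keep
}

# ---- labelings -------------------------------------------------------------

# All compositions of m into k ordered positive parts (rows).
.compositions <- function(m, k) {
  if (k == 1L) return(matrix(m, 1, 1))
  if (m < k) return(matrix(integer(0), 0, k))
  out <- list()
  for (first in seq_len(m - k + 1L)) {
    rest <- .compositions(m - first, k - 1L)
    out[[first]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

.labeling_obj <- function(solid, P, labels) {
  list(symbol = solid$symbol, P = P, labels = as.integer(labels))
}

#' Test connectivity invariance of a corner labeling
#'
#' A labeling is connectivity-invariant when the subgroup of rotations that
#' preserves every corner label still maps any vertex onto any other, so that
#' all p-cage faces are indistinguishable from their connectivity.
#'
#' @param labeling A labeling as produced by [enumerate_distributions()] (a
#'   list with fields `symbol`, `P`, `labels`, the labels indexed by corner
#'   id), or a bare integer vector of corner labels.
#' @param group The solid's [rotation_group()].
#' @param solid The `pcage_solid`; required when `labeling` is a bare vector.
#' @return `TRUE` or `FALSE`.
#' @export
is_connectivity_invariant <- function(labeling, group, solid = NULL) {
  if (is.numeric(labeling)) labeling <- list(labels = as.integer(labeling))
  labels <- labeling$labels
  if (is.null(solid)) solid <- build_solid(group$symbol)
  C <- solid$V * solid$Eh
  if (length(labels) != C)
    stop("invalid labeling: expected one label per corner (", C, ")")
  if (any(labels < 1L))
    stop("invalid labeling: all corner labels must be >= 1")
  sums <- rowSums(matrix(labels, solid$V, solid$Eh, byrow = TRUE))
  if (length(unique(sums)) != 1L)
    stop("invalid labeling: vertex sums of labels differ between vertices")
  stab <- which(vapply(seq_len(group$order), function(i) {
    all(labels[group$cperm[i, ]] == labels)
  }, TRUE))
  if (length(stab) == 0L) return(FALSE)
  orb <- .perm_orbits(group$vperm[stab, , drop = FALSE], solid$V)
  length(unique(orb)) == 1L
}

# The q-list of every hole (solid face): labels of corners (v, F) around F.
.hole_q_lists <- function(solid, labels) {
  ci <- .corner_index(solid)
  lapply(seq_len(solid$F), function(fi) {
    vs <- solid$faces[[fi]]
    unname(labels[ci[cbind(vs, fi)]])
  })
}

#' Enumerate connectivity-invariant hole-edge distributions
#'
#' Finds every connectivity-invariant assignment of hole-edge counts to the
#' corners of a hole-polyhedron for faces with `P` edges, up to rotations of
#' the solid.  A labeling is found by scanning the vertex-transitive
#' subgroups of the rotation group: any labeling constant on the corner
#' orbits of such a subgroup (with per-vertex sums `P - Eh` and positive
#' entries) is connectivity-invariant, and every connectivity-invariant
#' labeling arises this way from its own stabilizer.
#'
#' Mirror-image pairs are retained; remove them with [dedup_chiral()].
#'
#' @param solid A `pcage_solid` or a solid symbol.
#' @param P Number of edges of each p-cage face (the study range is 6--17).
#' @param group Optional precomputed [rotation_group()].
#' @return A tibble of class `pcage_labelings` with one row per labeling:
#'   `symbol`, `P`, `name`, `labels` (list of per-corner integer vectors),
#'   `vertex_labels` (labels around vertex 1, anticlockwise), and `holes`
#'   (list of per-hole q-vectors indexed by solid face).
#' @export
#' @examples
#' enumerate_distributions("Pdo", 9)$name  # the single all-2 labeling
enumerate_distributions <- function(solid, P, group = NULL) {
  if (is.character(solid)) solid <- build_solid(solid)
  if (is.null(group)) group <- rotation_group(solid)
  P <- as.integer(P)
  if (P <= solid$Eh) {
    return(.labelings_tibble(solid, P, list()))
  }
  subs <- .vertex_transitive_subgroups(solid, group)
  C <- solid$V * solid$Eh
  base_corners <- seq_len(solid$Eh)  # corners of vertex 1, anticlockwise
  found <- new.env(parent = emptyenv())
  out <- list()
  for (s in subs) {
    orb <- .perm_orbits(group$cperm[s, , drop = FALSE], C)
    base_orb <- orb[base_corners]
    comps <- .compositions(P - solid$Eh, solid$Eh)
    if (nrow(comps) == 0L) next
    # labels must agree on corners of vertex 1 sharing an orbit
    pattern_ok <- apply(comps, 1, function(v) {
      all(tapply(v, base_orb, function(x) length(unique(x)) == 1L))
    })
    for (r in which(pattern_ok)) {
      vals <- comps[r, ]
      orb_val <- integer(max(orb))
      orb_val[base_orb] <- vals
      if (any(orb_val[orb] < 1L)) next  # orbit absent from vertex 1 (cannot happen)
      labels <- orb_val[orb]
      key <- .perm_key(labels)
      if (is.null(found[[key]])) {
        found[[key]] <- TRUE
        out[[length(out) + 1L]] <- labels
      }
    }
  }
  # keep one representative per orbit under the rotation group
  reps <- list()
  seen <- new.env(parent = emptyenv())
  for (labels in out) {
    key <- .perm_key(labels)
    if (!is.null(seen[[key]])) next
    orbit_keys <- unique(apply(group$cperm, 1, function(p) .perm_key(labels[p])))
    for (k in orbit_keys) seen[[k]] <- TRUE
    reps[[length(reps) + 1L]] <- labels
  }
  .labelings_tibble(solid, P, reps)
}

.labelings_tibble <- function(solid, P, label_list) {
  if (length(label_list) == 0L) {
    tb <- tibble::tibble(
      symbol = character(0), P = integer(0), name = character(0),
      labels = list(), vertex_labels = list(), holes = list()
    )
  } else {
    names <- vapply(label_list, function(l) canonical_name(.labeling_obj(solid, P, l)), "")
    # disambiguate structurally distinct labelings that read identically
    names <- .disambiguate_names(solid, names, label_list)
    ord <- order(names)
    tb <- tibble::tibble(
      symbol = solid$symbol, P = P,
      name = names[ord],
      labels = label_list[ord],
      vertex_labels = lapply(label_list[ord], function(l) unname(l[seq_len(solid$Eh)])),
      holes = lapply(label_list[ord], function(l) .hole_q_lists(solid, l))
    )
  }
  class(tb) <- c("pcage_labelings", class(tb))
  tb
}

# Reading of a labeling: labels anticlockwise around a vertex, starting at a
# corner whose face lies in `allowed`; lexicographically smallest reading.
.read_labels <- function(solid, labels, allowed) {
  Eh <- solid$Eh
  best <- NULL; bestkey <- NULL
  for (v in seq_len(solid$V)) {
    fs <- solid$vertex_cycles[[v]]
    for (s in which(fs %in% allowed)) {
      idx <- ((s - 1L + 0:(Eh - 1L)) %% Eh) + 1L
      r <- unname(labels[(v - 1L) * Eh + idx])
      key <- paste(sprintf("%04d", r), collapse = "")
      if (is.null(bestkey) || key < bestkey) { bestkey <- key; best <- r }
    }
  }
  best
}

# Constant-valued faces whose orbit under the labeling's stabilizer has at
# most two elements; these pin down the 'a' role for Platonic labelings
# (e.g. the two all-'a' faces of the octahedron's first diagram family).
.anchor_faces <- function(solid, group, labels) {
  ci <- .corner_index(solid)
  const <- vapply(seq_len(solid$F), function(fi) {
    length(unique(labels[ci[cbind(solid$faces[[fi]], fi)]])) == 1L
  }, TRUE)
  if (!any(const)) return(integer(0))
  stab <- which(vapply(seq_len(group$order), function(i) {
    all(labels[group$cperm[i, ]] == labels)
  }, TRUE))
  forb <- .perm_orbits(group$fperm[stab, , drop = FALSE], solid$F)
  sizes <- table(forb)
  keep <- which(const & sizes[as.character(forb)] <= 2)
  as.integer(keep)
}

# Octahedron diagram family: 2 when the labels are constant per face and form
# a proper two-colouring with two distinct values (equal faces never share an
# edge); 1 otherwise (two opposite all-'a' faces).
.poc_family <- function(solid, labels) {
  ci <- .corner_index(solid)
  per_face <- vapply(seq_len(solid$F), function(fi) {
    vals <- labels[ci[cbind(solid$faces[[fi]], fi)]]
    if (length(unique(vals)) == 1L) vals[1] else NA_integer_
  }, 1L)
  if (anyNA(per_face) || length(unique(per_face)) != 2L) return(1L)
  for (fi in seq_len(solid$F)) for (fj in seq_len(solid$F)) {
    if (fi < fj && length(intersect(solid$faces[[fi]], solid$faces[[fj]])) == 2L &&
        per_face[fi] == per_face[fj]) return(1L)
  }
  2L
}

# Platonic readings are anchored on invariant constant faces where possible;
# the octahedron gains its Poc1/Poc2 family prefix; any residual collision
# between structurally distinct labelings gets a deterministic letter suffix.
.disambiguate_names <- function(solid, names, label_list) {
  if (solid$family == "platonic" && length(label_list)) {
    group <- rotation_group(solid)
    P <- as.integer(sub(".*_P(\\d+)_.*", "\\1", names[1]))
    for (k in seq_along(label_list)) {
      anchor <- .anchor_faces(solid, group, label_list[[k]])
      if (length(anchor)) {
        r <- .read_labels(solid, label_list[[k]], anchor)
        names[k] <- paste0(solid$symbol, "_P", P, "_", paste(r, collapse = "_"))
      }
    }
    if (solid$symbol == "Poc") {
      fam <- vapply(label_list, function(l) .poc_family(solid, l), 1L)
      names <- paste0("Poc", fam, sub("^Poc", "", names))
    }
  }
  dup <- duplicated(names) | duplicated(names, fromLast = TRUE)
  if (any(dup)) {
    for (nm in unique(names[dup])) {
      idx <- which(names == nm)
      keys <- vapply(label_list[idx], .perm_key, "")
      for (j in seq_along(idx)) {
        names[idx[j]] <- sub("_P", paste0(letters[rank(keys)[j]], "_P"), nm)
      }
    }
  }
  names
}

#' Canonical name of a corner labeling
#'
#' Builds the `SYM_P<P>_<a>_<b>_...` name: the labels are read anticlockwise
#' around a vertex starting from a corner on the designated face class (the
#' base polygon for prisms and antiprisms, the smallest face for Archimedean
#' solids except the snub cube and snub dodecahedron where the square and the
#' pentagon are used, any face for Platonic solids), taking the
#' lexicographically smallest admissible reading.
#'
#' @param labeling A labeling list (fields `symbol`, `P`, `labels`).
#' @return A string such as `"Pic_P10_1_1_1_1_1"`.
#' @export
canonical_name <- function(labeling) {
  solid <- build_solid(labeling$symbol)
  best <- .read_labels(solid, labeling$labels, solid$a_faces)
  if (is.null(best))
    stop("no admissible 'a' corner; face-class error for ", solid$symbol)
  paste0(solid$symbol, "_P", labeling$P, "_", paste(best, collapse = "_"))
}

#' Remove chiral duplicates from a set of labelings
#'
#' Two labelings that differ only by an orientation-reversing automorphism of
#' the hole-polyhedron describe mirror-image p-cages; only one of each such
#' pair is kept (the one with the lexicographically smallest name).  Achiral
#' labelings, and all labelings on chiral solids such as the snub cube (which
#' have no reversing automorphisms), are retained unchanged.
#'
#' @param labelings A `pcage_labelings` tibble from [enumerate_distributions()].
#' @param full_group Optional [full_automorphisms()] group of the solid.
#' @return The deduplicated `pcage_labelings` tibble.
#' @export
dedup_chiral <- function(labelings, full_group = NULL) {
  if (nrow(labelings) == 0L) return(labelings)
  stopifnot(length(unique(labelings$symbol)) == 1L)
  solid <- build_solid(labelings$symbol[1])
  if (is.null(full_group)) full_group <- full_automorphisms(solid)
  n <- nrow(labelings)
  keep <- rep(TRUE, n)
  keys <- vapply(labelings$labels, .perm_key, "")
  rev_rows <- which(full_group$reversing)
  if (length(rev_rows) == 0L) return(labelings)
  # all images of each labeling under the full group, keyed
  group_keys <- lapply(labelings$labels, function(l) {
    unique(apply(full_group$cperm, 1, function(p) .perm_key(l[p])))
  })
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (j == i || !keep[j]) next
      if (keys[j] %in% group_keys[[i]]) {
        # i and j are mirror images; drop the one with the larger name
        drop <- if (labelings$name[i] <= labelings$name[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  out <- labelings[keep, ]
  class(out) <- c("pcage_labelings", class(tibble::as_tibble(out)))
  out
}
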