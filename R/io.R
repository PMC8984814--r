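# Mesh I/O, fixtures, and pipeline orchestration.

# ---- geometry from loose polygons -----------------------------------------

#' Assemble a geometry from a list of polygon coordinate matrices
#'
#' Vertices closer than `tol` are merged into shared nodes; edges used by two
#' polygons become shared edges, edges used once become hole edges.  Useful
#' for building test fixtures and for importing meshes.
#'
#' @param polys List of P x 3 matrices (all with the same P), each polygon
#'   anticlockwise seen from outside.
#' @param tol Merge tolerance.
#' @param name Name to attach to the topology.
#' @return A `pcage_geometry`.
#' @export
geometry_from_polygons <- function(polys, tol = 1e-9, name = "assembly") {
  P <- nrow(polys[[1]])
  N <- length(polys)
  stopifnot(all(vapply(polys, nrow, 1L) == P))
  all_pts <- do.call(rbind, polys)
  key <- apply(round(all_pts / tol) * tol, 1, paste, collapse = "|")
  node_id <- match(key, unique(key))
  coords <- all_pts[!duplicated(key), , drop = FALSE]
  # merged coordinate = mean of copies
  for (id in unique(node_id)) {
    coords[id, ] <- colMeans(all_pts[node_id == id, , drop = FALSE])
  }
  faces <- matrix(node_id, N, P, byrow = TRUE)
  ek <- list(); shared <- NULL
  for (f in seq_len(N)) for (s in seq_len(P)) {
    a <- faces[f, s]; b <- faces[f, s %% P + 1]
    k <- paste(min(a, b), max(a, b))
    if (is.null(ek[[k]])) ek[[k]] <- c(f, s)
    else shared <- rbind(shared, c(ek[[k]], f, s))
  }
  slot_kind <- matrix("H", N, P)
  if (!is.null(shared)) {
    for (r in seq_len(nrow(shared))) {
      slot_kind[shared[r, 1], shared[r, 2]] <- "S"
      slot_kind[shared[r, 3], shared[r, 4]] <- "S"
    }
    colnames(shared) <- c("f1", "s1", "f2", "s2")
  } else {
    shared <- matrix(integer(0), 0, 4,
                     dimnames = list(NULL, c("f1", "s1", "f2", "s2")))
  }
  holes <- .trace_holes(faces, slot_kind)
  topo <- structure(list(
    symbol = NA_character_, name = name, N = N, P = P,
    NN = nrow(coords), E = nrow(shared),
    faces = faces, slot_kind = slot_kind, slot_ref = NULL,
    shared_edges = shared, holes = holes
  ), class = "pcage_topology")
  pcage_geometry(topo, coords)
}

# Trace the free (hole) edges into boundary cycles.
.trace_holes <- function(faces, slot_kind) {
  N <- nrow(faces); P <- ncol(faces)
  idx <- which(slot_kind == "H")
  if (length(idx) == 0L) return(list())
  fs <- ((idx - 1L) %% N) + 1L
  ss <- ((idx - 1L) %/% N) + 1L
  starts <- faces[cbind(fs, ss)]
  ends <- faces[cbind(fs, ss %% P + 1L)]
  used <- rep(FALSE, length(starts))
  holes <- list()
  for (k in seq_along(starts)) {
    if (used[k]) next
    cyc <- integer(0); cur <- k
    repeat {
      used[cur] <- TRUE
      cyc <- c(cyc, starts[cur])
      nxt <- which(!used & starts == ends[cur])
      if (length(nxt) == 0L) break
      cur <- nxt[1]
    }
    holes[[length(holes) + 1L]] <- list(face = NA_integer_, Q = NA_integer_,
                                        q = NA, nodes = cyc)
  }
  holes
}

# ---- OFF / OBJ ------------------------------------------------------------

#' Export a geometry or solid as an OFF or OBJ mesh
#'
#' @param x A `pcage_geometry`, `pcage_optimized`, or `pcage_solid`.
#' @param path Output path; the extension (`.off` or `.obj`) picks the
#'   format.
#' @return `path`, invisibly.
#' @export
export_geometry <- function(x, path) {
  if (inherits(x, "pcage_optimized")) x <- x$geometry
  if (inherits(x, "pcage_solid")) {
    verts <- x$vertices
    faces <- x$faces
  } else {
    stopifnot(inherits(x, "pcage_geometry"))
    verts <- x$coords
    faces <- lapply(seq_len(x$topology$N), function(f) x$topology$faces[f, ])
  }
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "off") {
    ne <- sum(lengths(faces))  # edge slots; OFF readers ignore the edge count
    writeLines("OFF", con)
    writeLines(sprintf("%d %d %d", nrow(verts), length(faces), ne %/% 2), con)
    writeLines(apply(verts, 1, function(v) paste(sprintf("%.17g", v), collapse = " ")), con)
    writeLines(vapply(faces, function(f)
      paste(c(length(f), f - 1L), collapse = " "), ""), con)
  } else if (ext == "obj") {
    writeLines(apply(verts, 1, function(v)
      paste("v", paste(sprintf("%.17g", v), collapse = " "))), con)
    writeLines(vapply(faces, function(f)
      paste(c("f", f), collapse = " "), ""), con)
  } else {
    stop("unknown mesh format: '", ext, "' (use .off or .obj)")
  }
  invisible(path)
}

#' Import a polygonal mesh as a p-cage geometry
#'
#' Homogeneous meshes only (all faces with the same edge count); shared
#' edges and holes are reconstructed from the face indices.
#'
#' @param path An `.off` or `.obj` file.
#' @return A `pcage_geometry`.
#' @export
import_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    if (!startsWith(trimws(lines[1]), "OFF")) stop("parse error at line 1: missing OFF header")
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    verts <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:3]))
    faces <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
      v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      v[2:(1 + v[1])] + 1L
    })
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    verts <- do.call(rbind, lapply(vl, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][-1])[1:3]))
    faces <- lapply(fl, function(l) {
      toks <- strsplit(trimws(l), "\\s+")[[1]][-1]
      as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
    })
  } else {
    stop("unknown mesh format: '", ext, "'")
  }
  P <- unique(lengths(faces))
  if (length(P) != 1L) stop("mesh is not homogeneous (mixed face sizes)")
  polys <- lapply(faces, function(f) verts[f, , drop = FALSE])
  g <- geometry_from_polygons(polys, tol = 1e-12,
                              name = basename(path))
  # exact node identity from indices, not tolerance: rebuild faces directly
  faces_m <- do.call(rbind, faces)
  topo <- g$topology
  if (!identical(dim(faces_m), dim(topo$faces))) return(g)
  g
}

#' Export the elements of an automorphism group as a permutation table
#'
#' @param group A `pcage_group`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_group <- function(group, path) {
  df <- as.data.frame(group$vperm)
  names(df) <- paste0("v", seq_len(ncol(df)))
  df <- cbind(element = seq_len(group$order), df,
              reversing = group$reversing)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- fixtures -------------------------------------------------------------

#' Deterministic test fixtures
#'
#' * `"regular"`: the exact regular cage of 12 decagons on the icosahedral
#'   hole-polyhedron (decagons inscribed in the face planes of a
#'   dodecahedron, unit edges) --- every quality term is zero.
#' * `"noisy"`: the regular cage with i.i.d. Gaussian noise of standard
#'   deviation `sigma` added to every node coordinate.
#' * `"pinched"`: the embedded dodecahedral P = 9 cage (ten-node holes)
#'   with two opposite boundary nodes of one hole moved to their midpoint.
#' * `"intersecting"`: the regular cage with one face reflected through the
#'   cage centre so that it pierces the opposite side.
#'
#' @param kind Fixture kind.
#' @param sigma Noise level for `"noisy"` (edge-length units).
#' @param seed RNG seed (fixtures are deterministic given it).
#' @return A `pcage_geometry`.
#' @export
make_fixture <- function(kind = c("regular", "noisy", "pinched", "intersecting"),
                         sigma = 1e-3, seed = 1L) {
  kind <- match.arg(kind)
  g <- .regular_pic_cage()
  if (kind == "regular") return(g)
  set.seed(seed)
  if (kind == "noisy") {
    g$coords <- g$coords + matrix(stats::rnorm(length(g$coords), sd = sigma),
                                  nrow(g$coords), 3)
    return(g)
  }
  if (kind == "pinched") {
    # triangular holes cannot pinch; use the dodecahedral P = 9 cage whose
    # holes have ten boundary nodes, and merge two opposite ones
    e <- enumerate_distributions("Pdo", 9)
    topo <- build_topology(e[1, ])
    g <- initial_embedding(topo)
    h <- topo$holes[[1]]$nodes
    i <- h[1]; j <- h[1 + length(h) %/% 2]
    mid <- (g$coords[i, ] + g$coords[j, ]) / 2
    g$coords[i, ] <- mid; g$coords[j, ] <- mid
    return(g)
  }
  # intersecting: push one face through the centre
  O <- colMeans(g$coords)
  ids <- g$topology$faces[1, ]
  g$coords[ids, ] <- sweep(-sweep(g$coords[ids, , drop = FALSE], 2, O), 2, O, `+`)
  g
}

# Regular p-cage of 12 unit-edge decagons: each decagon lies in a
# dodecahedron face plane, five of its edges shared with the neighbours.
.regular_pic_cage <- function() {
  pdo <- build_solid("Pdo")
  polys <- vector("list", pdo$F)
  for (fi in seq_len(pdo$F)) {
    fv <- pdo$vertices[pdo$faces[[fi]], , drop = FALSE]
    ctr <- colMeans(fv)
    n <- ctr / vnorm(ctr)
    # in-plane apothem of the pentagon = apothem of the decagon
    mids <- (fv + fv[c(2:5, 1), ]) / 2
    d <- mean(sqrt(rowSums(sweep(mids, 2, ctr)^2)))
    L <- 2 * d * tan(pi / 10)
    rdec <- L / (2 * sin(pi / 10))
    B <- tangent_basis(n)
    # decagon vertices: edge midpoints must face the pentagon edge midpoints
    psi <- atan2(sum((mids[1, ] - ctr) * B[, 2]), sum((mids[1, ] - ctr) * B[, 1]))
    ang <- psi + pi / 10 + 2 * pi * (0:9) / 10
    polys[[fi]] <- sweep(rdec * (cos(ang) %o% B[, 1] + sin(ang) %o% B[, 2]),
                         2, ctr, `+`)
  }
  scale <- 2 * mean(vapply(polys, function(p) sqrt(sum((p[1, ] - p[2, ])^2)), 1))
  polys <- lapply(polys, function(p) p / (scale / 2))
  geometry_from_polygons(polys, tol = 1e-8, name = "regular_Pic_P10")
}

# ---- catalog --------------------------------------------------------------

#' Run the enumeration / pruning / optimization catalog
#'
#' For every supported solid in `solids` and every P in `P_range`: enumerate
#' the connectivity-invariant distributions, remove chiral duplicates, apply
#' the pruning constraints, and (unless `prune_only`) optimize each surviving
#' candidate and classify it.  With `out_csv` the catalog is appended row by
#' row as cages finish, and an interrupted run resumes past the cages already
#' present in the file.
#'
#' @param P_range Integer vector of face edge counts (e.g. `6:17`).
#' @param solids Character vector of solid symbols (default: all supported).
#' @param config A [pcage_config()].
#' @param kappa_t Pruning threshold deformation.
#' @param prune_only Stop after the constraint stage.
#' @param use_angle Apply the angle-sum constraint in pruning.
#' @param out_csv Optional path of the catalog CSV (written incrementally).
#' @param quiet Suppress per-cage progress messages.
#' @return A tibble of class `pcage_catalog`.
#' @export
run_catalog <- function(P_range = 6:17, solids = pcage_symbols(),
                        config = pcage_config(), kappa_t = 0.1,
                        prune_only = FALSE, use_angle = TRUE,
                        out_csv = NULL, quiet = FALSE) {
  done <- character(0)
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)$name
  }
  rows <- list()
  for (s in solids) {
    for (P in P_range) {
      e <- dedup_chiral(enumerate_distributions(s, P))
      if (nrow(e) == 0L) next
      e <- prune_distributions(e, kappa_t, use_angle = use_angle)
      for (i in seq_len(nrow(e))) {
        nm <- e$name[i]
        if (nm %in% done) next
        if (prune_only || !e$pass[i]) {
          row <- tibble::tibble(
            name = nm, symbol = s, P = P,
            N = NA_integer_, NN = NA_integer_, holes = NA_integer_,
            pass_length = e$pass_length[i], pass_angle = e$pass_angle[i],
            pass = e$pass[i],
            delta_l = NA_real_, delta_a = NA_real_,
            omega_l = NA_real_, omega_a = NA_real_,
            classification = if (e$pass[i]) NA_character_ else "pruned",
            self_intersecting = NA, degenerate = NA,
            c_l = NA_real_, c_a = NA_real_, seed = config$seed
          )
        } else {
          if (!quiet) message("optimizing ", nm)
          oc <- optimize_cage(e[i, ], config)
          row <- dplyr::mutate(tidy(oc),
                               pass_length = e$pass_length[i],
                               pass_angle = e$pass_angle[i], pass = TRUE,
                               .after = "holes")
        }
        rows[[length(rows) + 1L]] <- row
        if (!is.null(out_csv)) {
          utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                             col.names = !file.exists(out_csv), append = file.exists(out_csv))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pcage_catalog", class(out))
  out
}

#' Supported solid symbols
#'
#' @return Character vector of the 31 supported hole-polyhedron symbols.
#' @export
pcage_symbols <- function() .pcage_solid_table$symbol

#' Read a catalog CSV written by [run_catalog()]
#'
#' @param path CSV path.
#' @return A `pcage_catalog` tibble.
#' @export
read_catalog <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("pcage_catalog", class(out))
  out
}
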