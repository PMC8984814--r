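# Geometric pruning constraints on hole-edge distributions.
#
# Around every hole of Q faces, the sub-face hole (the generally non-planar
# Q-gon formed by the chords that close each face's run of hole edges) must
# be able to fold up into a convex arrangement with face deformations below a
# threshold kappa_t.  Two necessary conditions are used to discard candidate
# distributions before any geometry is built: a projected angle-sum bound and
# a polygon inequality on the chord lengths.

#' Hole specification
#'
#' Collects the data describing one hole of a candidate p-cage: the number of
#' faces `Q` around it, the edges `q` each face contributes, the face edge
#' count `P`, and the threshold deformation factor `kappa_t`.
#'
#' @param Q Number of faces surrounding the hole.
#' @param q Integer vector of length `Q`: hole edges contributed per face.
#' @param P Number of edges of each face.
#' @param kappa_t Threshold deformation factor (default 0.1, i.e. 10%).
#' @return A list of class `hole_spec`.
#' @export
hole_spec <- function(Q, q, P, kappa_t = 0.1) {
  Q <- as.integer(Q)
  if (Q < 3L) stop("degenerate hole: Q must be at least 3")
  q <- as.integer(q)
  stopifnot(length(q) == Q, all(q >= 1L), P > max(q))
  structure(list(Q = Q, q = q, P = as.integer(P), kappa_t = kappa_t),
            class = "hole_spec")
}

#' Projected angle-sum constraint on a hole
#'
#' For the sub-face hole to close into a convex ring, the projected angle sum
#' of its corners must reach that of a planar Q-gon, which bounds P:
#' `P <= (2 * sum(q_i + 1) / (Q - 2)) * (1 + kappa_t * (P - 2) / 2)`.
#' At `kappa_t = 0` and all `q_i = 1` this reduces to `P <= 4 Q / (Q - 2)`.
#'
#' @param h A [hole_spec()].
#' @return `TRUE` if the hole passes.
#' @export
angle_constraint_ok <- function(h) {
  stopifnot(inherits(h, "hole_spec"))
  bound <- (2 * sum(h$q + 1) / (h$Q - 2)) * (1 + h$kappa_t * (h$P - 2) / 2)
  h$P <= bound + 1e-12
}

#' Chord length of a face's hole-edge run
#'
#' Length (in units of the reference edge length) of the straight chord that
#' replaces the `qk` hole edges a face contributes to a hole, when every edge
#' and angle of the run is uniformly stretched or contracted by the factor
#' `K`:
#' even `qk`: `2 * sum_{i=0}^{qk/2-1} cos(pi * K * (qk - 1 - 2i) / P)`;
#' odd `qk`: `1 + 2 * sum_{i=0}^{(qk-3)/2} cos(pi * K * (qk - 1 - 2i) / P)`,
#' so `qk = 1` gives exactly 1.
#'
#' @param qk Number of hole edges in the run.
#' @param P Face edge count.
#' @param K Uniform deformation factor applied to the run (e.g. `1 + kappa_t`
#'   to majorate, `1 / (1 + kappa_t)` to minorate).
#' @return The chord length, a positive number (units of the edge length).
#' @export
subface_hole_edge_length <- function(qk, P, K) {
  if (K <= 0) stop("deformation factor K must be positive")
  qk <- as.integer(qk)
  stopifnot(qk >= 1L, P > qk)
  if (qk == 1L) return(1)
  if (qk %% 2L == 0L) {
    i <- 0:(qk / 2L - 1L)
    2 * sum(cos(pi * K * (qk - 1 - 2 * i) / P))
  } else {
    i <- 0:((qk - 3L) / 2L)
    1 + 2 * sum(cos(pi * K * (qk - 1 - 2 * i) / P))
  }
}

#' Hole-edge-length polygon constraint
#'
#' Each chord of the sub-face hole must not exceed the sum of the others,
#' even in the extreme configuration where the left-hand chord is contracted
#' and the right-hand chords stretched by the threshold factor:
#' `A_j(K = 1/(1+kappa_t)) <= (1+kappa_t)/(1-kappa_t) * sum_{i != j} A_i(K =
#' 1+kappa_t)`, tested for every j.
#'
#' @param h A [hole_spec()].
#' @return `TRUE` if the hole passes for every choice of j.
#' @export
length_constraint_ok <- function(h) {
  stopifnot(inherits(h, "hole_spec"))
  kt <- h$kappa_t
  lo <- vapply(h$q, subface_hole_edge_length, 1, P = h$P, K = 1 / (1 + kt))
  hi <- vapply(h$q, subface_hole_edge_length, 1, P = h$P, K = 1 + kt)
  fac <- (1 + kt) / (1 - kt)
  all(vapply(seq_len(h$Q), function(j) {
    lo[j] <= fac * (sum(hi) - hi[j]) + 1e-12
  }, TRUE))
}

#' Prune a corner labeling with the hole constraints
#'
#' Builds the [hole_spec()] of every hole-polyhedron face (its `q` list being
#' the corner labels around that face) and tests the hole-edge-length
#' constraint, optionally together with the angle-sum constraint, on each.
#'
#' @param labeling A labeling row/list with fields `symbol`, `P`, `labels`,
#'   or a one-row slice of a `pcage_labelings` tibble.
#' @param kappa_t Threshold deformation factor (default 0.1).
#' @param use_angle Also apply the angle-sum test (default `TRUE`; both
#'   necessary conditions must hold before a candidate is worth realizing
#'   geometrically).
#' @return Logical scalar with attribute `"report"`: a tibble with one row
#'   per hole (`hole`, `Q`, `q`, `length_ok`, `angle_ok`, `pass`).
#' @export
prune_configuration <- function(labeling, kappa_t = 0.1, use_angle = TRUE) {
  lab <- .as_labeling(labeling)
  solid <- build_solid(lab$symbol)
  qs <- .hole_q_lists(solid, lab$labels)
  rows <- purrr::map_dfr(seq_along(qs), function(fi) {
    h <- hole_spec(length(qs[[fi]]), qs[[fi]], lab$P, kappa_t)
    lok <- length_constraint_ok(h)
    aok <- angle_constraint_ok(h)
    tibble::tibble(
      hole = fi, Q = h$Q, q = paste(h$q, collapse = ","),
      length_ok = lok, angle_ok = aok,
      pass = lok && (!use_angle || aok)
    )
  })
  structure(all(rows$pass), report = rows)
}

#' Prune a whole table of labelings
#'
#' @param labelings A `pcage_labelings` tibble.
#' @inheritParams prune_configuration
#' @return The tibble with logical columns `pass_length`, `pass_angle`, and
#'   `pass` added.
#' @export
prune_distributions <- function(labelings, kappa_t = 0.1, use_angle = TRUE) {
  if (nrow(labelings) == 0L) {
    return(dplyr::mutate(labelings, pass_length = logical(0),
                         pass_angle = logical(0), pass = logical(0)))
  }
  fac <- (1 + kappa_t) / (1 - kappa_t)
  len_ok <- function(q, P) {
    lo <- vapply(q, subface_hole_edge_length, 1, P = P, K = 1 / (1 + kappa_t))
    hi <- vapply(q, subface_hole_edge_length, 1, P = P, K = 1 + kappa_t)
    s <- sum(hi)
    all(lo <= fac * (s - hi) + 1e-12)
  }
  ang_ok <- function(q, P) {
    Q <- length(q)
    P <= (2 * sum(q + 1) / (Q - 2)) * (1 + kappa_t * (P - 2) / 2) + 1e-12
  }
  res <- purrr::map(seq_len(nrow(labelings)), function(i) {
    qs <- labelings$holes[[i]]
    P <- labelings$P[i]
    c(length = all(vapply(qs, len_ok, TRUE, P = P)),
      angle = all(vapply(qs, ang_ok, TRUE, P = P)))
  })
  labelings$pass_length <- vapply(res, `[[`, TRUE, "length")
  labelings$pass_angle <- vapply(res, `[[`, TRUE, "angle")
  labelings$pass <- labelings$pass_length &
    (if (use_angle) labelings$pass_angle else TRUE)
  labelings
}

# Accept a labeling as a list or as a one-row pcage_labelings slice.
.as_labeling <- function(labeling) {
  if (inherits(labeling, "data.frame")) {
    stopifnot(nrow(labeling) == 1L)
    list(symbol = labeling$symbol[[1]], P = labeling$P[[1]],
         labels = labeling$labels[[1]], name = labeling$name[[1]])
  } else {
    labeling
  }
}
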