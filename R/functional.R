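# The face-deformation quality functional and the deformation/similarity
# metrics.  The functional is the weighted sum of five non-negative terms:
# squared relative edge-length deviations, squared corner-angle deviations
# (radians), squared out-of-plane facelet components, and Heaviside counts of
# face-convexity and cage-convexity violations.  It is zero exactly when all
# faces are regular planar convex P-gons of edge length L_f assembled into a
# locally convex cage.

#' Functional weights
#'
#' @param c_l,c_a Edge-length and angle weights (defaults 1 and 1; the
#'   optimizer sweeps them with `c_l + c_a = 2`).
#' @param c_p Planarity weight (default 1000).
#' @param c_cf,c_cp Face and cage convexity weights (default 100).
#' @param L_f Reference edge length (default 1; all lengths are in these
#'   units).
#' @param variant Cage-convexity variant: `"midpoint"` (edge-midpoint
#'   condition) or `"normal"` (normal-tip distance condition, more expensive
#'   but stricter; useful for cages that prefer concave configurations).
#' @return A list of class `pcage_weights`.
#' @export
pcage_weights <- function(c_l = 1, c_a = 1, c_p = 1000, c_cf = 100,
                          c_cp = 100, L_f = 1, variant = c("midpoint", "normal")) {
  variant <- match.arg(variant)
  stopifnot(c_l >= 0, c_a >= 0, c_p >= 0, c_cf >= 0, c_cp >= 0, L_f > 0)
  structure(list(c_l = c_l, c_a = c_a, c_p = c_p, c_cf = c_cf, c_cp = c_cp,
                 L_f = L_f, variant = variant), class = "pcage_weights")
}

.weights_vec <- function(w) c(w$c_l, w$c_a, w$c_p, w$c_cf, w$c_cp, w$L_f)
.variant_code <- function(w) if (w$variant == "midpoint") 1L else 2L

.quality_raw <- function(geometry, weights) {
  pc_quality_cpp(geometry$coords, geometry$topology$faces,
                 geometry$topology$shared_edges, .weights_vec(weights),
                 .variant_code(weights))
}

#' Quality functional breakdown
#'
#' @param geometry A `pcage_geometry`.
#' @param weights A [pcage_weights()].
#' @return A tibble (class `pcage_quality`) with the five terms, the weighted
#'   total, and the maximum deformations `delta_l`, `delta_a`.
#' @export
total_q <- function(geometry, weights = pcage_weights()) {
  q <- .quality_raw(geometry, weights)
  out <- tibble::as_tibble(as.list(q))
  class(out) <- c("pcage_quality", class(out))
  out
}

#' Edge-length quality term
#'
#' Sum over all faces and edges of `((l - L_f) / L_f)^2`.
#'
#' @inheritParams total_q
#' @param L_f Reference edge length.
#' @return Non-negative scalar, zero iff all edges have length `L_f`.
#' @export
q_length <- function(geometry, L_f = 1) {
  unname(.quality_raw(geometry, pcage_weights(L_f = L_f))["q_length"])
}

#' Corner-angle quality term
#'
#' Sum over all faces and corners of `(alpha - pi * (1 - 2 / P))^2`, angles
#' in radians.
#'
#' @inheritParams total_q
#' @return Non-negative scalar, zero iff every corner has the regular-P-gon
#'   angle.
#' @export
q_angle <- function(geometry) {
  unname(.quality_raw(geometry, pcage_weights())["q_angle"])
}

#' Face-planarity quality term
#'
#' Sum of the squared components of the facelet normals orthogonal to the
#' face normal; zero iff every face is planar.
#'
#' @inheritParams total_q
#' @return Non-negative scalar.
#' @export
q_planar <- function(geometry) {
  unname(.quality_raw(geometry, pcage_weights())["q_planar"])
}

#' Face-convexity violation count
#'
#' Number of corners whose consecutive edge vectors turn the wrong way for
#' an outward-oriented convex face (Heaviside count; boundary cases are not
#' penalized).
#'
#' @inheritParams total_q
#' @return Non-negative integer-valued scalar.
#' @export
q_conv_face <- function(geometry) {
  unname(.quality_raw(geometry, pcage_weights())["q_conv_face"])
}

#' Cage-convexity violation count
#'
#' Number of shared edges at which the two incident faces bend towards the
#' cage centre (variant `"midpoint"`), or adjacent face pairs whose outward
#' normal tips are closer than their bases (variant `"normal"`).
#'
#' @inheritParams total_q
#' @param variant `"midpoint"` or `"normal"`.
#' @return Non-negative integer-valued scalar.
#' @export
q_conv_cage <- function(geometry, variant = c("midpoint", "normal")) {
  variant <- match.arg(variant)
  unname(.quality_raw(geometry, pcage_weights(variant = variant))["q_conv_cage"])
}

#' Maximum deformations of a cage
#'
#' `delta_l` is the largest absolute edge-length deviation from `L_f`;
#' `delta_a` the largest relative corner-angle deviation from the regular
#' P-gon angle.
#'
#' @inheritParams q_length
#' @return A list with `delta_l` and `delta_a`.
#' @export
deformation <- function(geometry, L_f = 1) {
  q <- .quality_raw(geometry, pcage_weights(L_f = L_f))
  list(delta_l = unname(q["delta_l"]), delta_a = unname(q["delta_a"]))
}

#' Cage metrics in one sweep
#'
#' @inheritParams q_length
#' @return List with `delta_l`, `delta_a`, `omega_l`, `omega_a`.
#' @export
cage_metrics <- function(geometry, L_f = 1) {
  d <- deformation(geometry, L_f)
  s <- face_similarity(geometry)
  c(d, s)
}

#' Pairwise face dissimilarity
#'
#' For every unordered pair of faces, the mean absolute difference between
#' their edge-length (resp. angle) sequences is minimized over cyclic
#' relabelings (shift delta in 1..P-1); `omega_l` and `omega_a` are the
#' maxima over all pairs, the angle version normalized by the regular angle.
#'
#' @inheritParams total_q
#' @return List with `omega_l` and `omega_a`.
#' @export
face_similarity <- function(geometry) {
  topo <- geometry$topology
  P <- topo$P; N <- topo$N
  L <- matrix(0, N, P); A <- matrix(0, N, P)
  for (f in seq_len(N)) {
    fg <- face_geometry(geometry, f)
    L[f, ] <- fg$lengths
    A[f, ] <- fg$angles
  }
  a0 <- pi * (1 - 2 / P)
  om_l <- 0; om_a <- 0
  for (f in seq_len(N - 1)) for (g in (f + 1):N) {
    best_l <- Inf; best_a <- Inf
    for (d in 1:(P - 1)) {
      idx <- ((seq_len(P) - 1 + d) %% P) + 1
      best_l <- min(best_l, sum(abs(L[f, ] - L[g, idx])) / P)
      best_a <- min(best_a, sum(abs(A[f, ] - A[g, idx])) / (P * a0))
    }
    om_l <- max(om_l, best_l)
    om_a <- max(om_a, best_a)
  }
  list(omega_l = om_l, omega_a = om_a)
}
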