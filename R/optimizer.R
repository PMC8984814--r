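# Realization of a candidate topology as a maximally regular convex p-cage.
#
# The §-pipeline: spring-relaxed embedding, simulated-annealing Metropolis on
# all node positions, a log-spaced sweep of the length/angle weights with
# c_l + c_a = 2, golden-section refinement of the weight ratio, a final deep
# zero-temperature polish plus downhill-simplex step, and classification of
# the result (regular / near-miss / rejected / degenerate / self-intersecting).

#' Optimization configuration
#'
#' @param seed Integer seed; every stochastic step is reproducible given it.
#' @param metropolis_sweeps Annealing sweeps (one proposal per node each).
#' @param temp0 Initial temperature (quality-functional units).
#' @param step0 Initial proposal step (edge-length units).
#' @param target_acc Target acceptance rate for step adaptation.
#' @param refine_sweeps Zero-temperature sweeps after annealing.
#' @param sweep_points Number of weight-ratio points, log-spaced over
#'   `ratio_range` with `c_l + c_a = 2`.
#' @param sweep_sweeps Zero-temperature sweeps per sweep point (warm-started).
#' @param ratio_range Range of `c_l / c_a` covered by the sweep.
#' @param bisection_iters Golden-section iterations on the weight ratio.
#' @param final_sweeps Zero-temperature sweeps at the winning weights.
#' @param descent_maxit,final_descent_maxit Iterations of the
#'   Barzilai-Borwein gradient descent that deepens each sweep point and the
#'   final polish.
#' @param pattern_passes,final_pattern_passes Passes of the deterministic
#'   coordinate pattern search after the stochastic stage (per sweep point,
#'   and at the winning weights).
#' @param pattern_step0 Initial pattern-search step (edge-length units).
#' @param simplex_maxit Nelder-Mead iterations for the simplex polish.
#' @param near_miss_threshold Classification threshold on `max(delta_l,
#'   delta_a)` (default 0.1).
#' @param regular_threshold Below this the cage counts as regular (default
#'   1e-5).
#' @param degenerate_tol Distance under which two non-adjacent hole-boundary
#'   nodes count as pinched (default 0.05 edge lengths).
#' @param weights Base [pcage_weights()].
#' @return A list of class `pcage_config`.
#' @export
pcage_config <- function(seed = 1L,
                         metropolis_sweeps = 1200L, temp0 = 0.05,
                         step0 = 0.05, target_acc = 0.3,
                         refine_sweeps = 3000L,
                         sweep_points = 100L, sweep_sweeps = 250L,
                         ratio_range = c(1e-2, 1e2),
                         bisection_iters = 10L, final_sweeps = 4000L,
                         descent_maxit = 400L, final_descent_maxit = 1500L,
                         pattern_passes = 60L, final_pattern_passes = 400L,
                         pattern_step0 = 0.02,
                         simplex_maxit = 2000L,
                         near_miss_threshold = 0.1,
                         regular_threshold = 1e-5,
                         degenerate_tol = 0.05,
                         weights = pcage_weights()) {
  stopifnot(near_miss_threshold > 0, regular_threshold > 0,
            sweep_points >= 1, ratio_range[1] > 0, ratio_range[2] >= ratio_range[1])
  structure(as.list(environment()), class = "pcage_config")
}

.run_metropolis <- function(geometry, weights, sweeps, temp0, cool,
                            step0, target_acc) {
  topo <- geometry$topology
  res <- pc_metropolis_cpp(geometry$coords, topo$faces, topo$shared_edges,
                           .weights_vec(weights), .variant_code(weights),
                           as.integer(sweeps), temp0, cool, step0, target_acc,
                           1e-10, 1e-12)
  pcage_geometry(topo, res$coords)
}

#' Metropolis optimization of the node positions
#'
#' Anneals the quality functional with per-node Gaussian proposals (geometric
#' cooling, step size adapted towards the target acceptance rate), then
#' continues at zero temperature where only improving moves are accepted.
#' Returns the best geometry seen; deterministic for a fixed RNG state.
#'
#' @param geometry A `pcage_geometry`.
#' @param weights A [pcage_weights()].
#' @param config A [pcage_config()]; its `seed` is applied via [set.seed()].
#' @return The optimized `pcage_geometry`.
#' @export
metropolis_optimize <- function(geometry, weights = pcage_weights(),
                                config = pcage_config()) {
  set.seed(config$seed)
  cool <- exp(log(1e-10 / config$temp0) / max(config$metropolis_sweeps, 1))
  g <- .run_metropolis(geometry, weights, config$metropolis_sweeps,
                       config$temp0, cool, config$step0, config$target_acc)
  .run_metropolis(g, weights, config$refine_sweeps, 0, 1, config$step0 / 10,
                  config$target_acc)
}

#' Downhill-simplex refinement
#'
#' Polishes the node coordinates with Nelder-Mead on the full coordinate
#' vector.  The result never has a larger quality value than the input (the
#' better of input and output is returned).
#'
#' @inheritParams metropolis_optimize
#' @return A `pcage_geometry`.
#' @export
simplex_refine <- function(geometry, weights = pcage_weights(),
                           config = pcage_config()) {
  topo <- geometry$topology
  wv <- .weights_vec(weights); vc <- .variant_code(weights)
  fn <- function(x) {
    pc_quality_cpp(matrix(x, ncol = 3), topo$faces, topo$shared_edges, wv, vc)[["total"]]
  }
  x0 <- as.vector(geometry$coords)
  q0 <- fn(x0)
  res <- stats::optim(x0, fn, method = "Nelder-Mead",
                      control = list(maxit = config$simplex_maxit,
                                     reltol = 1e-12))
  if (res$value < q0) pcage_geometry(topo, matrix(res$par, ncol = 3)) else geometry
}

.run_descent <- function(geometry, weights, maxit, rel_tol = 1e-9) {
  topo <- geometry$topology
  res <- pc_descend_cpp(geometry$coords, topo$faces, topo$shared_edges,
                        .weights_vec(weights), .variant_code(weights),
                        as.integer(maxit), 1e-6, 1e-10, rel_tol)
  pcage_geometry(topo, res$coords)
}

.run_bfgs <- function(geometry, weights, maxit, rel_tol = 1e-13) {
  topo <- geometry$topology
  res <- pc_lbfgs_cpp(geometry$coords, topo$faces, topo$shared_edges,
                      .weights_vec(weights), .variant_code(weights),
                      as.integer(maxit), 1e-6, rel_tol)
  pcage_geometry(topo, res$coords)
}

.run_pattern <- function(geometry, weights, step0, passes) {
  topo <- geometry$topology
  res <- pc_pattern_cpp(geometry$coords, topo$faces, topo$shared_edges,
                        .weights_vec(weights), .variant_code(weights),
                        step0, 1e-10, as.integer(passes))
  pcage_geometry(topo, res$coords)
}

.max_def <- function(geometry, L_f = 1) {
  d <- deformation(geometry, L_f)
  max(d$delta_l, d$delta_a)
}

#' Weight sweep with c_l + c_a = 2
#'
#' Relaxes the cage at `sweep_points` weight ratios `c_l / c_a` spread
#' logarithmically over `ratio_range`, warm-starting each point from the
#' previous optimum, and records the deformations.
#'
#' @param topology A `pcage_topology` (or a geometry to start from).
#' @param config A [pcage_config()].
#' @return A tibble with columns `ratio`, `c_l`, `c_a`, `delta_l`, `delta_a`,
#'   `max_def` and a `coords` list-column.
#' @export
weight_sweep <- function(topology, config = pcage_config()) {
  set.seed(config$seed)
  g0 <- if (inherits(topology, "pcage_geometry")) topology
        else initial_embedding(topology)
  cool <- exp(log(1e-10 / config$temp0) / max(config$metropolis_sweeps, 1))
  g <- .run_metropolis(g0, config$weights, config$metropolis_sweeps,
                       config$temp0, cool, config$step0, config$target_acc)
  ratios <- exp(seq(log(config$ratio_range[1]), log(config$ratio_range[2]),
                    length.out = config$sweep_points))
  rows <- vector("list", length(ratios))
  # walk outward from the balanced point in both directions, warm-starting
  # each chain, so extreme-ratio basins do not contaminate the centre
  mid <- which.min(abs(log(ratios)))
  order_idx <- c(mid:length(ratios), if (mid > 1) (mid - 1):1)
  cur <- g
  for (i in order_idx) {
    if (i == mid - 1) cur <- rows[[mid]]$geometry[[1]]
    w <- .sweep_weights(config$weights, ratios[i])
    cur <- .run_metropolis(cur, w, config$sweep_sweeps, 0, 1,
                           config$step0 / 10, config$target_acc)
    cur <- if (i == mid) {
      # try both the annealed state and the raw embedding at the balanced
      # point; hot annealing sometimes trades the best basin away
      cand1 <- .run_descent(cur, w, config$descent_maxit, rel_tol = 1e-10)
      cand2 <- .run_descent(g0, w, config$descent_maxit, rel_tol = 1e-10)
      best_c <- if (total_q(cand1, w)$total <= total_q(cand2, w)$total)
        cand1 else cand2
      .run_bfgs(best_c, w, config$final_descent_maxit)
    } else {
      .run_bfgs(.run_descent(cur, w, 50L, rel_tol = 1e-8), w,
                config$descent_maxit, rel_tol = 1e-11)
    }
    d <- deformation(cur, config$weights$L_f)
    rows[[i]] <- tibble::tibble(
      ratio = ratios[i], c_l = 2 * ratios[i] / (1 + ratios[i]),
      c_a = 2 / (1 + ratios[i]),
      delta_l = d$delta_l, delta_a = d$delta_a,
      max_def = max(d$delta_l, d$delta_a),
      coords = list(cur$coords),
      geometry = list(cur)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$geometry <- NULL
  out
}

.sweep_weights <- function(base, ratio) {
  pcage_weights(c_l = 2 * ratio / (1 + ratio), c_a = 2 / (1 + ratio),
                c_p = base$c_p, c_cf = base$c_cf, c_cp = base$c_cp,
                L_f = base$L_f, variant = base$variant)
}

#' Golden-section refinement of the weight ratio
#'
#' Starting from the best sweep point, searches the log-ratio axis for the
#' weights minimizing `max(delta_l, delta_a)`, keeping `c_l + c_a = 2`.  The
#' returned cage is never worse than the best sweep candidate.
#'
#' @param topology A `pcage_topology`.
#' @param sweep The tibble returned by [weight_sweep()] (the bracket).
#' @param config A [pcage_config()].
#' @return A list with `geometry`, `ratio`, `max_def`.
#' @export
bisection_refine <- function(topology, sweep, config = pcage_config()) {
  stopifnot(nrow(sweep) >= 1)
  best_i <- which.min(sweep$max_def)
  best <- list(
    geometry = pcage_geometry(topology, sweep$coords[[best_i]]),
    ratio = sweep$ratio[best_i], max_def = sweep$max_def[best_i]
  )
  if (nrow(sweep) < 3 || config$bisection_iters < 1) return(best)
  lo <- log(sweep$ratio[max(best_i - 1, 1)])
  hi <- log(sweep$ratio[min(best_i + 1, nrow(sweep))])
  if (hi - lo < 1e-12) return(best)
  evalr <- function(logr, start) {
    w <- .sweep_weights(config$weights, exp(logr))
    g <- .run_metropolis(start, w, config$sweep_sweeps, 0, 1,
                         config$step0 / 20, config$target_acc)
    g <- .run_descent(g, w, config$descent_maxit, rel_tol = 1e-10)
    g <- .run_bfgs(g, w, 200L)
    list(geometry = g, ratio = exp(logr),
         max_def = .max_def(g, config$weights$L_f))
  }
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- evalr(x1, best$geometry); f2 <- evalr(x2, best$geometry)
  if (f1$max_def < best$max_def) best <- f1
  if (f2$max_def < best$max_def) best <- f2
  for (it in seq_len(config$bisection_iters)) {
    if (f1$max_def <= f2$max_def) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- evalr(x1, best$geometry)
      if (f1$max_def < best$max_def) best <- f1
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- evalr(x2, best$geometry)
      if (f2$max_def < best$max_def) best <- f2
    }
  }
  best
}

#' Detect pinched (degenerate) holes
#'
#' A hole is pinched when two non-adjacent nodes of its boundary cycle come
#' closer than `tolerance`, i.e. opposite hole edges have merged and the cage
#' is equivalent to one with smaller holes.
#'
#' @param geometry A `pcage_geometry`.
#' @param tolerance Distance threshold (edge-length units).
#' @return Logical; attribute `"pinched"` lists the offending hole indices.
#' @export
detect_degenerate <- function(geometry, tolerance = 0.05) {
  topo <- geometry$topology
  pinched <- integer(0)
  for (hi in seq_along(topo$holes)) {
    nodes <- topo$holes[[hi]]$nodes
    m <- length(nodes)
    if (m < 4) next
    pts <- geometry$coords[nodes, , drop = FALSE]
    D <- as.matrix(stats::dist(pts))
    bad <- FALSE
    for (i in seq_len(m - 2)) {
      for (j in (i + 2):m) {
        if (i == 1 && j == m) next  # cyclically adjacent
        if (D[i, j] <= tolerance) { bad <- TRUE; break }
      }
      if (bad) break
    }
    if (bad) pinched <- c(pinched, hi)
  }
  structure(length(pinched) > 0, pinched = pinched)
}

.classify <- function(max_def, degenerate, intersecting, config) {
  if (degenerate) return("degenerate")
  if (intersecting) return("self-intersecting")
  if (max_def <= config$regular_threshold) return("regular")
  if (max_def <= config$near_miss_threshold) return("near-miss")
  "rejected"
}

#' Optimize one candidate labeling into a p-cage
#'
#' Runs the full realization pipeline: topology, spring-relaxed embedding,
#' Metropolis annealing, the `c_l + c_a = 2` weight sweep, golden-section
#' weight refinement, a final deep zero-temperature polish with a
#' downhill-simplex step, then degeneracy and self-intersection checks and
#' classification.
#'
#' @param labeling A labeling (one-row `pcage_labelings` slice or list with
#'   `symbol`, `P`, `labels`, optionally `name`).
#' @param config A [pcage_config()].
#' @param simplex Apply the final Nelder-Mead polish (default `TRUE`).
#' @return An object of class `pcage_optimized`: fields `name`, `geometry`,
#'   `metrics` (`delta_l`, `delta_a`, `omega_l`, `omega_a`), `quality`,
#'   `best_weights`, `classification`, `self_intersecting`, `degenerate`.
#' @export
optimize_cage <- function(labeling, config = pcage_config(), simplex = TRUE) {
  lab <- .as_labeling(labeling)
  topo <- build_topology(lab)
  set.seed(config$seed)
  g <- tryCatch(initial_embedding(topo, seed = NULL),
                error = function(e) NULL)
  if (is.null(g)) g <- initial_embedding(topo, seed = config$seed)
  sw <- weight_sweep(g, config)
  best <- bisection_refine(topo, sw, config)
  w <- .sweep_weights(config$weights, best$ratio)
  g <- .run_bfgs(best$geometry, w, config$final_descent_maxit)
  g <- .run_pattern(g, w, config$pattern_step0 / 10,
                    config$final_pattern_passes)
  g <- .run_bfgs(g, w, config$final_descent_maxit)
  if (simplex) g <- simplex_refine(g, w, config)
  if (.max_def(g, config$weights$L_f) > best$max_def)
    g <- best$geometry
  met <- cage_metrics(g, config$weights$L_f)
  deg <- detect_degenerate(g, config$degenerate_tol)
  xs <- cage_self_intersects(g)
  cls <- .classify(max(met$delta_l, met$delta_a), isTRUE(deg[1]), isTRUE(xs[1]),
                  config)
  structure(list(
    name = topo$name, symbol = topo$symbol, P = topo$P,
    topology = topo, geometry = g,
    metrics = met, quality = total_q(g, w),
    best_weights = w, best_ratio = best$ratio,
    classification = cls,
    degenerate = isTRUE(deg[1]), pinched = attr(deg, "pinched"),
    self_intersecting = isTRUE(xs[1]),
    seed = config$seed
  ), class = "pcage_optimized")
}

#' @export
print.pcage_optimized <- function(x, ...) {
  cat(sprintf("<pcage_optimized> %s: %s (delta_l=%.3g, delta_a=%.3g, c_l=%.3g)\n",
              x$name, x$classification, x$metrics$delta_l, x$metrics$delta_a,
              x$best_weights$c_l))
  invisible(x)
}

#' Tidy an optimized cage
#'
#' @param x A `pcage_optimized`.
#' @param ... Unused.
#' @return One-row tibble with the catalog fields.
#' @method tidy pcage_optimized
#' @export
tidy.pcage_optimized <- function(x, ...) {
  tibble::tibble(
    name = x$name, symbol = x$symbol, P = x$P,
    N = x$topology$N, NN = x$topology$NN, holes = length(x$topology$holes),
    delta_l = x$metrics$delta_l, delta_a = x$metrics$delta_a,
    omega_l = x$metrics$omega_l, omega_a = x$metrics$omega_a,
    classification = x$classification,
    self_intersecting = x$self_intersecting,
    degenerate = x$degenerate,
    c_l = x$best_weights$c_l, c_a = x$best_weights$c_a,
    seed = x$seed
  )
}

#' Summarize an optimized cage
#'
#' @param x A `pcage_optimized`.
#' @param ... Unused.
#' @return One-row tibble with `name`, `classification`, `max_def`, `total`.
#' @method glance pcage_optimized
#' @export
glance.pcage_optimized <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    classification = x$classification,
    max_def = max(x$metrics$delta_l, x$metrics$delta_a),
    total = x$quality$total
  )
}
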