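# Reduced problem sizes keep the optimizer tests fast; the full-depth runs
# live in the acceptance suite.
small_config <- function(seed = 1L) {
  pcage_config(seed = seed, metropolis_sweeps = 150L, refine_sweeps = 200L,
               sweep_points = 5L, sweep_sweeps = 60L, descent_maxit = 150L,
               final_descent_maxit = 300L, final_sweeps = 300L,
               final_pattern_passes = 80L, bisection_iters = 3L,
               simplex_maxit = 200L)
}

test_that("metropolis descends on a perturbed regular cage", {
  g <- make_fixture("noisy", sigma = 1e-3, seed = 3)
  q0 <- total_q(g)$total
  g1 <- metropolis_optimize(g, config = small_config())
  expect_lt(total_q(g1)$total, q0)
})

test_that("optimization runs are deterministic given the seed", {
  g <- make_fixture("noisy", sigma = 1e-3, seed = 3)
  a <- metropolis_optimize(g, config = small_config(5))
  b <- metropolis_optimize(g, config = small_config(5))
  expect_identical(a$coords, b$coords)
  c <- metropolis_optimize(g, config = small_config(6))
  expect_false(identical(a$coords, c$coords))
})

test_that("simplex refinement never worsens the functional", {
  g <- make_fixture("noisy", sigma = 2e-3, seed = 8)
  q0 <- total_q(g)$total
  g1 <- simplex_refine(g, config = small_config())
  expect_lte(total_q(g1)$total, q0)
  # no-op at an exact minimum
  reg <- make_fixture("regular")
  g2 <- simplex_refine(reg, config = small_config())
  expect_lt(total_q(g2)$total, 1e-9)
})

test_that("re-optimizing a regular cage keeps it regular (idempotence)", {
  reg <- make_fixture("regular")
  g <- metropolis_optimize(reg, config = small_config())
  d <- deformation(g)
  expect_lt(max(d$delta_l, d$delta_a), 1e-5)
})

test_that("the weight sweep respects its contract", {
  e <- enumerate_distributions("Pdo", 9)
  topo <- build_topology(e[1, ])
  cfg <- small_config()
  sw <- weight_sweep(topo, cfg)
  expect_equal(nrow(sw), cfg$sweep_points)
  expect_equal(sw$c_l + sw$c_a, rep(2, nrow(sw)), tolerance = 1e-12)
  expect_equal(sw$max_def, pmax(sw$delta_l, sw$delta_a))
  best <- bisection_refine(topo, sw, cfg)
  expect_lte(best$max_def, min(sw$max_def) + 1e-12)
  # single-point sweep: bisection returns that point
  cfg1 <- small_config(); cfg1$sweep_points <- 1L
  sw1 <- weight_sweep(topo, cfg1)
  b1 <- bisection_refine(topo, sw1, cfg1)
  expect_equal(b1$ratio, sw1$ratio[1])
})

test_that("candidate selection minimizes the larger deformation", {
  # of (0.02, 0.03) and (0.01, 0.05) the first has the smaller maximum
  sw <- tibble::tibble(ratio = c(1, 2), c_l = c(1, 4/3), c_a = c(1, 2/3),
                       delta_l = c(0.02, 0.01), delta_a = c(0.03, 0.05),
                       max_def = pmax(delta_l, delta_a),
                       coords = list(matrix(0, 1, 3), matrix(1, 1, 3)))
  expect_equal(which.min(sw$max_def), 1L)
})

test_that("degenerate (pinched-hole) cages are detected", {
  expect_false(as.logical(detect_degenerate(make_fixture("regular"))))
  pinched <- make_fixture("pinched")
  res <- detect_degenerate(pinched, tolerance = 0.05)
  expect_true(as.logical(res))
  expect_gt(length(attr(res, "pinched")), 0)
  # zero tolerance flags only exact coincidences
  expect_true(as.logical(detect_degenerate(pinched, tolerance = 0)))
  expect_false(as.logical(detect_degenerate(make_fixture("regular"), tolerance = 0)))
})

test_that("a prism labeling with an oversized hole run collapses to a degenerate cage", {
  e <- enumerate_distributions("tp", 8)
  lab <- e[e$name == "tp_P8_1_1_3", ]
  expect_equal(nrow(lab), 1L)
  oc <- optimize_cage(lab, small_config(2))
  expect_true(oc$degenerate || oc$classification == "degenerate")
})

test_that("optimize_cage classifies a small regular construction", {
  e <- enumerate_distributions("Pdo", 9)
  cfg <- small_config(3)
  oc <- optimize_cage(e[1, ], cfg)
  expect_s3_class(oc, "pcage_optimized")
  expect_true(max(oc$metrics$delta_l, oc$metrics$delta_a) < 0.1)
  td <- tidy(oc)
  expect_equal(td$name, "Pdo_P9_2_2_2")
  expect_equal(td$N, 20L)
  expect_equal(td$holes, 12L)
  gl <- glance(oc)
  expect_equal(gl$classification, oc$classification)
})
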