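test_that("q_length matches hand-computed cases", {
  g <- single_face_geometry(regular_polygon(6))
  expect_equal(q_length(g), 0, tolerance = 1e-14)
  # isoceles triangle with base 1.05 and unit legs: one squared deviation
  h <- sqrt(1 - 0.525^2)
  tri <- single_face_geometry(rbind(c(0, 0, 0), c(1.05, 0, 0), c(0.525, h, 0)))
  expect_equal(q_length(tri), 0.05^2, tolerance = 1e-12)
  # doubling all coordinates: every edge contributes (2 - 1)^2
  g2 <- g; g2$coords <- 2 * g2$coords
  expect_equal(q_length(g2), 6, tolerance = 1e-12)
})

test_that("q_angle matches hand-computed cases", {
  g <- single_face_geometry(regular_polygon(8))
  expect_equal(q_angle(g), 0, tolerance = 1e-14)
  # rhombus with angles 100 and 80 degrees
  a <- 100 * pi / 180
  rh <- rbind(c(0, 0, 0), c(1, 0, 0),
              c(1 + cos(pi - a), sin(pi - a), 0), c(cos(pi - a), sin(pi - a), 0))
  expect_equal(q_angle(single_face_geometry(rh)), 4 * (10 * pi / 180)^2,
               tolerance = 1e-9)
})

test_that("q_planar agrees with an explicit facelet projection oracle", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.1), c(0, 1, 0))
  g <- single_face_geometry(sq)
  # oracle: recompute the four facelet normals and project off the unit
  # normal of the summed area vector
  ctr <- colMeans(sq)
  nu <- sweep(sq, 2, ctr)
  cross <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  w <- t(vapply(1:4, function(i) 0.5 * cross(nu[i, ], nu[i %% 4 + 1, ]), numeric(3)))
  W <- colSums(w); Wh <- W / sqrt(sum(W^2))
  expected <- sum(vapply(1:4, function(i) {
    sum(w[i, ]^2) - sum(w[i, ] * Wh)^2
  }, 1))
  expect_equal(q_planar(g), expected, tolerance = 1e-12)
  expect_gt(expected, 0)
  expect_equal(q_planar(single_face_geometry(regular_polygon(7))), 0,
               tolerance = 1e-14)
})

test_that("face convexity counts reflex corners of outward-oriented faces", {
  # a dart: one reflex corner; pair it with a far face so the cage centre
  # lies outside the dart and F_f is meaningful
  dart <- rbind(c(0, 0, 1), c(1, 0.4, 1), c(2, 0, 1), c(1, 2, 1))
  far <- rbind(c(0, 0, -1), c(0, 1, -1), c(1, 1, -1), c(1, 0, -1))
  g <- geometry_from_polygons(list(dart, far))
  expect_gte(q_conv_face(g), 1)
  g2 <- geometry_from_polygons(list(dart[4:1, ], far))  # reversed orientation
  expect_false(q_conv_face(g2) == q_conv_face(g))
  expect_equal(q_conv_face(make_fixture("regular")), 0)
})

test_that("cage convexity penalizes inward folds under both variants", {
  # a locally convex cage passes both variants
  g <- make_fixture("regular")
  expect_equal(q_conv_cage(g, "midpoint"), 0)
  expect_equal(q_conv_cage(g, "normal"), 0)
  # pull one shared edge towards the cage centre: the edge-midpoint test
  # sees the inward fold
  folded <- g
  edge <- g$topology$shared_edges[1, ]
  P <- g$topology$P
  ids <- c(g$topology$faces[edge[1], edge[2]],
           g$topology$faces[edge[1], edge[2] %% P + 1])
  O <- colMeans(g$coords)
  folded$coords[ids, ] <- sweep(0.5 * sweep(g$coords[ids, , drop = FALSE], 2, O),
                                2, O, `+`)
  expect_gte(q_conv_cage(folded, "midpoint"), 1)
  # normal-tip test on an isolated face pair: normals diverge when the pair
  # bends away from the normal side, converge on a reflex fold
  expect_equal(q_conv_cage(roof_geometry(pi * 1.3), "normal"), 0)
  expect_gte(q_conv_cage(roof_geometry(pi * 0.7), "normal"), 1)
  # exactly coplanar adjacent faces: boundary case, not penalized
  flat <- roof_geometry(pi)
  expect_equal(q_conv_cage(flat, "normal"), 0)
})

test_that("the total vanishes on a regular cage and only there", {
  g <- make_fixture("regular")
  q <- total_q(g)
  expect_lt(q$total, 1e-9)
  expect_lt(max(unlist(q[1, 1:5])), 1e-11)
  noisy <- make_fixture("noisy", sigma = 1e-3, seed = 4)
  qn <- total_q(noisy)
  expect_gt(qn$q_length, 0)
  expect_gt(qn$q_angle, 0)
  expect_gt(qn$q_planar, 0)
  expect_gt(qn$total, 0)
})

test_that("all functional terms are invariant under rigid motions", {
  g <- make_fixture("noisy", sigma = 5e-3, seed = 9)
  q0 <- unlist(total_q(g))
  for (sd in 1:3) {
    rm <- random_rigid_motion(sd)
    g2 <- g; g2$coords <- apply_rigid(g$coords, rm)
    expect_equal(unlist(total_q(g2)), q0, tolerance = 1e-10)
  }
})

test_that("length and angle terms carry equal weight to first order", {
  # deform an isoceles right triangle either by opening the right angle or
  # by stretching one leg so that the hypotenuse elongates equally; the
  # matched deformations must satisfy (dl)^2 / l^2 = (dtheta)^2
  l <- 1
  for (delta in c(1e-3, 1e-4)) {
    L1 <- 2 * l * sin(pi / 4 + delta / 2)           # angle route
    eps <- 2 * (L1 - sqrt(2) * l) / (sqrt(2) * l)   # length route, first order
    L2 <- sqrt((l * (1 + eps))^2 + l^2)
    expect_equal(L1, L2, tolerance = 10 * delta)
    expect_equal(eps^2 / delta^2, 1, tolerance = 20 * delta)
  }
})

test_that("deformation metrics report maxima as printed", {
  g <- make_fixture("regular")
  d <- deformation(g)
  expect_lt(d$delta_l, 1e-9)
  expect_lt(d$delta_a, 1e-9)
  # uniform 2% scaling: delta_l = 0.02, angles untouched
  g2 <- g; g2$coords <- 1.02 * g2$coords
  d2 <- deformation(g2)
  expect_equal(d2$delta_l, 0.02, tolerance = 1e-6)
  expect_lt(d2$delta_a, 1e-9)
})

test_that("face similarity minimizes over cyclic shifts", {
  g <- make_fixture("regular")
  s <- face_similarity(g)
  expect_equal(s$omega_l, 0, tolerance = 1e-10)
  expect_equal(s$omega_a, 0, tolerance = 1e-10)
  # two triangles differing in a single edge by x: omega_l = x / P
  x <- 0.2
  t1 <- regular_polygon(3)
  h <- sqrt((1 + x)^2 - ((1 + x) / 2)^2)
  t2 <- rbind(c(10, 0, 0), c(11 + x, 0, 0), c(10 + (1 + x) / 2, h, 0))
  # second triangle has edges (1+x, r, r); build isoceles with two unit legs
  t2 <- rbind(c(10, 0, 0), c(11.2, 0, 0),
              c(10.6, sqrt(1 - 0.6^2), 0))
  g2 <- geometry_from_polygons(list(t1, t2))
  s2 <- face_similarity(g2)
  expect_equal(s2$omega_l, x / 3, tolerance = 1e-9)
})
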