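test_that("embedding produces near-unit edges and merged shared nodes", {
  e <- enumerate_distributions("Asc", 11)
  topo <- build_topology(e[e$name == "Asc_P11_2_1_1_1_1", ])
  g <- initial_embedding(topo)
  expect_equal(nrow(g$coords), topo$NN)
  d <- deformation(g)
  expect_lt(d$delta_l, 0.05)
  expect_lt(d$delta_a, 0.05)
})

test_that("the icosahedral cage embeds with icosahedral symmetry", {
  e <- enumerate_distributions("Pic", 10)
  topo <- build_topology(e[1, ])
  g <- initial_embedding(topo)
  # rotate by 2pi/5 about a vertex axis of the icosahedron: the node set
  # must map onto itself (to within the relaxation tolerance)
  axis <- build_solid("Pic")$vertices[1, ]
  th <- 2 * pi / 5
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rotated <- g$coords %*% t(R)
  mismatch <- max(apply(rotated, 1, function(p) {
    min(sqrt(rowSums(sweep(g$coords, 2, p)^2)))
  }))
  expect_lt(mismatch, 1e-6)
})

test_that("embedding is equivariant under rotations of the solid", {
  e <- enumerate_distributions("Pdo", 9)
  topo <- build_topology(e[1, ])
  solid <- build_solid("Pdo")
  g1 <- initial_embedding(topo, solid)
  rm <- random_rigid_motion(11)
  solid2 <- solid
  solid2$vertices <- solid$vertices %*% t(rm$R)
  g2 <- initial_embedding(topo, solid2)
  expect_equal(g2$coords, g1$coords %*% t(rm$R), tolerance = 1e-6)
})

test_that("face geometry follows the stated conventions", {
  # regular planar unit decagon: all angles pi(1 - 2/10)
  g <- single_face_geometry(regular_polygon(10))
  fg <- face_geometry(g, 1)
  expect_equal(fg$angles, rep(pi * 0.8, 10), tolerance = 1e-12)
  expect_equal(fg$lengths, rep(1, 10), tolerance = 1e-12)
  # planar face: facelet normals parallel, |W| = area
  w <- fg$facelet_normals
  expect_true(all(abs(w %*% fg$unit_normal - sqrt(rowSums(w^2))) < 1e-12))
  areal <- 10 * (1 / (2 * sin(pi / 10)))^2 * sin(2 * pi / 10) / 2
  expect_equal(sqrt(sum(fg$area_vector^2)), areal, tolerance = 1e-12)
  # anticlockwise unit square in the xy-plane: normal +z
  sq <- single_face_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(face_geometry(sq, 1)$unit_normal, c(0, 0, 1))
  # degenerate edge errors
  bad <- single_face_geometry(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_error(face_geometry(bad, 1), "degenerate edge")
})
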