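test_that("triangle-triangle worked examples", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_false(triangles_intersect(a, b))  # parallel planes
  # crossing through each other's interiors
  c1 <- rbind(c(0.2, 0.2, -0.5), c(0.3, 0.2, 0.5), c(0.2, 0.3, 0.5))
  expect_true(triangles_intersect(a, c1))
  # identical triangles (coplanar overlap)
  expect_true(triangles_intersect(a, a))
  # coplanar but disjoint
  d <- rbind(c(5, 5, 0), c(6, 5, 0), c(5, 6, 0))
  expect_false(triangles_intersect(a, d))
  # degenerate input
  z <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(triangles_intersect(a, z), "degenerate")
})

test_that("the test is symmetric and agrees with an independent oracle", {
  set.seed(101)
  n_agree <- 0L
  for (k in 1:300) {
    t1 <- matrix(stats::runif(9, -1, 1), 3)
    t2 <- matrix(stats::runif(9, -1, 1), 3)
    # skip near-degenerate draws
    area <- function(tt) {
      e1 <- tt[2, ] - tt[1, ]; e2 <- tt[3, ] - tt[1, ]
      sqrt(sum(c(e1[2]*e2[3]-e1[3]*e2[2], e1[3]*e2[1]-e1[1]*e2[3],
                 e1[1]*e2[2]-e1[2]*e2[1])^2)) / 2
    }
    if (area(t1) < 1e-3 || area(t2) < 1e-3) next
    r1 <- triangles_intersect(t1, t2)
    expect_identical(r1, triangles_intersect(t2, t1))
    expect_identical(r1, oracle_tri_tri(t1, t2),
                     info = paste("pair", k))
    n_agree <- n_agree + 1L
  }
  expect_gt(n_agree, 250)
})

test_that("cage self-intersection is detected and adjacency excluded", {
  g <- make_fixture("regular")
  expect_false(as.logical(cage_self_intersects(g)))  # touching along shared
                                                     # edges only
  bad <- make_fixture("intersecting")
  res <- cage_self_intersects(bad)
  expect_true(as.logical(res))
  expect_gt(nrow(attr(res, "pairs")), 0)
})
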