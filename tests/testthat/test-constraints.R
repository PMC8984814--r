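test_that("angle-sum constraint evaluates the printed bound", {
  expect_true(angle_constraint_ok(hole_spec(3, c(1, 1, 1), 10, kappa_t = 0)))
  expect_false(angle_constraint_ok(hole_spec(3, c(1, 1, 1), 13, kappa_t = 0)))
  # the bound relaxes with the threshold: 12 * (1 + 0.55) = 18.6 >= 13
  expect_true(angle_constraint_ok(hole_spec(3, c(1, 1, 1), 13, kappa_t = 0.1)))
})

test_that("at kappa = 0 and unit contributions the bound is 4Q/(Q-2)", {
  for (Q in 3:5) {
    lim <- 4 * Q / (Q - 2)
    below <- floor(lim)
    expect_true(angle_constraint_ok(hole_spec(Q, rep(1, Q), below, kappa_t = 0)))
    expect_false(angle_constraint_ok(hole_spec(Q, rep(1, Q), below + 1, kappa_t = 0)))
  }
})

test_that("sub-face chord lengths match the closed forms", {
  expect_equal(subface_hole_edge_length(1, 10, 1), 1)
  expect_equal(subface_hole_edge_length(1, 13, 0.5), 1)
  expect_equal(subface_hole_edge_length(2, 10, 1), 2 * cos(pi / 10))
  expect_equal(subface_hole_edge_length(3, 12, 1), 1 + sqrt(3), tolerance = 1e-12)
  expect_error(subface_hole_edge_length(2, 10, 0), "positive")
})

test_that("length constraint flags over-long chords", {
  # all contributions equal always passes
  expect_true(length_constraint_ok(hole_spec(4, c(2, 2, 2, 2), 12)))
  # a 12-edge run against two single edges at P = 17 cannot close
  expect_false(length_constraint_ok(hole_spec(3, c(12, 1, 1), 17, kappa_t = 0.1)))
  expect_true(length_constraint_ok(hole_spec(3, c(2, 1, 1), 10, kappa_t = 0.1)))
})

test_that("both constraints relax monotonically in kappa_t", {
  specs <- list(c(3, 12, 1, 1, 17), c(4, 1, 1, 1, 1, 15), c(3, 5, 2, 1, 13))
  kts <- c(0, 0.05, 0.1, 0.2, 0.4)
  for (sp in specs) {
    Q <- sp[1]; q <- sp[2:(1 + Q)]; P <- sp[length(sp)]
    lasta <- FALSE; lastl <- FALSE
    for (kt in kts) {
      h <- hole_spec(Q, q, P, kt)
      a <- angle_constraint_ok(h); l <- length_constraint_ok(h)
      expect_true(a >= lasta, info = paste("angle", kt))
      expect_true(l >= lastl, info = paste("length", kt))
      lasta <- a; lastl <- l
    }
  }
})

test_that("pruning worked examples", {
  e <- enumerate_distributions("Pic", 10)
  lab <- e[e$name == "Pic_P10_1_1_1_1_1", ]
  expect_true(as.logical(prune_configuration(lab)))
  e <- enumerate_distributions("Asc", 11)
  lab <- e[e$name == "Asc_P11_2_1_1_1_1", ]
  p <- prune_configuration(lab)
  expect_true(as.logical(p))
  rep <- attr(p, "report")
  expect_equal(nrow(rep), 38)
  expect_equal(sum(rep$Q == 3), 32)
  expect_error(hole_spec(2, c(1, 1), 8), "degenerate hole")
})

test_that("prune_distributions annotates a labeling table", {
  e <- dedup_chiral(enumerate_distributions("7p", 17))
  pr <- prune_distributions(e, kappa_t = 0.1, use_angle = FALSE)
  expect_true(all(pr$pass_length))            # prism holes always close
  pr2 <- prune_distributions(e, kappa_t = 0.1, use_angle = TRUE)
  expect_true(any(!pr2$pass))                 # the angle bound does prune
  expect_true(all(pr2$pass == (pr2$pass_length & pr2$pass_angle)))
})
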