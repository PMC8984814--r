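test_that("worked topology examples are reproduced", {
  e <- enumerate_distributions("Asc", 11)
  topo <- build_topology(e[e$name == "Asc_P11_2_1_1_1_1", ])
  expect_equal(topo$N, 24)
  expect_equal(topo$NN, 24 * 11 - 2 * 60)
  expect_equal(length(topo$holes), 38)
  blen <- vapply(topo$holes, function(h) length(h$nodes), 1L)
  expect_equal(sum(blen == 3), 32)
  expect_equal(sum(blen == 8), 6)

  e <- enumerate_distributions("Pic", 10)
  topo <- build_topology(e[1, ])
  expect_equal(topo$N, 12)
  expect_equal(topo$NN, 60)
  expect_equal(length(topo$holes), 20)
  expect_true(all(vapply(topo$holes, function(h) length(h$nodes), 1L) == 3))

  e <- enumerate_distributions("Arcd", 12)
  nm <- e$name[vapply(e$holes, function(h) {
    setequal(unique(vapply(h, sum, 1)), c(3, 8, 15))
  }, TRUE)]
  expect_gt(length(nm), 0)
  topo <- build_topology(e[e$name == nm[1], ])
  expect_equal(topo$N, 60)
  expect_equal(topo$NN, 60 * 12 - 2 * 120)
  expect_setequal(unique(vapply(topo$holes, function(h) length(h$nodes), 1L)),
                  c(3, 8, 15))
})

test_that("counting identities hold across enumerated labelings", {
  for (s in c("7p", "sa", "Poc", "Aco")) {
    solid <- build_solid(s)
    e <- enumerate_distributions(s, 10)
    for (i in seq_len(min(nrow(e), 5))) {
      topo <- build_topology(e[i, ], solid)
      expect_equal(topo$NN, topo$N * topo$P - 2 * solid$E, info = e$name[i])
      expect_equal(length(topo$holes), solid$F, info = e$name[i])
      # hole boundary length equals the sum of the labels around its face
      for (h in topo$holes) {
        expect_equal(length(h$nodes), sum(h$q), info = e$name[i])
      }
    }
  }
})

test_that("nodes belong to one hole and at most two faces", {
  e <- enumerate_distributions("Pic", 10)
  topo <- build_topology(e[1, ])
  face_count <- tabulate(as.vector(topo$faces), topo$NN)
  # each node counted once per incident face
  expect_true(all(face_count %in% c(1L, 2L)))
  hole_count <- tabulate(unlist(lapply(topo$holes, `[[`, "nodes")), topo$NN)
  expect_true(all(hole_count == 1L))
  # nodes on two faces have three edges, nodes on one face have two
  expect_equal(sum(face_count == 2L), 2 * topo$E)
})

test_that("shared edges are traversed oppositely by their two faces", {
  e <- enumerate_distributions("Asc", 11)
  topo <- build_topology(e[1, ])
  P <- topo$P
  for (r in seq_len(nrow(topo$shared_edges))) {
    f1 <- topo$shared_edges[r, 1]; s1 <- topo$shared_edges[r, 2]
    f2 <- topo$shared_edges[r, 3]; s2 <- topo$shared_edges[r, 4]
    a1 <- topo$faces[f1, s1]; b1 <- topo$faces[f1, s1 %% P + 1]
    a2 <- topo$faces[f2, s2]; b2 <- topo$faces[f2, s2 %% P + 1]
    expect_equal(c(a1, b1), c(b2, a2))
  }
})
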