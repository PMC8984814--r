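test_that("worked enumeration examples are reproduced", {
  e <- enumerate_distributions("Pdo", 9)
  expect_equal(e$name, "Pdo_P9_2_2_2")
  expect_true(all(e$labels[[1]] == 2L))

  expect_equal(nrow(enumerate_distributions("Pdo", 10)), 0L)

  e <- enumerate_distributions("Pic", 10)
  expect_true("Pic_P10_1_1_1_1_1" %in% e$name)

  e <- enumerate_distributions("Asc", 11)
  expect_true("Asc_P11_2_1_1_1_1" %in% e$name)

  # P <= Eh yields nothing
  expect_equal(nrow(enumerate_distributions("Asc", 5)), 0L)
})

test_that("connectivity invariance matches its definition on triangle faces", {
  solid <- build_solid("Pte")
  group <- rotation_group(solid)
  # all corners equal: trivially invariant
  expect_true(is_connectivity_invariant(rep(2L, 12), group, solid))
  # three distinct labels consistently ordered (from the enumeration)
  e <- enumerate_distributions("Pte", 9)
  distinct <- e[vapply(e$labels, function(l) length(unique(l)) == 3L, TRUE), ]
  expect_gt(nrow(distinct), 0)
  lab <- distinct$labels[[1]]
  expect_true(is_connectivity_invariant(lab, group, solid))
  # swapping two labels at one vertex (keeping the sum) breaks invariance
  bad <- lab
  bad[1:2] <- bad[2:1]
  expect_false(is_connectivity_invariant(bad, group, solid))
})

test_that("invalid labelings are rejected", {
  solid <- build_solid("Pte")
  group <- rotation_group(solid)
  expect_error(is_connectivity_invariant(rep(0L, 12), group, solid), "invalid labeling")
  lab <- rep(2L, 12); lab[1] <- 3L
  expect_error(is_connectivity_invariant(lab, group, solid), "invalid labeling")
  expect_error(is_connectivity_invariant(rep(1L, 5), group, solid), "invalid labeling")
})

test_that("enumeration agrees with the exhaustive oracle on small solids", {
  cases <- list(c("Pte", 9), c("tp", 8), c("Pcu", 7), c("Poc", 9))
  for (cs in cases) {
    s <- cs[1]; P <- as.integer(cs[2])
    oracle <- brute_force_labelings(s, P)
    e <- enumerate_distributions(s, P)
    group <- rotation_group(build_solid(s))
    keys <- sort(vapply(e$labels, orbit_key, "", group = group))
    expect_equal(keys, oracle, info = paste(s, P))
  }
})

test_that("every enumerated labeling passes the invariance test (idempotence)", {
  for (s in c("7p", "sa", "Aco", "Poc", "Asc")) {
    solid <- build_solid(s)
    group <- rotation_group(solid)
    e <- enumerate_distributions(s, 11)
    expect_gt(nrow(e), 0)
    for (l in e$labels) {
      expect_true(is_connectivity_invariant(l, group, solid))
    }
  }
})

test_that("diagram structure matches the case analysis", {
  # octahedron: exactly the two diagram families
  e <- enumerate_distributions("Poc", 12)
  fams <- unique(sub("_.*", "", e$name))
  expect_setequal(fams, c("Poc1", "Poc2"))

  # icosidodecahedron: triangles all one value, pentagons all another
  solid <- build_solid("Aid")
  ci <- pcage:::.corner_index(solid)
  e <- enumerate_distributions("Aid", 12)
  expect_gt(nrow(e), 0)
  for (l in e$labels) {
    per_face <- vapply(seq_len(solid$F), function(fi) {
      vals <- l[ci[cbind(solid$faces[[fi]], fi)]]
      expect_equal(length(unique(vals)), 1L)
      vals[1]
    }, 1L)
    tri <- per_face[lengths(solid$faces) == 3]
    pent <- per_face[lengths(solid$faces) == 5]
    expect_equal(length(unique(tri)), 1L)
    expect_equal(length(unique(pent)), 1L)
  }

  # cube faces: corners all equal or equal in diagonal pairs
  solid <- build_solid("Pcu")
  ci <- pcage:::.corner_index(solid)
  e <- enumerate_distributions("Pcu", 9)
  for (l in e$labels) {
    for (fi in seq_len(solid$F)) {
      vals <- l[ci[cbind(solid$faces[[fi]], fi)]]
      expect_true(length(unique(vals)) == 1L ||
                  (vals[1] == vals[3] && vals[2] == vals[4]))
    }
  }
})

test_that("canonical names follow the labeling convention", {
  e <- enumerate_distributions("Pic", 10)
  lab <- e[e$name == "Pic_P10_1_1_1_1_1", ]
  expect_equal(canonical_name(pcage:::.as_labeling(lab)), "Pic_P10_1_1_1_1_1")
  # snub cube: 'a' sits on the square
  e <- enumerate_distributions("Asc", 11)
  two_on_square <- e$name[vapply(seq_len(nrow(e)), function(i)
    e$vertex_labels[[i]][
      match(TRUE, build_solid("Asc")$vertex_cycles[[1]] %in% build_solid("Asc")$a_faces)
    ] == 2L, TRUE)]
  expect_true("Asc_P11_2_1_1_1_1" %in% e$name)
})

test_that("chiral deduplication keeps one of each mirror pair", {
  e <- enumerate_distributions("tp", 9)
  expect_equal(nrow(e), 10)  # compositions of 6 into 3
  d <- dedup_chiral(e)
  expect_equal(nrow(d), 6)   # unordered {b, c} per a
  # mirror pairs: one representative, the lexicographically smaller name
  expect_true("tp_P9_1_2_3" %in% d$name)
  expect_false("tp_P9_1_3_2" %in% d$name)
  # achiral labelings survive
  expect_true("tp_P9_2_2_2" %in% d$name)
  expect_true("tp_P9_4_1_1" %in% d$name)
  # labelings on chiral solids are never merged
  e <- enumerate_distributions("Asc", 11)
  expect_equal(nrow(dedup_chiral(e)), nrow(e))
})
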