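test_that("every supported solid satisfies the polyhedron invariants", {
  tab <- pcage_solids()
  for (i in seq_len(nrow(tab))) {
    hp <- build_solid(tab$symbol[i])
    expect_equal(hp$V - hp$E + hp$F, 2, info = hp$symbol)
    deg <- tabulate(c(hp$edges), hp$V)
    expect_true(all(deg == hp$Eh), info = hp$symbol)
    expect_equal(sum(deg), 2 * hp$E, info = hp$symbol)
    # coordinates on the unit circumsphere
    expect_equal(sqrt(rowSums(hp$vertices^2)), rep(1, hp$V),
                 tolerance = 1e-9, info = hp$symbol)
    # every edge lies in exactly two faces and each direction appears once
    dir_edges <- do.call(rbind, lapply(hp$faces, function(f) {
      cbind(f, f[c(2:length(f), 1)])
    }))
    expect_equal(nrow(dir_edges), 2 * hp$E, info = hp$symbol)
    expect_false(anyDuplicated(paste(dir_edges[, 1], dir_edges[, 2])) > 0,
                 info = hp$symbol)
  }
})

test_that("face-size multisets match the known vertex configurations", {
  sizes <- function(s) as.vector(table(lengths(build_solid(s)$faces)))
  expect_equal(sort(lengths(build_solid("Pic")$faces)), rep(3, 20))
  expect_equal(unname(table(lengths(build_solid("Asc")$faces))),
               array(c(32L, 6L)))  # 32 triangles + 6 squares
  expect_equal(unname(table(lengths(build_solid("Arcd")$faces))),
               array(c(20L, 30L, 12L)))
  hp <- build_solid("7p")
  expect_equal(c(hp$V, hp$E, hp$F, hp$Eh), c(14, 21, 9, 3))
  asc <- build_solid("Asc")
  expect_equal(c(asc$V, asc$Eh, asc$F), c(24, 5, 38))
  pic <- build_solid("Pic")
  expect_equal(c(pic$V, pic$E, pic$F, pic$Eh), c(12, 30, 20, 5))
})

test_that("rotation groups have the expected orders and act transitively", {
  orders <- c(Pte = 12, Pcu = 24, Poc = 24, Pdo = 60, Pic = 60,
              tp = 6, `7p` = 14, ta = 6, sa = 8, Asc = 24, Asd = 60,
              Aco = 24, Aid = 60)
  for (s in names(orders)) {
    hp <- build_solid(s)
    g <- rotation_group(hp)
    expect_equal(g$order, unname(orders[s]), info = s)
    expect_false(any(g$reversing), info = s)
    orb <- pcage:::.perm_orbits(g$vperm, hp$V)
    expect_equal(length(unique(orb)), 1L, info = s)
  }
})

test_that("full automorphism groups flag orientation-reversing elements", {
  g <- full_automorphisms(build_solid("Pte"))
  expect_equal(g$order, 24)
  expect_equal(sum(g$reversing), 12)
  g <- full_automorphisms(build_solid("Pcu"))
  expect_equal(g$order, 48)
  # the snub solids are chiral: no reversing automorphisms at all
  expect_equal(sum(full_automorphisms(build_solid("Asc"))$reversing), 0)
  # rotation_group is the subgroup of unflagged elements
  r <- rotation_group(build_solid("Pte"))
  expect_equal(r$order, 12)
})

test_that("rotation elements preserve the cyclic orientation of vertex cycles", {
  for (s in c("Pte", "tp", "Asc", "Aco")) {
    hp <- build_solid(s)
    g <- rotation_group(hp)
    for (i in seq_len(min(g$order, 8))) {
      for (v in c(1L, hp$V)) {
        w <- g$vperm[i, v]
        imgs <- g$fperm[i, hp$vertex_cycles[[v]]]
        pos <- match(imgs, hp$vertex_cycles[[w]])
        steps <- unique((diff(pos)) %% hp$Eh)
        expect_equal(steps, 1, info = paste(s, "element", i))
      }
    }
  }
})

test_that("unsupported and excluded solids raise the documented errors", {
  expect_error(build_solid("Qxx"), "unsupported solid")
  expect_error(build_solid("Atco"), "reflection-only")
  expect_error(build_solid("Atid"), "reflection-only")
})
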