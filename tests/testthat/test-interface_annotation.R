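test_that("rolling-probe ASA converges and matches a dense-quadrature run", {
  # one isolated residue (backbone + CB)
  gly <- ppiface:::helix_backbone(3)
  res2 <- gly[gly$res_idx == 2, ]
  res2$res_idx <- 1L
  coarse <- residue_asa(res2, n_points = 960)
  dense <- residue_asa(res2, n_points = 10000)
  expect_true(all(coarse > 0))
  expect_lt(abs(coarse[["1"]] - dense[["1"]]) / dense[["1"]], 0.05)
  # doubling the quadrature changes per-residue ASA by < 2%
  ch <- build_chain(35, 9, "A")
  a1 <- residue_asa(ch, n_points = 960)
  a2 <- residue_asa(ch, n_points = 1920)
  expect_true(all(abs(a1 - a2) / pmax(a2, 1) < 0.02))
})

test_that("a residue enclosed in a shell of atoms has zero ASA", {
  k <- 0:199
  z <- 1 - 2 * (k + 0.5) / 200
  r <- sqrt(1 - z^2)
  th <- pi * (3 - sqrt(5)) * k
  shell <- cbind(4 * r * cos(th), 4 * r * sin(th), 4 * z)
  atoms <- data.frame(res_idx = c(1L, rep(2L, 200)), atom = "CB",
                      element = "C", x = c(0, shell[, 1]),
                      y = c(0, shell[, 2]), z = c(0, shell[, 3]))
  asa <- residue_asa(atoms, n_points = 960)
  expect_equal(asa[["1"]], 0)
})

test_that("dASA is zero for distant chains and positive at the interface", {
  far <- point_dimer(c(0, 0, 0), c(50, 0, 0))
  d_far <- delta_asa(far)
  expect_true(all(d_far$X == 0) && all(d_far$Y == 0))

  dim1 <- docked_dimer()
  das <- delta_asa(dim1)
  dm <- oracle_res_min_dist(dim1$chainX, dim1$chainY)
  near_x <- which(apply(dm, 1, min) < 5)
  expect_true(all(das$X[as.character(near_x)] > 0))
  near_y <- which(apply(dm, 2, min) < 5)
  expect_true(all(das$Y[as.character(near_y)] > 0))

  # occlusion is monotone: a second copy of the partner can only bury more
  B2 <- dim1$chainY
  B2$atoms$z <- B2$atoms$z + 12
  twice <- dim1
  twice$chainY <- new_chain("B", paste0(dim1$chainY$seqres,
                                        dim1$chainY$seqres),
                            rbind(dim1$chainY$atoms,
                                  transform(B2$atoms,
                                            res_idx = res_idx + 40L)))
  d_twice <- delta_asa(twice)
  expect_true(all(d_twice$X >= das$X - 1e-6))
})

test_that("distance rule admits close pairs; dASA rule admits near-misses", {
  # plain 5 A contact -> rule (a)
  d5 <- annotate_interface(point_dimer(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(d5$interface$pairs), 1)
  expect_identical(d5$interface$pairs$rule, "distance")
  expect_equal(d5$interface$pairs$d, 5)

  # 6.1 A: above the cutoff but still burying surface -> rule (b)
  d61 <- annotate_interface(point_dimer(c(0, 0, 0), c(6.1, 0, 0)))
  expect_equal(nrow(d61$interface$pairs), 1)
  expect_identical(d61$interface$pairs$rule, "dasa")
  expect_equal(d61$interface$pairs$d, 6.1)
  expect_true(all(d61$interface$pairs$dASA_X > 0,
                  d61$interface$pairs$dASA_Y > 0))

  # beyond any burial range: no interface at all
  d8 <- annotate_interface(point_dimer(c(0, 0, 0), c(8, 0, 0)))
  expect_equal(nrow(d8$interface$pairs), 0)

  # rule (b)(ii): a residue that already has a partner within the cutoff
  # cannot adopt a second, more distant one (one-directional evaluation)
  toy <- point_dimer(c(0, 0, 0), rbind(c(5, 0, 0), c(0, 6.1, 0)))
  dd1 <- annotate_interface(toy, annotation_config(both_directions = FALSE))
  expect_equal(nrow(dd1$interface$pairs), 1)
  expect_equal(dd1$interface$pairs$posY, 1)
  # under the symmetric union the far residue is adopted from the partner
  # side, where it has no sub-cutoff contact of its own
  dd2 <- annotate_interface(toy)
  expect_equal(nrow(dd2$interface$pairs), 2)
  expect_identical(sort(dd2$interface$pairs$rule), c("dasa", "distance"))
})

test_that("full annotation equals the literal two-rule oracle", {
  for (k in 1:2) {
    dim_k <- docked_dimer(mode_k = k, seed_a = 30 + k, seed_b = 40 + k)
    das <- delta_asa(dim_k)
    want <- oracle_annotation_pairs(dim_k, use_dasa = TRUE, dasa = das)
    got <- dim_k$interface$pairs[, c("posX", "posY")]
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("pure distance mode equals the brute-force distance oracle", {
  dim1 <- docked_dimer(use_dasa = FALSE)
  want <- oracle_annotation_pairs(dim1, use_dasa = FALSE)
  got <- dim1$interface$pairs[, c("posX", "posY")]
  rownames(got) <- NULL
  expect_equal(got, want)
  expect_true(all(dim1$interface$pairs$rule == "distance"))
  expect_true(all(dim1$interface$pairs$d < 6))
})

test_that("annotation is symmetric and rigid-motion invariant", {
  dim1 <- docked_dimer()
  # transpose: swap the chains and annotate again
  swapped <- ppiface:::new_hetero_dimer("t", dim1$chainY, dim1$chainX,
                                        "P2", "P1", "F2", "F1")
  swapped <- annotate_interface(swapped)
  expect_equal(swapped$interface$pairs$posX, dim1$interface$pairs$posY[
    order(dim1$interface$pairs$posY, dim1$interface$pairs$posX)])
  expect_identical(swapped$interface$faceX, dim1$interface$faceY)
  expect_identical(swapped$interface$faceY, dim1$interface$faceX)

  set.seed(77)
  moved <- apply_rigid_dimer(dim1, random_rigid())
  moved <- annotate_interface(moved)
  expect_equal(moved$interface$pairs$posX, dim1$interface$pairs$posX)
  expect_equal(moved$interface$pairs$posY, dim1$interface$pairs$posY)
  expect_equal(moved$interface$pairs$d, dim1$interface$pairs$d,
               tolerance = 1e-6)
})

test_that("rule (b) only ever adds pairs at or beyond the cutoff", {
  dim1 <- docked_dimer(use_dasa = TRUE)
  dim0 <- annotate_interface(dim1, annotation_config(use_dasa = FALSE))
  pa <- dim1$interface$pairs
  expect_true(all(pa$d[pa$rule == "dasa"] >= 6))
  # rule (a) pairs unchanged by toggling dASA
  expect_equal(pa[pa$rule == "distance", c("posX", "posY", "d")],
               dim0$interface$pairs[, c("posX", "posY", "d")])
})

test_that("size filter requires five residues on either face", {
  ann <- list(faceX = 1:4, faceY = 1:12)
  expect_false(passes_size_filter(ann))
  expect_true(passes_size_filter(list(faceX = 1:5, faceY = 21:25)))
  expect_false(passes_size_filter(list(faceX = integer(0),
                                       faceY = integer(0))))
})

test_that("copy numbers count sequence-identical dimers per assembly", {
  # single interface
  d1 <- docked_dimer()
  expect_equal(assign_copy_numbers(list(d1))[[1]]$copy_number, 1L)
  # Fig 2-style: two interfaces with the same sequence pair in one complex
  w <- fig2_world()
  c2 <- w$dimers[grepl("^c2", names(w$dimers))]
  expect_true(all(vapply(c2, function(d) d$copy_number, 0L) == 2L))
  expect_equal(w$dimers[["c1:A:B"]]$copy_number, 1L)
  # ring: three alpha-gamma and three beta-gamma copies, six alpha-beta
  rw <- generate_world(world_spec(n_families = 1, prots_per_family = 1,
                                  seqs_per_prot = 1, homomer_rate = 0,
                                  copy_number_dist = c(1),
                                  include_ring = TRUE, seed = 13))
  aid <- grep("ring", names(rw$assemblies), value = TRUE)[1]
  ds <- extract_hetero_dimers(rw$assemblies[[aid]], rw$mapping)
  ds <- assign_copy_numbers(ds)
  keys <- vapply(ds, function(d) paste(d$seq_pair, collapse = "\r"), "")
  want <- as.integer(table(keys)[keys]) # exhaustive count oracle
  expect_equal(vapply(ds, function(d) d$copy_number, 0L), want)
  expect_setequal(unique(want), c(3L, 6L))
})
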