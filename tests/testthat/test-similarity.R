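test_that("Face Position Similarity reproduces the worked example", {
  map <- setNames(1:10, 1:10) # identity correspondence
  fps <- face_position_similarity(c(1, 2, 3), c(1, 3, 7, 8), map)
  expect_equal(fps, 2 / sqrt(3 * 4))
  expect_equal(round(sqrt(3 * 4), 1), 3.5)
  expect_equal(fps, 2 / 3.5, tolerance = 0.02) # the one-decimal print form
  expect_equal(face_position_similarity(1:5, 1:5, map), 1)
  expect_equal(face_position_similarity(1:3, 7:9, map), 0)
  # empty face after reduction: undefined
  expect_true(is.na(face_position_similarity(integer(0), 1:3, map)))
  expect_true(is.na(face_position_similarity(11:12, 1:3, map)))
})

test_that("removing a shared residue never increases fps", {
  map <- setNames(1:20, 1:20)
  faceA <- c(1, 2, 3, 5, 8)
  faceB <- c(1, 3, 5, 9, 11, 12)
  full <- face_position_similarity(faceA, faceB, map)
  for (drop in intersect(faceA, faceB)) {
    expect_lte(face_position_similarity(setdiff(faceA, drop), faceB, map),
               full + 1e-12)
  }
})

test_that("per-side combination is the arithmetic mean", {
  expect_equal(combine_sides(1, 1), 1)
  expect_equal(combine_sides(0, 1), 0.5)
  expect_equal(combine_sides(0.6, 0.8), 0.7)
})

test_that("common residues: identity, unresolved positions and mutations", {
  d1 <- docked_dimer()
  corr <- common_residues(d1, d1)
  expect_equal(corr$coverage, 1)
  expect_identical(unname(corr$mapX), as.integer(names(corr$mapX)))

  # unresolved residues in one structure drop out of the map
  d2 <- d1
  d2$chainX$atoms <- d2$chainX$atoms[!(d2$chainX$atoms$res_idx %in% 3:7), ]
  corr2 <- common_residues(d1, d2)
  expect_false(any(3:7 %in% as.integer(names(corr2$mapX))))
  expect_equal(length(corr2$mapX), 85)

  # a point mutation keeps an identity position map (gap-free alignment)
  mut <- make_variants(d1$chainX, "point_mutation", 0.05, seed = 4)
  d3 <- d1
  d3$chainX <- mut
  corr3 <- common_residues(d1, d3)
  expect_identical(unname(corr3$mapX), as.integer(names(corr3$mapX)))
  expect_equal(corr3$coverage, 1)
})

test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    A <- matrix(rnorm(n * 3, sd = 5), n, 3)
    rg <- random_rigid()
    B <- sweep(A %*% t(rg$R), 2, rg$t, "+")
    noisy <- B + matrix(rnorm(n * 3, sd = runif(1, 0, 1)), n, 3)
    fit <- kabsch_superpose(A, noisy)
    expect_equal(fit$rmsd, oracle_quaternion_rmsd(A, noisy),
                 tolerance = 1e-6)
    # exact recovery for a pure rigid copy
    expect_lt(kabsch_superpose(A, B)$rmsd, 1e-6)
    # proper rotation, never a reflection
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  # mirror image: still a proper rotation, positive residual
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  M <- A %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(A, M)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(fit$rmsd, oracle_quaternion_rmsd(A, M), tolerance = 1e-6)
  expect_error(kabsch_superpose(A[1:2, ], M[1:2, ]), "3 paired points")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("self-comparison gives fps 1 and zero RMSD measures", {
  d1 <- docked_dimer()
  rec <- compare_dimers(d1, d1)
  expect_equal(rec$fps, 1)
  expect_equal(rec$l_rms, 0, tolerance = 1e-6)
  expect_equal(rec$i_rms, 0, tolerance = 1e-6)
})

test_that("all measures are symmetric and rigid-motion invariant", {
  dA <- docked_dimer(mode_k = 1, seed_a = 51, seed_b = 52)
  dB <- docked_dimer(mode_k = 2, seed_a = 51, seed_b = 52)
  ab <- compare_dimers(dA, dB)
  ba <- compare_dimers(dB, dA)
  expect_equal(ab$fps, ba$fps, tolerance = 1e-9)
  expect_equal(ab$l_rms, ba$l_rms, tolerance = 1e-6)
  expect_equal(ab$i_rms, ba$i_rms, tolerance = 1e-6)

  set.seed(9)
  moved <- annotate_interface(apply_rigid_dimer(dB, random_rigid()))
  mv <- compare_dimers(dA, moved)
  expect_equal(mv$fps, ab$fps, tolerance = 1e-9)
  expect_equal(mv$l_rms, ab$l_rms, tolerance = 1e-5)
  expect_equal(mv$i_rms, ab$i_rms, tolerance = 1e-5)
})

test_that("L_rms sees conformational change outside the binding region", {
  dA <- docked_dimer()
  # hinge-bend the receptor far from the interface (residues 60-90 displaced)
  dB <- dA
  hit <- dB$chainX$atoms$res_idx >= 60
  dB$chainX$atoms$x[hit] <- dB$chainX$atoms$x[hit] + 6
  dB <- annotate_interface(dB)
  rec <- compare_dimers(dA, dB)
  expect_equal(rec$fps, 1)          # faces untouched
  expect_gt(rec$l_rms, 0.5)         # receptor frame shifts the ligand
  expect_lt(rec$i_rms, rec$l_rms)   # common interface region barely moves
})

test_that("L_rms and I_rms agree with a naive two-step oracle", {
  dA <- docked_dimer(mode_k = 1, seed_a = 61, seed_b = 62)
  # ligand spun in place about its own axis: same site, rotated pose
  dB <- dA
  ctr <- colMeans(as.matrix(dB$chainY$atoms[, c("x", "y", "z")]))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- sweep(as.matrix(dB$chainY$atoms[, c("x", "y", "z")]), 2, ctr)
  xyz <- sweep(xyz %*% R, 2, ctr, "+")
  dB$chainY$atoms$x <- xyz[, 1]
  dB$chainY$atoms$y <- xyz[, 2]
  dB$chainY$atoms$z <- xyz[, 3]
  dB <- annotate_interface(dB)
  corr <- common_residues(dA, dB)
  got_l <- l_rms(dA, dB, corr)
  got_i <- i_rms(dA, dB, corr)
  expect_gt(got_i, 0)

  # oracle: superpose receptors with the quaternion method's rotation via
  # an explicit grid-free two-step recomputation using generic tools
  bb <- c("N", "CA", "C", "O")
  pick <- function(ch, pos) {
    a <- ch$atoms[ch$atoms$res_idx %in% pos & ch$atoms$atom %in% bb, ]
    a <- a[order(a$res_idx, match(a$atom, bb)), ]
    as.matrix(a[, c("x", "y", "z")])
  }
  common <- as.integer(names(corr$mapX))
  RA <- pick(dA$chainX, common)
  RB <- pick(dB$chainX, common)
  # receptors are identical here, so the optimal transform is the identity;
  # the oracle L_rms is the direct ligand RMSD
  commonY <- as.integer(names(corr$mapY))
  LA <- pick(dA$chainY, commonY)
  LB <- pick(dB$chainY, commonY)
  expect_lt(max(abs(RA - RB)), 1e-9)
  oracle_l <- sqrt(mean(rowSums((LA - LB)^2)))
  expect_equal(got_l, oracle_l, tolerance = 1e-6)

  # I_rms oracle: quaternion rmsd over the union interface region
  uniX <- sort(union(dA$interface$faceX, dB$interface$faceX))
  uniX <- intersect(uniX, common)
  uniY <- sort(union(dA$interface$faceY, dB$interface$faceY))
  uniY <- intersect(uniY, commonY)
  IA <- rbind(pick(dA$chainX, uniX), pick(dA$chainY, uniY))
  IB <- rbind(pick(dB$chainX, uniX), pick(dB$chainY, uniY))
  expect_equal(got_i, oracle_quaternion_rmsd(IA, IB), tolerance = 1e-6)
})

test_that("comparisons below the coverage floor are skipped", {
  dA <- docked_dimer()
  dB <- dA
  keep <- dB$chainX$atoms$res_idx <= 20 # only 20 of 90 receptor residues
  dB$chainX$atoms <- dB$chainX$atoms[keep, ]
  dB <- annotate_interface(dB)
  rec <- compare_dimers(dA, dB, min_coverage = 0.9)
  expect_true(rec$skipped)
  expect_identical(rec$skip_reason, "coverage_floor")
})
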