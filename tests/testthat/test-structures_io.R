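canonical_atoms <- function(chain) {
  a <- chain$atoms[order(chain$atoms$res_idx, chain$atoms$atom), ]
  a$x <- round(a$x, 3); a$y <- round(a$y, 3); a$z <- round(a$z, 3)
  rownames(a) <- NULL
  a
}

test_that("PDB writer/reader round-trips a two-chain assembly", {
  A <- build_chain(45, 1, "A")
  B <- build_chain(40, 2, "B")
  asm <- dock(A, B, dock_mode(23), "rt01", resolution = 1.8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_assembly_pdb(asm, path)
  got <- load_assembly(path)
  expect_s3_class(got, "Assembly")
  expect_named(got$chains, c("A", "B"))
  expect_equal(got$resolution, 1.8)
  expect_match(got$method, "X-RAY")
  expect_identical(got$chains$A$seqres, A$seqres)
  expect_equal(canonical_atoms(got$chains$A)[, c("x", "y", "z")],
               canonical_atoms(asm$chains$A)[, c("x", "y", "z")])
})

test_that("unresolved residues stay atom-less with intact SEQRES", {
  A <- build_chain(45, 1, "A")
  gap <- 10:12
  A2 <- new_chain("A", A$seqres, A$atoms[!(A$atoms$res_idx %in% gap), ])
  B <- build_chain(40, 2, "B")
  asm <- new_assembly("gap", list(A2, ppiface:::place_partner(B,
                                                              dock_mode(23))),
                      resolution = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_assembly_pdb(asm, path)
  got <- load_assembly(path)
  expect_equal(nchar(got$chains$A$seqres), 45)
  expect_false(any(gap %in% got$chains$A$atoms$res_idx))
  expect_setequal(setdiff(1:45, gap), unique(got$chains$A$atoms$res_idx))
})

test_that("the same assembly parses identically from PDB and mmCIF", {
  A <- build_chain(45, 5, "A")
  B <- build_chain(40, 6, "B")
  asm <- dock(A, B, dock_mode(23), "fmt", resolution = 2.1)
  pp <- withr::local_tempfile(fileext = ".pdb")
  pc <- withr::local_tempfile(fileext = ".cif")
  write_assembly_pdb(asm, pp)
  write_assembly_cif(asm, pc)
  from_pdb <- load_assembly(pp, assembly_id = "fmt")
  from_cif <- load_assembly(pc, assembly_id = "fmt")
  expect_identical(names(from_pdb$chains), names(from_cif$chains))
  expect_equal(from_pdb$resolution, from_cif$resolution)
  for (cid in names(from_pdb$chains)) {
    expect_identical(from_pdb$chains[[cid]]$seqres,
                     from_cif$chains[[cid]]$seqres)
    expect_equal(canonical_atoms(from_pdb$chains[[cid]]),
                 canonical_atoms(from_cif$chains[[cid]]))
  }
})

test_that("entry filter enforces method, strict resolution and two proteins", {
  A <- build_chain(45, 1, "A")
  B <- build_chain(40, 2, "B")
  mk <- function(res, method = "X-RAY DIFFRACTION") {
    new_assembly("t", list(A, ppiface:::place_partner(B, dock_mode(23))),
                 resolution = res, method = method)
  }
  m2 <- two_chain_mapping()
  expect_true(passes_entry_filter(mk(2.4), m2))
  expect_false(passes_entry_filter(mk(2.5), m2))   # strict inequality
  expect_false(passes_entry_filter(mk(2.4, "SOLUTION NMR"), m2))
  m_same <- two_chain_mapping(accs = c("P1", "P1"))
  expect_false(passes_entry_filter(mk(1.2), m_same))
  expect_message(val <- passes_entry_filter(mk(NA_real_), m2))
  expect_false(val)
  # monotone in max_resolution
  hits <- vapply(c(1, 2, 2.4001, 3), function(mx) {
    passes_entry_filter(mk(2.4), m2, max_resolution = mx)
  }, TRUE)
  expect_identical(hits, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("hetero-dimer extraction respects the 6 A atom-pair rule", {
  near <- point_dimer(c(0, 0, 0), c(5.9, 0, 0))
  asmN <- new_assembly("t", list(near$chainX, near$chainY), resolution = 2)
  expect_length(extract_hetero_dimers(asmN, two_chain_mapping()), 1)
  asmF <- new_assembly("t", list(point_chain("A", c(0, 0, 0)),
                                 point_chain("B", c(6.1, 0, 0))),
                       resolution = 2)
  expect_length(extract_hetero_dimers(asmF, two_chain_mapping()), 0)
})

test_that("extraction equals the brute-force all-pairs oracle on a ring", {
  w <- generate_world(world_spec(n_families = 1, prots_per_family = 1,
                                 seqs_per_prot = 1, homomer_rate = 0,
                                 copy_number_dist = c(1),
                                 include_ring = TRUE, seed = 21))
  ring_ids <- grep("ring", names(w$assemblies), value = TRUE)
  asm <- w$assemblies[[ring_ids[1]]]
  dimers <- extract_hetero_dimers(asm, w$mapping)
  got <- sort(vapply(dimers, function(d) d$id, ""))
  # oracle: all chain pairs, different accessions, brute-force min distance
  cids <- sort(names(asm$chains))
  acc <- vapply(cids, function(cid) {
    w$mapping$accession[w$mapping$assembly_id == asm$assembly_id &
                          w$mapping$chain_id == cid]
  }, "")
  want <- character(0)
  for (i in seq_len(length(cids) - 1)) for (j in (i + 1):length(cids)) {
    if (acc[i] == acc[j]) next
    xi <- as.matrix(asm$chains[[cids[i]]]$atoms[, c("x", "y", "z")])
    xj <- as.matrix(asm$chains[[cids[j]]]$atoms[, c("x", "y", "z")])
    mind <- min(vapply(seq_len(nrow(xi)), function(k) {
      min(sqrt(colSums((t(xj) - xi[k, ])^2)))
    }, 0))
    if (mind < 6)
      want <- c(want, paste(asm$assembly_id, cids[i], cids[j], sep = ":"))
  }
  expect_identical(got, sort(want))
  # order of chains must not matter
  asm_rev <- new_assembly(asm$assembly_id, rev(asm$chains),
                          resolution = asm$resolution)
  got_rev <- sort(vapply(extract_hetero_dimers(asm_rev, w$mapping),
                         function(d) d$id, ""))
  expect_identical(got_rev, got)
})

test_that("identity mapping fallback honours length gate, coverage and ties", {
  refs <- c(Q1 = paste(rep("ACDEFGHIK", 5), collapse = ""),
            Q2 = paste(rep("LMNPQRSTV", 5), collapse = ""))
  ch <- build_chain(45, 3, "Z", seq = refs[["Q1"]])
  expect_identical(map_by_identity(ch, refs), "Q1")
  short <- point_chain("S", matrix(rnorm(29 * 3), 29, 3))
  expect_true(is.na(map_by_identity(short, refs)))
  # equidistant references: lexicographically smallest accession wins
  refs_tie <- c(B2 = refs[["Q1"]], A1 = refs[["Q1"]])
  expect_identical(map_by_identity(ch, refs_tie), "A1")
  # a reference too short to align 90% of the chain is not mapped
  refs_bad <- c(Q9 = substr(refs[["Q1"]], 1, 20))
  expect_true(is.na(map_by_identity(ch, refs_bad)))
})

test_that("chains missing from the mapping are skipped with a warning", {
  near <- point_dimer(c(0, 0, 0), c(5, 0, 0))
  asm <- new_assembly("t", list(near$chainX, near$chainY), resolution = 2)
  m1 <- two_chain_mapping(chains = "A", accs = "P1", fams = "F1")
  expect_warning(out <- extract_hetero_dimers(asm, m1), "no protein mapping")
  expect_length(out, 0)
})
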