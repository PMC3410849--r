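# Fixture builders shared by the tests. All fixtures are constructed in code
# at test time; nothing is read from disk except files the tests write.

two_chain_mapping <- function(assembly_id = "t", chains = c("A", "B"),
                              accs = c("P1", "P2"), fams = c("F1", "F2")) {
  data.frame(assembly_id = assembly_id, chain_id = chains, accession = accs,
             family = fams, stringsAsFactors = FALSE)
}

# a standard docked hetero-dimer on the default helical chains
docked_dimer <- function(mode_k = 1, seed_a = 1, seed_b = 2,
                         annotate = TRUE, use_dasa = TRUE,
                         assembly_id = "t") {
  A <- build_chain(90, seed_a, "A")
  B <- build_chain(40, seed_b, "B")
  modes <- ppiface:::unit_modes(world_spec())
  asm <- dock(A, B, modes[[mode_k]], assembly_id)
  d <- extract_hetero_dimers(asm, two_chain_mapping(assembly_id))[[1]]
  if (annotate)
    d <- annotate_interface(d, annotation_config(use_dasa = use_dasa))
  d
}

# minimal chain whose residues are single CB pseudo-atoms at given positions
point_chain <- function(chain_id, xyz, acc_len = nrow(xyz)) {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(res_idx = seq_len(nrow(xyz)), atom = "CB",
                      element = "C", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  new_chain(chain_id, paste(rep("A", nrow(xyz)), collapse = ""), atoms)
}

point_dimer <- function(xyzX, xyzY, assembly_id = "pt",
                        accs = c("P1", "P2"), fams = c("F1", "F2")) {
  ppiface:::new_hetero_dimer(assembly_id, point_chain("A", xyzX),
                             point_chain("B", xyzY), accs[1], accs[2],
                             fams[1], fams[2])
}

# lightweight pseudo-dimer carrying only grouping keys (for hierarchy and
# distribution tests that need no geometry)
key_dimer <- function(id, assembly_id, seqs, prots, fams) {
  structure(list(id = id, assembly_id = assembly_id,
                 seq_pair = sort(seqs), prot_pair = sort(prots),
                 fam_pair = sort(fams)),
            class = "HeteroDimer")
}

# synthetic records table for distribution tests: one row per comparison
key_record <- function(dimerA, dimerB, fps, seqA, seqB, protA, protB, fam,
                       asmA = "a1", asmB = "a2", l_rms = NA_real_) {
  data.frame(dimerA = dimerA, dimerB = dimerB, assemblyA = asmA,
             assemblyB = asmB, fps = fps, l_rms = l_rms, i_rms = NA_real_,
             fps_X = fps, fps_Y = fps, seq_keyA = seqA, seq_keyB = seqB,
             prot_keyA = protA, prot_keyB = protB, fam_key = fam,
             skipped = FALSE, skip_reason = "", stringsAsFactors = FALSE)
}

# the two-complex homomer scenario: complex 1 holds a single Px-Py
# interface; complex 2 holds two sequence-identical copies of Px bound to Py
# at two adjacent sites, the copies in contact (a homo-dimer connecting the
# two interfaces)
fig2_world <- function(focal_mode = 2) {
  Y <- build_chain(90, 101, "A")
  X <- build_chain(40, 102, "B")
  modes <- ppiface:::unit_modes(world_spec())
  c1 <- new_assembly("c1", list(Y, ppiface:::transform_chain(
    ppiface:::place_partner(X, modes[[focal_mode]]), chain_id = "B")),
    resolution = 2)
  c2 <- new_assembly("c2", list(
    ppiface:::transform_chain(Y, chain_id = "A"),
    ppiface:::transform_chain(ppiface:::place_partner(X, modes[[1]]),
                              chain_id = "B"),
    ppiface:::transform_chain(ppiface:::place_partner(X, modes[[2]]),
                              chain_id = "C")), resolution = 2)
  mapping <- rbind(two_chain_mapping("c1", c("A", "B"), c("PY", "PX"),
                                     c("FY", "FX")),
                   two_chain_mapping("c2", c("A", "B"), c("PY", "PX"),
                                     c("FY", "FX")),
                   two_chain_mapping("c2", "C", "PX", "FX"))
  assemblies <- list(c1 = c1, c2 = c2)
  dimers <- list()
  for (a in assemblies) {
    ad <- extract_hetero_dimers(a, mapping)
    ad <- lapply(ad, annotate_interface)
    dimers <- c(dimers, assign_copy_numbers(ad))
  }
  names(dimers) <- vapply(dimers, function(d) d$id, "")
  list(assemblies = assemblies, mapping = mapping, dimers = dimers)
}

# quick world for end-to-end tests: small but covering every level
small_world <- function(seed = 3, ...) {
  generate_world(world_spec(n_families = 2, prots_per_family = 2,
                            seqs_per_prot = 2, n_assemblies_per_seq = 2,
                            modes_per_pair = 2, mode_mixture = c(0.8, 0.2),
                            copy_number_dist = c(0.7, 0.3),
                            homomer_rate = 0, include_ring = FALSE,
                            seed = seed, ...))
}
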