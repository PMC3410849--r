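# Idealized helical chain geometry. Backbone atoms (N, CA, C, O) plus CB
# are placed along a straight alpha-helical curve: CA rise 1.5 A and twist
# 100 degrees per residue give consecutive CA-CA distances of 3.83 A and no
# non-consecutive CA pair below ~5 A. CB points radially outward, so a
# residue's "side" is its helical phase.
HELIX_RADIUS <- 2.3
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
CB_LENGTH <- 1.53
# axis-to-axis separation of docked helices; calibrated once so that the
# facing residues come within the 6 A contact rule and faces comfortably
# pass the minimum-face-size filter
DOCK_DISTANCE <- 11.6

.GEN_ALPHABET <- setdiff(names(.AA3), "G") # no glycine: every residue has CB

helix_phase <- function(i) (HELIX_TWIST * (i - 1)) %% (2 * pi)

helix_backbone <- function(n) {
  i <- seq_len(n)
  th <- HELIX_TWIST * (i - 1)
  ca <- cbind(HELIX_RADIUS * cos(th), HELIX_RADIUS * sin(th), HELIX_RISE * i)
  u_rad <- cbind(cos(th), sin(th), 0) # outward radial unit vector
  # tangent along the chain (one-sided at the termini)
  tang <- rbind(ca[2, ] - ca[1, ],
                if (n > 2) ca[3:n, ] - ca[1:(n - 2), ] else NULL,
                ca[n, ] - ca[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  atoms <- rbind(
    data.frame(res_idx = i, atom = "N", element = "N",
               ca - 0.70 * tang - 1.0 * u_rad),
    data.frame(res_idx = i, atom = "CA", element = "C", ca),
    data.frame(res_idx = i, atom = "C", element = "C",
               ca + 0.70 * tang - 1.0 * u_rad),
    data.frame(res_idx = i, atom = "O", element = "O",
               ca + 0.85 * tang - 2.1 * u_rad),
    data.frame(res_idx = i, atom = "CB", element = "C",
               ca + CB_LENGTH * u_rad))
  names(atoms)[4:6] <- c("x", "y", "z")
  atoms <- atoms[order(atoms$res_idx, match(atoms$atom,
                                            c("N", "CA", "C", "O", "CB"))), ]
  rownames(atoms) <- NULL
  atoms
}

#' Build an idealized synthetic protein chain
#'
#' Deterministic given `fold_seed`: a random (glycine-free) sequence on an
#' idealized helical backbone. Consecutive CA-CA distances are ~3.8 A and no
#' non-consecutive CA pair comes below 4 A (checked).
#'
#' @param length number of residues (>= 30, so the chain passes the
#'   identity-mapping length gate).
#' @param fold_seed RNG seed for the sequence.
#' @param chain_id chain label.
#' @param seq optional explicit sequence (length must match).
#' @return a [new_chain()] object.
#' @export
build_chain <- function(length, fold_seed = 1, chain_id = "A", seq = NULL) {
  stopifnot(length >= 30)
  if (is.null(seq)) {
    seq <- run_with_seed(fold_seed, function() {
      paste(sample(.GEN_ALPHABET, length, replace = TRUE), collapse = "")
    })
  }
  stopifnot(nchar(seq) == length)
  atoms <- helix_backbone(length)
  ca <- as.matrix(atoms[atoms$atom == "CA", c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(ca))
  off <- abs(row(dmat) - col(dmat)) > 1
  if (any(dmat[off] < 4)) stop("self-collision in generated backbone")
  new_chain(chain_id, seq, atoms)
}

transform_atoms <- function(atoms, spin = 0, shift = c(0, 0, 0)) {
  if (spin != 0) {
    R <- matrix(c(cos(spin), -sin(spin), 0, sin(spin), cos(spin), 0, 0, 0, 1),
                3, 3)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  atoms
}

transform_chain <- function(chain, spin = 0, shift = c(0, 0, 0),
                            chain_id = chain$chain_id) {
  new_chain(chain_id, chain$seqres, transform_atoms(chain$atoms, spin, shift),
            author_ids = chain$author_ids)
}

#' Binding-mode specification for docking
#'
#' A mode designates one patch per chain: a helical-phase band (the side of
#' the helix, `phi` +/- 50 degrees) intersected with the axial window the
#' partner covers. Distinct modes of [world_spec()] worlds use disjoint
#' windows on the receptor-side chain and well-separated phases on the
#' ligand-side chain, so faces of different modes are essentially disjoint.
#'
#' @param center_a patch-center residue index on chain A.
#' @param phi_a patch phase on chain A in degrees.
#' @param center_b,phi_b likewise for chain B.
#' @return list of class `dock_mode`.
#' @export
dock_mode <- function(center_a, phi_a = 0, center_b = NULL, phi_b = 0) {
  structure(list(center_a = center_a, phi_a = phi_a * pi / 180,
                 center_b = center_b, phi_b = phi_b * pi / 180),
            class = "dock_mode")
}

# chain B placed against canonical chain A according to a mode
place_partner <- function(chainB, mode, distance = DOCK_DISTANCE) {
  nb <- nchar(chainB$seqres)
  cb <- if (is.null(mode$center_b)) (nb + 1) / 2 else mode$center_b
  # spin so B's patch phase points back toward A's axis
  spin <- mode$phi_a + pi - (mode$phi_b + helix_phase(cb))
  # after spinning, shift so B's axis sits at distance along phi_a and the
  # patch centers share a z level
  shift <- c(distance * cos(mode$phi_a), distance * sin(mode$phi_a),
             HELIX_RISE * (mode$center_a - cb))
  # spin is about B's own axis (z), which passes through the origin before
  # shifting, so order spin-then-shift is exact
  transform_chain(chainB, spin = spin, shift = shift)
}

# residues of a canonical chain whose phase lies within half_band of phi and
# whose z falls inside [zlo, zhi]
patch_residues <- function(chain, phi, zlo, zhi, half_band = 50 * pi / 180) {
  n <- nchar(chain$seqres)
  i <- seq_len(n)
  dphi <- (helix_phase(i) - phi + pi) %% (2 * pi) - pi
  z <- HELIX_RISE * i
  i[abs(dphi) <= half_band & z >= zlo & z <= zhi]
}

# designated patches implied by a mode (geometric prediction of the faces)
mode_patches <- function(chainA, chainB, mode) {
  nb <- nchar(chainB$seqres)
  cb <- if (is.null(mode$center_b)) (nb + 1) / 2 else mode$center_b
  span_b <- HELIX_RISE * nb / 2
  zc <- HELIX_RISE * mode$center_a
  pa <- patch_residues(chainA, mode$phi_a, zc - span_b, zc + span_b)
  na <- nchar(chainA$seqres)
  span_a_lo <- max(1, mode$center_a - (cb - 1))
  span_a_hi <- min(na, mode$center_a + (nb - cb))
  pb <- patch_residues(chainB, mode$phi_b + helix_phase(cb),
                       HELIX_RISE * (cb - (mode$center_a - span_a_lo)),
                       HELIX_RISE * (cb + (span_a_hi - mode$center_a)))
  list(A = pa, B = pb)
}

#' Dock two chains in a given binding mode
#'
#' Chain A stays canonical (axis on z); chain B is spun and translated so
#' its designated patch faces A's designated patch at contact range.
#'
#' @param chainA,chainB chains from [build_chain()].
#' @param mode a [dock_mode()].
#' @param assembly_id identifier for the resulting assembly.
#' @param resolution reported resolution of the synthetic entry (default 2).
#' @return an [new_assembly()] with the two placed chains.
#' @export
dock <- function(chainA, chainB, mode, assembly_id = "synthetic",
                 resolution = 2.0) {
  placed <- place_partner(chainB, mode)
  new_assembly(assembly_id, list(chainA, placed), resolution = resolution)
}

#' Sequence variants with preserved backbone
#'
#' Substitutes residues at the given per-residue rate while keeping every
#' atom fixed, emulating point mutations of the same protein
#' (`kind = "point_mutation"`) or family-level homologs with preserved fold
#' (`kind = "family_divergence"`). Accession and family bookkeeping is the
#' caller's (the world generator assigns a new accession only for family
#' divergence).
#'
#' @param chain a chain.
#' @param kind "point_mutation" or "family_divergence" (label only; the
#'   substitution process is the same, rates differ by convention).
#' @param rate per-residue substitution probability in (0, 1).
#' @param seed RNG seed.
#' @return a chain with mutated SEQRES and identical coordinates.
#' @export
make_variants <- function(chain, kind = c("point_mutation",
                                          "family_divergence"),
                          rate, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(rate > 0, rate < 1)
  run_with_seed(seed, function() {
    s <- strsplit(chain$seqres, "")[[1]]
    hit <- runif(length(s)) < rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(old) {
        sample(setdiff(.GEN_ALPHABET, old), 1)
      }, "")
    }
    new_chain(chain$chain_id, paste(s, collapse = ""), chain$atoms,
              author_ids = chain$author_ids)
  })
}

#' World specification for the synthetic-assembly generator
#'
#' Defines the statistical structure of a generated data set: how many
#' family pairs (Interolog units), protein pairs per family, sequence
#' variants per protein, repeated structure determinations per sequence
#' pair, alternative binding modes and their mixture, interface copy
#' numbers, homomer topologies and sequence divergence rates.
#'
#' @param n_families number of family-pair units.
#' @param prots_per_family protein (accession) pairs per family pair.
#' @param seqs_per_prot sequence-variant pairs per protein pair.
#' @param n_assemblies_per_seq independent assemblies per sequence pair.
#' @param modes_per_pair distinct binding modes per family pair (1-3 with
#'   the default chain lengths).
#' @param mode_mixture probability of each mode (sums to 1).
#' @param copy_number_dist named or plain probability vector over interface
#'   copy numbers 1..6.
#' @param homomer_rate probability that an assembly realizes the two-copy
#'   homo-dimer topology (partner bound at two adjacent modes by two copies
#'   of the same chain, the copies in contact).
#' @param mutation_rate per-residue substitution rate between sequence
#'   variants of one protein.
#' @param family_divergence substitution fraction between proteins of one
#'   family.
#' @param len_a,len_b chain lengths (receptor-role and ligand-role).
#' @param include_ring append a structural-homomer ring unit (two same-family
#'   proteins alternating in a hexameric ring around a third protein).
#' @param resolution resolution stamped on generated entries.
#' @param seed world RNG seed (all randomness derives from it).
#' @return list of class `world_spec`.
#' @export
world_spec <- function(n_families = 6, prots_per_family = 2,
                       seqs_per_prot = 2, n_assemblies_per_seq = 2,
                       modes_per_pair = 2, mode_mixture = c(0.8, 0.2),
                       copy_number_dist = c(0.45, 0.25, 0.15, 0.08, 0.05,
                                            0.02),
                       homomer_rate = 0.2, mutation_rate = 0.03,
                       family_divergence = 0.35, len_a = 90, len_b = 40,
                       include_ring = TRUE, resolution = 2.0, seed = 1) {
  stopifnot(length(mode_mixture) == modes_per_pair,
            abs(sum(mode_mixture) - 1) < 1e-9, all(mode_mixture >= 0),
            abs(sum(copy_number_dist) - 1) < 1e-9,
            length(copy_number_dist) <= 6,
            homomer_rate >= 0, homomer_rate <= 1)
  if (modes_per_pair > 1) {
    # A-side mode windows must be at least one partner-length apart so that
    # the partner placements of different modes do not overlap axially
    spacing <- (len_a - 50) / (modes_per_pair - 1)
    if (spacing < len_b)
      stop("len_a too short for ", modes_per_pair,
           " axially disjoint modes with partner length ", len_b)
  }
  structure(list(n_families = n_families, prots_per_family = prots_per_family,
                 seqs_per_prot = seqs_per_prot,
                 n_assemblies_per_seq = n_assemblies_per_seq,
                 modes_per_pair = modes_per_pair, mode_mixture = mode_mixture,
                 copy_number_dist = copy_number_dist,
                 homomer_rate = homomer_rate, mutation_rate = mutation_rate,
                 family_divergence = family_divergence, len_a = len_a,
                 len_b = len_b, include_ring = include_ring,
                 resolution = resolution, seed = seed),
            class = "world_spec")
}

# the shared mode definitions of one family-pair unit: disjoint axial
# windows on the A-side chain, well-separated phases on the B-side chain
unit_modes <- function(spec) {
  m <- spec$modes_per_pair
  centers <- if (m == 1) (spec$len_a + 1) / 2
  else round(seq(25, spec$len_a - 25, length.out = m))
  lapply(seq_len(m), function(k) {
    dock_mode(center_a = centers[k], phi_a = 0,
              center_b = (spec$len_b + 1) / 2, phi_b = (k - 1) * 120)
  })
}

#' Expected fraction of cross-mode comparisons
#'
#' For worlds without homomer topologies, two independently generated
#' interfaces of the same pair fall in different binding modes with
#' probability `1 - sum(mixture^2)` (for two modes at p and 1-p this is
#' `2 p (1-p)`). Same-mode comparisons have Face Position Similarity 1,
#' cross-mode comparisons fall below 0.2, so this is the expected
#' D-SameSeq mass below any threshold in [0.2, 1).
#'
#' @param spec a [world_spec()].
#' @return expected cross-mode comparison fraction, or `NA` when homomer
#'   topologies are enabled (their modes are drawn dependently).
#' @export
expected_cross_mode_fraction <- function(spec) {
  if (spec$homomer_rate > 0) return(NA_real_)
  1 - sum(spec$mode_mixture^2)
}

#' Generate a synthetic world of biological assemblies
#'
#' Realizes the statistical structure of a [world_spec()]: per family pair,
#' a set of protein pairs (diverged sequences, preserved backbones), per
#' protein pair a set of point-mutant sequence pairs, per sequence pair
#' several assemblies with copy numbers and binding modes drawn from the
#' spec's distributions; optionally homo-dimer topologies (the same partner
#' bound twice at different sites by two interacting identical chains) and a
#' structural-homomer ring unit. Deterministic given `spec$seed`.
#'
#' @param spec a [world_spec()].
#' @param dir optional directory: when given, PDB files, `mapping.tsv`,
#'   `truth.tsv` and `manifest.json` are written there (byte-deterministic).
#' @return list of class `synthetic_world`: `assemblies` (named list),
#'   `mapping`, `truth` (one row per planted hetero-dimer), `expected`,
#'   `spec`.
#' @export
generate_world <- function(spec = world_spec(), dir = NULL) {
  run_with_seed(spec$seed, function() generate_world_impl(spec, dir))
}

generate_world_impl <- function(spec, dir) {
  modes <- unit_modes(spec)
  assemblies <- list()
  mapping <- list()
  truth <- list()
  add_map <- function(aid, cid, acc, fam) {
    mapping[[length(mapping) + 1]] <<- data.frame(
      assembly_id = aid, chain_id = cid, accession = acc, family = fam,
      stringsAsFactors = FALSE)
  }
  add_truth <- function(aid, cx, cy, mode, cn, homomer) {
    truth[[length(truth) + 1]] <<- data.frame(
      assembly_id = aid, chainX = cx, chainY = cy, mode_label = mode,
      copy_number = cn, homomer_context = homomer, stringsAsFactors = FALSE)
  }

  for (f in seq_len(spec$n_families)) {
    famA <- sprintf("FA%02d", f)
    famB <- sprintf("FB%02d", f)
    baseA <- build_chain(spec$len_a, fold_seed = NULL)
    baseB <- build_chain(spec$len_b, fold_seed = NULL)
    for (p in seq_len(spec$prots_per_family)) {
      accA <- sprintf("PA%02d_%02d", f, p)
      accB <- sprintf("PB%02d_%02d", f, p)
      protA <- if (p == 1) baseA else
        make_variants(baseA, "family_divergence", spec$family_divergence,
                      seed = NULL)
      protB <- if (p == 1) baseB else
        make_variants(baseB, "family_divergence", spec$family_divergence,
                      seed = NULL)
      for (s in seq_len(spec$seqs_per_prot)) {
        seqA <- if (s == 1) protA else
          make_variants(protA, "point_mutation", spec$mutation_rate,
                        seed = NULL)
        seqB <- if (s == 1) protB else
          make_variants(protB, "point_mutation", spec$mutation_rate,
                        seed = NULL)
        for (r in seq_len(spec$n_assemblies_per_seq)) {
          aid <- sprintf("w%03d_f%02dp%02ds%02dr%02d", spec$seed, f, p, s, r)
          homomer <- spec$modes_per_pair >= 2 &&
            runif(1) < spec$homomer_rate
          chains <- list()
          cid_pool <- c(LETTERS, paste0(LETTERS, rep(LETTERS, each = 26)))
          next_cid <- 1
          take_cid <- function() {
            cid <- cid_pool[next_cid]
            next_cid <<- next_cid + 1
            cid
          }
          if (homomer) {
            # two copies of the B-protein bound at adjacent modes; the two
            # copies touch end-to-end and form a sequence homomer
            k <- if (spec$modes_per_pair == 2) 1 else
              sample(seq_len(spec$modes_per_pair - 1), 1,
                     prob = spec$mode_mixture[-spec$modes_per_pair] *
                       spec$mode_mixture[-1])
            mode_pair <- sample(c(k, k + 1))
            ca <- take_cid()
            chains[[ca]] <- transform_chain(seqA, chain_id = ca)
            add_map(aid, ca, accA, famA)
            for (mk in mode_pair) {
              cb <- take_cid()
              chains[[cb]] <- transform_chain(
                place_partner(seqB, modes[[mk]]), chain_id = cb)
              add_map(aid, cb, accB, famB)
              add_truth(aid, ca, cb, mk, 2L, TRUE)
            }
          } else {
            ncopy <- sample(seq_along(spec$copy_number_dist), 1,
                            prob = spec$copy_number_dist)
            for (cpy in seq_len(ncopy)) {
              shift <- c(0, 200 * (cpy - 1), 0)
              mk <- sample(spec$modes_per_pair, 1, prob = spec$mode_mixture)
              ca <- take_cid()
              cb <- take_cid()
              chains[[ca]] <- transform_chain(seqA, shift = shift,
                                              chain_id = ca)
              chains[[cb]] <- transform_chain(
                place_partner(seqB, modes[[mk]]), shift = shift,
                chain_id = cb)
              add_map(aid, ca, accA, famA)
              add_map(aid, cb, accB, famB)
              add_truth(aid, ca, cb, mk, ncopy, FALSE)
            }
          }
          assemblies[[aid]] <- new_assembly(aid, chains,
                                            resolution = spec$resolution)
        }
      }
    }
  }

  if (spec$include_ring) {
    ring <- generate_ring_assemblies(spec)
    assemblies <- c(assemblies, ring$assemblies)
    mapping <- c(mapping, list(ring$mapping))
    truth <- c(truth, list(ring$truth))
  }

  world <- structure(list(assemblies = assemblies,
                          mapping = do.call(rbind, mapping),
                          truth = do.call(rbind, truth),
                          expected = list(
                            cross_mode_fraction =
                              expected_cross_mode_fraction(spec)),
                          spec = spec),
                     class = "synthetic_world")
  if (!is.null(dir)) write_world(world, dir)
  world
}

# hexameric ring of two same-family proteins (alternating) around a central
# chain from a third protein: the structural-homomer scenario
generate_ring_assemblies <- function(spec) {
  fam_ring <- "FRAB"
  fam_g <- "FRG"
  acc_a <- "PRA01"
  acc_b <- "PRB01"
  acc_g <- "PRG01"
  gamma <- build_chain(spec$len_a, fold_seed = NULL)
  alpha <- build_chain(spec$len_b, fold_seed = NULL)
  beta <- make_variants(alpha, "family_divergence", spec$family_divergence,
                        seed = NULL)
  z_center <- HELIX_RISE * (spec$len_a + 1) / 2
  assemblies <- list()
  mapping <- list()
  truth <- list()
  for (r in 1:2) {
    aid <- sprintf("w%03d_ring_r%02d", spec$seed, r)
    offset <- (r - 1) * 60 * pi / 180 # ring rotated between determinations
    chains <- list(G = transform_chain(gamma, chain_id = "G"))
    mapping[[length(mapping) + 1]] <- data.frame(
      assembly_id = aid, chain_id = "G", accession = acc_g, family = fam_g,
      stringsAsFactors = FALSE)
    cids <- c("A", "B", "C", "D", "E", "F")
    for (k in 0:5) {
      az <- k * 60 * pi / 180 + offset
      is_alpha <- k %% 2 == 0
      ch <- if (is_alpha) alpha else beta
      nb <- nchar(ch$seqres)
      spin <- az + pi - helix_phase((nb + 1) / 2)
      shift <- c(DOCK_DISTANCE * cos(az), DOCK_DISTANCE * sin(az),
                 z_center - HELIX_RISE * (nb + 1) / 2)
      cid <- cids[k + 1]
      chains[[cid]] <- transform_chain(ch, spin = spin, shift = shift,
                                       chain_id = cid)
      mapping[[length(mapping) + 1]] <- data.frame(
        assembly_id = aid, chain_id = cid,
        accession = if (is_alpha) acc_a else acc_b, family = fam_ring,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        assembly_id = aid, chainX = cid, chainY = "G",
        mode_label = paste0("ring_az", k * 60 + (r - 1) * 60),
        copy_number = 3L, homomer_context = TRUE, stringsAsFactors = FALSE)
    }
    assemblies[[aid]] <- new_assembly(aid, chains,
                                      resolution = spec$resolution)
  }
  list(assemblies = assemblies, mapping = do.call(rbind, mapping),
       truth = do.call(rbind, truth))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world (seed %d): %d assemblies, %d mapped chains, %d planted dimers\n",
              x$spec$seed, length(x$assemblies), nrow(x$mapping),
              nrow(x$truth)))
  invisible(x)
}

write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aid in names(world$assemblies))
    write_assembly_pdb(world$assemblies[[aid]], file.path(dir,
                                                          paste0(aid, ".pdb")))
  write.table(world$mapping, file.path(dir, "mapping.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(world$spec[setdiff(names(world$spec), "mode_mixture")],
                list(mode_mixture = world$spec$mode_mixture,
                     expected = world$expected,
                     n_assemblies = length(world$assemblies)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
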