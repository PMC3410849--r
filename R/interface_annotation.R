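#' Annotation configuration
#'
#' Parameters of the interface definition. The defaults express the standard
#' configuration: a 6 Angstrom contact rule complemented by a buried-surface
#' (dASA) rule that admits near-miss pairs just above the distance cutoff.
#'
#' @param distance_cutoff contact distance in Angstrom (default 6; 4 is the
#'   common strict alternative).
#' @param use_dasa enable the dASA admission rule (default TRUE).
#' @param dasa_min positivity floor in Angstrom^2 for dASA, absorbing
#'   quadrature discretisation noise (default 0.1).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom for the rolling-probe ASA
#'   (default 960).
#' @param both_directions evaluate the dASA rule in both chain orientations
#'   and union the results so annotation is symmetric (default TRUE); the
#'   one-directional mode exists for sensitivity analysis.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(distance_cutoff = 6, use_dasa = TRUE,
                              dasa_min = 0.1, probe_radius = 1.4,
                              n_points = 960, both_directions = TRUE) {
  stopifnot(distance_cutoff > 0, dasa_min >= 0, probe_radius > 0,
            n_points >= 100)
  structure(list(distance_cutoff = distance_cutoff, use_dasa = use_dasa,
                 dasa_min = dasa_min, probe_radius = probe_radius,
                 n_points = n_points, both_directions = both_directions),
            class = "annotation_config")
}

#' Per-residue solvent accessible surface area
#'
#' Rolling-probe (Shrake-Rupley) ASA with deterministic spiral quadrature
#' points, summed per residue.
#'
#' @param chain a [new_chain()] object (or any atom table with `res_idx`,
#'   `element`, `x`, `y`, `z`).
#' @param probe_radius probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960; >= 100).
#' @return named numeric vector of ASA in Angstrom^2, indexed by SEQRES
#'   position; unresolved residues are absent.
#' @export
residue_asa <- function(chain, probe_radius = 1.4, n_points = 960) {
  atoms <- if (inherits(chain, "Chain")) chain$atoms else chain
  atom_table_asa(atoms, probe_radius, n_points)
}

atom_table_asa <- function(atoms, probe_radius, n_points) {
  stopifnot(n_points >= 100)
  if (nrow(atoms) == 0) return(setNames(numeric(0), character(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  per_atom <- cpp_sasa(xyz, atom_radii(atoms$element), probe_radius,
                       as.integer(n_points))
  tapply(per_atom, atoms$res_idx, sum)
}

#' Change in accessible surface area upon binding
#'
#' For each residue of each chain: ASA of the chain alone minus ASA of the
#' same residue with the partner chain present (the partner replaces water).
#' Values below `tol` are clamped to zero.
#'
#' @param dimer a hetero-dimer from [extract_hetero_dimers()].
#' @param probe_radius,n_points see [residue_asa()].
#' @param tol positivity floor in Angstrom^2 (default 0.1).
#' @return list with named vectors `X` and `Y` of per-residue dASA.
#' @export
delta_asa <- function(dimer, probe_radius = 1.4, n_points = 960, tol = 0.1) {
  ax <- dimer$chainX$atoms
  ay <- dimer$chainY$atoms
  if (nrow(ax) == 0 || nrow(ay) == 0)
    stop("chain without resolved atoms in dimer ", dimer$id)
  asaX <- atom_table_asa(ax, probe_radius, n_points)
  asaY <- atom_table_asa(ay, probe_radius, n_points)
  # complex: offset chainY residue keys to keep the two chains separate
  off <- max(ax$res_idx) + 1000L
  both <- rbind(ax, transform(ay, res_idx = res_idx + off))
  asaC <- atom_table_asa(both, probe_radius, n_points)
  dX <- asaX - asaC[names(asaX)]
  yk <- as.character(as.integer(names(asaY)) + off)
  dY <- asaY - asaC[yk]
  names(dY) <- names(asaY)
  dX[dX < tol] <- 0
  dY[dY < tol] <- 0
  list(X = dX, Y = dY)
}

#' Annotate the interface of a hetero-dimer
#'
#' A residue pair (Rx, Ry) belongs to the interface when (a) its minimal
#' inter-atomic distance is below `distance_cutoff`, or (b) all three of:
#' both residues bury surface on binding (dASA > 0), Rx has no partner
#' within the cutoff, and Ry is the closest dASA-positive partner residue of
#' Rx. Rule (b) is applied in both chain orientations and the results are
#' unioned (configurable), which keeps the annotation symmetric. Every pair
#' carries its distance `d` and the dASA of both residues.
#'
#' @param dimer a hetero-dimer.
#' @param config an [annotation_config()].
#' @return the dimer with `$interface` set: a list with `pairs` (data.frame
#'   `posX`, `posY`, `d`, `dASA_X`, `dASA_Y`, `rule`) and the induced
#'   position sets `faceX`, `faceY`.
#' @export
annotate_interface <- function(dimer, config = annotation_config()) {
  ax <- dimer$chainX$atoms
  ay <- dimer$chainY$atoms
  if (nrow(ax) == 0 || nrow(ay) == 0)
    stop("chain without resolved atoms in dimer ", dimer$id)
  xyzX <- as.matrix(ax[, c("x", "y", "z")])
  xyzY <- as.matrix(ay[, c("x", "y", "z")])
  cp <- cpp_contact_pairs(xyzX, as.integer(ax$res_idx),
                          xyzY, as.integer(ay$res_idx),
                          config$distance_cutoff)
  pairs <- data.frame(posX = as.integer(cp[, "resA"]),
                      posY = as.integer(cp[, "resB"]),
                      d = cp[, "d"], dASA_X = rep(NA_real_, nrow(cp)),
                      dASA_Y = rep(NA_real_, nrow(cp)),
                      rule = rep("distance", nrow(cp)),
                      stringsAsFactors = FALSE)

  if (config$use_dasa) {
    das <- delta_asa(dimer, config$probe_radius, config$n_points,
                     config$dasa_min)
    pairs$dASA_X <- unname(das$X[as.character(pairs$posX)])
    pairs$dASA_Y <- unname(das$Y[as.character(pairs$posY)])
    add <- dasa_rule_pairs(ax, ay, das$X, das$Y, pairs$posX, config)
    if (config$both_directions) {
      addT <- dasa_rule_pairs(ay, ax, das$Y, das$X, pairs$posY, config)
      if (nrow(addT) > 0)
        addT <- data.frame(posX = addT$posY, posY = addT$posX, d = addT$d,
                           dASA_X = addT$dASA_Y, dASA_Y = addT$dASA_X,
                           rule = addT$rule, stringsAsFactors = FALSE)
      add <- unique(rbind(add, addT))
    }
    if (nrow(add) > 0) {
      dup <- paste(add$posX, add$posY) %in% paste(pairs$posX, pairs$posY)
      pairs <- rbind(pairs, add[!dup, , drop = FALSE])
    }
  }
  pairs <- pairs[order(pairs$posX, pairs$posY), , drop = FALSE]
  rownames(pairs) <- NULL
  dimer$interface <- list(pairs = pairs,
                          faceX = sort(unique(pairs$posX)),
                          faceY = sort(unique(pairs$posY)))
  dimer
}

# rule (b), direction A -> B: A-residues burying surface but with no contact
# partner within the cutoff adopt their closest dASA-positive B-residue
dasa_rule_pairs <- function(atomsA, atomsB, dasA, dasB, contactedA, config) {
  empty <- data.frame(posX = integer(0), posY = integer(0), d = numeric(0),
                      dASA_X = numeric(0), dASA_Y = numeric(0),
                      rule = character(0), stringsAsFactors = FALSE)
  candA <- as.integer(names(dasA)[dasA > 0])
  candA <- setdiff(candA, unique(contactedA))
  candB <- as.integer(names(dasB)[dasB > 0])
  if (length(candA) == 0 || length(candB) == 0) return(empty)
  subA <- atomsA[atomsA$res_idx %in% candA, , drop = FALSE]
  # check "no partner within cutoff" against ALL partner residues
  dm_all <- cpp_res_min_dist(as.matrix(subA[, c("x", "y", "z")]),
                             match(subA$res_idx, candA), length(candA),
                             as.matrix(atomsB[, c("x", "y", "z")]),
                             rep(1L, nrow(atomsB)), 1L)
  free <- dm_all[, 1] >= config$distance_cutoff
  candA <- candA[free]
  if (length(candA) == 0) return(empty)
  subA <- atomsA[atomsA$res_idx %in% candA, , drop = FALSE]
  subB <- atomsB[atomsB$res_idx %in% candB, , drop = FALSE]
  dm <- cpp_res_min_dist(as.matrix(subA[, c("x", "y", "z")]),
                         match(subA$res_idx, candA), length(candA),
                         as.matrix(subB[, c("x", "y", "z")]),
                         match(subB$res_idx, candB), length(candB))
  ry <- candB[apply(dm, 1, which.min)] # ties: smaller position
  d <- apply(dm, 1, min)
  ok <- is.finite(d)
  data.frame(posX = candA[ok], posY = ry[ok], d = d[ok],
             dASA_X = unname(dasA[as.character(candA[ok])]),
             dASA_Y = unname(dasB[as.character(ry[ok])]),
             rule = rep("dasa", sum(ok)), stringsAsFactors = FALSE)
}

#' Minimum-face-size filter
#'
#' A hetero-dimer is retained only when both faces have at least
#' `min_face_size` interacting residues.
#'
#' @param annotation the `$interface` of an annotated dimer.
#' @param min_face_size minimum residues per face (default 5).
#' @return logical.
#' @export
passes_size_filter <- function(annotation, min_face_size = 5) {
  length(annotation$faceX) >= min_face_size &&
    length(annotation$faceY) >= min_face_size
}

#' Assign interface copy numbers within an assembly
#'
#' The copy number of a hetero-dimer is the number of dimers extracted from
#' the same assembly whose unordered SEQRES sequence pair is identical
#' (including the dimer itself).
#'
#' @param dimers list of hetero-dimers from one assembly.
#' @return the list with `$copy_number` set on every dimer.
#' @export
assign_copy_numbers <- function(dimers) {
  if (length(dimers) == 0) return(dimers)
  stopifnot(length(unique(vapply(dimers, function(d) d$assembly_id, ""))) == 1)
  keys <- vapply(dimers, function(d) paste(d$seq_pair, collapse = "\r"), "")
  counts <- table(keys)
  for (i in seq_along(dimers))
    dimers[[i]]$copy_number <- as.integer(counts[[keys[i]]])
  dimers
}

#' Serialize interface annotations to TSV
#'
#' One row per annotated residue pair across all dimers.
#'
#' @param dimers list of annotated hetero-dimers.
#' @param path output TSV path (optional).
#' @return the data.frame, invisibly when `path` is given.
#' @export
annotation_table <- function(dimers, path = NULL) {
  rows <- lapply(dimers, function(d) {
    if (is.null(d$interface) || nrow(d$interface$pairs) == 0) return(NULL)
    cbind(data.frame(assembly_id = d$assembly_id,
                     chainX = d$chainX$chain_id, chainY = d$chainY$chain_id,
                     stringsAsFactors = FALSE),
          d$interface$pairs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(assembly_id = character(0), chainX = character(0),
                      chainY = character(0), posX = integer(0),
                      posY = integer(0), d = numeric(0), dASA_X = numeric(0),
                      dASA_Y = numeric(0), rule = character(0))
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
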