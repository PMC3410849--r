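BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Decide which chain of dimerB corresponds to dimerA's X side.
# Preference: protein accession match, then family match. When both
# orientations score equally (e.g. both chains from one family), the
# orientation maximising the combined Face Position Similarity is used,
# with ties resolved by pairing lexicographically smallest accessions.
match_chains <- function(dimerA, dimerB) {
  score <- function(orient) {
    bx <- if (orient == "XY") "X" else "Y"
    by <- if (orient == "XY") "Y" else "X"
    unname(2 * ((dimerA$acc[["X"]] == dimerB$acc[[bx]]) +
                  (dimerA$acc[["Y"]] == dimerB$acc[[by]])) +
             (dimerA$fam[["X"]] == dimerB$fam[[bx]]) +
             (dimerA$fam[["Y"]] == dimerB$fam[[by]]))
  }
  s <- c(XY = score("XY"), YX = score("YX"))
  if (s["XY"] == s["YX"]) return(NA_character_) # ambiguous
  names(which.max(s))
}

b_side <- function(orientation, side) {
  if (orientation == "XY") side else setdiff(c("X", "Y"), side)
}

#' Residue correspondence between two hetero-dimers
#'
#' Chains are paired X to X' and Y to Y' (by accession, then family; see
#' Details), then for each side a position map is built: the identity on
#' positions resolved in both when the SEQRES sequences are equal, otherwise
#' a global alignment of the two SEQRES sequences restricted to aligned,
#' non-gap positions resolved in both structures. All comparisons operate on
#' these common residues only.
#'
#' @param dimerA,dimerB annotated hetero-dimers.
#' @param orientation "XY" (A's X corresponds to B's X) or "YX"; `NULL`
#'   resolves it automatically.
#' @param min_coverage comparisons whose mapped fraction falls below this
#'   floor are flagged unusable (default 0.3).
#' @return list with `mapX`, `mapY` (named integer vectors, position in A ->
#'   position in B), `coverage`, `orientation`, `usable`.
#' @export
common_residues <- function(dimerA, dimerB, orientation = NULL,
                            min_coverage = 0.3) {
  if (is.null(orientation)) {
    orientation <- match_chains(dimerA, dimerB)
    if (is.na(orientation)) orientation <- "XY" # caller handles ambiguity
  }
  side_map <- function(side) {
    chA <- dimerA[[paste0("chain", side)]]
    chB <- dimerB[[paste0("chain", b_side(orientation, side))]]
    resA <- resolved_positions(chA)
    resB <- resolved_positions(chB)
    if (chA$seqres == chB$seqres) {
      common <- intersect(resA, resB)
      map <- setNames(common, common)
    } else {
      al <- Biostrings::pairwiseAlignment(chA$seqres, chB$seqres,
                                          type = "global",
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 10, gapExtension = 0.5)
      map <- alignment_position_map(al)
      keep <- as.integer(names(map)) %in% resA & map %in% resB
      map <- setNames(as.integer(map[keep]), names(map)[keep])
    }
    denom <- min(nchar(chA$seqres), nchar(chB$seqres))
    list(map = map, n = length(map), denom = denom)
  }
  mx <- side_map("X")
  my <- side_map("Y")
  coverage <- (mx$n + my$n) / (mx$denom + my$denom)
  list(mapX = mx$map, mapY = my$map, coverage = coverage,
       orientation = orientation, usable = coverage >= min_coverage)
}

#' Face Position Similarity
#'
#' Size of the intersection of two faces divided by the geometric mean of
#' their sizes, after restriction to common residues. For faces of sizes 3
#' and 4 sharing two positions this is 2 / sqrt(3 * 4) = 2 / 3.5 (one
#' decimal).
#'
#' @param faceA,faceB integer sets of SEQRES positions (A- and B-side faces).
#' @param map named integer vector, position in A -> position in B, from
#'   [common_residues()].
#' @return similarity in `[0, 1]`, or `NA` when either face is empty after
#'   reduction to common residues (undefined similarity).
#' @export
face_position_similarity <- function(faceA, faceB, map) {
  fA <- intersect(faceA, as.integer(names(map)))
  fB <- intersect(faceB, unname(map))
  if (length(fA) == 0 || length(fB) == 0) return(NA_real_)
  inter <- sum(unname(map[as.character(fA)]) %in% fB)
  inter / sqrt(length(fA) * length(fB))
}

#' Combine the two per-side Face Position Similarities
#'
#' Arithmetic mean; both per-side values are kept in every similarity record
#' so alternative combiners can be applied downstream.
#'
#' @param fps_X,fps_Y per-side similarities.
#' @return combined similarity.
#' @export
combine_sides <- function(fps_X, fps_Y) (fps_X + fps_Y) / 2

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of paired point sets via singular value
#' decomposition, constrained to a proper rotation (no reflection).
#'
#' @param coordsA,coordsB N x 3 matrices of paired coordinates; B is rotated
#'   onto A.
#' @param check_degenerate error on collinear point sets (default TRUE).
#' @return list with `rotation` (3 x 3, applied as `coordsB %*% rotation`),
#'   `translation` (length-3), and `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(coordsA, coordsB, check_degenerate = TRUE) {
  stopifnot(ncol(coordsA) == 3, ncol(coordsB) == 3)
  n <- nrow(coordsA)
  if (n < 3 || nrow(coordsB) != n)
    stop("superposition requires >= 3 paired points")
  cA <- colMeans(coordsA)
  cB <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2, cA)
  Bc <- sweep(coordsB, 2, cB)
  if (check_degenerate) {
    sv <- svd(Ac)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12))
      stop("degenerate (collinear) point set")
  }
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  list(rotation = R, translation = as.numeric(cA - cB %*% R), rmsd = rmsd)
}

# paired backbone coordinates over mapped residues; atoms present in both
# residues among `atom_set` are paired. CA-only fallback when a residue has
# no complete backbone overlap.
paired_backbone <- function(chA, chB, map, atom_set = BACKBONE_ATOMS) {
  A <- list(); B <- list()
  aA <- chA$atoms; aB <- chB$atoms
  for (k in seq_along(map)) {
    pa <- as.integer(names(map)[k])
    pb <- unname(map[k])
    ra <- aA[aA$res_idx == pa & aA$atom %in% atom_set, , drop = FALSE]
    rb <- aB[aB$res_idx == pb & aB$atom %in% atom_set, , drop = FALSE]
    common <- intersect(ra$atom, rb$atom)
    if (length(common) == 0) next
    ra <- ra[match(common, ra$atom), , drop = FALSE]
    rb <- rb[match(common, rb$atom), , drop = FALSE]
    A[[length(A) + 1]] <- as.matrix(ra[, c("x", "y", "z")])
    B[[length(B) + 1]] <- as.matrix(rb[, c("x", "y", "z")])
  }
  if (length(A) == 0)
    return(list(A = matrix(numeric(0), 0, 3), B = matrix(numeric(0), 0, 3),
                n_res = 0))
  list(A = do.call(rbind, A), B = do.call(rbind, B), n_res = length(A))
}

# receptor side: more residues (combined over both dimers so the choice is
# symmetric in A and B); ties by smaller accession
receptor_side <- function(dimerA, dimerB, orientation) {
  lenX <- nchar(dimerA$chainX$seqres) +
    nchar(dimerB[[paste0("chain", b_side(orientation, "X"))]]$seqres)
  lenY <- nchar(dimerA$chainY$seqres) +
    nchar(dimerB[[paste0("chain", b_side(orientation, "Y"))]]$seqres)
  if (lenX > lenY) return("X")
  if (lenY > lenX) return("Y")
  if (dimerA$acc["X"] <= dimerA$acc["Y"]) "X" else "Y"
}

#' Ligand RMSD after receptor superposition (L_rms)
#'
#' The receptors (larger chains) of the two dimers are optimally superposed
#' on their common-residue backbone atoms; the same transform is applied to
#' the second dimer's ligand and the backbone RMSD between the two ligands
#' over common residues is returned. Captures both alternative binding
#' positions and conformational change of the ligand.
#'
#' @param dimerA,dimerB hetero-dimers.
#' @param corr correspondence from [common_residues()].
#' @return RMSD in Angstrom, or `NA` when fewer than 3 common receptor or
#'   ligand residues are available.
#' @export
l_rms <- function(dimerA, dimerB, corr) {
  rec <- receptor_side(dimerA, dimerB, corr$orientation)
  lig <- setdiff(c("X", "Y"), rec)
  map_rec <- corr[[paste0("map", rec)]]
  map_lig <- corr[[paste0("map", lig)]]
  recA <- dimerA[[paste0("chain", rec)]]
  recB <- dimerB[[paste0("chain", b_side(corr$orientation, rec))]]
  ligA <- dimerA[[paste0("chain", lig)]]
  ligB <- dimerB[[paste0("chain", b_side(corr$orientation, lig))]]
  pr <- paired_backbone(recA, recB, map_rec)
  pl <- paired_backbone(ligA, ligB, map_lig)
  if (pr$n_res < 3 || pl$n_res < 3) return(NA_real_)
  fit <- kabsch_superpose(pr$A, pr$B, check_degenerate = FALSE)
  moved <- sweep(pl$B %*% fit$rotation, 2, fit$translation, "+")
  sqrt(mean(rowSums((pl$A - moved)^2)))
}

#' Interface RMSD (I_rms)
#'
#' Backbone RMSD over the interface region common to both dimers: the union
#' of the two annotations' faces, mapped through the residue correspondence,
#' superposed jointly across both chains. Compares the shapes of the shared
#' interface regions.
#'
#' @inheritParams l_rms
#' @return RMSD in Angstrom, or `NA` when the common interface has fewer
#'   than 3 residues.
#' @export
i_rms <- function(dimerA, dimerB, corr) {
  side_pairs <- function(side) {
    map <- corr[[paste0("map", side)]]
    bside <- b_side(corr$orientation, side)
    faceA <- dimerA$interface[[paste0("face", side)]]
    faceB <- dimerB$interface[[paste0("face", bside)]]
    keep <- as.integer(names(map)) %in% faceA | unname(map) %in% faceB
    sub <- map[keep]
    if (length(sub) == 0)
      return(list(A = matrix(numeric(0), 0, 3), B = matrix(numeric(0), 0, 3),
                  n_res = 0))
    paired_backbone(dimerA[[paste0("chain", side)]],
                    dimerB[[paste0("chain", bside)]], sub)
  }
  px <- side_pairs("X")
  py <- side_pairs("Y")
  if (px$n_res + py$n_res < 3) return(NA_real_)
  A <- rbind(px$A, py$A)
  B <- rbind(px$B, py$B)
  kabsch_superpose(A, B, check_degenerate = FALSE)$rmsd
}

#' Compare two hetero-dimers of the same interaction
#'
#' Resolves the chain correspondence, reduces to common residues and
#' computes the requested similarity measures. Ambiguous chain pairings
#' (both orientations equally supported by accessions and families) are
#' resolved in favour of the orientation with the higher combined Face
#' Position Similarity.
#'
#' @param dimerA,dimerB annotated hetero-dimers.
#' @param measures subset of `c("fps", "l_rms", "i_rms")`.
#' @param min_coverage coverage floor for [common_residues()].
#' @return one-row data.frame (a similarity record): ids, orientation,
#'   coverage, `fps_X`, `fps_Y`, `fps`, `l_rms`, `i_rms`, `skipped`,
#'   `skip_reason`.
#' @export
compare_dimers <- function(dimerA, dimerB,
                           measures = c("fps", "l_rms", "i_rms"),
                           min_coverage = 0.3) {
  rec <- data.frame(dimerA = dimerA$id, dimerB = dimerB$id,
                    assemblyA = dimerA$assembly_id,
                    assemblyB = dimerB$assembly_id,
                    orientation = NA_character_, coverage = NA_real_,
                    fps_X = NA_real_, fps_Y = NA_real_, fps = NA_real_,
                    l_rms = NA_real_, i_rms = NA_real_, skipped = FALSE,
                    skip_reason = "", stringsAsFactors = FALSE)
  orientation <- match_chains(dimerA, dimerB)
  corrs <- if (is.na(orientation)) {
    list(common_residues(dimerA, dimerB, "XY", min_coverage),
         common_residues(dimerA, dimerB, "YX", min_coverage))
  } else {
    list(common_residues(dimerA, dimerB, orientation, min_coverage))
  }
  evaluate_fps <- function(corr) {
    fx <- face_position_similarity(dimerA$interface$faceX,
                                   dimerB$interface[[paste0("face",
                                     b_side(corr$orientation, "X"))]],
                                   corr$mapX)
    fy <- face_position_similarity(dimerA$interface$faceY,
                                   dimerB$interface[[paste0("face",
                                     b_side(corr$orientation, "Y"))]],
                                   corr$mapY)
    list(fx = fx, fy = fy,
         comb = if (is.na(fx) || is.na(fy)) -Inf else combine_sides(fx, fy))
  }
  evals <- lapply(corrs, evaluate_fps)
  pick <- 1
  if (length(corrs) == 2) {
    if (evals[[2]]$comb > evals[[1]]$comb) pick <- 2
    else if (evals[[2]]$comb == evals[[1]]$comb) {
      # tie: pair smallest accessions
      bx <- which.min(dimerB$acc)
      ax <- which.min(dimerA$acc)
      pick <- if ((ax == 1) == (bx == 1)) 1 else 2
    }
  }
  corr <- corrs[[pick]]
  ev <- evals[[pick]]
  rec$orientation <- corr$orientation
  rec$coverage <- corr$coverage
  if (!corr$usable) {
    rec$skipped <- TRUE
    rec$skip_reason <- "coverage_floor"
    return(rec)
  }
  if ("fps" %in% measures) {
    if (is.na(ev$fx) || is.na(ev$fy)) {
      rec$skipped <- TRUE
      rec$skip_reason <- "empty_face_after_reduction"
      return(rec)
    }
    rec$fps_X <- ev$fx
    rec$fps_Y <- ev$fy
    rec$fps <- combine_sides(ev$fx, ev$fy)
  }
  if ("l_rms" %in% measures) rec$l_rms <- l_rms(dimerA, dimerB, corr)
  if ("i_rms" %in% measures) rec$i_rms <- i_rms(dimerA, dimerB, corr)
  rec
}
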