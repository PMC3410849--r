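#' @useDynLib ppiface, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rmultinom runif
#' @importFrom utils read.delim write.table combn head
NULL

# van der Waals radii (Angstrom) used by the rolling-probe ASA engine
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.VDW_DEFAULT <- 1.70

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- setNames(names(.AA3), .AA3)

aa_three <- function(one) unname(.AA3[strsplit(one, "")[[1]]])
aa_one <- function(three) {
  out <- unname(.AA1[three])
  out[is.na(out)] <- "X"
  out
}

#' Construct a protein chain
#'
#' A chain couples the full deposited sequence (SEQRES) with the resolved
#' atoms. Atoms reference residues by their 1-based SEQRES position, so faces
#' are comparable across entries regardless of author numbering.
#'
#' @param chain_id single-character chain label, unique within an assembly.
#' @param seqres one-letter amino-acid sequence string (full sequence,
#'   including residues without resolved coordinates).
#' @param atoms data.frame with columns `res_idx` (1-based SEQRES position),
#'   `atom` (label, e.g. "CA"), `element`, `x`, `y`, `z` (Angstrom).
#' @param author_ids optional integer vector of author residue numbers per
#'   SEQRES position (metadata only).
#' @return an object of class `Chain`.
#' @export
new_chain <- function(chain_id, seqres, atoms, author_ids = NULL) {
  stopifnot(nchar(seqres) >= 1)
  n <- nchar(seqres)
  if (nrow(atoms) > 0) {
    stopifnot(all(atoms$res_idx >= 1 & atoms$res_idx <= n),
              all(is.finite(atoms$x)), all(is.finite(atoms$y)),
              all(is.finite(atoms$z)), all(nzchar(atoms$element)))
  }
  if (is.null(author_ids)) author_ids <- seq_len(n)
  structure(list(chain_id = chain_id, seqres = seqres,
                 res_names = aa_three(seqres), atoms = atoms,
                 author_ids = author_ids),
            class = "Chain")
}

#' @export
print.Chain <- function(x, ...) {
  cat(sprintf("Chain %s: %d residues (%d resolved), %d atoms\n", x$chain_id,
              nchar(x$seqres), length(resolved_positions(x)), nrow(x$atoms)))
  invisible(x)
}

chain_xyz <- function(chain, positions = NULL, atom_names = NULL) {
  a <- chain$atoms
  if (!is.null(positions)) a <- a[a$res_idx %in% positions, , drop = FALSE]
  if (!is.null(atom_names)) a <- a[a$atom %in% atom_names, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

resolved_positions <- function(chain) sort(unique(chain$atoms$res_idx))

atom_radii <- function(elements) {
  r <- .VDW_RADII[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elements[unknown]), collapse = ", "),
            "; using default radius ", .VDW_DEFAULT)
    r[unknown] <- .VDW_DEFAULT
  }
  unname(r)
}

#' Construct a biological assembly
#'
#' @param assembly_id identifier (used as the key into the chain-to-protein
#'   mapping table).
#' @param chains list of [new_chain()] objects with unique chain ids.
#' @param resolution resolution in Angstrom, or `NA` when absent.
#' @param method experimental method tag (default "X-RAY DIFFRACTION").
#' @return an object of class `Assembly`.
#' @export
new_assembly <- function(assembly_id, chains, resolution = NA_real_,
                         method = "X-RAY DIFFRACTION") {
  ids <- vapply(chains, function(ch) ch$chain_id, "")
  stopifnot(!anyDuplicated(ids), is.na(resolution) || resolution > 0)
  names(chains) <- ids
  structure(list(assembly_id = assembly_id, chains = chains,
                 resolution = resolution, method = method),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly %s: %d chains [%s], resolution %s, %s\n",
              x$assembly_id, length(x$chains),
              paste(names(x$chains), collapse = ","),
              ifelse(is.na(x$resolution), "NA",
                     sprintf("%.2f A", x$resolution)), x$method))
  invisible(x)
}

#' Read a biological assembly from a PDB or mmCIF file
#'
#' Residues are re-indexed onto the full SEQRES sequence: when author residue
#' numbers do not directly index SEQRES, the resolved residue sequence is
#' globally aligned to SEQRES. Unresolved residues remain present (atom-less).
#' Hetero records (waters, ligands, non-standard residues) are dropped; only
#' standard amino acids participate in the analysis.
#'
#' @param path file path.
#' @param format "pdb", "cif" or "auto" (by extension).
#' @param assembly_id identifier; defaults to the file name without extension.
#' @return an [new_assembly()] object.
#' @export
load_assembly <- function(path, format = c("auto", "pdb", "cif"),
                          assembly_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (is.null(assembly_id)) assembly_id <- sub("\\.[^.]+$", "", basename(path))
  parsed <- if (format == "pdb") parse_pdb_file(path) else parse_cif_file(path)
  atoms <- parsed$atoms
  atoms <- atoms[atoms$resid %in% names(.AA1), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no protein chains in ", path)
  chains <- list()
  for (cid in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == cid, , drop = FALSE]
    seqres3 <- parsed$seqres[[cid]]
    chains[[cid]] <- build_chain_from_atoms(cid, ca, seqres3)
  }
  new_assembly(assembly_id, chains, parsed$resolution, parsed$method)
}

# map resolved residues (author numbering) onto SEQRES positions
build_chain_from_atoms <- function(chain_id, ca, seqres3) {
  resno <- ca$resno
  ures <- unique(resno)
  resolved3 <- ca$resid[match(ures, resno)]
  if (is.null(seqres3)) {
    seqres3 <- resolved3
    pos_of <- setNames(seq_along(ures), ures)
  } else {
    n <- length(seqres3)
    direct <- all(ures >= 1 & ures <= n) &&
      all(seqres3[ures] == resolved3)
    if (direct) {
      pos_of <- setNames(ures, ures)
    } else {
      sr1 <- paste(aa_one(seqres3), collapse = "")
      rs1 <- paste(aa_one(resolved3), collapse = "")
      al <- Biostrings::pairwiseAlignment(rs1, sr1, type = "global",
                                          gapOpening = 10, gapExtension = 0.5)
      map <- alignment_position_map(al)
      if (length(map) < length(ures))
        warning("chain ", chain_id, ": ", length(ures) - length(map),
                " resolved residue(s) could not be placed on SEQRES")
      pos_of <- setNames(unname(map), ures[as.integer(names(map))])
    }
  }
  keep <- as.character(ca$resno) %in% names(pos_of)
  ca <- ca[keep, , drop = FALSE]
  atoms <- data.frame(res_idx = unname(pos_of[as.character(ca$resno)]),
                      atom = ca$elety, element = ca$elesy,
                      x = ca$x, y = ca$y, z = ca$z,
                      stringsAsFactors = FALSE)
  author <- rep(NA_integer_, length(seqres3))
  author[pos_of] <- as.integer(names(pos_of))
  new_chain(chain_id, paste(aa_one(seqres3), collapse = ""), atoms,
            author_ids = author)
}

# pattern position -> subject position for aligned, non-gap sites
alignment_position_map <- function(al) {
  pm <- Biostrings::aligned(Biostrings::pattern(al))
  sm <- Biostrings::aligned(Biostrings::subject(al))
  p <- strsplit(as.character(pm), "")[[1]]
  s <- strsplit(as.character(sm), "")[[1]]
  ip <- Biostrings::start(Biostrings::pattern(al)) - 1L
  is <- Biostrings::start(Biostrings::subject(al)) - 1L
  out <- integer(0)
  for (k in seq_along(p)) {
    gp <- p[k] == "-"
    gs <- s[k] == "-"
    if (!gp) ip <- ip + 1L
    if (!gs) is <- is + 1L
    if (!gp && !gs) out[as.character(ip)] <- is
  }
  out
}

parse_pdb_file <- function(path) {
  lines <- readLines(path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE),
                  error = function(e) stop("unparseable PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy))))
    elesy <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety), elesy = trimws(elesy),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres) > 0)
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))
  res <- NA_real_
  m <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(m) > 0) {
    tail_part <- sub(".*RESOLUTION\\.?", "", m[1])
    num <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
    if (length(num) > 0) res <- as.numeric(num)
  }
  method <- "UNKNOWN"
  m <- grep("^EXPDTA", lines, value = TRUE)
  if (length(m) > 0) method <- trimws(sub("^EXPDTA", "", m[1]))
  list(atoms = atoms, seqres = seqres, resolution = res, method = method)
}

parse_cif_file <- function(path) {
  lines <- readLines(path)
  loops <- cif_loops(lines)
  as <- loops[["atom_site"]]
  if (is.null(as)) stop("unparseable mmCIF file ", path, ": no atom_site loop")
  grp <- if ("group_PDB" %in% names(as)) as$group_PDB else "ATOM"
  keep <- grp == "ATOM"
  atoms <- data.frame(chain = as$auth_asym_id[keep],
                      resno = as.integer(as$auth_seq_id[keep]),
                      resid = as$auth_comp_id[keep],
                      elety = as$auth_atom_id[keep],
                      elesy = as$type_symbol[keep],
                      x = as.numeric(as$Cartn_x[keep]),
                      y = as.numeric(as$Cartn_y[keep]),
                      z = as.numeric(as$Cartn_z[keep]),
                      stringsAsFactors = FALSE)
  seqres <- NULL
  ps <- loops[["pdbx_poly_seq_scheme"]]
  if (!is.null(ps)) {
    seqres <- lapply(split(seq_len(length(ps$asym_id)), ps$asym_id), function(ix) {
      ps$mon_id[ix][order(as.integer(ps$seq_id[ix]))]
    })
  }
  res <- NA_real_
  m <- grep("^_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(m) > 0) res <- suppressWarnings(as.numeric(strsplit(trimws(m[1]),
                                                                 "\\s+")[[1]][2]))
  method <- "UNKNOWN"
  m <- grep("^_exptl\\.method", lines, value = TRUE)
  if (length(m) > 0) {
    v <- sub("^_exptl\\.method\\s+", "", m[1])
    method <- gsub("^['\"]|['\"]$", "", trimws(v))
  }
  list(atoms = atoms, seqres = seqres, resolution = res, method = method)
}

# minimal mmCIF loop reader (simple tokenised dialect, as emitted by
# write_assembly_cif and by standard writers for the loops used here)
cif_loops <- function(lines) {
  out <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      i <- i + 1
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i]))
        i <- i + 1
      }
      if (length(tags) == 0) next
      cat_name <- sub("\\..*$", "", sub("^_", "", tags[1]))
      fields <- sub("^[^.]*\\.", "", tags)
      rows <- list()
      while (i <= n) {
        ln <- trimws(lines[i])
        if (ln == "" || grepl("^(loop_|_|#|data_)", ln)) break
        rows[[length(rows) + 1]] <- scan(text = ln, what = "character",
                                         quiet = TRUE)
        i <- i + 1
      }
      if (length(rows) > 0) {
        m <- do.call(rbind, rows)
        df <- as.list(as.data.frame(m, stringsAsFactors = FALSE))
        names(df) <- fields[seq_len(ncol(m))]
        out[[cat_name]] <- df
      }
    } else i <- i + 1
  }
  out
}

#' Write an assembly as a PDB file
#'
#' Emits EXPDTA, resolution remark, SEQRES records and ATOM coordinates in
#' fixed-width PDB format. Output is deterministic (byte-identical for equal
#' assemblies).
#'
#' @param assembly an [new_assembly()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(assembly, path) {
  out <- c(sprintf("HEADER    SYNTHETIC COMPLEX                       01-JAN-00   %s",
                   substr(toupper(assembly$assembly_id), 1, 4)),
           sprintf("EXPDTA    %s", assembly$method))
  if (!is.na(assembly$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          assembly$resolution))
  for (ch in assembly$chains) {
    res3 <- ch$res_names
    nres <- length(res3)
    nlin <- ceiling(nres / 13)
    for (k in seq_len(nlin)) {
      chunk <- res3[((k - 1) * 13 + 1):min(k * 13, nres)]
      out <- c(out, sprintf("SEQRES %3d %s %4d  %s", k, ch$chain_id, nres,
                            paste(sprintf("%-3s", chunk), collapse = " ")))
    }
  }
  serial <- 0
  for (ch in assembly$chains) {
    a <- ch$atoms[order(ch$atoms$res_idx), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1
      nm <- a$atom[i]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                            serial, nm_fmt, ch$res_names[a$res_idx[i]],
                            ch$chain_id, a$res_idx[i], a$x[i], a$y[i], a$z[i],
                            a$element[i]))
    }
    out <- c(out, sprintf("TER   %5d      %3s %s%4d", serial + 1,
                          ch$res_names[a$res_idx[nrow(a)]], ch$chain_id,
                          a$res_idx[nrow(a)]))
    serial <- serial + 1
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write an assembly as a minimal mmCIF file
#'
#' Mirror of [write_assembly_pdb()]: emits experimental metadata, a
#' `pdbx_poly_seq_scheme` loop carrying the full sequence and an `atom_site`
#' loop with the resolved atoms.
#'
#' @inheritParams write_assembly_pdb
#' @return `path`, invisibly.
#' @export
write_assembly_cif <- function(assembly, path) {
  out <- c(sprintf("data_%s", assembly$assembly_id),
           "#",
           sprintf("_exptl.method '%s'", assembly$method))
  if (!is.na(assembly$resolution))
    out <- c(out, sprintf("_refine.ls_d_res_high %.2f", assembly$resolution))
  out <- c(out, "#", "loop_", "_pdbx_poly_seq_scheme.asym_id",
           "_pdbx_poly_seq_scheme.seq_id", "_pdbx_poly_seq_scheme.mon_id")
  for (ch in assembly$chains) {
    out <- c(out, sprintf("%s %d %s", ch$chain_id,
                          seq_along(ch$res_names), ch$res_names))
  }
  out <- c(out, "#", "loop_", "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.auth_atom_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z")
  serial <- 0
  for (ch in assembly$chains) {
    a <- ch$atoms[order(ch$atoms$res_idx), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1
      out <- c(out, sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f",
                            serial, a$element[i], a$atom[i],
                            ch$res_names[a$res_idx[i]], ch$chain_id,
                            a$res_idx[i], a$x[i], a$y[i], a$z[i]))
    }
  }
  out <- c(out, "#")
  writeLines(out, path)
  invisible(path)
}

#' Read a chain-to-protein mapping table
#'
#' The table stands in for external sequence-database mappings: it assigns
#' each chain of each assembly a protein accession and a family identifier.
#'
#' @param path TSV file with header columns `assembly_id`, `chain_id`,
#'   `accession`, `family`.
#' @return data.frame with those four character columns.
#' @export
read_mapping <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("assembly_id", "chain_id", "accession", "family")
  if (!all(need %in% names(m)))
    stop("mapping table must have columns ", paste(need, collapse = ", "))
  m[, need]
}

mapping_lookup <- function(mapping, assembly_id, chain_id) {
  hit <- mapping$assembly_id == assembly_id & mapping$chain_id == chain_id
  if (!any(hit)) return(NULL)
  mapping[which(hit)[1], c("accession", "family")]
}

#' Entry-level structure filter
#'
#' Retains X-ray structures with resolution below `max_resolution` whose
#' chains map to at least two distinct protein accessions (i.e. the assembly
#' can contain an external interaction). Entries with absent resolution are
#' rejected.
#'
#' @param assembly an [new_assembly()] object.
#' @param mapping mapping table from [read_mapping()].
#' @param max_resolution resolution threshold in Angstrom (strict `<`;
#'   default 2.5).
#' @param require_xray reject non-X-ray methods (default TRUE).
#' @return logical.
#' @export
passes_entry_filter <- function(assembly, mapping, max_resolution = 2.5,
                                require_xray = TRUE) {
  if (require_xray && !grepl("X-RAY", assembly$method, ignore.case = TRUE))
    return(FALSE)
  if (is.na(assembly$resolution)) {
    message("assembly ", assembly$assembly_id, ": no resolution record; rejected")
    return(FALSE)
  }
  if (assembly$resolution >= max_resolution) return(FALSE)
  accs <- character(0)
  for (cid in names(assembly$chains)) {
    e <- mapping_lookup(mapping, assembly$assembly_id, cid)
    if (!is.null(e)) accs <- c(accs, e$accession)
  }
  length(unique(accs)) >= 2
}

#' Map a chain to a protein accession by sequence identity
#'
#' Deterministic fallback used when a chain is absent from the mapping table:
#' the chain SEQRES is globally aligned against each reference sequence and
#' the accession of the best-identity reference is returned, provided at
#' least `min_coverage` of the chain is aligned. Chains shorter than
#' `min_length` residues are never mapped. Ties are broken by
#' lexicographically smallest accession.
#'
#' @param chain a [new_chain()] object.
#' @param reference_sequences named character vector, accession -> sequence.
#' @param min_length minimum chain length (default 30 residues).
#' @param min_coverage minimum aligned fraction of the chain (default 0.9).
#' @return accession string, or `NA_character_` when no reference qualifies.
#' @export
map_by_identity <- function(chain, reference_sequences, min_length = 30,
                            min_coverage = 0.9) {
  if (nchar(chain$seqres) < min_length) return(NA_character_)
  accs <- sort(names(reference_sequences))
  best_acc <- NA_character_
  best_ident <- -Inf
  for (acc in accs) {
    al <- Biostrings::pairwiseAlignment(chain$seqres,
                                        reference_sequences[[acc]],
                                        type = "global")
    map <- alignment_position_map(al)
    cov <- length(map) / nchar(chain$seqres)
    if (cov < min_coverage) next
    chain_chars <- strsplit(chain$seqres, "")[[1]]
    ref_chars <- strsplit(reference_sequences[[acc]], "")[[1]]
    ident <- sum(chain_chars[as.integer(names(map))] == ref_chars[map]) /
      length(map)
    if (ident > best_ident) {
      best_ident <- ident
      best_acc <- acc
    }
  }
  best_acc
}

dimer_id <- function(assembly_id, cidX, cidY) {
  paste(assembly_id, cidX, cidY, sep = ":")
}

new_hetero_dimer <- function(assembly_id, chainX, chainY, accX, accY,
                             famX, famY) {
  stopifnot(accX != accY)
  structure(list(id = dimer_id(assembly_id, chainX$chain_id, chainY$chain_id),
                 assembly_id = assembly_id, chainX = chainX, chainY = chainY,
                 acc = c(X = accX, Y = accY), fam = c(X = famX, Y = famY),
                 seq_pair = sort(c(chainX$seqres, chainY$seqres)),
                 prot_pair = sort(c(accX, accY)),
                 fam_pair = sort(c(famX, famY)),
                 interface = NULL, copy_number = NA_integer_),
            class = "HeteroDimer")
}

#' @export
print.HeteroDimer <- function(x, ...) {
  cat(sprintf("HeteroDimer %s (%s-%s), copy number %s, %s\n", x$id,
              x$acc["X"], x$acc["Y"],
              ifelse(is.na(x$copy_number), "?", x$copy_number),
              ifelse(is.null(x$interface), "unannotated",
                     sprintf("%d interface pairs", nrow(x$interface$pairs)))))
  invisible(x)
}

#' Extract candidate external hetero-dimers from an assembly
#'
#' Every unordered pair of chains mapping to two different protein accessions
#' and having at least one inter-chain atom pair closer than `contact_cutoff`
#' becomes a hetero-dimer. Chains absent from the mapping table are mapped by
#' sequence identity against `reference_sequences` when provided, otherwise
#' skipped with a warning. Output order is deterministic (sorted chain ids).
#'
#' @param assembly an [new_assembly()] object.
#' @param mapping mapping table from [read_mapping()].
#' @param contact_cutoff contact distance in Angstrom (default 6).
#' @param reference_sequences optional accession -> sequence vector for the
#'   identity fallback; matched chains inherit the family of the accession's
#'   first mapping-table row, or a singleton family.
#' @return list of hetero-dimers.
#' @export
extract_hetero_dimers <- function(assembly, mapping, contact_cutoff = 6,
                                  reference_sequences = NULL) {
  cids <- sort(names(assembly$chains))
  info <- list()
  for (cid in cids) {
    e <- mapping_lookup(mapping, assembly$assembly_id, cid)
    if (is.null(e) && !is.null(reference_sequences)) {
      acc <- map_by_identity(assembly$chains[[cid]], reference_sequences)
      if (!is.na(acc)) {
        fam_rows <- mapping$family[mapping$accession == acc]
        fam <- if (length(fam_rows) > 0) fam_rows[1] else paste0("FAM_", acc)
        e <- data.frame(accession = acc, family = fam,
                        stringsAsFactors = FALSE)
      }
    }
    if (is.null(e)) {
      warning("assembly ", assembly$assembly_id, ": chain ", cid,
              " has no protein mapping; skipped")
      next
    }
    info[[cid]] <- e
  }
  mapped <- names(info)
  dimers <- list()
  if (length(mapped) >= 2) {
    for (i in seq_len(length(mapped) - 1)) {
      for (j in (i + 1):length(mapped)) {
        ci <- mapped[i]; cj <- mapped[j]
        if (info[[ci]]$accession == info[[cj]]$accession) next
        if (!cpp_any_contact(chain_xyz(assembly$chains[[ci]]),
                             chain_xyz(assembly$chains[[cj]]),
                             contact_cutoff)) next
        dimers[[length(dimers) + 1]] <-
          new_hetero_dimer(assembly$assembly_id, assembly$chains[[ci]],
                           assembly$chains[[cj]], info[[ci]]$accession,
                           info[[cj]]$accession, info[[ci]]$family,
                           info[[cj]]$family)
      }
    }
  }
  dimers
}
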