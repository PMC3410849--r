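seq_key_of <- function(d) paste(d$seq_pair, collapse = "\r")
prot_key_of <- function(d) paste(d$prot_pair, collapse = "|")
fam_key_of <- function(d) paste(d$fam_pair, collapse = "|")

#' Build the three-level redundancy hierarchy
#'
#' Hetero-dimers are partitioned by identical unordered SEQRES sequence pair
#' (SameSeq), SameSeq groups by identical unordered protein accession pair
#' (SameProt), and SameProt groups by identical unordered family pair
#' (Interolog). Keys are unordered, so swapping a dimer's chain order never
#' changes its membership. Dimers lacking a family id are placed in singleton
#' pseudo-families with a warning.
#'
#' @param dimers list of hetero-dimers.
#' @return object of class `dimer_hierarchy`: `index` (data.frame dimer_id,
#'   assembly_id, seq_key, prot_key, fam_key) and `forest` (list of Interolog
#'   nodes, each with SameProt children holding SameSeq leaf groups),
#'   deterministically ordered by key.
#' @export
build_hierarchy <- function(dimers) {
  stopifnot(length(dimers) > 0)
  fam_keys <- vapply(dimers, fam_key_of, "")
  missing_fam <- vapply(dimers, function(d) any(is.na(d$fam_pair)) ||
                          any(!nzchar(d$fam_pair)), TRUE)
  if (any(missing_fam)) {
    warning(sum(missing_fam), " dimer(s) without family id placed in ",
            "singleton pseudo-families")
    fam_keys[missing_fam] <- paste0("_singleton_",
                                    vapply(dimers[missing_fam],
                                           function(d) d$id, ""))
  }
  index <- data.frame(dimer_id = vapply(dimers, function(d) d$id, ""),
                      assembly_id = vapply(dimers,
                                           function(d) d$assembly_id, ""),
                      seq_key = vapply(dimers, seq_key_of, ""),
                      prot_key = vapply(dimers, prot_key_of, ""),
                      fam_key = fam_keys, stringsAsFactors = FALSE)
  forest <- lapply(split(index, index$fam_key), function(fi) {
    sameprot <- lapply(split(fi, fi$prot_key), function(pi) {
      sameseq <- lapply(split(pi, pi$seq_key), function(si) {
        list(level = "SameSeq", key = si$seq_key[1],
             members = sort(si$dimer_id),
             assemblies = sort(unique(si$assembly_id)))
      })
      list(level = "SameProt", key = pi$prot_key[1],
           children = sameseq[order(names(sameseq))])
    })
    list(level = "Interolog", key = fi$fam_key[1],
         children = sameprot[order(names(sameprot))])
  })
  structure(list(index = index, forest = forest[order(names(forest))]),
            class = "dimer_hierarchy")
}

#' @export
print.dimer_hierarchy <- function(x, ...) {
  cat(sprintf("dimer_hierarchy: %d dimers, %d SameSeq / %d SameProt / %d Interolog groups\n",
              nrow(x$index), length(unique(x$index$seq_key)),
              length(unique(x$index$prot_key)),
              length(unique(x$index$fam_key))))
  invisible(x)
}

#' Groups eligible for a level's distribution
#'
#' SameSeq groups need at least two member dimers (from two assemblies, or
#' two copies within one assembly, flagged `intra_assembly`); SameProt groups
#' need at least two SameSeq children; Interolog groups at least two SameProt
#' children.
#'
#' @param hierarchy a [build_hierarchy()] object.
#' @param level "SameSeq", "SameProt" or "Interolog".
#' @return data.frame with group `key` and, for SameSeq, `n_members`,
#'   `n_assemblies`, `intra_assembly`.
#' @export
eligible_groups <- function(hierarchy, level = c("SameSeq", "SameProt",
                                                 "Interolog")) {
  level <- match.arg(level)
  ix <- hierarchy$index
  if (level == "SameSeq") {
    out <- do.call(rbind, lapply(split(ix, ix$seq_key), function(si) {
      data.frame(key = si$seq_key[1], n_members = nrow(si),
                 n_assemblies = length(unique(si$assembly_id)),
                 intra_assembly = length(unique(si$assembly_id)) == 1,
                 stringsAsFactors = FALSE)
    }))
    out <- out[out$n_members >= 2, , drop = FALSE]
  } else if (level == "SameProt") {
    out <- do.call(rbind, lapply(split(ix, ix$prot_key), function(pi) {
      data.frame(key = pi$prot_key[1],
                 n_children = length(unique(pi$seq_key)),
                 stringsAsFactors = FALSE)
    }))
    out <- out[out$n_children >= 2, , drop = FALSE]
  } else {
    out <- do.call(rbind, lapply(split(ix, ix$fam_key), function(fi) {
      data.frame(key = fi$fam_key[1],
                 n_children = length(unique(fi$prot_key)),
                 stringsAsFactors = FALSE)
    }))
    out <- out[out$n_children >= 2, , drop = FALSE]
  }
  if (is.null(out)) out <- data.frame(key = character(0))
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Dump the hierarchy as a table
#'
#' @param hierarchy a [build_hierarchy()] object.
#' @param path optional TSV output path.
#' @return data.frame: dimer_id, assembly_id, sameseq_key_hash, sameprot_key,
#'   interolog_key. Sequence keys are long, so they are reported as a compact
#'   integer hash (group ordinal).
#' @export
hierarchy_table <- function(hierarchy, path = NULL) {
  ix <- hierarchy$index
  out <- data.frame(dimer_id = ix$dimer_id, assembly_id = ix$assembly_id,
                    sameseq_key_hash = match(ix$seq_key,
                                             sort(unique(ix$seq_key))),
                    sameprot_key = ix$prot_key, interolog_key = ix$fam_key,
                    stringsAsFactors = FALSE)
  out <- out[order(out$dimer_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
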