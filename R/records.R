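#' All pairwise similarity records within Interolog groups
#'
#' Every unordered pair of annotated hetero-dimers sharing a family-pair key
#' is compared (all three distribution levels draw only on such pairs). Each
#' record carries the grouping keys of both dimers, its divergence level and
#' an intra-assembly flag.
#'
#' @param dimers list of annotated hetero-dimers (size-filtered).
#' @param measures subset of `c("fps", "l_rms", "i_rms")`.
#' @param min_coverage coverage floor for [common_residues()].
#' @return data.frame of similarity records.
#' @export
pairwise_records <- function(dimers, measures = c("fps", "l_rms", "i_rms"),
                             min_coverage = 0.3) {
  ids <- vapply(dimers, function(d) d$id, "")
  names(dimers) <- ids
  fam <- vapply(dimers, fam_key_of, "")
  rows <- list()
  for (fk in sort(unique(fam))) {
    grp <- dimers[fam == fk]
    if (length(grp) < 2) next
    ord <- sort(names(grp))
    for (i in seq_len(length(ord) - 1)) {
      for (j in (i + 1):length(ord)) {
        a <- grp[[ord[i]]]
        b <- grp[[ord[j]]]
        rec <- compare_dimers(a, b, measures, min_coverage)
        rec$seq_keyA <- seq_key_of(a)
        rec$seq_keyB <- seq_key_of(b)
        rec$prot_keyA <- prot_key_of(a)
        rec$prot_keyB <- prot_key_of(b)
        rec$fam_key <- fk
        rec$copy_number_A <- a$copy_number
        rec$copy_number_B <- b$copy_number
        rec$level <- if (rec$seq_keyA == rec$seq_keyB) "SameSeq"
          else if (rec$prot_keyA == rec$prot_keyB) "SameProt"
          else "Interolog"
        rows[[length(rows) + 1]] <- rec
      }
    }
  }
  if (length(rows) == 0) {
    stop("no comparable dimer pairs (no family-pair key shared)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset-style pairwise comparison table
#'
#' Mirrors the per-comparison report: similarity values, copy numbers,
#' best-homomer-match indicator and divergence level, one row per compared
#' dimer pair.
#'
#' @param records records from [pairwise_records()], optionally augmented
#'   with best-match columns by [best_match_filter()].
#' @param path optional TSV output path.
#' @return data.frame.
#' @export
records_table <- function(records, path = NULL) {
  cols <- c("dimerA", "dimerB", "fps", "fps_X", "fps_Y", "l_rms", "i_rms",
            "copy_number_A", "copy_number_B", "level", "skipped",
            "skip_reason")
  extra <- grep("^best_match", names(records), value = TRUE)
  out <- records[, c(cols, extra), drop = FALSE]
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
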