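#' Homo-oligomer partners of a chain
#'
#' Chains of the same assembly that are equivalent to the query chain --
#' identical SEQRES sequence (`mode = "sequence"`) or identical family
#' (`mode = "structural"`) -- and connected to it through the interaction
#' graph among such equivalent chains (at least one atom pair below `cutoff`
#' per edge, transitively closed so an n-ring counts as one oligomer even
#' when its chains are not pairwise in contact).
#'
#' @param assembly an [new_assembly()] object.
#' @param chain_id query chain.
#' @param mode "sequence" or "structural".
#' @param mapping mapping table (required for `mode = "structural"`).
#' @param cutoff contact distance in Angstrom (default 6).
#' @return character vector of partner chain ids (excluding the query).
#' @export
find_homomer_partners <- function(assembly, chain_id,
                                  mode = c("sequence", "structural"),
                                  mapping = NULL, cutoff = 6) {
  mode <- match.arg(mode)
  comp <- homomer_components(assembly, mapping, mode, cutoff)
  setdiff(names(comp)[comp == comp[[chain_id]]], chain_id)
}

# connected components of the equivalent-chain interaction graph
homomer_components <- function(assembly, mapping, mode, cutoff = 6) {
  cids <- names(assembly$chains)
  eq_label <- if (mode == "sequence") {
    vapply(assembly$chains, function(ch) ch$seqres, "")
  } else {
    if (is.null(mapping)) stop("structural mode requires a mapping table")
    vapply(cids, function(cid) {
      e <- mapping_lookup(mapping, assembly$assembly_id, cid)
      if (is.null(e)) paste0("_unmapped_", cid) else e$family
    }, "")
  }
  comp <- setNames(seq_along(cids), cids)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (length(cids) >= 2) {
    for (i in seq_len(length(cids) - 1)) {
      for (j in (i + 1):length(cids)) {
        if (eq_label[i] != eq_label[j]) next
        if (!cpp_any_contact(chain_xyz(assembly$chains[[cids[i]]]),
                             chain_xyz(assembly$chains[[cids[j]]]), cutoff))
          next
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(cids), find, 0L)
  setNames(roots, cids)
}

#' Alternative interfaces connected through a homomer
#'
#' For a focal hetero-dimer X'/Y' inside its assembly, the alternatives are
#' all interfaces of X' with homomer partners of Y', all interfaces of Y'
#' with homomer partners of X', and X'/Y' itself. In structural mode the
#' focal interaction must join two different families.
#'
#' @param dimer the focal hetero-dimer.
#' @param dimers list (or id-named list) of all hetero-dimers.
#' @param assembly the dimer's assembly.
#' @param mode "sequence" or "structural".
#' @param mapping mapping table (structural mode).
#' @param cutoff contact distance in Angstrom.
#' @return character vector of alternative dimer ids (always includes the
#'   focal dimer id).
#' @export
collect_alternatives <- function(dimer, dimers, assembly,
                                 mode = c("sequence", "structural"),
                                 mapping = NULL, cutoff = 6) {
  mode <- match.arg(mode)
  if (mode == "structural" && dimer$fam["X"] == dimer$fam["Y"])
    stop("structural homomer filtering is only defined for interactions ",
         "between two different families")
  comp <- homomer_components(assembly, mapping, mode, cutoff)
  cx <- dimer$chainX$chain_id
  cy <- dimer$chainY$chain_id
  partnersX <- setdiff(names(comp)[comp == comp[[cx]]], cx)
  partnersY <- setdiff(names(comp)[comp == comp[[cy]]], cy)
  want <- rbind(if (length(partnersY) > 0) cbind(cx, partnersY),
                if (length(partnersX) > 0) cbind(partnersX, cy))
  ids <- dimer$id
  if (!is.null(want)) {
    for (k in seq_len(nrow(want))) {
      pair <- sort(want[k, ])
      ids <- c(ids, dimer_id(dimer$assembly_id, pair[1], pair[2]))
    }
  }
  all_ids <- vapply(dimers, function(d) d$id, "")
  sort(unique(intersect(ids, all_ids)))
}

measure_better <- function(measure) {
  # "best" means maximal similarity for fps, minimal distance for RMSDs
  if (measure == "fps") {
    list(best = function(v) max(v), is_best = function(x, v) x >= max(v) - 1e-12,
         self = 1)
  } else {
    list(best = function(v) min(v), is_best = function(x, v) x <= min(v) + 1e-12,
         self = 0)
  }
}

#' Best-match filtering of homomer-induced interface diversity
#'
#' For every comparison record X/Y vs X'/Y', the focal similarity is compared
#' against the similarities of X/Y with every homomer-connected alternative
#' interface of X'/Y' (including X'/Y' itself): the record survives only when
#' it is the best match (ties retained). The roles of the two sides are then
#' switched and the test repeated; a comparison survives only in both
#' directions, which makes the retained set symmetric. When one side of a
#' record is itself among the other side's alternatives (interface copies
#' within one assembly), its self-match is perfect and outcompetes any
#' non-identical focal comparison.
#'
#' @param records records from [pairwise_records()].
#' @param dimers list of the annotated hetero-dimers behind the records.
#' @param assemblies named list of assemblies (by assembly id).
#' @param mapping mapping table.
#' @param mode "sequence" or "structural".
#' @param measure similarity measure the filter is applied to ("fps",
#'   "l_rms" or "i_rms"); the filter is per measure.
#' @param cutoff contact distance in Angstrom.
#' @return `records` with a logical column `best_match_<mode>_<measure>`
#'   (NA for skipped records and, in structural mode, for same-family-pair
#'   interactions which are outside the filter's scope).
#' @export
best_match_filter <- function(records, dimers, assemblies, mapping,
                              mode = c("sequence", "structural"),
                              measure = "fps", cutoff = 6) {
  mode <- match.arg(mode)
  cmp <- measure_better(measure)
  ids <- vapply(dimers, function(d) d$id, "")
  names(dimers) <- ids
  # similarity lookup by unordered record pair
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "~")
  sim <- setNames(records[[measure]],
                  mapply(pair_key, records$dimerA, records$dimerB))
  sim <- sim[!records$skipped & !is.na(records[[measure]])]
  comp_cache <- list()
  alternatives_of <- function(d) {
    key <- paste(d$assembly_id, d$id)
    if (is.null(comp_cache[[key]])) {
      comp_cache[[key]] <<- collect_alternatives(d, dimers,
                                                 assemblies[[d$assembly_id]],
                                                 mode, mapping, cutoff)
    }
    comp_cache[[key]]
  }
  n <- nrow(records)
  out <- rep(NA, n)
  for (r in seq_len(n)) {
    if (records$skipped[r] || is.na(records[[measure]][r])) next
    dA <- dimers[[records$dimerA[r]]]
    dB <- dimers[[records$dimerB[r]]]
    if (mode == "structural" &&
        (dA$fam["X"] == dA$fam["Y"] || dB$fam["X"] == dB$fam["Y"])) next
    focal <- records[[measure]][r]
    survives <- function(this, other) {
      alts <- alternatives_of(other)
      vals <- vapply(alts, function(aid) {
        if (aid == this$id) return(cmp$self)
        v <- sim[pair_key(this$id, aid)]
        if (is.na(v)) NA_real_ else unname(v)
      }, 0)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) return(TRUE)
      cmp$is_best(focal, vals)
    }
    out[r] <- survives(dA, dB) && survives(dB, dA)
  }
  records[[paste0("best_match_", mode, "_", measure)]] <- out
  records
}

#' Distributions after homomer best-match filtering
#'
#' Recomputes the three hierarchical distributions from retained records
#' only. Structural mode is restricted to the Interolog level (at the other
#' levels it would compare interfaces of different protein pairs) and to
#' interactions between two different families.
#'
#' @inheritParams best_match_filter
#' @param hierarchy a [build_hierarchy()] object.
#' @param bins a [bin_spec()] or NULL for the measure default.
#' @param caps,seed,include_intra passed to the distribution estimators.
#' @return list with elements `sameseq`, `sameprot`, `interolog`
#'   (`interolog` only, for structural mode) plus the augmented `records`.
#' @export
filtered_distributions <- function(records, hierarchy, dimers, assemblies,
                                   mapping, bins = NULL, measure = "fps",
                                   mode = c("sequence", "structural"),
                                   caps = list(max_prot_pairs = 50,
                                               max_seq_pairs = 50),
                                   seed = NULL, include_intra = TRUE,
                                   cutoff = 6) {
  mode <- match.arg(mode)
  col <- paste0("best_match_", mode, "_", measure)
  if (!col %in% names(records))
    records <- best_match_filter(records, dimers, assemblies, mapping, mode,
                                 measure, cutoff)
  keep <- !is.na(records[[col]]) & records[[col]]
  kept <- records[keep, , drop = FALSE]
  if (mode == "structural") {
    return(list(interolog = d_interolog(kept, hierarchy, bins, measure,
                                        caps, seed, include_intra),
                records = records))
  }
  list(sameseq = d_sameseq(kept, hierarchy, bins, measure, include_intra),
       sameprot = d_sameprot(kept, hierarchy, bins, measure, include_intra),
       interolog = d_interolog(kept, hierarchy, bins, measure, caps, seed,
                               include_intra),
       records = records)
}
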