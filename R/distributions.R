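#' Bin specification for similarity histograms
#'
#' Bins are half-open `[a, b)` with the last bin closed at the top, or
#' unbounded when `open_top` (for Angstrom-valued measures).
#'
#' @param edges strictly increasing numeric boundaries.
#' @param open_top append an unbounded last bin above the final edge.
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(edges, open_top = FALSE) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  structure(list(edges = edges, open_top = open_top,
                 n_bins = length(edges) - 1L + as.integer(open_top)),
            class = "bin_spec")
}

#' @rdname bin_spec
#' @export
fps_bins <- function() bin_spec(seq(0, 1, by = 0.1))

#' @rdname bin_spec
#' @details `lrms_bins()` uses 1 Angstrom steps from 0 to 9 with an open
#'   top bin (`> 9`), expressing the conventional reporting thresholds
#'   (`< 1`, `> 2`, `> 9` Angstrom).
#' @export
lrms_bins <- function() bin_spec(0:9, open_top = TRUE)

bin_labels <- function(bins) {
  e <- bins$edges
  lab <- sprintf("[%g,%g)", e[-length(e)], e[-1])
  if (bins$open_top) c(lab, sprintf(">=%g", e[length(e)]))
  else {
    lab[length(lab)] <- sprintf("[%g,%g]", e[length(e) - 1], e[length(e)])
    lab
  }
}

#' Normalized histogram over a bin specification
#'
#' @param values numeric vector (NAs dropped).
#' @param bins a [bin_spec()].
#' @return probability vector over bins, or `NULL` when no values remain
#'   (undefined distribution).
#' @export
histogram_prob <- function(values, bins) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NULL)
  breaks <- if (bins$open_top) c(bins$edges, Inf) else bins$edges
  if (any(values < breaks[1]) || (!bins$open_top &&
                                  any(values > breaks[length(breaks)])))
    stop("values outside bin range")
  idx <- findInterval(values, breaks, rightmost.closed = !bins$open_top)
  tabulate(idx, nbins = bins$n_bins) / length(values)
}

new_distribution <- function(bins, group_p, level_name, measure,
                             n_comparisons) {
  p <- if (nrow(group_p) > 0) colMeans(group_p) else rep(NA_real_, bins$n_bins)
  structure(list(bins = bins, p = p, se = NULL,
                 n_top_groups = nrow(group_p), group_p = group_p,
                 level = level_name, measure = measure,
                 n_comparisons = n_comparisons),
            class = "interface_distribution")
}

#' @export
print.interface_distribution <- function(x, ...) {
  cat(sprintf("D-%s (%s): %d top-level groups, %d comparisons\n", x$level,
              x$measure, x$n_top_groups, x$n_comparisons))
  tab <- rbind(p = round(x$p, 4))
  colnames(tab) <- bin_labels(x$bins)
  if (!is.null(x$se)) tab <- rbind(tab, se = round(x$se, 4))
  print(tab)
  invisible(x)
}

# valid comparison values of one measure, with group keys attached
measure_values <- function(records, measure) {
  v <- records[[measure]]
  ok <- !records$skipped & !is.na(v)
  data.frame(value = v[ok], seqA = records$seq_keyA[ok],
             seqB = records$seq_keyB[ok], protA = records$prot_keyA[ok],
             protB = records$prot_keyB[ok], fam = records$fam_key[ok],
             intra = records$assemblyA[ok] == records$assemblyB[ok],
             stringsAsFactors = FALSE)
}

run_with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Distribution of interface similarity between identical sequence pairs
#'
#' Per eligible SameSeq group, the histogram of all pairwise similarities of
#' its members is computed; SameProt distributions average the SameSeq
#' histograms of their children, Interolog distributions average the
#' SameProt distributions, and the overall distribution averages the
#' Interolog distributions. Every averaging step is unweighted, so each
#' group counts equally regardless of how many structures it contains.
#'
#' @param records pairwise comparison records from [pairwise_records()].
#' @param hierarchy a [build_hierarchy()] object.
#' @param bins a [bin_spec()]; defaults to [fps_bins()] for fps and
#'   [lrms_bins()] for RMSD measures.
#' @param measure "fps", "l_rms" or "i_rms".
#' @param include_intra include comparisons between interface copies within
#'   one assembly (default TRUE).
#' @return an `interface_distribution` (per-top-group distributions kept in
#'   `$group_p` for resampling), or `NULL` when no group is eligible.
#' @export
d_sameseq <- function(records, hierarchy, bins = NULL, measure = "fps",
                      include_intra = TRUE) {
  bins <- default_bins(bins, measure)
  mv <- measure_values(records, measure)
  if (!include_intra) mv <- mv[!mv$intra, , drop = FALSE]
  mv <- mv[mv$seqA == mv$seqB, , drop = FALSE]
  hier_average(hierarchy, bins, measure, "SameSeq",
               function(seqset) {
                 vals <- mv$value[mv$seqA %in% seqset & mv$seqB %in% seqset]
                 list(vals = vals)
               })
}

#' Distribution of interface similarity between point variants of a protein
#' pair
#'
#' Within each SameProt group, every unordered pair of distinct SameSeq
#' children contributes the histogram of all cross-child comparisons (no
#' within-child pairs); these are averaged into the SameProt distribution
#' and averaged upward as in [d_sameseq()].
#'
#' @inheritParams d_sameseq
#' @export
d_sameprot <- function(records, hierarchy, bins = NULL, measure = "fps",
                       include_intra = TRUE) {
  bins <- default_bins(bins, measure)
  mv <- measure_values(records, measure)
  if (!include_intra) mv <- mv[!mv$intra, , drop = FALSE]
  mv <- mv[mv$seqA != mv$seqB & mv$protA == mv$protB, , drop = FALSE]
  cross_hist <- function(k1, k2) {
    sel <- (mv$seqA == k1 & mv$seqB == k2) | (mv$seqA == k2 & mv$seqB == k1)
    histogram_prob(mv$value[sel], bins)
  }
  out_groups <- list()
  n_comp <- 0
  for (inode in hierarchy$forest) {
    prot_dists <- list()
    for (pnode in inode$children) {
      keys <- names(pnode$children)
      if (length(keys) < 2) next
      pair_hists <- list()
      cmb <- combn(keys, 2)
      for (k in seq_len(ncol(cmb))) {
        h <- cross_hist(cmb[1, k], cmb[2, k])
        if (!is.null(h)) pair_hists[[length(pair_hists) + 1]] <- h
      }
      if (length(pair_hists) > 0)
        prot_dists[[length(prot_dists) + 1]] <-
          colMeans(do.call(rbind, pair_hists))
    }
    if (length(prot_dists) > 0)
      out_groups[[inode$key]] <- colMeans(do.call(rbind, prot_dists))
  }
  n_comp <- nrow(mv)
  finalize_distribution(out_groups, bins, "SameProt", measure, n_comp)
}

#' Distribution of interface similarity between interologous protein pairs
#'
#' Within each Interolog group, every unordered pair of distinct SameProt
#' children is considered (subsampled to `caps$max_prot_pairs` children with
#' a seeded RNG when exceeded); for each such pair, every combination of one
#' SameSeq child from each side (subsampled to `caps$max_seq_pairs`)
#' contributes the histogram of its cross comparisons. Averaging proceeds
#' combination -> SameProt pair -> Interolog group -> overall.
#'
#' @inheritParams d_sameseq
#' @param caps list with `max_prot_pairs` and `max_seq_pairs` (default 50
#'   and 50; `Inf` disables a cap).
#' @param seed RNG seed for subsampling under the caps (recorded nowhere
#'   else; pass the run seed).
#' @export
d_interolog <- function(records, hierarchy, bins = NULL, measure = "fps",
                        caps = list(max_prot_pairs = 50, max_seq_pairs = 50),
                        seed = NULL, include_intra = TRUE) {
  bins <- default_bins(bins, measure)
  mv <- measure_values(records, measure)
  if (!include_intra) mv <- mv[!mv$intra, , drop = FALSE]
  mv <- mv[mv$protA != mv$protB, , drop = FALSE]
  run_with_seed(seed, function() {
    cap_sample <- function(x, cap) {
      if (is.finite(cap) && length(x) > cap) sort(sample(x, cap)) else x
    }
    out_groups <- list()
    for (inode in hierarchy$forest) {
      pkeys <- names(inode$children)
      if (length(pkeys) < 2) next
      pkeys <- cap_sample(pkeys, caps$max_prot_pairs)
      if (length(pkeys) < 2) next
      pair_dists <- list()
      cmb <- combn(pkeys, 2)
      for (k in seq_len(ncol(cmb))) {
        s1 <- cap_sample(names(inode$children[[cmb[1, k]]]$children),
                         caps$max_seq_pairs)
        s2 <- cap_sample(names(inode$children[[cmb[2, k]]]$children),
                         caps$max_seq_pairs)
        combo_hists <- list()
        for (a in s1) for (b in s2) {
          sel <- (mv$seqA == a & mv$seqB == b) |
            (mv$seqA == b & mv$seqB == a)
          h <- histogram_prob(mv$value[sel], bins)
          if (!is.null(h)) combo_hists[[length(combo_hists) + 1]] <- h
        }
        if (length(combo_hists) > 0)
          pair_dists[[length(pair_dists) + 1]] <-
            colMeans(do.call(rbind, combo_hists))
      }
      if (length(pair_dists) > 0)
        out_groups[[inode$key]] <- colMeans(do.call(rbind, pair_dists))
    }
    finalize_distribution(out_groups, bins, "Interolog", measure, nrow(mv))
  })
}

default_bins <- function(bins, measure) {
  if (!is.null(bins)) return(bins)
  if (measure == "fps") fps_bins() else lrms_bins()
}

# SameSeq-level engine: leaf histograms, then unweighted averaging up
hier_average <- function(hierarchy, bins, measure, level_name, leaf_vals) {
  out_groups <- list()
  n_comp <- 0
  for (inode in hierarchy$forest) {
    prot_dists <- list()
    for (pnode in inode$children) {
      seq_dists <- list()
      for (snode in pnode$children) {
        lv <- leaf_vals(snode$key)
        h <- histogram_prob(lv$vals, bins)
        if (!is.null(h)) {
          seq_dists[[length(seq_dists) + 1]] <- h
          n_comp <- n_comp + length(lv$vals)
        }
      }
      if (length(seq_dists) > 0)
        prot_dists[[length(prot_dists) + 1]] <-
          colMeans(do.call(rbind, seq_dists))
    }
    if (length(prot_dists) > 0)
      out_groups[[inode$key]] <- colMeans(do.call(rbind, prot_dists))
  }
  finalize_distribution(out_groups, bins, level_name, measure, n_comp)
}

finalize_distribution <- function(out_groups, bins, level_name, measure,
                                  n_comp) {
  if (length(out_groups) == 0) return(NULL)
  gp <- do.call(rbind, out_groups)
  rownames(gp) <- names(out_groups)
  new_distribution(bins, gp, level_name, measure, n_comp)
}

#' Bootstrap standard errors for a hierarchical distribution
#'
#' Top-level (Interolog) group distributions are resampled with replacement
#' and the overall distribution recomputed; the per-bin standard deviation
#' across resamples is the standard error. Seeded and reproducible.
#'
#' @param dist an `interface_distribution`.
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed.
#' @return the distribution with `$se` set (and `$boot` holding the
#'   resampled overall distributions); `$se` stays `NULL` when fewer than 2
#'   top-level groups exist.
#' @export
bootstrap_se <- function(dist, n_boot = 500, seed = 1) {
  stopifnot(n_boot >= 100)
  g <- nrow(dist$group_p)
  if (g < 2) {
    message("fewer than 2 top-level groups: standard errors undefined")
    return(dist)
  }
  boot <- run_with_seed(seed, function() {
    t(vapply(seq_len(n_boot), function(b) {
      colMeans(dist$group_p[sample.int(g, g, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(dist$group_p))))
  })
  dist$se <- apply(boot, 2, stats::sd)
  dist$boot <- boot
  dist
}

#' Cumulative mass of a distribution against a threshold
#'
#' Sums the probability of bins lying entirely below (or above) the
#' threshold, which must coincide with a bin edge: no interpolation is
#' performed.
#'
#' @param dist an `interface_distribution`.
#' @param threshold bin-edge value.
#' @param direction "below" or "above".
#' @return fraction in `[0, 1]`.
#' @export
cumulative_mass <- function(dist, threshold, direction = c("below", "above")) {
  direction <- match.arg(direction)
  e <- dist$bins$edges
  k <- which(abs(e - threshold) < 1e-12)
  if (length(k) == 0) stop("threshold ", threshold, " is not a bin edge")
  if (direction == "below") {
    if (k == 1) 0 else sum(dist$p[seq_len(k - 1)])
  } else {
    lo_edges <- seq_len(dist$bins$n_bins)
    sum(dist$p[lo_edges >= k])
  }
}

#' Confidence interval for a cumulative mass, by group bootstrap
#'
#' Per-top-group cumulative masses are bootstrap-resampled; the interval is
#' the group mean plus/minus the Student-t quantile times the bootstrap
#' standard error, appropriate for the small group counts typical of
#' desk-scale runs.
#'
#' @inheritParams cumulative_mass
#' @param n_boot resamples (default 500).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return named numeric: `estimate`, `lower`, `upper`, `se`.
#' @export
cumulative_mass_ci <- function(dist, threshold, direction = c("below", "above"),
                               n_boot = 500, seed = 1, level = 0.95) {
  direction <- match.arg(direction)
  e <- dist$bins$edges
  k <- which(abs(e - threshold) < 1e-12)
  if (length(k) == 0) stop("threshold ", threshold, " is not a bin edge")
  sel <- if (direction == "below") {
    if (k == 1) integer(0) else seq_len(k - 1)
  } else which(seq_len(dist$bins$n_bins) >= k)
  gmass <- rowSums(dist$group_p[, sel, drop = FALSE])
  g <- length(gmass)
  est <- mean(gmass)
  if (g < 2) return(c(estimate = est, lower = NA, upper = NA, se = NA))
  se <- run_with_seed(seed, function() {
    stats::sd(vapply(seq_len(n_boot), function(b) {
      mean(gmass[sample.int(g, g, replace = TRUE)])
    }, 0))
  })
  tq <- stats::qt(1 - (1 - level) / 2, df = g - 1)
  c(estimate = est, lower = est - tq * se, upper = est + tq * se, se = se)
}

#' Grouped-bar plot of similarity distributions
#'
#' Plots one distribution, or several side by side (e.g. the three
#' divergence levels), as grouped bars with standard-error whiskers.
#'
#' @param x an `interface_distribution`.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @method plot interface_distribution
#' @export
plot.interface_distribution <- function(x, ...) plot_distributions(list(x), ...)

#' @rdname plot.interface_distribution
#' @param dists list of `interface_distribution` objects sharing one
#'   bin specification (e.g. the three divergence levels).
#' @export
plot_distributions <- function(dists, ...) {
  mat <- do.call(rbind, lapply(dists, function(d) d$p))
  rownames(mat) <- vapply(dists, function(d) paste0("D-", d$level), "")
  colnames(mat) <- bin_labels(dists[[1]]$bins)
  mids <- graphics::barplot(mat, beside = TRUE, las = 2,
                            ylab = "probability",
                            xlab = dists[[1]]$measure,
                            legend.text = nrow(mat) > 1, ...)
  for (k in seq_along(dists)) {
    se <- dists[[k]]$se
    if (is.null(se)) next
    nz <- se > 0
    if (!any(nz)) next
    graphics::arrows(mids[k, nz], pmax(0, mat[k, nz] - se[nz]),
                     mids[k, nz], mat[k, nz] + se[nz], angle = 90,
                     code = 3, length = 0.02)
  }
  invisible(mids)
}

#' Distribution table for output
#'
#' @param dist an `interface_distribution`.
#' @param path optional TSV path.
#' @return data.frame: bin_low, bin_high, p, se.
#' @export
distribution_table <- function(dist, path = NULL) {
  e <- dist$bins$edges
  lo <- e[-length(e)]
  hi <- e[-1]
  if (dist$bins$open_top) {
    lo <- c(lo, e[length(e)])
    hi <- c(hi, Inf)
  }
  out <- data.frame(bin_low = lo, bin_high = hi, p = dist$p,
                    se = if (is.null(dist$se)) NA_real_ else dist$se)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
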