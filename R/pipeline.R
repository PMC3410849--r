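#' Run configuration for the end-to-end pipeline
#'
#' Collects every threshold of the analysis; the configuration is serialized
#' into the run manifest so outputs are self-describing.
#'
#' @param input_dir directory of PDB/mmCIF assembly files (ignored when a
#'   `synthetic_world` object is passed to [run_pipeline()]).
#' @param mapping_path chain-to-protein mapping TSV (ditto).
#' @param distance_cutoff interface contact distance in Angstrom (default 6).
#' @param use_dasa enable the dASA admission rule (default TRUE).
#' @param max_resolution entry-filter resolution in Angstrom (default 2.5).
#' @param min_face_size minimum interacting residues per face (default 5).
#' @param measures subset of `c("fps", "l_rms", "i_rms")`.
#' @param caps Interolog subsampling caps (default 50 protein pairs per
#'   family, 50 sequence pairs per protein pair).
#' @param homomer_mode "off", "sequence" or "structural".
#' @param n_boot bootstrap resamples for standard errors (default 200).
#' @param seed run seed (subsampling, bootstrap).
#' @param report_threshold Face Position Similarity below which compared
#'   pairs are listed in the divergent-pair report (default 0.9).
#' @param min_coverage common-residue coverage floor (default 0.3).
#' @param include_intra include intra-assembly copy comparisons (default
#'   TRUE).
#' @param require_xray restrict to X-ray entries (default TRUE).
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, mapping_path = NULL,
                       distance_cutoff = 6, use_dasa = TRUE,
                       max_resolution = 2.5, min_face_size = 5,
                       measures = c("fps", "l_rms", "i_rms"),
                       caps = list(max_prot_pairs = 50, max_seq_pairs = 50),
                       homomer_mode = c("off", "sequence", "structural"),
                       n_boot = 200, seed = 1, report_threshold = 0.9,
                       min_coverage = 0.3, include_intra = TRUE,
                       require_xray = TRUE, output_dir = NULL) {
  homomer_mode <- match.arg(homomer_mode)
  stopifnot(distance_cutoff > 0, max_resolution > 0, min_face_size > 0,
            report_threshold > 0)
  structure(list(input_dir = input_dir, mapping_path = mapping_path,
                 distance_cutoff = distance_cutoff, use_dasa = use_dasa,
                 max_resolution = max_resolution,
                 min_face_size = min_face_size, measures = measures,
                 caps = caps, homomer_mode = homomer_mode, n_boot = n_boot,
                 seed = seed, report_threshold = report_threshold,
                 min_coverage = min_coverage, include_intra = include_intra,
                 require_xray = require_xray, output_dir = output_dir),
            class = "run_config")
}

#' Run the complete interface-variability analysis
#'
#' Ingest, entry filter, hetero-dimer extraction, interface annotation,
#' size filter, copy numbers, hierarchy, pairwise comparison, similarity
#' distributions at all three levels (with bootstrap standard errors),
#' optional homomer best-match filtering and the divergent-pair report.
#' Deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @param world optional `synthetic_world` object; when absent, assemblies
#'   and mapping are read from `config$input_dir` / `config$mapping_path`.
#' @return list of class `pipeline_result`: `assemblies`, `dimers`,
#'   `hierarchy`, `records`, `distributions` (per measure, per level),
#'   `filtered` (when requested), `report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), world = NULL) {
  if (!is.null(world)) {
    assemblies <- world$assemblies
    mapping <- world$mapping
  } else {
    stopifnot(!is.null(config$input_dir), !is.null(config$mapping_path))
    files <- sort(list.files(config$input_dir, "\\.(pdb|cif)$",
                             full.names = TRUE))
    assemblies <- lapply(files, load_assembly)
    names(assemblies) <- vapply(assemblies, function(a) a$assembly_id, "")
    mapping <- read_mapping(config$mapping_path)
  }
  manifest <- list(config = config[setdiff(names(config), "output_dir")],
                   n_entries_read = length(assemblies))

  keep <- vapply(assemblies, function(a) {
    passes_entry_filter(a, mapping, config$max_resolution,
                        config$require_xray)
  }, TRUE)
  assemblies <- assemblies[keep]
  manifest$n_entries_passing_filter <- length(assemblies)
  if (length(assemblies) == 0) stop("no assembly passes the entry filter")

  anno_cfg <- annotation_config(distance_cutoff = config$distance_cutoff,
                                use_dasa = config$use_dasa)
  dimers <- list()
  n_extracted <- 0
  for (a in assemblies) {
    ad <- extract_hetero_dimers(a, mapping, config$distance_cutoff)
    n_extracted <- n_extracted + length(ad)
    if (length(ad) == 0) next
    ad <- lapply(ad, annotate_interface, config = anno_cfg)
    ad <- assign_copy_numbers(ad)
    ad <- Filter(function(d) passes_size_filter(d$interface,
                                                config$min_face_size), ad)
    dimers <- c(dimers, ad)
  }
  manifest$n_dimers_extracted <- n_extracted
  manifest$n_dimers_passing_size_filter <- length(dimers)
  if (length(dimers) < 2) stop("fewer than two hetero-dimers survive")
  names(dimers) <- vapply(dimers, function(d) d$id, "")

  hierarchy <- build_hierarchy(dimers)
  manifest$n_eligible_groups <- list(
    SameSeq = nrow(eligible_groups(hierarchy, "SameSeq")),
    SameProt = nrow(eligible_groups(hierarchy, "SameProt")),
    Interolog = nrow(eligible_groups(hierarchy, "Interolog")))

  records <- pairwise_records(dimers, config$measures, config$min_coverage)
  manifest$n_comparisons_computed <- nrow(records)
  manifest$n_comparisons_valid <- sum(!records$skipped)

  distributions <- list()
  for (m in config$measures) {
    bins <- default_bins(NULL, m)
    dists <- list(
      sameseq = d_sameseq(records, hierarchy, bins, m, config$include_intra),
      sameprot = d_sameprot(records, hierarchy, bins, m,
                            config$include_intra),
      interolog = d_interolog(records, hierarchy, bins, m, config$caps,
                              config$seed, config$include_intra))
    dists <- lapply(dists, function(d) {
      if (is.null(d) || d$n_top_groups < 2) return(d)
      bootstrap_se(d, max(100, config$n_boot), config$seed)
    })
    distributions[[m]] <- dists
  }

  filtered <- NULL
  if (config$homomer_mode != "off") {
    filtered <- list()
    for (m in config$measures) {
      fd <- filtered_distributions(records, hierarchy, dimers, assemblies,
                                   mapping, default_bins(NULL, m), m,
                                   config$homomer_mode, config$caps,
                                   config$seed, config$include_intra,
                                   config$distance_cutoff)
      records <- fd$records
      filtered[[m]] <- fd[setdiff(names(fd), "records")]
    }
    bm_cols <- grep("^best_match", names(records), value = TRUE)
    manifest$n_comparisons_retained <- lapply(
      setNames(bm_cols, bm_cols),
      function(cl) sum(records[[cl]], na.rm = TRUE))
  }

  report <- report_divergent_pairs(records, config$report_threshold)
  manifest$n_divergent_pairs <- nrow(report)

  result <- structure(list(assemblies = assemblies, dimers = dimers,
                           hierarchy = hierarchy, records = records,
                           distributions = distributions,
                           filtered = filtered, report = report,
                           manifest = manifest, mapping = mapping),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(result,
                                                          config$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result: %d/%d entries passed, %d dimers, %d comparisons (%d valid)\n",
              m$n_entries_passing_filter, m$n_entries_read,
              m$n_dimers_passing_size_filter, m$n_comparisons_computed,
              m$n_comparisons_valid))
  invisible(x)
}

#' Report of strongly divergent interface pairs
#'
#' All compared pairs whose combined Face Position Similarity falls below
#' the threshold, sorted ascending, with copy numbers, L_rms, best-match
#' indicators and divergence level.
#'
#' @param records records from [pairwise_records()].
#' @param threshold fps threshold (default 0.9).
#' @param path optional TSV output path.
#' @return data.frame.
#' @export
report_divergent_pairs <- function(records, threshold = 0.9, path = NULL) {
  ok <- !records$skipped & !is.na(records$fps) & records$fps < threshold
  cols <- c("dimerA", "dimerB", "fps", "fps_X", "fps_Y", "l_rms",
            "copy_number_A", "copy_number_B", "level",
            grep("^best_match", names(records), value = TRUE))
  cols <- intersect(cols, names(records))
  out <- records[ok, cols, drop = FALSE]
  out <- out[order(out$fps, out$dimerA, out$dimerB), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num_fmt <- function(df) {
    for (cl in names(df)) if (is.numeric(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], digits = 6, format = "g")
    df
  }
  write.table(num_fmt(records_table(result$records)),
              file.path(dir, "records.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hierarchy_table(result$hierarchy, file.path(dir, "hierarchy.tsv"))
  write.table(num_fmt(result$report), file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(result$distributions)) {
    for (lv in names(result$distributions[[m]])) {
      d <- result$distributions[[m]][[lv]]
      if (is.null(d)) next
      write.table(num_fmt(distribution_table(d)),
                  file.path(dir, sprintf("distribution_%s_%s.tsv", m, lv)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(result$filtered)) {
    for (m in names(result$filtered)) {
      for (lv in names(result$filtered[[m]])) {
        d <- result$filtered[[m]][[lv]]
        if (is.null(d)) next
        write.table(num_fmt(distribution_table(d)),
                    file.path(dir,
                              sprintf("distribution_%s_%s_filtered.tsv",
                                      m, lv)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
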