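#!/usr/bin/env Rscript
# Step 3: the redundancy hierarchy and the pairwise similarity records.
# Dumps the three-level grouping, the full comparison table and the
# divergent-pair report (Face Position Similarity < 0.9).

suppressPackageStartupMessages(library(ppiface))

cache <- "scratch/pipeline_main.rds"
if (!file.exists(cache)) stop("run analysis/02_annotate_interfaces.R first")
res <- readRDS(cache)

hierarchy_table(res$hierarchy, "results/hierarchy.tsv")
for (lv in c("SameSeq", "SameProt", "Interolog")) {
  el <- eligible_groups(res$hierarchy, lv)
  cat(sprintf("%-9s: %d eligible groups\n", lv, nrow(el)))
}

records_table(res$records, "results/pairwise_records.tsv")
ok <- !res$records$skipped
cat(sprintf("\n%d pairwise comparisons (%d valid)\n",
            nrow(res$records), sum(ok)))
cat("by divergence level:\n")
print(as.data.frame(table(level = res$records$level[ok])), row.names = FALSE)
cat(sprintf("median fps %.2f; median L_rms %.2f A; median I_rms %.2f A\n",
            median(res$records$fps[ok], na.rm = TRUE),
            median(res$records$l_rms[ok], na.rm = TRUE),
            median(res$records$i_rms[ok], na.rm = TRUE)))

rep <- report_divergent_pairs(res$records, 0.9, "results/divergent_pairs.tsv")
cat(sprintf("%d comparisons fall below fps 0.9 (results/divergent_pairs.tsv)\n",
            nrow(rep)))
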