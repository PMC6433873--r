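#!/usr/bin/env Rscript
# Printed-table analyses and cross-study comparison: temporal classification
# of the packaged published tables, the cell-wall morphometry test, and
# Venn/overlap analysis of the simulation DEG calls against synthetic
# external-study lists with ortholog-style collapse.
# Reads:  results/sim/*, results/deg.tsv
# Writes: results/table_classes.tsv, results/overlap.tsv

library(abatime)

## published-table fixtures
t3 <- load_fixture_table("table3_early")
cls3 <- classify_printed_table(t3)
cat(sprintf("early ABA-induced table: %d rows; %d early_sustained, %d early_transient, %d annotated Unknown\n",
            nrow(t3), sum(cls3 == "early_sustained"),
            sum(cls3 == "early_transient"), sum(t3$annotation == "Unknown")))

t2 <- load_fixture_table("table2_aba")
bio <- t2[t2$section == "biosynthesis", ]
hit <- bio[!is.na(bio$fc_30) | !is.na(bio$fc_60) | !is.na(bio$fc_180), ]
cat(sprintf("ABA-biosynthesis section: %d of %d genes respond (%s)\n",
            nrow(hit), nrow(bio), paste(hit$gene_id, collapse = ", ")))

t1 <- load_fixture_table("table1_cellwall")
cls1 <- classify_printed_table(t1)
tab_out <- rbind(data.frame(table = "table1_cellwall", gene_id = t1$gene_id,
                            temporal_class = cls1),
                 data.frame(table = "table3_early", gene_id = t3$gene_id,
                            temporal_class = cls3))
dir.create("results", showWarnings = FALSE)
write.table(tab_out, "results/table_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## cell-wall morphometry (printed summaries: 53 +/- 11 vs 37 +/- 8 um, n = 11)
pct <- percent_increase(53, 37)
tt <- two_sample_t_from_summary(53, 11, 11, 37, 8, 11)
cat(sprintf("cell wall %d%% thicker under ABA; Welch t = %.2f, df = %.1f, p = %.2g\n",
            attr(pct, "rounded"), tt$t, tt$df, tt$p_two_sided))

## cross-study comparison on the simulation
truth <- read.delim("results/sim/truth.tsv", stringsAsFactors = FALSE)
degs <- read.delim("results/deg.tsv", stringsAsFactors = FALSE)
ours <- degs$gene_id[degs$temporal_class != "none"]
studies <- list(
  study_A = make_study_lists(truth, dropout = 0.2, contamination = 0.02,
                             seed = 71),
  study_B = make_study_lists(truth, dropout = 0.4, contamination = 0.05,
                             seed = 72))
ov <- cross_study_overlap(ours, studies)
print(ov$pairwise)
cat("regulated in at least k sets:", paste(ov$at_least_k, collapse = " "), "\n")
write.table(ov$pairwise, "results/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## ortholog-style collapse through a synthetic many-to-one best-hit map
set.seed(73)
targets <- sprintf("AT%04d", sample(9999, 1500))
map <- setNames(sample(targets, length(truth$gene_id), replace = TRUE),
                truth$gene_id)
col <- collapse_orthologs(ours, map)
cat(sprintf("%d DEGs collapse to %d unique orthologs (%d paralog groups)\n",
            length(ours), length(col$mapped), length(col$paralog_groups)))
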