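#!/usr/bin/env Rscript
# Step 2 — target prediction tables and non-target composition.
#
# Reads the bundle written by 01_simulate.R, unifies the two prediction
# dialects, summarizes seed-type and region composition of the predicted
# sites, compares the two tools' pair sets, and reports non-target set
# sizes. Tables land in results/tables/.

library(isomirITA)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
p <- bundle_paths("results/bundle")

transcripts <- read_transcripts(p$transcripts_fasta, p$regions)
iso_df <- read.delim(p$isomir_seqs, stringsAsFactors = FALSE)
iso_seqs <- isomir_sequences(iso_df$isomir, iso_df$seq)

rna22 <- read_rna22_table(p$rna22, transcripts, iso_seqs)
ts <- read_targetscan_table(p$targetscan, transcripts, iso_seqs)
both <- union_interactions(rna22, ts)

pct <- function(x) round(100 * table(x) / length(x), 1)
seed_pct <- as.data.frame(pct(rna22$seed_type))
names(seed_pct) <- c("seed_type", "percent")
region_pct <- as.data.frame(pct(rna22$region))
names(region_pct) <- c("region", "percent")
write.table(seed_pct, "results/tables/rna22_seed_type_percent.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(region_pct, "results/tables/rna22_region_percent.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("RNA22-dialect sites: ", nrow(rna22), "; seed-type composition:")
print(seed_pct)

pair_key <- function(tbl) {
  pr <- interaction_pairs(tbl)
  paste(pr$isomir, pr$transcript_id)
}
tool_overlap <- compare_sets(list(RNA22 = pair_key(rna22),
                                  TargetScan = pair_key(ts)))
write.table(tool_overlap$jaccard, "results/tables/tool_pair_overlap.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("pair-level overlap between the two dialects: Jaccard = ",
        round(tool_overlap$jaccard$jaccard, 3))

index <- build_kmer_index(transcripts)
nontargets <- lapply(setNames(iso_seqs$seq, iso_seqs$isomir),
                     compose_nontarget_set, index = index)
sizes <- data.frame(isomir = names(nontargets), n_nontargets = lengths(nontargets))
write.table(sizes, "results/tables/nontarget_set_sizes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("non-target set sizes: median ", median(sizes$n_nontargets),
        ", range ", min(sizes$n_nontargets), "-", max(sizes$n_nontargets))
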