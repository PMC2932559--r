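#!/usr/bin/env Rscript
# Build the synthetic study: four replicate communities sampled 1 mm apart
# in spirit — a shared abundant core, a largely replicate-specific rare
# tail (rho = 0.8), plus representative sequences with planted
# NUNN/UNN/UN structure and raw reads with planted QC failures.

library(finescale)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(preset = "small", rho = 0.8, seed = 42)
cm <- generate_community(spec)
write_count_table(cm$table, file.path(out, "counts.tsv"))
write_count_table(cm$table, file.path(out, "counts.shared"), "mothur-shared")

message(sprintf("community: %d OTUs x %d replicates, %d reads/replicate",
                nrow(cm$table), ncol(cm$table), spec$depth))
message(sprintf("core species: %d of %d; rare-tail replacement rho = %.1f",
                length(cm$truth$core), spec$S, spec$rho))

gs <- generate_sequences(cm, abundant_cutoff = 5)
write_rep_seqs(gs$rep_seqs, file.path(out, "rep_seqs.fasta"))
write_rep_seqs(gs$reference, file.path(out, "reference.fasta"))
write.table(gs$planted, file.path(out, "planted_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("sequences: %d abundant, %d rare (planted: %s)",
                length(gs$abundant_ids), nrow(gs$planted),
                paste(names(table(gs$planted$label)),
                      table(gs$planted$label), collapse = " ", sep = "=")))

reads <- generate_reads_with_quality(
  2000, rates = c(mean_quality = 0.06, primer = 0.03, ambiguous = 0.03,
                  homopolymer = 0.02, length = 0.02),
  seed = spec$seed + 2L)
write_fastq(reads$reads, file.path(out, "reads.fastq"))
message(sprintf("reads: %d with %.0f%% planted failures",
                length(reads$reads), 100 * mean(reads$planted != "pass")))

jsonlite::write_json(
  list(spec = unclass(spec), core = cm$truth$core,
       planted_counts = as.list(table(gs$planted$label))),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", out)
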