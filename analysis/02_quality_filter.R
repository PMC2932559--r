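#!/usr/bin/env Rscript
# Apply the five read filters (mean quality >= 25, exact 27F primer, no
# ambiguous base, homopolymer <= 8, >= 80 bp after trimming) to the
# simulated raw reads and report per-filter attrition.

library(finescale)

reads <- read_fastq("results/sim/reads.fastq")
res <- filter_batch(reads, qc_config())
print(res$report)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_qc_report(res$report, "results/qc/qc_report.tsv")
write_reads_fasta(res$retained, "results/qc/retained.fasta")

message(sprintf("retained %d / %d reads (%.1f%%)",
                res$report$passed, res$report$total_in,
                100 * res$report$retention_fraction))
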