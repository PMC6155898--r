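#!/usr/bin/env Rscript
# Vote-based TDC/TYDC classification of the simulated family and the
# near-identical pTDC pair, using the packaged signature set.
# Run analysis/03_simulate_family.R first.

suppressPackageStartupMessages(library(tdcsig))

fam <- read_fasta("results/family.fasta")
res <- classify_set(fam)
truth <- fam$class_label
cat(sprintf("family classification accuracy: %d/%d\n",
            sum(res$label == truth), nrow(res)))
print(attr(res, "summary"))
write.table(res, "results/family_classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pair <- read_fasta("results/citrus_like_pair.fasta")
pres <- classify_set(pair)
cat("citrus-like pair labels:",
    paste(pres$id, pres$label, sprintf("(%d:%d)", pres$votes_tdc,
                                       pres$votes_tydc)), "\n")
write.table(pres, "results/citrus_pair_classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/family_classification.tsv,",
    "results/citrus_pair_classification.tsv\n")
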