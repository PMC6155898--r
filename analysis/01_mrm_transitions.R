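#!/usr/bin/env Rscript
# The MRM identification arithmetic for tryptamine and its N-methyl
# derivatives: all eight precursor -> product transitions (unlabeled and
# indole-d5), the shared vinylindole products (m/z 144 / 149), and the
# protonated trimethylamine diagnostic ion (m/z 60).

suppressPackageStartupMessages(library(tdcsig))
dir.create("results", showWarnings = FALSE)

tt <- transition_table()
print(tt, row.names = FALSE)
cat(sprintf("\nprotonated trimethylamine diagnostic ion: m/z %d\n",
            protonated_loss_mz(analyte_spec(3))))
cat(sprintf("d5 mass shift across the series: %.4f Da\n",
            formula_mz(analyte_formula(analyte_spec(0, TRUE))) -
              formula_mz(analyte_formula(analyte_spec(0, FALSE)))))

write.table(tt, "results/mrm_transitions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nwrote results/mrm_transitions.tsv\n")
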