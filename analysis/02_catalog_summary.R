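#!/usr/bin/env Rscript
# Bookkeeping of the labeled reference panel: 42 plant aromatic L-amino-acid
# decarboxylase accessions (14 TDC from 10 species, 28 TYDC from 13 species).

suppressPackageStartupMessages(library(tdcsig))
dir.create("results", showWarnings = FALSE)

catalog <- load_catalog()
by_class <- aggregate(accession ~ class, catalog, length)
species <- aggregate(species ~ class, catalog,
                     function(s) length(unique(s)))
summary <- merge(by_class, species, by = "class")
names(summary) <- c("class", "n_accessions", "n_species")
print(summary, row.names = FALSE)
cat(sprintf("total: %d accessions from %d species; Papaver somniferum has %d\n",
            nrow(catalog), length(unique(catalog$species)),
            sum(catalog$species == "Papaver somniferum")))

write.table(summary, "results/catalog_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/catalog_summary.tsv\n")
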