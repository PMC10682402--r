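#!/usr/bin/env Rscript
# Step 5 — gene-set enrichment of the long-lived strains.
#
# Takes the genes whose deletion significantly extended lifespan in the
# screen (step 3) as the hit list, the full set of screened deletion
# genes as the universe, and the synthetic GO-slim style annotation as
# term sets; hypergeometric upper-tail p per term, enrichment score
# -log10(p), Benjamini-Hochberg FDR across terms.

library(rlsfit)

scr <- read_screen_table("results/screen.tsv")
hits <- scr$strain[scr$significant]
universe <- scr$strain[scr$strain != "WT"]
message(length(hits), " hit genes of ", length(universe), " screened")

gmt <- read_gmt(system.file("extdata", "synthetic_goslim.gmt",
                            package = "rlsfit"))
enr <- hypergeom_enrichment(hits, gmt, universe)
utils::write.table(format(enr, digits = 6), "results/enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(enr))) {
  message(sprintf("%-24s k=%d/%d p=%.4g score=%.2f FDR=%.4g%s",
                  enr$term[i], enr$k[i], enr$K[i], enr$p[i],
                  enr$enrichment_score[i], enr$fdr[i],
                  if (enr$strong[i]) "  (FDR < 0.05)" else ""))
}
message("wrote results/enrichment.tsv")
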