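#!/usr/bin/env Rscript
# Step 3 — classify strains against wild-type.
#
# Right-sided two-sample Z tests of each deletion strain's predicted mean
# RLS against the wild-type's, flagged at raw p < 0.05, plus the
# fold-change scatter columns. Also reports replicate concordance: each
# replicate of each strain fitted separately and the two replicate means
# correlated.

library(rlsfit)

fits <- read_screen_table("results/strain_fits.tsv")
scr <- classify_screen(fits, wildtype_id = "WT")
write_screen_table(scr, "results/screen.tsv")

n_tested <- sum(scr$strain != "WT" & scr$converged)
message(sum(scr$significant), " of ", n_tested,
        " deletion strains live significantly longer than wild-type ",
        "(right-sided p < 0.05)")

# replicate concordance on the same cells
cells <- read_cell_table("results/cells.tsv")
rep_means <- lapply(c("rep1", "rep2"), function(rp) {
  f <- fit_strains(cells[cells$replicate == rp, ])
  f$mean_rls[order(f$strain)]
})
pcc <- pearson_cc(rep_means[[1]], rep_means[[2]])
message(sprintf("replicate concordance: PCC = %.3f over %d strains",
                pcc$pcc, pcc$n))
message("wrote results/screen.tsv")
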