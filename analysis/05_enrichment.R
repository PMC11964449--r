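#!/usr/bin/env Rscript
# Step 5: differential enrichment of mutations between the blue-only and
# green-only counter-selection regimes (single-copy runs, final generation).
# Mutations must reach >= 5% frequency in at least one final-generation
# replicate of either regime; each candidate is tested with the binomial
# likelihood-ratio test on replicate-pooled counts and Bonferroni-adjusted.
# Green-shifting mutations (G147S, V162D) are expected to surface as
# green_only-enriched; blue-shifted or neutral markers should not.

library(dupevol)
suppressMessages(library(dplyr))

varroot <- "results/variants"
outroot <- "results"
gen_final <- 5L

load_regime <- function(regime) {
  files <- list.files(varroot,
                      pattern = paste0("^", regime,
                                       "_single_rep[0-9]+_g", gen_final,
                                       "_variants\\.tsv$"),
                      full.names = TRUE)
  if (length(files) == 0) stop("run steps 01-02 first (missing ", regime, ")")
  v <- list(); t <- list()
  for (f in files) {
    rep_id <- as.integer(sub(".*_rep([0-9]+)_g.*", "\\1", f))
    vv <- tibble::as_tibble(utils::read.delim(f))
    pp <- utils::read.delim(sub("_variants\\.tsv$", "_proteins.tsv", f))
    vv <- vv[vv$copy == 1L, ]            # the active copy drives selection
    vv$replicate <- rep_id; vv$generation <- gen_final
    v[[f]] <- vv
    t[[f]] <- tibble::tibble(replicate = rep_id, generation = gen_final,
                             n_genes = length(unique(pp$read_id)))
  }
  list(variants = dplyr::bind_rows(v), totals = dplyr::bind_rows(t))
}

blue <- load_regime("blue_only")
green <- load_regime("green_only")
res <- enrichment_scan(blue$variants, blue$totals,
                       green$variants, green$totals,
                       min_freq = 0.05, alpha = 0.05,
                       final_generation = gen_final)
utils::write.table(res, file.path(outroot, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

res <- res[order(res$p_adjusted), ]
cat("Differential enrichment, blue-only vs green-only (single copy, g5);\n")
cat("strongest 12 of", nrow(res), "candidates:\n")
print(as.data.frame(head(res, 12)), digits = 3)
cat(sprintf("\n%d candidate mutations tested; %d differentially enriched at alpha = 0.05\n",
            nrow(res), sum(res$enriched_in != "none")))
cat("Expect the color trade-off variants at residue 147 at the top;\n")
cat("further significant candidates are hitchhikers on the swept haplotypes\n")
cat("and mutations fixed by drift in bottlenecked replicates - pooling\n")
cat("replicates, as the regime-only GLM does, cannot distinguish those\n")
cat("from selection.\n")
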