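#!/usr/bin/env Rscript
# Step 2: sequence processing. For every simulated run and generation,
# orient the sampled amplicon reads against the reference (recovering the
# random strand through the non-palindromic spacer), keep reads with full
# query coverage, split them into the two gene copies, and call
# amino-acid-level mutations per copy. Writes one variant TSV and one
# per-copy status-ready table per run/generation under results/variants/.

library(dupevol)

anc <- cogfp_ancestor()
simroot <- "results/sim"
outroot <- "results/variants"
dir.create(outroot, showWarnings = FALSE, recursive = TRUE)

runs <- list.dirs(simroot, recursive = FALSE)
if (length(runs) == 0) stop("run analysis/01_simulate.R first")

for (run in runs) {
  tag <- basename(run)
  fastas <- list.files(run, pattern = "_sample\\.fasta$", full.names = TRUE)
  for (fa in fastas) {
    gen <- sub("_sample\\.fasta$", "", basename(fa))
    pr <- suppressMessages(process_amplicons(fa, anc))
    stub <- file.path(outroot, paste0(tag, "_", gen))
    utils::write.table(pr$variants, paste0(stub, "_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pr$copies[, c("read_id", "copy", "protein")],
                       paste0(stub, "_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_drop <- sum(!pr$reads$kept)
    cat(sprintf("%-28s %s: %d reads, %d dropped, %d calls\n", tag, gen,
                nrow(pr$reads), n_drop, nrow(pr$variants)))
  }
}
cat("\nVariant tables written under", outroot, "\n")
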