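#!/usr/bin/env Rscript
# Step 4: population statistics over the processed variant tables.
#   - mean number of nonsynonymous mutations per gene copy, by copy scope
#     (active copy of single-copy runs, its engineered-inactive partner,
#     both copies of double-copy runs);
#   - average pairwise amino-acid distance within each scope;
#   - pooled dN/dS per scope with NG86 site counts on the ancestor;
#   - allele-frequency trajectories of the key mutations G147S, V162D, L98M
#     and their combinations in the green-selection runs.
# The engineered chromophore substitutions (Q74A/Y75S/G76A) are discounted
# from the inactive-copy statistics so that its burden reflects divergence
# accumulated during evolution.

library(dupevol)
suppressMessages(library(dplyr))

anc <- cogfp_ancestor()
sites <- count_sites(anc)
varroot <- "results/variants"
outroot <- "results/stats"
dir.create(outroot, showWarnings = FALSE, recursive = TRUE)

var_files <- list.files(varroot, pattern = "_variants\\.tsv$",
                        full.names = TRUE)
if (length(var_files) == 0) stop("run analysis/02_process_reads.R first")
engineered <- c("Q74A", "Y75S", "G76A")

stats <- list(); traj_v <- list(); traj_t <- list()
for (vf in var_files) {
  base <- sub("_variants\\.tsv$", "", basename(vf))
  gen <- as.integer(sub(".*_g([0-9]+)$", "\\1", base))
  tag <- sub("_g[0-9]+$", "", base)
  parts <- strsplit(tag, "_")[[1]]
  rep_id <- as.integer(sub("rep", "", parts[length(parts)]))
  copy_mode <- parts[length(parts) - 1]
  regime <- paste(parts[-c(length(parts) - 1, length(parts))], collapse = "_")
  variants <- tibble::as_tibble(utils::read.delim(vf))
  prot <- tibble::as_tibble(utils::read.delim(
    file.path(varroot, paste0(base, "_proteins.tsv"))))
  n_reads <- length(unique(prot$read_id))
  scopes <- if (copy_mode == "single")
    list(single_active = 1L, single_inactive = 2L) else
      list(double_both = c(1L, 2L))
  for (sc in names(scopes)) {
    cps <- scopes[[sc]]
    v <- variants[variants$copy %in% cps, ]
    p <- prot[prot$copy %in% cps & !is.na(prot$protein), ]
    excl <- if (sc == "single_inactive") engineered else NULL
    if (!is.null(excl)) {
      # the engineered chromophore substitutions are constitutive, not
      # accumulated divergence: drop them from burden and dN/dS alike
      lab <- paste0(v$ref_aa, v$protein_position, v$alt_aa)
      v <- v[!(lab %in% excl), ]
    }
    samp <- population_sample(p$protein, v, n_genes = n_reads * length(cps),
                              ancestor = anc)
    dn <- suppressWarnings(dnds(samp, sites))
    stats[[paste(base, sc)]] <- tibble::tibble(
      regime = regime, copy_mode = copy_mode, replicate = rep_id,
      generation = gen, copy_scope = sc, n_genes = samp$n,
      mean_nonsyn = mean_mutations(samp, exclude = excl),
      avg_pairwise_dist = avg_pairwise_distance(samp),
      dnds = dn)
  }
  if (regime == "green") {
    variants$generation <- gen; variants$replicate <- rep_id
    variants$copy_mode <- copy_mode
    traj_v[[base]] <- variants
    traj_t[[base]] <- tibble::tibble(copy_mode = copy_mode, generation = gen,
                                     replicate = rep_id, n_genes = 2 * n_reads)
  }
}

stats_tbl <- dplyr::bind_rows(stats)
utils::write.table(stats_tbl, file.path(outroot, "divergence_stats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

key <- c("G147S", "V162D", "L98M", "G147S/L98M", "V162D/L98M",
         "G147S/V162D/L98M")
tv <- dplyr::bind_rows(traj_v); tt <- dplyr::bind_rows(traj_t)
traj <- dplyr::bind_rows(lapply(split(tv, tv$copy_mode), function(v)
  dplyr::mutate(allele_trajectories(v, tt[tt$copy_mode == v$copy_mode[1], -1],
                                    key, anc),
                copy_mode = v$copy_mode[1], .before = 1)))
utils::write.table(traj, file.path(outroot, "key_mutation_trajectories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Divergence statistics (green regime, generation medians over replicates):\n")
med <- stats_tbl |>
  dplyr::filter(.data$regime == "green") |>
  dplyr::group_by(.data$generation, .data$copy_scope) |>
  dplyr::summarise(mean_nonsyn = stats::median(.data$mean_nonsyn),
                   apd = stats::median(.data$avg_pairwise_dist),
                   dnds = stats::median(.data$dnds), .groups = "drop")
print(as.data.frame(med), digits = 3)
cat("\nKey-mutation frequencies at generation 5 (median over replicates):\n")
fin <- traj |>
  dplyr::filter(.data$generation == 5) |>
  dplyr::group_by(.data$copy_mode, .data$mutation) |>
  dplyr::summarise(frequency = stats::median(.data$frequency), .groups = "drop")
print(as.data.frame(fin), digits = 3)
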