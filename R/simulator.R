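# Forward simulator for the directed-evolution experiment: repeated rounds of
# whole-amplicon mutagenesis, genotype -> fluorescence mapping, FACS
# truncation selection, regrowth (multinomial resampling) and re-cloning with
# random promoter swaps. Populations are matrices of integer-encoded
# nucleotides, one row per plasmid, so a 10^4-plasmid round is a handful of
# vectorised operations.

#' Configuration for the directed-evolution simulator
#'
#' Defaults encode the study conditions: libraries above 10^4 plasmids, five
#' generations with survival fractions 60%, 1%, then 0.01% in generations
#' 3-5, a mutagenesis dose of about two nonsynonymous substitutions per gene
#' copy per round, and a per-nonsynonymous-substitution inactivation
#' probability q = 0.668 calibrated so that one round of mutagenesis
#' inactivates a single active copy with probability 1 - exp(-2q) = 0.737.
#'
#' @param population_size Number of plasmids per generation (default 10000).
#' @param generations Number of mutagenesis/selection rounds (default 5).
#' @param survival_fractions Numeric vector, one survival fraction per
#'   generation (default `c(0.60, 0.01, 1e-4, 1e-4, 1e-4)`).
#' @param mean_nonsyn_per_gene Target mean number of nonsynonymous amino-acid
#'   substitutions per gene copy per round (default 2).
#' @param inactivation_prob Probability `q` that a single nonsynonymous
#'   substitution destroys the copy's fluorescence (default 0.668).
#' @param regime Selection regime, one of `"green"`, `"blue"`,
#'   `"green_and_blue"`, `"green_only"`, `"blue_only"`, `"no_selection"`.
#' @param copy_mode `"double"` (two active copies) or `"single"` (copy 2
#'   carries the engineered chromophore knockout for the whole experiment).
#' @param orientation_swap_prob Probability that re-cloning exchanges the
#'   promoter assignment of the two copies (default 0.5).
#' @param seed Integer seed; all randomness of [run_experiment()] derives
#'   from it.
#' @param replicate Replicate label used in FASTA headers (default 1).
#' @param sample_size Number of plasmids sequenced (written to FASTA) per
#'   generation (default 300, the scale of the per-generation clone samples).
#' @return A validated list of class `simulator_config`.
#' @export
simulator_config <- function(population_size = 10000L,
                             generations = 5L,
                             survival_fractions = c(0.60, 0.01, 1e-4, 1e-4, 1e-4),
                             mean_nonsyn_per_gene = 2,
                             inactivation_prob = 0.668,
                             regime = c("green", "blue", "green_and_blue",
                                        "green_only", "blue_only",
                                        "no_selection"),
                             copy_mode = c("double", "single"),
                             orientation_swap_prob = 0.5,
                             seed = 1L,
                             replicate = 1L,
                             sample_size = 300L) {
  regime <- match.arg(regime)
  copy_mode <- match.arg(copy_mode)
  if (population_size < 1) stop("population_size must be >= 1")
  if (generations < 0) stop("generations must be >= 0")
  if (generations > 0 && length(survival_fractions) != generations)
    stop("survival_fractions must have one entry per generation")
  if (any(survival_fractions <= 0 | survival_fractions > 1))
    stop("survival fractions must lie in (0, 1]")
  if (mean_nonsyn_per_gene < 0) stop("mean_nonsyn_per_gene must be >= 0")
  if (inactivation_prob < 0 || inactivation_prob >= 1)
    stop("inactivation_prob must lie in [0, 1)")
  if (orientation_swap_prob < 0 || orientation_swap_prob > 1)
    stop("orientation_swap_prob must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 survival_fractions = survival_fractions,
                 mean_nonsyn_per_gene = mean_nonsyn_per_gene,
                 inactivation_prob = inactivation_prob,
                 regime = regime, copy_mode = copy_mode,
                 orientation_swap_prob = orientation_swap_prob,
                 seed = as.integer(seed), replicate = replicate,
                 sample_size = as.integer(sample_size)),
            class = "simulator_config")
}

#' Genotype-to-fluorescence model
#'
#' A cell's fluorescence in each channel is autofluorescence plus the sum of
#' the contributions of its induced, active gene copies; each active copy
#' contributes the channel base level times the multiplicative factors of any
#' key mutations it carries. Both the copy signal and the autofluorescence
#' term carry multiplicative lognormal cell-to-cell noise (mean 1, coefficient
#' of variation `noise_cv`), so a non-induced negative control yields a
#' continuous autofluorescence distribution to gate against.
#'
#' The default effect table gives the green-shifting substitutions G147S
#' (green x2, blue x0.5) and V162D (green x3, blue x0.3) and the
#' folding-stabilising L98M (x1.5 in both channels). The magnitudes are model
#' defaults, not measured quantities.
#'
#' @param base_green,base_blue Fluorescence of one active ancestral copy
#'   (default 1).
#' @param effects Data frame with columns `position`, `alt`, `green`, `blue`:
#'   a factor applies when the copy's amino acid at `position` equals `alt`.
#' @param noise_cv Lognormal coefficient of variation (default 0.3).
#' @param autofluorescence Autofluorescence level (default 0.05).
#' @return A list of class `phenotype_model`.
#' @export
phenotype_model <- function(base_green = 1, base_blue = 1,
                            effects = default_effects(),
                            noise_cv = 0.3, autofluorescence = 0.05) {
  if (base_green <= 0 || base_blue <= 0) stop("base levels must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!all(c("position", "alt", "green", "blue") %in% names(effects)))
    stop("effects needs columns position, alt, green, blue")
  if (any(effects$green <= 0) || any(effects$blue <= 0))
    stop("effect factors must be positive")
  structure(list(base_green = base_green, base_blue = base_blue,
                 effects = effects, noise_cv = noise_cv,
                 autofluorescence = autofluorescence),
            class = "phenotype_model")
}

#' @rdname phenotype_model
#' @export
default_effects <- function() {
  tibble::tibble(position = c(147L, 162L, 98L),
                 alt = c("S", "D", "M"),
                 green = c(2, 3, 1.5),
                 blue = c(0.5, 0.3, 1.5))
}

#' Calibrate the per-site nucleotide substitution rate
#'
#' Finds the uniform per-site substitution probability `mu` such that a
#' mutagenesis round produces on average `mean_nonsyn_per_gene` nonsynonymous
#' amino-acid changes per gene: `mu = mean / (L * f_nonsyn)`, with `f_nonsyn`
#' the fraction of nonsynonymous changes among all `3L` single-nucleotide
#' mutants of the ancestral coding sequence.
#'
#' @param ancestor An [cogfp_ancestor()] reference (or any object with a
#'   `coding_dna` field).
#' @param mean_nonsyn_per_gene Target mean; 0 returns a zero rate, negative
#'   values are an error.
#' @return The per-site substitution probability.
#' @examples
#' calibrate_nucleotide_rate(cogfp_ancestor(), 2)
#' @export
calibrate_nucleotide_rate <- function(ancestor = cogfp_ancestor(),
                                      mean_nonsyn_per_gene = 2) {
  if (mean_nonsyn_per_gene < 0)
    stop("mean_nonsyn_per_gene must be non-negative")
  if (mean_nonsyn_per_gene == 0) return(0)
  prot <- translate_dna(ancestor$coding_dna)
  if (grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
    stop("ancestor contains an internal stop codon")
  L <- nchar(ancestor$coding_dna)
  f <- enumerate_single_mutants(ancestor$coding_dna)$f_nonsyn
  mu <- mean_nonsyn_per_gene / (L * f)
  if (mu >= 1) stop("requested mutation load exceeds one substitution per site")
  mu
}

# ---- population container ----------------------------------------------

#' Create an unmutated plasmid population
#'
#' @param n Number of plasmids.
#' @param ancestor Reference object.
#' @param copy_mode `"double"` or `"single"`; in single mode copy 2 starts as
#'   the engineered chromophore knockout and is marked `engineered_inactive`.
#' @return A `plasmid_population`: integer DNA matrices `dna1`/`dna2` (one
#'   row per plasmid), functional states `state1`/`state2`, promoter of copy
#'   1 (`promoter1`, copy 2 always carries the other promoter), the ancestor
#'   and the copy mode.
#' @export
new_population <- function(n, ancestor = cogfp_ancestor(),
                           copy_mode = c("double", "single")) {
  copy_mode <- match.arg(copy_mode)
  anc_int <- dna_to_int(ancestor$coding_dna)
  L <- length(anc_int)
  dna1 <- matrix(rep(anc_int, each = n), nrow = n)
  if (copy_mode == "single") {
    dna2 <- matrix(rep(dna_to_int(engineered_inactive_dna(ancestor)), each = n),
                   nrow = n)
    state2 <- rep("engineered_inactive", n)
  } else {
    dna2 <- dna1
    state2 <- rep("active", n)
  }
  structure(list(dna1 = dna1, dna2 = dna2,
                 state1 = rep("active", n), state2 = state2,
                 promoter1 = rep("Ptet", n),
                 copy_mode = copy_mode, ancestor = ancestor,
                 last_round = NULL),
            class = "plasmid_population")
}

#' @export
print.plasmid_population <- function(x, ...) {
  cat("plasmid_population:", nrow(x$dna1), "plasmids,", x$copy_mode,
      "copy mode\n")
  cat("  copy 1 states:", paste(names(table(x$state1)),
                                table(x$state1), collapse = "; "), "\n")
  cat("  copy 2 states:", paste(names(table(x$state2)),
                                table(x$state2), collapse = "; "), "\n")
  invisible(x)
}

# Mutate one copy matrix in place; returns list(m, events) where events is a
# data frame of changed codons (row, codon, aa_old, aa_new).
mutate_matrix <- function(m, mu) {
  n <- nrow(m); L <- ncol(m)
  M <- stats::rbinom(1, n * L, mu)
  if (M == 0)
    return(list(m = m, events = data.frame(row = integer(), codon = integer(),
                                           aa_old = character(),
                                           aa_new = character())))
  pos <- sample.int(n * L, M)
  row <- ((pos - 1L) %% n) + 1L
  col <- ((pos - 1L) %/% n) + 1L
  codon <- ((col - 1L) %/% 3L) + 1L
  key <- (codon - 1L) * n + row
  u <- !duplicated(key)
  urow <- row[u]; ucod <- codon[u]
  c1 <- 3L * ucod - 2L
  old_idx <- (m[cbind(urow, c1)] - 1L) * 16L +
    (m[cbind(urow, c1 + 1L)] - 1L) * 4L + m[cbind(urow, c1 + 2L)]
  m[pos] <- ((m[pos] - 1L + sample.int(3L, M, replace = TRUE)) %% 4L) + 1L
  new_idx <- (m[cbind(urow, c1)] - 1L) * 16L +
    (m[cbind(urow, c1 + 1L)] - 1L) * 4L + m[cbind(urow, c1 + 2L)]
  list(m = m,
       events = data.frame(row = urow, codon = ucod,
                           aa_old = CODON_AA[old_idx],
                           aa_new = CODON_AA[new_idx]))
}

# Apply the inactivation model to one copy's events. Rule-violating
# substitutions (chromophore residues 75/76, premature stop at codons <=220)
# inactivate deterministically; every other nonsynonymous substitution
# inactivates with q_generic, chosen so the marginal inactivation probability
# per nonsynonymous substitution is exactly q.
apply_inactivation <- function(state, events, q, rho) {
  ns <- events[events$aa_new != events$aa_old, , drop = FALSE]
  if (nrow(ns) == 0) return(list(state = state, n_kill = 0L))
  q_generic <- if (rho < q) (q - rho) / (1 - rho) else 0
  rule <- rule_violating(ns$codon, ns$aa_new)
  kills <- rule | (stats::runif(nrow(ns)) < q_generic)
  hit_rows <- unique(ns$row[kills])
  newly <- hit_rows[state[hit_rows] == "active"]
  state[newly] <- "inactivated_by_mutation"
  list(state = state, n_kill = length(newly))
}

#' Mutagenize a population (one round)
#'
#' Every nucleotide of both copies -- including an engineered-inactive copy,
#' which keeps mutating just as it does in the experiment -- is substituted
#' independently with probability `mu`, uniformly among the three alternative
#' bases. Each changed codon whose amino acid differs from the pre-round
#' amino acid is a new nonsynonymous substitution; such a substitution on an
#' `active` copy flips it to `inactivated_by_mutation` deterministically if
#' it violates a sequence activity rule (chromophore residues 75/76,
#' premature stop at codons 1-220) and otherwise with probability
#' `q_generic`, calibrated so the marginal per-substitution inactivation
#' probability equals `q`.
#'
#' @param pop A `plasmid_population`.
#' @param mu Per-site substitution probability in `[0, 1)`.
#' @param q Per-nonsynonymous-substitution inactivation probability.
#' @return The mutated population; `pop$last_round` summarises the round
#'   (per-copy counts of new nonsynonymous/synonymous substitutions).
#' @export
mutagenize <- function(pop, mu, q = 0.668) {
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  if (mu == 0) {
    pop$last_round <- NULL
    return(pop)
  }
  rho <- enumerate_single_mutants(pop$ancestor$coding_dna)$rho_rule
  n <- nrow(pop$dna1)
  summarise_copy <- function(events) {
    ns <- events$aa_new != events$aa_old
    list(nonsyn = tabulate(events$row[ns], nbins = n),
         syn = tabulate(events$row[!ns], nbins = n))
  }
  r1 <- mutate_matrix(pop$dna1, mu)
  pop$dna1 <- r1$m
  i1 <- apply_inactivation(pop$state1, r1$events, q, rho)
  pop$state1 <- i1$state
  r2 <- mutate_matrix(pop$dna2, mu)
  pop$dna2 <- r2$m
  i2 <- apply_inactivation(pop$state2, r2$events, q, rho)
  pop$state2 <- i2$state
  s1 <- summarise_copy(r1$events); s2 <- summarise_copy(r2$events)
  pop$last_round <- list(nonsyn1 = s1$nonsyn, syn1 = s1$syn,
                         nonsyn2 = s2$nonsyn, syn2 = s2$syn)
  pop
}

#' Simulate per-cell fluorescence of a population
#'
#' @param pop A `plasmid_population`.
#' @param model A [phenotype_model()].
#' @param induction Character subset of `c("copy1", "copy2")`; empty means a
#'   non-induced negative control.
#' @param noise Apply lognormal cell-to-cell noise? (default TRUE; FALSE gives
#'   the deterministic expectation).
#' @return A tibble (`FlowEventTable`): `cell_id`, `green`, `blue`,
#'   `induction`.
#' @export
phenotype <- function(pop, model = phenotype_model(),
                      induction = c("copy1", "copy2"), noise = TRUE) {
  n <- nrow(pop$dna1)
  stopifnot(all(induction %in% c("copy1", "copy2")))
  copy_factors <- function(dna) {
    fg <- rep(1, n); fb <- rep(1, n)
    for (k in seq_len(nrow(model$effects))) {
      pos <- model$effects$position[k]
      c1 <- 3L * pos - 2L
      idx <- (dna[, c1] - 1L) * 16L + (dna[, c1 + 1L] - 1L) * 4L + dna[, c1 + 2L]
      hit <- CODON_AA[idx] == model$effects$alt[k]
      fg[hit] <- fg[hit] * model$effects$green[k]
      fb[hit] <- fb[hit] * model$effects$blue[k]
    }
    list(g = fg, b = fb)
  }
  sig_g <- numeric(n); sig_b <- numeric(n)
  if ("copy1" %in% induction) {
    on <- pop$state1 == "active"
    f <- copy_factors(pop$dna1)
    sig_g <- sig_g + ifelse(on, model$base_green * f$g, 0)
    sig_b <- sig_b + ifelse(on, model$base_blue * f$b, 0)
  }
  if ("copy2" %in% induction) {
    on <- pop$state2 == "active"
    f <- copy_factors(pop$dna2)
    sig_g <- sig_g + ifelse(on, model$base_green * f$g, 0)
    sig_b <- sig_b + ifelse(on, model$base_blue * f$b, 0)
  }
  ln <- function() {
    if (!noise || model$noise_cv == 0) return(rep(1, n))
    s2 <- log(1 + model$noise_cv^2)
    exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
  }
  green <- model$autofluorescence * ln() + sig_g * ln()
  blue <- model$autofluorescence * ln() + sig_b * ln()
  tibble::tibble(cell_id = seq_len(n), green = green, blue = blue,
                 induction = paste(induction, collapse = "+"))
}

#' Truncation selection on a flow-event table
#'
#' Models a FACS sorting gate as truncation selection: keep the top
#' `round(fraction * n)` cells (at least one) ranked on the regime's
#' channel(s), with ties broken at random. `green_and_blue` ranks cells by
#' the worse of their two channel ranks (the analogue of intersecting two
#' truncation gates at an exact survivor count); `green_only`/`blue_only`
#' first restrict to cells below the opposite channel's negative-control
#' threshold; `no_selection` draws a uniform random sample.
#'
#' @param events A flow-event table with columns `green` and `blue`.
#' @param regime Selection regime (see [simulator_config()]).
#' @param fraction Survival fraction in (0, 1].
#' @param thresholds Named numeric `c(green=, blue=)` negative-control gate
#'   thresholds; required for the `*_only` regimes.
#' @return Integer vector of surviving row indices.
#' @export
select_survivors <- function(events, regime, fraction, thresholds = NULL) {
  n <- nrow(events)
  if (n == 0) stop("empty event table")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  k <- max(1L, round(fraction * n))
  rank_desc <- function(x) {
    # rank 1 = highest value; random tie-break
    ord <- order(-x, stats::runif(n))
    r <- integer(n); r[ord] <- seq_len(n); r
  }
  pick_top <- function(score_rank, idx = seq_len(n), kk = k) {
    idx[order(score_rank[idx])][seq_len(min(kk, length(idx)))]
  }
  switch(regime,
    green = pick_top(rank_desc(events$green)),
    blue = pick_top(rank_desc(events$blue)),
    green_and_blue = pick_top(pmax(rank_desc(events$green),
                                   rank_desc(events$blue))),
    green_only = {
      if (is.null(thresholds)) stop("green_only needs negative-gate thresholds")
      elig <- which(events$blue <= thresholds[["blue"]])
      if (length(elig) == 0) stop("no cells below the blue negative gate")
      pick_top(rank_desc(events$green), elig)
    },
    blue_only = {
      if (is.null(thresholds)) stop("blue_only needs negative-gate thresholds")
      elig <- which(events$green <= thresholds[["green"]])
      if (length(elig) == 0) stop("no cells below the green negative gate")
      pick_top(rank_desc(events$blue), elig)
    },
    no_selection = sample.int(n, k),
    stop("unknown regime: ", regime)
  )
}

#' Re-cloning step: random promoter swap
#'
#' Re-inserting the mutagenized two-copy cassette into a fresh backbone can
#' occur in either direction, so with probability `swap_prob` each plasmid's
#' two copies exchange promoters. Sequences and functional states are
#' untouched.
#'
#' @param pop A `plasmid_population`.
#' @param swap_prob Swap probability in `[0, 1]`.
#' @return The population with updated `promoter1`.
#' @export
reclone <- function(pop, swap_prob = 0.5) {
  if (swap_prob < 0 || swap_prob > 1) stop("swap_prob must lie in [0, 1]")
  if (swap_prob == 0) return(pop)
  n <- length(pop$promoter1)
  swap <- stats::runif(n) < swap_prob
  pop$promoter1[swap] <- ifelse(pop$promoter1[swap] == "Ptet", "Ptac", "Ptet")
  pop
}

# Multinomial resampling of survivors back to full library size.
resample_population <- function(pop, idx, size) {
  take <- idx[sample.int(length(idx), size, replace = TRUE)]
  pop$dna1 <- pop$dna1[take, , drop = FALSE]
  pop$dna2 <- pop$dna2[take, , drop = FALSE]
  pop$state1 <- pop$state1[take]
  pop$state2 <- pop$state2[take]
  pop$promoter1 <- pop$promoter1[take]
  pop$last_round <- NULL
  pop
}

# ---- truth tables and sequence export -----------------------------------

#' Per-copy truth table of a population
#'
#' Mutation calls are counted against the *active* ancestral coding sequence
#' for both copies (the reference the read-processing stage uses), so the
#' engineered chromophore substitutions of a single-copy control appear in
#' the counts of copy 2.
#'
#' @param pop A `plasmid_population`.
#' @param indices Rows to report (default all).
#' @return Tibble: `index`, `copy`, `functional_state`, `n_nonsyn`, `n_syn`.
#' @export
truth_table <- function(pop, indices = seq_len(nrow(pop$dna1))) {
  anc_aa <- strsplit(pop$ancestor$protein, "")[[1]]
  anc_int <- dna_to_int(pop$ancestor$coding_dna)
  one_copy <- function(dna, state, copy) {
    m <- dna[indices, , drop = FALSE]
    aa <- aa_matrix(m)
    changed_codon <- codon_index_matrix(m) !=
      rep(codon_index_matrix(matrix(anc_int, nrow = 1)), each = nrow(m))
    nonsyn <- changed_codon & (aa != rep(anc_aa, each = nrow(m)))
    syn <- changed_codon & !nonsyn
    tibble::tibble(index = indices, copy = copy,
                   functional_state = state[indices],
                   n_nonsyn = rowSums(nonsyn), n_syn = rowSums(syn))
  }
  dplyr::bind_rows(one_copy(pop$dna1, pop$state1, 1L),
                   one_copy(pop$dna2, pop$state2, 2L))
}

#' Full mutation calls for a population (simulator truth)
#'
#' Codon-by-codon comparison of every copy against the active ancestral
#' coding sequence, in the same format as [call_mutations()] produces from
#' reads.
#'
#' @param pop A `plasmid_population`.
#' @param indices Rows to report (default all).
#' @return Tibble: `index`, `copy`, `protein_position`, `ref_aa`, `alt_aa`,
#'   `synonymous`, `codon_ref`, `codon_alt`.
#' @export
truth_calls <- function(pop, indices = seq_len(nrow(pop$dna1))) {
  anc_int <- dna_to_int(pop$ancestor$coding_dna)
  anc_cod <- codon_index_matrix(matrix(anc_int, nrow = 1))[1, ]
  anc_aa <- CODON_AA[anc_cod]
  one_copy <- function(dna, copy) {
    m <- dna[indices, , drop = FALSE]
    cod <- codon_index_matrix(m)
    hit <- which(cod != rep(anc_cod, each = nrow(m)), arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    pos <- hit[, 2]
    alt_idx <- cod[hit]
    tibble::tibble(index = indices[hit[, 1]], copy = copy,
                   protein_position = as.integer(pos),
                   ref_aa = anc_aa[pos], alt_aa = CODON_AA[alt_idx],
                   synonymous = anc_aa[pos] == CODON_AA[alt_idx],
                   codon_ref = CODON_STRINGS[anc_cod[pos]],
                   codon_alt = CODON_STRINGS[alt_idx])
  }
  out <- dplyr::bind_rows(one_copy(pop$dna1, 1L), one_copy(pop$dna2, 2L))
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, .data$index, .data$copy, .data$protein_position)
}

#' Export plasmids as full-length amplicon reads on random strands
#'
#' Emulates consensus long reads of the palindromic construct: one record per
#' sampled plasmid, the full amplicon (copy1 + spacer + revcomp(copy2)),
#' emitted on a uniformly random strand so that downstream processing must
#' recover the orientation.
#'
#' @param pop A `plasmid_population`.
#' @param indices Plasmid rows to export.
#' @param generation,replicate,regime Header fields; headers read
#'   `g{gen}_r{rep}_{regime}_{index}`.
#' @return A named [Biostrings::DNAStringSet] with a `strand` metadata column
#'   (`+` as constructed, `-` reverse-complemented).
#' @export
population_fasta <- function(pop, indices, generation, replicate = 1,
                             regime = "green") {
  seqs <- vapply(seq_along(indices), function(j) {
    i <- indices[j]
    build_amplicon(int_to_dna(pop$dna1[i, ]), int_to_dna(pop$dna2[i, ]),
                   pop$ancestor)
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sprintf("g%d_r%s_%s_%d", generation, replicate, regime,
                        seq_along(indices))
  flip <- stats::runif(length(dss)) < 0.5
  dss[flip] <- Biostrings::reverseComplement(dss[flip])
  S4Vectors::mcols(dss)$strand <- ifelse(flip, "-", "+")
  dss
}

# ---- orchestration ------------------------------------------------------

#' Run a full directed-evolution experiment
#'
#' For each generation: mutagenize the whole library, record the
#' pre-selection flow-event table and a matched non-induced negative control
#' (for robustness gating), apply truncation selection, resample survivors
#' with replacement back to the library size (regrowth), re-clone with random
#' promoter swaps, and export a sequenced sample (FASTA on random strands)
#' with its truth tables. All randomness derives from `config$seed`.
#'
#' @param config A [simulator_config()].
#' @param model A [phenotype_model()].
#' @param keep_populations Keep each generation's post-selection population
#'   matrices in the result? (memory-heavy; default FALSE).
#' @return An object of class `evo_experiment`: `config`, `model`, and
#'   `generations`, a list with one entry per generation holding `events`
#'   (pre-selection), `negative_control`, `gate` (a [gate_and_summarize()]
#'   result on the pre-selection events), `survivors`, `reads` (FASTA sample
#'   of the post-selection population), `truth` and `truth_calls` for the
#'   sampled plasmids, and `activity` (population fractions of plasmids with
#'   both/one/no active copies after selection). With `generations = 0` the
#'   ancestral population is exported unchanged as generation 0.
#' @export
run_experiment <- function(config = simulator_config(),
                           model = phenotype_model(),
                           keep_populations = FALSE) {
  set.seed(config$seed)
  anc <- cogfp_ancestor()
  mu <- calibrate_nucleotide_rate(anc, config$mean_nonsyn_per_gene)
  pop <- new_population(config$population_size, anc, config$copy_mode)
  gens <- list()
  channel <- switch(config$regime,
                    green = , green_only = "green",
                    blue = , blue_only = "blue",
                    green_and_blue = , no_selection = "either")
  emit_sample <- function(pop, gen) {
    idx <- sample.int(nrow(pop$dna1), min(config$sample_size, nrow(pop$dna1)))
    list(reads = population_fasta(pop, idx, gen, config$replicate,
                                  config$regime),
         truth = truth_table(pop, idx),
         truth_calls = truth_calls(pop, idx),
         sample_indices = idx)
  }
  if (config$generations == 0) {
    s <- emit_sample(pop, 0L)
    gens[["g0"]] <- c(s, list(events = phenotype(pop, model),
                              negative_control = phenotype(pop, model,
                                                           character(0))))
    return(structure(list(config = config, model = model, generations = gens,
                          final_population = pop),
                     class = "evo_experiment"))
  }
  for (g in seq_len(config$generations)) {
    pop <- mutagenize(pop, mu, config$inactivation_prob)
    events <- phenotype(pop, model)
    negctrl <- phenotype(pop, model, character(0))
    gate <- gate_and_summarize(events, negctrl, channel = channel)
    thr <- c(green = gate$threshold_green, blue = gate$threshold_blue)
    surv <- select_survivors(events, config$regime,
                             config$survival_fractions[g], thr)
    pop <- resample_population(pop, surv, config$population_size)
    pop <- reclone(pop, config$orientation_swap_prob)
    s <- emit_sample(pop, g)
    act <- plasmid_activity(pop$state1, pop$state2)
    gens[[paste0("g", g)]] <- c(
      list(generation = g, events = events, negative_control = negctrl,
           gate = gate, survivors = surv,
           activity = c(prop.table(table(factor(act,
             levels = c("both_active", "one_active", "none_active")))))),
      s,
      if (keep_populations) list(population = pop) else NULL)
  }
  structure(list(config = config, model = model, generations = gens,
                 final_population = pop),
            class = "evo_experiment")
}

#' Write the outputs of an experiment to disk
#'
#' One FASTA (sequenced sample), one flow-event TSV, one negative-control
#' TSV, and one truth TSV per generation, plus a run summary TSV.
#'
#' @param exp An `evo_experiment`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(exp, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list()
  for (nm in names(exp$generations)) {
    g <- exp$generations[[nm]]
    Biostrings::writeXStringSet(g$reads, file.path(outdir,
                                                   paste0(nm, "_sample.fasta")))
    tsv(g$events, paste0(nm, "_events.tsv"))
    tsv(g$negative_control, paste0(nm, "_negctrl.tsv"))
    tsv(g$truth, paste0(nm, "_truth.tsv"))
    if (!is.null(g$truth_calls) && nrow(g$truth_calls) > 0)
      tsv(g$truth_calls, paste0(nm, "_truth_calls.tsv"))
    if (!is.null(g$gate))
      summ[[nm]] <- tibble::tibble(
        generation = g$generation,
        fraction_fluorescent = g$gate$fraction_fluorescent,
        median_green = g$gate$median_green, median_blue = g$gate$median_blue,
        both_active = g$activity[["both_active"]],
        one_active = g$activity[["one_active"]],
        none_active = g$activity[["none_active"]])
  }
  if (length(summ) > 0) tsv(dplyr::bind_rows(summ), "run_summary.tsv")
  invisible(outdir)
}
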