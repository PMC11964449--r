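# Population-level statistics: mutation burden, average pairwise amino-acid
# distance, Nei-Gojobori (NG86) dN/dS with the pooled-count formula,
# allele-frequency trajectories, flow-cytometry gating, and the two
# closed-form robustness quantities for duplicated genes.

#' A population sample of per-copy gene variants
#'
#' Light container for the sequence statistics: per-copy protein (and
#' optionally DNA) sequences of a sample from one generation / replicate /
#' regime, plus their mutation calls against the shared ancestor.
#'
#' @param proteins Character vector of amino-acid sequences (one per gene
#'   copy in the sample).
#' @param calls Tibble of mutation calls (as from [call_mutations()] or
#'   [truth_calls()]); may be NULL if only pairwise distances are needed.
#' @param n_genes Number of gene copies the calls refer to (defaults to
#'   `length(proteins)`); required because genes without mutations have no
#'   call rows.
#' @param ancestor The shared [cogfp_ancestor()] reference.
#' @return A list of class `population_sample`.
#' @export
population_sample <- function(proteins, calls = NULL,
                              n_genes = length(proteins),
                              ancestor = cogfp_ancestor()) {
  structure(list(proteins = proteins, calls = calls,
                 n = as.integer(n_genes), ancestor = ancestor),
            class = "population_sample")
}

#' Mean number of mutations per gene
#'
#' Arithmetic mean of per-gene amino-acid mutation counts (nonsynonymous
#' only by default), counting genes without calls as zero.
#'
#' @param sample A [population_sample()] with calls.
#' @param nonsyn_only Count only nonsynonymous calls? (default TRUE)
#' @param exclude Optional character vector of mutation labels (e.g.
#'   `c("Q74A","Y75S","G76A")`) to ignore — used to discount the engineered
#'   chromophore knockout of single-copy controls.
#' @return The mean count.
#' @export
mean_mutations <- function(sample, nonsyn_only = TRUE, exclude = NULL) {
  if (sample$n < 1) stop("empty sample")
  calls <- sample$calls
  if (is.null(calls)) stop("sample carries no mutation calls")
  calls <- calls[!is.na(calls$protein_position), ]  # drops frameshift rows
  if (nonsyn_only) calls <- calls[!calls$synonymous, ]
  if (!is.null(exclude)) {
    lab <- paste0(calls$ref_aa, calls$protein_position, calls$alt_aa)
    calls <- calls[!(lab %in% exclude), ]
  }
  nrow(calls) / sample$n
}

#' Average pairwise amino-acid distance within a sample
#'
#' The mean number of amino-acid differences over all ordered pairs,
#' `1/(n(n-1)) * sum_i sum_{j!=i} delta_ij`. Computed exactly (via per-site
#' letter counts, which equals the brute-force double sum) whenever
#' `n(n-1) <= 2 * max_pairs`; otherwise estimated from `max_pairs` uniformly
#' sampled pairs, an unbiased estimator of the exact value.
#'
#' @param sample A [population_sample()] (equal-length proteins; sequences of
#'   deviating length are dropped with a warning).
#' @param max_pairs Subsampling threshold (default 250000 unordered pairs).
#' @param seed Optional seed for the pair subsample.
#' @return The average pairwise distance.
#' @export
avg_pairwise_distance <- function(sample, max_pairs = 250000L, seed = NULL) {
  prot <- sample$proteins
  len <- nchar(prot)
  if (length(unique(len)) > 1) {
    keep <- len == stats::median(len)
    warning(sum(!keep), " sequences of deviating length dropped")
    prot <- prot[keep]
  }
  n <- length(prot)
  if (n < 2) stop("need at least 2 sequences for pairwise distances")
  m <- do.call(rbind, strsplit(prot, ""))
  if (n * (n - 1) <= 2 * max_pairs) {
    # exact: per column, ordered unequal pairs = n^2 - sum_a count_a^2
    tot <- 0
    for (j in seq_len(ncol(m))) {
      cnt <- table(m[, j])
      tot <- tot + (n^2 - sum(cnt^2))
    }
    return(tot / (n * (n - 1)))
  }
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n - 1L, max_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)   # uniform over ordered pairs i != j
  mean(rowSums(m[i, , drop = FALSE] != m[j, , drop = FALSE]))
}

#' Nei-Gojobori (NG86) synonymous and nonsynonymous site counts
#'
#' For each codon of the ancestral coding sequence, the nonsynonymous
#' (synonymous) site count is the number of the nine single-nucleotide
#' neighbours that change (preserve) the amino acid, divided by three;
#' stop-introducing changes count as nonsynonymous. A terminal stop codon is
#' excluded. Per codon N + S = 3.
#'
#' @param ancestor An [cogfp_ancestor()] reference (or a list with
#'   `coding_dna`).
#' @return A list of class `site_counts`: `N` (nonsynonymous sites), `S`
#'   (synonymous sites), `n_codons` (codons considered).
#' @examples
#' count_sites(list(coding_dna = "TTT"))  # Phe: S = 1/3, N = 8/3
#' @export
count_sites <- function(ancestor = cogfp_ancestor()) {
  x <- dna_to_int(ancestor$coding_dna)
  aa <- aa_matrix(matrix(x, nrow = 1))[1, ]
  n_cod <- length(aa)
  if (any(aa[-n_cod] == "*")) stop("internal stop codon in ancestor")
  keep <- if (aa[n_cod] == "*") seq_len(n_cod - 1) else seq_len(n_cod)
  N <- 0; S <- 0
  for (cod in keep) {
    base <- x[(3 * cod - 2):(3 * cod)]
    idx0 <- (base[1] - 1L) * 16L + (base[2] - 1L) * 4L + base[3]
    for (p in 1:3) {
      mult <- c(16L, 4L, 1L)[p]
      for (shift in 1:3) {
        alt <- ((base[p] - 1L + shift) %% 4L) + 1L
        idx <- idx0 + (alt - base[p]) * mult
        if (CODON_AA[idx] == aa[cod]) S <- S + 1 / 3 else N <- N + 1 / 3
      }
    }
  }
  structure(list(N = N, S = S, n_codons = length(keep)),
            class = "site_counts")
}

#' Pooled dN/dS ratio of a sample
#'
#' The raw pooled-count ratio: (nonsynonymous mutations / nonsynonymous
#' sites) divided by (synonymous mutations / synonymous sites), with no
#' multiple-hit correction. Calls at the terminal stop codon are excluded,
#' matching the site counts.
#'
#' @param sample A [population_sample()] with calls.
#' @param sites A [count_sites()] result for the shared ancestor.
#' @return The ratio; `Inf` with attribute `undefined = TRUE` and a warning
#'   when the pooled sample has no synonymous mutation.
#' @export
dnds <- function(sample, sites = count_sites(sample$ancestor)) {
  calls <- sample$calls
  if (is.null(calls)) stop("sample carries no mutation calls")
  calls <- calls[!is.na(calls$protein_position) &
                   calls$protein_position <= sites$n_codons, ]
  n_non <- sum(!calls$synonymous)
  n_syn <- sum(calls$synonymous)
  if (n_syn == 0) {
    warning("no synonymous mutations in the pooled sample; dN/dS undefined")
    return(structure(Inf, undefined = TRUE))
  }
  (n_non / sites$N) / (n_syn / sites$S)
}

#' Allele-frequency trajectories of mutations and combinations
#'
#' The frequency of a mutation is the fraction of gene copies carrying the
#' call; a combination label such as `"V162D/L98M"` requires all component
#' calls on the same copy. Frequencies are computed per generation and
#' replicate (and regime, when present).
#'
#' @param variants Tidy tibble of calls with at least `generation`,
#'   `replicate`, `read_id`, `copy`, `protein_position`, `ref_aa`, `alt_aa`
#'   (a `regime` column is carried through if present).
#' @param totals Tibble with `generation`, `replicate` (and `regime`) and
#'   `n_genes`, the number of gene copies sampled per group (genes without
#'   calls do not appear in `variants`).
#' @param mutations Character vector of labels (`"G147S"`, or combinations
#'   `"V162D/L98M"`). Default: every single mutation present. Unknown labels
#'   (never seen and not parseable against the ancestor) are an error.
#' @param ancestor Reference used to validate labels.
#' @return Tibble: grouping columns, `mutation`, `frequency`.
#' @export
allele_trajectories <- function(variants, totals, mutations = NULL,
                                ancestor = cogfp_ancestor()) {
  grp <- intersect(c("generation", "replicate", "regime"), names(totals))
  variants <- dplyr::mutate(
    variants, label = paste0(.data$ref_aa, .data$protein_position,
                             .data$alt_aa))
  if (is.null(mutations)) mutations <- sort(unique(variants$label))
  anc_aa <- strsplit(ancestor$protein, "")[[1]]
  parse_ok <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Z*])([0-9]+)([A-Z*])$", lab))[[1]]
    length(m) == 4 && as.integer(m[3]) <= length(anc_aa) &&
      anc_aa[as.integer(m[3])] == m[2]
  }
  for (lab in unlist(strsplit(mutations, "/", fixed = TRUE)))
    if (!lab %in% variants$label && !parse_ok(lab))
      stop("unknown mutation label: ", lab)
  out <- list()
  for (mut in mutations) {
    parts <- strsplit(mut, "/", fixed = TRUE)[[1]]
    hits <- dplyr::summarise(
      dplyr::group_by(variants[variants$label %in% parts, ],
                      dplyr::across(dplyr::all_of(c(grp, "read_id", "copy")))),
      all_present = length(unique(.data$label)) == length(parts),
      .groups = "drop")
    cnt <- dplyr::summarise(
      dplyr::group_by(hits[hits$all_present, ],
                      dplyr::across(dplyr::all_of(grp))),
      k = dplyr::n(), .groups = "drop")
    tab <- dplyr::left_join(totals, cnt, by = grp)
    tab$k[is.na(tab$k)] <- 0L
    tab <- dplyr::mutate(tab, mutation = mut,
                         frequency = .data$k / .data$n_genes)
    out[[mut]] <- tab[, c(grp, "mutation", "frequency")]
  }
  dplyr::bind_rows(out)
}

#' Gate a flow-event table against a non-induced negative control
#'
#' Thresholds are per-channel quantiles of the negative control (default
#' 0.999); a cell is fluorescent when it exceeds the threshold of the
#' relevant channel (`"green"`, `"blue"`, or `"either"`). Median
#' fluorescence is reported over all events, or over the gated events when
#' `gated_medians = TRUE` (the convention for post-selection population
#' summaries).
#'
#' @param events,negative_control Flow-event tables (columns `green`,
#'   `blue`), both non-empty.
#' @param quantile Negative-control quantile defining the gate, in (0, 1).
#' @param channel Which channel(s) define "fluorescent".
#' @param gated_medians Compute medians on gated events only?
#' @return A list of class `gating_result`: `threshold_green`,
#'   `threshold_blue`, `fraction_fluorescent` (percent), `median_green`,
#'   `median_blue`, `n_events`.
#' @export
gate_and_summarize <- function(events, negative_control, quantile = 0.999,
                               channel = c("green", "blue", "either"),
                               gated_medians = FALSE) {
  channel <- match.arg(channel)
  if (nrow(events) == 0 || nrow(negative_control) == 0)
    stop("empty event table")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  thr_g <- stats::quantile(negative_control$green, quantile, names = FALSE)
  thr_b <- stats::quantile(negative_control$blue, quantile, names = FALSE)
  fluor <- switch(channel,
                  green = events$green > thr_g,
                  blue = events$blue > thr_b,
                  either = events$green > thr_g | events$blue > thr_b)
  sel <- if (gated_medians) fluor else rep(TRUE, nrow(events))
  structure(list(threshold_green = thr_g, threshold_blue = thr_b,
                 fraction_fluorescent = 100 * mean(fluor),
                 median_green = stats::median(events$green[sel]),
                 median_blue = stats::median(events$blue[sel]),
                 n_events = nrow(events)),
            class = "gating_result")
}

#' Predicted fraction of double-copy plasmids with no active copy
#'
#' If one round of mutagenesis preserves a single copy's function with
#' probability `p_preserve`, then `100 * (1 - p_preserve)^2` percent of
#' double-copy plasmids are expected to lose both copies.
#'
#' @param p_preserve Per-copy preservation probability in `[0, 1]`.
#' @return A list: `percent` (unrounded) and `display` (nearest integer
#'   percent, for reporting).
#' @examples
#' predicted_double_copy_loss(0.26)  # 54.76, displayed 55
#' @export
predicted_double_copy_loss <- function(p_preserve) {
  if (p_preserve < 0 || p_preserve > 1)
    stop("p_preserve must lie in [0, 1]")
  pct <- 100 * (1 - p_preserve)^2
  list(percent = pct, display = round(pct))
}

#' Ratio of per-mutation hit probabilities: two copies vs one
#'
#' The probability that at least one of two copies receives a specific
#' mutation, relative to a single copy: `[1 - (1 - p)^2] / p`, which tends
#' to 2 for rare mutations.
#'
#' @param p_mut Per-copy mutation probability in `[0, 1]`.
#' @return The ratio; at `p_mut = 0` the limit 2 is returned with attribute
#'   `limit = TRUE`.
#' @examples
#' duplicate_hit_ratio(0.5)  # 1.5
#' @export
duplicate_hit_ratio <- function(p_mut) {
  if (p_mut < 0 || p_mut > 1) stop("p_mut must lie in [0, 1]")
  if (p_mut == 0) return(structure(2, limit = TRUE))
  (1 - (1 - p_mut)^2) / p_mut
}

#' Selection-free sequence evolution (neutral baseline)
#'
#' Evolves `n` independent copies of the ancestral gene through `rounds` of
#' uniform nucleotide substitution with no selection and no inactivation —
#' the neutral baseline whose pooled dN/dS should equal 1 under NG86 site
#' counting. `mode = "synonymous_only"` reverts every amino-acid-changing
#' substitution, leaving purely synonymous divergence (used to probe
#' classifier specificity).
#'
#' @param ancestor The reference.
#' @param n Number of genes.
#' @param rounds Number of mutagenesis rounds.
#' @param mu Per-site substitution probability per round (default: the
#'   calibrated rate for 2 nonsynonymous substitutions per gene).
#' @param mode `"all"` or `"synonymous_only"`.
#' @return A [population_sample()] whose calls are the truth-style codon
#'   comparison against the ancestor.
#' @export
simulate_neutral_genes <- function(ancestor = cogfp_ancestor(), n = 1000,
                                   rounds = 5,
                                   mu = calibrate_nucleotide_rate(ancestor, 2),
                                   mode = c("all", "synonymous_only")) {
  mode <- match.arg(mode)
  anc_int <- dna_to_int(ancestor$coding_dna)
  m <- matrix(rep(anc_int, each = n), nrow = n)
  for (r in seq_len(rounds)) {
    res <- mutate_matrix(m, mu)
    if (mode == "synonymous_only" && nrow(res$events) > 0) {
      ns <- res$events[res$events$aa_new != res$events$aa_old, , drop = FALSE]
      if (nrow(ns) > 0) {
        # restore the pre-round codon contents
        for (p in 0:2) {
          cols <- 3L * ns$codon - 2L + p
          res$m[cbind(ns$row, cols)] <- m[cbind(ns$row, cols)]
        }
      }
    }
    m <- res$m
  }
  aa <- aa_matrix(m)
  proteins <- apply(aa, 1, paste, collapse = "")
  pop <- list(dna1 = m, dna2 = m[0, , drop = FALSE], state1 = rep("active", n),
              state2 = character(0), ancestor = ancestor)
  anc_cod <- codon_index_matrix(matrix(anc_int, nrow = 1))[1, ]
  cod <- codon_index_matrix(m)
  hit <- which(cod != rep(anc_cod, each = n), arr.ind = TRUE)
  calls <- if (nrow(hit) == 0) NULL else {
    pos <- hit[, 2]
    anc_aa <- CODON_AA[anc_cod]
    tibble::tibble(index = hit[, 1], copy = 1L,
                   protein_position = as.integer(pos),
                   ref_aa = anc_aa[pos], alt_aa = CODON_AA[cod[hit]],
                   synonymous = anc_aa[pos] == CODON_AA[cod[hit]])
  }
  population_sample(proteins, calls, n_genes = n, ancestor = ancestor)
}
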