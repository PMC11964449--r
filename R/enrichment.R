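# Differential enrichment of mutations between two selection regimes
# (blue-only vs green-only): restrict to mutations that reached at least 5%
# frequency in some final-generation replicate, test each with a binomial
# likelihood-ratio test (the analysis-of-deviance of a logit-link GLM with
# regime as the sole predictor), and Bonferroni-adjust.

#' Frequency filter for candidate mutations
#'
#' A mutation is a candidate if its frequency is at least `min_freq`
#' (inclusive) in at least one replicate of either regime at the final
#' generation.
#'
#' @param trajectories Output of [allele_trajectories()] with `regime`,
#'   `replicate`, `generation`, `mutation`, `frequency` columns covering the
#'   final generation of both regimes.
#' @param min_freq Frequency threshold (default 0.05).
#' @param final_generation Generation at which the filter applies
#'   (default 5).
#' @return Character vector of candidate mutation labels.
#' @export
frequency_filter <- function(trajectories, min_freq = 0.05,
                             final_generation = 5L) {
  fin <- trajectories[trajectories$generation == final_generation, ]
  if (nrow(fin) == 0) stop("trajectories do not cover the final generation")
  sort(unique(fin$mutation[fin$frequency >= min_freq]))
}

#' Binomial likelihood-ratio test of two proportions
#'
#' `2 * [l(k1/n1) + l(k2/n2) - l((k1+k2)/(n1+n2))]` under the binomial
#' likelihood (with the 0*log(0) = 0 convention), which equals the deviance
#' difference between a logit-link binomial GLM with a two-level group
#' predictor and its null model; the p-value is from the chi-square
#' distribution with one degree of freedom.
#'
#' @param k1,n1,k2,n2 Mutant counts and totals in the two groups
#'   (vectorised; `0 <= k <= n`, `n > 0`).
#' @return A list: `statistic`, `p_value` (vectors).
#' @examples
#' lrt_binomial(10, 100, 20, 200)$statistic  # identical proportions: 0
#' @export
lrt_binomial <- function(k1, n1, k2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("group totals must be positive")
  if (any(k1 < 0 | k1 > n1) || any(k2 < 0 | k2 > n2))
    stop("counts must satisfy 0 <= k <= n")
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll <- function(k, n, p) xlogy(k, p) + xlogy(n - k, 1 - p)
  p1 <- k1 / n1; p2 <- k2 / n2; p0 <- (k1 + k2) / (n1 + n2)
  stat <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) -
                 ll(k1, n1, p0) - ll(k2, n2, p0))
  stat <- pmax(stat, 0)  # guard tiny negative rounding
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Scan for differentially enriched mutations between two regimes
#'
#' Pools replicates into regime-level counts (mutant gene copies / total
#' gene copies), applies the final-generation frequency filter, tests each
#' candidate with [lrt_binomial()], Bonferroni-adjusts over the number of
#' candidates, and assigns the enrichment direction when the adjusted
#' p-value clears `alpha`. Intended for single-copy populations, where a
#' cell's fluorescence reflects one variant; pass `allow_double = TRUE` to
#' scan double-copy tables anyway (with a warning).
#'
#' @param blue_variants,green_variants Tidy call tables for the final
#'   generation of the two regimes (columns `replicate`, `read_id`, `copy`,
#'   `protein_position`, `ref_aa`, `alt_aa`, `synonymous`; a `generation`
#'   column, if present, is restricted to `final_generation`).
#' @param blue_totals,green_totals Tibbles with `replicate` (and optionally
#'   `generation`) and `n_genes`.
#' @param min_freq Frequency filter threshold (default 0.05).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param final_generation Final generation (default 5).
#' @param copy_mode `"single"` or `"double"` population tables.
#' @param allow_double Permit scanning double-copy tables (default FALSE).
#' @param nonsyn_only Restrict to nonsynonymous calls (default TRUE).
#' @return Tibble of `EnrichmentResult` rows: `mutation`, `k_blue`,
#'   `n_blue`, `k_green`, `n_green`, `lrt_statistic`, `p_value`,
#'   `p_adjusted`, `enriched_in` (`"blue_only"`, `"green_only"` or
#'   `"none"`).
#' @export
enrichment_scan <- function(blue_variants, blue_totals,
                            green_variants, green_totals,
                            min_freq = 0.05, alpha = 0.05,
                            final_generation = 5L,
                            copy_mode = c("single", "double"),
                            allow_double = FALSE, nonsyn_only = TRUE) {
  copy_mode <- match.arg(copy_mode)
  if (copy_mode == "double") {
    if (!allow_double)
      stop("double-copy tables conflate two variants per cell; ",
           "set allow_double = TRUE to scan them anyway")
    warning("scanning double-copy tables: fluorescence may reflect either copy")
  }
  if (nrow(blue_totals) == 0 || nrow(green_totals) == 0)
    stop("empty regime table")
  prep <- function(variants, totals, regime) {
    if ("generation" %in% names(variants))
      variants <- variants[variants$generation == final_generation, ]
    if ("generation" %in% names(totals))
      totals <- totals[totals$generation == final_generation, ]
    if (nonsyn_only) variants <- variants[!variants$synonymous, ]
    variants$regime <- regime
    totals$regime <- regime
    totals$generation <- final_generation
    variants$generation <- final_generation
    list(v = variants, t = totals)
  }
  b <- prep(blue_variants, blue_totals, "blue_only")
  g <- prep(green_variants, green_totals, "green_only")
  traj <- allele_trajectories(dplyr::bind_rows(b$v, g$v),
                              dplyr::bind_rows(b$t, g$t))
  candidates <- frequency_filter(traj, min_freq, final_generation)
  if (length(candidates) == 0)
    return(tibble::tibble(mutation = character(), k_blue = integer(),
                          n_blue = integer(), k_green = integer(),
                          n_green = integer(), lrt_statistic = numeric(),
                          p_value = numeric(), p_adjusted = numeric(),
                          enriched_in = character()))
  count_regime <- function(v, t, muts) {
    n_tot <- sum(t$n_genes)
    lab <- paste0(v$ref_aa, v$protein_position, v$alt_aa)
    k <- vapply(muts, function(mm)
      length(unique(paste(v$replicate, v$read_id, v$copy)[lab == mm])),
      integer(1))
    list(k = k, n = n_tot)
  }
  cb <- count_regime(b$v, b$t, candidates)
  cg <- count_regime(g$v, g$t, candidates)
  lrt <- lrt_binomial(cb$k, cb$n, cg$k, cg$n)
  m <- length(candidates)
  p_adj <- pmin(1, lrt$p_value * m)
  dir <- ifelse(p_adj < alpha,
                ifelse(cb$k / cb$n > cg$k / cg$n, "blue_only", "green_only"),
                "none")
  tibble::tibble(mutation = candidates,
                 k_blue = as.integer(cb$k), n_blue = as.integer(cb$n),
                 k_green = as.integer(cg$k), n_green = as.integer(cg$n),
                 lrt_statistic = lrt$statistic, p_value = lrt$p_value,
                 p_adjusted = p_adj, enriched_in = dir)
}
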