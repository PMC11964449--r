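# Independent oracles used to validate the package's computations. These are
# deliberately naive (exhaustive enumeration, generic numeric optimisation)
# and share no code with the implementation paths they check.

# Exhaustive global alignment: recursively enumerates every alignment path,
# scoring matches/mismatches and affine gaps (a gap of length L costs
# open + L * extend, charged when the gap opens and per position). Feasible
# for sequences up to length ~8.
bf_align_score <- function(q, r, match = 5, mismatch = -4, open = 10,
                           extend = 0.5) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  nq <- length(qs); nr <- length(rs)
  rec <- function(i, j, prev) {
    if (i > nq && j > nr) return(0)
    best <- -Inf
    if (i <= nq && j <= nr) {
      s <- if (qs[i] == rs[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i <= nq) {
      cost <- extend + if (identical(prev, "q")) 0 else open
      best <- max(best, rec(i + 1, j, "q") - cost)
    }
    if (j <= nr) {
      cost <- extend + if (identical(prev, "r")) 0 else open
      best <- max(best, rec(i, j + 1, "r") - cost)
    }
    best
  }
  rec(1, 1, "n")
}

# Brute-force average pairwise distance: explicit double sum over all
# ordered pairs.
bf_avg_pairwise <- function(proteins) {
  n <- length(proteins)
  chars <- strsplit(proteins, "")
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + sum(chars[[i]] != chars[[j]])
  tot / (n * (n - 1))
}

# Numeric-likelihood oracle for the two-proportion binomial LRT: maximises
# each binomial log-likelihood by generic 1-D optimisation instead of using
# the closed-form MLE. Interior counts only (0 < k < n).
bf_lrt <- function(k1, n1, k2, n2) {
  ll <- function(k, n, p) k * log(p) + (n - k) * log(1 - p)
  opt <- function(f) stats::optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE,
                                     tol = 1e-12)$objective
  l1 <- opt(function(p) ll(k1, n1, p))
  l2 <- opt(function(p) ll(k2, n2, p))
  l0 <- opt(function(p) ll(k1, n1, p) + ll(k2, n2, p))
  2 * (l1 + l2 - l0)
}

# NG86 per-codon site counts by direct enumeration of the 9 single-nt
# mutants, using the standard genetic code table.
bf_ng86_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa0 <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  n <- 0; s <- 0
  for (p in 1:3) for (b in setdiff(nts, substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (gc[[mut]] == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
  }
  c(N = n, S = s)
}

# Tiny ancestors for unit tests (coding length 696 is not required by most
# operations; these keep brute-force oracles cheap).
toy_ancestor <- function(coding = "ATGTTTGGCGTTTAA",
                         spacer = "ACCTGA") {
  cogfp_ancestor(coding_dna = coding, spacer = spacer)
}

parse_mutation_labels <- function(labs) {
  m <- regmatches(labs, regexec("^([A-Z*])([0-9]+)([A-Z*])$", labs))
  list(ref = vapply(m, `[`, character(1), 2),
       pos = as.integer(vapply(m, `[`, character(1), 3)),
       alt = vapply(m, `[`, character(1), 4))
}

random_protein <- function(len, n,
                           alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
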