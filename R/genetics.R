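# Low-level codon machinery shared by the simulator and the variant caller.
# Sequences are held internally as integer matrices (1=A, 2=C, 3=G, 4=T),
# one row per gene copy, which keeps whole-population mutagenesis and
# translation vectorised.

NT <- c("A", "C", "G", "T")

# codon index = (a-1)*16 + (b-1)*4 + c for bases a,b,c in 1..4
CODON_STRINGS <- paste0(rep(NT, each = 16L), rep(rep(NT, each = 4L), 4L),
                        rep(NT, 16L))
CODON_AA <- unname(Biostrings::GENETIC_CODE[CODON_STRINGS])

#' Convert a DNA string to the internal integer encoding
#'
#' @param dna A character scalar over the alphabet ACGT.
#' @return Integer vector with 1=A, 2=C, 3=G, 4=T.
#' @keywords internal
dna_to_int <- function(dna) {
  x <- match(strsplit(toupper(dna), "")[[1]], NT)
  if (anyNA(x)) stop("sequence contains characters outside ACGT")
  x
}

#' @keywords internal
int_to_dna <- function(x) paste(NT[x], collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()].
#'
#' @param dna A character scalar.
#' @return The reverse-complemented character scalar.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Codon indices (1..64) for an integer matrix of sequences, n x (L/3).
codon_index_matrix <- function(m) {
  L <- ncol(m)
  a <- m[, seq(1L, L, 3L), drop = FALSE]
  b <- m[, seq(2L, L, 3L), drop = FALSE]
  cc <- m[, seq(3L, L, 3L), drop = FALSE]
  (a - 1L) * 16L + (b - 1L) * 4L + cc
}

# Amino-acid character matrix, n x (L/3).
aa_matrix <- function(m) {
  idx <- codon_index_matrix(m)
  matrix(CODON_AA[idx], nrow = nrow(m))
}

#' Translate a coding DNA string
#'
#' @param dna Character scalar; length must be a multiple of 3.
#' @return Amino-acid string; stop codons appear as `*`.
#' @export
translate_dna <- function(dna) {
  if (nchar(dna) %% 3 != 0) stop("length of coding sequence is not a multiple of 3")
  m <- matrix(dna_to_int(dna), nrow = 1)
  paste(aa_matrix(m)[1, ], collapse = "")
}

#' Enumerate all single-nucleotide mutants of a coding sequence
#'
#' Classifies each of the 3L possible single-nucleotide substitutions of a
#' coding sequence as synonymous or nonsynonymous (stop-introducing changes
#' count as nonsynonymous), and flags the nonsynonymous ones that violate an
#' activity rule of the copy classifier (chromophore residue 75 outside
#' \{W,F,Y\}, residue 76 not glycine, or a premature stop at codons 1-220).
#'
#' @param coding_dna Coding sequence (multiple of 3, ACGT).
#' @return A list with `n_total` (=3L), `n_nonsyn`, `f_nonsyn`,
#'   `rho_rule` (rule-violating fraction of nonsynonymous changes).
#' @export
enumerate_single_mutants <- function(coding_dna) {
  x <- dna_to_int(coding_dna)
  L <- length(x)
  n_cod <- L %/% 3
  aa0 <- aa_matrix(matrix(x, nrow = 1))[1, ]
  # 3L mutants: for each site, the 3 alternative bases
  site <- rep(seq_len(L), each = 3)
  shift <- rep(1:3, times = L)
  alt <- ((x[site] - 1L + shift) %% 4L) + 1L
  cod <- (site - 1L) %/% 3L + 1L
  pos_in_cod <- (site - 1L) %% 3L + 1L
  # codon index of each mutant
  base_idx <- (x[3 * cod - 2] - 1L) * 16L + (x[3 * cod - 1] - 1L) * 4L + x[3 * cod]
  mult <- c(16L, 4L, 1L)[pos_in_cod]
  idx_new <- base_idx + (alt - x[site]) * mult
  aa_new <- CODON_AA[idx_new]
  nonsyn <- aa_new != aa0[cod]
  viol <- nonsyn & rule_violating(cod, aa_new)
  list(n_total = 3L * L,
       n_nonsyn = sum(nonsyn),
       f_nonsyn = mean(nonsyn),
       rho_rule = if (any(nonsyn)) sum(viol) / sum(nonsyn) else 0)
}

# Which (codon position, new amino acid) pairs violate an activity rule.
rule_violating <- function(codon_pos, aa_new) {
  (codon_pos == 75L & !(aa_new %in% c("W", "F", "Y"))) |
    (codon_pos == 76L & aa_new != "G") |
    (aa_new == "*" & codon_pos <= 220L)
}
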