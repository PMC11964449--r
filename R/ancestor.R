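# The ancestral two-copy amplicon: one coding sequence present twice on a
# plasmid, convergently oriented (copy 1 on the plus strand, copy 2 on the
# minus strand) and separated by a short non-palindromic spacer. The spacer is
# the only asymmetric context, so strand recovery of a read must resolve
# orientation through it -- exactly the situation created by sequencing a
# near-palindromic construct.

# 232 codons (231 residues + stop). Chromophore tripeptide at residues 74-76
# (Q-Y-G); the key positions seen to sweep under color selection are 98 (L),
# 147 (G) and 162 (V).
COGFP_CODING <- paste0(
  "ATGGGGACCGCAACACTAGTTCTAGAAGCGAGTTCAACAACCCGGCGCTTAGGGTTTGCACGGCATTCATTT",
  "TGGCCGAGCGATGGTCTCTCTGTAAGCTCAACCGAAGCATTTACAGGCTTAAAAAGCGCAAATAGCAATACC",
  "TCGTCTTCAAGGCTAGATTCACACTGCAGTGCCTTCACAGATTACCGAGTTGCTCATGCGCCGGGCAAGTCC",
  "GAACAATATGGTGCAATAAGTATTGCCGGGTGGATGCATGTATATTCGCCATGCAGCAGCGCTTATACAACA",
  "AGACTGGAACCGGCCTGTCCAGCTAGAGAAGCGTGTATGTCTACGAGTACATATCGTGTTTACGCTTGCCGC",
  "CACCATCCTAGACGGTGTCATGGTGTTTTAATACGATCGACATCCCGTCCGCTTTTGGGATCTCAGTGTTTA",
  "TTCAACGGCTCTATTAAAGTAAGAACATTGGTTGCTTTGTCTCCCCATCTAGTTGTATATTACTTAAGCCCT",
  "TTTCCCTTCTCGCTTAATGCAGCGGTAATAATCTCTAATGTATGCAAGAATAAGCGGGCACTGAGATCAGGA",
  "CCCGACTCGCACTCGCAGGGGGCACTCTACCGTCTTGCCTACCTCCACTTATTTTCCTGGCCCATGCGTATG",
  "AATTACGTTATTTCTACAATTATTGTAGTATCTGATCAGGGCGTGTAA")

COGFP_SPACER <- "TCAAGCTGATGCCACGATCGTTCAGGTCTCACTACCGTATTTGCCCCCTC"

#' Ancestral reference for a two-copy fluorescent-gene amplicon
#'
#' Builds the reference object used throughout the pipeline: the ancestral
#' coding sequence, its translation, the chromophore and key residue
#' positions, and the layout of the two-copy amplicon (copy 1 in coding
#' orientation, a fixed spacer, then copy 2 reverse-complemented, i.e. the
#' two copies are convergently oriented).
#'
#' @param coding_dna Coding sequence of one gene copy (default: the built-in
#'   232-codon ancestor). Length must be a multiple of 3, with no internal
#'   stop codon; a terminal stop is allowed.
#' @param spacer Nucleotide spacer separating the two copies on the amplicon
#'   (default: the built-in 50-nt non-palindromic spacer).
#' @return An object of class `ancestor_ref`: a list with elements
#'   `coding_dna`, `protein`, `n_codons`, `chromophore_positions` (74:76),
#'   `key_positions` (98, 147, 162), `spacer`, `amplicon`, and `layout`
#'   (1-based closed intervals of copy 1, spacer, copy 2 on the amplicon).
#' @examples
#' anc <- cogfp_ancestor()
#' substr(anc$protein, 75, 76)  # "YG": intact chromophore
#' nchar(anc$amplicon)          # 2 * 696 + 50
#' @export
cogfp_ancestor <- function(coding_dna = COGFP_CODING, spacer = COGFP_SPACER) {
  if (nchar(coding_dna) %% 3 != 0)
    stop("coding_dna length must be a multiple of 3")
  protein <- translate_dna(coding_dna)
  n_codons <- nchar(protein)
  internal <- substr(protein, 1, n_codons - 1)
  if (grepl("*", internal, fixed = TRUE))
    stop("coding_dna contains an internal stop codon")
  L <- nchar(coding_dna)
  sL <- nchar(spacer)
  amplicon <- paste0(coding_dna, spacer, revcomp(coding_dna))
  structure(list(
    coding_dna = coding_dna,
    protein = protein,
    n_codons = n_codons,
    chromophore_positions = 74:76,
    key_positions = c(98L, 147L, 162L),
    spacer = spacer,
    amplicon = amplicon,
    layout = list(copy1 = c(1L, L),
                  spacer = c(L + 1L, L + sL),
                  copy2 = c(L + sL + 1L, 2L * L + sL))
  ), class = "ancestor_ref")
}

#' @export
print.ancestor_ref <- function(x, ...) {
  cat("Two-copy amplicon reference\n")
  cat("  coding length:", nchar(x$coding_dna), "nt (", x$n_codons, "codons )\n")
  cat("  amplicon length:", nchar(x$amplicon), "nt; spacer:",
      nchar(x$spacer), "nt\n")
  cat("  chromophore residues:", paste(x$chromophore_positions, collapse = ","),
      " key residues:", paste(x$key_positions, collapse = ","), "\n")
  invisible(x)
}

#' Engineered-inactive version of the ancestral coding sequence
#'
#' The single-copy control plasmid carries one copy inactivated by three
#' engineered chromophore substitutions (Q74A, Y75S, G76A). This returns the
#' ancestral coding sequence with codons 74-76 replaced accordingly.
#'
#' @param ancestor An [cogfp_ancestor()] reference.
#' @return A coding DNA string.
#' @export
engineered_inactive_dna <- function(ancestor = cogfp_ancestor()) {
  if (ancestor$n_codons < 76) stop("ancestor too short for chromophore codons")
  x <- ancestor$coding_dna
  substr(x, 3 * 74 - 2, 3 * 74) <- "GCT"  # Q74A
  substr(x, 3 * 75 - 2, 3 * 75) <- "TCT"  # Y75S
  substr(x, 3 * 76 - 2, 3 * 76) <- "GCT"  # G76A
  x
}

#' Amplicon sequence for one plasmid genotype
#'
#' @param copy1_dna,copy2_dna Coding-orientation sequences of the two copies.
#' @param ancestor Reference supplying the spacer.
#' @return The amplicon string: copy1 + spacer + reverse-complement(copy2).
#' @export
build_amplicon <- function(copy1_dna, copy2_dna, ancestor = cogfp_ancestor()) {
  paste0(copy1_dna, ancestor$spacer, revcomp(copy2_dna))
}
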