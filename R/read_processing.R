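# From full-length amplicon reads (random strand) to per-copy,
# coding-orientation variant calls against the ancestor. The construct is
# near-palindromic (two convergent copies of the same gene), so a read's
# strand is recovered by global alignment of both orientations against the
# reference amplicon; the non-palindromic spacer provides the signal.

#' Alignment scoring scheme
#'
#' EMBOSS-needle-style defaults: match 5, mismatch -4, and an affine gap of
#' length L costing `gap_open + L * gap_extend` (open 10, extend 0.5).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (must be >= 0).
#' @return A named list.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = 10,
                          gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

# Query coverage from a gapped alignment pair: the fraction of query bases
# lying inside the query span that is aligned to reference bases. Query
# bases hanging off the reference (opposite terminal reference gaps) are
# uncovered flanks, as for reads contaminated by unrelated sequence.
alignment_coverage <- function(aligned_query, aligned_ref) {
  q <- strsplit(aligned_query, "")[[1]]
  r <- strsplit(aligned_ref, "")[[1]]
  qb <- q != "-"
  both <- qb & r != "-"
  if (!any(both)) return(0)
  span <- range(which(both))
  covered <- sum(qb[span[1]:span[2]])
  covered / sum(qb)
}

#' Global (Needleman-Wunsch) alignment of a read against a reference
#'
#' End-to-end alignment with affine gap penalties, as produced by the EMBOSS
#' `needle` program; computed with [Biostrings::pairwiseAlignment()].
#'
#' @param query,ref Nucleotide strings (non-empty).
#' @param scoring An [align_scoring()] scheme.
#' @return A list (`alignment_result`): `score`, `aligned_query`,
#'   `aligned_ref` (gapped strings of equal length), `query_coverage`.
#' @examples
#' global_align("ACGT", "ACGT")$score  # 4 matches x 5
#' @export
global_align <- function(query, ref, scoring = align_scoring()) {
  if (nchar(query) == 0 || nchar(ref) == 0) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  aq <- as.character(Biostrings::alignedPattern(al))[[1]]
  ar <- as.character(Biostrings::alignedSubject(al))[[1]]
  structure(list(score = Biostrings::score(al), aligned_query = aq,
                 aligned_ref = ar,
                 query_coverage = alignment_coverage(aq, ar)),
            class = "alignment_result")
}

#' Orient a read against the two-copy reference amplicon
#'
#' Aligns the read and its reverse complement globally to the reference
#' amplicon and keeps the orientation with the higher score, so all reads
#' end up in reference (plus) orientation. An exact score tie carries no
#' orientation information (a perfectly palindromic read) and is flagged
#' ambiguous.
#'
#' @param read Nucleotide string.
#' @param ancestor An [cogfp_ancestor()] reference.
#' @param scoring An [align_scoring()] scheme.
#' @return A list: `sequence` (reference-orientation read), `orientation`
#'   (`"plus"` or `"minus"`; `NA` if ambiguous), `ambiguous`, `alignment`
#'   (the winning `alignment_result`).
#' @export
orient_read <- function(read, ancestor = cogfp_ancestor(),
                        scoring = align_scoring()) {
  fwd <- global_align(read, ancestor$amplicon, scoring)
  rc <- revcomp(read)
  rev <- global_align(rc, ancestor$amplicon, scoring)
  if (fwd$score == rev$score) {
    return(list(sequence = read, orientation = NA_character_,
                ambiguous = TRUE, alignment = fwd))
  }
  if (fwd$score > rev$score) {
    list(sequence = read, orientation = "plus", ambiguous = FALSE,
         alignment = fwd)
  } else {
    list(sequence = rc, orientation = "minus", ambiguous = FALSE,
         alignment = rev)
  }
}

#' Full-query-coverage filter
#'
#' Keep only reads whose alignment covers the query completely (emulating
#' removal of reads contaminated by unrelated genomic DNA).
#'
#' @param alignment An `alignment_result` (or anything with a
#'   `query_coverage` field).
#' @param min_coverage Minimum coverage to keep (default 1.0 = full).
#' @return Logical: keep?
#' @export
filter_full_coverage <- function(alignment, min_coverage = 1.0) {
  alignment$query_coverage >= min_coverage
}

#' Split an oriented amplicon read into its two gene copies
#'
#' Uses the alignment to the reference layout to extract, gap-aware, the
#' query segment aligned to each copy's reference interval. Copy 1 lies on
#' the plus strand; copy 2 is reverse-complemented so both come back in
#' coding (5'->3') orientation. Query insertions between reference positions
#' inherit the preceding reference position; an insertion at a segment
#' boundary is flagged.
#'
#' @param alignment An `alignment_result` of an oriented read against the
#'   reference amplicon.
#' @param ancestor The reference (supplies the layout).
#' @return A list: `copy1_dna`, `copy2_dna` (coding orientation),
#'   `boundary_flag` (insertion at a segment boundary).
#' @export
split_copies <- function(alignment, ancestor = cogfp_ancestor()) {
  q <- strsplit(alignment$aligned_query, "")[[1]]
  r <- strsplit(alignment$aligned_ref, "")[[1]]
  refpos <- cumsum(r != "-")       # insertions inherit the previous position
  lay <- ancestor$layout
  boundary <- any(r == "-" & refpos %in% c(0L, lay$copy1[2], lay$spacer[2],
                                           lay$copy2[2]))
  seg <- function(interval) {
    sel <- q != "-" & refpos >= interval[1] & refpos <= interval[2]
    paste(q[sel], collapse = "")
  }
  list(copy1_dna = seg(lay$copy1),
       copy2_dna = revcomp(seg(lay$copy2)),
       boundary_flag = boundary)
}

#' Call amino-acid-level mutations of one gene copy against the ancestor
#'
#' Codon-by-codon comparison in the coordinates of the ancestral protein
#' (1-based residue numbering). A codon changed at multiple nucleotides
#' yields a single call; a call is synonymous when the amino acid is
#' unchanged. A copy whose length is not the ancestral coding length cannot
#' be compared codon-wise and is returned as a single frameshift-flagged
#' record with no codon calls.
#'
#' @param copy_dna Coding-orientation copy sequence.
#' @param ancestor The reference.
#' @param copy_index 1 or 2.
#' @return Tibble: `copy`, `protein_position`, `ref_aa`, `alt_aa`,
#'   `synonymous`, `codon_ref`, `codon_alt`, `frameshift`.
#' @examples
#' anc <- cogfp_ancestor()
#' x <- anc$coding_dna
#' substr(x, 3 * 147 - 2, 3 * 147) <- "AGC"   # G147S
#' call_mutations(x, anc, 1)
#' @export
call_mutations <- function(copy_dna, ancestor = cogfp_ancestor(),
                           copy_index = 1L) {
  empty <- tibble::tibble(copy = integer(), protein_position = integer(),
                          ref_aa = character(), alt_aa = character(),
                          synonymous = logical(), codon_ref = character(),
                          codon_alt = character(), frameshift = logical())
  if (nchar(copy_dna) != nchar(ancestor$coding_dna)) {
    return(tibble::tibble(copy = as.integer(copy_index),
                          protein_position = NA_integer_,
                          ref_aa = NA_character_, alt_aa = NA_character_,
                          synonymous = NA, codon_ref = NA_character_,
                          codon_alt = NA_character_, frameshift = TRUE))
  }
  x <- dna_to_int(copy_dna)
  a <- dna_to_int(ancestor$coding_dna)
  xc <- codon_index_matrix(matrix(x, nrow = 1))[1, ]
  ac <- codon_index_matrix(matrix(a, nrow = 1))[1, ]
  pos <- which(xc != ac)
  if (length(pos) == 0) return(empty)
  tibble::tibble(copy = as.integer(copy_index),
                 protein_position = as.integer(pos),
                 ref_aa = CODON_AA[ac[pos]], alt_aa = CODON_AA[xc[pos]],
                 synonymous = CODON_AA[ac[pos]] == CODON_AA[xc[pos]],
                 codon_ref = CODON_STRINGS[ac[pos]],
                 codon_alt = CODON_STRINGS[xc[pos]],
                 frameshift = FALSE)
}

#' Process a set of amplicon reads into per-copy variant calls
#'
#' The full read-processing stage: orient every read against the reference
#' amplicon (both orientations aligned globally, vectorised), drop ambiguous
#' orientations and reads failing the full-query-coverage filter, split each
#' surviving read into its two copies, and call mutations per copy.
#'
#' @param reads A [Biostrings::DNAStringSet], a character vector of
#'   sequences, or the path to a FASTA file.
#' @param ancestor The reference.
#' @param scoring An [align_scoring()] scheme.
#' @param min_coverage Full-coverage threshold (default 1.0).
#' @return A list: `variants` (tibble `read_id`, `copy`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `synonymous`, `codon_ref`, `codon_alt`,
#'   `frameshift`), `reads` (per-read tibble `read_id`, `orientation`,
#'   `score`, `query_coverage`, `ambiguous`, `kept`), and `copies` (tibble
#'   `read_id`, `copy`, `dna`, `protein` for kept reads).
#' @export
process_amplicons <- function(reads, ancestor = cogfp_ancestor(),
                              scoring = align_scoring(), min_coverage = 1.0) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (length(reads) == 0) stop("no reads supplied")
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  S4Vectors::mcols(reads) <- NULL
  ref <- Biostrings::DNAString(ancestor$amplicon)
  sm <- submat(scoring)
  rc <- Biostrings::reverseComplement(reads)
  # orientation decision needs scores only (no traceback); the full
  # alignment is then computed once, for the winning orientation
  s_f <- Biostrings::pairwiseAlignment(reads, ref, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend,
                                       scoreOnly = TRUE)
  s_r <- Biostrings::pairwiseAlignment(rc, ref, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend,
                                       scoreOnly = TRUE)
  ambiguous <- s_f == s_r
  use_rev <- s_r > s_f
  oriented <- reads
  oriented[use_rev] <- rc[use_rev]
  aq <- ar <- rep(NA_character_, length(reads))
  if (any(!ambiguous)) {
    al <- Biostrings::pairwiseAlignment(oriented[!ambiguous], ref,
                                        type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = scoring$gap_open,
                                        gapExtension = scoring$gap_extend)
    aq[!ambiguous] <- as.character(Biostrings::alignedPattern(al))
    ar[!ambiguous] <- as.character(Biostrings::alignedSubject(al))
  }
  cov <- rep(0, length(reads))
  cov[!ambiguous] <- vapply(which(!ambiguous), function(i)
    alignment_coverage(aq[i], ar[i]), numeric(1))
  kept <- !ambiguous & cov >= min_coverage
  read_tbl <- tibble::tibble(
    read_id = ids,
    orientation = ifelse(ambiguous, NA_character_,
                         ifelse(use_rev, "minus", "plus")),
    score = pmax(s_f, s_r), query_coverage = cov,
    ambiguous = ambiguous, kept = kept)
  n_dropped <- sum(!kept)
  if (n_dropped > 0)
    message(n_dropped, " of ", length(reads),
            " reads dropped (ambiguous orientation or incomplete coverage)")
  variants <- list(); copies <- list()
  for (i in which(kept)) {
    sp <- split_copies(list(aligned_query = aq[i], aligned_ref = ar[i]),
                       ancestor)
    for (cp in 1:2) {
      dna <- if (cp == 1) sp$copy1_dna else sp$copy2_dna
      calls <- call_mutations(dna, ancestor, cp)
      if (nrow(calls) > 0)
        variants[[length(variants) + 1]] <-
          dplyr::mutate(calls, read_id = ids[i], .before = 1)
      prot <- if (nchar(dna) %% 3 == 0) translate_dna(dna) else NA_character_
      copies[[length(copies) + 1]] <-
        tibble::tibble(read_id = ids[i], copy = cp, dna = dna, protein = prot)
    }
  }
  variants <- dplyr::bind_rows(variants)
  if (nrow(variants) == 0)
    variants <- tibble::tibble(read_id = character(), copy = integer(),
                               protein_position = integer(),
                               ref_aa = character(), alt_aa = character(),
                               synonymous = logical(), codon_ref = character(),
                               codon_alt = character(), frameshift = logical())
  list(variants = variants, reads = read_tbl,
       copies = dplyr::bind_rows(copies))
}
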