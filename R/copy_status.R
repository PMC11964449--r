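# Rule-based classification of gene copies as active or inactive from their
# called protein sequence. The rules deliberately mirror what sequence data
# can reveal: a disrupted chromophore or a truncation. Inactivating
# mutations elsewhere in the fold are invisible to these rules, so the
# classifier's sensitivity against simulator truth is below one by design.

#' Classify one gene copy as active or inactive
#'
#' A copy is inactive if any rule fires: residue 75 is not tryptophan,
#' phenylalanine or tyrosine (`res75_not_WFY`); residue 76 is not glycine
#' (`res76_not_G`); a stop codon occurs at residue positions 1-220
#' (`premature_stop_1_220`); or the copy carries a frameshift
#' (`frameshift`). Rules are evaluated on the called sequence itself, never
#' on any engineering label.
#'
#' @param protein Amino-acid string (stops as `*`); may be `NA` when
#'   `frameshift` is TRUE.
#' @param frameshift Was the copy frameshift-flagged by the caller?
#' @return A list of class `copy_status`: `status` (`"active"` or
#'   `"inactive"`) and `triggered_rules` (character vector, empty iff
#'   active).
#' @examples
#' classify_copy(cogfp_ancestor()$protein)$status  # "active"
#' @export
classify_copy <- function(protein, frameshift = FALSE) {
  rules <- character()
  if (frameshift) {
    rules <- "frameshift"
  } else {
    if (is.na(protein) || nchar(protein) < 220)
      stop("protein shorter than 220 residues without a frameshift flag")
    aa75 <- substr(protein, 75, 75)
    aa76 <- substr(protein, 76, 76)
    if (!(aa75 %in% c("W", "F", "Y"))) rules <- c(rules, "res75_not_WFY")
    if (aa76 != "G") rules <- c(rules, "res76_not_G")
    if (grepl("*", substr(protein, 1, 220), fixed = TRUE))
      rules <- c(rules, "premature_stop_1_220")
  }
  structure(list(status = if (length(rules) > 0) "inactive" else "active",
                 triggered_rules = rules),
            class = "copy_status")
}

#' Classify all copies of a processed read set
#'
#' @param copies The `copies` tibble from [process_amplicons()] (columns
#'   `read_id`, `copy`, `protein`; `NA` protein means frameshift).
#' @return Tibble: `read_id`, `copy`, `status`, `rules` (comma-separated).
#' @export
classify_copies <- function(copies) {
  res <- lapply(seq_len(nrow(copies)), function(i) {
    fs <- is.na(copies$protein[i])
    cs <- classify_copy(copies$protein[i], frameshift = fs)
    tibble::tibble(read_id = copies$read_id[i], copy = copies$copy[i],
                   status = cs$status,
                   rules = paste(cs$triggered_rules, collapse = ","))
  })
  dplyr::bind_rows(res)
}

#' Aggregate the two copies' statuses into plasmid-level activity
#'
#' @param status1,status2 Character vectors of per-copy statuses; any value
#'   other than `"active"` counts as inactive.
#' @return Character vector: `"both_active"`, `"one_active"`, or
#'   `"none_active"`.
#' @examples
#' plasmid_activity("active", "inactive")  # "one_active"
#' @export
plasmid_activity <- function(status1, status2) {
  n_active <- (status1 == "active") + (status2 == "active")
  c("none_active", "one_active", "both_active")[n_active + 1L]
}

#' Per-generation summary of plasmid activity fractions
#'
#' @param status_tbl Tibble from [classify_copies()], with one row per
#'   (read, copy); reads must have both copies present.
#' @return Tibble: `n`, `both_active`, `one_active`, `none_active`
#'   (fractions).
#' @export
summarize_activity <- function(status_tbl) {
  wide <- dplyr::summarise(dplyr::group_by(status_tbl, .data$read_id),
                           s1 = .data$status[.data$copy == 1],
                           s2 = .data$status[.data$copy == 2],
                           .groups = "drop")
  act <- factor(plasmid_activity(wide$s1, wide$s2),
                levels = c("both_active", "one_active", "none_active"))
  p <- prop.table(table(act))
  tibble::tibble(n = nrow(wide), both_active = p[["both_active"]],
                 one_active = p[["one_active"]],
                 none_active = p[["none_active"]])
}
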