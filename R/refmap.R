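# Mapping basecall ordinals onto reference-amplicon coordinates. A global
# (Needleman-Wunsch) alignment with affine gap penalties pairs each called
# base with a 1-based reference position; IUPAC ambiguity letters in the
# basecalls (mixed peaks at partially edited sites, e.g. R for A/G) count as
# matches when their base set contains the reference base, so heavily edited
# reads still align.

iupac_match_matrix <- function(match = 2, mismatch = -2) {
  map <- Biostrings::IUPAC_CODE_MAP
  letters <- names(map)
  sets <- strsplit(unname(map), "")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (i in seq_along(letters))
    for (j in seq_along(letters))
      if (length(intersect(sets[[i]], sets[[j]]))) m[i, j] <- match
  m
}

#' Globally align basecalls to the reference amplicon
#'
#' Produces the call-ordinal to reference-position map used to look up peak
#' areas at candidate editing sites. Scoring: match +2, mismatch -2 (IUPAC
#' ambiguity codes match any reference base contained in their set), affine
#' gaps with open -5 and extend -1 per position. Alignments whose identity
#' over aligned columns falls below `identity_floor` are rejected, since a
#' poorly mapping read would silently misassign editing values.
#'
#' @param basecalls Character scalar, the called sequence (IUPAC letters).
#' @param reference Character scalar, the reference amplicon sequence.
#' @param identity_floor Minimum fraction of aligned (non-gap) columns that
#'   must match (IUPAC-aware); default 0.7.
#' @return A `site_map` data frame with columns `call_index` (0-based) and
#'   `ref_position` (1-based) for aligned columns, plus attributes
#'   `identity`, `score`, `unaligned_calls` and `uncovered_ref`.
#' @export
align_basecalls <- function(basecalls, reference, identity_floor = 0.7) {
  basecalls <- toupper(paste(basecalls, collapse = ""))
  reference <- toupper(paste(reference, collapse = ""))
  if (!nchar(basecalls) || !nchar(reference))
    stop_sangeredit("basecalls and reference must be non-empty",
                    "sangeredit_content_error")
  mat <- iupac_match_matrix()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(basecalls), Biostrings::DNAString(reference),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 1,
    type = "global")
  pal <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sal <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ci <- cumsum(pal != "-") - 1L   # 0-based call ordinal at each column
  rp <- cumsum(sal != "-")        # 1-based ref position at each column
  both <- pal != "-" & sal != "-"
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  is_match <- both & mapply(function(a, b)
    a != "-" && b != "-" && length(intersect(sets[[a]], sets[[b]])) > 0,
    pal, sal)
  identity <- if (any(both)) sum(is_match) / sum(both) else 0
  if (identity < identity_floor)
    stop_sangeredit(sprintf(
      "alignment identity %.1f%% below floor %.1f%%; read does not map to this reference",
      100 * identity, 100 * identity_floor), "sangeredit_mapping_error")

  map <- data.frame(call_index = ci[both], ref_position = rp[both])
  structure(map,
            class = c("site_map", "data.frame"),
            identity = identity,
            score = Biostrings::score(aln),
            unaligned_calls = unique(ci[pal != "-" & sal == "-"]),
            uncovered_ref = setdiff(seq_len(nchar(reference)), map$ref_position))
}

#' Enumerate candidate editing sites on the reference
#'
#' All 1-based reference positions whose base is the editing substrate:
#' adenosines for A-to-G (ADAR-family deamination, inosine read as G) or
#' cytosines for C-to-T (APOBEC-family, uracil read as T in cDNA).
#'
#' @param reference Character scalar, the reference amplicon.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @return A data frame of class `candidate_sites` with columns
#'   `ref_position` and `ref_base`, ordered by position.
#' @export
enumerate_candidates <- function(reference, edit_mode = c("A_to_G", "C_to_T")) {
  edit_mode <- match.arg(edit_mode)
  reference <- toupper(paste(reference, collapse = ""))
  substrate <- edit_substrate(edit_mode)
  pos <- which(strsplit(reference, "")[[1]] == substrate)
  structure(data.frame(ref_position = pos,
                       ref_base = rep(substrate, length(pos))),
            class = c("candidate_sites", "data.frame"),
            edit_mode = edit_mode)
}

edit_substrate <- function(edit_mode) c(A_to_G = "A", C_to_T = "C")[[edit_mode]]
edit_product <- function(edit_mode) c(A_to_G = "G", C_to_T = "T")[[edit_mode]]
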