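#' Alignment scoring parameters
#'
#' Global (Needleman-Wunsch) alignment with affine gaps: a gap of length
#' L costs `gap_open + L * gap_extend`. Nucleotide match/mismatch scoring
#' (default +5 / -4) replaces the protein substitution matrix sometimes
#' quoted for this step, which is undefined for RNA.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend non-negative affine gap penalties (defaults
#'   10 and 0.1).
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.1) {
  stopifnot(gap_open >= 0, gap_extend >= 0,
            is.finite(match), is.finite(mismatch))
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

# RNA -> DNA for Biostrings machinery; input validation lives here.
as_dna <- function(seq) {
  s <- toupper(seq)
  if (any(nchar(s) == 0L)) stop("empty sequence cannot be aligned")
  bad <- grepl("[^ACGUT]", s)
  if (any(bad)) stop("sequences must use the A/C/G/U alphabet (T accepted)")
  chartr("U", "T", s)
}

subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)
}

#' Global pairwise alignment of two mature miRNA sequences
#'
#' Computes the optimal global affine-gap alignment score (dynamic
#' programming via Biostrings) and the percent identity, defined as
#' matching columns / alignment columns x 100.
#'
#' @param seq_a,seq_b RNA sequences (character; `T` is read as `U`).
#' @param params an [alignment_params()].
#' @return one-row data frame: `query`, `target`, `score`,
#'   `pct_identity`, `aligned_length`.
#' @examples
#' align_pair("ACGU", "ACGU")$score  # 4 matches x 5
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params()) {
  a <- as_dna(seq_a)
  b <- as_dna(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  data.frame(query = names(seq_a) %||% NA_character_,
             target = names(seq_b) %||% NA_character_,
             score = Biostrings::score(aln),
             pct_identity = Biostrings::pid(aln, type = "PID1"),
             aligned_length = Biostrings::nchar(aln))
}

#' Best-scoring reference match(es) for a query sequence
#'
#' Aligns the query against every reference sequence and returns all
#' targets achieving the maximal score (ties retained), ordered by target
#' ID.
#'
#' @param query single named RNA sequence (character of length 1).
#' @param references named character vector of reference RNA sequences.
#' @param params an [alignment_params()].
#' @return data frame with one row per tied best target: `query`,
#'   `target`, `score`, `pct_identity`, `aligned_length`.
#' @export
top_match <- function(query, references, params = alignment_params()) {
  stopifnot(length(query) == 1L, length(references) >= 1L,
            !is.null(names(references)))
  q <- as_dna(query)
  refs <- as_dna(references)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(q),
    substitutionMatrix = subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  sc <- Biostrings::score(aln)
  best <- which(sc >= max(sc) - 1e-9)
  best <- best[order(names(references)[best])]
  data.frame(query = names(query) %||% NA_character_,
             target = names(references)[best],
             score = sc[best],
             pct_identity = Biostrings::pid(aln, type = "PID1")[best],
             aligned_length = Biostrings::nchar(aln)[best],
             row.names = NULL)
}
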