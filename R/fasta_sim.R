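#' Cross-species homology map
#'
#' Declares which species-A features have a homologue in species B and the
#' percent identity the simulated pair should realise.
#'
#' @param feature_a,feature_b character vectors of paired feature IDs.
#' @param identity numeric vector of requested percent identities in
#'   \[0, 100\].
#' @return object of class `homology_map` (a data frame).
#' @export
homology_map <- function(feature_a = character(0), feature_b = character(0),
                         identity = numeric(0)) {
  stopifnot(length(feature_a) == length(feature_b),
            length(feature_a) == length(identity))
  if (length(identity) && any(identity < 0 | identity > 100)) {
    stop("requested percent identity must lie in [0, 100]")
  }
  structure(
    data.frame(feature_a = as.character(feature_a),
               feature_b = as.character(feature_b),
               identity = as.numeric(identity)),
    class = c("homology_map", "data.frame")
  )
}

#' @rdname homology_map
#' @param config a [sim_config()]; the default map pairs the first 60% of
#'   features with a human-style counterpart at 95% identity, leaving the
#'   rest unpaired (their best cross-species match is then the ~25-50%
#'   identity expected of unrelated short RNA).
#' @export
default_homology_map <- function(config) {
  n <- floor(0.6 * config$n_features)
  ids <- feature_ids(config$n_features)[seq_len(n)]
  homology_map(ids, sub("^sim-", "hsa-sim-", ids), rep(95, n))
}

#' Simulate paired mature miRNA FASTA files for two species
#'
#' Generates a random mature RNA sequence (alphabet A/C/G/U) for every
#' feature of the configured cohort (species A) and, for every pair in the
#' homology map, a species-B counterpart obtained by substituting bases at
#' random non-repeating positions until the requested percent identity is
#' met. Identities not achievable at the drawn sequence length are rounded
#' to the nearest achievable value and reported in the returned table.
#' Additional unrelated species-B decoys can be appended.
#'
#' @param config a [sim_config()] (supplies the feature IDs and seed).
#' @param homology a [homology_map()].
#' @param file_a,file_b output FASTA paths; `NULL` skips writing.
#' @param length_range integer range the mature sequence lengths are drawn
#'   from (default 20--24 nt, the typical mature miRNA length; must stay
#'   within 18--30 nt).
#' @param n_decoys_b number of unrelated species-B sequences to append.
#' @return list of class `mirna_fasta_sim` with `seq_a`, `seq_b` (named
#'   character vectors of RNA sequences) and `pairs` (data frame with the
#'   requested and realised identity per homologous pair).
#' @export
simulate_mirna_fasta <- function(config, homology = default_homology_map(config),
                                 file_a = NULL, file_b = NULL,
                                 length_range = c(20L, 24L), n_decoys_b = 0L) {
  stopifnot(inherits(config, "sim_config"), inherits(homology, "homology_map"))
  if (length_range[1] < 18L || length_range[2] > 30L) {
    stop("mature miRNA lengths must stay within 18-30 nt")
  }
  restore <- set_local_seed(config$seed + 104729L)  # independent stream from counts
  on.exit(restore())

  alphabet <- c("A", "C", "G", "U")
  rand_seq <- function(len) paste(sample(alphabet, len, replace = TRUE), collapse = "")
  ids_a <- feature_ids(config$n_features)
  len_pool <- seq(length_range[1], length_range[2])
  lens <- len_pool[sample.int(length(len_pool), length(ids_a), replace = TRUE)]
  seq_a <- setNames(vapply(lens, rand_seq, character(1)), ids_a)

  missing <- setdiff(homology$feature_a, ids_a)
  if (length(missing)) stop("homology map names unknown features: ",
                            paste(missing, collapse = ", "))

  mutate_to_identity <- function(s, identity) {
    chars <- strsplit(s, "")[[1]]
    len <- length(chars)
    k <- round((1 - identity / 100) * len)
    if (k > 0) {
      pos <- sample.int(len, k)
      for (i in pos) chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
    }
    list(seq = paste(chars, collapse = ""), realized = 100 * (len - k) / len)
  }

  pairs <- homology
  pairs$realized_identity <- rep(NA_real_, nrow(pairs))
  seq_b <- character(0)
  for (r in seq_len(nrow(pairs))) {
    m <- mutate_to_identity(seq_a[[pairs$feature_a[r]]], pairs$identity[r])
    seq_b[pairs$feature_b[r]] <- m$seq
    pairs$realized_identity[r] <- m$realized
  }
  rounded <- which(abs(pairs$realized_identity - pairs$identity) > 1e-9)
  if (length(rounded)) {
    message(length(rounded), " requested identities rounded to the nearest value ",
            "achievable at the drawn sequence length")
  }
  if (n_decoys_b > 0) {
    dl <- len_pool[sample.int(length(len_pool), n_decoys_b, replace = TRUE)]
    decoys <- setNames(vapply(dl, rand_seq, character(1)),
                       sprintf("hsa-decoy-%04d", seq_len(n_decoys_b)))
    seq_b <- c(seq_b, decoys)
  }

  if (!is.null(file_a)) write_rna_fasta(seq_a, file_a)
  if (!is.null(file_b)) write_rna_fasta(seq_b, file_b)
  structure(list(seq_a = seq_a, seq_b = seq_b, pairs = pairs),
            class = "mirna_fasta_sim")
}

#' Read and write mature miRNA FASTA
#'
#' Thin wrappers around Biostrings: sequences are handled as uppercase RNA
#' (`A`/`C`/`G`/`U`; `T` on input is read as `U`) and written wrapped at
#' 60 columns.
#'
#' @param sequences named character vector of RNA sequences.
#' @param path FASTA file path.
#' @return `read_rna_fasta()` returns a named character vector.
#' @export
write_rna_fasta <- function(sequences, path) {
  set <- Biostrings::RNAStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname write_rna_fasta
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readRNAStringSet(path)
  setNames(as.character(set), names(set))
}
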