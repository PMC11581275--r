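#' Sequentially conserved miRNAs (sc set)
#'
#' Aligns each differentially expressed species-A miRNA against the full
#' species-B (human) mature set and keeps those whose top-scoring match
#' reaches `min_identity` percent identity. The homologue map (query,
#' best target(s), score, identity) is recorded for downstream set
#' intersection.
#'
#' @param de_features character vector of DE species-A feature IDs.
#' @param seq_a,seq_b named character vectors of mature RNA sequences
#'   (e.g. from [read_rna_fasta()]).
#' @param params an [alignment_params()].
#' @param min_identity percent identity threshold for calling a
#'   homologue (default 90).
#' @return list of class `sc_set`: `sc` (character), `map` (data frame of
#'   all top matches for the DE features), `min_identity`.
#' @export
curate_sc <- function(de_features, seq_a, seq_b,
                      params = alignment_params(), min_identity = 90) {
  missing <- setdiff(de_features, names(seq_a))
  if (length(missing)) {
    message("excluding ", length(missing),
            " DE feature(s) absent from the species-A FASTA: ",
            paste(missing, collapse = ", "))
    de_features <- setdiff(de_features, missing)
  }
  maps <- lapply(de_features, function(f) {
    top_match(setNames(seq_a[f], f), seq_b, params)
  })
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(query = character(0), target = character(0), score = numeric(0),
               pct_identity = numeric(0), aligned_length = integer(0))
  sc <- unique(map$query[map$pct_identity >= min_identity])
  structure(list(sc = sc, map = map, min_identity = min_identity),
            class = "sc_set")
}

#' Functionally similar miRNAs (fs set)
#'
#' Approximates re-quantification against the human reference at
#' mature-sequence granularity: each measured species-A feature is
#' re-assigned to its best-matching human mature miRNA (first target by
#' ID on ties, requiring `min_identity` percent identity), counts mapping
#' to the same human ID are summed, and the standard screening pipeline
#' (prefilter, TMM, CPM, per-animal log2 fold change, four-way ANOVA) is
#' re-run on the human-ID matrix. The fs set is the union of features
#' significant in at least one term at `alpha`.
#'
#' @param counts species-A count matrix, features x samples.
#' @param meta sample metadata.
#' @param seq_a named sequences of the measured species-A features.
#' @param seq_human named human mature reference sequences.
#' @param params an [alignment_params()].
#' @param alpha ANOVA significance cut-off.
#' @param min_identity minimal percent identity for a feature to map to a
#'   human ID at all (default 60; unrelated short RNA pairs align well
#'   below this).
#' @param min_nonzero_frac prefilter threshold for the re-quantified
#'   matrix.
#' @return list of class `fs_set`: `fs` (human IDs), `assignment` (data
#'   frame feature -> human ID), `anova` (the re-run screen).
#' @export
curate_fs <- function(counts, meta, seq_a, seq_human,
                      params = alignment_params(), alpha = 0.05,
                      min_identity = 60, min_nonzero_frac = 0.40) {
  feats <- intersect(rownames(counts), names(seq_a))
  assignment <- data.frame(feature = character(0), human_id = character(0),
                           pct_identity = numeric(0))
  for (f in feats) {
    tm <- top_match(setNames(seq_a[f], f), seq_human, params)
    if (nrow(tm) && tm$pct_identity[1] >= min_identity) {
      assignment <- rbind(assignment, data.frame(
        feature = f, human_id = tm$target[1], pct_identity = tm$pct_identity[1]))
    }
  }
  if (!nrow(assignment)) {
    warning("no measured feature maps to the human reference; fs set is empty")
    return(structure(list(fs = character(0), assignment = assignment,
                          anova = NULL), class = "fs_set"))
  }
  human_counts <- rowsum(counts[assignment$feature, , drop = FALSE],
                         group = assignment$human_id)
  human_counts <- human_counts[order(rownames(human_counts)), , drop = FALSE]
  storage.mode(human_counts) <- "integer"

  kept <- prefilter_features(human_counts, min_nonzero_frac)
  f <- tmm_factors(kept)
  cpm <- cpm_matrix(kept, f)
  fcm <- log2fc_baseline(cpm, meta)
  res <- fit_four_way_anova(fcm, alpha = alpha)
  fs <- curate_de_union(res, alpha)$union
  structure(list(fs = fs, assignment = assignment, anova = res),
            class = "fs_set")
}

#' Conserved miRNA set (cnvd = sc intersect fs)
#'
#' Maps each sc feature to its human homologue (best target of the sc
#' homologue map) and intersects with the fs set: a feature is conserved
#' if its mapped human ID was re-identified as differentially expressed
#' against the human reference. Unmapped sc features are treated as
#' non-overlapping and reported.
#'
#' @param sc an `sc_set` (or character vector of species-A features, in
#'   which case `map` must be supplied).
#' @param fs an `fs_set` (or character vector of human IDs).
#' @param map homologue map data frame (`query`, `target`,
#'   `pct_identity`); defaults to the map inside `sc`.
#' @return list of class `conserved_sets`: `sc`, `fs`, `cnvd` (species-A
#'   IDs), `cnvd_human` (their human IDs), `venn` (named counts).
#' @export
intersect_sets <- function(sc, fs, map = NULL) {
  if (inherits(sc, "sc_set")) {
    map <- map %||% sc$map
    sc <- sc$sc
  }
  if (inherits(fs, "fs_set")) fs <- fs$fs
  if (is.null(map)) stop("a homologue map is required to compare the two sets")
  mapped <- map[map$query %in% sc, , drop = FALSE]
  unmapped <- setdiff(sc, mapped$query)
  if (length(unmapped)) {
    message(length(unmapped), " sc feature(s) without a homologue mapping ",
            "treated as non-overlapping")
  }
  hit <- mapped[mapped$target %in% fs, , drop = FALSE]
  cnvd <- unique(hit$query)
  structure(
    list(sc = sc, fs = fs, cnvd = cnvd,
         cnvd_human = unique(hit$target),
         venn = c(sc = length(sc), fs = length(fs), cnvd = length(cnvd))),
    class = "conserved_sets"
  )
}

#' @export
print.conserved_sets <- function(x, ...) {
  cat(sprintf("Conserved miRNA curation: %d sc, %d fs, %d cnvd (= sc intersect fs)\n",
              x$venn["sc"], x$venn["fs"], x$venn["cnvd"]))
  invisible(x)
}
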