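#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Every threshold is range
#' checked; unknown keys in a configuration file are rejected. When the
#' input paths are `NULL` the pipeline starts by simulating a cohort
#' under the default study design.
#'
#' @param counts,metadata,fasta_a,fasta_b input paths (TSV counts,
#'   TSV metadata, two mature miRNA FASTA files); all `NULL` to simulate.
#' @param outdir output directory (created if needed).
#' @param seed integer seed for every stochastic stage.
#' @param n_features simulated feature count (used only when simulating).
#' @param alpha ANOVA / marker significance level, in (0, 1).
#' @param min_nonzero_frac prefilter threshold, in (0, 1\].
#' @param min_identity sc-homologue percent identity threshold, in
#'   \[0, 100\].
#' @param auc_min,p_max panel screening thresholds.
#' @param min_size,max_size panel size bounds, within \[2, 10\].
#' @param rf_reps,top_panels,panel_size,num_trees forest-ranking
#'   settings.
#' @param split,n_repeats,k cross-validation settings.
#' @param verbose print stage messages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL,
                            fasta_a = NULL, fasta_b = NULL,
                            outdir = tempfile("radmir_run_"),
                            seed = 1L, n_features = 200L,
                            alpha = 0.05, min_nonzero_frac = 0.40,
                            min_identity = 90, auc_min = 0.80, p_max = 0.05,
                            min_size = 2L, max_size = 10L,
                            rf_reps = 2000L, top_panels = 200L,
                            panel_size = 10L, num_trees = 100L,
                            split = 0.70, n_repeats = 10L, k = 10L,
                            verbose = TRUE) {
  cfg <- list(counts = counts, metadata = metadata, fasta_a = fasta_a,
              fasta_b = fasta_b, outdir = outdir, seed = as.integer(seed),
              n_features = as.integer(n_features), alpha = alpha,
              min_nonzero_frac = min_nonzero_frac,
              min_identity = min_identity, auc_min = auc_min, p_max = p_max,
              min_size = as.integer(min_size), max_size = as.integer(max_size),
              rf_reps = as.integer(rf_reps), top_panels = as.integer(top_panels),
              panel_size = as.integer(panel_size),
              num_trees = as.integer(num_trees), split = split,
              n_repeats = as.integer(n_repeats), k = as.integer(k),
              verbose = isTRUE(verbose))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  check(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  check(cfg$min_nonzero_frac > 0 && cfg$min_nonzero_frac <= 1,
        "min_nonzero_frac must lie in (0, 1]")
  check(cfg$min_identity >= 0 && cfg$min_identity <= 100,
        "min_identity must lie in [0, 100]")
  check(cfg$auc_min >= 0 && cfg$auc_min <= 1, "auc_min must lie in [0, 1]")
  check(cfg$p_max > 0 && cfg$p_max <= 1, "p_max must lie in (0, 1]")
  check(cfg$min_size >= 2 && cfg$max_size <= 10 && cfg$min_size <= cfg$max_size,
        "panel sizes must satisfy 2 <= min_size <= max_size <= 10")
  check(cfg$split > 0 && cfg$split < 1, "split must lie in (0, 1)")
  check(cfg$k >= 2, "k must be at least 2")
  check(cfg$rf_reps >= 1 && cfg$top_panels >= 1 && cfg$num_trees >= 1,
        "forest settings must be positive")
  check(cfg$n_features >= 20, "n_features must be at least 20")
  given <- !vapply(cfg[c("counts", "metadata")], is.null, logical(1))
  check(all(given) || all(!given),
        "counts and metadata must be supplied together (or both omitted)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML `key: value` configuration; keys must match [pipeline_config()]
#' arguments, anything else is rejected.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Run the full discovery pipeline
#'
#' Orchestrates every stage end to end: cohort simulation (when no input
#' paths are given), prefilter + TMM/CPM normalization, per-animal log2
#' fold change, four-way ANOVA and DE-union curation, cross-species
#' conservation (sc / fs / cnvd), dose- and time-response marker
#' screening, 2BDP panel discovery on the conserved set, and descriptive
#' PCA / clustering reports. All artifacts are written under
#' `config$outdir` together with a checksum manifest; identical
#' configuration and seed reproduce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `status` (0 on success), `manifest`
#'   (data frame: file, stage, md5), and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0))
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    writeLines(line, log_con)
    if (config$verbose) message(line)
  }
  emit <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(file = basename(path), stage = stage))
  }
  out <- function(name) file.path(config$outdir, name)

  # --- inputs -------------------------------------------------------------
  if (is.null(config$counts)) {
    scfg <- sim_config(n_features = config$n_features,
                       planted = default_planted_truth(config$n_features),
                       seed = config$seed)
    cohort <- simulate_cohort(scfg, default_study_design())
    counts <- cohort$counts
    meta <- cohort$metadata
    fsim <- simulate_mirna_fasta(scfg, file_a = out("mirna_a.fasta"),
                                 file_b = out("mirna_b.fasta"),
                                 n_decoys_b = 20L)
    seq_a <- fsim$seq_a
    seq_b <- fsim$seq_b
    write_matrix_tsv(counts, out("counts.tsv"))
    write_metadata_tsv(meta, out("metadata.tsv"))
    write_planted_truth_json(cohort$planted, out("planted_truth.json"))
    for (f in c("counts.tsv", "metadata.tsv", "planted_truth.json",
                "mirna_a.fasta", "mirna_b.fasta")) emit("simulate", out(f))
    say("simulate", "%d features x %d samples, %d animals",
        nrow(counts), ncol(counts), length(unique(meta$animal_id)))
  } else {
    counts <- read_matrix_tsv(config$counts)
    meta <- read_metadata_tsv(config$metadata)
    seq_a <- read_rna_fasta(config$fasta_a)
    seq_b <- read_rna_fasta(config$fasta_b)
    say("input", "read %d features x %d samples", nrow(counts), ncol(counts))
  }

  # --- normalize ----------------------------------------------------------
  kept <- prefilter_features(counts, config$min_nonzero_frac)
  factors <- tmm_factors(kept)
  cpm <- cpm_matrix(kept, factors)
  fc <- log2fc_baseline(cpm, meta)
  write_matrix_tsv(kept, out("filtered_counts.tsv"))
  write_norm_factors_tsv(factors, out("norm_factors.tsv"))
  write_matrix_tsv(round(cpm, 4), out("cpm.tsv"))
  write_matrix_tsv(round(fc$fc, 6), out("log2fc.tsv"))
  for (f in c("filtered_counts.tsv", "norm_factors.tsv", "cpm.tsv", "log2fc.tsv"))
    emit("normalize", out(f))
  say("normalize", "%d of %d features pass the %.0f%% non-zero prefilter",
      nrow(kept), nrow(counts), 100 * config$min_nonzero_frac)

  # --- differential -------------------------------------------------------
  screen <- fit_four_way_anova(fc, alpha = config$alpha)
  de <- curate_de_union(screen)
  write.table(screen, out("anova_results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(de$union, out("de_union.txt"))
  emit("differential", out("anova_results.tsv"))
  emit("differential", out("de_union.txt"))
  say("differential", "%d features significant in >=1 of 15 terms", length(de$union))

  # --- conservation -------------------------------------------------------
  params <- alignment_params()
  sc <- curate_sc(de$union, seq_a, seq_b, params, config$min_identity)
  fs <- curate_fs(kept, meta, seq_a, seq_b, params, config$alpha,
                  min_nonzero_frac = config$min_nonzero_frac)
  conserved <- intersect_sets(sc, fs)
  write.table(sc$map, out("homologue_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(conserved$sc, out("sc_mirna.txt"))
  writeLines(conserved$fs, out("fs_mirna.txt"))
  writeLines(conserved$cnvd, out("cnvd_mirna.txt"))
  jsonlite::write_json(as.list(conserved$venn), out("venn_counts.json"),
                       auto_unbox = TRUE)
  for (f in c("homologue_map.tsv", "sc_mirna.txt", "fs_mirna.txt",
              "cnvd_mirna.txt", "venn_counts.json")) emit("conservation", out(f))
  say("conservation", "%d sc / %d fs / %d cnvd",
      length(conserved$sc), length(conserved$fs), length(conserved$cnvd))

  # --- marker screen ------------------------------------------------------
  fc_cnvd <- fc
  if (length(conserved$cnvd) >= 2L) {
    fc_cnvd$fc <- fc$fc[intersect(rownames(fc$fc), conserved$cnvd), , drop = FALSE]
  }
  markers <- rbind(screen_markers(fc_cnvd, "dose", config$alpha),
                   screen_markers(fc_cnvd, "time", config$alpha))
  write.table(markers, out("markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  emit("marker_screen", out("markers.tsv"))
  n_hits <- sum(markers$stratum == "all" & markers$label != "none")
  say("marker_screen", "%d features screened, %d with a dose/time label",
      nrow(markers) / 6L, n_hits)

  top <- markers[markers$stratum == "all" & markers$label != "none", ]
  roc <- NULL
  if (nrow(top)) {
    top_feat <- top$feature[which.min(top$p)]
    pre_cpm <- cpm[top_feat, meta$sample_id[meta$timepoint == "pre"]]
    post_cpm <- cpm[top_feat, fc$meta$sample_id]
    roc <- single_marker_auc(c(pre_cpm, post_cpm),
                             c(rep(FALSE, length(pre_cpm)), rep(TRUE, length(post_cpm))),
                             seed = config$seed)
    jsonlite::write_json(
      list(feature = top_feat, auc = roc$auc, ci_low = roc$ci_low,
           ci_high = roc$ci_high, n_pos = roc$n_pos, n_neg = roc$n_neg),
      out("roc_summary.json"), auto_unbox = TRUE, digits = NA)
    emit("marker_screen", out("roc_summary.json"))
  }

  # --- panel discovery ----------------------------------------------------
  pin <- panel_input_matrix(fc, features = if (length(conserved$cnvd) >= config$min_size)
    conserved$cnvd else NULL)
  bdp <- discover_panels(pin$x, pin$y, method = "kfold",
                         n_reps = config$rf_reps, top_panels = config$top_panels,
                         panel_size = config$panel_size,
                         num_trees = config$num_trees,
                         min_size = config$min_size, max_size = config$max_size,
                         split = config$split, n_repeats = config$n_repeats,
                         k = config$k, auc_min = config$auc_min,
                         p_max = config$p_max, seed = config$seed)
  write.table(bdp$screened, out("panels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  panel_json <- lapply(attr(bdp$screened, "evaluations"), function(e) {
    list(features = e$features, intercept = e$model$intercept,
         coefficients = as.list(e$model$coefficients), method = e$method,
         mean_auc = e$mean_auc, auc_ci = e$auc_ci,
         sensitivity = e$sensitivity, specificity = e$specificity,
         mcfadden_r2 = e$mcfadden_r2, fit_p = e$fit_p)
  })
  jsonlite::write_json(panel_json, out("panels.json"), auto_unbox = TRUE,
                       digits = NA)
  emit("panel_discovery", out("panels.tsv"))
  emit("panel_discovery", out("panels.json"))
  say("panel_discovery", "%d subpanels evaluated, %d passed the screen",
      bdp$n_subpanels, nrow(bdp$screened))

  # --- reports ------------------------------------------------------------
  pca <- pca_report(fc)
  write_matrix_tsv(round(t(pca$scores), 6), out("pca_scores.tsv"))
  jsonlite::write_json(list(explained = pca$explained), out("pca_explained.json"),
                       auto_unbox = FALSE, digits = NA)
  hc <- hclust_report(fc_cnvd)
  jsonlite::write_json(list(order = hc$order, heights = hc$heights),
                       out("hclust.json"), auto_unbox = FALSE, digits = NA)
  for (f in c("pca_scores.tsv", "pca_explained.json", "hclust.json"))
    emit("report", out(f))
  say("report", "PCA PC1 explains %.1f%% of variance", 100 * pca$explained[1])

  manifest$md5 <- unname(tools::md5sum(file.path(config$outdir, manifest$file)))
  write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("done", "%d artifacts in %s", nrow(manifest), config$outdir)
  invisible(list(status = 0L, manifest = manifest, de = de,
                 conserved = conserved, markers = markers, roc = roc,
                 bdp = bdp, pca = pca))
}
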