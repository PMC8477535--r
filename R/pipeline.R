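#' Default pipeline run configuration
#'
#' The bundled configuration simulates the paired-lesion study design (3
#' patients, patch + tumor samples, 300 dominant-clone cells per lesion class
#' per patient, the 6-gene panel planted at log-fold-change -0.8, seed 1) and
#' runs every stage with the study thresholds: clone comparisons at
#' |logFC| > 0.3, microenvironment comparisons at |logFC| > 0.25, adjusted
#' p < 0.05, Bonferroni within each comparison.
#'
#' @param out_dir output directory.
#' @param seed integer seed (propagated to simulation and permutations).
#' @return a `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("mfclone_run_"), seed = 1L) {
  structure(list(
    simulate = list(cells_per_sample = 715, seed = as.integer(seed)),
    counts = NULL, features = NULL, barcodes = NULL,
    metadata = NULL, contigs = NULL,
    pairs = system.file("extdata", "demo_pairs.tsv", package = "mfclone"),
    classes_a = c("plaque", "tumor"), classes_b = "patch",
    clone_thresholds = de_thresholds(min_abs_logfc = 0.3),
    micro_thresholds = de_thresholds(min_abs_logfc = 0.25),
    markers = c(cd4 = "CD4", cd8a = "CD8A", foxp3 = "FOXP3"),
    scope = "patient",
    n_perm = 1000L, min_frac = 0.1,
    seed = as.integer(seed), out_dir = out_dir), class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Keys mirror [default_run_config()]; unspecified keys keep their defaults.
#' Threshold entries may be given as lists with `min_abs_logfc`, `alpha`,
#' `min_pct`.
#'
#' @param path JSON file.
#' @param out_dir,seed overrides applied after reading.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (k in names(raw)) {
    if (k %in% c("clone_thresholds", "micro_thresholds")) {
      cfg[[k]] <- do.call(de_thresholds, as.list(raw[[k]]))
    } else if (k == "markers") {
      cfg[[k]] <- unlist(raw[[k]])
    } else cfg[[k]] <- raw[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(cfg$simulate) && !is.null(seed))
    cfg$simulate$seed <- as.integer(seed)
  cfg
}

#' Cross-check counts, metadata and contigs for consistency
#'
#' Report-only: returns a data.frame of issues (empty when everything is
#' consistent) listing orphan contig barcodes, cells missing on either side
#' of the counts/metadata join, duplicate gene symbols in a raw feature list,
#' and clusters without cells.
#'
#' @param cm a `CountMatrix`.
#' @param metadata cell metadata data.frame.
#' @param contigs contig data.frame (optional).
#' @param features optional raw feature-symbol vector (pre-deduplication),
#'   checked for duplicates with their row indices.
#' @return data.frame with columns `issue`, `detail`.
#' @export
validate_inputs <- function(cm, metadata, contigs = NULL, features = NULL) {
  issues <- list()
  add <- function(issue, detail)
    issues[[length(issues) + 1]] <<- data.frame(issue = issue, detail = detail,
                                                stringsAsFactors = FALSE)
  if (!is.null(contigs)) {
    orphans <- setdiff(unique(contigs$cell_id), metadata$cell_id)
    for (o in orphans) add("orphan_contig_barcode", o)
  }
  for (m in setdiff(metadata$cell_id, cm$cells))
    add("metadata_cell_missing_from_counts", m)
  for (m in setdiff(cm$cells, metadata$cell_id))
    add("counts_cell_missing_from_metadata", m)
  if (!is.null(features)) {
    up <- toupper(features)
    for (d in unique(up[duplicated(up)]))
      add("duplicate_gene_symbol",
          paste0(d, " (rows ", paste(which(up == d), collapse = ","), ")"))
  }
  cl <- table(factor(metadata$cluster))
  for (d in names(cl)[cl == 0]) add("empty_cluster", d)
  out <- do.call(rbind, issues)
  if (is.null(out)) out <- data.frame(issue = character(0), detail = character(0))
  out
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(do.call(synthetic_config, config$simulate))
    return(sim)
  }
  for (f in c("counts", "features", "barcodes", "metadata", "contigs")) {
    if (is.null(config[[f]]))
      stop("run_pipeline: config lacks both 'simulate' and input path '", f, "'")
    if (!file.exists(config[[f]]))
      stop("run_pipeline: input file not found: ", config[[f]])
  }
  list(counts = read_counts(config$counts, config$features, config$barcodes),
       metadata = read_metadata(config$metadata),
       contigs = read_contigs(config$contigs),
       truth = NULL)
}

#' Run the full clonality-aware analysis pipeline
#'
#' Executes simulate/load, validation, clonotyping, normalization, gating,
#' per-cluster DEG counting, per-patient malignant-clone DE, the
#' cross-patient consistent marker panel with its benign-subset specificity
#' check, and ligand-receptor interaction scoring with between-lesion
#' deltas. Every intermediate table is written to `config$out_dir`, plus a
#' JSON manifest with file checksums, the seed and per-stage timings. Reruns
#' with the same config are bit-identical.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param stages character vector of optional stages to execute, any of
#'   `"de"`, `"panel"`, `"interactions"` (clonotyping, normalization and
#'   gating always run).
#' @return invisibly, a list with all stage results plus the `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("de", "panel", "interactions")) {
  stopifnot(is.list(config))
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c(); t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3); t0 <<- t1
  }
  log_msg <- function(...) message("[mfclone] ", ...)

  inputs <- load_pipeline_inputs(config)
  cm <- inputs$counts; metadata <- inputs$metadata; contigs <- inputs$contigs
  log_msg(length(cm$cells), " cells, ", length(cm$genes), " genes, ",
          nrow(contigs), " contigs across ",
          length(unique(metadata$sample_id)), " samples")
  tick("load")

  report <- validate_inputs(cm, metadata, contigs)
  if (nrow(report)) log_msg("validation: ", nrow(report), " issue(s)")
  write_table(report, file.path(out_dir, "validation.tsv"))
  tick("validate")

  ct <- group_clonotypes(contigs)
  dom <- dominant_clone(ct, metadata, scope = config$scope)
  assignments <- assign_clonality(ct, dom, metadata)
  for (i in seq_len(nrow(dom)))
    log_msg(sprintf("dominant clone %s in %s: %.1f%% of %d TCR+ cells",
                    dom$clone_id[i], dom$sample_id[i], 100 * dom$fraction[i],
                    dom$n_tcr_cells[i]))
  write_table(ct$clones, file.path(out_dir, "clones.tsv"))
  write_table(dom, file.path(out_dir, "clone_stats.tsv"))
  write_table(alpha_share(ct, dom, contigs, metadata),
              file.path(out_dir, "alpha_share.tsv"))
  tick("clonotype")

  cm <- log_normalize(cm)
  assignments <- gate_subsets(cm, assignments, config$markers)
  write_table(assignments, file.path(out_dir, "assignments.tsv"))
  tick("gate")

  res <- list(clonotypes = ct, dominant = dom, assignments = assignments,
              validation = report, counts = cm, metadata = metadata,
              truth = inputs$truth)

  if ("de" %in% stages) {
    degc <- deg_count_per_cluster(cm, metadata, config$classes_a,
                                  config$classes_b, config$micro_thresholds)
    write_table(degc, file.path(out_dir, "deg_per_cluster.tsv"))
    res$deg_per_cluster <- degc
    tick("de")
  }

  if ("panel" %in% stages) {
    pp <- per_patient_clone_de(cm, metadata, assignments, config$classes_a,
                               config$classes_b, config$clone_thresholds)
    for (p in names(pp))
      write_table(pp[[p]], file.path(out_dir, paste0("de_clone_", p, ".tsv")))
    panel <- consistent_panel(pp)
    log_msg("panel: up = {", paste(panel$up, collapse = ", "),
            "}, down = {", paste(panel$down, collapse = ", "), "}")
    panel_df <- data.frame(gene = c(panel$up, panel$down),
                           direction = c(rep("up", length(panel$up)),
                                         rep("down", length(panel$down))))
    write_table(panel_df, file.path(out_dir, "panel.tsv"))
    spec <- specificity_check(cm, metadata, assignments, panel,
                              config$classes_a, config$classes_b,
                              config$clone_thresholds)
    write_table(spec$flags, file.path(out_dir, "specificity.tsv"))
    jsonlite::write_json(
      list(panel_up = panel$up, panel_down = panel$down,
           specificity = spec$flags),
      file.path(out_dir, "panel_summary.json"), digits = 10)
    res$per_patient_de <- pp; res$panel <- panel; res$specificity <- spec
    tick("panel")
  }

  if ("interactions" %in% stages) {
    pairs <- read_pairs(config$pairs)
    # evaluate each pair in both orientations relative to the malignant
    # clone: ligand on the clone, or receptor on the clone (reversed entry)
    rev_pairs <- data.frame(pair_id = paste0(pairs$pair_id, ":rev"),
                            ligand_gene = pairs$receptor_gene,
                            receptor_gene = pairs$ligand_gene,
                            stringsAsFactors = FALSE)
    pairs <- rbind(pairs, rev_pairs)
    clusters <- metadata$cluster
    mal <- assignments$clonality[match(cm$cells, assignments$cell_id)] == "dominant"
    clusters <- clusters[match(cm$cells, metadata$cell_id)]
    clusters[mal] <- "Malignant"
    scores <- list()
    for (s in unique(metadata$sample_id)) {
      in_s <- metadata$cell_id[metadata$sample_id == s]
      keep <- cm$cells %in% in_s
      sub_cm <- cm
      sub_cm$counts <- cm$counts[, keep, drop = FALSE]
      sub_cm$normalized <- cm$normalized[, keep, drop = FALSE]
      sub_cm$cells <- cm$cells[keep]
      cl_s <- clusters[keep]
      if (!any(cl_s == "Malignant")) next
      ys <- setdiff(unique(cl_s[!(cl_s %in% c("Malignant"))]), character(0))
      scores[[s]] <- score_interactions(sub_cm, cl_s, pairs, "Malignant",
                                        Ys = ys, n_perm = config$n_perm,
                                        seed = config$seed,
                                        min_frac = config$min_frac,
                                        sample_id = s)
    }
    scores <- do.call(rbind, scores)
    write_table(scores, file.path(out_dir, "interactions.tsv"))
    pairing <- stage_pairing(metadata, config$classes_a, config$classes_b)
    deltas <- if (nrow(pairing))
      interaction_deltas(scores, pairing) else data.frame()
    write_table(deltas, file.path(out_dir, "interaction_deltas.tsv"))
    res$interactions <- scores; res$interaction_deltas <- deltas
    tick("interactions")
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mfclone")),
    seed = config$seed, timings_sec = as.list(timings),
    n_cells = length(cm$cells), n_genes = length(cm$genes),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = 10, auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# Patient-wise pairing of one palpable and one patch sample, where both exist.
stage_pairing <- function(metadata, classes_a, classes_b) {
  out <- list()
  for (p in unique(metadata$patient_id)) {
    md <- metadata[metadata$patient_id == p, , drop = FALSE]
    sa <- unique(md$sample_id[md$lesion_class %in% classes_a])
    sb <- unique(md$sample_id[md$lesion_class %in% classes_b])
    if (length(sa) == 1 && length(sb) == 1)
      out[[p]] <- data.frame(patient_id = p, sample_palpable = sa,
                             sample_patch = sb, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(patient_id = character(0), sample_palpable = character(0),
                      sample_patch = character(0))
  rownames(res) <- NULL
  res
}
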