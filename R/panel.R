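#' Per-patient differential expression within the malignant clone
#'
#' For each patient independently, runs [de_genes()] on dominant-clone cells
#' of the `classes_a` lesion classes versus dominant-clone cells of the
#' `classes_b` classes (default palpable plaque/tumor vs flat patch).
#' Patients lacking malignant cells in either condition are skipped with a
#' warning. Because each patient's test is self-contained, results are
#' invariant to processing order.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param metadata cell metadata data.frame.
#' @param assignments gated output of [assign_clonality()]/[gate_subsets()].
#' @param classes_a,classes_b lesion-class label vectors.
#' @param thresholds a [de_thresholds()] (clone default `min_abs_logfc` 0.3).
#' @param subset which gated subset to compare within (default
#'   `"malignant"`; benign subsets serve the specificity check).
#' @return named list (one element per eligible patient) of significant
#'   `DEResult` data.frames, each carrying the full tested table as
#'   attribute `"all"`.
#' @export
per_patient_clone_de <- function(cm, metadata, assignments,
                                 classes_a = c("plaque", "tumor"),
                                 classes_b = "patch",
                                 thresholds = de_thresholds(min_abs_logfc = 0.3),
                                 subset = "malignant") {
  sub_cells <- assignments$cell_id[assignments$subset == subset]
  out <- list()
  for (p in unique(metadata$patient_id)) {
    md <- metadata[metadata$patient_id == p, , drop = FALSE]
    ca <- intersect(md$cell_id[md$lesion_class %in% classes_a], sub_cells)
    cb <- intersect(md$cell_id[md$lesion_class %in% classes_b], sub_cells)
    ca <- intersect(ca, cm$cells); cb <- intersect(cb, cm$cells)
    if (!length(ca) || !length(cb)) {
      warning("per_patient_clone_de: patient ", p, " lacks '", subset,
              "' cells in one condition; skipped")
      next
    }
    full <- de_genes(cm, ca, cb, thresholds, significant_only = FALSE)
    sig <- full[full$p_adj < thresholds$alpha &
                  abs(full$logfc) > thresholds$min_abs_logfc, , drop = FALSE]
    rownames(sig) <- NULL
    attr(sig, "all") <- full
    out[[p]] <- sig
  }
  if (!length(out)) warning("per_patient_clone_de: no eligible patient")
  out
}

#' Cross-patient direction-consistent marker panel
#'
#' Intersects per-patient significant gene lists: a gene enters the panel iff
#' it is significant with the same sign of log fold change in every patient
#' (strict intersection, mirroring a Venn-diagram construction). A relaxed
#' `min_patients` ("k of n") mode is available but off by default. Panel
#' genes are ordered by their worst (largest) per-patient adjusted p-value,
#' ascending.
#'
#' @param per_patient named list from [per_patient_clone_de()] (>= 2
#'   patients).
#' @param min_patients minimum number of patients a gene must be
#'   consistently significant in (default: all).
#' @return object of class `marker_panel`: list with `up` and `down` gene
#'   vectors, `per_patient` evidence (data.frame of the panel genes' per-
#'   patient statistics) and `n_patients`.
#' @export
consistent_panel <- function(per_patient, min_patients = length(per_patient)) {
  if (length(per_patient) < 2)
    stop("consistent_panel: need results from at least 2 patients")
  stopifnot(min_patients >= 1, min_patients <= length(per_patient))
  pick <- function(dir) {
    tabs <- lapply(per_patient, function(d) d[d$direction == dir, , drop = FALSE])
    counts <- table(unlist(lapply(tabs, `[[`, "gene")))
    genes <- names(counts)[counts >= min_patients]
    # exclude genes significant with the opposite sign anywhere
    other <- unique(unlist(lapply(per_patient, function(d)
      d$gene[d$direction != dir])))
    genes <- setdiff(genes, other)
    if (!length(genes)) return(character(0))
    worst <- vapply(genes, function(g)
      max(vapply(tabs, function(d)
        if (g %in% d$gene) d$p_adj[d$gene == g] else NA_real_, 0),
        na.rm = TRUE), 0)
    genes[order(worst)]
  }
  up <- pick("up"); down <- pick("down")
  both <- intersect(up, down)
  stopifnot(length(both) == 0)
  ev <- do.call(rbind, lapply(names(per_patient), function(p) {
    d <- per_patient[[p]]
    d <- d[d$gene %in% c(up, down), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    cbind(patient_id = p, d, stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) ev <- data.frame()
  structure(list(up = up, down = down, per_patient = ev,
                 n_patients = length(per_patient),
                 min_patients = min_patients),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel (%d patients, consistency >= %d):\n",
              x$n_patients, x$min_patients))
  cat("  up:  ", if (length(x$up)) paste(x$up, collapse = ", ") else "(none)", "\n")
  cat("  down:", if (length(x$down)) paste(x$down, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Benign-subset specificity check for a marker panel
#'
#' Re-runs the per-patient comparison within each benign gated subset
#' (helper, regulatory, cytotoxic) and reports, per panel gene, whether it is
#' consistently significant with the panel's direction in all patients of
#' that subset — the expectation for a malignant-clone-restricted panel being
#' `FALSE` everywhere. Also reports each benign subset's own full consistent
#' panel. Subsets lacking cells in both conditions for some patient are
#' marked not evaluable (NA flags).
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param metadata cell metadata data.frame.
#' @param assignments gated assignments.
#' @param panel a [consistent_panel()] result.
#' @param classes_a,classes_b lesion-class label vectors (same comparison as
#'   the panel).
#' @param thresholds a [de_thresholds()].
#' @return list with `flags` (data.frame `subset`, `gene`, `direction`,
#'   `consistent`) and `benign_panels` (named list of `marker_panel` or NULL
#'   when not evaluable).
#' @export
specificity_check <- function(cm, metadata, assignments, panel,
                              classes_a = c("plaque", "tumor"),
                              classes_b = "patch",
                              thresholds = de_thresholds(min_abs_logfc = 0.3)) {
  stopifnot(inherits(panel, "marker_panel"))
  genes <- c(panel$up, panel$down)
  dirs <- c(rep("up", length(panel$up)), rep("down", length(panel$down)))
  subsets <- c("helper", "regulatory", "cytotoxic")
  flags <- list(); benign_panels <- list()
  n_patients <- length(unique(metadata$patient_id))
  for (s in subsets) {
    pp <- withCallingHandlers(
      per_patient_clone_de(cm, metadata, assignments, classes_a, classes_b,
                           thresholds, subset = s),
      warning = function(w) invokeRestart("muffleWarning"))
    evaluable <- length(pp) == n_patients && n_patients >= 2
    if (evaluable) {
      bp <- consistent_panel(pp)
      benign_panels[[s]] <- bp
      consistent <- (dirs == "up" & genes %in% bp$up) |
        (dirs == "down" & genes %in% bp$down)
    } else {
      benign_panels[s] <- list(NULL)
      consistent <- rep(NA, length(genes))
    }
    if (length(genes))
      flags[[s]] <- data.frame(subset = s, gene = genes, direction = dirs,
                               consistent = consistent, stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, flags)
  if (is.null(flags))
    flags <- data.frame(subset = character(0), gene = character(0),
                        direction = character(0), consistent = logical(0))
  rownames(flags) <- NULL
  list(flags = flags, benign_panels = benign_panels)
}
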