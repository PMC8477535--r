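AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Injective base-20 encoding of a non-negative integer into amino acids,
# fixed width, so generated CDR3s are unique and valid by construction.
aa_encode <- function(i, width = 5) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k]; s <- character(width)
    for (j in width:1) { s[j] <- AA20[v %% 20 + 1]; v <- v %/% 20 }
    out[k] <- paste(s, collapse = "")
  }
  out
}

#' Configuration for the synthetic paired-lesion dataset
#'
#' Defaults emulate the study design the pipeline assumes: a handful of
#' patients, each contributing one flat (patch) and one palpable (progressed)
#' lesion sample; in every sample one strongly expanded clonotype (the same
#' clonotype across a patient's samples) occupying a stated fraction of TCR+
#' cells, a polyclonal T-cell background with CD4/CD8A/FOXP3-defined subsets,
#' non-T microenvironment cells, negative-binomial counts with log-normal
#' library-size factors, and clone-restricted expression effects planted in
#' the progressed lesion class only.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient lesion-class label per sample (each patient
#'   gets one sample per label).
#' @param cells_per_sample total cells per sample.
#' @param n_genes total genes (>= built-in marker/program genes).
#' @param nb_mean_log_range range of baseline per-gene log mean expression.
#' @param nb_dispersion negative-binomial dispersion theta (variance
#'   mu + mu^2/theta).
#' @param clone_fraction fraction of TCR+ cells in the dominant clone;
#'   scalar or one value per patient.
#' @param tcr_detection_rate fraction of T cells with any chain recovered.
#' @param allelic_exclusion_rate fraction of dominant-clone cells carrying a
#'   secondary alpha CDR3 (in [0, 1)).
#' @param planted_effects named numeric vector, gene -> log-fold-change
#'   multiplier `exp(lfc)` applied to dominant-clone cells of the progressed
#'   class.
#' @param marker_genes names of the CD4/CD8A/FOXP3 analogues used by gating.
#' @param progressed_class lesion class receiving the planted effects.
#' @param chain_type `"ab"` (TRA/TRB) or `"gd"` (TRG/TRD).
#' @param t_cell_frac fraction of cells that are T cells.
#' @param planted_base_mean baseline NB mean for planted genes (high, so
#'   planted log fold changes survive the pseudocounted logFC convention).
#' @param libsize_sdlog sdlog of the log-normal library-size factors.
#' @param gene_names optional explicit gene list (must contain marker and
#'   planted genes).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 3,
                             samples_per_patient = c("patch", "tumor"),
                             cells_per_sample = 700,
                             n_genes = 2000,
                             nb_mean_log_range = c(-4, 0.5),
                             nb_dispersion = 2,
                             clone_fraction = 0.6,
                             tcr_detection_rate = 1,
                             allelic_exclusion_rate = 0.1,
                             planted_effects = c(CXCR4 = -0.8, CD69 = -0.8,
                                                 HSPA1A = -0.8, ZFP36 = -0.8,
                                                 IL7R = -0.8, TXNIP = -0.8),
                             marker_genes = c(cd4 = "CD4", cd8a = "CD8A",
                                              foxp3 = "FOXP3"),
                             progressed_class = NULL,
                             chain_type = c("ab", "gd"),
                             t_cell_frac = 0.7,
                             planted_base_mean = 5,
                             libsize_sdlog = 0.25,
                             gene_names = NULL,
                             seed = 1L) {
  chain_type <- match.arg(chain_type)
  if (n_patients < 1 || cells_per_sample < 1 || n_genes < 1)
    stop("synthetic_config: dimensions must be positive")
  if (!length(samples_per_patient))
    stop("synthetic_config: samples_per_patient must be non-empty")
  bad <- setdiff(samples_per_patient, LESION_CLASSES)
  if (length(bad))
    stop("synthetic_config: unknown lesion class(es): ", paste(bad, collapse = ", "))
  if (any(clone_fraction <= 0 | clone_fraction >= 1))
    stop("synthetic_config: clone_fraction must be in (0, 1)")
  if (!(length(clone_fraction) %in% c(1L, n_patients)))
    stop("synthetic_config: clone_fraction must be scalar or one per patient")
  if (nb_dispersion <= 0) stop("synthetic_config: nb_dispersion must be > 0")
  if (tcr_detection_rate <= 0 || tcr_detection_rate > 1)
    stop("synthetic_config: tcr_detection_rate must be in (0, 1]")
  if (allelic_exclusion_rate < 0 || allelic_exclusion_rate >= 1)
    stop("synthetic_config: allelic_exclusion_rate must be in [0, 1)")
  stopifnot(all(c("cd4", "cd8a", "foxp3") %in% names(marker_genes)))
  if (is.null(progressed_class)) {
    cand <- setdiff(samples_per_patient, c("nonlesional", "healthy"))
    progressed_class <- cand[length(cand)]
  }
  planted <- if (length(planted_effects)) {
    stats::setNames(as.numeric(planted_effects), toupper(names(planted_effects)))
  } else stats::setNames(numeric(0), character(0))
  marker_genes <- stats::setNames(toupper(marker_genes), names(marker_genes))
  # Microenvironment expression programs: gene -> (group, NB mean). These
  # make the bundled ligand-receptor demo pairs scoreable.
  programs <- data.frame(
    gene = c("CXCL12", "CD34", "CD74", "MIF", "SELL", "CCL5", "CCR4"),
    group = c("FB", "FB", "Myeloid", "malignant", "malignant",
              "cytotoxic", "malignant"),
    mean = c(4, 2, 4, 3, 2, 3, 2), stringsAsFactors = FALSE)
  programs <- programs[!(programs$gene %in% names(planted)), , drop = FALSE]
  if (is.null(gene_names)) {
    special <- unique(c(unname(marker_genes), names(planted), programs$gene))
    n_fill <- n_genes - length(special)
    if (n_fill < 0) stop("synthetic_config: n_genes too small for the ",
                         length(special), " marker/planted/program genes")
    gene_names <- c(special, sprintf("G%05d", seq_len(n_fill)))
  } else {
    gene_names <- toupper(gene_names)
    if (length(gene_names) != n_genes)
      stop("synthetic_config: gene_names length must equal n_genes")
    miss <- setdiff(c(unname(marker_genes), names(planted)), gene_names)
    if (length(miss))
      stop("synthetic_config: planted/marker gene(s) not in gene list: ",
           paste(miss, collapse = ", "))
    programs <- programs[programs$gene %in% gene_names, , drop = FALSE]
  }
  structure(list(n_patients = as.integer(n_patients),
                 samples_per_patient = samples_per_patient,
                 cells_per_sample = as.integer(cells_per_sample),
                 n_genes = as.integer(n_genes),
                 nb_mean_log_range = nb_mean_log_range,
                 nb_dispersion = nb_dispersion,
                 clone_fraction = rep(clone_fraction, length.out = n_patients),
                 tcr_detection_rate = tcr_detection_rate,
                 allelic_exclusion_rate = allelic_exclusion_rate,
                 planted_effects = planted,
                 marker_genes = marker_genes,
                 progressed_class = progressed_class,
                 chain_type = chain_type,
                 t_cell_frac = t_cell_frac,
                 planted_base_mean = planted_base_mean,
                 libsize_sdlog = libsize_sdlog,
                 gene_names = gene_names,
                 programs = programs,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic integer split of n into proportions p (largest-remainder-free
# cumulative rounding; sums to n exactly).
split_counts <- function(n, p) {
  cum <- round(cumsum(p) / sum(p) * n)
  diff(c(0L, cum))
}

#' Simulate a paired-lesion single-cell RNA + TCR dataset
#'
#' See [synthetic_config()] for the emulated design. Counts are drawn
#' gene-wise from a negative binomial with per-cell log-normal library-size
#' factors; gating markers are near-binary (high mean in the intended subset,
#' ~0 elsewhere); planted effects multiply the NB mean of the named genes by
#' `exp(lfc)` in dominant-clone cells of the progressed lesion class only.
#' Cell-type and clonality allocations are deterministic (rounded counts),
#' so tiny fixtures are exactly checkable.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `counts` (a `CountMatrix`), `metadata`
#'   (data.frame), `contigs` (data.frame), `truth` (ground-truth list with a
#'   per-cell table and the planted parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  cells <- list()
  for (p in seq_len(cfg$n_patients)) {
    patient <- sprintf("P%02d", p)
    for (cls in cfg$samples_per_patient) {
      sample_id <- paste0(patient, "_", cls)
      n <- cfg$cells_per_sample
      n_t <- round(cfg$t_cell_frac * n)
      n_non <- n - n_t
      non_split <- split_counts(n_non, c(FB = 0.6, Myeloid = 0.4))
      n_tcr <- round(cfg$tcr_detection_rate * n_t)
      n_clone <- round(cfg$clone_fraction[p] * n_tcr)
      n_rest <- n_t - n_clone                     # polyclonal + undetected T
      rest_subsets <- rep(c("helper", "cytotoxic", "regulatory"),
                          length.out = n_rest)
      sub_split <- split_counts(n_rest, c(helper = 0.5, cytotoxic = 0.35,
                                          regulatory = 0.15))
      rest_subsets <- rep(c("helper", "cytotoxic", "regulatory"), sub_split)
      n_poly <- n_tcr - n_clone
      # detection picked round-robin across subsets so detected and
      # undetected polyclonal cells share the same subset composition
      has_tcr_rest <- logical(n_rest)
      if (n_poly > 0 && n_rest > 0) {
        rank_within <- stats::ave(seq_len(n_rest), rest_subsets, FUN = seq_along)
        ord <- order(rank_within, rest_subsets)
        has_tcr_rest[ord[seq_len(n_poly)]] <- TRUE
      }
      df <- data.frame(
        cell_id = sprintf("%s_c%04d", sample_id, seq_len(n)),
        sample_id = sample_id, patient_id = patient, lesion_class = cls,
        cluster = c(rep("TC", n_t), rep(c("FB", "Myeloid"), non_split)),
        subset = c(rep("malignant", n_clone), rest_subsets,
                   rep(c("stromal", "myeloid"), non_split)),
        is_clone = c(rep(TRUE, n_clone), rep(FALSE, n - n_clone)),
        has_tcr = c(rep(TRUE, n_clone), has_tcr_rest, rep(FALSE, n_non)),
        stringsAsFactors = FALSE)
      cells[[length(cells) + 1]] <- df
    }
  }
  cells <- do.call(rbind, cells)
  n_cells <- nrow(cells)

  sf <- stats::rlnorm(n_cells, 0, cfg$libsize_sdlog)
  base_logmu <- stats::runif(cfg$n_genes, cfg$nb_mean_log_range[1],
                             cfg$nb_mean_log_range[2])
  names(base_logmu) <- cfg$gene_names

  marker_of <- c(cfg$marker_genes[["cd4"]], cfg$marker_genes[["cd8a"]],
                 cfg$marker_genes[["foxp3"]])
  marker_groups <- list(c("malignant", "helper", "regulatory"),
                        "cytotoxic", "regulatory")
  progressed_clone <- cells$is_clone & cells$lesion_class == cfg$progressed_class

  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells)
  for (g in seq_len(cfg$n_genes)) {
    gene <- cfg$gene_names[g]
    mu <- rep(exp(base_logmu[g]), n_cells)
    mi <- match(gene, marker_of)
    if (!is.na(mi)) {
      # near-binary: on-target mean 30 keeps NB dropout ~0.4% at theta = 2,
      # off-target 0.001 keeps false positives ~0.1%, so gating is
      # unambiguous in fixtures
      mu <- rep(0.001, n_cells)
      mu[cells$subset %in% marker_groups[[mi]]] <- 30
    }
    pi <- match(gene, cfg$programs$gene)
    if (!is.na(pi)) {
      mu <- rep(0.05, n_cells)
      grp <- cfg$programs$group[pi]
      mu[cells$subset == grp | cells$cluster == grp] <- cfg$programs$mean[pi]
    }
    if (gene %in% names(cfg$planted_effects)) {
      mu <- rep(cfg$planted_base_mean, n_cells)
      mu[progressed_clone] <- mu[progressed_clone] *
        exp(cfg$planted_effects[[gene]])
    }
    counts[g, ] <- stats::rnbinom(n_cells, mu = mu * sf,
                                  size = cfg$nb_dispersion)
  }
  cm <- count_matrix(counts, cfg$gene_names, cells$cell_id)

  contigs <- make_contigs(cells, cfg)
  contigs <- plant_allelic_exclusion(contigs, cfg)

  metadata <- cells[, c("cell_id", "sample_id", "patient_id",
                        "lesion_class", "cluster")]
  rownames(metadata) <- NULL
  truth <- list(cells = cells,
                clone_beta = clone_beta_cdr3(seq_len(cfg$n_patients)),
                planted_effects = as.list(cfg$planted_effects),
                progressed_class = cfg$progressed_class,
                seed = cfg$seed)
  list(counts = cm, metadata = metadata, contigs = contigs, truth = truth)
}

clone_beta_cdr3 <- function(p) paste0("CASSF", aa_encode(p, 4), "PLHF")
clone_alpha_cdr3 <- function(p) paste0("CAG", aa_encode(p, 4), "DKVIF")

# Primary contigs: one beta + one alpha per dominant-clone cell (shared
# within a patient), unique beta + alpha per detected polyclonal cell.
make_contigs <- function(cells, cfg) {
  chains <- if (cfg$chain_type == "ab") c(primary = "TRB", secondary = "TRA")
            else c(primary = "TRD", secondary = "TRG")
  det <- cells[cells$has_tcr, , drop = FALSE]
  pnum <- as.integer(sub("^P", "", det$patient_id))
  is_clone <- det$is_clone
  poly_idx <- which(!is_clone)
  beta <- character(nrow(det)); alpha <- character(nrow(det))
  beta[is_clone] <- clone_beta_cdr3(pnum[is_clone])
  alpha[is_clone] <- clone_alpha_cdr3(pnum[is_clone])
  beta[poly_idx] <- paste0("CASS", aa_encode(seq_along(poly_idx)), "TQYF")
  alpha[poly_idx] <- paste0("CAV", aa_encode(seq_along(poly_idx)), "KLVF")
  umis_b <- 1L + stats::rpois(nrow(det), ifelse(is_clone, 15, 5))
  umis_a <- 1L + stats::rpois(nrow(det), ifelse(is_clone, 10, 4))
  data.frame(cell_id = rep(det$cell_id, 2),
             chain = rep(c(chains[["primary"]], chains[["secondary"]]),
                         each = nrow(det)),
             cdr3_aa = c(beta, alpha),
             productive = TRUE,
             umis = c(umis_b, umis_a),
             stringsAsFactors = FALSE)
}

#' Plant incomplete allelic exclusion in a contig table
#'
#' Adds a secondary alpha (gamma) CDR3 — distinct from the primary, derived
#' deterministically from the clone's beta chain — to a fraction
#' `allelic_exclusion_rate` of dominant-clone cells, where the dominant clone
#' is the most common primary-chain CDR3 in the table. All clone cells keep
#' sharing the one beta CDR3, which is what lets the clonotyper merge the two
#' alpha variants into a single clone. Selection is deterministic (first
#' `round(rate * n)` clone cells per sample in table order).
#'
#' @param contigs a contig data.frame (as produced internally or by
#'   [read_contigs()]).
#' @param config a [synthetic_config()] (fields `allelic_exclusion_rate`,
#'   `chain_type` are used).
#' @return the augmented contig data.frame.
#' @export
plant_allelic_exclusion <- function(contigs, config) {
  rate <- config$allelic_exclusion_rate
  if (rate >= 1) stop("plant_allelic_exclusion: rate must be < 1")
  if (rate <= 0) return(contigs)
  primary_chain <- if (config$chain_type == "ab") "TRB" else "TRD"
  secondary_chain <- if (config$chain_type == "ab") "TRA" else "TRG"
  prim <- contigs[contigs$chain == primary_chain, , drop = FALSE]
  if (!nrow(prim)) stop("plant_allelic_exclusion: no primary-chain contigs")
  # expanded clones are the betas shared by >= 2 cells (polyclonal betas are
  # unique per cell in this generator's world); fall back to the single most
  # common beta for degenerate tables
  tab <- table(prim$cdr3_aa)
  clone_betas <- names(tab)[tab >= 2]
  if (!length(clone_betas)) clone_betas <- names(tab)[which.max(tab)]
  extra <- list()
  for (b in clone_betas) {
    members <- unique(prim$cell_id[prim$cdr3_aa == b])
    k <- round(rate * length(members))
    if (!k) next
    chosen <- members[seq_len(k)]
    extra[[b]] <- data.frame(cell_id = chosen, chain = secondary_chain,
                             cdr3_aa = paste0("CAVS", substring(b, 6)),
                             productive = TRUE, umis = 3L,
                             stringsAsFactors = FALSE)
  }
  out <- rbind(contigs, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the MatrixMarket triplets, metadata CSV, contig CSV and a
#' ground-truth JSON under `dir`. Byte-identical for identical configs.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_counts(sim$counts, dir)
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(sim$metadata, meta_path, row.names = FALSE, quote = FALSE)
  contig_path <- file.path(dir, "contigs.csv")
  write_contigs(sim$contigs, contig_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, digits = 10, dataframe = "columns")
  invisible(c(mtx = paths[1], features = paths[2], barcodes = paths[3],
              metadata = meta_path, contigs = contig_path, truth = truth_path))
}
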