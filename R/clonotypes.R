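#' Group cells into clonotypes from CDR3 amino-acid sequences
#'
#' The beta chain (delta for gamma/delta data) is the clonotype primary key:
#' cells sharing any beta CDR3 are merged transitively into one clonotype.
#' Alpha (gamma) chains are secondary and accumulate on the clonotype, which
#' is how two alpha variants arising from incomplete allelic exclusion — two
#' rearranged alpha chains paired with one beta chain — end up in a single
#' clone. A cell carrying only alpha chains joins the unique beta-defined
#' clonotype whose accumulated alpha set contains all of the cell's alpha
#' CDR3s; if several such clonotypes exist the cell is left unassigned (and
#' logged), and if none exists the cell founds a new clonotype, merging
#' transitively with other alpha-only cells that share an alpha CDR3. Cells
#' with more than two distinct beta CDR3s are treated as putative doublets
#' and excluded (reported, assigned `no_tcr` downstream).
#'
#' @param contigs a productive-filtered contig data.frame as returned by
#'   [read_contigs()] (columns `cell_id`, `chain`, `cdr3_aa`, `umis`).
#' @return an object of class `clonotype_set`: a list with
#'   \describe{
#'     \item{clones}{data.frame `clone_id`, `size`, `beta_cdr3s`,
#'       `alpha_cdr3s` (`;`-collapsed, sorted), `umis` (total)}
#'     \item{cells}{data.frame `cell_id`, `clone_id`}
#'     \item{doublets}{cell_ids excluded for >2 beta chains}
#'     \item{unassigned}{alpha-only cell_ids matching >=2 beta clonotypes}
#'   }
#' @export
group_clonotypes <- function(contigs) {
  stopifnot(all(c("cell_id", "chain", "cdr3_aa", "umis") %in% names(contigs)))
  primary <- contigs$chain %in% c("TRB", "TRD")
  cells <- unique(contigs$cell_id)

  beta_by_cell <- split(contigs$cdr3_aa[primary], contigs$cell_id[primary])
  beta_by_cell <- lapply(beta_by_cell, unique)
  doublets <- names(beta_by_cell)[vapply(beta_by_cell, length, 1L) > 2]
  if (length(doublets))
    message("group_clonotypes: excluding ", length(doublets),
            " putative doublet cell(s) with >2 beta/delta chains")
  keep <- !(contigs$cell_id %in% doublets)
  contigs <- contigs[keep, , drop = FALSE]
  cells <- setdiff(cells, doublets)
  primary <- contigs$chain %in% c("TRB", "TRD")

  alpha_by_cell <- split(contigs$cdr3_aa[!primary], contigs$cell_id[!primary])
  alpha_by_cell <- lapply(alpha_by_cell, unique)
  beta_by_cell <- split(contigs$cdr3_aa[primary], contigs$cell_id[primary])
  beta_by_cell <- lapply(beta_by_cell, unique)

  has_beta <- cells %in% names(beta_by_cell)
  beta_cells <- cells[has_beta]
  alpha_only <- cells[!has_beta]

  # Union-find over beta-bearing cells keyed by shared beta CDR3s.
  parent <- seq_along(beta_cells)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(beta_cells)) {
    for (b in beta_by_cell[[beta_cells[i]]]) {
      j <- seen[[b]]
      if (is.null(j)) assign(b, i, envir = seen) else union2(i, j)
    }
  }
  comp <- if (length(beta_cells)) vapply(seq_along(beta_cells), find, 1L) else integer(0)
  comp <- match(comp, unique(comp))
  n_beta_clones <- length(unique(comp))

  clone_of <- integer(length(cells))
  names(clone_of) <- cells
  clone_of[beta_cells] <- comp

  # Accumulated alpha set per beta clonotype.
  clone_alphas <- vector("list", n_beta_clones)
  for (i in seq_along(beta_cells)) {
    a <- alpha_by_cell[[beta_cells[i]]]
    if (!is.null(a))
      clone_alphas[[comp[i]]] <- union(clone_alphas[[comp[i]]], a)
  }

  unassigned <- character(0)
  pending <- character(0)                 # alpha-only cells founding new clones
  for (cl in alpha_only) {
    a <- alpha_by_cell[[cl]]
    hits <- which(vapply(clone_alphas, function(s) all(a %in% s), TRUE))
    if (length(hits) == 1) {
      clone_of[cl] <- hits
    } else if (length(hits) >= 2) {
      message("group_clonotypes: alpha-only cell ", cl,
              " matches ", length(hits), " beta-defined clonotypes; left unassigned")
      unassigned <- c(unassigned, cl)
      clone_of[cl] <- NA_integer_
    } else {
      pending <- c(pending, cl)
    }
  }

  # Transitive grouping of unattached alpha-only cells by shared alpha CDR3.
  if (length(pending)) {
    parent <- seq_along(pending)
    seen <- new.env(parent = emptyenv())
    for (i in seq_along(pending)) {
      for (a in alpha_by_cell[[pending[i]]]) {
        j <- seen[[a]]
        if (is.null(j)) assign(a, i, envir = seen) else union2(i, j)
      }
    }
    pcomp <- vapply(seq_along(pending), find, 1L)
    pcomp <- match(pcomp, unique(pcomp))
    clone_of[pending] <- n_beta_clones + pcomp
  }

  assigned <- !is.na(clone_of) & clone_of > 0
  cell_tab <- data.frame(cell_id = cells[assigned],
                         clone_idx = clone_of[assigned],
                         stringsAsFactors = FALSE)

  umis_by_cell <- tapply(contigs$umis, contigs$cell_id, sum)
  n_clones <- max(c(0L, cell_tab$clone_idx))
  rows <- lapply(seq_len(n_clones), function(k) {
    members <- cell_tab$cell_id[cell_tab$clone_idx == k]
    betas <- sort(unique(unlist(beta_by_cell[members], use.names = FALSE)))
    alphas <- sort(unique(unlist(alpha_by_cell[members], use.names = FALSE)))
    data.frame(clone_idx = k, size = length(members),
               beta_cdr3s = paste(betas, collapse = ";"),
               alpha_cdr3s = paste(alphas, collapse = ";"),
               umis = sum(umis_by_cell[members]),
               key = if (length(betas)) betas[1] else alphas[1],
               stringsAsFactors = FALSE)
  })
  clones <- do.call(rbind, rows)
  if (is.null(clones))
    clones <- data.frame(clone_idx = integer(0), size = integer(0),
                         beta_cdr3s = character(0), alpha_cdr3s = character(0),
                         umis = numeric(0), key = character(0))
  # Stable, content-derived clone ids: ordered by size desc, umis desc, key.
  ord <- order(-clones$size, -clones$umis, clones$key)
  clones <- clones[ord, , drop = FALSE]
  clones$clone_id <- sprintf("clone_%04d", seq_len(nrow(clones)))
  cell_tab$clone_id <- clones$clone_id[match(cell_tab$clone_idx, clones$clone_idx)]
  clones <- clones[, c("clone_id", "size", "beta_cdr3s", "alpha_cdr3s", "umis")]
  rownames(clones) <- NULL
  structure(list(clones = clones,
                 cells = cell_tab[, c("cell_id", "clone_id")],
                 doublets = doublets, unassigned = unassigned),
            class = "clonotype_set")
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat(sprintf("clonotype_set: %d clonotypes over %d cells (%d doublets, %d unassigned)\n",
              nrow(x$clones), nrow(x$cells), length(x$doublets), length(x$unassigned)))
  invisible(x)
}

#' Identify the dominant (top expanded) clone and its per-sample fraction
#'
#' The dominant clone is the clonotype with the most member cells within the
#' scope — per patient by default, pooling that patient's samples, which is
#' the natural reading of "top expanded clone within each patient"; per-sample
#' scope serves healthy-control baselines. Ties are broken by total UMI count,
#' then by lexicographically smallest beta CDR3, so results are reproducible.
#' Fractions are always reported per sample, among that sample's TCR+
#' (clonotype-assigned) cells.
#'
#' @param ct a `clonotype_set`.
#' @param metadata cell metadata data.frame (see [read_metadata()]).
#' @param scope `"patient"` (default) or `"sample"`.
#' @return data.frame with columns `patient_id`, `sample_id`, `clone_id`,
#'   `n_clone_cells`, `n_tcr_cells`, `fraction` (one row per sample with at
#'   least one TCR+ cell; empty with a warning if there are none).
#' @export
dominant_clone <- function(ct, metadata, scope = c("patient", "sample")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ct, "clonotype_set"))
  cells <- merge(ct$cells, metadata, by = "cell_id")
  empty <- data.frame(patient_id = character(0), sample_id = character(0),
                      clone_id = character(0), n_clone_cells = integer(0),
                      n_tcr_cells = integer(0), fraction = numeric(0))
  if (!nrow(cells)) {
    warning("dominant_clone: no TCR+ cells in metadata scope")
    return(empty)
  }
  key <- if (scope == "patient") cells$patient_id else cells$sample_id
  out <- list()
  for (g in unique(key)) {
    sub <- cells[key == g, , drop = FALSE]
    sz <- table(sub$clone_id)
    top_n <- max(sz)
    cand <- names(sz)[sz == top_n]
    if (length(cand) > 1) {
      ci <- match(cand, ct$clones$clone_id)
      um <- ct$clones$umis[ci]
      cand <- cand[um == max(um)]
      if (length(cand) > 1) {
        bk <- vapply(strsplit(ct$clones$beta_cdr3s[match(cand, ct$clones$clone_id)], ";"),
                     function(b) if (length(b) && nzchar(b[1])) b[1] else "~", "")
        cand <- cand[order(bk)][1]
      }
    }
    dom <- cand[1]
    for (s in unique(sub$sample_id)) {
      ss <- sub[sub$sample_id == s, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        patient_id = ss$patient_id[1], sample_id = s, clone_id = dom,
        n_clone_cells = sum(ss$clone_id == dom), n_tcr_cells = nrow(ss),
        fraction = sum(ss$clone_id == dom) / nrow(ss),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$patient_id, res$sample_id), , drop = FALSE]
}

#' Label every cell's clonality
#'
#' Partitions all cells of the metadata table into `dominant` (member of the
#' patient's dominant clone), `polyclonal` (any other clonotype-assigned
#' cell) and `no_tcr` (no productive contig, putative doublet, or
#' unassignable). The partition is exhaustive and disjoint. Cells present in
#' contigs but absent from metadata are skipped with a warning.
#'
#' @param ct a `clonotype_set`.
#' @param dom output of [dominant_clone()].
#' @param metadata cell metadata data.frame.
#' @return data.frame `cell_id`, `clonality`, `clone_id` (NA for `no_tcr`),
#'   `subset` (NA until [gate_subsets()]), in metadata order.
#' @export
assign_clonality <- function(ct, dom, metadata) {
  stopifnot(inherits(ct, "clonotype_set"))
  orphan <- setdiff(ct$cells$cell_id, metadata$cell_id)
  if (length(orphan))
    warning("assign_clonality: ", length(orphan),
            " clonotyped cell(s) absent from metadata; skipped")
  clone_id <- ct$cells$clone_id[match(metadata$cell_id, ct$cells$cell_id)]
  dom_of_cell <- dom$clone_id[match(metadata$sample_id, dom$sample_id)]
  clonality <- ifelse(is.na(clone_id), "no_tcr",
                      ifelse(!is.na(dom_of_cell) & clone_id == dom_of_cell,
                             "dominant", "polyclonal"))
  data.frame(cell_id = metadata$cell_id, clonality = clonality,
             clone_id = ifelse(clonality == "no_tcr", NA_character_, clone_id),
             subset = NA_character_, stringsAsFactors = FALSE)
}

#' Per-sample sharing of alpha CDR3 variants within the dominant clone
#'
#' For tracking incomplete allelic exclusion over time: among dominant-clone
#' cells carrying at least one alpha (gamma) chain, reports the fraction
#' carrying each alpha CDR3 variant, per sample.
#'
#' @param ct a `clonotype_set`.
#' @param dom output of [dominant_clone()].
#' @param contigs productive contig data.frame.
#' @param metadata cell metadata data.frame.
#' @return data.frame `patient_id`, `sample_id`, `alpha_cdr3`, `n_cells`,
#'   `share`.
#' @export
alpha_share <- function(ct, dom, contigs, metadata) {
  res <- list()
  alpha <- contigs[contigs$chain %in% c("TRA", "TRG"), , drop = FALSE]
  for (i in seq_len(nrow(dom))) {
    members <- ct$cells$cell_id[ct$cells$clone_id == dom$clone_id[i]]
    members <- intersect(members,
                         metadata$cell_id[metadata$sample_id == dom$sample_id[i]])
    sub <- alpha[alpha$cell_id %in% members, , drop = FALSE]
    n_bearing <- length(unique(sub$cell_id))
    if (!n_bearing) next
    tab <- tapply(sub$cell_id, sub$cdr3_aa, function(x) length(unique(x)))
    res[[length(res) + 1]] <- data.frame(
      patient_id = dom$patient_id[i], sample_id = dom$sample_id[i],
      alpha_cdr3 = names(tab), n_cells = as.integer(tab),
      share = as.numeric(tab) / n_bearing, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), sample_id = character(0),
                      alpha_cdr3 = character(0), n_cells = integer(0),
                      share = numeric(0))
  rownames(out) <- NULL
  out
}
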