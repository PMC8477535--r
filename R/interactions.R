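#' Interaction score for one ligand-receptor pair between two clusters
#'
#' `I_R(X, Y)` is the arithmetic mean of the ligand's mean normalized
#' expression over all cells of cluster X and the receptor's mean over all
#' cells of cluster Y. A pair is evaluated only when the ligand is detected
#' (count > 0) in at least `min_frac` of X cells and the receptor in at least
#' `min_frac` of Y cells.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param clusters named character vector of cluster labels (names are cell
#'   ids) or a vector aligned with `cm$cells`.
#' @param pair one-row data.frame with `ligand_gene`, `receptor_gene` (and
#'   optionally `pair_id`).
#' @param X,Y cluster labels for the ligand- and receptor-expressing side.
#' @param min_frac detection-fraction filter (default 0.1).
#' @return list with `score` (NA when not evaluated) and `evaluated`.
#' @export
interaction_score <- function(cm, clusters, pair, X, Y, min_frac = 0.1) {
  norm <- norm_view(cm)
  clusters <- align_clusters(cm, clusters)
  lg <- toupper(pair$ligand_gene); rg <- toupper(pair$receptor_gene)
  miss <- setdiff(c(lg, rg), cm$genes)
  if (length(miss))
    stop("interaction_score: gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  xi <- which(clusters == X); yi <- which(clusters == Y)
  if (!length(xi) || !length(yi))
    stop("interaction_score: empty cluster ", if (!length(xi)) X else Y)
  lv <- as.numeric(norm[lg, ]); rv <- as.numeric(norm[rg, ])
  evaluated <- mean(lv[xi] > 0) >= min_frac && mean(rv[yi] > 0) >= min_frac
  score <- (mean(lv[xi]) + mean(rv[yi])) / 2
  list(score = if (evaluated) score else NA_real_, evaluated = evaluated,
       raw_score = score)
}

align_clusters <- function(cm, clusters) {
  if (!is.null(names(clusters))) {
    cl <- clusters[cm$cells]
    if (any(is.na(cl))) stop("clusters: missing label for some cells")
    return(unname(cl))
  }
  if (length(clusters) != length(cm$cells))
    stop("clusters: length must match number of cells")
  clusters
}

#' Permutation test for an interaction score
#'
#' Shuffles cluster labels over all cells `n_perm` times (cluster sizes
#' preserved) and reports the add-one empirical p-value
#' `(1 + #\{permuted >= observed\}) / (1 + n_perm)`, which can never be
#' exactly zero. Deterministic given `seed`.
#'
#' @inheritParams interaction_score
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `score`, `p_emp`, `evaluated`.
#' @export
permutation_test <- function(cm, clusters, pair, X, Y, n_perm = 1000L,
                             seed = 1L, min_frac = 0.1) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("permutation_test: n_perm must be >= 1")
  obs <- interaction_score(cm, clusters, pair, X, Y, min_frac)
  if (!obs$evaluated)
    return(list(score = NA_real_, p_emp = NA_real_, evaluated = FALSE))
  norm <- norm_view(cm)
  clusters <- align_clusters(cm, clusters)
  lv <- as.numeric(norm[toupper(pair$ligand_gene), ])
  rv <- as.numeric(norm[toupper(pair$receptor_gene), ])
  xi <- clusters == X; yi <- clusters == Y
  n <- length(clusters)
  set.seed(as.integer(seed))
  hits <- 0L
  for (m in seq_len(n_perm)) {
    perm <- sample.int(n)
    s <- (mean(lv[perm[xi]]) + mean(rv[perm[yi]])) / 2
    if (s >= obs$score) hits <- hits + 1L
  }
  list(score = obs$score, p_emp = (1 + hits) / (1 + n_perm), evaluated = TRUE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values of the same length (empty input gives empty output).
#' @export
fdr_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Score all ligand-receptor pairs between a cluster and its partners
#'
#' Computes `I_R(X, Y)` with a shared set of label permutations for every
#' (pair, Y) combination within one sample, then BH-adjusts the empirical
#' p-values across all evaluated combinations of that sample.
#'
#' @param cm a log-normalized `CountMatrix` restricted to one sample's cells.
#' @param clusters cluster labels (see [interaction_score()]).
#' @param pairs data.frame from [read_pairs()].
#' @param X ligand-side cluster label (e.g. the malignant clone).
#' @param Ys receptor-side cluster labels (default: all other clusters).
#' @param n_perm,seed,min_frac as in [permutation_test()].
#' @param sample_id label copied into the output.
#' @return data.frame `pair_id`, `cluster_x`, `cluster_y`, `score`, `p_emp`,
#'   `q_fdr`, `sample_id` (non-evaluated combinations have NA score/p/q).
#' @export
score_interactions <- function(cm, clusters, pairs, X,
                               Ys = NULL, n_perm = 1000L, seed = 1L,
                               min_frac = 0.1, sample_id = NA_character_) {
  clusters <- align_clusters(cm, clusters)
  if (is.null(Ys)) Ys <- setdiff(sort(unique(clusters)), X)
  norm <- norm_view(cm)
  n <- length(clusters)
  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  grid <- expand.grid(pi = seq_len(nrow(pairs)), Y = Ys,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pr <- pairs[grid$pi[k], , drop = FALSE]
    Y <- grid$Y[k]
    obs <- interaction_score(cm, clusters, pr, X, Y, min_frac)
    if (!obs$evaluated)
      return(data.frame(pair_id = pr$pair_id, cluster_x = X, cluster_y = Y,
                        score = NA_real_, p_emp = NA_real_,
                        stringsAsFactors = FALSE))
    lv <- as.numeric(norm[toupper(pr$ligand_gene), ])
    rv <- as.numeric(norm[toupper(pr$receptor_gene), ])
    xi <- clusters == X; yi <- clusters == Y
    hits <- 0L
    for (perm in perms) {
      s <- (mean(lv[perm[xi]]) + mean(rv[perm[yi]])) / 2
      if (s >= obs$score) hits <- hits + 1L
    }
    data.frame(pair_id = pr$pair_id, cluster_x = X, cluster_y = Y,
               score = obs$score, p_emp = (1 + hits) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- NA_real_
  ev <- !is.na(out$p_emp)
  if (any(ev)) out$q_fdr[ev] <- fdr_bh(out$p_emp[ev])
  out$sample_id <- sample_id
  rownames(out) <- NULL
  out
}

#' Between-lesion interaction-score deltas
#'
#' For each patient, `delta = score(palpable sample) - score(patch sample)`
#' for every (pair, cluster) combination significant (q <= `q_max`) in at
#' least one of the two samples and evaluated in both.
#'
#' @param scores data.frame row-binding [score_interactions()] results for
#'   the involved samples.
#' @param pairing data.frame `patient_id`, `sample_palpable`, `sample_patch`.
#' @param q_max significance cutoff (default 0.05).
#' @return data.frame `patient_id`, `pair_id`, `cluster_x`, `cluster_y`,
#'   `score_palpable`, `score_patch`, `delta`.
#' @export
interaction_deltas <- function(scores, pairing, q_max = 0.05) {
  need <- c("patient_id", "sample_palpable", "sample_patch")
  if (!all(need %in% names(pairing)))
    stop("interaction_deltas: pairing needs columns ",
         paste(need, collapse = ", "))
  miss <- setdiff(c(pairing$sample_palpable, pairing$sample_patch),
                  scores$sample_id)
  if (length(miss))
    stop("interaction_deltas: no scores for sample(s): ",
         paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(pairing))) {
    a <- scores[scores$sample_id == pairing$sample_palpable[i], , drop = FALSE]
    b <- scores[scores$sample_id == pairing$sample_patch[i], , drop = FALSE]
    m <- merge(a, b, by = c("pair_id", "cluster_x", "cluster_y"),
               suffixes = c("_palpable", "_patch"))
    keep <- !is.na(m$score_palpable) & !is.na(m$score_patch) &
      ((!is.na(m$q_fdr_palpable) & m$q_fdr_palpable <= q_max) |
         (!is.na(m$q_fdr_patch) & m$q_fdr_patch <= q_max))
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) next
    out[[i]] <- data.frame(patient_id = pairing$patient_id[i],
                           pair_id = m$pair_id, cluster_x = m$cluster_x,
                           cluster_y = m$cluster_y,
                           score_palpable = m$score_palpable,
                           score_patch = m$score_patch,
                           delta = m$score_palpable - m$score_patch,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(patient_id = character(0), pair_id = character(0),
                      cluster_x = character(0), cluster_y = character(0),
                      score_palpable = numeric(0), score_patch = numeric(0),
                      delta = numeric(0))
  rownames(res) <- NULL
  res
}
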