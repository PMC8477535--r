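#' Differential-expression thresholds
#'
#' The study convention: a gene is differentially expressed when its
#' Bonferroni-adjusted p-value is below `alpha` and its absolute log fold
#' change exceeds `min_abs_logfc` — 0.3 for malignant-clone comparisons and
#' 0.25 for cluster/microenvironment comparisons. `min_pct` restricts testing
#' to genes detected in at least that fraction of cells in one of the groups.
#'
#' @param min_abs_logfc non-negative log-fold-change threshold.
#' @param alpha significance level for the adjusted p-value.
#' @param min_pct minimum detection fraction in the better-detected group.
#' @return a `de_thresholds` list.
#' @export
de_thresholds <- function(min_abs_logfc = 0.3, alpha = 0.05, min_pct = 0.1) {
  stopifnot(is.numeric(min_abs_logfc), min_abs_logfc >= 0,
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(min_pct), min_pct >= 0, min_pct <= 1)
  structure(list(min_abs_logfc = min_abs_logfc, alpha = alpha,
                 min_pct = min_pct), class = "de_thresholds")
}

# Internal: logistic IRLS fit of labels ~ intercept + expr, returning the
# residual deviance. Probabilities are clamped to [1e-10, 1 - 1e-10] so that
# perfect separation (common for marker genes) stays finite.
logistic_deviance <- function(x, y, max_iter = 100L, tol = 1e-12) {
  n <- length(y)
  phat <- mean(y)
  beta0 <- log(phat / (1 - phat))
  beta1 <- 0
  dev_old <- Inf
  clamp <- function(p) pmin(pmax(p, 1e-10), 1 - 1e-10)
  for (iter in seq_len(max_iter)) {
    eta <- beta0 + beta1 * x
    mu <- clamp(1 / (1 + exp(-eta)))
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x * x)
    swz <- sum(w * z); swxz <- sum(w * x * z)
    det <- sw * swx2 - swx * swx
    if (!is.finite(det) || abs(det) < 1e-300) break
    beta0 <- (swx2 * swz - swx * swxz) / det
    beta1 <- (sw * swxz - swx * swz) / det
  }
  eta <- beta0 + beta1 * x
  mu <- clamp(1 / (1 + exp(-eta)))
  -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
}

#' Logistic-regression likelihood-ratio test for one gene
#'
#' Tests association between expression and a binary group label by comparing
#' the logistic model `logit P(label) = b0 + b1 * expr` against the
#' intercept-only model with a 1-df chi-squared likelihood-ratio test. Fitted
#' by iteratively reweighted least squares (max 100 iterations, fitted
#' probabilities clamped to `[1e-10, 1 - 1e-10]`); p-values floor at 1e-300.
#' Constant expression carries no information and returns p = 1.
#'
#' @param expr numeric vector of (normalized) expression values.
#' @param labels binary vector (0/1, logical, or two-level factor) of the
#'   same length; both classes must be present.
#' @return the likelihood-ratio p-value.
#' @export
lr_test <- function(expr, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  if (length(expr) != length(labels))
    stop("lr_test: expr and labels lengths differ")
  if (!all(labels %in% c(0, 1)))
    stop("lr_test: labels must be binary")
  if (length(unique(labels)) < 2)
    stop("lr_test: both classes must be present")
  if (any(!is.finite(expr))) stop("lr_test: expr must be finite")
  if (max(expr) == min(expr)) return(1)
  n <- length(labels)
  k <- sum(labels)
  phat <- k / n
  dev0 <- -2 * (k * log(phat) + (n - k) * log(1 - phat))
  dev1 <- logistic_deviance(expr, labels)
  stat <- max(dev0 - dev1, 0)
  max(stats::pchisq(stat, df = 1, lower.tail = FALSE), 1e-300)
}

#' Per-gene log fold change between two cell groups
#'
#' `logfc[g] = ln(mean_a(expm1(norm)) + pseudo) - ln(mean_b(expm1(norm)) + pseudo)`,
#' i.e. the natural log of pseudocounted mean de-logged normalized expression
#' — the convention under which the 0.3 / 0.25 thresholds are interpreted.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param cells_a,cells_b non-empty, disjoint character vectors of cell ids.
#' @param pseudo pseudocount (default 1).
#' @return named numeric vector of per-gene log fold changes (a minus b).
#' @export
log_fold_change <- function(cm, cells_a, cells_b, pseudo = 1) {
  norm <- norm_view(cm)
  if (!length(cells_a) || !length(cells_b))
    stop("log_fold_change: both groups must be non-empty")
  ea <- expm1_means(norm, cells_a)
  eb <- expm1_means(norm, cells_b)
  log(ea + pseudo) - log(eb + pseudo)
}

# Row means of expm1(norm) over a cell subset; expm1(0) = 0 keeps sparsity.
expm1_means <- function(norm, cells) {
  sub <- norm[, cells, drop = FALSE]
  sub@x <- expm1(sub@x)
  Matrix::rowMeans(sub)
}

#' Differential expression between two cell groups
#'
#' Genes detected (count > 0) in at least `min_pct` of cells in one group are
#' tested with [lr_test()]; p-values are Bonferroni-adjusted by the number of
#' genes tested (capped at 1). With `significant_only = TRUE` (default) only
#' genes passing `p_adj < alpha` and `|logfc| > min_abs_logfc` are returned,
#' sorted by `p_adj` then by `|logfc|` descending.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param cells_a,cells_b disjoint, non-empty character vectors of cell ids.
#' @param thresholds a [de_thresholds()].
#' @param significant_only return only significant genes (default) or the
#'   full tested table.
#' @return data.frame `gene`, `logfc`, `p`, `p_adj`, `pct_a`, `pct_b`,
#'   `direction`.
#' @export
de_genes <- function(cm, cells_a, cells_b, thresholds = de_thresholds(),
                     significant_only = TRUE) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  norm <- norm_view(cm)
  cells_a <- intersect(cells_a, cm$cells)
  cells_b <- intersect(cells_b, cm$cells)
  if (!length(cells_a) || !length(cells_b))
    stop("de_genes: both groups must be non-empty")
  if (length(intersect(cells_a, cells_b)))
    stop("de_genes: groups must be disjoint")
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  pct_a <- Matrix::rowSums(a > 0) / length(cells_a)
  pct_b <- Matrix::rowSums(b > 0) / length(cells_b)
  test_idx <- which(pmax(pct_a, pct_b) >= thresholds$min_pct)
  n_tested <- length(test_idx)
  if (!n_tested) {
    out <- data.frame(gene = character(0), logfc = numeric(0), p = numeric(0),
                      p_adj = numeric(0), pct_a = numeric(0), pct_b = numeric(0),
                      direction = character(0))
    return(out)
  }
  labels <- c(rep(1, length(cells_a)), rep(0, length(cells_b)))
  abt <- methods::as(Matrix::t(cbind(a, b)), "CsparseMatrix")  # cells x genes
  p <- vapply(test_idx, function(g)
    lr_test(as.numeric(abt[, g, drop = TRUE]), labels), 0)
  lfc <- log_fold_change(cm, cells_a, cells_b)[test_idx]
  out <- data.frame(gene = cm$genes[test_idx], logfc = as.numeric(lfc), p = p,
                    p_adj = pmin(p * n_tested, 1),
                    pct_a = pct_a[test_idx], pct_b = pct_b[test_idx],
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  if (significant_only)
    out <- out[out$p_adj < thresholds$alpha &
                 abs(out$logfc) > thresholds$min_abs_logfc, , drop = FALSE]
  out <- out[order(out$p_adj, -abs(out$logfc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate benign T-cell subsets by canonical markers
#'
#' Dominant-clone cells are labelled `malignant` regardless of marker
#' expression. Among polyclonal TCR+ cells, gating follows the study's
#' definitions with regulatory taking precedence: FOXP3+ cells are
#' `regulatory`; else CD8A+ FOXP3- cells are `cytotoxic`; else CD4+ FOXP3-
#' cells are `helper`; the remainder (and all `no_tcr` cells) are `other`.
#' "Positive" means normalized expression > 0.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param assignments output of [assign_clonality()].
#' @param markers named character vector giving the CD4, CD8A and FOXP3
#'   analogue gene symbols (names `cd4`, `cd8a`, `foxp3`).
#' @return `assignments` with the `subset` column filled.
#' @export
gate_subsets <- function(cm, assignments,
                         markers = c(cd4 = "CD4", cd8a = "CD8A", foxp3 = "FOXP3")) {
  norm <- norm_view(cm)
  stopifnot(all(c("cd4", "cd8a", "foxp3") %in% names(markers)))
  miss <- setdiff(toupper(unname(markers)), cm$genes)
  if (length(miss))
    stop("gate_subsets: gating gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  idx <- match(assignments$cell_id, cm$cells)
  pos <- function(g) as.numeric(norm[toupper(markers[[g]]), ])[idx] > 0
  cd4 <- pos("cd4"); cd8a <- pos("cd8a"); foxp3 <- pos("foxp3")
  subset <- rep("other", nrow(assignments))
  poly <- assignments$clonality == "polyclonal" & !is.na(idx)
  subset[poly & foxp3] <- "regulatory"
  subset[poly & !foxp3 & cd8a] <- "cytotoxic"
  subset[poly & !foxp3 & !cd8a & cd4] <- "helper"
  subset[assignments$clonality == "dominant"] <- "malignant"
  assignments$subset <- subset
  assignments
}

#' DEG counts per cluster between two lesion-class conditions
#'
#' Applies [de_genes()] within each cluster, comparing cells of
#' `classes_a` vs `classes_b` (lesion-class label vectors; e.g.
#' `c("plaque","tumor")` vs `"patch"`). Clusters lacking cells in either
#' condition are reported as absent (NA), not zero.
#'
#' @param cm a log-normalized `CountMatrix`.
#' @param metadata cell metadata data.frame.
#' @param classes_a,classes_b character vectors of lesion-class labels.
#' @param thresholds a [de_thresholds()] (the 0.25 microenvironment default
#'   is appropriate here).
#' @return data.frame `cluster`, `n_deg` (NA when not evaluable).
#' @export
deg_count_per_cluster <- function(cm, metadata, classes_a, classes_b,
                                  thresholds = de_thresholds(min_abs_logfc = 0.25)) {
  clusters <- sort(unique(metadata$cluster))
  n <- vapply(clusters, function(cl) {
    md <- metadata[metadata$cluster == cl, , drop = FALSE]
    ca <- intersect(md$cell_id[md$lesion_class %in% classes_a], cm$cells)
    cb <- intersect(md$cell_id[md$lesion_class %in% classes_b], cm$cells)
    if (!length(ca) || !length(cb)) return(NA_integer_)
    nrow(de_genes(cm, ca, cb, thresholds))
  }, 1L)
  data.frame(cluster = clusters, n_deg = n, stringsAsFactors = FALSE,
             row.names = NULL)
}
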