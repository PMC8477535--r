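# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (adjacency matrices, exhaustive enumeration, stats::glm)
# and share no code with the implementation they check.

# Brute-force clonotype partition: transitive closure over the relation
# "shares a beta/delta CDR3"; alpha-only cells then attach to the unique
# closed group whose alpha union contains all their alphas (unassigned if
# several match), and remaining alpha-only cells close transitively over
# shared alphas. Cells with > 2 distinct betas are doublets and dropped.
oracle_clonotypes <- function(contigs) {
  cells <- unique(contigs$cell_id)
  beta <- lapply(cells, function(cl)
    unique(contigs$cdr3_aa[contigs$cell_id == cl &
                             contigs$chain %in% c("TRB", "TRD")]))
  alpha <- lapply(cells, function(cl)
    unique(contigs$cdr3_aa[contigs$cell_id == cl &
                             contigs$chain %in% c("TRA", "TRG")]))
  names(beta) <- names(alpha) <- cells
  doublets <- cells[vapply(beta, length, 1L) > 2]
  cells <- setdiff(cells, doublets)
  bcells <- cells[vapply(beta[cells], length, 1L) > 0]
  acells <- setdiff(cells, bcells)

  closure_groups <- function(ids, feat) {
    n <- length(ids)
    if (!n) return(list())
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- i == j || length(intersect(feat[[ids[i]]], feat[[ids[j]]])) > 0
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    unique(lapply(seq_len(n), function(i) sort(ids[adj[i, ]])))
  }

  groups <- closure_groups(bcells, beta)
  group_alpha <- lapply(groups, function(g)
    unique(unlist(alpha[g], use.names = FALSE)))
  unassigned <- character(0)
  pending <- character(0)
  for (cl in acells) {
    a <- alpha[[cl]]
    hit <- which(vapply(group_alpha, function(s) all(a %in% s), TRUE))
    if (length(hit) == 1) {
      groups[[hit]] <- sort(c(groups[[hit]], cl))
    } else if (length(hit) >= 2) {
      unassigned <- c(unassigned, cl)
    } else pending <- c(pending, cl)
  }
  groups <- c(groups, closure_groups(pending, alpha))
  list(partition = groups, doublets = sort(doublets),
       unassigned = sort(unassigned))
}

# Canonical form of a partition (set of sorted member vectors) for comparison.
canon_partition <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(unname(g))))
  groups[order(vapply(groups, `[`, "", 1))]
}

clonotype_set_partition <- function(ct) {
  canon_partition(split(ct$cells$cell_id, ct$cells$clone_id))
}

# Random small contig tables for oracle comparison: a pool of beta and alpha
# CDR3s small enough to force shared chains and alpha-only cells.
random_contigs <- function(n_cells, seed) {
  set.seed(seed)
  betas <- paste0("CASS", LETTERS[1:6], "F")
  alphas <- paste0("CAV", LETTERS[1:6], "W")
  rows <- list()
  for (i in seq_len(n_cells)) {
    cell <- sprintf("c%02d", i)
    nb <- sample(0:2, 1, prob = c(0.25, 0.6, 0.15))
    na <- sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
    if (nb + na == 0) nb <- 1
    for (b in sample(betas, nb))
      rows[[length(rows) + 1]] <- data.frame(cell_id = cell, chain = "TRB",
                                             cdr3_aa = b, productive = TRUE,
                                             umis = sample(1:20, 1))
    for (a in sample(alphas, na))
      rows[[length(rows) + 1]] <- data.frame(cell_id = cell, chain = "TRA",
                                             cdr3_aa = a, productive = TRUE,
                                             umis = sample(1:20, 1))
  }
  do.call(rbind, rows)
}

# Reference logistic LRT p-value via stats::glm.
oracle_glm_p <- function(x, y) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12,
                                                                  maxit = 100)))
  stats::pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
}

# Exact permutation p for the interaction score on a tiny instance: averages
# over every distinct assignment of cluster labels to cells.
oracle_exact_perm_p <- function(lv, rv, clusters, X, Y) {
  n <- length(clusters)
  xi <- clusters == X; yi <- clusters == Y
  obs <- (mean(lv[xi]) + mean(rv[yi])) / 2
  perms <- combinat_permutations(n)
  ok <- vapply(perms, function(p) {
    s <- (mean(lv[p[xi]]) + mean(rv[p[yi]])) / 2
    s >= obs
  }, TRUE)
  mean(ok)
}

combinat_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_permutations(n - 1)
  out <- list()
  for (p in sub) for (k in seq_len(n))
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

# Small log-normalized CountMatrix built from an explicit dense matrix.
tiny_cm <- function(mat, genes = NULL, cells = NULL, normalize = TRUE) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(mat)))
  cm <- count_matrix(mat, genes, cells)
  if (normalize) cm <- log_normalize(cm) else cm
}
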