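contig_row <- function(cell, chain, cdr3, umis = 5) {
  data.frame(cell_id = cell, chain = chain, cdr3_aa = cdr3,
             productive = TRUE, umis = umis, stringsAsFactors = FALSE)
}

test_that("two alpha variants sharing one beta chain merge into one clone", {
  tg <- rbind(contig_row("c1", "TRA", "CAGKTSYDKVIF"),
              contig_row("c1", "TRB", "CASSFGGVSPLHF"),
              contig_row("c2", "TRA", "CAVSEGGGAQKLVF"),
              contig_row("c2", "TRB", "CASSFGGVSPLHF"))
  ct <- group_clonotypes(tg)
  expect_equal(nrow(ct$clones), 1L)
  expect_equal(ct$clones$size, 2L)
  expect_setequal(strsplit(ct$clones$alpha_cdr3s, ";")[[1]],
                  c("CAGKTSYDKVIF", "CAVSEGGGAQKLVF"))
  expect_equal(ct$clones$beta_cdr3s, "CASSFGGVSPLHF")
})

test_that("single cells and disjoint betas found singleton clonotypes", {
  ct1 <- group_clonotypes(contig_row("c1", "TRB", "CASSA"))
  expect_equal(ct1$clones$size, 1L)
  tg <- do.call(rbind, lapply(1:10, function(i)
    contig_row(sprintf("c%02d", i), "TRB", paste0("CASS", LETTERS[i]))))
  ct <- group_clonotypes(tg)
  expect_equal(nrow(ct$clones), 10L)
  expect_true(all(ct$clones$size == 1L))
})

test_that("alpha-only cells attach uniquely, ambiguously match -> unassigned", {
  tg <- rbind(contig_row("b1", "TRB", "CASSA"), contig_row("b1", "TRA", "CAVA"),
              contig_row("b2", "TRB", "CASSG"), contig_row("b2", "TRA", "CAVG"),
              contig_row("a1", "TRA", "CAVA"),          # unique -> joins b1
              contig_row("a2", "TRA", "CAVN"))          # no match -> new clone
  ct <- group_clonotypes(tg)
  part <- clonotype_set_partition(ct)
  expect_true(list(c("a1", "b1")) %in% part)
  expect_true(list("a2") %in% part)

  # same alpha accumulated in two beta clones -> ambiguous
  tg2 <- rbind(tg[1:4, ],
               contig_row("b3", "TRB", "CASSG"), contig_row("b3", "TRA", "CAVA"),
               contig_row("amb", "TRA", "CAVA"))
  expect_message(ct2 <- group_clonotypes(tg2), "unassigned")
  expect_equal(ct2$unassigned, "amb")
  expect_false("amb" %in% ct2$cells$cell_id)
})

test_that("cells with more than two beta chains are excluded as doublets", {
  tg <- rbind(contig_row("d1", "TRB", "CASSA"), contig_row("d1", "TRB", "CASSG"),
              contig_row("d1", "TRB", "CASSN"), contig_row("ok", "TRB", "CASSA"))
  expect_message(ct <- group_clonotypes(tg), "doublet")
  expect_equal(ct$doublets, "d1")
  expect_equal(ct$cells$cell_id, "ok")
})

test_that("clonotype partition matches the brute-force transitive-closure oracle", {
  for (seed in 1:50) {
    tg <- random_contigs(n_cells = sample(3:20, 1), seed = seed)
    got <- suppressMessages(group_clonotypes(tg))
    want <- oracle_clonotypes(tg)
    expect_identical(clonotype_set_partition(got),
                     canon_partition(want$partition),
                     label = paste("partition, seed", seed))
    expect_identical(sort(got$doublets), want$doublets,
                     label = paste("doublets, seed", seed))
    expect_identical(sort(got$unassigned), want$unassigned,
                     label = paste("unassigned, seed", seed))
  }
})

test_that("grouping is idempotent on its own output", {
  tg <- random_contigs(15, seed = 99)
  ct1 <- suppressMessages(group_clonotypes(tg))
  tg2 <- tg[tg$cell_id %in% ct1$cells$cell_id, ]
  ct2 <- suppressMessages(group_clonotypes(tg2))
  expect_identical(clonotype_set_partition(ct1), clonotype_set_partition(ct2))
})

meta_for <- function(cells, sample = "s1", patient = "p1", class = "patch") {
  data.frame(cell_id = cells, sample_id = sample, patient_id = patient,
             lesion_class = class, cluster = "TC", stringsAsFactors = FALSE)
}

test_that("dominant clone: size, then UMI, then lexicographic beta tie-breaks", {
  tg <- rbind(contig_row("c1", "TRB", "CASSB", umis = 1),
              contig_row("c2", "TRB", "CASSB", umis = 1),
              contig_row("c3", "TRB", "CASSA", umis = 10),
              contig_row("c4", "TRB", "CASSA", umis = 10))
  ct <- group_clonotypes(tg)
  dom <- dominant_clone(ct, meta_for(paste0("c", 1:4)))
  # sizes tie (2 vs 2); CASSA clone wins on UMIs
  expect_equal(ct$clones$beta_cdr3s[match(dom$clone_id, ct$clones$clone_id)],
               "CASSA")
  expect_equal(dom$fraction, 0.5)

  tg2 <- rbind(contig_row("c1", "TRB", "CASSB", umis = 5),
               contig_row("c2", "TRB", "CASSA", umis = 5))
  ct2 <- group_clonotypes(tg2)
  dom2 <- dominant_clone(ct2, meta_for(c("c1", "c2")))
  expect_equal(ct2$clones$beta_cdr3s[match(dom2$clone_id, ct2$clones$clone_id)],
               "CASSA")
})

test_that("dominant clone matches an enumeration oracle on a random fixture", {
  tg <- random_contigs(50, seed = 7)
  ct <- suppressMessages(group_clonotypes(tg))
  md <- meta_for(unique(tg$cell_id))
  dom <- dominant_clone(ct, md)
  umis_by_cell <- tapply(tg$umis, tg$cell_id, sum)
  cl <- ct$clones
  cl$tot_umis <- vapply(cl$clone_id, function(id)
    sum(umis_by_cell[ct$cells$cell_id[ct$cells$clone_id == id]]), 0)
  cl$first_beta <- vapply(strsplit(cl$beta_cdr3s, ";"), `[`, "", 1)
  want <- cl$clone_id[order(-cl$size, -cl$tot_umis, cl$first_beta)][1]
  expect_equal(unique(dom$clone_id), want)
})

test_that("patient scope pools samples; single-sample patients match sample scope", {
  tg <- rbind(contig_row("c1", "TRB", "CASSA"), contig_row("c2", "TRB", "CASSA"),
              contig_row("c3", "TRB", "CASSG"), contig_row("c4", "TRB", "CASSG"),
              contig_row("c5", "TRB", "CASSG"))
  md <- rbind(meta_for(c("c1", "c2", "c3"), sample = "s1"),
              meta_for(c("c4", "c5"), sample = "s2", class = "tumor"))
  dom_p <- dominant_clone(tg |> group_clonotypes(), md, scope = "patient")
  # CASSG has 3 cells pooled vs CASSA 2 -> dominant everywhere
  expect_equal(dom_p$fraction[dom_p$sample_id == "s1"], 1 / 3)
  expect_equal(dom_p$fraction[dom_p$sample_id == "s2"], 1)

  md1 <- meta_for(paste0("c", 1:5))
  ct <- group_clonotypes(tg)
  expect_equal(dominant_clone(ct, md1, scope = "patient"),
               dominant_clone(ct, md1, scope = "sample"))
})

test_that("clonality assignment partitions cells exhaustively and disjointly", {
  tg <- rbind(contig_row("c1", "TRB", "CASSA"), contig_row("c2", "TRB", "CASSA"),
              contig_row("c3", "TRB", "CASSA"),
              contig_row("c4", "TRB", "CASSG"), contig_row("c5", "TRB", "CASSN"))
  md <- meta_for(paste0("c", 1:10))
  ct <- group_clonotypes(tg)
  asg <- assign_clonality(ct, dominant_clone(ct, md), md)
  expect_equal(nrow(asg), 10L)
  expect_equal(sum(asg$clonality == "dominant"), 3L)
  expect_equal(sum(asg$clonality == "polyclonal"), 2L)
  expect_equal(sum(asg$clonality == "no_tcr"), 5L)
  expect_true(all(is.na(asg$clone_id[asg$clonality == "no_tcr"])))
  expect_true(all(!is.na(asg$clone_id[asg$clonality != "no_tcr"])))
})

test_that("contig cells absent from metadata are skipped with a warning", {
  tg <- rbind(contig_row("c1", "TRB", "CASSA"), contig_row("zz", "TRB", "CASSG"))
  md <- meta_for("c1")
  ct <- group_clonotypes(tg)
  expect_warning(asg <- assign_clonality(ct, dominant_clone(ct, md), md),
                 "absent from metadata")
  expect_equal(asg$cell_id, "c1")
})

test_that("zero TCR+ cells yields an empty result with a warning, not an error", {
  tg <- contig_row("c1", "TRB", "CASSA")
  ct <- group_clonotypes(tg)
  expect_warning(dom <- dominant_clone(ct, meta_for("other_cell")), "no TCR")
  expect_equal(nrow(dom), 0L)
})

test_that("gamma/delta fixture: dominant gd clone, empty polyclonal gd allowed", {
  tg <- rbind(contig_row("g1", "TRD", "CADTA"), contig_row("g1", "TRG", "CAGW"),
              contig_row("g2", "TRD", "CADTA"), contig_row("g3", "TRD", "CADTA"))
  md <- meta_for(c("g1", "g2", "g3", "n1"))
  ct <- group_clonotypes(tg)
  asg <- assign_clonality(ct, dominant_clone(ct, md), md)
  expect_equal(sum(asg$clonality == "dominant"), 3L)
  expect_equal(sum(asg$clonality == "polyclonal"), 0L)
  expect_equal(sum(asg$clonality == "no_tcr"), 1L)
})

test_that("per-sample alpha-variant shares track allelic exclusion", {
  tg <- rbind(contig_row("c1", "TRB", "CASSB"), contig_row("c1", "TRA", "CAVA"),
              contig_row("c2", "TRB", "CASSB"), contig_row("c2", "TRA", "CAVA"),
              contig_row("c2", "TRA", "CAVG"),
              contig_row("c3", "TRB", "CASSB"), contig_row("c3", "TRA", "CAVG"))
  md <- meta_for(paste0("c", 1:3))
  ct <- group_clonotypes(tg)
  sh <- alpha_share(ct, dominant_clone(ct, md), tg, md)
  expect_equal(sh$share[sh$alpha_cdr3 == "CAVA"], 2 / 3)
  expect_equal(sh$share[sh$alpha_cdr3 == "CAVG"], 2 / 3)
})
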