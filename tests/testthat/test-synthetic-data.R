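test_that("generate_transcriptome honors gene count, anchors and determinism", {
  tx <- generate_transcriptome(100, seed = 1)
  expect_length(unique(tx$gene_id), 100)
  expect_false(any(duplicated(tx$transcript_id)))

  all_anchored <- generate_transcriptome(50, frac_without_anchor = 0, seed = 2)
  expect_true(all(grepl("CATG", all_anchored$sequence, fixed = TRUE)))
  # anchored genes always yield a full 26-bp tag
  expect_false(any(is.na(transcript_tags(all_anchored)$tag)))

  again <- generate_transcriptome(100, seed = 1)
  expect_identical(tx, again)

  expect_error(generate_transcriptome(0), "n_genes")
  expect_error(generate_transcriptome(10, frac_without_anchor = 1), "frac_without_anchor")
})

test_that("anchor-free gene count matches the binomial model and is anchor-clean", {
  tx <- generate_transcriptome(1000, frac_without_anchor = 0.2, seed = 7)
  per_gene <- tapply(grepl("CATG", tx$sequence, fixed = TRUE), tx$gene_id, any)
  n_free <- sum(!per_gene)
  # within 3 SD of Binomial(1000, 0.2)
  expect_lt(abs(n_free - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  # anchor-free transcripts contain no CATG anywhere
  free_tx <- tx$sequence[tx$gene_id %in% names(per_gene)[!per_gene]]
  expect_false(any(grepl("CATG", free_tx, fixed = TRUE)))
})

test_that("generate_design reproduces the 24-library factorial layout", {
  des <- generate_design()
  expect_equal(nrow(des), 24)
  expect_equal(as.integer(table(des$treatment)), rep(8L, 3))
  expect_equal(as.integer(table(des$population)), c(12L, 12L))
  # one male and one female per (population, family, treatment) cell
  cells <- dplyr::count(des, population, family, treatment, sex)
  expect_true(all(cells$n == 1))
  expect_equal(nrow(cells), 24)
  # two families per population, nested labels
  fams <- dplyr::distinct(des, population, family)
  expect_equal(as.integer(table(fams$population)), c(2L, 2L))
})

test_that("simulate_counts hits the requested mean and is deterministic", {
  tx <- generate_transcriptome(200, seed = 3)
  sim <- simulate_counts(tx, baseline_mean = 50, dispersion = 0, seed = 4)
  m <- counts_mat(sim$counts)
  # Poisson: SE of a per-gene mean over 24 libraries is sqrt(mu/24)
  se <- sqrt(50 / 24)
  expect_true(all(abs(rowMeans(m) - 50) < 4 * se))

  again <- simulate_counts(tx, baseline_mean = 50, dispersion = 0, seed = 4)
  expect_identical(sim$counts, again$counts)

  bad <- effect_spec("not_a_gene", "lake", "control_to_once", 2)
  expect_error(simulate_counts(tx, effects = bad, seed = 1), "unknown gene")
})

test_that("effects scale the expected means of the targeted libraries only", {
  tx <- generate_transcriptome(50, seed = 5)
  g <- unique(tx$gene_id)[1:5]
  eff <- effect_spec(g, "lake", "control_to_once", 2)
  sim <- simulate_counts(tx, baseline_mean = 100, effects = eff, seed = 6)
  mu <- counts_mat(sim$mu)
  des <- sim$design
  hit <- des$library_id[des$population == "lake" &
                          des$treatment %in% c("once_exposed", "twice_exposed")]
  expect_true(all(mu[g, hit] == 400))
  expect_true(all(mu[g, setdiff(des$library_id, hit)] == 100))
  expect_true(all(mu[setdiff(rownames(mu), g), ] == 100))
})

test_that("simulated reads have the fixed layout and round-trip through dedup", {
  tx <- generate_transcriptome(40, seed = 11)
  sim <- simulate_counts(tx, baseline_mean = 8, dispersion = 0.3, seed = 12)
  rd <- simulate_reads(sim, tx, error_rate = 0, pcr_duplication_rate = 0, seed = 13)

  expect_true(all(nchar(rd$reads$sequence) == 8 + 26))

  tab <- dedup_truequant(extract_tags(rd$reads))
  got <- dplyr::arrange(tab, library_id, tag)
  want <- dplyr::arrange(rd$truth_tags, library_id, tag)
  expect_equal(got$tag, want$tag)
  expect_equal(got$count, want$count)
})

test_that("PCR duplication inflates raw reads but not deduplicated counts", {
  tx <- generate_transcriptome(40, seed = 21)
  sim <- simulate_counts(tx, baseline_mean = 8, dispersion = 0.3, seed = 22)
  rd <- simulate_reads(sim, tx, error_rate = 0, pcr_duplication_rate = 0.5,
                       seed = 23)
  expect_gt(nrow(rd$reads), sum(rd$truth_tags$count))
  tab <- dedup_truequant(extract_tags(rd$reads))
  got <- dplyr::arrange(tab, library_id, tag)
  want <- dplyr::arrange(rd$truth_tags, library_id, tag)
  expect_equal(got$count, want$count)
})

test_that("simulate_reads is deterministic and logs anchorless copies", {
  tx <- generate_transcriptome(30, frac_without_anchor = 0.3, seed = 31)
  sim <- simulate_counts(tx, baseline_mean = 5, seed = 32)
  r1 <- simulate_reads(sim, tx, seed = 33)
  r2 <- simulate_reads(sim, tx, seed = 33)
  expect_identical(r1$reads, r2$reads)
  expect_gt(r1$n_skipped, 0)
  # anchor-free genes never appear in the ground truth
  detectable <- unique(transcript_tags(tx)$gene_id[!is.na(transcript_tags(tx)$tag)])
  nonzero <- rowSums(counts_mat(r1$truth_genes)) > 0
  expect_true(all(names(nonzero)[nonzero] %in% detectable))
})

test_that("generate_go builds a rooted acyclic ontology with nested immune sets", {
  genes <- sprintf("G%05d", 1:100)
  go <- generate_go(genes, n_terms = 25, immune_genes = genes[1:10], seed = 41)
  dag <- go$dag
  expect_s3_class(dag, "go_dag")
  expect_equal(dag$root, "GO:ROOT")
  # every term reaches the root by parent links
  anc <- dag_ancestors(dag)
  non_root <- setdiff(dag$terms, dag$root)
  expect_true(all(vapply(anc[non_root], function(a) "GO:ROOT" %in% a, logical(1))))

  closed <- propagate_annotations(dag, go$annotations)
  gene_sets <- split(closed$gene_id, closed$term_id)
  # transitive closure: child gene sets nest inside the immune parent's set
  expect_true(all(gene_sets[["GO:INNATE"]] %in% gene_sets[["GO:IMM"]]))
  expect_true(all(gene_sets[["GO:ADAPT"]] %in% gene_sets[["GO:IMM"]]))
  expect_true(all(genes[1:10] %in% gene_sets[["GO:IMM"]]))
  expect_error(generate_go(genes, n_terms = 5), "n_terms")
})

test_that("null simulations stay null through the DE stage", {
  # no effects: the fraction of genes at BH-FDR < 0.05 averages <= 0.05
  des <- generate_design()
  libs_a <- des$library_id[des$population == "lake" & des$treatment == "control"]
  libs_b <- des$library_id[des$population == "lake" & des$treatment == "once_exposed"]
  frac <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      cnt <- null_counts(300, des$library_id)
      de <- exact_test(cnt, libs_a, libs_b, 0.2)
      mean(de$fdr < 0.05)
    })
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
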