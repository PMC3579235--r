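test_that("DAG loading handles chains, diamonds, TSV and OBO-lite input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), tsv)
  chain <- load_dag(tsv)
  expect_equal(chain$root, "c")
  expect_equal(length(chain$terms), 3)
  expect_equal(dag_ancestors(chain, "a")[["a"]], c("b", "c"))

  dia <- toy_dag()
  expect_equal(dia$root, "d")
  expect_setequal(dag_ancestors(dia, "a")[["a"]], c("b", "c", "d"))

  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root process", "",
    "[Term]", "id: GO:2", "name: child one", "is_a: GO:1 ! root process", "",
    "[Term]", "id: GO:3", "name: child two", "is_a: GO:1", "is_a: GO:2"
  ), obo)
  dag <- load_dag(obo)
  expect_equal(dag$root, "GO:1")
  expect_equal(unname(dag$names["GO:2"]), "child one")
  expect_setequal(dag_ancestors(dag, "GO:3")[["GO:3"]], c("GO:1", "GO:2"))

  cyc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta"), cyc)
  expect_error(load_dag(cyc), "cycle")

  two_roots <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "c\td"), two_roots)
  expect_error(load_dag(two_roots), "single root")
})

test_that("annotation propagation follows the true-path rule", {
  dag <- toy_dag()
  direct <- tibble::tibble(gene_id = c("g1", "g2"), term_id = c("a", "d"))
  closed <- propagate_annotations(dag, direct)
  g1 <- closed$term_id[closed$gene_id == "g1"]
  expect_setequal(g1, c("a", "b", "c", "d")) # leaf reaches the root
  g2 <- closed$term_id[closed$gene_id == "g2"]
  expect_equal(g2, "d") # root-only annotation is already closed
  expect_error(
    propagate_annotations(dag, tibble::tibble(gene_id = "g", term_id = "zz")),
    "unknown term"
  )
})

test_that("closed child gene sets nest inside their parents'", {
  withr::with_seed(61, {
    genes <- sprintf("G%03d", 1:60)
    go <- generate_go(genes, n_terms = 40, seed = 62)
    closed <- propagate_annotations(go$dag, go$annotations)
    sets <- split(closed$gene_id, closed$term_id)
    for (i in seq_len(nrow(go$dag$edges))) {
      child <- go$dag$edges$child[i]
      parent <- go$dag$edges$parent[i]
      if (is.null(sets[[child]])) next
      expect_true(all(sets[[child]] %in% sets[[parent]]))
    }
  })
})

test_that("Fisher enrichment equals the hypergeometric enumeration", {
  universe <- sprintf("u%02d", 1:20)
  dag <- new_go_dag(tibble::tibble(child = c("t5", "t4"), parent = "root"))
  ann <- tibble::tibble(
    gene_id = c(universe, universe[1:5], universe[6:9]),
    term_id = c(rep("root", 20), rep("t5", 5), rep("t4", 4))
  )
  study <- universe[1:5] # exactly the five t5 genes
  got <- fisher_enrichment(study, universe, ann, min_genes = 5)
  # drawing all five annotated genes in a study of five: p = 1/C(20,5)
  expect_equal(got$p_value[got$term_id == "t5"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(got$expected[got$term_id == "t5"], 5 * 5 / 20)
  # a term annotated to four genes is omitted entirely
  expect_false("t4" %in% got$term_id)
  # the root covers every universe gene: upper-tail p is exactly 1
  expect_equal(got$p_value[got$term_id == "root"], 1)
  # a study with zero hits of a term also has upper-tail p = 1 at observed 0
  none <- fisher_enrichment(universe[10:12], universe, ann, min_genes = 5)
  expect_equal(none$p_value[none$term_id == "t5"],
               stats::phyper(-1, 5, 15, 3, lower.tail = FALSE))
  expect_error(fisher_enrichment(c(study, "alien"), universe, ann), "universe")
})

test_that("the one-sided tail is anti-monotone in the observed count", {
  p_at <- function(obs) stats::phyper(obs - 1, 8, 42, 10, lower.tail = FALSE)
  ps <- vapply(0:8, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("second-order profiles count branch membership via closure", {
  # root d; level-2 terms b and c; gene set hand-checkable
  dag <- toy_dag()
  direct <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    term_id = c("a", "e", "c") # a sits under both b and c
  )
  closed <- propagate_annotations(dag, direct)
  prof <- second_order_profile(c("g1", "g2", "g3"), dag, closed)
  expect_equal(prof$proportion[prof$term_id == "b"], 2 / 3) # g1 via a, g2 via e
  expect_equal(prof$proportion[prof$term_id == "c"], 2 / 3) # g1 via a, g3 direct
  # g1 counts toward BOTH branches
  expect_equal(sum(prof$n_genes), 4)

  # brute-force closure on a random toy DAG agrees with the op
  withr::with_seed(63, {
    genes <- sprintf("G%03d", 1:40)
    go <- generate_go(genes, n_terms = 30, seed = 64)
    closed <- propagate_annotations(go$dag, go$annotations)
    set <- sample(unique(closed$gene_id), 12)
    prof <- second_order_profile(set, go$dag, closed)
    level2 <- sort(go$dag$edges$child[go$dag$edges$parent == go$dag$root])
    anc <- dag_ancestors(go$dag)
    for (t2 in level2) {
      in_branch <- vapply(set, function(g) {
        terms <- closed$term_id[closed$gene_id == g]
        any(vapply(terms, function(tt) tt == t2 || t2 %in% anc[[tt]], logical(1)))
      }, logical(1))
      expect_equal(prof$proportion[prof$term_id == t2], mean(in_branch))
    }
  })
  expect_error(second_order_profile(character(0), dag, closed), "nonempty")
})

test_that("simulated immune up-regulation is recovered as enrichment", {
  # lake-specific four-fold up-regulation of immune-annotated genes must be
  # detected as over-representation of the immune parent term
  des <- generate_design()
  lib <- function(p, t) des$library_id[des$population == p & des$treatment == t]
  hits <- vapply(1:8, function(s) {
    tx <- generate_transcriptome(400, seed = 800 + s)
    genes <- unique(tx$gene_id)
    go <- generate_go(genes, n_terms = 30,
                      immune_genes = withr::with_seed(900 + s, sample(genes, 30)),
                      seed = 1000 + s)
    immune <- unique(go$annotations$gene_id[
      go$annotations$term_id %in% c("GO:INNATE", "GO:ADAPT")
    ])
    eff <- effect_spec(immune, "lake", "control_to_once", 2, "immune")
    sim <- simulate_counts(tx, des, 100, 0.2, eff, seed = 1100 + s)
    de_l <- exact_test(sim$counts, lib("lake", "once_exposed"),
                       lib("lake", "control"), 0.2)
    de_r <- exact_test(sim$counts, lib("river", "once_exposed"),
                       lib("river", "control"), 0.2)
    sets <- classify_population_specific(de_l, de_r)
    closed <- propagate_annotations(go$dag, go$annotations)
    uni <- unique(closed$gene_id)
    study <- intersect(sets$lake_only_up, uni)
    if (length(study) == 0) return(FALSE)
    enr <- fisher_enrichment(study, uni, closed, min_genes = 5)
    enr$p_value[enr$term_id == "GO:IMM"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
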