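#' Construct a validated GO DAG
#'
#' @param edges Tibble/data frame with columns `child`, `parent`
#'   (`is_a`-style links, child -> parent).
#' @param term_names Optional named character vector of term descriptions.
#' @return An object of class `go_dag` with elements `terms`, `edges`,
#'   `root`, `names`.
#' @export
new_go_dag <- function(edges, term_names = NULL) {
  edges <- as_tibble(edges[, c("child", "parent")])
  terms <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, edges$child)

  # Kahn's algorithm: peel terms that are no one's parent; leftovers = cycle
  frontier <- terms[!terms %in% edges$parent]
  remaining <- edges
  active <- terms
  while (length(frontier) > 0) {
    active <- setdiff(active, frontier)
    remaining <- remaining[!remaining$child %in% frontier, , drop = FALSE]
    frontier <- setdiff(active, remaining$parent)
  }
  if (length(active) > 0) {
    cyc <- find_cycle(edges, active)
    abort(paste0("cycle in DAG: ", paste(cyc, collapse = " -> ")))
  }
  roots <- setdiff(terms, edges$child)
  if (length(roots) != 1) {
    abort(paste0("DAG must have a single root; found: ",
                 paste(roots, collapse = ", ")))
  }
  structure(
    list(terms = terms, edges = edges, root = roots,
         names = term_names, parents = parents),
    class = "go_dag"
  )
}

find_cycle <- function(edges, active) {
  # walk parent links from an affected node until a repeat appears
  cur <- active[1]
  seen <- character(0)
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    nxt <- edges$parent[edges$child == cur]
    nxt <- nxt[nxt %in% active]
    if (length(nxt) == 0) break
    cur <- nxt[1]
  }
  c(seen[which(seen == cur)[1]:length(seen)], cur)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$terms), "terms,", nrow(x$edges),
      "links, root =", x$root, "\n")
  invisible(x)
}

#' Load a GO DAG from OBO-lite or a parent-child TSV
#'
#' Two plain-text layouts are accepted: a minimal OBO file (only `[Term]`,
#' `id:`, `name:`, `is_a:` lines are interpreted; `part_of` relationship
#' lines are ignored) or a headerless/headered two-column TSV of
#' `child<TAB>parent` links. The result is checked to be acyclic with one
#' root.
#'
#' @param path Path to the file.
#' @return A `go_dag` object.
#' @export
load_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\[Term\\]", lines))) {
    return(parse_obo_lite(lines))
  }
  tab <- readr::read_tsv(path, col_names = c("child", "parent"),
                         col_types = "cc", comment = "#")
  if (identical(unlist(tab[1, ], use.names = FALSE), c("child", "parent"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  new_go_dag(tab)
}

parse_obo_lite <- function(lines) {
  blocks <- split(lines, cumsum(grepl("^\\[", lines)))
  edges <- list()
  nms <- character(0)
  for (b in blocks) {
    if (length(b) == 0 || !grepl("^\\[Term\\]", b[1])) next
    id <- sub("^id:\\s*", "", grep("^id:", b, value = TRUE)[1])
    nm <- sub("^name:\\s*", "", grep("^name:", b, value = TRUE)[1])
    isa <- grep("^is_a:", b, value = TRUE)
    isa <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", isa))
    if (!is.na(nm)) nms[id] <- nm
    if (length(isa) > 0) {
      edges[[length(edges) + 1]] <- tibble(child = id, parent = isa)
    }
  }
  new_go_dag(bind_rows(edges), term_names = nms)
}

#' Ancestors of terms in a GO DAG
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of term ids.
#' @return Named list: for each input term, the character vector of all its
#'   ancestors (excluding the term itself).
#' @export
dag_ancestors <- function(dag, terms = dag$terms) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag$parents[[t]]
    out <- if (is.null(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    }
    memo[[t]] <- out
    out
  }
  setNames(lapply(terms, anc), terms)
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term, so parent counts always nest child counts.
#'
#' @param dag A `go_dag`.
#' @param direct Tibble of direct annotations (`gene_id`, `term_id`).
#' @return Tibble (`gene_id`, `term_id`) of the upward-closed annotation
#'   sets (direct unions ancestors), one row per pair.
#' @export
propagate_annotations <- function(dag, direct) {
  unknown <- setdiff(direct$term_id, dag$terms)
  if (length(unknown) > 0) {
    abort(paste0("unknown term in annotations: '", unknown[1], "'"))
  }
  anc <- dag_ancestors(dag, unique(direct$term_id))
  closed <- direct |>
    mutate(closure = purrr::map(.data$term_id, ~ c(.x, anc[[.x]]))) |>
    select("gene_id", "closure") |>
    tidyr::unnest_longer("closure", values_to = "term_id") |>
    distinct(.data$gene_id, .data$term_id)
  closed
}

#' Fisher over-representation test of a study set against a gene universe
#'
#' For each term annotated (after propagation) to at least `min_genes`
#' universe genes, tests whether the study set contains more genes of that
#' term than expected under hypergeometric sampling from the universe
#' (one-sided, upper tail). The universe is the set of genes with at least
#' one annotation — genes without GO information carry no signal for the
#' test.
#'
#' @param study Character vector of study genes (subset of the universe).
#' @param universe Character vector of universe genes.
#' @param annotations Closed annotation tibble from
#'   [propagate_annotations()] (`gene_id`, `term_id`).
#' @param min_genes Minimum universe annotation count for a term to be
#'   tested (default 5); smaller terms are omitted entirely.
#' @param fdr If `TRUE` (default) a BH-adjusted column is added alongside
#'   the raw p-values.
#' @return A tibble with `term_id`, `annotated` (universe count),
#'   `observed` (study count), `expected` and `p_value` (plus `fdr`),
#'   ordered by p-value.
#' @export
fisher_enrichment <- function(study, universe, annotations, min_genes = 5L,
                              fdr = TRUE) {
  check_scalar_int(min_genes, "min_genes", min = 1)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    abort(paste0("study gene outside the universe: '", outside[1], "'"))
  }
  ann <- annotations |> filter(.data$gene_id %in% universe)
  n_universe <- length(unique(universe))
  n_study <- length(unique(study))
  per_term <- ann |>
    group_by(.data$term_id) |>
    summarise(
      annotated = dplyr::n_distinct(.data$gene_id),
      observed = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% study]),
      .groups = "drop"
    ) |>
    filter(.data$annotated >= min_genes) |>
    mutate(
      expected = n_study * .data$annotated / n_universe,
      p_value = stats::phyper(.data$observed - 1, .data$annotated,
                              n_universe - .data$annotated, n_study,
                              lower.tail = FALSE)
    ) |>
    arrange(.data$p_value, .data$term_id)
  if (fdr) per_term <- per_term |> mutate(fdr = bh_adjust(.data$p_value))
  per_term
}

#' Second-order GO profile of a gene set
#'
#' For every direct child of the ontology root ("second-order" term), the
#' proportion of the gene set annotated — via the upward closure — with
#' that term. A gene hitting several second-order branches counts toward
#' each, so the proportions need not sum to one.
#'
#' @param gene_set Nonempty character vector of genes.
#' @param dag A `go_dag`.
#' @param annotations Closed annotation tibble from
#'   [propagate_annotations()].
#' @return A tibble (class `sage_profile` added) with `term_id`, `n_genes`
#'   and `proportion`.
#' @export
second_order_profile <- function(gene_set, dag, annotations) {
  if (length(gene_set) == 0) abort("`gene_set` is nonempty by contract")
  level2 <- sort(dag$edges$child[dag$edges$parent == dag$root])
  hits <- annotations |>
    filter(.data$gene_id %in% gene_set, .data$term_id %in% level2) |>
    count(.data$term_id, name = "n_genes")
  out <- tibble(term_id = level2) |>
    left_join(hits, by = "term_id") |>
    mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      proportion = .data$n_genes / length(unique(gene_set))
    )
  class(out) <- c("sage_profile", class(out))
  out
}

#' Bar-chart of one or more second-order GO profiles
#'
#' @param object A `sage_profile` tibble, optionally with an added
#'   grouping column `set` (e.g. lake vs river) for dodged bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sage_profile <- function(object, ...) {
  aes <- if ("set" %in% names(object)) {
    ggplot2::aes(.data$term_id, .data$proportion, fill = .data$set)
  } else {
    ggplot2::aes(.data$term_id, .data$proportion)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of gene set") +
    ggplot2::theme_minimal()
}
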