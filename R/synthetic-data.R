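#' Generate a synthetic reference transcriptome
#'
#' Creates a set of protein-coding transcripts in sense (mRNA) orientation.
#' A configurable fraction of genes is "anchor-free": none of their
#' transcripts contain the NlaIII recognition site `CATG`, so no 26-bp tag
#' can ever be extracted from them and they are undetectable by the tagging
#' protocol — by design, mirroring the fact that a tag-based protocol only
#' sees genes carrying the anchoring site in their transcripts. All other
#' genes are guaranteed at least one `CATG` with a complete 22-base 3'
#' extension, so they yield a well-defined tag.
#'
#' @param n_genes Number of genes (>= 1).
#' @param variants_per_gene_rate Poisson rate of extra splice variants per
#'   gene, so a gene owns `1 + Pois(rate)` transcripts. The default 0.31
#'   reproduces a reference with ~1.31 transcripts per gene.
#' @param mean_len Mean transcript length in bases (gamma-distributed,
#'   minimum 60).
#' @param frac_without_anchor Fraction of genes whose transcripts carry no
#'   `CATG` anywhere; in `[0, 1)`.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A tibble with columns `gene_id`, `transcript_id`, `sequence`.
#' @export
generate_transcriptome <- function(n_genes,
                                   variants_per_gene_rate = 0.31,
                                   mean_len = 500,
                                   frac_without_anchor = 0.1,
                                   seed = NULL) {
  check_scalar_int(n_genes, "n_genes", min = 1)
  check_fraction(frac_without_anchor, "frac_without_anchor", open_hi = TRUE)
  with_seed_if(seed, {
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    n_tx <- 1L + stats::rpois(n_genes, variants_per_gene_rate)
    anchor_free <- stats::runif(n_genes) < frac_without_anchor
    tx <- tibble(
      gene_id = rep(gene_id, n_tx),
      anchor_free = rep(anchor_free, n_tx)
    )
    tx <- tx |>
      group_by(.data$gene_id) |>
      mutate(transcript_id = paste0(.data$gene_id, ".", row_number())) |>
      ungroup()
    len <- pmax(60L, round(stats::rgamma(nrow(tx), shape = 10, scale = mean_len / 10)))
    seqs <- random_dna(nrow(tx), len)
    seqs <- ifelse(tx$anchor_free, scrub_anchor(seqs), plant_anchor(seqs))
    tx |>
      mutate(sequence = seqs) |>
      select("gene_id", "transcript_id", "sequence")
  })
}

# Remove every CATG occurrence by point mutation of its first base.
scrub_anchor <- function(seqs) {
  repeat {
    hit <- regexpr("CATG", seqs, fixed = TRUE)
    if (all(hit < 0)) return(seqs)
    idx <- which(hit > 0)
    for (i in idx) {
      p <- hit[i]
      substr(seqs[i], p, p) <- sample(c("A", "G", "T"), 1)
    }
  }
}

# Guarantee a CATG with a full 22-base 3' extension; extra random CATGs that
# the random sequence already contains are left alone.
plant_anchor <- function(seqs) {
  len <- nchar(seqs)
  # position so that positions p..p+25 fit inside the transcript, in the
  # 3' half of the sequence
  lo <- pmax(1L, len - 25L - pmin(len %/% 2L, 100L))
  hi <- len - 25L
  p <- lo + floor(stats::runif(length(seqs)) * (hi - lo + 1))
  substr(seqs, p, p + 3L) <- "CATG"
  seqs
}

#' Generate the factorial library design
#'
#' The study design: 2 populations (lake, river) x 2 families nested within
#' population x 3 treatments (control, once exposed, twice exposed) x 2
#' sexes, one fish per cell — 24 libraries in total, 8 per treatment group.
#'
#' @return A tibble with columns `library_id`, `population`, `family`,
#'   `sex`, `treatment` (24 rows).
#' @export
generate_design <- function() {
  design <- tidyr::expand_grid(
    population = c("lake", "river"),
    family_no = 1:2,
    treatment = c("control", "once_exposed", "twice_exposed"),
    sex = c("F", "M")
  ) |>
    mutate(
      family = paste0(.data$population, "_f", .data$family_no),
      library_id = sprintf("lib%02d", row_number())
    ) |>
    select("library_id", "population", "family", "sex", "treatment")
  design
}

#' Build an effect specification for simulated expression changes
#'
#' Encodes a population-specific expression response to a treatment
#' transition, applied to a named gene set (typically the "immune" genes of
#' the synthetic annotation). An effect for transition `control_to_once`
#' alters expected expression in the `once_exposed` *and* `twice_exposed`
#' libraries of the given population (the change persists once triggered);
#' `once_to_twice` alters only `twice_exposed` libraries.
#'
#' @param gene_ids Character vector of member genes.
#' @param population `"lake"` or `"river"`.
#' @param transition `"control_to_once"` or `"once_to_twice"`.
#' @param log2_fc Signed log2 fold change (positive = up-regulation).
#' @param gene_set_id Label for the set.
#' @return A tibble with one row per member gene.
#' @export
effect_spec <- function(gene_ids, population, transition, log2_fc,
                        gene_set_id = "set1") {
  population <- match.arg(population, c("lake", "river"))
  transition <- match.arg(transition, c("control_to_once", "once_to_twice"))
  if (!is.finite(log2_fc)) abort("`log2_fc` must be finite")
  tibble(
    gene_set_id = gene_set_id,
    gene_id = unique(gene_ids),
    population = population,
    transition = transition,
    log2_fc = log2_fc
  )
}

treatments_hit <- function(transition) {
  switch(transition,
    control_to_once = c("once_exposed", "twice_exposed"),
    once_to_twice = "twice_exposed",
    abort(paste0("unknown transition '", transition, "'"))
  )
}

#' Simulate a gene x library count matrix
#'
#' Draws negative-binomial tag counts per gene and library with
#' `log2 mu = log2(baseline_mean) + sum of applicable effect terms` and
#' variance `mu + phi * mu^2`. Genes of anchor-free transcripts still
#' receive expression: they are lost only at tag extraction, not in the
#' underlying biology.
#'
#' @param transcripts Transcript tibble from [generate_transcriptome()].
#' @param design Library design from [generate_design()].
#' @param baseline_mean Baseline expected tag count per gene and library.
#' @param dispersion NB dispersion phi (scalar, or one value per gene);
#'   `0` gives Poisson counts.
#' @param effects Effect tibble from [effect_spec()] (or several,
#'   row-bound), or `NULL` for a global null.
#' @param seed Integer seed.
#' @return An object of class `sage_sim`: a list with `counts` (wide tibble,
#'   `gene_id` + one column per library), `mu` (expected means, same shape),
#'   `dispersion`, `effects` and `design`.
#' @export
simulate_counts <- function(transcripts, design = generate_design(),
                            baseline_mean = 100, dispersion = 0.2,
                            effects = NULL, seed = NULL) {
  if (baseline_mean <= 0) abort("`baseline_mean` must be > 0")
  if (any(dispersion < 0)) abort("`dispersion` must be >= 0")
  genes <- unique(transcripts$gene_id)
  n_g <- length(genes)
  n_l <- nrow(design)
  phi <- rep_len(dispersion, n_g)

  mu <- matrix(baseline_mean, n_g, n_l, dimnames = list(genes, design$library_id))
  if (!is.null(effects) && nrow(effects) > 0) {
    unknown <- setdiff(effects$gene_id, genes)
    if (length(unknown) > 0) {
      abort(paste0("effect references unknown gene(s): ",
                   paste(utils::head(unknown, 5), collapse = ", ")))
    }
    for (i in seq_len(nrow(effects))) {
      libs <- design$library_id[design$population == effects$population[i] &
                                  design$treatment %in% treatments_hit(effects$transition[i])]
      mu[effects$gene_id[i], libs] <- mu[effects$gene_id[i], libs] * 2^effects$log2_fc[i]
    }
  }

  counts <- with_seed_if(seed, {
    k <- matrix(0L, n_g, n_l, dimnames = dimnames(mu))
    pois <- phi == 0
    if (any(pois)) {
      k[pois, ] <- stats::rpois(sum(pois) * n_l, lambda = mu[pois, , drop = FALSE])
    }
    if (any(!pois)) {
      k[!pois, ] <- stats::rnbinom(sum(!pois) * n_l,
                                   mu = mu[!pois, , drop = FALSE],
                                   size = rep(1 / phi[!pois], n_l))
    }
    k
  })

  structure(
    list(
      counts = matrix_to_counts(counts),
      mu = matrix_to_counts(mu),
      dispersion = phi,
      effects = effects,
      design = design
    ),
    class = "sage_sim"
  )
}

#' @export
print.sage_sim <- function(x, ...) {
  cat("Simulated tag counts:", nrow(x$counts), "genes x",
      ncol(x$counts) - 1, "libraries\n")
  cat("dispersion range:", paste(signif(range(x$dispersion), 3), collapse = "-"),
      "| effects:", if (is.null(x$effects)) 0 else nrow(x$effects), "rows\n")
  invisible(x)
}

# 3'-most CATG that still allows a complete barcodeless 26-bp tag
# (anchor + 22 bases); NA when the transcript has none.
tag_site <- function(sequence, tag_len = 26L) {
  vapply(sequence, function(s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits + tag_len - 1L <= nchar(s)]
    if (length(hits) == 0) NA_integer_ else max(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Tag sequences of a transcript set
#'
#' The 26-bp tag of a transcript starts at its 3'-most `CATG` that leaves a
#' complete 22-base extension; transcripts without such a site have `NA`.
#'
#' @param transcripts Transcript tibble.
#' @param tag_len Tag length including the 4-base anchor.
#' @return The input with an added `tag` column.
#' @export
transcript_tags <- function(transcripts, tag_len = 26L) {
  p <- tag_site(transcripts$sequence, tag_len)
  transcripts |>
    mutate(tag = ifelse(is.na(p), NA_character_,
                        substr(.data$sequence, p, p + tag_len - 1L)))
}

#' Simulate raw barcoded tag reads, one library at a time
#'
#' Each simulated transcript copy whose transcript carries a usable `CATG`
#' yields one read: a random barcode of `barcode_len` bases followed by the
#' 26-bp tag at the transcript's 3'-most anchor. Within a library the
#' original copies of one tag receive distinct barcodes (the barcode
#' universe of `4^barcode_len` molecules is sampled without replacement), so
#' that barcode-based de-duplication can recover the pre-PCR molecule count
#' exactly. PCR duplicates then replicate existing (barcode, tag) pairs;
#' substitution errors are applied per base after duplication. Copies
#' falling on transcripts without a usable anchor site are skipped and
#' tallied.
#'
#' @param sim A `sage_sim` object or a wide counts tibble.
#' @param transcripts The transcript tibble the counts were simulated from.
#' @param barcode_len Random barcode length (default 8).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param pcr_duplication_rate Expected duplicates per original read (each
#'   read spawns `Geom(1 - rate)` PCR copies); in `[0, 1)`.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, one FASTQ file per library
#'   (`<library_id>.fastq`) is written there.
#' @return An object of class `sage_reads`: list with `reads` (long tibble
#'   `library_id`, `read_id`, `sequence`), `truth_tags` (long tibble
#'   `library_id`, `tag`, `count` of original molecules), `truth_genes`
#'   (wide gene x library tibble of extracted-tag ground truth),
#'   `n_skipped` (copies lost to missing anchor sites) and `files`
#'   (written FASTQ paths or `NULL`).
#' @export
simulate_reads <- function(sim, transcripts, barcode_len = 8L,
                           error_rate = 0, pcr_duplication_rate = 0,
                           seed = NULL, out_dir = NULL) {
  check_fraction(error_rate, "error_rate", open_hi = TRUE)
  check_fraction(pcr_duplication_rate, "pcr_duplication_rate", open_hi = TRUE)
  check_scalar_int(barcode_len, "barcode_len", min = 1)
  counts <- if (inherits(sim, "sage_sim")) sim$counts else sim
  m <- counts_to_matrix(counts)
  tags <- transcript_tags(transcripts)
  tx_by_gene <- split(seq_len(nrow(tags)), tags$gene_id)

  with_seed_if(seed, {
    per_lib <- lapply(colnames(m), function(lib) {
      simulate_library_reads(m[, lib], lib, tags, tx_by_gene,
                             barcode_len, error_rate, pcr_duplication_rate)
    })
    reads <- bind_rows(lapply(per_lib, `[[`, "reads"))
    truth_tags <- bind_rows(lapply(per_lib, `[[`, "truth_tags"))
    truth_genes_long <- bind_rows(lapply(per_lib, `[[`, "truth_genes"))
    n_skipped <- sum(vapply(per_lib, `[[`, numeric(1), "n_skipped"))

    truth <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    if (nrow(truth_genes_long) > 0) {
      truth[cbind(match(truth_genes_long$gene_id, rownames(truth)),
                  match(truth_genes_long$library_id, colnames(truth)))] <-
        truth_genes_long$count
    }

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- vapply(colnames(m), function(lib) {
        path <- file.path(out_dir, paste0(lib, ".fastq"))
        write_fastq(reads[reads$library_id == lib, c("read_id", "sequence")], path)
        path
      }, character(1))
    }

    structure(
      list(reads = reads, truth_tags = truth_tags,
           truth_genes = matrix_to_counts(truth),
           n_skipped = n_skipped, files = files),
      class = "sage_reads"
    )
  })
}

simulate_library_reads <- function(gene_counts, lib, tags, tx_by_gene,
                                   barcode_len, error_rate, dup_rate) {
  active <- names(gene_counts)[gene_counts > 0]
  n_skipped <- 0
  tag_seq <- character(0)
  gene_of <- character(0)
  for (g in active) {
    idx <- tx_by_gene[[g]]
    c_g <- gene_counts[[g]]
    # copies distributed uniformly over the gene's splice variants
    pick <- if (length(idx) == 1) rep(idx, c_g) else sample(idx, c_g, replace = TRUE)
    t_g <- tags$tag[pick]
    lost <- is.na(t_g)
    n_skipped <- n_skipped + sum(lost)
    t_g <- t_g[!lost]
    tag_seq <- c(tag_seq, t_g)
    gene_of <- c(gene_of, rep(g, length(t_g)))
  }
  if (length(tag_seq) == 0) {
    return(list(
      reads = tibble(library_id = character(0), read_id = character(0),
                     sequence = character(0)),
      truth_tags = tibble(library_id = character(0), tag = character(0),
                          count = integer(0)),
      truth_genes = tibble(library_id = character(0), gene_id = character(0),
                           count = integer(0)),
      n_skipped = n_skipped
    ))
  }

  # distinct barcodes among the original copies of each tag
  n_bc <- 4^barcode_len
  ord <- order(tag_seq)
  tag_seq <- tag_seq[ord]
  gene_of <- gene_of[ord]
  barcodes <- unlist(lapply(split(seq_along(tag_seq), tag_seq), function(i) {
    if (length(i) > n_bc) {
      abort(paste0("more molecules of one tag (", length(i),
                   ") than barcode combinations (", n_bc, ")"))
    }
    int_to_dna(sample.int(n_bc, length(i)) - 1, barcode_len)
  }))
  barcodes <- barcodes[order(unlist(split(seq_along(tag_seq), tag_seq)))]

  truth_tags <- tibble(library_id = lib, tag = tag_seq) |>
    count(.data$library_id, .data$tag, name = "count")
  truth_genes <- tibble(library_id = lib, gene_id = gene_of) |>
    count(.data$library_id, .data$gene_id, name = "count")

  seqs <- paste0(barcodes, tag_seq)
  if (dup_rate > 0) {
    n_dup <- stats::rgeom(length(seqs), prob = 1 - dup_rate)
    seqs <- rep(seqs, times = 1L + n_dup)
  }
  seqs <- apply_substitution_errors(seqs, error_rate)

  list(
    reads = tibble(
      library_id = lib,
      read_id = sprintf("%s_r%06d", lib, seq_along(seqs)),
      sequence = seqs
    ),
    truth_tags = truth_tags,
    truth_genes = truth_genes,
    n_skipped = n_skipped
  )
}

int_to_dna <- function(idx, len) {
  out <- matrix("", length(idx), len)
  for (j in seq_len(len)) {
    out[, len - j + 1] <- DNA_BASES[idx %% 4 + 1]
    idx <- idx %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate == 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  total <- sum(len)
  n_mut <- stats::rbinom(1, total, error_rate)
  if (n_mut == 0) return(seqs)
  pos <- sample.int(total, n_mut)
  ends <- cumsum(len)
  read_idx <- findInterval(pos - 1, ends) + 1
  offset <- pos - c(0, ends)[read_idx]
  for (i in seq_len(n_mut)) {
    r <- read_idx[i]; p <- offset[i]
    old <- substr(seqs[r], p, p)
    substr(seqs[r], p, p) <- sample(setdiff(DNA_BASES, old), 1)
  }
  seqs
}

#' Generate a toy Gene Ontology
#'
#' Builds a small acyclic single-root DAG shaped like the biological-process
#' ontology: a root (`GO:ROOT`, "biological_process") with second-level
#' children that include an immune-system term (`GO:IMM`) owning innate
#' (`GO:INNATE`) and adaptive (`GO:ADAPT`) children, plus random deeper
#' leaves. Genes are annotated to leaf terms; a designated immune gene set
#' is annotated under the immune branch.
#'
#' @param genes Character vector of gene ids, or a transcript tibble.
#' @param n_terms Total number of terms (>= 10).
#' @param frac_annotated Fraction of genes receiving at least one direct
#'   annotation.
#' @param immune_genes Genes to annotate under the immune branch (`NULL`
#'   for none).
#' @param seed Integer seed.
#' @return An object of class `sage_go`: list with `dag` (a `go_dag`) and
#'   `annotations` (tibble `gene_id`, `term_id` of direct annotations).
#' @export
generate_go <- function(genes, n_terms = 30, frac_annotated = 0.9,
                        immune_genes = NULL, seed = NULL) {
  check_scalar_int(n_terms, "n_terms", min = 10)
  if (is.data.frame(genes)) genes <- unique(genes$gene_id)
  with_seed_if(seed, {
    level2 <- c("GO:IMM", "GO:RESP", "GO:CELL", "GO:METAB", "GO:DEVEL", "GO:LOCOM")
    level2_names <- c("immune system process", "response to stimulus",
                      "cellular process", "metabolic process",
                      "developmental process", "locomotion")
    fixed <- c("GO:ROOT", level2, "GO:INNATE", "GO:ADAPT")
    n_extra <- max(0L, n_terms - length(fixed))
    extra <- sprintf("GO:X%03d", seq_len(n_extra))
    # each extra term hangs under a random level-2 term or a previous extra
    parents_pool <- c(level2, extra)
    extra_parent <- vapply(seq_len(n_extra), function(i) {
      sample(c(level2, utils::head(extra, i - 1)), 1)
    }, character(1))
    edges <- bind_rows(
      tibble(child = level2, parent = "GO:ROOT"),
      tibble(child = c("GO:INNATE", "GO:ADAPT"), parent = "GO:IMM"),
      tibble(child = extra, parent = extra_parent)
    )
    term_names <- setNames(
      c("biological_process", level2_names,
        "innate immune response", "adaptive immune response",
        paste("synthetic process", seq_len(n_extra))),
      c("GO:ROOT", level2, "GO:INNATE", "GO:ADAPT", extra)
    )
    dag <- new_go_dag(edges, term_names)

    leaves <- setdiff(c(edges$child, edges$parent), edges$parent)
    annotated <- genes[stats::runif(length(genes)) < frac_annotated]
    ann <- tibble(
      gene_id = rep(annotated, times = 1L + stats::rpois(length(annotated), 1)),
    ) |>
      mutate(term_id = sample(leaves, n(), replace = TRUE))
    if (!is.null(immune_genes) && length(immune_genes) > 0) {
      ann <- bind_rows(ann, tibble(
        gene_id = immune_genes,
        term_id = sample(c("GO:INNATE", "GO:ADAPT"), length(immune_genes),
                         replace = TRUE, prob = c(0.7, 0.3))
      ))
    }
    ann <- distinct(ann, .data$gene_id, .data$term_id)
    structure(list(dag = dag, annotations = ann), class = "sage_go")
  })
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
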