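pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    fastq_dir = NULL,
    # synthetic inputs
    n_genes = 300L,
    variants_per_gene_rate = 0.31,
    mean_len = 500L,
    frac_without_anchor = 0.1,
    baseline_mean = 100,
    dispersion = 0.2,
    n_immune_genes = 30L,
    effect_log2_fc = 2,
    n_go_terms = 30L,
    error_rate = 0,
    pcr_duplication_rate = 0.1,
    # tag processing
    barcode_len = 8L,
    tag_len = 26L,
    anchor = "CATG",
    ratio_threshold = 100,
    min_libraries = 7L,
    # mapping
    max_mismatch = 1L,
    # statistics
    n_permutations = 999L,
    nmds_starts = 5L,
    alpha = 0.05,
    min_genes_go = 5L
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for every
#' unspecified key and rejects unknown keys. An empty file yields the full
#' default configuration.
#'
#' @param config Path to a YAML file, a list, or `NULL` for all defaults.
#' @return The completed configuration list (class `sage_config`).
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a path, a list, or NULL")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  check_scalar_int(cfg$min_libraries, "min_libraries", min = 1)
  check_scalar_int(cfg$n_permutations, "n_permutations", min = 1)
  check_scalar_int(cfg$n_genes, "n_genes", min = 1)
  check_scalar_int(cfg$tag_len, "tag_len", min = 5)
  check_fraction(cfg$alpha, "alpha")
  check_fraction(cfg$error_rate, "error_rate", open_hi = TRUE)
  check_fraction(cfg$pcr_duplication_rate, "pcr_duplication_rate", open_hi = TRUE)
  if (cfg$ratio_threshold <= 1) abort("`ratio_threshold` must be > 1")
  structure(cfg, class = c("sage_config", "list"))
}

#' Run the digital gene expression pipeline end to end
#'
#' Executes simulate (unless `fastq_dir` supplies real per-library FASTQ
#' files) -> extract -> de-duplicate -> artifact-reduce -> occurrence
#' filter -> tag mapping -> gene counting -> normalization -> PerMANOVA
#' (overall and per treatment group) -> NMDS -> NB exact-test differential
#' expression (both treatment transitions, within each population) ->
#' population-specific classification with chi-squared contrasts -> GO
#' enrichment of the up-regulated sets -> second-order GO profiles. Each
#' stage logs its input/output row counts into the run manifest; when
#' `out_dir` is set, every tabular output is also written as TSV there.
#'
#' @param config A configuration from [validate_config()] (or anything it
#'   accepts).
#' @return A list of class `sage_run` with the stage outputs
#'   (`transcriptome`, `design`, `go`, `sim`, `tag_tables`, `assignments`,
#'   `counts_raw`, `counts_norm`, `permanova`, `nmds`, `de`, `popsets`,
#'   `chisq`, `enrichment`, `profiles`) and the `manifest` tibble.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  manifest <- list()
  note <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, rows_in = as.integer(n_in), rows_out = as.integer(n_out)
    )
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }

  design <- generate_design()
  tx <- generate_transcriptome(
    cfg$n_genes, cfg$variants_per_gene_rate, cfg$mean_len,
    cfg$frac_without_anchor, seed = cfg$seed
  )
  genes <- unique(tx$gene_id)
  note("transcriptome", cfg$n_genes, nrow(tx))

  go <- generate_go(
    genes, n_terms = cfg$n_go_terms,
    immune_genes = with_seed_if(cfg$seed + 1L,
                                sample(genes, min(cfg$n_immune_genes, length(genes)))),
    seed = cfg$seed + 2L
  )
  immune_genes <- unique(go$annotations$gene_id[
    go$annotations$term_id %in% c("GO:INNATE", "GO:ADAPT")
  ])
  note("go_annotation", length(genes), nrow(go$annotations))

  effects <- effect_spec(immune_genes, "lake", "control_to_once",
                         cfg$effect_log2_fc, gene_set_id = "immune")
  sim <- simulate_counts(tx, design, cfg$baseline_mean, cfg$dispersion,
                         effects, seed = cfg$seed + 3L)

  if (is.null(cfg$fastq_dir)) {
    reads_obj <- simulate_reads(sim, tx, cfg$barcode_len, cfg$error_rate,
                                cfg$pcr_duplication_rate, seed = cfg$seed + 4L)
    reads <- reads_obj$reads
  } else {
    paths <- file.path(cfg$fastq_dir, paste0(design$library_id, ".fastq"))
    missing <- !file.exists(paths)
    if (any(missing)) {
      abort(paste0("missing FASTQ for library '",
                   design$library_id[which(missing)[1]], "'"))
    }
    reads <- purrr::map2_dfr(paths, design$library_id, function(p, lib) {
      read_fastq(p) |> mutate(library_id = lib)
    })
  }
  note("reads", nrow(sim$counts), nrow(reads))

  obs <- extract_tags(reads, cfg$barcode_len, cfg$tag_len, cfg$anchor)
  note("extract", nrow(reads), nrow(obs))

  tables <- dedup_truequant(obs)
  note("dedup", nrow(obs), nrow(tables))

  n_before <- nrow(tables)
  tables <- reduce_artifacts(tables, cfg$ratio_threshold)
  note("artifact_reduce", n_before, nrow(tables))

  n_before <- dplyr::n_distinct(tables$tag)
  tables <- filter_tags(tables, cfg$min_libraries)
  note("occurrence_filter", n_before, dplyr::n_distinct(tables$tag))

  assignments <- match_tags(unique(tables$tag), tx, cfg$max_mismatch)
  note("tag_mapping", dplyr::n_distinct(tables$tag), sum(assignments$status == "assigned"))

  counts_raw <- build_gene_counts(assignments, tables,
                                  libraries = design$library_id)
  counts_norm <- normalize_cpm(counts_raw)
  note("gene_counts", nrow(assignments), nrow(counts_raw))

  dist <- correlation_distance(counts_norm)
  fits <- list(
    overall = permanova(dist, design,
                        c("treatment", "population", "family", "sex"),
                        cfg$n_permutations, seed = cfg$seed + 5L)
  )
  for (tr in unique(design$treatment)) {
    keep <- design$library_id[design$treatment == tr]
    sub <- stats::as.dist(as.matrix(dist)[keep, keep])
    fits[[tr]] <- permanova(sub, design[design$treatment == tr, ],
                            c("population", "family", "sex"),
                            cfg$n_permutations, seed = cfg$seed + 6L)
  }
  note("permanova", nrow(counts_norm), length(fits))

  ord <- nmds(dist, dims = 2, n_starts = cfg$nmds_starts,
              seed = cfg$seed + 7L)
  note("nmds", attr(stats::as.dist(dist), "Size"), nrow(ord$points))

  lib_of <- function(pop, tr) design$library_id[design$population == pop &
                                                  design$treatment == tr]
  disp <- estimate_dispersion(
    counts_raw,
    groups = setNames(paste(design$population, design$treatment, sep = "."),
                      design$library_id)
  )
  de <- list()
  for (pop in c("lake", "river")) {
    de[[paste0(pop, "_control_to_once")]] <- exact_test(
      counts_raw, lib_of(pop, "once_exposed"), lib_of(pop, "control"),
      disp, alpha = cfg$alpha
    )
    de[[paste0(pop, "_once_to_twice")]] <- exact_test(
      counts_raw, lib_of(pop, "twice_exposed"), lib_of(pop, "once_exposed"),
      disp, alpha = cfg$alpha
    )
  }
  note("differential_expression", nrow(counts_raw), length(de))

  popsets <- list(
    control_to_once = classify_population_specific(
      de$lake_control_to_once, de$river_control_to_once, cfg$alpha
    ),
    once_to_twice = classify_population_specific(
      de$lake_once_to_twice, de$river_once_to_twice, cfg$alpha
    )
  )
  chisq <- purrr::map(popsets, function(ps) {
    tab <- rbind(
      lake = c(up = length(ps$lake_only_up), down = length(ps$lake_only_down)),
      river = c(up = length(ps$river_only_up), down = length(ps$river_only_down))
    )
    tryCatch(chisq_2x2(tab), error = function(e) {
      tibble(chi2 = NA_real_, df = NA_real_, p_value = NA_real_)
    })
  })
  note("classification", length(de), length(popsets))

  closed <- propagate_annotations(go$dag, go$annotations)
  universe <- unique(closed$gene_id)
  enr <- purrr::imap(popsets, function(ps, trans) {
    purrr::imap(ps[c("lake_only_up", "river_only_up")], function(set, nm) {
      set <- intersect(set, universe)
      if (length(set) == 0) return(tibble())
      fisher_enrichment(set, universe, closed, cfg$min_genes_go)
    })
  })
  profiles <- purrr::map(popsets$control_to_once[c("lake_only_up", "river_only_up")],
                         function(set) {
                           set <- intersect(set, universe)
                           if (length(set) == 0) return(NULL)
                           second_order_profile(set, go$dag, closed)
                         })
  note("enrichment", length(universe), length(enr))

  run <- structure(
    list(
      config = cfg, transcriptome = tx, design = design, go = go, sim = sim,
      tag_tables = tables, assignments = assignments,
      counts_raw = counts_raw, counts_norm = counts_norm,
      permanova = fits, nmds = ord, dispersion = disp, de = de,
      popsets = popsets, chisq = chisq, enrichment = enr,
      profiles = profiles, manifest = bind_rows(manifest)
    ),
    class = "sage_run"
  )
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

#' @export
print.sage_run <- function(x, ...) {
  cat("sagescape pipeline run —", nrow(x$counts_raw), "genes detected in",
      ncol(x$counts_raw) - 1, "libraries\n")
  print(x$manifest, n = Inf)
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(run$design, "design.tsv")
  w(run$tag_tables, "tag_counts.tsv")
  w(run$assignments, "tag_assignments.tsv")
  w(run$counts_raw, "gene_counts_raw.tsv")
  w(run$counts_norm, "gene_counts_cpm.tsv")
  for (nm in names(run$permanova)) {
    w(tidy(run$permanova[[nm]]), paste0("permanova_", nm, ".tsv"))
  }
  w(run$nmds$points, "nmds_coordinates.tsv")
  for (nm in names(run$de)) w(run$de[[nm]], paste0("de_", nm, ".tsv"))
  for (trans in names(run$enrichment)) {
    for (nm in names(run$enrichment[[trans]])) {
      tab <- run$enrichment[[trans]][[nm]]
      if (nrow(tab) > 0) w(tab, paste0("enrichment_", trans, "_", nm, ".tsv"))
    }
  }
  w(run$manifest, "manifest.tsv")
  invisible(out_dir)
}
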