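#' Assign tags to genes under uniqueness, orientation and mismatch rules
#'
#' Each tag is scanned against the forward (sense) strand of every
#' reference transcript at every offset, ungapped. A position contributes
#' one mismatch when the reference base is a standard base differing from
#' the tag base — and *always* one mismatch when the reference base is an
#' IUPAC ambiguity code, so that at a segregating site both alleles of a
#' tag score the gene with the same mismatch count (consensus neutrality;
#' the same behaviour as a BLAST search that treats ambiguity codes as
#' unknown `N`s). Transcripts whose best offset has at most `max_mismatch`
#' mismatches are hits; hits confined to the splice variants of a single
#' gene give an assignment, hits spanning several genes are ambiguous, no
#' hit leaves the tag unmatched.
#'
#' @param tags Character vector of tag sequences, or a data frame with a
#'   `tag` column.
#' @param reference A `sage_consensus` object or a transcript tibble
#'   (`gene_id`, `transcript_id`, `sequence`).
#' @param max_mismatch Maximum mismatches for a hit (default 1 — "fewer
#'   than two").
#' @return A tibble with columns `tag`, `status` (`assigned`,
#'   `ambiguous_multi_gene` or `unmatched`), `gene_id` (`NA` unless
#'   assigned) and `mismatches` (`NA` when unmatched).
#' @export
match_tags <- function(tags, reference, max_mismatch = 1L) {
  check_scalar_int(max_mismatch, "max_mismatch", min = 0)
  if (is.data.frame(tags)) tags <- tags$tag
  tags <- unique(tags)
  if (any(grepl("[^ACGT]", tags))) {
    abort(paste0("tag with non-ACGT base: '",
                 tags[grepl("[^ACGT]", tags)][1], "' (filter tags first)"))
  }
  ref <- if (inherits(reference, "sage_consensus")) reference$transcripts else reference
  subject <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$transcript_id))

  purrr::map_dfr(tags, function(tg) {
    best <- NA_integer_
    hit_tx <- integer(0)
    for (mm in 0:max_mismatch) {
      # fixed = TRUE compares letters literally, so a reference IUPAC code
      # mismatches every standard tag base — the neutrality rule above
      n_hit <- Biostrings::vcountPattern(tg, subject, max.mismatch = mm,
                                         fixed = TRUE)
      if (any(n_hit > 0)) {
        best <- mm
        hit_tx <- which(n_hit > 0)
        break
      }
    }
    if (length(hit_tx) == 0) {
      return(tibble(tag = tg, status = "unmatched",
                    gene_id = NA_character_, mismatches = NA_integer_))
    }
    genes <- unique(ref$gene_id[hit_tx])
    if (length(genes) > 1) {
      tibble(tag = tg, status = "ambiguous_multi_gene",
             gene_id = NA_character_, mismatches = best)
    } else {
      tibble(tag = tg, status = "assigned", gene_id = genes,
             mismatches = best)
    }
  })
}

#' Exhaustive reference scan for one tag (oracle path)
#'
#' Pure-R sliding-window scan over every offset of every transcript,
#' returning the minimum mismatch count per transcript under the same
#' mismatch rule as [match_tags()]. Kept as the independent reference
#' implementation for the optimized scan.
#'
#' @param tag A single tag sequence.
#' @param reference Transcript tibble or `sage_consensus`.
#' @return Named integer vector of best mismatch counts per transcript.
#' @export
scan_tag_exhaustive <- function(tag, reference) {
  ref <- if (inherits(reference, "sage_consensus")) reference$transcripts else reference
  tl <- nchar(tag)
  tchars <- strsplit(tag, "")[[1]]
  vapply(ref$sequence, function(s) {
    n <- nchar(s)
    if (n < tl) return(NA_integer_)
    best <- tl
    for (off in 0:(n - tl)) {
      w <- strsplit(substr(s, off + 1L, off + tl), "")[[1]]
      mm <- sum(w != tchars | !(w %in% DNA_BASES))
      if (mm < best) best <- mm
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE) |>
    setNames(ref$transcript_id)
}

#' Build the raw gene x library count matrix
#'
#' Sums the deduplicated counts of all tags assigned to each gene, per
#' library; splice variants of a gene were already collapsed during
#' assignment. Ambiguous and unmatched tags contribute nothing; their
#' count share is reported in the attached `log` attribute.
#'
#' @param assignments Assignment tibble from [match_tags()].
#' @param tables Long tag count tibble (`library_id`, `tag`, `count`).
#' @param libraries Optional character vector fixing the library columns
#'   (defaults to the libraries present in `tables`).
#' @param genes Optional character vector fixing the gene rows (defaults to
#'   all assigned genes).
#' @return A wide tibble (`gene_id` + one integer column per library);
#'   attribute `log` reports tag and count totals by assignment status.
#' @export
build_gene_counts <- function(assignments, tables, libraries = NULL,
                              genes = NULL) {
  libraries <- libraries %||% sort(unique(tables$library_id))
  status_of <- setNames(assignments$status, assignments$tag)
  tab_status <- status_of[tables$tag]
  log <- tibble(
    status = c("assigned", "ambiguous_multi_gene", "unmatched"),
    n_tags = vapply(c("assigned", "ambiguous_multi_gene", "unmatched"),
                    function(s) sum(assignments$status == s), numeric(1)),
    total_count = vapply(c("assigned", "ambiguous_multi_gene", "unmatched"),
                         function(s) sum(tables$count[tab_status %in% s]),
                         numeric(1))
  )
  assigned <- assignments |> filter(.data$status == "assigned")
  genes <- genes %||% sort(unique(assigned$gene_id))
  m <- matrix(0, length(genes), length(libraries),
              dimnames = list(genes, libraries))
  hits <- tables |>
    inner_join(select(assigned, "tag", "gene_id"), by = "tag") |>
    group_by(.data$gene_id, .data$library_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (nrow(hits) > 0) {
    m[cbind(match(hits$gene_id, genes), match(hits$library_id, libraries))] <-
      hits$count
  }
  out <- matrix_to_counts(m)
  attr(out, "log") <- log
  out
}

#' Normalize a count matrix to one million tags per library
#'
#' Library sizes differ for purely technical reasons, so raw counts are
#' rescaled to a common library size of one million assigned tags:
#' `normalized[g, l] = raw[g, l] * 1e6 / total[l]`, where `total[l]` is the
#' library's sum of assigned-tag counts.
#'
#' @param counts Wide raw count tibble from [build_gene_counts()].
#' @return The normalized wide tibble; per-library raw totals are attached
#'   as attribute `library_sizes`.
#' @export
normalize_cpm <- function(counts) {
  m <- counts_to_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("library with zero total count: '",
                 names(totals)[totals == 0][1], "'"))
  }
  norm <- sweep(m, 2, totals, "/") * 1e6
  out <- matrix_to_counts(norm)
  attr(out, "library_sizes") <- totals
  out
}
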