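#' Extract barcoded 26-bp tags from raw reads
#'
#' A read is laid out as `barcode_len` random barcode bases immediately
#' followed by the tag, whose first four bases must be the anchoring-enzyme
#' recognition site (`CATG` for NlaIII). Reads that are too short or whose
#' tag does not begin with the anchor are skipped and tallied.
#'
#' @param reads A data frame with a `sequence` column (and optionally
#'   `library_id`, which is carried through), or a path to a FASTQ file.
#' @param barcode_len Barcode length (default 8).
#' @param tag_len Tag length (default 26).
#' @param anchor Required tag prefix; `NULL` disables the anchor check.
#' @return A tibble of tag observations with columns `barcode` and `tag`
#'   (plus `library_id` if present in the input). The number of skipped
#'   reads is attached as attribute `n_skipped`.
#' @export
extract_tags <- function(reads, barcode_len = 8L, tag_len = 26L,
                         anchor = "CATG") {
  check_scalar_int(barcode_len, "barcode_len", min = 1)
  check_scalar_int(tag_len, "tag_len", min = 1)
  reads <- as_reads_tibble(reads, "fastq")
  need <- barcode_len + tag_len
  long_enough <- nchar(reads$sequence) >= need
  obs <- reads[long_enough, , drop = FALSE]
  barcode <- substr(obs$sequence, 1L, barcode_len)
  tag <- substr(obs$sequence, barcode_len + 1L, need)
  ok <- if (is.null(anchor)) rep(TRUE, length(tag)) else startsWith(tag, anchor)
  out <- tibble(barcode = barcode[ok], tag = tag[ok])
  if ("library_id" %in% names(obs)) {
    out <- dplyr::bind_cols(tibble(library_id = obs$library_id[ok]), out)
  }
  attr(out, "n_skipped") <- sum(!long_enough) + sum(!ok)
  out
}

#' Remove PCR duplicates by the random-barcode (TrueQuant) rule
#'
#' PCR copies carry the same (barcode, tag) combination as the original
#' molecule they were amplified from, so identical combinations collapse to
#' one and a tag's count is the number of *distinct* barcodes observed with
#' it. Two genuinely distinct molecules that drew the same barcode are
#' under-counted by one — a limitation inherent to the protocol itself.
#'
#' @param observations Tag observations from [extract_tags()] (columns
#'   `barcode`, `tag`, optional `library_id`).
#' @return A tag count tibble with columns `tag`, `count` (and `library_id`
#'   if present), one row per tag (per library).
#' @export
dedup_truequant <- function(observations) {
  keys <- intersect("library_id", names(observations))
  observations |>
    distinct(across(dplyr::all_of(c(keys, "barcode", "tag")))) |>
    count(across(dplyr::all_of(c(keys, "tag"))), name = "count")
}

#' Absorb likely sequencing artifacts into neighbouring tags
#'
#' A tag whose count is dwarfed by a Hamming-distance-1 neighbour is most
#' plausibly a sequencing error of that neighbour. Each tag with a
#' neighbour whose count is at least `ratio_threshold` times its own is
#' absorbed: its count is added to the neighbour and the tag is dropped.
#' Ties between candidate absorbers go to the highest count, then to the
#' lexicographically smallest tag. Tags are processed in increasing count
#' order against the original (pre-absorption) counts, so the rule is
#' deterministic; total counts are conserved.
#'
#' @param table A tag count tibble (`tag`, `count`, optional `library_id`;
#'   multi-library tables are processed per library).
#' @param ratio_threshold Minimum neighbour/count ratio for absorption
#'   (> 1; default 100).
#' @return The reduced tag count tibble.
#' @export
reduce_artifacts <- function(table, ratio_threshold = 100) {
  if (ratio_threshold <= 1) abort("`ratio_threshold` must be > 1")
  if ("library_id" %in% names(table)) {
    return(
      table |>
        group_by(.data$library_id) |>
        dplyr::group_modify(~ reduce_artifacts_one(.x, ratio_threshold)) |>
        ungroup()
    )
  }
  reduce_artifacts_one(table, ratio_threshold)
}

reduce_artifacts_one <- function(table, ratio_threshold) {
  counts <- setNames(as.numeric(table$count), table$tag)
  ref <- counts # decision counts frozen before any absorption
  ord <- names(sort(ref)) # ascending: small tags resolved first
  for (tg in ord) {
    if (is.na(counts[tg])) next
    nb <- hamming1_neighbors(tg)
    nb <- nb[nb %in% names(counts) & !is.na(counts[nb])]
    nb <- nb[ref[nb] >= ratio_threshold * ref[tg]]
    if (length(nb) == 0) next
    nb <- nb[order(-ref[nb], nb)][1]
    counts[nb] <- counts[nb] + counts[tg]
    counts[tg] <- NA_real_
  }
  keep <- !is.na(counts)
  tibble(tag = names(counts)[keep], count = unname(counts[keep]))
}

hamming1_neighbors <- function(tag) {
  n <- nchar(tag)
  out <- character(3 * n)
  k <- 0
  for (p in seq_len(n)) {
    for (b in DNA_BASES) {
      if (b == substr(tag, p, p)) next
      k <- k + 1
      out[k] <- tag
      substr(out[k], p, p) <- b
    }
  }
  out[seq_len(k)]
}

#' Filter tags on base content and cross-library occurrence
#'
#' Removes tags containing any base outside `A/C/G/T` (e.g. `N`s), then
#' removes tags observed in fewer than `min_libraries` libraries — a
#' conservative guard against family-specific alleles and low-frequency
#' tags with no statistical power.
#'
#' @param tables A long tag count tibble (`library_id`, `tag`, `count`)
#'   covering all libraries.
#' @param min_libraries Minimum number of libraries a tag must appear in
#'   (default 7).
#' @return The filtered long tibble.
#' @export
filter_tags <- function(tables, min_libraries = 7L) {
  check_scalar_int(min_libraries, "min_libraries", min = 1)
  n_lib <- dplyr::n_distinct(tables$library_id)
  if (min_libraries > n_lib) {
    abort(paste0("`min_libraries` (", min_libraries,
                 ") exceeds the number of libraries (", n_lib, ")"))
  }
  clean <- tables |> filter(!grepl("[^ACGT]", .data$tag))
  keep <- clean |>
    filter(.data$count >= 1) |>
    distinct(.data$tag, .data$library_id) |>
    count(.data$tag, name = "n_lib") |>
    filter(.data$n_lib >= min_libraries)
  clean |> dplyr::semi_join(keep, by = "tag")
}
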