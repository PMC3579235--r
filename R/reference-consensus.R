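#' Align cDNA reads to backbone transcripts by seeded ungapped matching
#'
#' A light-weight seed-and-extend aligner in the spirit of reference-guided
#' mapping assembly: reads vote for transcripts via shared k-mers, each read
#' is placed ungapped on the diagonal with the most seed support of its
#' best transcript, and its bases are accumulated into a per-position
#' pileup. A read is assigned to at most one transcript — the one with the
#' most shared k-mers, ties resolved by alignment identity, then (within a
#' gene) by the longest transcript. Reads below `min_identity` or with tied
#' best hits across *different* genes are discarded and tallied.
#'
#' @param reads A data frame with a `sequence` column, or a FASTA/FASTQ
#'   path.
#' @param backbone Backbone transcript tibble (`gene_id`, `transcript_id`,
#'   `sequence`).
#' @param k Seed k-mer length (>= 8).
#' @param min_identity Minimum fraction of matching bases over the aligned
#'   overlap, in `(0, 1]`.
#' @param min_len Reads shorter than this are discarded up front.
#' @param max_n Reads with more than this many non-ACGT bases are discarded
#'   up front.
#' @return A pileup tibble with columns `transcript_id`, `pos` (1-based),
#'   `base`, `count`; attribute `log` holds a named vector of discard
#'   tallies (`too_short`, `too_many_n`, `no_hit`, `low_identity`,
#'   `ambiguous_gene`, `aligned`).
#' @export
align_reads_to_backbone <- function(reads, backbone, k = 12L,
                                    min_identity = 0.9,
                                    min_len = 20L, max_n = 1L) {
  check_scalar_int(k, "k", min = 8)
  check_fraction(min_identity, "min_identity", lo = 1e-12)
  if (nrow(backbone) == 0) abort("`backbone` is empty")
  reads <- as_reads_tibble(reads, "fasta")

  log <- c(too_short = 0, too_many_n = 0, no_hit = 0, low_identity = 0,
           ambiguous_gene = 0, aligned = 0)
  len <- nchar(reads$sequence)
  log[["too_short"]] <- sum(len < pmax(min_len, k))
  reads <- reads[len >= pmax(min_len, k), , drop = FALSE]
  n_amb <- nchar(gsub("[ACGT]", "", reads$sequence))
  log[["too_many_n"]] <- sum(n_amb > max_n)
  reads <- reads[n_amb <= max_n, , drop = FALSE]

  index <- kmer_index(backbone$sequence, k)
  hits <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    placement <- place_read(reads$sequence[i], backbone, index, k, min_identity)
    if (is.character(placement)) {
      log[[placement]] <- log[[placement]] + 1
      next
    }
    log[["aligned"]] <- log[["aligned"]] + 1
    hits[[i]] <- placement
  }
  pile <- bind_rows(hits)
  if (nrow(pile) == 0) {
    pile <- tibble(transcript_id = character(0), pos = integer(0),
                   base = character(0), count = integer(0))
  } else {
    pile <- pile |>
      count(.data$transcript_id, .data$pos, .data$base, name = "count") |>
      arrange(.data$transcript_id, .data$pos, .data$base)
  }
  attr(pile, "log") <- log
  pile
}

# kmer -> "txIdx:pos" postings, stored in a hashed environment
kmer_index <- function(sequences, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(sequences)) {
    s <- sequences[t]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (j in seq_along(kmers)) {
      km <- kmers[j]
      env[[km]] <- c(env[[km]], c(t, starts[j]))
    }
  }
  env
}

place_read <- function(seq, backbone, index, k, min_identity) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  postings <- lapply(seq_along(kmers), function(j) {
    p <- index[[kmers[j]]]
    if (is.null(p)) return(NULL)
    m <- matrix(p, ncol = 2, byrow = TRUE)
    # diagonal = transcript position of the read's first base
    cbind(tx = m[, 1], diag = m[, 2] - starts[j] + 1L)
  })
  postings <- do.call(rbind, postings)
  if (is.null(postings) || nrow(postings) == 0) return("no_hit")

  votes <- table(postings[, "tx"])
  best_tx <- as.integer(names(votes)[votes == max(votes)])
  cand <- lapply(best_tx, function(t) {
    diags <- postings[postings[, "tx"] == t, "diag"]
    d <- as.integer(names(which.max(table(diags))))
    ident <- ungapped_identity(seq, backbone$sequence[t], d)
    list(tx = t, diag = d, identity = ident)
  })
  ident <- vapply(cand, `[[`, numeric(1), "identity")
  if (max(ident) < min_identity) return("low_identity")
  top <- cand[ident == max(ident)]
  genes <- unique(backbone$gene_id[vapply(top, `[[`, integer(1), "tx")])
  if (length(genes) > 1) return("ambiguous_gene")
  # same gene: keep the longest transcript (stable tie-break)
  tx_len <- nchar(backbone$sequence[vapply(top, `[[`, integer(1), "tx")])
  pickd <- top[[order(-tx_len, vapply(top, `[[`, integer(1), "tx"))[1]]]

  t <- pickd$tx; d <- pickd$diag
  tlen <- nchar(backbone$sequence[t])
  r_from <- max(1L, 2L - d)
  r_to <- min(n, tlen - d + 1L)
  pos <- (r_from:r_to) + d - 1L
  tibble(
    transcript_id = backbone$transcript_id[t],
    pos = pos,
    base = strsplit(substr(seq, r_from, r_to), "")[[1]]
  )
}

ungapped_identity <- function(read, ref, diag) {
  n <- nchar(read)
  tlen <- nchar(ref)
  r_from <- max(1L, 2L - diag)
  r_to <- min(n, tlen - diag + 1L)
  if (r_to < r_from) return(0)
  a <- strsplit(substr(read, r_from, r_to), "")[[1]]
  b <- strsplit(substr(ref, r_from + diag - 1L, r_to + diag - 1L), "")[[1]]
  sum(a == b) / n
}

#' Call an IUPAC consensus over a backbone from a read pileup
#'
#' At each covered position, non-backbone bases supported by at least
#' `min_minor_count` reads *and* at least `min_minor_frac` of the local
#' depth are treated as real segregating variants; the position is recoded
#' as the IUPAC ambiguity code covering the backbone base together with the
#' qualifying variants. All other positions keep the backbone base, so the
#' consensus has exactly the backbone's length (ungapped contract).
#'
#' @param backbone Backbone transcript tibble.
#' @param pileup Pileup tibble from [align_reads_to_backbone()].
#' @param min_minor_count Minimum supporting reads for a variant base
#'   (>= 1).
#' @param min_minor_frac Minimum fraction of local depth for a variant
#'   base, in `(0, 0.5]`.
#' @return An object of class `sage_consensus`: list with `transcripts`
#'   (tibble `gene_id`, `transcript_id`, `sequence` — sequences may contain
#'   IUPAC codes) and `ambiguities` (tibble `transcript_id`, `pos`,
#'   `code`).
#' @export
call_consensus <- function(backbone, pileup, min_minor_count = 2L,
                           min_minor_frac = 0.2) {
  check_scalar_int(min_minor_count, "min_minor_count", min = 1)
  check_fraction(min_minor_frac, "min_minor_frac", lo = 1e-12, hi = 0.5)
  seqs <- setNames(backbone$sequence, backbone$transcript_id)
  bad <- !pileup$transcript_id %in% names(seqs)
  if (any(bad)) {
    abort(paste0("pileup references unknown transcript '",
                 pileup$transcript_id[which(bad)[1]], "'"))
  }
  out_of_range <- pileup$pos < 1 |
    pileup$pos > nchar(seqs[pileup$transcript_id])
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    abort(paste0("pileup position ", pileup$pos[i],
                 " outside transcript '", pileup$transcript_id[i], "'"))
  }

  amb <- pileup |>
    group_by(.data$transcript_id, .data$pos) |>
    mutate(depth = sum(.data$count)) |>
    ungroup() |>
    mutate(backbone_base = substr(seqs[.data$transcript_id], .data$pos, .data$pos)) |>
    filter(
      .data$base != .data$backbone_base,
      .data$base %in% DNA_BASES,
      .data$count >= min_minor_count,
      .data$count / .data$depth >= min_minor_frac
    ) |>
    group_by(.data$transcript_id, .data$pos, .data$backbone_base) |>
    summarise(minor = list(.data$base), .groups = "drop") |>
    mutate(code = purrr::map2_chr(.data$minor, .data$backbone_base,
                                  ~ iupac_code(c(.y, .x)))) |>
    select("transcript_id", "pos", "code") |>
    arrange(.data$transcript_id, .data$pos)

  for (i in seq_len(nrow(amb))) {
    substr(seqs[[amb$transcript_id[i]]], amb$pos[i], amb$pos[i]) <- amb$code[i]
  }
  structure(
    list(
      transcripts = backbone |>
        mutate(sequence = unname(seqs[backbone$transcript_id])),
      ambiguities = amb
    ),
    class = "sage_consensus"
  )
}

#' @export
print.sage_consensus <- function(x, ...) {
  cat("Consensus reference:", nrow(x$transcripts), "transcripts,",
      nrow(x$ambiguities), "IUPAC consensus bases\n")
  invisible(x)
}
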