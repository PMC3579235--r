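#' @importFrom rlang .data abort %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join anti_join bind_rows distinct count n pull
#'   row_number rename relocate if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code for every non-empty subset of {A,C,G,T}, keyed by the sorted,
# concatenated base set.
IUPAC_BY_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V",
  ACGT = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_BY_SET[[key]]
  if (is.null(code)) abort(paste0("no IUPAC code for base set '", key, "'"))
  code
}

#' Draw random DNA sequences
#' @noRd
random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  bases <- sample(DNA_BASES, sum(lengths), replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  vapply(
    seq_len(n),
    function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
    character(1)
  )
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer"))
  }
  if (x < min) abort(paste0("`", name, "` must be >= ", min))
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    abort(paste0("`", name, "` must be a single number"))
  }
  if (x < lo || x > hi || (open_hi && x >= hi)) {
    abort(paste0("`", name, "` must be in [", lo, ", ", hi, if (open_hi) ")" else "]"))
  }
  invisible(as.numeric(x))
}

# Counts tibbles are wide: a gene_id column plus one numeric column per library.
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}
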