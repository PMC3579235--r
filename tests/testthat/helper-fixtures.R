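# Hand-written miniature fixtures used across test files.

# Three genes, four transcripts; tags are hand-placed CATG + 22 bases.
tiny_transcriptome <- function() {
  pad <- function(x) paste(rep(x, 10), collapse = "")
  tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_id = c("gA.1", "gA.2", "gB.1", "gC.1"),
    sequence = c(
      paste0(pad("AC"), "CATG", strrep("A", 22), pad("GT")),
      paste0(pad("AG"), "CATG", strrep("A", 22), pad("TT")),
      paste0(pad("CT"), "CATG", strrep("C", 22), pad("AA")),
      paste0(pad("GA"), "CATG", strrep("G", 22), pad("CC"))
    )
  )
}

# diamond a -> {b, c} -> d plus a leaf under b; root is d
toy_dag <- function() {
  new_go_dag(tibble::tibble(
    child = c("a", "a", "b", "c", "e"),
    parent = c("b", "c", "d", "d", "b")
  ))
}

counts_tbl <- function(m) sagescape:::matrix_to_counts(m)
counts_mat <- function(tbl) sagescape:::counts_to_matrix(tbl)

# null NB count matrix helper
null_counts <- function(n_genes, libs, mu = 100, phi = 0.2) {
  m <- matrix(stats::rnbinom(n_genes * length(libs), mu = mu, size = 1 / phi),
              n_genes, length(libs),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), libs))
  counts_tbl(m)
}
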