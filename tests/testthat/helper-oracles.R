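# Independent oracles and shared fixtures.

# Plain-R affine-gap local alignment score (textbook three-state DP,
# written independently of the compiled implementation).
sw_oracle_score <- function(query, subject, mat, gap_open, gap_extend) {
  qr <- strsplit(query, "")[[1]]
  sr <- strsplit(subject, "")[[1]]
  m <- length(qr); n <- length(sr)
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(-Inf, m + 1, n + 1)
  Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      M[i, j] <- mat[qr[i - 1], sr[j - 1]] +
        max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     X[i, j - 1] - gap_extend)
      Y[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     Y[i - 1, j] - gap_extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Brute-force containment classification (strict inequalities, HC priority).
brute_assign_category <- function(chrom, lo, hi, models) {
  containing <- Filter(function(m)
    m$chrom == chrom && lo > m$gene_start && hi < m$gene_end, models)
  if (!length(containing)) return("NOVEL")
  if (any(vapply(containing, function(m) m$confidence == "HC", logical(1))))
    "HC" else "LC"
}

random_peptide <- function(len) {
  paste0(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                len, replace = TRUE), collapse = "")
}

# toy two-exon plus-strand gene: exon1 1..9, intron 10..15, exon2 16..24
toy_gene <- function(strand = "+") {
  if (strand == "+") {
    gene_model("toy", "chrT", "+", "HC", rbind(c(1, 9), c(16, 24)))
  } else {
    gene_model("toyM", "chrT", "-", "HC", rbind(c(16, 24), c(1, 9)))
  }
}

# small cached bundle + searches, shared by the search-driven tests
.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_bundle(
      synth_config(seed = 101, n_chroms = 2L, chrom_length_nt = 20000L,
                   n_genes = 10L, n_novel_orfs = 2L))
  }
  .fixture_env$bundle
}

small_hits <- function() {
  if (is.null(.fixture_env$hits)) {
    b <- small_bundle()
    .fixture_env$hits <- tblastn_search(b$peptides, b$genome)
  }
  .fixture_env$hits
}
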