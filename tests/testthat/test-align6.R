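test_that("sw_align matches hand-checkable cases", {
  m <- load_score_matrix("PAM30")
  a <- sw_align("WWWW", "WWWW", "PAM30", 10, 1)
  expect_equal(a$score, 4 * m["W", "W"])
  expect_equal(a$qseq, "WWWW")
  expect_equal(a$sseq, "WWWW")
  # all pair scores negative -> no local alignment
  expect_equal(sw_align("AAAA", "CCCC", "PAM30", 10, 1)$score, 0)
  expect_error(sw_align("", "AAA", "PAM30"), "empty")
})

test_that("sw_align equals the plain-R DP oracle on random instances", {
  set.seed(11)
  for (name in c("PAM30", "BLOSUM90")) {
    mat <- load_score_matrix(name)
    for (i in 1:60) {
      q <- random_peptide(sample(3:12, 1))
      s <- random_peptide(sample(5:40, 1))
      go <- sample(5:12, 1); ge <- sample(1:3, 1)
      expect_equal(sw_align(q, s, mat, go, ge)$score,
                   sw_oracle_score(q, s, mat, go, ge),
                   info = paste(name, q, s, go, ge))
    }
  }
})

test_that("sw_align agrees with Biostrings pairwiseAlignment scores", {
  set.seed(12)
  mat <- load_score_matrix("PAM30")
  sub <- mat[1:20, 1:20]   # standard residues
  for (i in 1:40) {
    q <- random_peptide(sample(4:12, 1))
    s <- random_peptide(sample(10:40, 1))
    ours <- sw_align(q, s, mat, 10, 1)$score
    ref <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = sub,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    if (ref > 0) expect_equal(ours, ref, info = paste(q, s))
  }
})

test_that("alignment gap of length g costs gap_open + g * gap_extend", {
  # identical flanks forced to align across an insertion in the subject
  q <- "WWWWWCCCWWWWW"
  s <- "WWWWWCCCAAAAAAWWWWW"   # 6-residue insertion in the subject
  m <- load_score_matrix("PAM30")
  flank <- 5 * m["W", "W"] + 3 * m["C", "C"] + 5 * m["W", "W"]
  a <- sw_align(q, s, m, 10, 1)
  expect_equal(a$score, flank - (10 + 6 * 1))
  expect_equal(sum(strsplit(a$qseq, "")[[1]] == "-"), 6)
})

test_that("evalue is linear in database size and monotone in score", {
  expect_equal(evalue_ka(50, 10, 2000, 0.3, 0.1),
               2 * evalue_ka(50, 10, 1000, 0.3, 0.1))
  expect_lt(evalue_ka(60, 10, 1000, 0.3, 0.1),
            evalue_ka(50, 10, 1000, 0.3, 0.1))
  expect_equal(evalue_ka(50, 10, 1000, 0.3, 0.1), 1000 * exp(-15),
               tolerance = 1e-12)
  expect_error(evalue_ka(50, 10, 1000, -0.3, 0.1), "positive")
})

test_that("ka_parameters resolves gapped constants with ungapped fallback", {
  ka <- ka_parameters("PAM30", 10, 1)
  expect_true(ka$exact)
  expect_equal(ka$lambda, 0.309)
  expect_equal(ka$K, 0.15)
  expect_warning(ka2 <- ka_parameters("PAM30", 7, 3), "ungapped")
  expect_false(ka2$exact)
})

test_that("planted peptides are found with exact coordinates and strand", {
  set.seed(13)
  pep <- "MKWLVDEGHTR"
  cds <- paste0(vapply(strsplit(pep, "")[[1]], function(a) {
    syn <- names(standard_genetic_code())[standard_genetic_code() == a]
    syn[1]
  }, character(1)), collapse = "")
  left <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  right <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  contig <- paste0(left, cds, right)
  genome <- c(ctg = contig)
  hits <- tblastn_search(c(p = pep), genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$mismatch, 0L)
  expect_equal(hits$gapopen, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$sstart, 301L)
  expect_equal(hits$send, 300L + 3L * nchar(pep))
  # same peptide on the reverse strand: start > end, negative frame
  genome_rc <- c(ctg = reverse_complement(contig))
  hits2 <- tblastn_search(c(p = pep), genome_rc)
  expect_equal(nrow(hits2), 1L)
  expect_lt(hits2$send, hits2$sstart)
  expect_lt(hits2$sframe, 0)
  L <- nchar(contig)
  expect_equal(hits2$sstart, L - hits$sstart + 1L)
  expect_equal(hits2$send, L - hits$send + 1L)
})

test_that("peptide over a planted 6-nt intron gives gapopen 1, gaps 2", {
  set.seed(14)
  pep <- "MKWLVDEGHTRYFNQAEK"
  syn <- function(a) names(standard_genetic_code())[standard_genetic_code() == a][1]
  cds <- paste0(vapply(strsplit(pep, "")[[1]], syn, character(1)), collapse = "")
  # split the CDS mid-peptide and insert a 6-nt intron at a codon boundary
  contig <- paste0(strrep("T", 90), substr(cds, 1, 27), "GGGGGG",
                   substr(cds, 28, nchar(cds)), strrep("T", 90))
  hits <- tblastn_search(c(p = pep), c(ctg = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gapopen, 1L)
  expect_equal(hits$gaps, 2L)
  expect_equal(hits$qstart, 1L)
  expect_equal(hits$qend, nchar(pep))
})

test_that("hit invariants and filters hold on synthetic hits", {
  hits <- small_hits()
  expect_gt(nrow(hits), 50)
  expect_equal(nchar(hits$qseq), hits$length)
  expect_equal(nchar(hits$sseq), hits$length)
  gaps_q <- vapply(strsplit(hits$qseq, ""), function(x) sum(x == "-"), integer(1))
  gaps_s <- vapply(strsplit(hits$sseq, ""), function(x) sum(x == "-"), integer(1))
  expect_equal(hits$gaps, gaps_q + gaps_s)
  expect_true(all(hits$gapopen <= hits$gaps))
  # genomic footprint = 3 x subject-consuming columns
  expect_equal(abs(hits$send - hits$sstart) + 1L, 3L * (hits$length - gaps_s))
  # query accounting
  expect_equal(hits$qend - hits$qstart + 1L + gaps_q, hits$length)
  expect_equal(hits$pident, round(100 * hits$nident / hits$length, 3))
  # filters: evalue and coverage
  p <- alignment_params()
  expect_true(all(hits$evalue <= p$evalue_cutoff))
  expect_true(all(100 * (hits$qend - hits$qstart + 1) / hits$qlen >=
                  p$min_query_coverage_pct))
  expect_true(all(hits$strand == ifelse(hits$sframe > 0, "+", "-")))
})

test_that("relaxing filters never removes hits", {
  b <- small_bundle()
  peps <- b$peptides[1:40]
  strictp <- alignment_params()
  relaxed <- alignment_params(evalue_cutoff = 10,
                              min_query_coverage_pct = 0)
  h1 <- tblastn_search(peps, b$genome, strictp)
  h2 <- tblastn_search(peps, b$genome, relaxed)
  key <- function(h) paste(h$qaccver, h$saccver, h$sstart, h$send, h$sframe)
  expect_true(all(key(h1) %in% key(h2)))
  expect_gte(nrow(h2), nrow(h1))
})

test_that("searching the reverse-complemented genome mirrors all hits", {
  b <- small_bundle()
  peps <- b$peptides[1:25]
  h1 <- tblastn_search(peps, b$genome)
  grc <- vapply(b$genome, reverse_complement, character(1))
  h2 <- tblastn_search(peps, grc)
  L <- nchar(b$genome[1])
  key1 <- paste(h1$qaccver, h1$saccver, L - h1$sstart + 1L, L - h1$send + 1L,
                -sign(h1$sframe))
  key2 <- paste(h2$qaccver, h2$saccver, h2$sstart, h2$send, sign(h2$sframe))
  expect_setequal(key1, key2)
})

test_that("single-exon planted peptides are recalled with exact intervals", {
  b <- small_bundle()
  tr <- b$truth[b$truth$n_blocks == 1L & b$truth$source == "gene", ]
  hits <- small_hits()
  found <- 0L
  for (i in seq_len(nrow(tr))) {
    bl <- parse_blocks(tr$blocks[i])
    hh <- hits[hits$qaccver == tr$peptide_id[i], , drop = FALSE]
    ok <- any(hh$saccver == tr$chrom[i] &
              pmin(hh$sstart, hh$send) == bl[1, "start"] &
              pmax(hh$sstart, hh$send) == bl[1, "end"])
    found <- found + ok
  }
  expect_gte(found / nrow(tr), 0.99)
})

test_that("empty inputs and short contigs are handled", {
  expect_equal(nrow(tblastn_search(character(0), c(c1 = "ACGTACGT"))), 0L)
  expect_warning(h <- tblastn_search(c(p = "MKLV"), c(tiny = "AC")),
                 "shorter than 3")
  expect_equal(nrow(h), 0L)
})

test_that("hit tables round-trip through the 25-column tabular format", {
  hits <- small_hits()[1:20, ]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, tmp)
  back <- read_hit_table(tmp)
  expect_equal(back$qaccver, hits$qaccver)
  expect_equal(back$sstart, hits$sstart)
  expect_equal(back$send, hits$send)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$qseq, hits$qseq)
  expect_equal(ncol(read.table(tmp, sep = "\t")), 25L)
})
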