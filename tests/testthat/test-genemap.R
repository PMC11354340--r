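test_that("gene_model validates and orders exons", {
  g <- gene_model("g1", "chr1", "+", "HC", rbind(c(16, 24), c(1, 9)))
  expect_equal(g$exons[, "start"], c(1L, 16L))
  gm <- gene_model("g2", "chr1", "-", "LC", rbind(c(1, 9), c(16, 24)))
  expect_equal(gm$exons[, "start"], c(16L, 1L))   # transcription order
  expect_error(gene_model("g3", "chr1", "+", "HC",
                          rbind(c(1, 10), c(5, 20))), "overlapping")
  expect_message(gene_model("g4", "chr1", "+", "HC", rbind(c(1, 10))),
                 "not divisible by 3")
})

test_that("parse_gff3 recovers toy gene structures", {
  g1 <- gene_model("alpha", "chr1", "+", "HC",
                   rbind(c(101, 160), c(221, 280)))
  g2 <- gene_model("beta", "chr2", "-", "HC",
                   rbind(c(501, 560), c(401, 460)))
  # replica of a five-exon / four-intron test-gene structure
  g3 <- gene_model("gamma", "chr1", "+", "HC",
                   rbind(c(1001, 1060), c(1121, 1180), c(1241, 1300),
                         c(1361, 1420), c(1481, 1540)))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(alpha = g1, beta = g2, gamma = g3), tmp)
  models <- parse_gff3(tmp, "HC")
  expect_length(models, 3)
  expect_equal(models$alpha$gene_start, 101L)
  expect_equal(models$alpha$gene_end, 280L)
  expect_equal(unname(models$alpha$exons), unname(g1$exons))
  # minus-strand exons come back in transcription order
  expect_equal(models$beta$exons[, "start"], c(501L, 401L))
  expect_equal(models$beta$strand, "-")
  expect_equal(nrow(models$gamma$exons), 5L)
  expect_equal(models$gamma$confidence, "HC")
})

test_that("exon_frames tracks intron-length phase shifts", {
  # intron length 6 (10..15): both exons in the same genomic frame
  g6 <- toy_gene("+")
  f6 <- exon_frames(g6)
  expect_equal(f6[1], f6[2])
  expect_false(attr(f6, "has_frameshift"))
  # intron length 7 (10..16): downstream frame differs
  g7 <- gene_model("t7", "chrT", "+", "HC", rbind(c(1, 9), c(17, 25)))
  f7 <- exon_frames(g7)
  expect_true(f7[1] != f7[2])
  expect_true(attr(f7, "has_frameshift"))
  # translating each exon in its assigned frame matches the protein:
  # one frame-shifting intron leaves exactly one exon in another frame
  set.seed(21)
  b <- small_bundle()
  n_checked <- 0L
  for (m in b$models) {
    fr <- exon_frames(m, contig_length = nchar(b$genome[[m$chrom]]))
    contig <- b$genome[[m$chrom]]
    prot <- b$proteins[[m$gene_id]]
    for (i in seq_len(nrow(m$exons))) {
      tf <- translate_frame(contig, fr[i])
      piece <- if (m$strand == "+") {
        substr(contig, m$exons[i, "start"], m$exons[i, "end"])
      } else {
        reverse_complement(substr(contig, m$exons[i, "start"],
                                  m$exons[i, "end"]))
      }
      expect_true(grepl(translate_frame(piece, 1), tf, fixed = TRUE),
                  info = paste(m$gene_id, "exon", i))
      n_checked <- n_checked + 1L
    }
    # frame labels recompute consistently under a whole-gene 3k-nt shift
    shifted <- m
    shifted$exons <- m$exons + 300L
    expect_equal(unclass(exon_frames(shifted,
                                     nchar(b$genome[[m$chrom]]) + 300L)),
                 unclass(fr))
  }
  expect_gt(n_checked, 20)
})

test_that("map_peptide_to_genome walks exons exactly", {
  g <- toy_gene("+")
  mp <- map_peptide_to_genome(2, 5, g)
  expect_equal(unname(mp$blocks), cbind(c(4L, 16L), c(9L, 21L)),
               ignore_attr = TRUE)
  mp1 <- map_peptide_to_genome(1, 3, g)
  expect_equal(nrow(mp1$blocks), 1L)
  expect_equal(unname(mp1$blocks[1, ]), c(1L, 9L))
  expect_error(map_peptide_to_genome(1, 99, g), "out of range.*toy")
})

test_that("spliced-mapping round trip holds for every bundle peptide", {
  b <- small_bundle()
  tr <- b$truth[b$truth$source == "gene", ]
  for (i in seq_len(nrow(tr))) {
    mp <- map_peptide_to_genome(tr$aa_start[i], tr$aa_end[i],
                                b$models[[tr$gene_id[i]]],
                                contig_length = nchar(b$genome[[tr$chrom[i]]]))
    expect_equal(translate_mapping(mp, b$genome), tr$seq[i],
                 info = tr$peptide_id[i])
    expect_equal(unname(mp$blocks), unname(parse_blocks(tr$blocks[i])),
                 info = tr$peptide_id[i])
    expect_equal(sum(mp$blocks[, 2] - mp$blocks[, 1] + 1L),
                 3L * (tr$aa_end[i] - tr$aa_start[i] + 1L))
  }
})

test_that("assign_hits applies strict containment with HC priority", {
  models <- list(
    gene_model("hcA", "chr1", "+", "HC", rbind(c(51, 500)), 50, 500),
    gene_model("lcB", "chr1", "+", "LC", rbind(c(40, 600)), 40, 600),
    gene_model("hcC", "chr2", "+", "HC", rbind(c(100, 400)), 100, 400))
  idx <- gene_index(models)
  hits <- data.frame(
    qaccver = c("p1", "p2", "p3", "p4"),
    saccver = c("chr1", "chr1", "chr2", "chr9"),
    sstart = c(100L, 50L, 250L, 10L),
    send = c(130L, 130L, 200L, 40L),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  expect_warning(asg <- assign_hits(hits, idx), "absent from the")
  # inside both HC and LC spans: HC category, both genes listed
  expect_equal(asg$category[1], "HC")
  expect_equal(asg$gene_id[1], "hcA")
  expect_setequal(strsplit(asg$containing_genes[1], ",")[[1]],
                  c("hcA", "lcB"))
  # start == gene_start: strict inequality excludes hcA, leaves LC
  expect_equal(asg$category[2], "LC")
  expect_equal(asg$gene_id[2], "lcB")
  # minus-strand hit is normalized before comparison
  expect_equal(asg$category[3], "HC")
  # unknown chromosome -> NOVEL
  expect_equal(asg$category[4], "NOVEL")
  expect_equal(asg$containing_genes[4], "")
})

test_that("assign_hits matches brute-force containment on random hits", {
  set.seed(22)
  b <- small_bundle()
  idx <- gene_index(b$models)
  n <- 400
  chroms <- sample(names(b$genome), n, replace = TRUE)
  lo <- sample.int(19000L, n)
  hi <- pmin(lo + sample.int(2000L, n), 20000L)
  hits <- data.frame(qaccver = sprintf("r%04d", seq_len(n)),
                     saccver = chroms, sstart = lo, send = hi,
                     strand = sample(c("+", "-"), n, TRUE),
                     stringsAsFactors = FALSE)
  asg <- assign_hits(hits, idx)
  ref <- vapply(seq_len(n), function(i)
    brute_assign_category(chroms[i], lo[i], hi[i], b$models), character(1))
  expect_equal(asg$category, ref)
})

test_that("stitch_frameshift merges junction pieces and nothing else", {
  mk <- function(q, chrom, qs, qe, ss, se, fr, qlen = 20L)
    data.frame(qaccver = q, saccver = chrom, qstart = qs, qend = qe,
               sstart = ss, send = se, sframe = fr,
               strand = if (fr > 0) "+" else "-", qlen = qlen,
               stringsAsFactors = FALSE)
  # textbook pair: abutting in query, nearby, different frames
  h <- rbind(mk("p", "c1", 1, 10, 101, 130, 3),
             mk("p", "c1", 11, 20, 201, 230, 2))
  st <- stitch_frameshift(h)
  expect_equal(nrow(st), 1L)
  expect_true(st$merged)
  expect_equal(st$n_blocks, 2L)
  expect_equal(st$aa_start, 1L)
  expect_equal(st$aa_end, 20L)
  # different peptides never merge
  h2 <- rbind(mk("p", "c1", 1, 10, 101, 130, 3),
              mk("q", "c1", 11, 20, 201, 230, 2))
  expect_true(all(!stitch_frameshift(h2)$merged))
  # beyond max_genomic_gap: no merge
  h3 <- rbind(mk("p", "c1", 1, 10, 101, 130, 3),
              mk("p", "c1", 11, 20, 50101, 50130, 2))
  expect_true(all(!stitch_frameshift(h3)$merged))
  # same frame: no merge
  h4 <- rbind(mk("p", "c1", 1, 10, 101, 130, 3),
              mk("p", "c1", 11, 20, 201, 230, 3))
  expect_true(all(!stitch_frameshift(h4)$merged))
  # query-overlapping pieces with disjoint genomic footprints do merge
  h5 <- rbind(mk("p", "c1", 1, 14, 101, 142, 3),
              mk("p", "c1", 10, 20, 201, 233, 2))
  expect_true(any(stitch_frameshift(h5)$merged))
})
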