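test_that("tryptic digestion applies the cleavage rule", {
  d <- tryptic_digest("AAKBBRCC")
  expect_equal(d$peptide, c("AAK", "BBR", "CC"))
  expect_equal(d$aa_start, c(1L, 4L, 7L))
  expect_equal(d$aa_end, c(3L, 6L, 8L))
  # KP suppression
  expect_equal(tryptic_digest("AAKPBB")$peptide, "AAKPBB")
  # missed cleavage adds the joined window
  d1 <- tryptic_digest("AAKBBR", missed_cleavages = 1)
  expect_setequal(d1$peptide, c("AAK", "BBR", "AAKBBR"))
  # length filter
  d2 <- tryptic_digest("AAKBBRCCCCCCCCC", min_len = 4)
  expect_equal(d2$peptide, "CCCCCCCCC")
  expect_equal(nrow(tryptic_digest("")), 0L)
})

test_that("generation is deterministic for a fixed seed", {
  b1 <- generate_bundle(synth_config(seed = 5, n_genes = 6L,
                                     chrom_length_nt = 15000L,
                                     n_chroms = 1L, n_novel_orfs = 1L))
  b2 <- generate_bundle(synth_config(seed = 5, n_genes = 6L,
                                     chrom_length_nt = 15000L,
                                     n_chroms = 1L, n_novel_orfs = 1L))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$peptides, b2$peptides)
  b3 <- generate_bundle(synth_config(seed = 6, n_genes = 6L,
                                     chrom_length_nt = 15000L,
                                     n_chroms = 1L, n_novel_orfs = 1L))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("bundle internal consistency: peptides, proteins, flags", {
  b <- small_bundle()
  tr <- b$truth
  # every gene peptide is a substring of its source protein
  gene_rows <- tr$source == "gene"
  expect_true(all(vapply(which(gene_rows), function(i)
    substr(b$proteins[[tr$gene_id[i]]], tr$aa_start[i], tr$aa_end[i]) ==
      tr$seq[i], logical(1))))
  # block lengths always sum to 3 x peptide length
  for (i in seq_len(nrow(tr))) {
    bl <- parse_blocks(tr$blocks[i])
    expect_equal(sum(bl[, "end"] - bl[, "start"] + 1L),
                 3L * (tr$aa_end[i] - tr$aa_start[i] + 1L))
  }
  # spliced CDS of every gene translates without internal stops
  for (m in b$models) {
    prot <- b$proteins[[m$gene_id]]
    expect_false(grepl("*", prot, fixed = TRUE))
    mp <- map_peptide_to_genome(1, nchar(prot), m)
    expect_equal(translate_mapping(mp, b$genome), prot)
  }
  # multi-exon genes carry at least one intron-spanning peptide, and
  # frame-shifting genes at least one junction-crossing peptide
  for (m in b$models) {
    if (nrow(m$exons) < 2) next
    g <- tr[tr$gene_id %in% m$gene_id, ]
    expect_true(any(g$introns_crossed > 0), info = m$gene_id)
    fr <- exon_frames(m, contig_length = nchar(b$genome[[m$chrom]]))
    if (attr(fr, "has_frameshift")) {
      expect_true(any(g$crosses_frameshift), info = m$gene_id)
    }
  }
  # tissues partition the searched peptides
  expect_setequal(unlist(lapply(b$tissues, names)), names(b$peptides))
})

test_that("novel ORFs sit outside gene spans and earn NOVEL assignments", {
  b <- small_bundle()
  orfs <- b$novel_orfs
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    for (m in b$models) {
      if (m$chrom != orfs$chrom[i]) next
      expect_true(orfs$end[i] < m$gene_start || orfs$start[i] > m$gene_end)
    }
  }
  # n = 0 leaves the genome untouched
  g0 <- plant_novel_orfs(b$genome, data.frame(chrom = character(0),
                                              start = integer(0),
                                              end = integer(0)), 0L)
  expect_identical(g0$genome, b$genome)
  # end-to-end: searched novel peptides classify as NOVEL
  hits <- small_hits()
  asg <- assign_hits(hits, gene_index(b$models))
  novel_ids <- b$truth$peptide_id[b$truth$source == "novel"]
  nov <- asg[asg$peptide %in% novel_ids, ]
  expect_gt(nrow(nov), 0)
  expect_true(all(nov$category == "NOVEL"))
})

test_that("gene-derived peptides classify to their true gene end-to-end", {
  b <- small_bundle()
  asg <- assign_hits(small_hits(), gene_index(b$models))
  tr <- b$truth
  merged <- merge(asg, tr[, c("peptide_id", "gene_id", "source")],
                  by.x = "peptide", by.y = "peptide_id")
  gd <- merged[merged$source == "gene", ]
  expect_gte(mean(gd$gene_id.x == gd$gene_id.y, na.rm = TRUE), 0.99)
})

test_that("frameshift_intron_fraction 0 yields no junction-crossing flags", {
  b0 <- generate_bundle(synth_config(seed = 9, n_genes = 8L,
                                     chrom_length_nt = 20000L,
                                     n_chroms = 1L,
                                     frameshift_intron_fraction = 0))
  expect_false(any(b0$truth$crosses_frameshift))
  for (m in b0$models) {
    fr <- exon_frames(m, contig_length = 20000L)
    expect_false(attr(fr, "has_frameshift"), info = m$gene_id)
  }
})

test_that("frame-shift census tracks 1-(1-p)^introns", {
  p <- 0.5
  obs <- 0; expv <- 0; varv <- 0
  for (seed in 61:63) {
    b <- generate_bundle(synth_config(seed = seed, n_genes = 30L,
                                      n_chroms = 3L,
                                      chrom_length_nt = 60000L,
                                      frameshift_intron_fraction = p,
                                      n_novel_orfs = 0L))
    for (m in b$models) {
      ni <- nrow(m$exons) - 1L
      if (ni == 0L) next
      fr <- exon_frames(m, contig_length = b$config$chrom_length_nt)
      obs <- obs + attr(fr, "has_frameshift")
      pg <- 1 - (1 - p)^ni
      expv <- expv + pg
      varv <- varv + pg * (1 - pg)
    }
  }
  expect_lt(abs(obs - expv), 4 * sqrt(varv) + 1)
})

test_that("mutation_rate lowers recovered identity in expectation", {
  base <- list(seed = 71, n_genes = 6L, n_chroms = 1L,
               chrom_length_nt = 15000L, n_novel_orfs = 0L)
  search <- function(rate) {
    cfg <- do.call(synth_config, c(base, list(mutation_rate = rate)))
    b <- generate_bundle(cfg)
    tblastn_search(b$peptides, b$genome, alignment_params(evalue_cutoff = 1))
  }
  h0 <- search(0); h1 <- search(0.05); h2 <- search(0.15)
  # without mutations the typical hit is a perfect copy (gapped
  # intron-bridging hits and chance partial extensions dilute the mean)
  expect_equal(stats::median(h0$pident), 100)
  expect_gt(mean(h0$pident), mean(h1$pident))
  expect_gt(mean(h1$pident), mean(h2$pident))
})

test_that("infeasible geometry fails loudly and bundles write to disk", {
  expect_error(generate_bundle(synth_config(seed = 1, n_genes = 50L,
                                            n_chroms = 1L,
                                            chrom_length_nt = 5000L)),
               "infeasible geometry")
  b <- generate_bundle(synth_config(seed = 8, n_genes = 4L, n_chroms = 1L,
                                    chrom_length_nt = 12000L,
                                    n_novel_orfs = 1L, n_tissues = 2L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fa", "hc.gff3",
                                               "lc.gff3", "proteins.fa",
                                               "truth.tsv", "truth.bed")))))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, b$genome)
  models <- c(parse_gff3(file.path(dir, "hc.gff3"), "HC"),
              parse_gff3(file.path(dir, "lc.gff3"), "LC"))
  expect_length(models, length(b$models))
  m0 <- b$models[[names(models)[1]]]
  expect_equal(models[[1]]$exons, m0$exons)
  expect_equal(models[[1]]$strand, m0$strand)
})
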