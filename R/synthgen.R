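## Seeded synthetic-fixture generator: genomes, HC/LC gene models with
## controlled exon/intron structure (including frame-shifting introns),
## proteins, tryptic peptides with tissue labels, planted novel ORFs, and
## exact ground-truth genomic mappings.
##
## Gene construction works protein-first: each gene's protein is assembled
## from tryptic peptides, with "anchor" peptides deliberately laid across
## every exon/exon junction so that intron-spanning and frame-shift-
## crossing peptides exist whenever the geometry allows.  Exon lengths are
## multiples of 3 (junctions at codon boundaries); genomic frame shifts
## come from introns whose length is not a multiple of 3.

#' Synthetic dataset configuration
#'
#' Defaults describe a desk-scale stand-in for a real genome + annotation
#' + multi-tissue peptide collection: a few 50-kb chromosomes, two dozen
#' multi-exon genes (a quarter of introns frame-shifting, as in a gene
#' with one shifted exon out of several), mixed strands, a few intergenic
#' ORFs, and complete tryptic digests.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_length_nt chromosome count and length.
#' @param n_genes total genes to place.
#' @param hc_fraction fraction of genes labelled High Confidence.
#' @param exon_count_range exons per gene (inclusive range).
#' @param exon_length_range exon length in nt; values are forced to
#'   multiples of 3 so the total CDS length is too.
#' @param intron_length_range intron length range in nt.
#' @param frameshift_intron_fraction probability that an intron length is
#'   not a multiple of 3 (shifting the downstream genomic frame).
#' @param minus_strand_prob probability a gene sits on the minus strand.
#' @param n_novel_orfs intergenic ORFs planted outside all gene spans.
#' @param digest list: `missed_cleavages`, `min_len`, `max_len`.
#' @param n_tissues number of tissue labels peptides are split across.
#' @param mutation_rate per-residue substitution probability applied to
#'   the searched peptide copies (for mismatch behaviour testing).
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_chroms = 3L, chrom_length_nt = 50000L,
                         n_genes = 24L, hc_fraction = 0.75,
                         exon_count_range = c(2L, 5L),
                         exon_length_range = c(60L, 180L),
                         intron_length_range = c(60L, 300L),
                         frameshift_intron_fraction = 0.25,
                         minus_strand_prob = 0.4, n_novel_orfs = 4L,
                         digest = list(missed_cleavages = 0L, min_len = 8L,
                                       max_len = 30L),
                         n_tissues = 3L, mutation_rate = 0) {
  stopifnot(exon_count_range[1] >= 1, exon_count_range[2] >= exon_count_range[1],
            exon_length_range[1] >= 30, intron_length_range[1] >= 4,
            hc_fraction >= 0, hc_fraction <= 1,
            frameshift_intron_fraction >= 0, frameshift_intron_fraction <= 1,
            minus_strand_prob >= 0, minus_strand_prob <= 1,
            mutation_rate >= 0, mutation_rate <= 1, n_tissues >= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length_nt = as.integer(chrom_length_nt),
                 n_genes = as.integer(n_genes), hc_fraction = hc_fraction,
                 exon_count_range = as.integer(exon_count_range),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 frameshift_intron_fraction = frameshift_intron_fraction,
                 minus_strand_prob = minus_strand_prob,
                 n_novel_orfs = as.integer(n_novel_orfs), digest = digest,
                 n_tissues = as.integer(n_tissues),
                 mutation_rate = mutation_rate),
            class = "synth_config")
}

## amino acids used for random peptide bodies (no K/R internally so the
## tryptic digest reproduces the construction; no C/W/M bias concerns here)
BODY_AA <- c("A", "N", "D", "Q", "E", "G", "H", "I", "L", "M", "F",
             "S", "T", "W", "Y", "V", "C", "P")

## sample one element of a vector (safe for length-1 vectors)
sample1 <- function(v) v[sample.int(length(v), 1L)]

random_tryptic_peptide <- function(len) {
  stopifnot(len >= 2)
  body <- sample(BODY_AA, len - 1L, replace = TRUE)
  body[1] <- sample1(setdiff(BODY_AA, "P"))  # no P after a cut site
  paste0(paste0(body, collapse = ""), sample1(c("K", "R")))
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P; windows with up
#' to `missed_cleavages` internal sites are emitted, length-filtered, in
#' order of start position then increasing span.
#'
#' @param protein protein sequence.
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len length filter (AA).
#' @return data.frame: `peptide`, `aa_start`, `aa_end` (1-based inclusive).
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L, min_len = 1L,
                           max_len = Inf) {
  res <- strsplit(toupper(protein), "")[[1]]
  n <- length(res)
  if (n == 0L) {
    return(data.frame(peptide = character(0), aa_start = integer(0),
                      aa_end = integer(0)))
  }
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[pmin(cuts + 1L, n)] != "P" | cuts == n]
  bounds <- unique(c(0L, cuts[cuts < n], n))   # fragment end positions
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nf <- length(starts)
  rows <- list()
  for (i in seq_len(nf)) {
    for (j in i:min(i + missed_cleavages, nf)) {
      len <- ends[j] - starts[i] + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste0(res[starts[i]:ends[j]], collapse = ""),
        aa_start = starts[i], aa_end = ends[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), aa_start = integer(0),
                      aa_end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$aa_start, out$aa_end), , drop = FALSE]
}

## reverse-translate a protein with uniform synonymous codon choice
reverse_translate <- function(protein, code = standard_genetic_code()) {
  syn <- split(names(code), unname(code))
  res <- strsplit(protein, "")[[1]]
  paste0(vapply(res, function(a) {
    cods <- syn[[a]]
    sample1(cods)
  }, character(1)), collapse = "")
}

random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## build one gene: protein laid out as tryptic peptides with anchor
## peptides across each exon junction, exon lengths multiples of 3.
build_gene_plan <- function(cfg) {
  k <- sample1(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]))
  elen <- 3L * sample(seq(cfg$exon_length_range[1] %/% 3L,
                          cfg$exon_length_range[2] %/% 3L), k, replace = TRUE)
  P <- sum(elen) %/% 3L
  bounds <- cumsum(elen %/% 3L)[seq_len(max(k - 1L, 0L))]  # internal AA bounds
  peps <- character(0)
  pos <- 1L
  for (b in bounds) {
    a_start <- b - 8L
    a_end <- min(b + 9L, P)
    if (a_start <= pos) { a_start <- pos } else {
      f <- a_start - pos
      while (f > 15L) {
        l <- sample1(8:min(14L, f - 8L))
        peps <- c(peps, random_tryptic_peptide(l))
        pos <- pos + l
        f <- a_start - pos
      }
      if (f >= 8L) {
        peps <- c(peps, random_tryptic_peptide(f))
        pos <- a_start
      } else if (f > 0L) {
        a_start <- a_start - f                # anchor absorbs the slack
      }
    }
    peps <- c(peps, random_tryptic_peptide(a_end - a_start + 1L))
    pos <- a_end + 1L
  }
  f <- P - pos + 1L
  while (f > 15L) {
    l <- sample1(8:min(14L, f - 8L))
    peps <- c(peps, random_tryptic_peptide(l))
    pos <- pos + l
    f <- P - pos + 1L
  }
  if (f >= 2L) {
    peps <- c(peps, random_tryptic_peptide(f))
  } else if (f == 1L) {
    peps <- c(peps, "G")                      # trailing residue, dropped by digest
  }
  protein <- paste0(peps, collapse = "")
  stopifnot(nchar(protein) == P)
  introns <- integer(0)
  fs_intron <- logical(0)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      len <- sample1(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]))
      fs <- stats::runif(1) < cfg$frameshift_intron_fraction
      if (fs) {
        len <- len - (len %% 3L) + sample1(1:2)
      } else {
        len <- len - (len %% 3L)
        if (len < cfg$intron_length_range[1]) len <- len + 3L
      }
      introns <- c(introns, len)
      fs_intron <- c(fs_intron, fs)
    }
  }
  list(protein = protein, exon_lens = elen, intron_lens = introns,
       frameshift_introns = fs_intron, n_exons = k)
}

#' Plant novel open reading frames into intergenic space
#'
#' Writes `n` ORFs (ATG + stop-free tryptic body + TAA) into regions of
#' the genome not covered by any gene span.  Their peptides are reported
#' so the caller can label them NOVEL in the ground truth.
#'
#' @param genome named character vector of contigs (modified copies
#'   returned).
#' @param gene_spans data.frame with `chrom`, `start`, `end`.
#' @param n number of ORFs to plant.
#' @param aa_length_range protein length range (AA) per ORF.
#' @return list: `genome` (updated), `orfs` (data.frame: orf_id, chrom,
#'   start, end, strand, protein).
#' @export
plant_novel_orfs <- function(genome, gene_spans, n, aa_length_range = c(30L, 80L)) {
  orfs <- list()
  if (n == 0L) return(list(genome = genome, orfs = data.frame()))
  margin <- 50L
  for (o in seq_len(n)) {
    P <- sample1(seq(aa_length_range[1], aa_length_range[2]))
    npep <- max(1L, P %/% 12L)
    lens <- rep(P %/% npep, npep)
    lens[npep] <- P - sum(lens[-npep])
    prot <- paste0(vapply(lens, random_tryptic_peptide, character(1)),
                   collapse = "")
    orf_nt <- paste0("ATG", reverse_translate(prot), "TAA")
    need <- nchar(orf_nt) + 2L * margin
    placed <- FALSE
    for (attempt in seq_len(50L)) {
      ci <- sample1(seq_along(genome))
      chrom <- names(genome)[ci]
      occ <- gene_spans[gene_spans$chrom == chrom, , drop = FALSE]
      if (length(orfs)) {
        prev <- do.call(rbind, lapply(orfs, function(x)
          data.frame(chrom = x$chrom, start = x$start, end = x$end)))
        occ <- rbind(occ[, c("chrom", "start", "end")],
                     prev[prev$chrom == chrom, , drop = FALSE])
      }
      L <- nchar(genome[[ci]])
      free_start <- sample.int(max(L - need, 1L), 1L)
      cand <- c(free_start + margin, free_start + margin + nchar(orf_nt) - 1L)
      if (nrow(occ) &&
          any(cand[1] <= occ$end + margin & cand[2] >= occ$start - margin)) next
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      seqnt <- if (strand == "+") orf_nt else reverse_complement(orf_nt)
      substr(genome[[ci]], cand[1], cand[2]) <- seqnt
      orfs[[length(orfs) + 1L]] <- list(orf_id = sprintf("orf%03d", o),
                                        chrom = chrom, start = cand[1],
                                        end = cand[2], strand = strand,
                                        protein = prot)
      placed <- TRUE
      break
    }
    if (!placed) {
      warning("could not place ORF ", o, ": insufficient intergenic space")
    }
  }
  orf_df <- if (length(orfs)) {
    do.call(rbind, lapply(orfs, function(x)
      data.frame(orf_id = x$orf_id, chrom = x$chrom, start = x$start,
                 end = x$end, strand = x$strand, protein = x$protein,
                 stringsAsFactors = FALSE)))
  } else data.frame()
  list(genome = genome, orfs = orf_df)
}

## ground-truth blocks for an AA interval, computed position-by-position
## from the gene's local layout (independent of the genemap exon walk):
## CDS nt -> gene-local nt (adding intron lengths) -> genomic nt.
truth_blocks <- function(aa_start, aa_end, exon_lens, intron_lens,
                         offset, gene_local_len, strand, contig_len) {
  cds_pos <- (3L * aa_start - 2L):(3L * aa_end)
  cum_ex <- cumsum(exon_lens)
  exon_of <- findInterval(cds_pos - 1L, cum_ex) + 1L
  intron_before <- c(0L, cumsum(intron_lens))[exon_of]
  local_pos <- cds_pos + intron_before
  genomic <- if (strand == "+") {
    offset + local_pos - 1L
  } else {
    offset + gene_local_len - local_pos
  }
  gsort <- sort(genomic)
  breaks <- which(diff(gsort) != 1L)
  bs <- c(gsort[1], gsort[breaks + 1L])
  be <- c(gsort[breaks], gsort[length(gsort)])
  # per-block genomic frame: locate a codon start inside each block
  frames <- integer(length(bs))
  for (bi in seq_along(bs)) {
    pos_in <- which(genomic >= bs[bi] & genomic <= be[bi])
    cstart <- cds_pos[pos_in][(cds_pos[pos_in] %% 3L) == 1L][1]
    if (is.na(cstart)) { frames[bi] <- NA_integer_; next }
    g <- genomic[which(cds_pos == cstart)]
    frames[bi] <- if (strand == "+") ((g - 1L) %% 3L) + 1L
      else -(((contig_len - g) %% 3L) + 1L)
  }
  list(starts = bs, ends = be, frames = frames,
       exons_touched = sort(unique(exon_of)))
}

#' Generate a complete synthetic bundle
#'
#' Deterministic for a fixed seed.  Guarantees at least one
#' intron-spanning peptide per multi-exon gene and at least one
#' junction-crossing peptide per frame-shifting intron whenever the exon
#' geometry allows (anchor peptides are laid across every junction).
#' Novel ORFs are placed outside all gene spans.
#'
#' @param cfg a [synth_config()].
#' @return object of class `"synth_bundle"`: list with `config`, `genome`,
#'   `models` (named list of [gene_model()]s), `proteins`, `peptides`
#'   (searchable copies, possibly mutated), `tissues` (named list of
#'   per-tissue peptide vectors), `truth` (ground-truth data.frame),
#'   `novel_orfs`.
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  genome <- stats::setNames(
    vapply(seq_len(cfg$n_chroms), function(i) random_dna(cfg$chrom_length_nt),
           character(1)),
    sprintf("chr%d", seq_len(cfg$n_chroms)))
  cursors <- rep(1L, cfg$n_chroms)
  models <- list()
  proteins <- character(0)
  gene_meta <- list()
  n_hc <- round(cfg$n_genes * cfg$hc_fraction)
  for (g in seq_len(cfg$n_genes)) {
    plan <- build_gene_plan(cfg)
    cds <- reverse_translate(plan$protein)
    ex_local <- list(); pos <- 1L; pieces <- character(0)
    cum <- 0L
    for (i in seq_len(plan$n_exons)) {
      e <- plan$exon_lens[i]
      pieces <- c(pieces, substr(cds, cum + 1L, cum + e))
      ex_local[[i]] <- c(pos, pos + e - 1L)
      pos <- pos + e
      cum <- cum + e
      if (i < plan$n_exons) {
        il <- plan$intron_lens[i]
        pieces <- c(pieces, random_dna(il))
        pos <- pos + il
      }
    }
    local_seq <- paste0(pieces, collapse = "")
    glen <- nchar(local_seq)
    strand <- if (stats::runif(1) < cfg$minus_strand_prob) "-" else "+"
    gap <- sample1(300:900)
    ci <- which(cursors + gap + glen + 300L <= cfg$chrom_length_nt)
    if (!length(ci)) {
      stop("infeasible geometry: chromosomes too short for ", cfg$n_genes,
           " genes (placed ", g - 1L, ")")
    }
    ci <- ci[which.min(cursors[ci])]
    offset <- cursors[ci] + gap
    seg <- if (strand == "+") local_seq else reverse_complement(local_seq)
    substr(genome[[ci]], offset, offset + glen - 1L) <- seg
    cursors[ci] <- offset + glen
    gid <- sprintf("gene%03d", g)
    exons <- t(vapply(ex_local, function(b) {
      if (strand == "+") offset + b - 1L
      else c(offset + glen - b[2], offset + glen - b[1])
    }, integer(2)))
    colnames(exons) <- c("start", "end")
    conf <- if (g <= n_hc) "HC" else "LC"
    models[[gid]] <- gene_model(gid, names(genome)[ci], strand, conf, exons)
    proteins[gid] <- plan$protein
    gene_meta[[gid]] <- list(plan = plan, offset = offset, glen = glen,
                             strand = strand, chrom = names(genome)[ci],
                             contig_len = cfg$chrom_length_nt)
  }

  gene_spans <- do.call(rbind, lapply(models, function(m)
    data.frame(chrom = m$chrom, start = m$gene_start, end = m$gene_end,
               stringsAsFactors = FALSE)))
  planted <- plant_novel_orfs(genome, gene_spans, cfg$n_novel_orfs)
  genome <- planted$genome
  orfs <- planted$orfs

  # tryptic peptides + ground truth
  truth_rows <- list()
  pep_seqs <- character(0)
  idx <- 0L
  dg <- cfg$digest
  for (gid in names(models)) {
    meta <- gene_meta[[gid]]
    peps <- tryptic_digest(proteins[[gid]], dg$missed_cleavages,
                           dg$min_len, dg$max_len)
    for (r in seq_len(nrow(peps))) {
      idx <- idx + 1L
      pid <- sprintf("pep%05d", idx)
      tb <- truth_blocks(peps$aa_start[r], peps$aa_end[r],
                         meta$plan$exon_lens, meta$plan$intron_lens,
                         meta$offset, meta$glen, meta$strand,
                         meta$contig_len)
      exl <- tb$exons_touched
      n_introns <- max(length(exl) - 1L, 0L)
      crosses_fs <- length(unique(tb$frames)) > 1L
      pep_seqs[pid] <- peps$peptide[r]
      truth_rows[[idx]] <- data.frame(
        peptide_id = pid, seq = peps$peptide[r], source = "gene",
        gene_id = gid, confidence = models[[gid]]$confidence,
        chrom = meta$chrom, strand = meta$strand,
        aa_start = peps$aa_start[r], aa_end = peps$aa_end[r],
        n_blocks = length(tb$starts),
        blocks = paste(sprintf("%d-%d", tb$starts, tb$ends), collapse = ";"),
        frames = paste(tb$frames, collapse = ","),
        introns_crossed = n_introns, crosses_frameshift = crosses_fs,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(orfs)) {
    for (r in seq_len(nrow(orfs))) {
      peps <- tryptic_digest(orfs$protein[r], dg$missed_cleavages,
                             dg$min_len, dg$max_len)
      for (q in seq_len(nrow(peps))) {
        idx <- idx + 1L
        pid <- sprintf("pep%05d", idx)
        # ORF protein starts right after ATG
        a <- peps$aa_start[q]; b <- peps$aa_end[q]
        if (orfs$strand[r] == "+") {
          bs <- orfs$start[r] + 3L + 3L * (a - 1L)
          be <- orfs$start[r] + 3L + 3L * b - 1L
        } else {
          bs <- orfs$end[r] - 3L - 3L * b + 1L
          be <- orfs$end[r] - 3L - 3L * (a - 1L)
        }
        pep_seqs[pid] <- peps$peptide[q]
        truth_rows[[idx]] <- data.frame(
          peptide_id = pid, seq = peps$peptide[q], source = "novel",
          gene_id = NA_character_, confidence = "NOVEL",
          chrom = orfs$chrom[r], strand = orfs$strand[r],
          aa_start = a, aa_end = b, n_blocks = 1L,
          blocks = sprintf("%d-%d", bs, be), frames = NA_character_,
          introns_crossed = 0L, crosses_frameshift = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  # searched copies, optionally mutated
  searched <- pep_seqs
  truth$mutations <- 0L
  if (cfg$mutation_rate > 0) {
    for (i in seq_along(searched)) {
      res <- strsplit(searched[[i]], "")[[1]]
      hit <- which(stats::runif(length(res)) < cfg$mutation_rate)
      for (h in hit) {
        res[h] <- sample(setdiff(BODY_AA, res[h]), 1L)
      }
      if (length(hit)) {
        searched[[i]] <- paste0(res, collapse = "")
        truth$mutations[i] <- length(hit)
      }
    }
  }
  tissue_of <- sample(seq_len(cfg$n_tissues), length(searched), replace = TRUE)
  tissues <- lapply(seq_len(cfg$n_tissues), function(t)
    searched[tissue_of == t])
  names(tissues) <- sprintf("tissue%02d", seq_len(cfg$n_tissues))

  structure(list(config = cfg, genome = genome, models = models,
                 proteins = proteins, peptides = searched,
                 tissues = tissues, truth = truth, novel_orfs = orfs),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d chrom(s) x %d nt, %d genes (%d HC), %d peptides, %d novel ORF peptide(s)\n",
              length(x$genome), x$config$chrom_length_nt, length(x$models),
              sum(vapply(x$models, function(m) m$confidence == "HC", logical(1))),
              length(x$peptides), sum(x$truth$source == "novel")))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS rows with ID/Parent attributes and
#' correct CDS phase.
#'
#' @param models named list of `gene_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    att <- sprintf("ID=%s", m$gene_id)
    writeLines(paste(m$chrom, "pepmapr", "gene", m$gene_start, m$gene_end,
                     ".", m$strand, ".", att, sep = "\t"), con)
    tid <- paste0(m$gene_id, ".1")
    writeLines(paste(m$chrom, "pepmapr", "mRNA", m$gene_start, m$gene_end,
                     ".", m$strand, ".",
                     sprintf("ID=%s;Parent=%s", tid, m$gene_id), sep = "\t"),
               con)
    widths <- m$exons[, "end"] - m$exons[, "start"] + 1L
    cds_before <- c(0L, cumsum(widths))[seq_len(nrow(m$exons))]
    phase <- (3L - cds_before %% 3L) %% 3L
    for (i in seq_len(nrow(m$exons))) {
      for (ty in c("exon", "CDS")) {
        writeLines(paste(m$chrom, "pepmapr", ty, m$exons[i, "start"],
                         m$exons[i, "end"], ".", m$strand,
                         if (ty == "CDS") phase[i] else ".",
                         sprintf("ID=%s.%s%d;Parent=%s", tid,
                                 tolower(ty), i, tid), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Write a synthetic bundle to a directory
#'
#' Emits genome.fa, hc.gff3, lc.gff3, proteins.fa, one peptide FASTA per
#' tissue, the ground truth as TSV, and the ground-truth footprints as
#' BED12.
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  hc <- Filter(function(m) m$confidence == "HC", bundle$models)
  lc <- Filter(function(m) m$confidence == "LC", bundle$models)
  write_gff3(hc, file.path(dir, "hc.gff3"))
  write_gff3(lc, file.path(dir, "lc.gff3"))
  write_fasta(bundle$proteins, file.path(dir, "proteins.fa"))
  for (t in names(bundle$tissues)) {
    write_fasta(bundle$tissues[[t]], file.path(dir, paste0(t, ".fa")))
  }
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- file.path(dir, "truth.bed")
  lines <- vapply(seq_len(nrow(bundle$truth)), function(i) {
    tr <- bundle$truth[i, ]
    bl <- parse_blocks(tr$blocks)
    chrom_start <- bl[1, 1] - 1L
    sizes <- bl[, 2] - bl[, 1] + 1L
    starts0 <- bl[, 1] - 1L - chrom_start
    paste(tr$chrom, chrom_start, bl[nrow(bl), 2], tr$peptide_id, 0L,
          tr$strand, chrom_start, bl[nrow(bl), 2], "0,0,0", nrow(bl),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts0, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, bed)
  invisible(dir)
}

#' Parse a "start-end;start-end" block string into a matrix
#' @param s block string.
#' @return integer matrix with columns start, end (ascending).
#' @export
parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}
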