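## Gene-model handling: GFF3 parsing, exact spliced AA->genomic coordinate
## mapping, per-exon genomic frame computation / frame-shift detection,
## hit-to-gene HC/LC/novel assignment, and frame-shift-aware stitching of
## adjacent hits.

#' Construct a gene model
#'
#' @param gene_id,chrom,strand,confidence identifiers; `confidence` is
#'   `"HC"` or `"LC"`.
#' @param exons two-column matrix or data.frame of 1-based inclusive
#'   (start, end) exon intervals.  Stored in transcription order
#'   (descending genomic coordinate on the minus strand).
#' @param gene_start,gene_end gene span; default = exon extremes.
#' @return object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, confidence, exons,
                       gene_start = NULL, gene_end = NULL) {
  stopifnot(strand %in% c("+", "-"), confidence %in% c("HC", "LC"))
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  stopifnot(all(exons[, "end"] >= exons[, "start"]))
  ord <- order(exons[, "start"], decreasing = (strand == "-"))
  if (!identical(ord, seq_len(nrow(exons)))) {
    exons <- exons[ord, , drop = FALSE]
  }
  if (nrow(exons) > 1L) {
    asc <- exons[order(exons[, "start"]), , drop = FALSE]
    if (any(asc[-1L, "start"] <= asc[-nrow(asc), "end"])) {
      stop("gene ", gene_id, ": overlapping exons")
    }
  }
  if (is.null(gene_start)) gene_start <- min(exons[, "start"])
  if (is.null(gene_end)) gene_end <- max(exons[, "end"])
  cds_len <- sum(exons[, "end"] - exons[, "start"] + 1L)
  if (cds_len %% 3L != 0L) {
    message("gene ", gene_id, ": CDS length ", cds_len,
            " not divisible by 3 (incomplete model?)")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 confidence = confidence,
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end), exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s [%s] %s:%d-%d (%s), %d exon(s)\n",
              x$gene_id, x$confidence, x$chrom, x$gene_start, x$gene_end,
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Protein length implied by a gene model's exons
#' @param gene a `gene_model`.
#' @return number of codons (integer division by 3).
#' @export
protein_length <- function(gene) {
  sum(gene$exons[, "end"] - gene$exons[, "start"] + 1L) %/% 3L
}

#' Parse gene models from a GFF3 file
#'
#' Exons are taken from the CDS features of the first mRNA of each gene;
#' genes without CDS fall back to exon features.  Coordinates stay 1-based
#' inclusive.  Records lacking an ID are skipped with a warning.
#'
#' @param path GFF3 file path.
#' @param confidence `"HC"` or `"LC"` label applied to every gene.
#' @return named list of `gene_model` objects.
#' @export
parse_gff3 <- function(path, confidence) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(meta)) {
    vapply(as.list(meta$Parent), function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  gene_rows <- which(type == "gene")
  no_id <- gene_rows[is.na(ids[gene_rows])]
  if (length(no_id)) {
    warning("skipping ", length(no_id), " gene record(s) without ID")
    gene_rows <- setdiff(gene_rows, no_id)
  }
  models <- list()
  for (gi in gene_rows) {
    gid <- ids[gi]
    mrna <- which(type %in% c("mRNA", "transcript") & parents == gid)
    feat <- integer(0)
    if (length(mrna)) {
      tid <- ids[mrna[1]]                       # first mRNA only
      feat <- which(type == "CDS" & parents == tid)
      if (!length(feat)) feat <- which(type == "exon" & parents == tid)
    }
    if (!length(feat)) feat <- which(type %in% c("CDS", "exon") & parents == gid)
    if (!length(feat)) {
      warning("gene ", gid, ": no CDS/exon features; skipped")
      next
    }
    ex <- cbind(start = GenomicRanges::start(gr)[feat],
                end = GenomicRanges::end(gr)[feat])
    models[[gid]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(GenomicRanges::strand(gr))[gi],
      confidence = confidence,
      exons = ex,
      gene_start = GenomicRanges::start(gr)[gi],
      gene_end = GenomicRanges::end(gr)[gi])
  }
  models
}

#' Genomic reading frame of each exon
#'
#' The frame of an exon is the BLAST frame id (`+1..+3` / `-1..-3`) in
#' which that exon's codons are read on the genome.  An intron whose
#' length is not a multiple of 3 shifts the genomic frame of all
#' downstream exons even though the spliced mRNA frame is continuous.
#'
#' @param gene a `gene_model`.
#' @param contig_length contig length in nt; required for minus-strand
#'   genes (BLAST minus-strand frames are anchored at the contig end).
#' @return integer vector of frame ids per exon (transcription order) with
#'   attribute `has_frameshift`.
#' @export
exon_frames <- function(gene, contig_length = NULL) {
  ex <- gene$exons
  nex <- nrow(ex)
  widths <- ex[, "end"] - ex[, "start"] + 1L
  cds_before <- c(0L, cumsum(widths))[seq_len(nex)]
  frames <- integer(nex)
  if (gene$strand == "+") {
    for (i in seq_len(nex)) {
      # genomic position of a codon start within exon i
      g <- ex[i, "start"] + ((-cds_before[i]) %% 3L)
      frames[i] <- ((g - 1L) %% 3L) + 1L
    }
  } else {
    if (is.null(contig_length)) {
      stop("contig_length is required for minus-strand frames")
    }
    for (i in seq_len(nex)) {
      p <- ex[i, "end"] - ((-cds_before[i]) %% 3L)
      frames[i] <- -((((contig_length - p) %% 3L)) + 1L)
    }
  }
  attr(frames, "has_frameshift") <- length(unique(frames)) > 1L
  frames
}

#' Map protein coordinates to spliced genomic blocks
#'
#' Converts a 1-based inclusive AA interval of a gene's protein into its
#' exact genomic footprint: the CDS-relative nucleotide interval
#' `[3*aa_start - 2, 3*aa_end]` walked through the exons in transcription
#' order, one block per exon touched.  Blocks are stored in ascending
#' genomic order with the strand flag; transcription order is recoverable.
#'
#' @param aa_start,aa_end 1-based AA interval.
#' @param gene a `gene_model`.
#' @param peptide_id optional id carried through.
#' @param contig_length optional contig length used to annotate per-block
#'   genomic frames on the minus strand.
#' @return object of class `"spliced_mapping"`: list with `peptide_id`,
#'   `gene_id`, `chrom`, `strand`, `blocks` (matrix, ascending genomic),
#'   `per_block_frame`, `aa_start`, `aa_end`.
#' @export
map_peptide_to_genome <- function(aa_start, aa_end, gene,
                                  peptide_id = NA_character_,
                                  contig_length = NULL) {
  plen <- protein_length(gene)
  if (aa_start < 1L || aa_end < aa_start || aa_end > plen) {
    stop("AA interval [", aa_start, ",", aa_end, "] out of range for gene ",
         gene$gene_id, " (protein length ", plen, ")")
  }
  lo <- 3L * aa_start - 2L
  hi <- 3L * aa_end
  ex <- gene$exons
  widths <- ex[, "end"] - ex[, "start"] + 1L
  cum <- c(0L, cumsum(widths))
  blocks <- NULL
  block_exon <- integer(0)
  for (i in seq_len(nrow(ex))) {
    c0 <- cum[i]; c1 <- cum[i + 1L]
    o1 <- max(lo, c0 + 1L) - c0          # 1-based offsets within the exon,
    o2 <- min(hi, c1) - c0               # in transcription order
    if (o1 > o2) next
    if (gene$strand == "+") {
      b <- c(ex[i, "start"] + o1 - 1L, ex[i, "start"] + o2 - 1L)
    } else {
      b <- c(ex[i, "end"] - o2 + 1L, ex[i, "end"] - o1 + 1L)
    }
    blocks <- rbind(blocks, b)
    block_exon <- c(block_exon, i)
  }
  frames <- tryCatch(exon_frames(gene, contig_length)[block_exon],
                     error = function(e) rep(NA_integer_, length(block_exon)))
  ord <- order(blocks[, 1])
  structure(list(peptide_id = peptide_id, gene_id = gene$gene_id,
                 chrom = gene$chrom, strand = gene$strand,
                 blocks = matrix(as.integer(blocks[ord, , drop = FALSE]),
                                 ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))),
                 per_block_frame = frames[ord],
                 aa_start = as.integer(aa_start), aa_end = as.integer(aa_end)),
            class = "spliced_mapping")
}

#' Extract, splice and translate a mapping's blocks
#'
#' The round-trip oracle: pulling the mapped blocks out of the genome,
#' splicing them in transcription order and translating must reproduce the
#' peptide subsequence exactly.
#'
#' @param mapping a `spliced_mapping`.
#' @param genome named character vector of contigs.
#' @return translated peptide (character scalar).
#' @export
translate_mapping <- function(mapping, genome) {
  contig <- genome[[mapping$chrom]]
  pieces <- apply(mapping$blocks, 1L, function(b)
    substr(contig, b[1], b[2]))
  if (mapping$strand == "-") {
    pieces <- rev(vapply(pieces, reverse_complement, character(1)))
  }
  translate_frame(paste0(pieces, collapse = ""), 1L)
}

#' Build an interval index over gene spans
#'
#' @param models list of `gene_model` objects.
#' @return object of class `"gene_index"` wrapping a `GRanges` of gene
#'   spans with gene_id and confidence metadata.
#' @export
gene_index <- function(models) {
  if (length(models) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(models, `[[`, character(1), "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(models, `[[`, integer(1), "gene_start"),
        end = vapply(models, `[[`, integer(1), "gene_end")),
      gene_id = vapply(models, `[[`, character(1), "gene_id"),
      confidence = vapply(models, `[[`, character(1), "confidence"))
  }
  structure(list(gr = gr, models = models), class = "gene_index")
}

#' Assign hits to High/Low-Confidence genes or flag them as novel
#'
#' A hit is contained in a gene when chromosomes match and, with hit
#' coordinates normalized to (min, max), `start > gene_start` and
#' `end < gene_end` -- strict inequalities, so boundary-touching hits are
#' unassigned.  If at least one HC gene contains the hit the category is
#' HC; else LC if an LC gene contains it; else NOVEL.  When several genes
#' of the winning class contain a hit, the smallest (most specific) gene
#' span is reported; all containing genes are listed.
#'
#' @param hits a `hit_table` (or data.frame with qaccver, saccver, sstart,
#'   send, strand).
#' @param index a [gene_index()].
#' @return data.frame: hit_id, peptide, chrom, start, end, strand,
#'   category, gene_id, containing_genes (comma-separated).
#' @export
assign_hits <- function(hits, index) {
  stopifnot(inherits(index, "gene_index"))
  n <- nrow(hits)
  out <- data.frame(hit_id = seq_len(n), peptide = hits$qaccver,
                    chrom = hits$saccver,
                    start = pmin(hits$sstart, hits$send),
                    end = pmax(hits$sstart, hits$send),
                    strand = hits$strand,
                    category = rep("NOVEL", n),
                    gene_id = NA_character_,
                    containing_genes = "",
                    stringsAsFactors = FALSE)
  if (n == 0L || length(index$gr) == 0L) return(out)
  known <- as.character(out$chrom) %in%
    unique(as.character(GenomicRanges::seqnames(index$gr)))
  if (any(!known)) {
    warning(sum(!known), " hit(s) on chromosomes absent from the ",
            "annotation; classified NOVEL")
  }
  qgr <- GenomicRanges::GRanges(out$chrom[known],
                                IRanges::IRanges(out$start[known],
                                                 out$end[known]))
  ov <- GenomicRanges::findOverlaps(qgr, index$gr, type = "within")
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  gs <- GenomicRanges::start(index$gr)[sh]
  ge <- GenomicRanges::end(index$gr)[sh]
  rowmap <- which(known)[qh]
  strict <- out$start[rowmap] > gs & out$end[rowmap] < ge
  qh <- qh[strict]; sh <- sh[strict]; rowmap <- rowmap[strict]
  if (!length(qh)) return(out)
  conf <- index$gr$confidence[sh]
  gid <- index$gr$gene_id[sh]
  span <- GenomicRanges::width(index$gr)[sh]
  sp <- split(seq_along(qh), rowmap)
  for (key in names(sp)) {
    ii <- sp[[key]]
    row <- as.integer(key)
    out$containing_genes[row] <- paste(gid[ii], collapse = ",")
    pick <- if (any(conf[ii] == "HC")) ii[conf[ii] == "HC"] else ii
    out$category[row] <- if (any(conf[ii] == "HC")) "HC" else "LC"
    pick <- pick[order(span[pick], gid[pick])][1]
    out$gene_id[row] <- gid[pick]
  }
  out
}

#' Stitch adjacent hits across genomic frame shifts
#'
#' Two hits of the same peptide on the same chromosome and strand, in
#' different genomic frames, contiguous in query coordinates and with
#' disjoint, consistently ordered genomic footprints within
#' `max_genomic_gap` nucleotides of each other, are merged into a
#' multi-block mapping.  "Contiguous" tolerates any query overlap --
#' local alignment ends extend several residues into the intron by chance,
#' so the two pieces of a junction-crossing peptide typically overlap --
#' and at most `adjacency_tol` residues of separation.  Chains longer
#' than two merge transitively.  Unmerged hits pass through as
#' single-block mappings.  Note that two genuine hits of the same peptide
#' at nearby repeated loci in different frames would also merge; the
#' synthetic fixtures contain no such repeats.
#'
#' @param hits a `hit_table`.
#' @param max_genomic_gap maximum genomic distance between stitched blocks.
#' @param adjacency_tol maximum separation, in residues, between where
#'   one hit ends and the next begins in the query (overlap is always
#'   tolerated; only gaps in query coverage are limited).
#' @return data.frame, one row per (merged) mapping: peptide, chrom,
#'   strand, aa_start, aa_end, qlen, n_blocks, blocks (\"start-end\"
#'   semicolon-joined, ascending genomic), frames, merged.
#' @export
stitch_frameshift <- function(hits, max_genomic_gap = 10000L,
                              adjacency_tol = 1L) {
  if (nrow(hits) == 0L) {
    return(data.frame(peptide = character(0), chrom = character(0),
                      strand = character(0), aa_start = integer(0),
                      aa_end = integer(0), qlen = integer(0),
                      n_blocks = integer(0), blocks = character(0),
                      frames = character(0), merged = logical(0)))
  }
  h <- as.data.frame(hits)
  h$.lo <- pmin(h$sstart, h$send)
  h$.hi <- pmax(h$sstart, h$send)
  ord <- order(h$qaccver, h$saccver, h$strand, h$qstart, h$.lo)
  h <- h[ord, ]
  key <- paste(h$qaccver, h$saccver, h$strand)
  out <- list()
  i <- 1L
  while (i <= nrow(h)) {
    chain <- i
    while (i + 1L <= nrow(h) && key[i + 1L] == key[chain[1]]) {
      a <- h[i, ]; b <- h[i + 1L, ]
      # the pieces may overlap in the query (local alignments extend a few
      # residues into the intron by chance) but must not be separated by
      # more than adjacency_tol residues
      adjacent <- b$qstart - (a$qend + 1L) <= adjacency_tol &&
        b$qend >= a$qend
      diff_frame <- b$sframe != a$sframe
      gdist <- max(b$.lo, a$.lo) - min(b$.hi, a$.hi)
      near <- gdist <= max_genomic_gap
      disjoint <- b$.lo > a$.hi || b$.hi < a$.lo
      # downstream in the query must be downstream in transcription
      ok_order <- if (a$strand == "+") b$.lo > a$.hi else b$.hi < a$.lo
      if (adjacent && diff_frame && near && disjoint && ok_order) {
        chain <- c(chain, i + 1L)
        i <- i + 1L
      } else break
    }
    rows <- h[chain, ]
    bl <- rows[order(rows$.lo), ]
    out[[length(out) + 1L]] <- data.frame(
      peptide = rows$qaccver[1], chrom = rows$saccver[1],
      strand = rows$strand[1],
      aa_start = min(rows$qstart), aa_end = max(rows$qend),
      qlen = rows$qlen[1], n_blocks = length(chain),
      blocks = paste(sprintf("%d-%d", bl$.lo, bl$.hi), collapse = ";"),
      frames = paste(rows$sframe, collapse = ","),
      merged = length(chain) > 1L, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
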