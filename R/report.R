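## Aggregation and export: per-tissue and per-chromosome summary tables,
## descriptive statistics and correlation matrix of hit columns, BED and
## Circos track writers.

#' Per-tissue summary table from count rows
#'
#' Low-level core: takes one row per tissue with `tissue`, `tissue_nb`,
#' `total_peptides`, `unique_sequences`, `hits` and computes the hit
#' percentage and the SUM/MIN/MAX/AVERAGE/SD footer.  The SUM row's
#' percentage is recomputed from the summed counts (not averaged);
#' zero-peptide tissues contribute zeros but are excluded from
#' AVERAGE/SD.
#'
#' @param rows data.frame of per-tissue counts.
#' @return list: `rows` (with `hit_pct`), `footer` (SUM/MIN/MAX/AVERAGE/SD
#'   over the numeric columns).
#' @export
tissue_summary_table <- function(rows) {
  stopifnot(all(c("tissue", "total_peptides", "unique_sequences", "hits")
                %in% names(rows)))
  if (any(rows$unique_sequences < 0)) stop("negative counts")
  rows$hit_pct <- ifelse(rows$unique_sequences > 0,
                         100 * rows$hits / rows$unique_sequences, 0)
  num <- c("total_peptides", "unique_sequences", "hits", "hit_pct")
  used <- rows$unique_sequences > 0
  footer <- rbind(
    SUM = colSums(rows[, num, drop = FALSE]),
    MIN = apply(rows[used, num, drop = FALSE], 2, min),
    MAX = apply(rows[used, num, drop = FALSE], 2, max),
    AVERAGE = colMeans(rows[used, num, drop = FALSE]),
    SD = apply(rows[used, num, drop = FALSE], 2, stats::sd))
  footer <- as.data.frame(footer)
  footer["SUM", "hit_pct"] <- 100 * footer["SUM", "hits"] /
    footer["SUM", "unique_sequences"]
  list(rows = rows, footer = footer)
}

#' Summarize hits by tissue
#'
#' @param peptide_counts data.frame: tissue, tissue_nb, total_peptides,
#'   unique_sequences.
#' @param hits either a `hit_table` carrying a `tissue` column (hits are
#'   counted as distinct peptides with at least one surviving hit) or a
#'   data.frame with `tissue` and `hits` columns of precomputed counts.
#' @return as [tissue_summary_table()].
#' @export
summarize_by_tissue <- function(peptide_counts, hits) {
  if (!"hits" %in% names(hits)) {
    counts <- vapply(split(hits$qaccver, hits$tissue),
                     function(x) length(unique(x)), integer(1))
    hits <- data.frame(tissue = names(counts), hits = as.integer(counts),
                       stringsAsFactors = FALSE)
  }
  rows <- merge(peptide_counts, hits[, c("tissue", "hits")],
                by = "tissue", all.x = TRUE, sort = FALSE)
  rows$hits[is.na(rows$hits)] <- 0L
  if ("tissue_nb" %in% names(rows)) rows <- rows[order(rows$tissue_nb), ]
  tissue_summary_table(rows)
}

#' Per-chromosome summary table from count rows
#'
#' Low-level core mirroring the per-chromosome table shape: takes one row
#' per chromosome with peptide counts by category, mapped-gene and
#' annotated-gene counts per confidence class, chromosome size and an
#' `exclude_from_stats` flag, and computes the SUM columns, percentage
#' columns, and two footers.  SUM rows always include every chromosome;
#' MIN/MAX/AVERAGE honour the exclusion flag in `footer_kept` and ignore
#' it in `footer_all`.
#'
#' @param rows data.frame with columns chrom, hc_peptides, lc_peptides,
#'   novel_peptides, hc_mapped_genes, lc_mapped_genes, all_hc_genes,
#'   all_lc_genes, chrom_size_nt, exclude_from_stats.
#' @return list: `rows` (augmented), `footer_all`, `footer_kept`.
#' @export
chromosome_summary_table <- function(rows) {
  need <- c("chrom", "hc_peptides", "lc_peptides", "novel_peptides",
            "hc_mapped_genes", "lc_mapped_genes", "all_hc_genes",
            "all_lc_genes", "chrom_size_nt")
  stopifnot(all(need %in% names(rows)))
  if (!"exclude_from_stats" %in% names(rows)) rows$exclude_from_stats <- FALSE
  rows$sum_peptides <- rows$hc_peptides + rows$lc_peptides + rows$novel_peptides
  rows$sum_mapped_genes <- rows$hc_mapped_genes + rows$lc_mapped_genes
  rows$sum_all_genes <- rows$all_hc_genes + rows$all_lc_genes
  rows$hc_pct <- 100 * rows$hc_mapped_genes / rows$all_hc_genes
  rows$lc_pct <- 100 * rows$lc_mapped_genes / rows$all_lc_genes
  rows$sum_pct <- 100 * rows$sum_mapped_genes / rows$sum_all_genes
  num <- c("hc_peptides", "lc_peptides", "novel_peptides", "sum_peptides",
           "hc_mapped_genes", "lc_mapped_genes", "sum_mapped_genes",
           "all_hc_genes", "all_lc_genes", "sum_all_genes",
           "hc_pct", "lc_pct", "sum_pct", "chrom_size_nt")
  make_footer <- function(sub) {
    footer <- rbind(SUM = colSums(rows[, num, drop = FALSE]),
                    MIN = apply(sub[, num, drop = FALSE], 2, min),
                    MAX = apply(sub[, num, drop = FALSE], 2, max),
                    AVERAGE = colMeans(sub[, num, drop = FALSE]))
    footer <- as.data.frame(footer)
    denom <- c(hc = "all_hc_genes", lc = "all_lc_genes", sum = "sum_all_genes")
    for (cls in c("hc", "lc", "sum")) {
      footer["SUM", paste0(cls, "_pct")] <-
        100 * footer["SUM", paste0(cls, "_mapped_genes")] /
        footer["SUM", denom[[cls]]]
    }
    footer
  }
  list(rows = rows,
       footer_all = make_footer(rows),
       footer_kept = make_footer(rows[!rows$exclude_from_stats, , drop = FALSE]))
}

#' Summarize assignments by chromosome
#'
#' Derives the per-chromosome counts from hit assignments and gene models:
#' peptide counts are distinct (peptide, chromosome, category)
#' occurrences; mapped-gene counts are distinct genes with at least one
#' assigned peptide.
#'
#' @param assignments output of [assign_hits()].
#' @param models named list of `gene_model`s (HC and LC together).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param exclude_chroms chromosomes flagged `exclude_from_stats`.
#' @return as [chromosome_summary_table()].
#' @export
summarize_by_chromosome <- function(assignments, models, chrom_sizes,
                                    exclude_chroms = character(0)) {
  chroms <- names(chrom_sizes)
  conf <- vapply(models, `[[`, character(1), "confidence")
  mchrom <- vapply(models, `[[`, character(1), "chrom")
  known_genes <- vapply(models, `[[`, character(1), "gene_id")
  bad <- !is.na(assignments$gene_id) & !assignments$gene_id %in% known_genes
  if (any(bad)) {
    message(sum(bad), " assignment(s) referencing unknown genes; counted as novel")
    assignments$category[bad] <- "NOVEL"
    assignments$gene_id[bad] <- NA_character_
  }
  rows <- lapply(chroms, function(ch) {
    a <- assignments[assignments$chrom == ch, , drop = FALSE]
    pepcount <- function(cat)
      length(unique(a$peptide[a$category == cat]))
    genecount <- function(cat)
      length(unique(a$gene_id[a$category == cat & !is.na(a$gene_id)]))
    data.frame(chrom = ch,
               hc_peptides = pepcount("HC"), lc_peptides = pepcount("LC"),
               novel_peptides = pepcount("NOVEL"),
               hc_mapped_genes = genecount("HC"),
               lc_mapped_genes = genecount("LC"),
               all_hc_genes = sum(mchrom == ch & conf == "HC"),
               all_lc_genes = sum(mchrom == ch & conf == "LC"),
               chrom_size_nt = unname(chrom_sizes[ch]),
               exclude_from_stats = ch %in% exclude_chroms,
               stringsAsFactors = FALSE)
  })
  chromosome_summary_table(do.call(rbind, rows))
}

#' Descriptive statistics of the numeric hit columns
#'
#' Quartiles use linear interpolation between order statistics.
#'
#' @param hits a `hit_table`.
#' @param columns numeric columns to describe.
#' @return data.frame, one row per column: count, mean, sd, min, q1,
#'   median, q3, max.  Empty input gives zero rows.
#' @export
descriptive_stats <- function(hits,
                              columns = c("pident", "length", "mismatch",
                                          "gapopen", "gaps", "score",
                                          "evalue", "sstart", "send",
                                          "sframe")) {
  columns <- intersect(columns, names(hits))
  if (nrow(hits) == 0L) {
    return(data.frame(column = character(0), count = integer(0),
                      mean = numeric(0), sd = numeric(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0)))
  }
  rows <- lapply(columns, function(cl) {
    x <- as.numeric(hits[[cl]])
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(column = cl, count = length(x), mean = mean(x),
               sd = stats::sd(x), min = min(x), q1 = q[1], median = q[2],
               q3 = q[3], max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of hit columns
#'
#' @param hits a `hit_table` (or any data.frame).
#' @param columns numeric columns to correlate.
#' @return list with symmetric matrices `r` (Pearson correlation; unit
#'   diagonal; `NA` for constant columns) and `r2` (`r^2`, sign dropped).
#' @export
correlation_matrix <- function(hits,
                               columns = c("pident", "length", "mismatch",
                                           "gapopen", "gaps", "score",
                                           "evalue", "sstart", "sframe")) {
  columns <- intersect(columns, names(hits))
  m <- as.matrix(as.data.frame(lapply(hits[columns], as.numeric)))
  consts <- apply(m, 2, function(x) stats::sd(x) == 0 || is.na(stats::sd(x)))
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  r[consts, ] <- NA; r[, consts] <- NA
  diag(r)[!consts] <- 1
  list(r = r, r2 = r^2)
}

clamp_score <- function(s) pmin(pmax(round(s), 0L), 1000L)

#' Write hits or spliced mappings as BED
#'
#' Hit tables are written as BED6 (chrom, 0-based half-open interval, the
#' gapless peptide sequence as name, raw score clamped to 0..1000,
#' strand).  Mapping tables (with a `blocks` column, e.g. from
#' [stitch_frameshift()] or a ground-truth table) are written as BED12
#' with one block per spliced segment.  Records extending outside their
#' contig are dropped with a warning.
#'
#' @param x `hit_table` or mappings data.frame.
#' @param path output file; with `per_tissue = TRUE`, a stem used as
#'   `<stem>_<tissue>.bed` in addition to the combined file.
#' @param per_tissue also write one BED per tissue label.
#' @return invisible character vector of files written.
#' @export
write_bed <- function(x, path, per_tissue = FALSE) {
  files <- character(0)
  if ("blocks" %in% names(x)) {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      bl <- parse_blocks(x$blocks[i])
      cs <- bl[1, "start"] - 1L
      ce <- bl[nrow(bl), "end"]
      name <- if ("peptide" %in% names(x)) x$peptide[i] else
        if ("peptide_id" %in% names(x)) x$peptide_id[i] else "."
      paste(x$chrom[i], cs, ce, name, 0L, x$strand[i], cs, ce, "0,0,0",
            nrow(bl),
            paste0(paste(bl[, "end"] - bl[, "start"] + 1L, collapse = ","), ","),
            paste0(paste(bl[, "start"] - 1L - cs, collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
    return(invisible(path))
  }
  stopifnot(inherits(x, "data.frame"))
  emit <- function(h, p) {
    if (nrow(h) && "slen" %in% names(h)) {
      bad <- pmax(h$sstart, h$send) > h$slen | pmin(h$sstart, h$send) < 1L
      if (any(bad)) {
        warning(sum(bad), " record(s) outside contig bounds dropped")
        h <- h[!bad, , drop = FALSE]
      }
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", h$saccver,
                     pmin(h$sstart, h$send) - 1L, pmax(h$sstart, h$send),
                     gsub("-", "", h$qseq), clamp_score(h$score), h$strand)
    writeLines(lines, p)
    p
  }
  files <- emit(x, path)
  if (per_tissue) {
    stem <- sub("\\.bed$", "", path)
    for (t in unique(x$tissue)) {
      f <- paste0(stem, "_", t, ".bed")
      emit(x[x$tissue %in% t, , drop = FALSE], f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Build a karyotype table from a genome
#'
#' @param genome named character vector of contigs.
#' @param centromeres optional named vector of centromere positions;
#'   defaults to the contig midpoints.
#' @return data.frame: chrom, start, end, centromere.
#' @export
make_karyotype <- function(genome, centromeres = NULL) {
  len <- nchar(genome)
  data.frame(chrom = names(genome), start = 1L, end = unname(len),
             centromere = if (is.null(centromeres)) unname(len %/% 2L)
               else unname(centromeres[names(genome)]),
             stringsAsFactors = FALSE)
}

#' Write Circos track and karyotype files
#'
#' One whitespace-delimited 3-column (chrom, sstart, send) file per
#' tissue, coordinates as in the hit table (1-based inclusive), plus a
#' karyotype file.
#'
#' @param hits a `hit_table` with a `tissue` column.
#' @param karyotype data.frame from [make_karyotype()].
#' @param dir output directory.
#' @param tissues tissue labels to emit (default: those present; an empty
#'   tissue still produces an empty file).
#' @return invisible character vector of files written.
#' @export
write_circos_tracks <- function(hits, karyotype, dir,
                                tissues = unique(hits$tissue)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (t in tissues) {
    h <- hits[hits$tissue %in% t, , drop = FALSE]
    f <- file.path(dir, paste0("track_", t, ".txt"))
    writeLines(sprintf("%s %d %d", h$saccver, h$sstart, h$send), f)
    files <- c(files, f)
  }
  kf <- file.path(dir, "karyotype.txt")
  writeLines(sprintf("%s %d %d %d", karyotype$chrom, karyotype$start,
                     karyotype$end, karyotype$centromere), kf)
  invisible(c(files, kf))
}
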