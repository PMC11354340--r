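## tBLASTn-style search: Smith-Waterman affine-gap local alignment of
## peptides against all six frame translations of each contig, with
## Karlin-Altschul e-values, filters and 25-column tabular output.

#' Alignment parameter set
#'
#' Defaults are the optimized production settings: PAM30, gap existence 10 /
#' extension 1, e-value cutoff 0.01, 3 maximum target contigs, 1 HSP per
#' target, 25% minimum query coverage.
#'
#' @param matrix substitution matrix name.
#' @param gap_open gap existence cost (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @param gap_extend per-residue gap extension cost.
#' @param evalue_cutoff maximum e-value for a reported hit.
#' @param max_target_seqs maximum number of target contigs per peptide.
#' @param max_hsps_per_target maximum HSPs kept per (peptide, contig).
#' @param min_query_coverage_pct minimum `100 * (qend - qstart + 1) / qlen`.
#' @param ka_lambda,ka_K Karlin-Altschul parameters; `NULL` looks them up
#'   from the bundled constants for (matrix, gap costs).
#' @return object of class `"alignment_params"`.
#' @export
alignment_params <- function(matrix = "PAM30", gap_open = 10L,
                             gap_extend = 1L, evalue_cutoff = 0.01,
                             max_target_seqs = 3L, max_hsps_per_target = 1L,
                             min_query_coverage_pct = 25,
                             ka_lambda = NULL, ka_K = NULL) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 1, evalue_cutoff > 0,
            max_target_seqs >= 1, max_hsps_per_target >= 1,
            min_query_coverage_pct >= 0)
  if (is.null(ka_lambda) || is.null(ka_K)) {
    ka <- suppressWarnings(ka_parameters(matrix, gap_open, gap_extend))
    if (is.null(ka_lambda)) ka_lambda <- ka$lambda
    if (is.null(ka_K)) ka_K <- ka$K
  }
  if (ka_lambda <= 0 || ka_K <= 0) stop("Karlin-Altschul parameters must be positive")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_cutoff = evalue_cutoff,
                 max_target_seqs = as.integer(max_target_seqs),
                 max_hsps_per_target = as.integer(max_hsps_per_target),
                 min_query_coverage_pct = min_query_coverage_pct,
                 ka_lambda = ka_lambda, ka_K = ka_K),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("alignment_params:", x$matrix,
      sprintf("gap %d/%d, evalue <= %g, max targets %d, max HSPs %d, min qcov %g%%\n",
              x$gap_open, x$gap_extend, x$evalue_cutoff, x$max_target_seqs,
              x$max_hsps_per_target, x$min_query_coverage_pct))
  invisible(x)
}

aa_indices <- function(seq, mat) {
  idx <- match(strsplit(seq, "")[[1]], rownames(mat))
  xi <- match("X", rownames(mat))
  idx[is.na(idx)] <- xi   # unknown residues score via the X column
  idx - 1L
}

#' Smith-Waterman affine-gap local alignment of two protein sequences
#'
#' @param query,subject protein sequences (character scalars).
#' @param matrix score matrix (name or matrix from [load_score_matrix()]).
#' @param gap_open,gap_extend gap costs (NCBI convention: a gap of length g
#'   costs `gap_open + g * gap_extend`).
#' @return list with `score` (0 when no positive-scoring alignment exists)
#'   and, for positive scores, 1-based `qstart`, `qend`, `sstart`, `send`
#'   plus aligned strings `qseq`, `sseq` with `-` for gaps.
#' @export
sw_align <- function(query, subject, matrix = "PAM30", gap_open = 10L,
                     gap_extend = 1L) {
  if (is.character(matrix)) matrix <- load_score_matrix(matrix)
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  qi <- aa_indices(query, matrix)
  si <- aa_indices(subject, matrix)
  res <- sw_align_cpp(qi, si, matrix, as.integer(gap_open),
                      as.integer(gap_extend))
  if (res$score <= 0) return(list(score = 0L))
  qr <- strsplit(query, "")[[1]]
  sr <- strsplit(subject, "")[[1]]
  qpos <- res$qstart - 1L
  spos <- res$sstart - 1L
  qa <- character(length(res$qcols))
  sa <- character(length(res$scols))
  for (k in seq_along(res$qcols)) {
    if (res$qcols[k] == 1L) { qpos <- qpos + 1L; qa[k] <- qr[qpos] } else qa[k] <- "-"
    if (res$scols[k] == 1L) { spos <- spos + 1L; sa[k] <- sr[spos] } else sa[k] <- "-"
  }
  list(score = res$score, qstart = res$qstart, qend = res$qend,
       sstart = res$sstart, send = res$send,
       qseq = paste0(qa, collapse = ""), sseq = paste0(sa, collapse = ""))
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length (AA) and
#' `n` the database length (nt).  No effective-length edge correction is
#' applied by default (the raw `m * n` search space).
#'
#' @param score raw alignment score.
#' @param query_len_aa query length in amino acids.
#' @param db_len_nt database length in nucleotides.
#' @param ka_lambda,ka_K Karlin-Altschul parameters (positive).
#' @return expected number of chance alignments scoring `>= score`.
#' @export
evalue_ka <- function(score, query_len_aa, db_len_nt, ka_lambda, ka_K) {
  if (ka_lambda <= 0 || ka_K <= 0) stop("Karlin-Altschul parameters must be positive")
  stopifnot(query_len_aa > 0, db_len_nt > 0)
  ka_K * query_len_aa * db_len_nt * exp(-ka_lambda * score)
}

#' Bit score from a raw score
#' @inheritParams evalue_ka
#' @return bit score `(lambda * S - ln K) / ln 2`.
#' @export
bitscore_ka <- function(score, ka_lambda, ka_K) {
  (ka_lambda * score - log(ka_K)) / log(2)
}

HIT_COLUMNS <- c("qaccver", "saccver", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "sallseqid", "score", "nident", "positive",
                 "gaps", "ppos", "qframe", "sframe", "qseq", "sseq",
                 "qlen", "slen", "salltitles")

empty_hit_table <- function() {
  df <- data.frame(qaccver = character(0), saccver = character(0),
                   pident = numeric(0), length = integer(0),
                   mismatch = integer(0), gapopen = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   sallseqid = character(0), score = integer(0),
                   nident = integer(0), positive = integer(0),
                   gaps = integer(0), ppos = numeric(0),
                   qframe = integer(0), sframe = integer(0),
                   qseq = character(0), sseq = character(0),
                   qlen = integer(0), slen = integer(0),
                   salltitles = character(0), strand = character(0),
                   tissue = character(0), stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Search peptides against the six-frame translation of a genome
#'
#' For every peptide, local alignments against all six frame translations
#' of every contig are computed by exact dynamic programming (no heuristic
#' seeding).  Per (peptide, contig), the best `max_hsps_per_target` HSPs
#' are kept (at most one HSP per frame); contigs are then ranked by best
#' score and the top `max_target_seqs` retained.  Hits failing the e-value
#' or query-coverage filter are dropped.  Subject coordinates are genomic,
#' 1-based, with `sstart > send` on the minus strand.
#'
#' @param peptides named character vector of peptide sequences.
#' @param genome named character vector of contig sequences.
#' @param params an [alignment_params()] object.
#' @param tissue optional tissue label recorded in every row.
#' @param verbose print progress.
#' @return a `hit_table` data.frame in 25-column tBLASTn-tabular semantics
#'   plus `strand` and `tissue`; attribute `provenance` records the
#'   parameters and input sizes, attribute `frame_counts` the per-frame hit
#'   census.
#' @export
tblastn_search <- function(peptides, genome, params = alignment_params(),
                           tissue = NA_character_, verbose = FALSE) {
  stopifnot(inherits(params, "alignment_params"))
  if (length(peptides) == 0L) return(empty_hit_table())
  mat <- load_score_matrix(params$matrix)
  keep <- nchar(genome) >= 3L
  if (any(!keep)) warning("skipping ", sum(!keep), " contig(s) shorter than 3 nt")
  genome <- genome[keep]
  db_len <- sum(nchar(genome))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)

  # pre-translate all frames of all contigs once
  translations <- lapply(genome, six_frame_translate)
  trans_idx <- lapply(translations, function(tr)
    lapply(tr, function(p) if (nzchar(p)) aa_indices(p, mat) else integer(0)))

  rows <- vector("list", 0L)
  for (p in seq_along(peptides)) {
    pep <- toupper(peptides[[p]])
    pid <- names(peptides)[p]
    qidx <- aa_indices(pep, mat)
    qlen <- nchar(pep)
    per_contig <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      cand <- list()
      for (fi in seq_along(frames)) {
        sidx <- trans_idx[[ci]][[fi]]
        if (length(sidx) == 0L) next   # zero-length frame: skipped silently
        res <- sw_align_cpp(qidx, sidx, mat, params$gap_open, params$gap_extend)
        if (res$score <= 0L) next
        res$frame <- frames[fi]
        res$contig <- ci
        cand[[length(cand) + 1L]] <- res
      }
      if (length(cand) == 0L) next
      sc <- vapply(cand, `[[`, numeric(1), "score")
      ord <- order(-sc, vapply(cand, function(x) abs(x$frame) + 3 * (x$frame < 0),
                               numeric(1)))
      cand <- cand[ord][seq_len(min(params$max_hsps_per_target, length(cand)))]
      per_contig[[ci]] <- cand
    }
    nhit <- vapply(per_contig, length, integer(1))
    if (all(nhit == 0L)) next
    best_per_contig <- vapply(per_contig, function(cc)
      if (length(cc)) max(vapply(cc, `[[`, numeric(1), "score")) else -Inf,
      numeric(1))
    contig_rank <- order(-best_per_contig)
    keep_contigs <- contig_rank[seq_len(min(params$max_target_seqs,
                                            sum(is.finite(best_per_contig) &
                                                best_per_contig > 0)))]
    for (ci in keep_contigs) {
      for (res in per_contig[[ci]]) {
        row <- finish_hit(res, pep, pid, names(genome)[ci],
                          nchar(genome[[ci]]), translations[[ci]],
                          db_len, params, tissue)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
    if (verbose && p %% 50L == 0L) message("  peptide ", p, "/", length(peptides))
  }
  if (length(rows) == 0L) {
    tab <- empty_hit_table()
  } else {
    tab <- do.call(rbind, rows)
    class(tab) <- c("hit_table", "data.frame")
    rownames(tab) <- NULL
  }
  fc <- table(factor(tab$sframe, levels = c(-3L, -2L, -1L, 1L, 2L, 3L)))
  attr(tab, "frame_counts") <- fc
  attr(tab, "provenance") <- list(params = unclass(params),
                                  n_peptides = length(peptides),
                                  n_contigs = length(genome),
                                  db_length_nt = db_len)
  tab
}

# assemble one tabular row from a raw C++ alignment, applying filters
finish_hit <- function(res, pep, pid, contig_id, contig_len, translations,
                       db_len, params, tissue) {
  qlen <- nchar(pep)
  cov <- 100 * (res$qend - res$qstart + 1) / qlen
  if (cov < params$min_query_coverage_pct) return(NULL)
  ev <- evalue_ka(res$score, qlen, db_len, params$ka_lambda, params$ka_K)
  if (ev > params$evalue_cutoff) return(NULL)

  fname <- c("+1", "+2", "+3", "-1", "-2", "-3")[match(res$frame,
                                                       c(1, 2, 3, -1, -2, -3))]
  sprot <- translations[[fname]]
  qr <- strsplit(pep, "")[[1]]
  sr <- strsplit(substr(sprot, res$sstart, res$send), "")[[1]]
  qa <- character(length(res$qcols)); sa <- character(length(res$qcols))
  qpos <- res$qstart - 1L; spos <- 0L
  for (k in seq_along(res$qcols)) {
    if (res$qcols[k] == 1L) { qpos <- qpos + 1L; qa[k] <- qr[qpos] } else qa[k] <- "-"
    if (res$scols[k] == 1L) { spos <- spos + 1L; sa[k] <- sr[spos] } else sa[k] <- "-"
  }
  len <- length(qa)
  ident <- sum(qa == sa & qa != "-")
  mat <- load_score_matrix(params$matrix)
  both <- qa != "-" & sa != "-"
  pos <- sum(mat[cbind(ifelse(qa[both] %in% rownames(mat), qa[both], "X"),
                       ifelse(sa[both] %in% rownames(mat), sa[both], "X"))] > 0)
  mism <- sum(both & qa != sa)
  gaps <- sum(qa == "-") + sum(sa == "-")
  rle_q <- rle(qa == "-"); rle_s <- rle(sa == "-")
  gapopen <- sum(rle_q$values) + sum(rle_s$values)
  g <- aa_to_genomic(res$frame, res$sstart, res$send, contig_len)
  df <- data.frame(
    qaccver = pid, saccver = contig_id,
    pident = round(100 * ident / len, 3), length = len,
    mismatch = mism, gapopen = gapopen,
    qstart = res$qstart, qend = res$qend,
    sstart = g[1], send = g[2],
    evalue = ev, bitscore = round(bitscore_ka(res$score, params$ka_lambda,
                                              params$ka_K), 1),
    sallseqid = contig_id, score = res$score, nident = ident,
    positive = pos, gaps = gaps, ppos = round(100 * pos / len, 2),
    qframe = 0L, sframe = res$frame,
    qseq = paste0(qa, collapse = ""), sseq = paste0(sa, collapse = ""),
    qlen = qlen, slen = contig_len, salltitles = contig_id,
    strand = if (res$frame > 0) "+" else "-",
    tissue = tissue, stringsAsFactors = FALSE)
  df
}

#' Write a hit table as a 25-column tab-separated file
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @param header write a header line.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, header = FALSE) {
  utils::write.table(hits[, HIT_COLUMNS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a 25-column tBLASTn-style tabular file
#'
#' @param path input path.
#' @param header whether the file carries a header line.
#' @param tissue tissue label to attach to every row.
#' @return a `hit_table`; `strand` is reconstructed from coordinate order.
#' @export
read_hit_table <- function(path, header = FALSE, tissue = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           col.names = if (header) NULL else HIT_COLUMNS)
  if (header) names(tab) <- HIT_COLUMNS
  if (nrow(tab) == 0) return(empty_hit_table())
  tab$strand <- ifelse(tab$sstart <= tab$send, "+", "-")
  tab$tissue <- tissue
  class(tab) <- c("hit_table", "data.frame")
  tab
}
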