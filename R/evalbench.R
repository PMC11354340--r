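## Ground-truth evaluation of alignment output: correct/wrong/not-found
## accounting, intron-gap detection, and the matrix/gap-cost sweep.

#' Genomic spans of the subject-consuming gaps of a hit
#'
#' Runs of `-` in the query string of an alignment correspond to subject
#' residues with no query counterpart -- on a genomic subject these are
#' candidate introns.  Returns their genomic spans (normalized min/max).
#'
#' @param hit one row of a `hit_table`.
#' @return matrix with columns start, end (0 rows when gapless).
#' @export
hit_gap_spans <- function(hit) {
  qa <- strsplit(hit$qseq, "")[[1]]
  sa <- strsplit(hit$sseq, "")[[1]]
  out <- NULL
  k <- 0L     # subject AA consumed so far
  i <- 1L
  while (i <= length(qa)) {
    if (qa[i] == "-") {
      k1 <- k + 1L
      while (i <= length(qa) && qa[i] == "-") {
        if (sa[i] != "-") k <- k + 1L
        i <- i + 1L
      }
      k2 <- k
      if (hit$sstart <= hit$send) {
        span <- c(hit$sstart + 3L * (k1 - 1L), hit$sstart + 3L * k2 - 1L)
      } else {
        span <- c(hit$sstart - 3L * k2 + 1L, hit$sstart - 3L * (k1 - 1L))
      }
      out <- rbind(out, sort(span))
    } else {
      if (sa[i] != "-") k <- k + 1L
      i <- i + 1L
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("start", "end")
  out
}

#' Evaluate a hit table against ground truth
#'
#' A peptide is CORRECT when some hit lies on the true chromosome and its
#' footprint (min..max of subject coordinates) covers every true block
#' within `tolerance_nt`; WRONG when hits exist but none qualifies;
#' NOT FOUND when it has no hits.  A true intron counts as FOUND when a
#' correct hit carries an alignment gap whose genomic span overlaps it.
#'
#' @param hits a `hit_table`.
#' @param truth ground-truth data.frame (as in `synth_bundle$truth`:
#'   peptide_id, chrom, blocks, introns_crossed).
#' @param tolerance_nt slack allowed at footprint boundaries (default 0,
#'   exact boundaries).
#' @return list of class `"eval_result"`: total_peptides, correct, wrong,
#'   not_found, total_gaps, gaps_found, gaps_missed,
#'   correct_alignment_pct, correct_gap_pct.
#' @export
evaluate <- function(hits, truth, tolerance_nt = 0L) {
  extra <- setdiff(unique(hits$qaccver), truth$peptide_id)
  if (length(extra)) {
    message(length(extra), " hit peptide(s) absent from ground truth; excluded")
    hits <- hits[!hits$qaccver %in% extra, , drop = FALSE]
  }
  total <- nrow(truth)
  correct <- 0L; wrong <- 0L; not_found <- 0L
  total_gaps <- sum(truth$introns_crossed)
  gaps_found <- 0L
  for (i in seq_len(total)) {
    tr <- truth[i, ]
    hh <- hits[hits$qaccver == tr$peptide_id, , drop = FALSE]
    if (nrow(hh) == 0L) { not_found <- not_found + 1L; next }
    bl <- parse_blocks(tr$blocks)
    lo <- min(bl[, "start"]); hi <- max(bl[, "end"])
    ok <- which(hh$saccver == tr$chrom &
                pmin(hh$sstart, hh$send) <= lo + tolerance_nt &
                pmax(hh$sstart, hh$send) >= hi - tolerance_nt)
    if (!length(ok)) { wrong <- wrong + 1L; next }
    correct <- correct + 1L
    if (tr$introns_crossed > 0L && nrow(bl) > 1L) {
      introns <- cbind(start = bl[-nrow(bl), "end"] + 1L,
                       end = bl[-1L, "start"] - 1L)
      gspans <- do.call(rbind, lapply(ok, function(j)
        hit_gap_spans(hh[j, ])))
      for (gi in seq_len(nrow(introns))) {
        if (!is.null(gspans) && nrow(gspans) &&
            any(gspans[, "start"] <= introns[gi, "end"] &
                gspans[, "end"] >= introns[gi, "start"])) {
          gaps_found <- gaps_found + 1L
        }
      }
    }
  }
  structure(list(total_peptides = total, correct = correct, wrong = wrong,
                 not_found = not_found, total_gaps = total_gaps,
                 gaps_found = gaps_found,
                 gaps_missed = total_gaps - gaps_found,
                 correct_alignment_pct = if (total) 100 * correct / total else NA,
                 correct_gap_pct = if (total_gaps) 100 * gaps_found / total_gaps
                   else NA),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: %d peptides | correct %d (%.1f%%), wrong %d, not found %d | gaps %d/%d (%.1f%%)\n",
    x$total_peptides, x$correct, x$correct_alignment_pct, x$wrong,
    x$not_found, x$gaps_found, x$total_gaps,
    ifelse(is.na(x$correct_gap_pct), 0, x$correct_gap_pct)))
  invisible(x)
}

#' The default 12-configuration matrix/gap-cost sweep
#'
#' Labels are the historical test numbers of the optimization experiment.
#'
#' @return data.frame: label, matrix, gap_open, gap_extend.
#' @export
default_sweep_configs <- function() {
  data.frame(
    label = paste0("test", c(8, 5, 7, 4, 6, 1, 9, 10, 3, 2, 12, 11)),
    matrix = c("PAM30", "BLOSUM90", "PAM30", "BLOSUM90", "PAM30",
               "BLOSUM90", "PAM30", "PAM30", "BLOSUM90", "BLOSUM90",
               "BLOSUM45", "PAM250"),
    gap_open = c(10L, 11L, 8L, 9L, 5L, 6L, 14L, 15L, 9L, 8L, 19L, 21L),
    gap_extend = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Run an alignment-parameter sweep against ground truth
#'
#' One search + evaluation per configuration; a configuration whose matrix
#' cannot be resolved yields a row flagged `failed` and the sweep
#' continues.
#'
#' @param peptides named peptide vector.
#' @param genome named contig vector.
#' @param configs data.frame like [default_sweep_configs()].
#' @param truth ground-truth data.frame.
#' @param tolerance_nt passed to [evaluate()].
#' @param base_params an [alignment_params()] supplying the non-swept
#'   settings (filters, HSP limits).
#' @return data.frame with one row per configuration: label, matrix,
#'   gap_open, gap_extend, total_peptides, wrong, not_found, correct,
#'   correct_alignment_pct, total_gaps, gaps_found, gaps_missed,
#'   correct_gap_pct, elapsed_s, failed.
#' @export
run_sweep <- function(peptides, genome, configs = default_sweep_configs(),
                      truth, tolerance_nt = 0L,
                      base_params = alignment_params()) {
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    cf <- configs[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      params <- alignment_params(
        matrix = cf$matrix, gap_open = cf$gap_open,
        gap_extend = cf$gap_extend,
        evalue_cutoff = base_params$evalue_cutoff,
        max_target_seqs = base_params$max_target_seqs,
        max_hsps_per_target = base_params$max_hsps_per_target,
        min_query_coverage_pct = base_params$min_query_coverage_pct)
      hits <- tblastn_search(peptides, genome, params)
      evaluate(hits, truth, tolerance_nt)
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      data.frame(label = cf$label, matrix = cf$matrix,
                 gap_open = cf$gap_open, gap_extend = cf$gap_extend,
                 total_peptides = NA, wrong = NA, not_found = NA,
                 correct = NA, correct_alignment_pct = NA, total_gaps = NA,
                 gaps_found = NA, gaps_missed = NA, correct_gap_pct = NA,
                 elapsed_s = elapsed, failed = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = cf$label, matrix = cf$matrix,
                 gap_open = cf$gap_open, gap_extend = cf$gap_extend,
                 total_peptides = res$total_peptides, wrong = res$wrong,
                 not_found = res$not_found, correct = res$correct,
                 correct_alignment_pct = res$correct_alignment_pct,
                 total_gaps = res$total_gaps, gaps_found = res$gaps_found,
                 gaps_missed = res$gaps_missed,
                 correct_gap_pct = res$correct_gap_pct,
                 elapsed_s = elapsed, failed = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank sweep results
#'
#' Orders by correct peptides (descending), then correctly detected gaps
#' (descending), then elapsed time (ascending).  Rows with identical keys
#' share a rank (competition ranking).
#'
#' @param rows output of [run_sweep()].
#' @return `rows` sorted, with a `rank` column.
#' @export
rank_sweep <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  ok <- !rows$failed
  r <- rows[ok, , drop = FALSE]
  ord <- order(-r$correct, -r$gaps_found, r$elapsed_s)
  r <- r[ord, , drop = FALSE]
  key <- paste(r$correct, r$gaps_found, r$elapsed_s)
  r$rank <- match(key, unique(key))
  # competition ranking: rank = 1 + number of strictly better rows
  first_of_key <- !duplicated(key)
  pos <- seq_len(nrow(r))
  r$rank <- pos[first_of_key][match(key, key[first_of_key])]
  f <- rows[!ok, , drop = FALSE]
  if (nrow(f)) { f$rank <- NA_integer_; r <- rbind(r, f) }
  rownames(r) <- NULL
  r
}
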