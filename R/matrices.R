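## Substitution matrices and Karlin-Altschul parameters.
##
## The matrices ship as NCBI-format text files under inst/extdata/matrices
## and are parsed at load time; values are fixtures, never hand-typed here.

matrix_cache <- new.env(parent = emptyenv())

#' Names of the bundled substitution matrices
#' @return character vector of matrix names.
#' @export
list_score_matrices <- function() {
  files <- list.files(system.file("extdata", "matrices", package = "pepmapr"),
                      pattern = "\\.txt$")
  sub("\\.txt$", "", files)
}

#' Parse an NCBI-format substitution matrix file
#'
#' @param path path to a whitespace-delimited matrix file with a column
#'   header row; `#` lines are comments.
#' @return integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1]), integer(length(header))))
  dimnames(vals) <- list(rows, header)
  if (!identical(rownames(vals), colnames(vals))) {
    stop("matrix file ", path, ": row/column alphabets differ")
  }
  vals
}

#' Load a bundled substitution matrix by name
#'
#' @param name one of [list_score_matrices()], e.g. `"PAM30"`.
#' @return integer score matrix (cached).
#' @export
load_score_matrix <- function(name) {
  if (!is.null(matrix_cache[[name]])) return(matrix_cache[[name]])
  path <- system.file("extdata", "matrices", paste0(name, ".txt"),
                      package = "pepmapr")
  if (!nzchar(path)) {
    stop("unknown substitution matrix: ", name,
         " (available: ", paste(list_score_matrices(), collapse = ", "), ")")
  }
  m <- read_score_matrix(path)
  attr(m, "name") <- name
  matrix_cache[[name]] <- m
  m
}

#' Karlin-Altschul parameters for a (matrix, gap cost) combination
#'
#' Values come from a bundled constants table (as reported by NCBI tblastn
#' for the supported combinations).  When the exact gapped combination is
#' absent, the matrix's ungapped (ideal) parameters are returned with a
#' warning; absolute e-values are then approximate, which the toolkit's
#' filters tolerate (ranking by score is unaffected).
#'
#' @param matrix matrix name.
#' @param gap_open,gap_extend gap costs; `NULL` requests ungapped values.
#' @return list with elements `lambda`, `K`, `H`, `exact` (logical).
#' @export
ka_parameters <- function(matrix, gap_open = NULL, gap_extend = NULL) {
  path <- system.file("extdata", "ka_constants.tsv", package = "pepmapr")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(gap_open)) {
    hit <- tab$matrix == matrix & !is.na(tab$gap_open) &
      tab$gap_open == gap_open & tab$gap_extend == gap_extend
    if (any(hit)) {
      r <- tab[which(hit)[1], ]
      return(list(lambda = r$lambda, K = r$K, H = r$H, exact = TRUE))
    }
  }
  hit <- tab$matrix == matrix & is.na(tab$gap_open)
  if (!any(hit)) stop("no Karlin-Altschul constants for matrix ", matrix)
  r <- tab[which(hit)[1], ]
  if (!is.null(gap_open)) {
    warning("no gapped Karlin-Altschul constants for ", matrix, " ",
            gap_open, "/", gap_extend, "; using ungapped values")
  }
  list(lambda = r$lambda, K = r$K, H = r$H, exact = is.null(gap_open))
}
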