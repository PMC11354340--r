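## Peptide physicochemical properties (length, average molecular weight,
## GRAVY, aromaticity, isoelectric point) and the risk flag for peptides
## that translated local alignment tends to miss.
##
## Conventions follow the ProtParam lineage: average residue masses, the
## Kyte-Doolittle hydropathy scale, and a Bjellqvist-style pK set with the
## isoelectric point solved by bisection on the Henderson-Hasselbalch net
## charge.

physchem_cache <- new.env(parent = emptyenv())

aa_property_table <- function() {
  if (is.null(physchem_cache$props)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "pepmapr")
    physchem_cache$props <- utils::read.table(path, header = TRUE, sep = "\t",
                                              comment.char = "#",
                                              stringsAsFactors = FALSE)
  }
  physchem_cache$props
}

pk_table <- function() {
  if (is.null(physchem_cache$pk)) {
    path <- system.file("extdata", "pk_table.tsv", package = "pepmapr")
    physchem_cache$pk <- utils::read.table(path, header = TRUE, sep = "\t",
                                           comment.char = "#",
                                           stringsAsFactors = FALSE,
                                           na.strings = "NA")
  }
  physchem_cache$pk
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the charged side chains (K, R, H
#' positive; D, E, C, Y negative) and both termini, with terminal pK
#' overrides for specific first/last residues.
#'
#' @param seq peptide sequence (standard 20 AA letters).
#' @param pH pH value.
#' @return net charge (can be negative).
#' @export
charge_at_ph <- function(seq, pH) {
  pk <- pk_table()
  res <- strsplit(toupper(seq), "")[[1]]
  counts <- table(res)
  getpk <- function(group, residue) {
    r <- pk[pk$group == group & pk$residue == residue, "pk"]
    if (length(r)) r[1] else NA_real_
  }
  pos <- 0
  nt <- getpk("nterm", res[1])
  if (is.na(nt)) nt <- getpk("pos", "Nterm")
  pos <- pos + 1 / (1 + 10^(pH - nt))
  for (r in c("K", "R", "H")) {
    n <- counts[r]
    if (!is.na(n)) pos <- pos + n / (1 + 10^(pH - getpk("pos", r)))
  }
  neg <- 0
  ct <- getpk("cterm", res[length(res)])
  if (is.na(ct)) ct <- getpk("neg", "Cterm")
  neg <- neg + 1 / (1 + 10^(ct - pH))
  for (r in c("D", "E", "C", "Y")) {
    n <- counts[r]
    if (!is.na(n)) neg <- neg + n / (1 + 10^(getpk("neg", r) - pH))
  }
  unname(pos - neg)
}

#' Isoelectric point by bisection
#'
#' Bisects the net charge between pH 4.05 and 12 (the ProtParam search
#' window) to an interval of 1e-4 pH units.
#'
#' @inheritParams charge_at_ph
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  lo <- 4.05; hi <- 12
  pH <- 7.775
  while (hi - lo > 1e-4) {
    if (charge_at_ph(seq, pH) > 0) lo <- pH else hi <- pH
    pH <- (lo + hi) / 2
  }
  pH
}

#' Physicochemical properties of a peptide
#'
#' @param seq peptide over the standard 20 amino acids (X and * rejected).
#' @return list of class `"peptide_properties"`: `length`, `mw` (average
#'   molecular weight, Da), `gravy` (mean Kyte-Doolittle hydropathy),
#'   `aromaticity` (fraction of F/W/Y), `pi`.
#' @export
compute_properties <- function(seq) {
  seq <- toupper(seq)
  res <- strsplit(seq, "")[[1]]
  props <- aa_property_table()
  bad <- setdiff(unique(res), props$aa)
  if (length(bad)) {
    stop("cannot compute properties: non-standard residue(s) ",
         paste(bad, collapse = ", "))
  }
  idx <- match(res, props$aa)
  n <- length(res)
  structure(list(
    length = n,
    mw = sum(props$mw[idx]) - (n - 1) * 18.0153,
    gravy = mean(props$kd[idx]),
    aromaticity = sum(res %in% c("F", "W", "Y")) / n,
    pi = isoelectric_point(seq)),
    class = "peptide_properties")
}

#' Default risk thresholds for translated-search misses
#'
#' Missed peptides tend to be short, with GRAVY outside (-2.2, 0.6) or
#' aromaticity above 0.14.
#'
#' @param gravy_low,gravy_high GRAVY bounds (flag outside the open range).
#' @param aromaticity_max aromaticity threshold (flag above).
#' @param min_length minimum length in AA (flag below).
#' @return list of class `"risk_thresholds"`.
#' @export
risk_thresholds <- function(gravy_low = -2.2, gravy_high = 0.6,
                            aromaticity_max = 0.14, min_length = 8L) {
  stopifnot(gravy_low < gravy_high)
  structure(list(gravy_low = gravy_low, gravy_high = gravy_high,
                 aromaticity_max = aromaticity_max,
                 min_length = as.integer(min_length)),
            class = "risk_thresholds")
}

#' Flag a peptide at risk of being missed by translated search
#'
#' @param props a `peptide_properties` object.
#' @param thresholds a [risk_thresholds()] object.
#' @return logical with attribute `reasons` (character vector naming each
#'   triggered criterion: "gravy", "aromaticity", "length").
#' @export
flag_tblastn_risk <- function(props, thresholds = risk_thresholds()) {
  reasons <- character(0)
  if (props$gravy > thresholds$gravy_high ||
      props$gravy < thresholds$gravy_low) reasons <- c(reasons, "gravy")
  if (props$aromaticity > thresholds$aromaticity_max) {
    reasons <- c(reasons, "aromaticity")
  }
  if (props$length < thresholds$min_length) reasons <- c(reasons, "length")
  structure(length(reasons) > 0L, reasons = reasons)
}

#' Property table for a set of peptides
#'
#' @param peptides named character vector.
#' @param thresholds a [risk_thresholds()].
#' @return data.frame: peptide_id, length, mw, gravy, aromaticity, pi,
#'   risk_flag, risk_reasons.
#' @export
peptide_property_table <- function(peptides, thresholds = risk_thresholds()) {
  rows <- lapply(seq_along(peptides), function(i) {
    p <- compute_properties(peptides[[i]])
    fl <- flag_tblastn_risk(p, thresholds)
    data.frame(peptide_id = names(peptides)[i], length = p$length,
               mw = p$mw, gravy = p$gravy, aromaticity = p$aromaticity,
               pi = p$pi, risk_flag = as.logical(fl),
               risk_reasons = paste(attr(fl, "reasons"), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
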