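#' Read a proteome FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @return named character vector of sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Read a PSM table
#'
#' Expects the tab-separated schema written by [write_dataset()]: `peptide`,
#' `protein_id`, `score`, `ion_score`, `consecutive_ions`, `decoy`,
#' `method`, `replicate`.
#'
#' @param path TSV file.
#' @return data frame of PSMs.
#' @export
read_psms <- function(path) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "protein_id", "score", "decoy")
  miss <- setdiff(need, names(psms))
  if (length(miss)) {
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  psms$decoy <- as.logical(psms$decoy)
  psms
}

#' Read paired XIC traces and their pair metadata
#'
#' @param trace_path TSV with columns `rt`, `intensity_light`,
#'   `intensity_heavy`, `peptide`, `replicate`.
#' @param pair_path TSV with per-pair metadata (`peptide`, `protein_id`,
#'   `replicate`, `ion_score`, ...), as written by [write_dataset()].
#' @return an `xic_set` usable by [quantify_xic_pairs()].
#' @export
read_xic_set <- function(trace_path, pair_path) {
  traces <- utils::read.delim(trace_path, stringsAsFactors = FALSE)
  pairs <- utils::read.delim(pair_path, stringsAsFactors = FALSE)
  need <- c("rt", "intensity_light", "intensity_heavy", "peptide")
  miss <- setdiff(need, names(traces))
  if (length(miss)) {
    stop("XIC trace table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(pairs = pairs, traces = traces), class = "xic_set")
}

#' Read a pigment absorbance readings table
#'
#' @param path TSV with columns `od615`, `od652`, `od665` and optional
#'   `sample`, `phase`, `timepoint`, `path_cm`, `dry_weight_mg`.
#' @return data frame of readings.
#' @export
read_readings <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
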