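# Monoisotopic residue masses (Da) for the 20 standard amino acids, plus the
# mass of water added at the peptide termini and the proton mass used for m/z.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO <- 18.010565
PROTON_MASS <- 1.007276

# Mass difference between one 13C6- and one 12C6-nicotinoyl ICPL label
# (6 x the 13C-12C neutron-binding mass difference).
ICPL_LABEL_DELTA <- 6.0201

#' Monoisotopic peptide mass
#'
#' @param peptides character vector of peptide sequences (standard residues).
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("AAK")
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(AA_MONO))
    if (length(bad)) {
      stop("unknown residue '", bad[1], "' in peptide ", p, call. = FALSE)
    }
    sum(AA_MONO[aa]) + WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
}

#' Number of ICPL label sites on a peptide
#'
#' Post-digest ICPL labels every lysine side chain and the peptide N-terminus,
#' so the site count is (number of K residues) + 1.
#'
#' @param peptides character vector of peptide sequences.
#' @return integer vector of label-site counts (always >= 1).
#' @examples
#' icpl_label_sites("AAK") # 2: one lysine + the N-terminus
#' @export
icpl_label_sites <- function(peptides) {
  vapply(peptides, function(p) {
    sum(strsplit(p, "", fixed = TRUE)[[1]] == "K") + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and returns every peptide carrying 0..`max_missed` internal missed
#' cleavage sites, together with its monoisotopic mass.
#'
#' @param sequence a single protein sequence (standard residues).
#' @param max_missed maximum number of missed cleavage sites per peptide.
#' @return data frame with columns `peptide`, `missed_cleavages`, `mass`.
#' @examples
#' digest("MKTAYIAKQR", max_missed = 0)$peptide
#' @export
digest <- function(sequence, max_missed = 1L) {
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad)) {
    stop("unknown residue '", bad[1], "' in sequence", call. = FALSE)
  }
  n <- length(aa)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  out_pep <- character(0)
  out_mc <- integer(0)
  for (m in 0:max_missed) {
    if (nfrag - m < 1L) break
    for (i in seq_len(nfrag - m)) {
      out_pep <- c(out_pep, substr(sequence, starts[i], ends[i + m]))
      out_mc <- c(out_mc, m)
    }
  }
  keep <- !duplicated(out_pep)
  data.frame(
    peptide = out_pep[keep],
    missed_cleavages = out_mc[keep],
    mass = peptide_mass(out_pep[keep]),
    stringsAsFactors = FALSE
  )
}

#' Observable tryptic peptides of a protein
#'
#' A tryptic peptide (with up to `max_missed` missed cleavages) counts as
#' observable when the m/z of its doubly protonated ion falls inside the MS
#' scan range. The count feeds the emPAI denominator.
#'
#' @param sequence protein sequence.
#' @param scan_range numeric `(low, high)` m/z window.
#' @param max_missed maximum missed cleavages.
#' @return integer count of observable peptides.
#' @export
observable_peptides <- function(sequence, scan_range = c(300, 1500),
                                max_missed = 1L) {
  pep <- digest(sequence, max_missed = max_missed)
  mz2 <- (pep$mass + 2 * PROTON_MASS) / 2
  sum(mz2 >= scan_range[1] & mz2 <= scan_range[2])
}
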