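#' Simulation configuration for synthetic proteomics datasets
#'
#' Bundles every knob of the synthetic-data generator: proteome size and
#' composition, the lognormal copy-number law, the light/dark fold-change
#' design, per-method peptide detection probabilities (which induce the Venn
#' structure across fractionation workflows), the decoy-PSM rate, the
#' multiplicative peptide-ratio noise, and the chromatographic grid used for
#' simulated XIC pairs.
#'
#' @param n_proteins number of proteins in the simulated proteome.
#' @param mean_protein_length mean sequence length in residues.
#' @param abundance_mu,abundance_sigma parameters of the lognormal copy-number
#'   distribution (natural-log scale).
#' @param fold_change_spec data frame with columns `fraction` and `ratio`:
#'   each row assigns `fraction` of the proteins the true light/dark ratio
#'   `ratio`. Fractions must sum to 1.
#' @param n_replicates number of biological replicates (the diel design uses 2).
#' @param peptide_ratio_noise_sigma standard deviation of natural-log peptide
#'   ratios around the protein's true log ratio.
#' @param method_detection_probs named numeric vector mapping a fractionation
#'   method label to its per-peptide detection probability.
#' @param decoy_psm_rate expected fraction of decoy rows among generated PSMs,
#'   in `[0, 1)`.
#' @param scan_range MS scan range `(low, high)` in m/z; doubly protonated
#'   tryptic peptides inside this window count as observable for emPAI.
#' @param seed integer seed; every generator call derives its random stream
#'   from it, so a fixed config yields bit-identical datasets.
#' @param max_missed maximum missed tryptic cleavages for observable peptides.
#' @param n_scans,rt_spacing retention-time grid for simulated XIC traces:
#'   `n_scans` points spaced `rt_spacing` time units apart.
#' @param peak_width Gaussian elution peak standard deviation, in scans.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_proteins = 20, seed = 1)
#' cfg$scan_range
#' @export
sim_config <- function(n_proteins = 200,
                       mean_protein_length = 300,
                       abundance_mu = log(1e4),
                       abundance_sigma = 1.5,
                       fold_change_spec = data.frame(
                         fraction = c(0.8, 0.1, 0.1),
                         ratio = c(1, 2, 0.5)
                       ),
                       n_replicates = 2,
                       peptide_ratio_noise_sigma = 0.2,
                       method_detection_probs = c(
                         IEF = 0.25, SDS_PAGE = 0.22,
                         LC2D = 0.45, LC3D = 0.35
                       ),
                       decoy_psm_rate = 0.01,
                       scan_range = c(300, 1500),
                       seed = 1L,
                       max_missed = 1L,
                       n_scans = 21L,
                       rt_spacing = 1,
                       peak_width = 2) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    mean_protein_length = mean_protein_length,
    abundance_mu = abundance_mu,
    abundance_sigma = abundance_sigma,
    fold_change_spec = as.data.frame(fold_change_spec),
    n_replicates = as.integer(n_replicates),
    peptide_ratio_noise_sigma = peptide_ratio_noise_sigma,
    method_detection_probs = method_detection_probs,
    decoy_psm_rate = decoy_psm_rate,
    scan_range = as.numeric(scan_range),
    seed = as.integer(seed),
    max_missed = as.integer(max_missed),
    n_scans = as.integer(n_scans),
    rt_spacing = rt_spacing,
    peak_width = peak_width
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$fold_change_spec))
  if (cfg$n_proteins < 1L) {
    stop("configuration error: n_proteins must be >= 1", call. = FALSE)
  }
  if (!all(c("fraction", "ratio") %in% names(cfg$fold_change_spec))) {
    stop("configuration error: fold_change_spec needs columns 'fraction' and 'ratio'",
      call. = FALSE
    )
  }
  if (abs(sum(cfg$fold_change_spec$fraction) - 1) > 1e-8) {
    stop("configuration error: fold_change_spec fractions must sum to 1",
      call. = FALSE
    )
  }
  if (any(cfg$fold_change_spec$ratio <= 0)) {
    stop("configuration error: true ratios must be positive", call. = FALSE)
  }
  if (!is.finite(cfg$peptide_ratio_noise_sigma) ||
    cfg$peptide_ratio_noise_sigma <= 0) {
    stop("configuration error: peptide_ratio_noise_sigma must be > 0",
      call. = FALSE
    )
  }
  if (length(cfg$method_detection_probs) &&
    (any(cfg$method_detection_probs < 0) ||
      any(cfg$method_detection_probs > 1))) {
    stop("configuration error: detection probabilities must lie in [0, 1]",
      call. = FALSE
    )
  }
  if (cfg$decoy_psm_rate < 0 || cfg$decoy_psm_rate >= 1) {
    stop("configuration error: decoy_psm_rate must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$scan_range) != 2L || cfg$scan_range[1] >= cfg$scan_range[2]) {
    stop("configuration error: scan_range must satisfy low < high", call. = FALSE)
  }
  if (!is.finite(cfg$abundance_sigma) || cfg$abundance_sigma <= 0) {
    stop("configuration error: abundance_sigma must be > 0", call. = FALSE)
  }
  if (is.na(cfg$seed)) {
    stop("configuration error: seed must be set", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic proteomics simulation config\n")
  cat(sprintf(
    "  %d proteins, mean length %g aa, %d replicate(s), seed %d\n",
    x$n_proteins, x$mean_protein_length, x$n_replicates, x$seed
  ))
  cat(sprintf(
    "  abundance ~ lognormal(%.3g, %.3g); peptide log-ratio sd %.3g\n",
    x$abundance_mu, x$abundance_sigma, x$peptide_ratio_noise_sigma
  ))
  cat(sprintf(
    "  methods: %s\n",
    paste(sprintf(
      "%s=%.2f", names(x$method_detection_probs),
      x$method_detection_probs
    ), collapse = ", ")
  ))
  cat(sprintf(
    "  decoy rate %.3g; scan range %g-%g m/z\n",
    x$decoy_psm_rate, x$scan_range[1], x$scan_range[2]
  ))
  invisible(x)
}
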