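# Typical amino-acid background frequencies (bacterial proteomes), used to
# sample synthetic sequences; K and R at realistic rates so tryptic digestion
# yields realistic peptide lengths.
AA_FREQ <- c(
  A = 0.089, R = 0.055, N = 0.039, D = 0.054, C = 0.010,
  Q = 0.038, E = 0.061, G = 0.074, H = 0.021, I = 0.060,
  L = 0.100, K = 0.052, M = 0.024, F = 0.039, P = 0.044,
  S = 0.058, T = 0.054, W = 0.012, Y = 0.029, V = 0.068
)

#' Generate a ground-truth proteome
#'
#' Draws random protein sequences, lognormal copy-number abundances, and true
#' light/dark fold changes according to `fold_change_spec`, then digests every
#' protein (fully cleaved peptides) and assigns each peptide a detectability
#' through a logistic link on protein abundance — more abundant proteins are
#' more likely to be sampled by the mass spectrometer, which is what makes a
#' handful of highly expressed proteins dominate shotgun runs.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `ground_truth`: a list with
#'   \describe{
#'     \item{proteins}{data frame `protein_id`, `sequence`, `abundance`,
#'       `true_ratio`}
#'     \item{peptides}{data frame `protein_id`, `peptide`, `mass`,
#'       `n_label_sites`, `detectability`, `true_ratio`}
#'   }
#' @examples
#' truth <- generate_proteome(sim_config(n_proteins = 5, seed = 42))
#' nrow(truth$proteins)
#' @export
generate_proteome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- pmax(30L, as.integer(round(
    stats::rgamma(n, shape = 9, scale = config$mean_protein_length / 9)
  )))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
      collapse = ""
    )
  }, character(1))
  abundance <- stats::rlnorm(n, config$abundance_mu, config$abundance_sigma)

  # deterministic partition of proteins into fold-change classes, then a
  # random permutation so class membership is not confounded with abundance
  fcs <- config$fold_change_spec
  counts <- diff(c(0L, round(cumsum(fcs$fraction) * n)))
  ratios <- sample(rep(fcs$ratio, counts))

  proteins <- data.frame(
    protein_id = sprintf("SYN_%04d", seq_len(n)),
    sequence = seqs,
    abundance = abundance,
    true_ratio = ratios,
    stringsAsFactors = FALSE
  )

  pep_list <- lapply(seq_len(n), function(i) {
    d <- digest(seqs[i], max_missed = 0L)
    d$protein_id <- proteins$protein_id[i]
    d
  })
  peptides <- do.call(rbind, pep_list)
  # logistic detectability link on log abundance, centred on the configured
  # median so the most abundant proteins approach certain detection
  z <- (log(proteins$abundance[match(
    peptides$protein_id, proteins$protein_id
  )]) - config$abundance_mu) / config$abundance_sigma
  peptides$detectability <- stats::plogis(1.5 * z + 1)
  peptides$n_label_sites <- icpl_label_sites(peptides$peptide)
  peptides$true_ratio <- proteins$true_ratio[match(
    peptides$protein_id, proteins$protein_id
  )]
  peptides <- peptides[, c(
    "protein_id", "peptide", "mass",
    "n_label_sites", "detectability", "true_ratio"
  )]
  rownames(peptides) <- NULL

  structure(list(proteins = proteins, peptides = peptides),
    class = "ground_truth"
  )
}

#' Simulate PSM tables for each fractionation method
#'
#' Every fully tryptic peptide is detected in method `m` with probability
#' `method_detection_probs[m] ^ (1 / detectability)` — the logistic
#' abundance link damps detection of low-abundance proteins while leaving
#' certain detection (probability 1) certain. Each detection produces one
#' target PSM with a high-scoring "correct" score component plus a minority
#' null component. Decoy PSMs (reversed peptide sequences, `DECOY_` protein
#' ids) are injected so that their expected share of all rows equals
#' `decoy_psm_rate`; decoy scores come from the null score component only,
#' the standard target-decoy assumption.
#'
#' @param truth a `ground_truth` object from [generate_proteome()].
#' @param config the [sim_config()] used to build it.
#' @return data frame with columns `peptide`, `protein_id`, `score`,
#'   `ion_score`, `consecutive_ions`, `decoy`, `method`, `replicate`.
#' @export
simulate_psm_tables <- function(truth, config) {
  validate_sim_config(config)
  if (!length(config$method_detection_probs)) {
    stop("configuration error: method_detection_probs must be non-empty",
      call. = FALSE
    )
  }
  set.seed(config$seed + 1L)
  pep <- truth$peptides
  tables <- lapply(names(config$method_detection_probs), function(m) {
    # abundance-linked exponent: detectability in (0,1), so low-abundance
    # peptides are penalized while certain detection (p = 1) stays certain
    p <- config$method_detection_probs[[m]]^(1 / pep$detectability)
    hit <- stats::runif(nrow(pep)) < p
    k <- sum(hit)
    if (k == 0L) {
      return(NULL)
    }
    correct <- stats::runif(k) < 0.9
    score <- ifelse(correct,
      pmax(1, stats::rnorm(k, 70, 15)),
      null_score(k)
    )
    data.frame(
      peptide = pep$peptide[hit],
      protein_id = pep$protein_id[hit],
      score = score,
      ion_score = pmax(1, stats::rnorm(k, 55, 12)),
      consecutive_ions = stats::rpois(k, 6),
      decoy = FALSE,
      method = m,
      replicate = 1L,
      stringsAsFactors = FALSE
    )
  })
  psms <- do.call(rbind, tables)
  if (is.null(psms)) {
    stop("no PSMs generated; detection probabilities too low", call. = FALSE)
  }
  rate <- config$decoy_psm_rate
  if (rate > 0) {
    n_target <- nrow(psms)
    n_decoy <- stats::rpois(1L, n_target * rate / (1 - rate))
    if (n_decoy > 0L) {
      src <- sample.int(n_target, n_decoy, replace = TRUE)
      rev_pep <- vapply(
        strsplit(psms$peptide[src], "", fixed = TRUE),
        function(x) paste(rev(x), collapse = ""), character(1)
      )
      decoys <- data.frame(
        peptide = rev_pep,
        protein_id = paste0("DECOY_", psms$protein_id[src]),
        score = null_score(n_decoy),
        ion_score = pmax(1, stats::rnorm(n_decoy, 25, 8)),
        consecutive_ions = stats::rpois(n_decoy, 2),
        decoy = TRUE,
        method = psms$method[src],
        replicate = 1L,
        stringsAsFactors = FALSE
      )
      psms <- rbind(psms, decoys)
    }
  }
  rownames(psms) <- NULL
  psms
}

# low-score null component shared by random target matches and decoys
null_score <- function(n) 5 + stats::rexp(n, rate = 1 / 12)

#' Simulate paired light/heavy XIC traces for one replicate
#'
#' Each quantifiable peptide (sampled by its detectability) yields a pair of
#' Gaussian elution peaks on a shared retention-time grid with identical peak
#' centre and width. The heavy:light area ratio is
#' `true_ratio * exp(N(0, peptide_ratio_noise_sigma))`; heavy label marks the
#' light-phase culture, light label the dark-phase culture, so the reported
#' heavy/light ratio is the light/dark abundance ratio. The heavy peptide
#' mass is the light mass plus 6.0201 Da per ICPL label site.
#'
#' @param truth a `ground_truth` object.
#' @param config the [sim_config()].
#' @param replicate replicate index (enters the random stream, so replicates
#'   are independent draws).
#' @param keep_all if `TRUE`, generate a pair for every peptide regardless of
#'   detectability (useful for calibration studies).
#' @return An object of class `xic_set`: list with `pairs` (one row per
#'   peptide: ids, ion score, masses, label sites, simulated area ratio) and
#'   `traces` (long data frame `rt`, `intensity_light`, `intensity_heavy`,
#'   `peptide`, `replicate`).
#' @export
simulate_xic_pairs <- function(truth, config, replicate = 1L,
                               keep_all = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed + 100L + as.integer(replicate))
  pep <- truth$peptides
  take <- if (keep_all) {
    rep(TRUE, nrow(pep))
  } else {
    stats::runif(nrow(pep)) < pep$detectability
  }
  pep <- pep[take, , drop = FALSE]
  k <- nrow(pep)
  if (k == 0L) {
    stop("no quantifiable peptides sampled; raise detection rates", call. = FALSE)
  }
  rt <- (seq_len(config$n_scans) - 1) * config$rt_spacing
  centre <- rt[ceiling(length(rt) / 2)]
  prot_ab <- truth$proteins$abundance[match(
    pep$protein_id, truth$proteins$protein_id
  )]
  area_light <- prot_ab * stats::rlnorm(k, 0, 0.3)
  noise <- exp(stats::rnorm(k, 0, config$peptide_ratio_noise_sigma))
  area_heavy <- area_light * pep$true_ratio * noise

  shape <- stats::dnorm(rt, centre, config$peak_width)
  traces <- data.frame(
    rt = rep(rt, k),
    intensity_light = as.vector(outer(shape, area_light)),
    intensity_heavy = as.vector(outer(shape, area_heavy)),
    peptide = rep(pep$peptide, each = length(rt)),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    peptide = pep$peptide,
    protein_id = pep$protein_id,
    replicate = as.integer(replicate),
    ion_score = pmax(1, stats::rnorm(k, 55, 12)),
    n_label_sites = pep$n_label_sites,
    mass_light = pep$mass,
    mass_heavy = pep$mass + ICPL_LABEL_DELTA * pep$n_label_sites,
    true_ratio = pep$true_ratio,
    sim_area_ratio = area_heavy / area_light,
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, traces = traces), class = "xic_set")
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_proteome()], [simulate_psm_tables()] and
#' [simulate_xic_pairs()] for every replicate under one seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `synthetic_dataset`: list with `truth`, `psms`,
#'   `xic` (list of `xic_set`, one per replicate) and the `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- generate_proteome(config)
  psms <- simulate_psm_tables(truth, config)
  xic <- lapply(seq_len(config$n_replicates), function(r) {
    simulate_xic_pairs(truth, config, replicate = r)
  })
  structure(list(truth = truth, psms = psms, xic = xic, config = config),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset to plain-text files
#'
#' Serializes the proteome as FASTA, PSMs and ground truth as TSV, and the
#' XIC traces as one TSV per replicate.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteome.fasta")
  seqs <- Biostrings::AAStringSet(dataset$truth$proteins$sequence)
  names(seqs) <- dataset$truth$proteins$protein_id
  Biostrings::writeXStringSet(seqs, fa)
  files <- fa

  psm_file <- file.path(dir, "psms.tsv")
  utils::write.table(dataset$psms, psm_file,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  files <- c(files, psm_file)

  truth_file <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth$proteins[, c("protein_id", "abundance", "true_ratio")],
    truth_file,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  files <- c(files, truth_file)

  for (x in dataset$xic) {
    r <- x$pairs$replicate[1]
    f <- file.path(dir, sprintf("xic_rep%d.tsv", r))
    utils::write.table(x$traces, f,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    p <- file.path(dir, sprintf("xic_pairs_rep%d.tsv", r))
    utils::write.table(x$pairs, p,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    files <- c(files, f, p)
  }
  invisible(files)
}
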