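#' Peptide quantification ratio from an accepted isotope pair
#'
#' The raw ratio is `area_heavy / area_light`; the heavy label marks the
#' light-phase culture and the light label the dark-phase culture, so the
#' ratio reads as light-phase over dark-phase abundance. Pairs whose peptide
#' identification carries an ion score of 30 or less are rejected, as is any
#' pair with a zero area.
#'
#' @param pair an accepted `isotope_pair` from [match_pair()].
#' @param ion_score the identification ion score of the peptide.
#' @param min_ion_score strict lower bound for quantification (default 30).
#' @return list with `accepted`, and either `ratio` or a `reason` code
#'   (`pair_rejected`, `low_ion_score`, `zero_light_area`,
#'   `zero_heavy_area`).
#' @export
peptide_ratio <- function(pair, ion_score, min_ion_score = 30) {
  if (!isTRUE(pair$accepted)) {
    return(list(accepted = FALSE, reason = "pair_rejected"))
  }
  if (ion_score <= min_ion_score) {
    return(list(accepted = FALSE, reason = "low_ion_score"))
  }
  if (pair$area_light == 0) {
    return(list(accepted = FALSE, reason = "zero_light_area"))
  }
  if (pair$area_heavy == 0) {
    return(list(accepted = FALSE, reason = "zero_heavy_area"))
  }
  list(accepted = TRUE, ratio = pair$area_heavy / pair$area_light)
}

#' Quantify every XIC pair of a replicate
#'
#' Runs [match_pair()] and [peptide_ratio()] over each simulated (or loaded)
#' pair of an `xic_set`, returning accepted peptide ratios and a rejection
#' table with reason codes.
#'
#' @param xic an `xic_set` (from [simulate_xic_pairs()] or [read_xic_set()]).
#' @param correlation_threshold,max_width,xic_threshold see [match_pair()].
#' @param min_ion_score see [peptide_ratio()].
#' @return list with `ratios` (data frame `peptide`, `protein_id`,
#'   `replicate`, `ratio`, `ion_score`, `correlation`) and `rejected`
#'   (data frame `peptide`, `replicate`, `reason`).
#' @export
quantify_xic_pairs <- function(xic, correlation_threshold = 0.8,
                               max_width = 7L, xic_threshold = 0.2,
                               min_ion_score = 30) {
  traces <- split(xic$traces, xic$traces$peptide)
  acc <- list()
  rej <- list()
  for (i in seq_len(nrow(xic$pairs))) {
    p <- xic$pairs[i, ]
    tr <- traces[[p$peptide]]
    pair <- match_pair(tr$rt, tr$intensity_light, tr$rt, tr$intensity_heavy,
      correlation_threshold = correlation_threshold,
      max_width = max_width, xic_threshold = xic_threshold
    )
    pr <- peptide_ratio(pair, ion_score = p$ion_score,
      min_ion_score = min_ion_score
    )
    if (pr$accepted) {
      acc[[length(acc) + 1L]] <- data.frame(
        peptide = p$peptide, protein_id = p$protein_id,
        replicate = p$replicate, ratio = pr$ratio,
        ion_score = p$ion_score, correlation = pair$correlation,
        stringsAsFactors = FALSE
      )
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        peptide = p$peptide, replicate = p$replicate,
        reason = pr$reason, stringsAsFactors = FALSE
      )
    }
  }
  list(
    ratios = if (length(acc)) do.call(rbind, acc) else empty_ratio_df(),
    rejected = if (length(rej)) {
      do.call(rbind, rej)
    } else {
      data.frame(
        peptide = character(0), replicate = integer(0),
        reason = character(0), stringsAsFactors = FALSE
      )
    }
  )
}

empty_ratio_df <- function() {
  data.frame(
    peptide = character(0), protein_id = character(0),
    replicate = integer(0), ratio = numeric(0),
    ion_score = numeric(0), correlation = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Median normalization of peptide ratios
#'
#' Divides every ratio by the median ratio of its run, removing the global
#' mixing-ratio bias between the two labeled samples; after normalization the
#' run median is 1 by construction.
#'
#' @param ratios numeric vector of raw ratios, or a data frame with a
#'   `ratio` column.
#' @param run optional grouping factor (e.g. replicate); each group is
#'   normalized by its own median.
#' @return same shape as the input with normalized ratios (the data-frame
#'   form gains a `ratio_normalized` column).
#' @examples
#' median_normalize(c(1, 2, 4)) # 0.5 1 2
#' @export
median_normalize <- function(ratios, run = NULL) {
  if (is.data.frame(ratios)) {
    grp <- if (is.null(run)) rep(1L, nrow(ratios)) else ratios[[run]]
    med <- stats::ave(ratios$ratio, grp, FUN = stats::median)
    ratios$ratio_normalized <- ratios$ratio / med
    return(ratios)
  }
  if (length(ratios) == 0L) {
    stop("median normalization needs at least one ratio", call. = FALSE)
  }
  if (is.null(run)) {
    ratios / stats::median(ratios)
  } else {
    ratios / stats::ave(ratios, run, FUN = stats::median)
  }
}

#' Protein-level rollup of peptide ratios with a significance-vs-unity test
#'
#' The protein ratio is the back-transformed mean of the natural-log peptide
#' ratios; its spread is the geometric standard deviation `exp(s)`, with `s`
#' the log-space standard deviation on `N - 1` degrees of freedom. A protein
#' is significantly different from unity when the one-sample Student
#' condition `|x̄| > t * s / sqrt(N)` holds, where `t` is the two-sided
#' critical value at confidence `1 - alpha` with `N - 1` degrees of freedom.
#' Both the ratio and the verdict are invariant to the logarithm base.
#'
#' @param ratios positive peptide ratios for one protein in one replicate.
#' @param protein_id,replicate identifiers carried into the output.
#' @param alpha two-sided test size (default 0.05, i.e. 95% confidence).
#' @return one-row data frame: `protein_id`, `replicate`, `n`, `log_mean`,
#'   `log_sd`, `ratio`, `sdgeo`, `t_crit`, `significant`.
#' @examples
#' rollup_protein(c(2, 0.5))$ratio # 1
#' @export
rollup_protein <- function(ratios, protein_id = NA_character_,
                           replicate = NA_integer_, alpha = 0.05) {
  n <- length(ratios)
  if (n == 0L) {
    stop("rollup needs at least one peptide ratio", call. = FALSE)
  }
  if (any(ratios <= 0)) {
    stop("peptide ratios must be positive", call. = FALSE)
  }
  lx <- log(ratios)
  xbar <- mean(lx)
  s <- if (n >= 2L) stats::sd(lx) else NA_real_
  t_crit <- if (n >= 2L) stats::qt(1 - alpha / 2, df = n - 1L) else NA_real_
  significant <- n >= 2L && abs(xbar) > t_crit * s / sqrt(n)
  data.frame(
    protein_id = protein_id,
    replicate = as.integer(replicate),
    n = n,
    log_mean = xbar,
    log_sd = s,
    ratio = exp(xbar),
    sdgeo = if (is.na(s)) NA_real_ else exp(s),
    t_crit = t_crit,
    significant = significant,
    stringsAsFactors = FALSE
  )
}

#' Roll up all proteins of one or more replicates
#'
#' @param ratios data frame with `protein_id`, `replicate` and either
#'   `ratio_normalized` (preferred) or `ratio`.
#' @param alpha test size passed to [rollup_protein()].
#' @return data frame of per-protein, per-replicate quantification records.
#' @export
rollup_proteins <- function(ratios, alpha = 0.05) {
  col <- if ("ratio_normalized" %in% names(ratios)) {
    "ratio_normalized"
  } else {
    "ratio"
  }
  parts <- split(ratios, list(ratios$protein_id, ratios$replicate),
    drop = TRUE
  )
  out <- do.call(rbind, lapply(parts, function(d) {
    rollup_protein(d[[col]],
      protein_id = d$protein_id[1],
      replicate = d$replicate[1], alpha = alpha
    )
  }))
  rownames(out) <- NULL
  out[order(out$protein_id, out$replicate), , drop = FALSE]
}

#' Significance-vs-unity verdict from printed summary statistics
#'
#' Re-evaluates the one-sample Student condition from a reported (ratio,
#' geometric SD, peptide count) triple instead of raw peptide ratios —
#' useful for auditing published differential tables.
#'
#' @param ratio protein-level ratio (back-transformed log mean).
#' @param sdgeo geometric standard deviation (`NA` allowed; yields `NA`).
#' @param n number of peptide ratios.
#' @param alpha two-sided test size.
#' @return logical vector: significantly different from unity?
#' @examples
#' significant_vs_unity(0.52, 1.04, 2) # TRUE
#' significant_vs_unity(0.55, 1.13, 2) # FALSE
#' @export
significant_vs_unity <- function(ratio, sdgeo, n, alpha = 0.05) {
  t_crit <- ifelse(n >= 2, stats::qt(1 - alpha / 2, df = pmax(n - 1, 1)),
    NA_real_
  )
  ifelse(is.na(sdgeo) | n < 2, NA,
    abs(log(ratio)) > t_crit * log(sdgeo) / sqrt(n)
  )
}

#' Combine replicate-level protein records
#'
#' For every protein quantified in all requested replicates, the combined
#' ratio is the back-transformed mean of the per-replicate log ratios (the
#' geometric mean) and the combined geometric SD is the back-transformed SD
#' of those log ratios. Proteins missing from any replicate are excluded
#' with a reason code.
#'
#' @param records per-replicate records from [rollup_proteins()] (columns
#'   `protein_id`, `replicate`, `ratio`, ...).
#' @param replicates replicate indices required (default: all present).
#' @return list with `summaries` (data frame `protein_id`,
#'   `combined_ratio`, `combined_sdgeo`, `n_replicates`, plus per-replicate
#'   ratio columns) and `excluded` (`protein_id`, `reason`).
#' @export
combine_replicates <- function(records, replicates = NULL) {
  if (is.null(replicates)) replicates <- sort(unique(records$replicate))
  parts <- split(records, records$protein_id)
  sm <- list()
  ex <- list()
  for (pid in names(parts)) {
    d <- parts[[pid]]
    if (!all(replicates %in% d$replicate)) {
      ex[[length(ex) + 1L]] <- data.frame(
        protein_id = pid, reason = "missing_replicate",
        stringsAsFactors = FALSE
      )
      next
    }
    d <- d[match(replicates, d$replicate), , drop = FALSE]
    lr <- log(d$ratio)
    row <- data.frame(
      protein_id = pid,
      combined_ratio = exp(mean(lr)),
      combined_sdgeo = if (length(lr) >= 2L) exp(stats::sd(lr)) else NA_real_,
      n_replicates = length(replicates),
      stringsAsFactors = FALSE
    )
    for (j in seq_along(replicates)) {
      row[[paste0("ratio_rep", replicates[j])]] <- d$ratio[j]
    }
    sm[[length(sm) + 1L]] <- row
  }
  list(
    summaries = if (length(sm)) do.call(rbind, sm) else NULL,
    excluded = if (length(ex)) {
      do.call(rbind, ex)
    } else {
      data.frame(
        protein_id = character(0), reason = character(0),
        stringsAsFactors = FALSE
      )
    }
  )
}

#' Differential-abundance filter with dual fold-change thresholds
#'
#' Retains a protein when it is quantified with at least `min_peptides`
#' peptide ratios in every replicate and, under the default
#' `"per_replicate"` rule, at least one replicate is both significantly
#' different from unity and beyond a fold-change threshold (ratio at or
#' above `up`, or at or below `down`) in that same replicate. The
#' `"strict_average"` variant instead requires the combined
#' (geometric-mean) ratio to lie beyond a threshold together with
#' significance in at least one replicate. Direction is `"up"` when the
#' combined ratio exceeds 1 and `"down"` otherwise.
#'
#' @param records per-replicate records (columns `protein_id`, `replicate`,
#'   `ratio`, `n`, `significant`; [rollup_proteins()] output qualifies).
#' @param up,down fold-change thresholds (inclusive), `0 < down < 1 < up`.
#' @param min_peptides minimum peptide ratios per replicate (default 2).
#' @param rule retention rule, see above.
#' @param replicates replicate indices that must all be present.
#' @return data frame of retained proteins: `protein_id`, per-replicate
#'   ratios, `combined_ratio`, `combined_sdgeo`, `direction`.
#' @export
differential_filter <- function(records, up = 1.25, down = 0.8,
                                min_peptides = 2L,
                                rule = c("per_replicate", "strict_average"),
                                replicates = NULL) {
  rule <- match.arg(rule)
  stopifnot(down > 0, down < 1, up > 1)
  if (is.null(replicates)) replicates <- sort(unique(records$replicate))

  quantified <- vapply(split(records, records$protein_id), function(d) {
    all(replicates %in% d$replicate[d$n >= min_peptides])
  }, logical(1))
  keep_ids <- names(quantified)[quantified]
  rec <- records[records$protein_id %in% keep_ids, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(empty_differential_df(replicates))
  }

  comb <- combine_replicates(rec, replicates)$summaries
  beyond <- function(r) r >= up | r <= down
  hit_ids <- if (rule == "per_replicate") {
    unique(rec$protein_id[rec$significant & beyond(rec$ratio)])
  } else {
    sig_any <- vapply(split(rec, rec$protein_id), function(d) {
      any(d$significant)
    }, logical(1))
    comb$protein_id[beyond(comb$combined_ratio) &
      sig_any[comb$protein_id]]
  }
  out <- comb[comb$protein_id %in% hit_ids, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(empty_differential_df(replicates))
  }
  out$direction <- ifelse(out$combined_ratio > 1, "up", "down")
  rownames(out) <- NULL
  out[order(out$combined_ratio), , drop = FALSE]
}

empty_differential_df <- function(replicates) {
  out <- data.frame(
    protein_id = character(0), combined_ratio = numeric(0),
    combined_sdgeo = numeric(0), n_replicates = integer(0),
    stringsAsFactors = FALSE
  )
  for (r in replicates) out[[paste0("ratio_rep", r)]] <- numeric(0)
  out$direction <- character(0)
  out
}
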