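#' Filter peptide-spectrum matches by score and ion-progression rules
#'
#' Accepts a PSM outright when its search score exceeds 50. Matches scoring
#' in the grey zone (greater than 25, at most 50) are accepted only when they
#' show an ion progression of at least 4 consecutive y- or b-type fragment
#' ions — the machine-checkable stand-in for manual spectrum inspection.
#' Everything else is rejected. Decoy flags pass through untouched so the
#' decoy FDR can be estimated on the accepted set.
#'
#' @param psms data frame with at least `score` and `consecutive_ions`.
#' @param score_accept score above which a PSM is accepted unconditionally.
#' @param score_review lower bound of the manual-review window (exclusive).
#' @param min_consecutive_ions consecutive-ion requirement inside the window.
#' @return the accepted subset of `psms`, rows in original order.
#' @examples
#' psms <- data.frame(score = c(60, 30, 25), consecutive_ions = c(0, 3, 9))
#' filter_psms(psms) # only the first row survives
#' @export
filter_psms <- function(psms, score_accept = 50, score_review = 25,
                        min_consecutive_ions = 4L) {
  stopifnot(all(c("score", "consecutive_ions") %in% names(psms)))
  keep <- psms$score > score_accept |
    (psms$score > score_review & psms$score <= score_accept &
      psms$consecutive_ions >= min_consecutive_ions)
  psms[keep, , drop = FALSE]
}

#' Decoy-based false discovery rate (percent)
#'
#' Estimates the peptide-level FDR of an accepted PSM set from its decoy
#' content. The default formula is the decoy-to-target ratio reported by
#' search engines (`100 * D / T`); the symmetric estimator
#' `100 * 2D / (T + D)` is available as a switch.
#'
#' @param psms data frame with a logical `decoy` column.
#' @param formula `"ratio"` for `100 * D/T`, `"two_times"` for
#'   `100 * 2D/(T + D)`.
#' @return FDR as a percentage.
#' @examples
#' decoy_fdr(data.frame(decoy = c(rep(FALSE, 99), TRUE))) # 1.0101...
#' @export
decoy_fdr <- function(psms, formula = c("ratio", "two_times")) {
  formula <- match.arg(formula)
  stopifnot("decoy" %in% names(psms))
  d <- sum(psms$decoy)
  t <- sum(!psms$decoy)
  if (t == 0L) {
    stop("FDR undefined: no target PSMs in the accepted set", call. = FALSE)
  }
  switch(formula,
    ratio = 100 * d / t,
    two_times = 100 * 2 * d / (t + d)
  )
}

#' Infer protein groups from accepted PSMs
#'
#' Builds one group per protein with at least one accepted (non-decoy) PSM.
#' A shared peptide counts toward every protein it matches, but proteins
#' whose observed peptide sets are identical are indistinguishable from the
#' evidence and are merged into a single group reported once. Each group
#' carries its distinct-peptide count, the count of observable tryptic
#' peptides (doubly protonated m/z inside the scan range), the emPAI
#' abundance index, the set of methods it was seen in, and a single-peptide
#' flag.
#'
#' @param psms accepted PSM data frame (`peptide`, `protein_id`, optionally
#'   `method`, `decoy`). Multiple protein ids per PSM may be
#'   semicolon-separated.
#' @param proteome named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences; every PSM protein id must resolve here.
#' @param scan_range m/z window defining observable peptides.
#' @param max_missed missed cleavages allowed for observable peptides.
#' @return data frame with one row per group: `protein_id` (semicolon-joined
#'   members), `n_observed`, `n_observable`, `empai`, `methods`,
#'   `single_peptide`.
#' @export
infer_proteins <- function(psms, proteome, scan_range = c(300, 1500),
                           max_missed = 1L) {
  if (methods::is(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  if ("decoy" %in% names(psms)) {
    psms <- psms[!psms$decoy, , drop = FALSE]
  }
  if (nrow(psms) == 0L) {
    stop("no target PSMs to infer proteins from", call. = FALSE)
  }
  ids <- strsplit(psms$protein_id, ";", fixed = TRUE)
  expanded <- data.frame(
    protein_id = unlist(ids),
    peptide = rep(psms$peptide, lengths(ids)),
    method = if ("method" %in% names(psms)) {
      rep(psms$method, lengths(ids))
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  missing <- setdiff(unique(expanded$protein_id), names(proteome))
  if (length(missing)) {
    stop("protein id(s) not in proteome: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  by_prot <- split(expanded, expanded$protein_id)
  pep_sets <- lapply(by_prot, function(d) sort(unique(d$peptide)))
  keys <- vapply(pep_sets, paste, character(1), collapse = "|")
  groups <- split(names(pep_sets), keys)

  rows <- lapply(groups, function(members) {
    members <- sort(members)
    peptides <- pep_sets[[members[1]]]
    mets <- sort(unique(unlist(lapply(
      by_prot[members], function(d) d$method
    ))))
    n_obs <- length(peptides)
    n_able <- observable_peptides(proteome[[members[1]]],
      scan_range = scan_range, max_missed = max_missed
    )
    data.frame(
      protein_id = paste(members, collapse = ";"),
      n_observed = n_obs,
      n_observable = n_able,
      empai = if (n_able >= 1L) empai(n_obs, n_able) else NA_real_,
      methods = paste(mets[!is.na(mets)], collapse = ","),
      single_peptide = n_obs == 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exponentially modified protein abundance index
#'
#' `emPAI = 10^(N_observed / N_observable) - 1`, a label-free proxy
#' proportional to protein content.
#'
#' @param n_observed distinct observed peptides.
#' @param n_observable observable tryptic peptides (must be >= 1).
#' @return numeric emPAI value(s).
#' @examples
#' empai(3, 6) # 10^0.5 - 1
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1L)) {
    stop("emPAI undefined: N_observable must be >= 1", call. = FALSE)
  }
  if (any(n_observed < 0) || any(n_observed > n_observable)) {
    stop("require 0 <= N_observed <= N_observable", call. = FALSE)
  }
  10^(n_observed / n_observable) - 1
}

#' Aggregate protein inventories across fractionation methods
#'
#' Computes every disjoint Venn region over the per-method protein
#' inventories (all 2^k - 1 non-empty membership patterns), per-method
#' totals and exclusives, pairwise overlaps, the non-redundant union, and —
#' when a theoretical proteome size is supplied — the coverage fraction of
#' the theoretical proteome.
#'
#' @param inventories named list of character vectors of protein ids.
#' @param theoretical_size optional count of proteins predicted from the
#'   genome.
#' @return object of class `coverage_report`: list with `venn` (data frame
#'   `region`, `count` over disjoint membership patterns), `per_method`,
#'   `exclusive`, `pairwise` (matrix of intersection sizes), `union_size`,
#'   `theoretical_size`, `coverage`.
#' @examples
#' rep <- aggregate_methods(list(A = c("p1", "p2"), B = "p2"),
#'   theoretical_size = 10
#' )
#' rep$union_size
#' @export
aggregate_methods <- function(inventories, theoretical_size = NULL) {
  stopifnot(length(inventories) >= 1L, !is.null(names(inventories)))
  inventories <- lapply(inventories, unique)
  methods <- names(inventories)
  all_ids <- unique(unlist(inventories))
  membership <- vapply(
    inventories, function(s) all_ids %in% s,
    logical(length(all_ids))
  )
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1, function(z) {
    paste(methods[z], collapse = "&")
  })

  k <- length(methods)
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(methods, m, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  venn <- data.frame(
    region = combos,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )

  per_method <- vapply(inventories, length, integer(1))
  exclusive <- vapply(methods, function(m) {
    sum(pattern == m)
  }, integer(1))
  pairwise <- outer(methods, methods, Vectorize(function(a, b) {
    length(intersect(inventories[[a]], inventories[[b]]))
  }))
  dimnames(pairwise) <- list(methods, methods)

  structure(list(
    venn = venn,
    per_method = per_method,
    exclusive = exclusive,
    pairwise = pairwise,
    union_size = length(all_ids),
    theoretical_size = theoretical_size,
    coverage = if (is.null(theoretical_size)) {
      NA_real_
    } else {
      length(all_ids) / theoretical_size
    }
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Coverage report: %d non-redundant proteins across %d method(s)\n",
    x$union_size, length(x$per_method)
  ))
  for (m in names(x$per_method)) {
    cat(sprintf(
      "  %-10s %5d proteins (%d exclusive)\n",
      m, x$per_method[[m]], x$exclusive[[m]]
    ))
  }
  if (!is.null(x$theoretical_size)) {
    cat(sprintf(
      "  theoretical proteome %d -> coverage %.1f%%\n",
      x$theoretical_size, 100 * x$coverage
    ))
  }
  invisible(x)
}

#' Rank protein groups by emPAI
#'
#' Returns the `n` most abundant groups in descending emPAI order, ties
#' broken by lexicographic protein id.
#'
#' @param groups data frame from [infer_proteins()] (needs `protein_id`,
#'   `empai`).
#' @param n number of groups to return (the whole list if fewer).
#' @return the ranked sublist.
#' @export
top_n_by_empai <- function(groups, n = 20L) {
  stopifnot(n >= 1L)
  ord <- order(-groups$empai, groups$protein_id)
  groups[utils::head(ord, n), , drop = FALSE]
}

#' Shared membership between two fractions' emPAI top lists
#'
#' @param groups_a,groups_b protein-group tables for two fractions.
#' @param n list depth (default the top 20).
#' @return integer count of protein ids present in both top-`n` lists.
#' @export
top_n_shared <- function(groups_a, groups_b, n = 20L) {
  length(intersect(
    top_n_by_empai(groups_a, n)$protein_id,
    top_n_by_empai(groups_b, n)$protein_id
  ))
}
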