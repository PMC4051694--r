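#' Run the complete simulate / identify / quantify pipeline
#'
#' Generates a synthetic dataset under `config`, filters its PSMs, estimates
#' the decoy FDR, infers protein groups with emPAI, aggregates the
#' per-method inventories into a coverage report, quantifies every XIC pair
#' of every replicate (match, Simpson integration, ion-score gate), median
#' normalizes per replicate, rolls ratios up to protein records with the
#' significance-vs-unity test, combines replicates, applies the
#' differential-abundance filter and bins the combined fold changes. The
#' same config and seed reproduce the bundle bit-exactly.
#'
#' @param config a [sim_config()].
#' @param readings optional absorbance readings data frame for the pigment
#'   stage (see [pigment_table()]).
#' @param output_dir optional directory; when given, all result tables are
#'   written there as TSV and their digests recorded in the manifest.
#' @param up,down,min_peptides,rule differential-filter settings, see
#'   [differential_filter()].
#' @return list of class `results_bundle` with elements `coverage`,
#'   `fdr_percent`, `groups`, `records`, `combined`, `differential`,
#'   `rejected`, `fold_change_summary`, `pigments`, `attrition`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, readings = NULL, output_dir = NULL,
                         up = 1.25, down = 0.8, min_peptides = 2L,
                         rule = "per_replicate") {
  t0 <- Sys.time()
  ds <- simulate_dataset(config)

  accepted <- filter_psms(ds$psms)
  fdr <- decoy_fdr(accepted)
  targets <- accepted[!accepted$decoy, , drop = FALSE]
  proteome <- stats::setNames(
    ds$truth$proteins$sequence, ds$truth$proteins$protein_id
  )
  groups <- infer_proteins(targets, proteome,
    scan_range = config$scan_range, max_missed = config$max_missed
  )
  inventories <- lapply(
    split(targets$protein_id, targets$method), unique
  )
  coverage <- aggregate_methods(inventories,
    theoretical_size = config$n_proteins
  )

  quants <- lapply(ds$xic, quantify_xic_pairs)
  ratios <- do.call(rbind, lapply(quants, `[[`, "ratios"))
  rejected <- do.call(rbind, lapply(quants, `[[`, "rejected"))
  if (nrow(ratios) == 0L) {
    stop("pipeline: no peptide ratio survived quantification filters",
      call. = FALSE
    )
  }
  ratios <- median_normalize(ratios, run = "replicate")
  records <- rollup_proteins(ratios)
  combined <- combine_replicates(records)
  differential <- differential_filter(records,
    up = up, down = down,
    min_peptides = min_peptides, rule = rule
  )
  fc_summary <- if (!is.null(combined$summaries)) {
    summarize_fold_changes(combined$summaries$combined_ratio)
  } else {
    NULL
  }
  pigments <- if (!is.null(readings)) pigment_table(readings) else NULL

  attrition <- c(
    psms_total = nrow(ds$psms),
    psms_accepted = nrow(accepted),
    proteins_identified = nrow(groups),
    xic_pairs = sum(vapply(ds$xic, function(x) nrow(x$pairs), integer(1))),
    peptide_ratios = nrow(ratios),
    proteins_quantified = nrow(records),
    proteins_in_all_replicates = if (is.null(combined$summaries)) {
      0L
    } else {
      nrow(combined$summaries)
    },
    proteins_differential = nrow(differential)
  )

  bundle <- structure(list(
    coverage = coverage,
    fdr_percent = fdr,
    groups = groups,
    records = records,
    combined = combined$summaries,
    differential = differential,
    rejected = rejected,
    fold_change_summary = fc_summary,
    pigments = pigments,
    attrition = attrition,
    manifest = NULL
  ), class = "results_bundle")

  files <- if (!is.null(output_dir)) {
    write_results(bundle, output_dir)
  } else {
    character(0)
  }
  bundle$manifest <- list(
    config = unclass(config),
    seed = config$seed,
    attrition = as.list(attrition),
    files = as.list(if (length(files)) tools::md5sum(files) else character(0)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(bundle$manifest,
      file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  bundle
}

#' Bin combined fold changes on a geometric (octave) grid
#'
#' Bins `log2(ratio)` into unit-width, left-closed bins `[2^k, 2^(k+1))`
#' covering the data range, and reports the occupied-bin table plus the
#' observed ratio range.
#'
#' @param ratios positive combined protein ratios.
#' @param bins_per_octave number of bins per doubling (default 1).
#' @return list with `bins` (data frame `lower`, `upper`, `count`),
#'   `range` (min/max ratio), `n`.
#' @examples
#' summarize_fold_changes(c(0.5, 1, 2))$bins
#' @export
summarize_fold_changes <- function(ratios, bins_per_octave = 1L) {
  stopifnot(length(ratios) >= 1L, all(ratios > 0))
  l2 <- log2(ratios) * bins_per_octave
  idx <- floor(l2)
  lev <- seq(min(idx), max(idx))
  counts <- table(factor(idx, levels = lev))
  bins <- data.frame(
    lower = 2^(lev / bins_per_octave),
    upper = 2^((lev + 1) / bins_per_octave),
    count = as.integer(counts)
  )
  list(bins = bins, range = range(ratios), n = length(ratios))
}

#' Write a results bundle as TSV tables
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wt <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wt(bundle$coverage$venn, "venn_regions.tsv")
  wt(
    data.frame(
      method = names(bundle$coverage$per_method),
      n_proteins = bundle$coverage$per_method,
      n_exclusive = bundle$coverage$exclusive
    ),
    "coverage_report.tsv"
  )
  wt(bundle$groups, "protein_groups.tsv")
  wt(bundle$records, "protein_quant_records.tsv")
  if (!is.null(bundle$combined)) wt(bundle$combined, "combined_ratios.tsv")
  wt(bundle$differential, "differential_table.tsv")
  wt(bundle$rejected, "rejected_peptides.tsv")
  if (!is.null(bundle$pigments)) wt(bundle$pigments, "pigments.tsv")
  invisible(files)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Proteomics pipeline results\n")
  a <- x$attrition
  cat(sprintf(
    "  PSMs %d -> accepted %d (decoy FDR %.2f%%)\n",
    a[["psms_total"]], a[["psms_accepted"]], x$fdr_percent
  ))
  cat(sprintf(
    "  proteins identified %d (union coverage %.1f%%)\n",
    a[["proteins_identified"]], 100 * x$coverage$coverage
  ))
  cat(sprintf(
    "  peptide ratios %d -> proteins in all replicates %d -> differential %d\n",
    a[["peptide_ratios"]], a[["proteins_in_all_replicates"]],
    a[["proteins_differential"]]
  ))
  invisible(x)
}
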