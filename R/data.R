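#' Published diel ICPL protein-ratio table for Arthrospira platensis
#'
#' Per-replicate light/dark protein abundance ratios, geometric standard
#' deviations, peptide counts and printed significance markings for the 30
#' proteins reported as differentially abundant across a 12 h light / 12 h
#' dark growth transition in *A. platensis* (two biological replicates,
#' post-digest ICPL labeling). The significance flags reproduce the
#' published markings; two entries report no geometric SD (`NA`). The table
#' serves as a reference input for auditing the differential-abundance rule
#' and the significance-vs-unity test against published summary statistics.
#'
#' @param long if `TRUE`, return one row per protein x replicate with
#'   columns `protein_id`, `replicate`, `ratio`, `sdgeo`, `n`,
#'   `significant` — the shape [differential_filter()] consumes. If
#'   `FALSE`, the wide published layout.
#' @return data frame (30 rows wide, 60 rows long).
#' @examples
#' nrow(diel_icpl_ratios())
#' @export
diel_icpl_ratios <- function(long = TRUE) {
  path <- system.file("extdata", "diel_icpl_ratios.tsv",
    package = "icplquant", mustWork = TRUE
  )
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!long) {
    return(wide)
  }
  do.call(rbind, lapply(1:2, function(r) {
    data.frame(
      protein_id = wide$accession,
      protein_name = wide$protein_name,
      replicate = r,
      ratio = wide[[paste0("ratio_rep", r)]],
      sdgeo = wide[[paste0("sdgeo_rep", r)]],
      n = wide[[paste0("npept_rep", r)]],
      significant = wide[[paste0("sig_rep", r)]],
      stringsAsFactors = FALSE
    )
  }))
}
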