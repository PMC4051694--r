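#' Phycocyanin concentration from absorbance
#'
#' Bennett–Bogorad estimate for phycocyanin in aqueous phosphate extracts:
#' `PC = (A615 - 0.474 * A652) / 5.34` mg/mL for a 1 cm path, where the
#' A652 term subtracts the allophycocyanin contribution at 615 nm. Negative
#' results (possible with distorted baselines) are returned as computed and
#' flagged with a warning rather than clipped.
#'
#' @param od615,od652 absorbances at 615 and 652 nm.
#' @param path_cm optical path length in cm (default 1).
#' @param apc_coef,pc_coef formula constants, overridable.
#' @return phycocyanin concentration in mg/mL.
#' @examples
#' phycocyanin_conc(5.34, 0) # 1 mg/mL
#' @export
phycocyanin_conc <- function(od615, od652, path_cm = 1,
                             apc_coef = 0.474, pc_coef = 5.34) {
  stopifnot(all(path_cm > 0))
  pc <- (od615 - apc_coef * od652) / (pc_coef * path_cm)
  if (any(pc < 0)) {
    warning("negative phycocyanin concentration computed; check baselines",
      call. = FALSE
    )
  }
  pc
}

#' Chlorophyll concentration from absorbance in pure methanol
#'
#' Beer-Lambert with the 100% methanol extinction coefficient
#' 74.5 mL mg^-1 cm^-1: `chl = OD665 / (74.5 * path)` mg/mL.
#'
#' @param od665 absorbance at 665 nm.
#' @param path_cm optical path length in cm (default 1).
#' @param epsilon extinction coefficient in mL mg^-1 cm^-1.
#' @return chlorophyll concentration in mg/mL.
#' @examples
#' chlorophyll_conc(74.5) # 1 mg/mL
#' @export
chlorophyll_conc <- function(od665, path_cm = 1, epsilon = 74.5) {
  stopifnot(all(path_cm > 0))
  od665 / (epsilon * path_cm)
}

#' Pigment concentrations for a table of absorbance readings
#'
#' @param readings data frame with columns `od615`, `od652`, `od665` and
#'   optionally `path_cm` (default 1), plus any identifier columns
#'   (`sample`, `phase`, `timepoint`), which are carried through.
#' @return the input with `phycocyanin_mg_ml`, `chlorophyll_mg_ml` and a
#'   logical `flagged` column marking negative concentrations.
#' @export
pigment_table <- function(readings) {
  stopifnot(all(c("od615", "od652", "od665") %in% names(readings)))
  path <- if ("path_cm" %in% names(readings)) readings$path_cm else 1
  pc <- suppressWarnings(
    phycocyanin_conc(readings$od615, readings$od652, path)
  )
  chl <- chlorophyll_conc(readings$od665, path)
  readings$phycocyanin_mg_ml <- pc
  readings$chlorophyll_mg_ml <- chl
  readings$flagged <- pc < 0 | chl < 0
  readings
}
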