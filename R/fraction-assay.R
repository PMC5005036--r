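#' Assemble fraction assays from protein amounts and PRM intensities
#'
#' Combines a protein assay (total micrograms per purification
#' fraction) with targeted-proteomics intensities. Either the per-µg
#' intensity or the fraction-total intensity may be supplied; the other
#' is derived as total = per-µg x µg.
#'
#' @param fraction character vector of fraction labels.
#' @param protein_ug total protein per fraction, µg (> 0).
#' @param per_ug_intensity PRM intensity per µg protein (arbitrary
#'   units/µg); optional if `total_intensity` given.
#' @param total_intensity fraction-total PRM intensity; optional if
#'   `per_ug_intensity` given.
#' @return data.frame with columns `fraction`, `protein_ug`,
#'   `per_ug_intensity`, `total_intensity`.
#' @export
fraction_assays <- function(fraction, protein_ug,
                            per_ug_intensity = NULL,
                            total_intensity = NULL) {
  fraction <- as.character(fraction)
  if (anyDuplicated(fraction))
    stop("duplicate fraction labels", call. = FALSE)
  if (any(!is.finite(protein_ug) | protein_ug <= 0))
    stop("`protein_ug` must be positive", call. = FALSE)
  if (is.null(per_ug_intensity) && is.null(total_intensity))
    stop("supply `per_ug_intensity` or `total_intensity`", call. = FALSE)
  if (is.null(total_intensity))
    total_intensity <- per_ug_intensity * protein_ug
  if (is.null(per_ug_intensity))
    per_ug_intensity <- total_intensity / protein_ug
  data.frame(fraction = fraction, protein_ug = protein_ug,
             per_ug_intensity = per_ug_intensity,
             total_intensity = total_intensity,
             stringsAsFactors = FALSE)
}

#' Fraction-total intensity as a percentage of a reference fraction
#'
#' The fraction-report arithmetic: each fraction's total target-protein
#' PRM intensity (per-µg intensity x total µg) expressed as a
#' percentage of the reference fraction's total (typically the
#' post-nuclear supernatant), rounded to the nearest integer for
#' reporting.
#'
#' @param assays data.frame from [fraction_assays()].
#' @param reference reference fraction label (the 100% row).
#' @return data.frame with columns `fraction`, `total_intensity`,
#'   `pct_of_reference` (unrounded) and `pct_report` (integer).
#' @export
fraction_of_reference <- function(assays, reference) {
  if (!reference %in% assays$fraction)
    stop("reference fraction `", reference, "` not present", call. = FALSE)
  ref_total <- assays$total_intensity[assays$fraction == reference]
  if (!is.finite(ref_total) || ref_total <= 0)
    stop("reference fraction has non-positive total intensity",
         call. = FALSE)
  pct <- 100 * assays$total_intensity / ref_total
  data.frame(fraction = assays$fraction,
             total_intensity = assays$total_intensity,
             pct_of_reference = pct,
             pct_report = as.integer(round(pct)),
             stringsAsFactors = FALSE)
}

#' Per-µg fold enrichment between two fractions
#'
#' The enrichment of the target protein per microgram of total protein
#' from one purification stage to another:
#' (total intensity / µg) of `to_fraction` divided by that of
#' `from_fraction`. For reporting, round with `signif(x, 1)` (one
#' significant figure), matching the convention of "around N-fold"
#' statements.
#'
#' @param assays data.frame from [fraction_assays()].
#' @param from_fraction,to_fraction fraction labels.
#' @return the fold enrichment (unrounded).
#' @export
per_ug_fold_enrichment <- function(assays, from_fraction, to_fraction) {
  for (f in c(from_fraction, to_fraction))
    if (!f %in% assays$fraction)
      stop("fraction `", f, "` not present", call. = FALSE)
  per_ug <- assays$per_ug_intensity
  names(per_ug) <- assays$fraction
  if (per_ug[[from_fraction]] <= 0)
    stop("zero per-ug intensity in `", from_fraction, "`", call. = FALSE)
  unname(per_ug[[to_fraction]] / per_ug[[from_fraction]])
}
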