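#' Relative iBAQ (riBAQ)
#'
#' Converts an iBAQ matrix to riBAQ, the molar-fraction estimate used
#' throughout the package: per sample, a protein's iBAQ divided by the
#' summed iBAQ of all non-contaminant proteins detected in that sample.
#' Contaminant rows are excluded from both the denominator and the
#' output; missing values stay missing.
#'
#' @param m a [quant_matrix()] on the `"ibaq"` scale.
#' @return a [quant_matrix()] on the `"ribaq"` scale with contaminant
#'   rows removed. Each sample's riBAQ sums to 1 over detected proteins.
#' @export
compute_ribaq <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$scale != "ibaq")
    stop("`m` must be on the ibaq scale, got ", m$scale, call. = FALSE)
  keep <- !m$contaminant
  if (!any(keep))
    stop("no non-contaminant proteins in the matrix", call. = FALSE)
  v <- m$values[keep, , drop = FALSE]
  denom <- colSums(v, na.rm = TRUE)
  zero <- denom <= 0
  if (any(zero))
    stop("sample(s) with zero non-contaminant signal: ",
         paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  out <- sweep(v, 2, denom, "/")
  quant_matrix(out,
               contaminant = rep(FALSE, sum(keep)),
               tm_helix = unname(m$tm_helix[keep]),
               scale = "ribaq")
}

#' Apportion a protein-group riBAQ across isoforms
#'
#' Splits a group-level riBAQ among the group's isoforms using
#' isoform-unique peptides: per sample, isoform k's share is the summed
#' intensity of peptides unique to k divided by the summed intensity of
#' all isoform-unique peptides of the group, and its riBAQ is that share
#' times the group riBAQ. Shared peptides never contribute to shares.
#' Samples with no detected isoform-unique peptide get `NA` for every
#' isoform (missing, not zero).
#'
#' @param group_value numeric vector of the group's riBAQ per sample
#'   (names = sample ids).
#' @param evidence a [peptide_evidence()]; only rows of one parent group
#'   may be present.
#' @return numeric matrix, isoforms x samples, rows summing to
#'   `group_value` per sample where defined.
#' @export
apportion_isoforms <- function(group_value, evidence) {
  stopifnot(inherits(evidence, "peptide_evidence"))
  meta <- evidence$meta
  if (length(unique(meta$parent_group)) != 1L)
    stop("`evidence` must contain peptides of exactly one parent group",
         call. = FALSE)
  samples <- colnames(evidence$intensity)
  if (is.null(names(group_value))) {
    if (length(group_value) != length(samples))
      stop("`group_value` length must match evidence samples", call. = FALSE)
    names(group_value) <- samples
  }
  group_value <- group_value[samples]
  uniq <- !is.na(meta$unique_to)
  if (!any(uniq))
    stop("no isoform-unique peptides in this group", call. = FALSE)
  isoforms <- sort(unique(meta$unique_to[uniq]))
  inten <- evidence$intensity[uniq, , drop = FALSE]
  owner <- meta$unique_to[uniq]
  num <- rowsum(ifelse(is.na(inten), 0, inten), group = owner)
  num <- num[isoforms, , drop = FALSE]
  denom <- colSums(num)
  share <- sweep(num, 2, denom, "/")
  share[, denom <= 0] <- NA_real_
  out <- sweep(share, 2, group_value, "*")
  rownames(out) <- isoforms
  out
}

#' Log2 transform with global median normalization
#'
#' Transforms intensities to log2 and subtracts each sample's median of
#' detected values, so every sample's median is 0; the preprocessing
#' applied before the moderated t-test.
#'
#' Applied to a matrix already on the `"log2"` scale it only re-centers
#' the medians, so the operation is idempotent.
#'
#' @param m a [quant_matrix()] on a raw scale (`ibaq` or `ribaq`, with
#'   strictly positive detected values) or already on `"log2"`.
#' @return a [quant_matrix()] on the `"log2"` scale.
#' @export
log2_median_normalize <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (!m$scale %in% c("ibaq", "ribaq", "log2"))
    stop("`m` must be on an intensity or log2 scale", call. = FALSE)
  v <- m$values
  n_det <- colSums(is.finite(v))
  if (any(n_det < 2))
    stop("sample(s) with fewer than 2 detected values: ",
         paste(colnames(v)[n_det < 2], collapse = ", "), call. = FALSE)
  lg <- if (m$scale == "log2") v else log2(v)
  med <- apply(lg, 2, stats::median, na.rm = TRUE)
  out <- sweep(lg, 2, med, "-")
  quant_matrix(out, contaminant = unname(m$contaminant),
               tm_helix = unname(m$tm_helix), scale = "log2")
}
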