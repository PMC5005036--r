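#' Protein-by-sample intensity matrix
#'
#' The central container of the label-free workflow: a non-negative
#' protein x sample intensity matrix (iBAQ, riBAQ, log2 or z scale)
#' with per-protein contaminant and transmembrane-helix flags.
#' Missing values are `NA` and mean *not detected*; a protein counts as
#' detected in a sample iff a positive finite intensity is present.
#' Zero intensities are coerced to `NA` on construction for the raw
#' scales, so detection filters behave identically on exports that use
#' zero and exports that use blanks for absent proteins.
#'
#' @param values numeric matrix with unique rownames (protein ids) and
#'   unique colnames (sample ids); `NA` marks missing.
#' @param contaminant logical vector, one per row. Default all `FALSE`.
#' @param tm_helix logical vector, one per row (transmembrane-helix
#'   annotation). Default all `FALSE`.
#' @param scale one of `"ibaq"`, `"ribaq"`, `"log2"`, `"z"`. Raw scales
#'   (`"ibaq"`, `"ribaq"`) must be non-negative.
#' @return an object of class `quant_matrix`: a list with elements
#'   `values`, `contaminant`, `tm_helix`, `scale`.
#' @examples
#' m <- matrix(c(3, 1, 6, 2), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S7")))
#' qm <- quant_matrix(m)
#' compute_ribaq(qm)$values
#' @export
quant_matrix <- function(values,
                         contaminant = NULL,
                         tm_helix = NULL,
                         scale = c("ibaq", "ribaq", "log2", "z")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (protein) and column (sample) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (scale %in% c("ibaq", "ribaq")) {
    if (any(values < 0, na.rm = TRUE))
      stop("negative intensities are not allowed on the ", scale, " scale",
           call. = FALSE)
    values[!is.na(values) & values == 0] <- NA_real_
  }
  n <- nrow(values)
  contaminant <- .row_flag(contaminant, n, rownames(values), "contaminant")
  tm_helix <- .row_flag(tm_helix, n, rownames(values), "tm_helix")
  structure(
    list(values = values, contaminant = contaminant,
         tm_helix = tm_helix, scale = scale),
    class = "quant_matrix"
  )
}

.row_flag <- function(flag, n, ids, what) {
  if (is.null(flag)) flag <- rep(FALSE, n)
  if (length(flag) != n)
    stop("`", what, "` must have one entry per protein", call. = FALSE)
  flag <- as.logical(flag)
  flag[is.na(flag)] <- FALSE
  names(flag) <- ids
  flag
}

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "quant_matrix [%s]: %d proteins x %d samples (%d contaminant, %d TM; %.1f%% detected)\n",
    x$scale, nrow(v), ncol(v), sum(x$contaminant), sum(x$tm_helix),
    100 * mean(is.finite(v))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Subset a quant_matrix by proteins and/or samples
#'
#' @param x a [quant_matrix()].
#' @param i protein selector (names, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return a `quant_matrix` with flags subset in step.
#' @export
`[.quant_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  quant_matrix(x$values[i, j, drop = FALSE],
               contaminant = unname(x$contaminant[i]),
               tm_helix = unname(x$tm_helix[i]),
               scale = x$scale)
}

#' Detection indicator matrix
#'
#' @param x a [quant_matrix()].
#' @return logical matrix, `TRUE` where a positive finite intensity exists.
#' @export
is_detected <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  d <- is.finite(x$values)
  if (x$scale %in% c("ibaq", "ribaq")) d <- d & x$values > 0
  d
}

#' Study design: purification-fraction order and IP run conditions
#'
#' Encodes the two experimental layouts the package analyses: the ordered
#' purification fractions (unit index spacing, used by
#' [enrichment_slope()]) and the immunoaffinity run map assigning each
#' mass-spectrometry run to condition `total` (starting extract),
#' `control` (nonspecific-IgG eluate) or `specific` (bait-antibody
#' eluate), with replicate ids.
#'
#' @param fraction_order character vector of fraction sample ids in
#'   purification order (index 0, 1, 2, ... with unit spacing), or `NULL`.
#' @param ip_conditions `NULL`, or a data.frame with columns `run`
#'   (sample id), `condition` (one of `"total"`, `"control"`,
#'   `"specific"`) and optionally `replicate`.
#' @return an object of class `study_design` with elements `fractions`
#'   (data.frame `sample`, `index`) and `ip` (data.frame `run`,
#'   `condition`, `replicate`).
#' @examples
#' study_design(fraction_order = c("S1", "P2", "M3", "P6", "S7"))
#' @export
study_design <- function(fraction_order = NULL, ip_conditions = NULL) {
  fractions <- NULL
  if (!is.null(fraction_order)) {
    fraction_order <- as.character(fraction_order)
    if (anyDuplicated(fraction_order))
      stop("fraction labels must be unique", call. = FALSE)
    fractions <- data.frame(sample = fraction_order,
                            index = seq_along(fraction_order) - 1L,
                            stringsAsFactors = FALSE)
  }
  ip <- NULL
  if (!is.null(ip_conditions)) {
    ip <- as.data.frame(ip_conditions, stringsAsFactors = FALSE)
    if (!all(c("run", "condition") %in% names(ip)))
      stop("`ip_conditions` needs columns `run` and `condition`",
           call. = FALSE)
    bad <- setdiff(unique(ip$condition), c("total", "control", "specific"))
    if (length(bad))
      stop("unknown IP condition(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(ip$run))
      stop("duplicate run ids in `ip_conditions`", call. = FALSE)
    if (is.null(ip$replicate)) ip$replicate <- seq_len(nrow(ip))
    ip <- ip[, c("run", "condition", "replicate")]
  }
  structure(list(fractions = fractions, ip = ip), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design\n")
  if (!is.null(x$fractions))
    cat("  fractions: ", paste(x$fractions$sample, collapse = " -> "), "\n")
  if (!is.null(x$ip)) {
    tab <- table(x$ip$condition)
    cat("  IP runs:   ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

ip_runs <- function(design, condition) {
  if (is.null(design$ip))
    stop("design carries no IP run conditions", call. = FALSE)
  design$ip$run[design$ip$condition == condition]
}

#' Peptide-level evidence table
#'
#' Peptide intensities with parent protein-group and isoform-uniqueness
#' annotation, as used by [apportion_isoforms()]. `unique_to = NA` marks
#' a peptide shared between isoforms of the group; such peptides support
#' group-level quantitation only and never enter isoform shares.
#'
#' @param meta data.frame with columns `peptide_id`, `sequence`,
#'   `parent_group`, `unique_to` (`NA` = shared).
#' @param intensity numeric matrix, one row per peptide (rownames =
#'   `peptide_id`), one column per sample; `NA`/0 = not detected.
#' @return object of class `peptide_evidence`.
#' @export
peptide_evidence <- function(meta, intensity) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence", "parent_group", "unique_to")
  if (!all(need %in% names(meta)))
    stop("`meta` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$peptide_id))
    stop("duplicate peptide ids", call. = FALSE)
  if (!is.matrix(intensity) || nrow(intensity) != nrow(meta))
    stop("`intensity` must be a matrix with one row per peptide",
         call. = FALSE)
  rownames(intensity) <- meta$peptide_id
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative peptide intensities", call. = FALSE)
  structure(list(meta = meta[, need], intensity = intensity),
            class = "peptide_evidence")
}

#' @export
print.peptide_evidence <- function(x, ...) {
  cat(sprintf("peptide_evidence: %d peptides, %d groups, %d samples\n",
              nrow(x$meta), length(unique(x$meta$parent_group)),
              ncol(x$intensity)))
  invisible(x)
}
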