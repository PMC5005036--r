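#' Purification-fraction enrichment slope
#'
#' For each protein, the ordinary least-squares slope of log riBAQ on
#' the purification-fraction index (unit spacing), fit over detected
#' fractions only. A steep positive slope marks co-enrichment with the
#' target membranes across the preparation. Proteins detected in fewer
#' than `min_detected` fractions are omitted.
#'
#' @param m a [quant_matrix()] of riBAQ values whose samples include the
#'   design's fractions.
#' @param design a [study_design()] with `fraction_order` set.
#' @param min_detected minimum fractions a protein must be detected in
#'   (default 3, i.e. at least three of five fractions).
#' @param log_base base of the log applied to riBAQ before the fit
#'   (default 10). Ranking is base-invariant.
#' @return data.frame with columns `protein_id`, `slope`,
#'   `n_fractions_detected`, `rank` (1 = steepest), sorted by rank.
#'   Ties in slope are broken by protein id.
#' @export
enrichment_slope <- function(m, design, min_detected = 3, log_base = 10) {
  stopifnot(inherits(m, "quant_matrix"), inherits(design, "study_design"))
  if (is.null(design$fractions))
    stop("design carries no fraction order", call. = FALSE)
  if (min_detected < 2)
    stop("`min_detected` must be at least 2", call. = FALSE)
  fr <- design$fractions
  missing_cols <- setdiff(fr$sample, colnames(m$values))
  if (length(missing_cols))
    stop("fractions absent from matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  v <- m$values[, fr$sample, drop = FALSE]
  det <- is.finite(v) & v > 0
  y <- log(v, base = log_base)
  x <- fr$index

  n_det <- rowSums(det)
  keep <- which(n_det >= min_detected)
  slope <- vapply(keep, function(i) {
    d <- det[i, ]
    xi <- x[d]; yi <- y[i, d]
    xc <- xi - mean(xi)
    sum(xc * yi) / sum(xc * xc)
  }, numeric(1))

  res <- data.frame(protein_id = rownames(v)[keep],
                    slope = slope,
                    n_fractions_detected = n_det[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-res$slope, res$protein_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Rolling average of transmembrane-helix annotation along the slope order
#'
#' Diagnostic for membrane enrichment: proteins are taken in enrichment
#' slope order, each carries a 0/1 transmembrane-helix flag, and the
#' mean flag is computed over consecutive non-overlapping blocks of
#' `window` proteins (the final partial block over its actual size).
#'
#' @param results data.frame from [enrichment_slope()] (already sorted
#'   by slope, steepest first).
#' @param tm_flags logical/0-1 vector named by protein id, or unnamed in
#'   row order of `results`.
#' @param window block size (default 50 proteins).
#' @return data.frame with columns `block`, `n`, `mean_tm`,
#'   `mean_slope`.
#' @export
tm_rolling_average <- function(results, tm_flags, window = 50) {
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (!is.null(names(tm_flags))) {
    miss <- setdiff(results$protein_id, names(tm_flags))
    if (length(miss))
      stop("tm_flags missing for: ", paste(utils::head(miss, 5),
                                           collapse = ", "), call. = FALSE)
    tm_flags <- tm_flags[results$protein_id]
  } else if (length(tm_flags) != nrow(results)) {
    stop("`tm_flags` length must match `results`", call. = FALSE)
  }
  f <- as.numeric(as.logical(tm_flags))
  blk <- ceiling(seq_along(f) / window)
  data.frame(block = seq_len(max(blk)),
             n = as.integer(tabulate(blk)),
             mean_tm = as.numeric(tapply(f, blk, mean)),
             mean_slope = as.numeric(tapply(results$slope, blk, mean)),
             row.names = NULL)
}

#' Row-standardize profiles to z scale
#'
#' Per protein, subtracts the row mean and divides by the row standard
#' deviation (sample SD, n - 1 denominator by default), giving each row
#' mean 0 and SD 1 -- the preprocessing for profile clustering. Rows
#' with zero variance (or any missing value, when `drop_incomplete`)
#' cannot be standardized and are dropped with a warning; their ids are
#' recorded in the `dropped` attribute.
#'
#' @param m a [quant_matrix()].
#' @param sample_sd use the n - 1 denominator (default `TRUE`); `FALSE`
#'   uses the population (n) denominator.
#' @param drop_incomplete drop rows containing missing values (default
#'   `TRUE`; clustering requires complete profiles).
#' @return a [quant_matrix()] on the `"z"` scale, with attribute
#'   `dropped` listing excluded protein ids.
#' @export
row_standardize <- function(m, sample_sd = TRUE, drop_incomplete = TRUE) {
  stopifnot(inherits(m, "quant_matrix"))
  v <- m$values
  incomplete <- rowSums(!is.finite(v)) > 0
  if (drop_incomplete && any(incomplete)) {
    v <- v[!incomplete, , drop = FALSE]
  }
  mu <- rowMeans(v, na.rm = TRUE)
  cent <- v - mu
  denom <- ncol(v) - if (sample_sd) 1 else 0
  sd_row <- sqrt(rowSums(cent^2, na.rm = TRUE) / denom)
  constant <- sd_row <= 0 | !is.finite(sd_row)
  dropped <- character(0)
  if (drop_incomplete) dropped <- rownames(m$values)[incomplete]
  if (any(constant)) {
    warning(sum(constant), " constant row(s) excluded from standardization",
            call. = FALSE)
    dropped <- c(dropped, rownames(v)[constant])
    cent <- cent[!constant, , drop = FALSE]
    sd_row <- sd_row[!constant]
  }
  z <- cent / sd_row
  keep <- rownames(z)
  out <- quant_matrix(z,
                      contaminant = unname(m$contaminant[keep]),
                      tm_helix = unname(m$tm_helix[keep]),
                      scale = "z")
  attr(out, "dropped") <- dropped
  out
}
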