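#' Model-based clustering of row-standardized fraction profiles
#'
#' Fits Gaussian-mixture models to z-scaled protein profiles for every
#' k in `k_range` and every covariance structure in `models`, selects
#' the model and number of clusters by BIC, and orders the resulting
#' clusters by decreasing mean enrichment slope of their members (so
#' cluster 1 always contains the most membrane-co-enriching profiles).
#'
#' Only complete profiles can be clustered; pass the output of
#' [row_standardize()], which already drops rows with missing values.
#'
#' @param z a [quant_matrix()] on the `"z"` scale (or a plain numeric
#'   matrix) with no missing values.
#' @param k_range candidate numbers of clusters (default `1:9`).
#' @param models covariance structures to try (see [fit_gmm()]).
#' @param slopes optional named numeric vector of per-protein enrichment
#'   slopes (from [enrichment_slope()]) used to order clusters. When
#'   absent, the slope of each cluster's mean profile against column
#'   index is used instead.
#' @param seed RNG seed for the k-means++ initializations.
#' @param nstart restarts per (k, model) combination.
#' @return object of class `profile_clusters`: list with `assignments`
#'   (data.frame `protein_id`, `cluster`), `k_selected`, `model`,
#'   `cluster_slope`, `means` (cluster x sample, z scale), `bic`
#'   (data.frame of all fits), `pi`.
#' @export
cluster_profiles <- function(z, k_range = 1:9,
                             models = c("diagonal", "full"),
                             slopes = NULL, seed = 1, nstart = 10) {
  x <- if (inherits(z, "quant_matrix")) z$values else z
  stopifnot(is.matrix(x))
  if (any(!is.finite(x)))
    stop("profiles contain missing values; cluster only complete profiles",
         call. = FALSE)
  n <- nrow(x)
  if (max(k_range) > n / 2)
    stop("`k_range` exceeds n/2 (n = ", n, ")", call. = FALSE)

  fits <- list()
  grid <- expand.grid(k = k_range, model = models,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    f <- fit_gmm(x, grid$k[i], grid$model[i], nstart = nstart,
                 seed = seed + grid$k[i])
    fits[[i]] <- f
  }
  bic_tab <- data.frame(k = grid$k, model = grid$model,
                        bic = vapply(fits, `[[`, numeric(1), "bic"),
                        loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  best <- fits[[which.max(bic_tab$bic)]]

  # mean enrichment slope of each cluster's members
  memb <- best$assignment
  if (!is.null(slopes)) {
    sl <- slopes[rownames(x)]
    cl_slope <- tapply(sl, memb, mean, na.rm = TRUE)
  } else {
    idx <- seq_len(ncol(x)) - 1
    cl_slope <- vapply(seq_len(best$k), function(j) {
      mu <- colMeans(x[memb == j, , drop = FALSE])
      xc <- idx - mean(idx)
      sum(xc * mu) / sum(xc * xc)
    }, numeric(1))
    names(cl_slope) <- seq_len(best$k)
  }
  # reindex clusters: 1 = steepest mean slope
  ord <- order(-cl_slope)
  relab <- integer(best$k)
  relab[ord] <- seq_len(best$k)
  structure(list(
    assignments = data.frame(protein_id = rownames(x),
                             cluster = relab[memb],
                             stringsAsFactors = FALSE),
    k_selected = best$k,
    model = best$model,
    cluster_slope = as.numeric(cl_slope[ord]),
    means = best$means[ord, , drop = FALSE],
    pi = best$pi[ord],
    bic = bic_tab
  ), class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: k = %d (%s covariance), %d proteins\n",
              x$k_selected, x$model, nrow(x$assignments)))
  cat("cluster slopes (1 = steepest): ",
      paste(sprintf("%.3g", x$cluster_slope), collapse = ", "), "\n")
  invisible(x)
}
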