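#' Empirical-Bayes moderated two-sample t-test
#'
#' Two-group differential-abundance testing with gene-wise variances
#' shrunk toward a prior: each protein's pooled residual variance
#' \eqn{s_g^2} (on \eqn{d_g} degrees of freedom) is combined with a
#' prior variance \eqn{s_0^2} on \eqn{d_0} prior degrees of freedom as
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated statistic
#' \eqn{\tilde{t}_g = \Delta\bar{y}_g / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})}
#' is referred to a t distribution on \eqn{d_0 + d_g} degrees of
#' freedom. The hyperparameters \eqn{(d_0, s_0^2)} are estimated from
#' the ensemble of sample variances by a method-of-moments fit to the
#' scaled-F model for \eqn{s_g^2} (the marginal implied by an
#' inverse-chi-square prior), using moments of \eqn{\log s_g^2}.
#'
#' As \eqn{d_0 \to 0} the test reduces to the ordinary pooled
#' two-sample t-test; as \eqn{d_0 \to \infty} every protein's
#' denominator uses \eqn{s_0^2} exactly.
#'
#' Proteins are kept whenever the model can be fitted: both group means
#' estimable and, unless a prior is available to stand in, at least one
#' residual degree of freedom. Rows constant within both groups (zero
#' variance) are omitted with a warning.
#'
#' @param m a [quant_matrix()] on the `"log2"` scale, or a plain
#'   numeric matrix (`NA` = missing).
#' @param groups list of two character vectors of sample ids (group 1
#'   vs group 2; the reported difference is group1 - group2), or a
#'   two-level factor over the columns of `m`.
#' @param prior_df override the estimated prior degrees of freedom
#'   (`0` = no shrinkage, `Inf` = full shrinkage); default `NULL`
#'   (estimate).
#' @param prior_var override the estimated prior variance; default
#'   `NULL` (estimate).
#' @return data.frame with columns `protein_id`, `mean_diff`, `t`,
#'   `df`, `p_value`, `s2`, `s2_post`, `n1`, `n2`; attributes
#'   `prior_df` and `prior_var` carry the hyperparameters used.
#' @export
moderated_t_test <- function(m, groups, prior_df = NULL, prior_var = NULL) {
  v <- if (inherits(m, "quant_matrix")) m$values else m
  stopifnot(is.matrix(v))
  if (is.factor(groups) || (is.character(groups) && !is.list(groups))) {
    f <- factor(groups)
    if (nlevels(f) != 2 || length(f) != ncol(v))
      stop("`groups` as a factor must have 2 levels over all columns",
           call. = FALSE)
    groups <- split(colnames(v), f)[levels(f)]
  }
  g1 <- intersect(groups[[1]], colnames(v))
  g2 <- intersect(groups[[2]], colnames(v))
  if (length(g1) < 1 || length(g2) < 1)
    stop("both groups must contain at least one sample present in `m`",
         call. = FALSE)

  y1 <- v[, g1, drop = FALSE]
  y2 <- v[, g2, drop = FALSE]
  n1 <- rowSums(is.finite(y1))
  n2 <- rowSums(is.finite(y2))
  m1 <- rowMeans(y1, na.rm = TRUE)
  m2 <- rowMeans(y2, na.rm = TRUE)
  ss1 <- rowSums((y1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y2 - m2)^2, na.rm = TRUE)
  d_res <- pmax(n1 + n2 - 2, 0)
  s2 <- ifelse(d_res > 0, (ss1 + ss2) / d_res, NA_real_)

  estimable <- n1 >= 1 & n2 >= 1
  zero_var <- estimable & d_res > 0 & s2 <= 0
  if (any(zero_var))
    warning(sum(zero_var), " protein(s) with zero residual variance omitted",
            call. = FALSE)
  keep_var <- estimable & d_res > 0 & s2 > 0

  # hyperparameter estimation on informative rows
  if (is.null(prior_df) || is.null(prior_var)) {
    fit <- fit_f_dist(s2[keep_var], d_res[keep_var])
    if (is.null(prior_df)) prior_df <- fit$df_prior
    if (is.null(prior_var)) prior_var <- fit$var_prior
  }

  keep <- estimable & !zero_var & (d_res > 0 | prior_df > 0)
  n1k <- n1[keep]; n2k <- n2[keep]
  dk <- d_res[keep]
  s2k <- ifelse(is.na(s2[keep]), 0, s2[keep])
  s2_post <- if (is.infinite(prior_df)) rep(prior_var, sum(keep))
             else (prior_df * prior_var + dk * s2k) / (prior_df + dk)
  diff <- (m1 - m2)[keep]
  tstat <- diff / sqrt(s2_post * (1 / n1k + 1 / n2k))
  # total df capped at the pooled residual df of the whole ensemble,
  # so an unbounded prior yields a z-like but finite-df reference
  df_pooled <- sum(d_res[keep_var])
  df_total <- pmin(prior_df + dk, df_pooled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(protein_id = rownames(v)[keep],
                    mean_diff = diff, t = tstat, df = df_total,
                    p_value = p, s2 = s2[keep], s2_post = s2_post,
                    n1 = as.integer(n1k), n2 = as.integer(n2k),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  out
}

#' Method-of-moments fit of a scaled F distribution to sample variances
#'
#' Estimates the prior degrees of freedom \eqn{d_0} and prior variance
#' \eqn{s_0^2} of the hierarchical variance model
#' \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)} by matching the first two moments
#' of \eqn{\log s_g^2}, whose theoretical mean and variance involve
#' digamma/trigamma functions of \eqn{d_g/2} and \eqn{d_0/2}.
#'
#' @param s2 vector of positive sample variances.
#' @param df vector of their residual degrees of freedom (recycled).
#' @return list with `df_prior` (possibly `Inf`) and `var_prior`.
#' @export
fit_f_dist <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]
  df <- df[ok]
  n <- length(s2)
  if (n < 2)
    return(list(df_prior = 0, var_prior = if (n) mean(s2) else NA_real_))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond sampling: variances look exchangeable,
    # prior df unbounded and the prior variance is the ensemble mean
    df_prior <- Inf
    var_prior <- mean(s2)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
# nearly linear in 1/x), with asymptotic starts at the extremes.
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}
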