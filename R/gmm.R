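# Gaussian mixture model with shared covariance, fit by EM.
# Two covariance structures are supported: "diagonal" (one variance per
# dimension, shared by all components) and "full" (one full covariance
# matrix shared by all components). Initialization is k-means++ from a
# seeded RNG with multiple restarts; the best log-likelihood is kept.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2 / sum(d2))
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

# log N(x | mu, Sigma) for all rows of x and all component means.
# chol_sigma: upper Cholesky factor of the shared covariance.
gmm_logdens <- function(x, means, chol_sigma) {
  d <- ncol(x)
  logdet <- 2 * sum(log(diag(chol_sigma)))
  k <- nrow(means)
  out <- matrix(NA_real_, nrow(x), k)
  for (j in seq_len(k)) {
    cent <- sweep(x, 2, means[j, ], "-")
    m <- backsolve(chol_sigma, t(cent), transpose = TRUE)
    out[, j] <- -0.5 * (d * log(2 * pi) + logdet + colSums(m^2))
  }
  out
}

gmm_em_once <- function(x, k, model, max_iter, tol, ridge = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  # hard initial assignment to nearest center
  dist2 <- vapply(seq_len(k), function(j)
    rowSums(sweep(x, 2, centers[j, ], "-")^2), numeric(n))
  r <- matrix(0, n, k)
  r[cbind(seq_len(n), max.col(-dist2, ties.method = "first"))] <- 1

  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(list(loglik = -Inf))
    pi_k <- nk / n
    means <- (t(r) %*% x) / nk
    # pooled (shared) covariance over all components
    sig <- matrix(0, d, d)
    for (j in seq_len(k)) {
      cent <- sweep(x, 2, means[j, ], "-")
      sig <- sig + crossprod(cent * sqrt(r[, j]))
    }
    sig <- sig / n
    if (model == "diagonal") sig <- diag(pmax(diag(sig), ridge), d)
    else sig <- sig + diag(ridge, d)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    ld <- gmm_logdens(x, means, ch)
    lw <- sweep(ld, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    new_loglik <- sum(lse)
    r <- exp(lw - lse)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol * abs(new_loglik))
      { loglik <- new_loglik; break }
    loglik <- new_loglik
  }
  list(loglik = loglik, means = means, sigma = sig, pi = pi_k,
       responsibilities = r,
       assignment = max.col(r, ties.method = "first"))
}

gmm_n_params <- function(k, d, model) {
  cov_par <- if (model == "diagonal") d else d * (d + 1) / 2
  k * d + (k - 1) + cov_par
}

#' Fit a shared-covariance Gaussian mixture by EM
#'
#' @param x numeric matrix (observations x dimensions), no missing
#'   values.
#' @param k number of components.
#' @param model `"diagonal"` (shared axis-aligned covariance) or
#'   `"full"` (shared full covariance).
#' @param nstart number of k-means++ restarts (best likelihood kept).
#' @param seed RNG seed for initialization.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return list with `loglik`, `bic` (higher is better), `means`,
#'   `sigma`, `pi`, `assignment`, `responsibilities`, `k`, `model`.
#' @export
fit_gmm <- function(x, k, model = c("diagonal", "full"), nstart = 10,
                    seed = 1, max_iter = 200, tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(is.matrix(x), all(is.finite(x)), k >= 1, k <= nrow(x))
  best <- list(loglik = -Inf)
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      fit <- gmm_em_once(x, k, model, max_iter, tol)
      if (fit$loglik > best$loglik) best <- fit
    }
  })
  if (!is.finite(best$loglik))
    stop("EM failed to converge for k = ", k, ", model = ", model,
         call. = FALSE)
  npar <- gmm_n_params(k, ncol(x), model)
  best$bic <- 2 * best$loglik - npar * log(nrow(x))
  best$k <- k
  best$model <- model
  best[c("loglik", "bic", "means", "sigma", "pi", "assignment",
         "responsibilities", "k", "model")]
}
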