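#' Repair a correlation matrix to the nearest positive semidefinite matrix
#'
#' Eigenvalues below `floor` are clipped to `floor`, the matrix is rebuilt and
#' rescaled to unit diagonal. Published or hand-assembled rank-correlation
#' matrices are frequently indefinite; this is the standard clipping repair.
#'
#' @param mat Symmetric numeric matrix with unit diagonal (approximately).
#' @param floor Smallest admissible eigenvalue (default `1e-8`).
#' @return A symmetric positive semidefinite correlation matrix.
#' @export
nearest_psd <- function(mat, floor = 1e-8) {
  if (!isSymmetric(unname(mat), tol = 1e-8)) {
    abort_config("correlation matrix must be symmetric")
  }
  eig <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  if (all(eig$values >= floor)) {
    return(mat)
  }
  vals <- pmax(eig$values, floor)
  fixed <- eig$vectors %*% diag(vals, nrow = length(vals)) %*% t(eig$vectors)
  d <- sqrt(diag(fixed))
  fixed <- fixed / tcrossprod(d)
  dimnames(fixed) <- dimnames(mat)
  (fixed + t(fixed)) / 2
}

#' Convert Spearman rank correlations to latent Gaussian correlations
#'
#' For a Gaussian copula the Pearson correlation `r` of the latent normals
#' that induces Spearman correlation `rho` between continuous margins is
#' `r = 2 * sin(pi * rho / 6)`.
#'
#' @param rho Spearman correlation value(s) or matrix.
#' @return Latent Pearson correlation(s), same shape as `rho`.
#' @export
spearman_to_pearson <- function(rho) {
  out <- 2 * sin(pi * rho / 6)
  if (is.matrix(out)) diag(out) <- 1
  out
}

# latent standard-normal draws with correlation `sigma`, deterministic per seed
sample_latent_normal <- function(n, sigma, seed) {
  p <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) {
    chol(nearest_psd(sigma, floor = 1e-8) + diag(1e-10, p))
  })
  z <- with_seed(seed, matrix(rnorm(n * p), nrow = n, ncol = p))
  x <- z %*% ch
  colnames(x) <- colnames(sigma)
  x
}

#' Sample a population from marginals and a rank-correlation matrix
#'
#' Gaussian-copula sampler: latent multivariate normal draws are transformed
#' to uniforms and pushed through each variable's fitted quantile function, so
#' both the marginal distributions and the rank-correlation structure of the
#' source summary statistics are reproduced.
#'
#' @param n Number of individuals to sample.
#' @param marginals A `marginal_spec` tibble ([fit_marginal()]), one row per
#'   variable.
#' @param correlation Named Spearman rank-correlation matrix covering every
#'   marginal variable (extra rows/columns are ignored); `NULL` means
#'   independence. Non-PSD matrices are repaired by eigenvalue clipping.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A tibble with one column per marginal variable.
#' @examples
#' m <- dplyr::bind_rows(
#'   fit_marginal(0, -0.67449, 0.67449, "normal", "a"),
#'   fit_marginal(1, 0.5, 1.6, "lognormal", "b")
#' )
#' rho <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' sample_population(100, m, rho, seed = 1)
#' @export
sample_population <- function(n, marginals, correlation = NULL, seed = 1L) {
  stopifnot_scalar_number(n, "n", min = 1)
  vars <- marginals$variable
  p <- length(vars)
  if (is.null(correlation)) {
    sigma <- diag(p)
    dimnames(sigma) <- list(vars, vars)
  } else {
    missing <- setdiff(vars, rownames(correlation))
    if (length(missing)) {
      abort_config(paste0("correlation matrix is missing variables: ",
                          paste(missing, collapse = ", ")))
    }
    sigma <- spearman_to_pearson(correlation[vars, vars, drop = FALSE])
    sigma <- nearest_psd(sigma)
  }
  z <- sample_latent_normal(n, sigma, seed)
  u <- pnorm(z)
  # clamp away from 0/1 so heavy-tailed quantile transforms stay finite
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  cols <- lapply(seq_len(p), function(j) {
    marginal_quantile(marginals[j, ], u[, j])
  })
  names(cols) <- vars
  as_tibble(cols)
}
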