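# Common Components Analysis (CCA): orthogonal components extracted from a
# salience-weighted association matrix, with per-component fixed-point
# iteration of the saliences and deflation, in the ComDim/CCSWA family with
# each variable treated as its own block.
#
# For component c on the working matrix X (n samples x p variables,
# column-centered), the converged solution satisfies:
#   (i)  lambda_j  proportional to  (x_j' t)^2,  sum_j lambda_j = 1
#   (ii) t is the dominant unit-norm eigenvector of
#        W = sum_j lambda_j x_j x_j'  =  X diag(lambda) X'
# Scores are t * sqrt(dominant eigenvalue); loadings are X' t; X is then
# deflated by projection, X <- X - t t' X.

#' Fit a Common Components Analysis model
#'
#' Extracts `n_components` orthogonal common components from a
#' column-centered matrix. For each component, per-variable non-negative
#' weights ("saliences") are iterated to a fixed point: the component is the
#' dominant eigenvector of the salience-weighted sum of variable outer
#' products, and each salience is proportional to the squared covariance of
#' its variable with the component. Variables that shape the dispersion of
#' the samples in the same way thus end up with large weights on the same
#' component. Initialization is deterministic (uniform saliences), so
#' identical inputs give bit-identical models.
#'
#' @param X Column-centered numeric matrix, samples x variables (e.g. a
#'   [pareto_scale()] result).
#' @param n_components Number of components to extract (default 2).
#' @param tol Convergence tolerance: maximum absolute change of the salience
#'   vector between iterations (default 1e-10).
#' @param max_iter Maximum salience iterations per component (default 500).
#' @return An object of class `cca_model` with elements:
#'   \describe{
#'     \item{scores}{n x K matrix; column c is the unit eigenvector scaled by
#'       the square root of the dominant eigenvalue.}
#'     \item{loadings}{p x K matrix of variable loadings `X' t`.}
#'     \item{saliences}{p x K matrix of non-negative weights, each column
#'       summing to 1.}
#'     \item{explained}{fraction of the initial total variation (squared
#'       Frobenius norm) removed by each component's deflation.}
#'     \item{iterations, converged}{per-component diagnostics.}
#'     \item{t_unit}{n x K unit-norm score directions (used for S-plots).}
#'     \item{X}{the input matrix (for per-component working matrices).}
#'     \item{tol, max_iter}{configuration echoes.}
#'   }
#'   Each component is oriented so that its largest-magnitude loading is
#'   positive (ties broken by the lowest variable index).
#' @seealso [splot()], [select_otus()]
#' @export
fit_cca <- function(X, n_components = 2L, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p < 1L || n < 2L) stop("need at least 2 samples and 1 variable",
                             call. = FALSE)
  cmeans <- colMeans(X)
  if (any(abs(cmeans) > 1e-6)) {
    stop("input is not column-centered (max |column mean| = ",
         format(max(abs(cmeans))), ")", call. = FALSE)
  }
  K <- as.integer(n_components)
  if (K < 1L || K > min(n - 1L, p)) {
    stop("n_components must lie in [1, min(n_samples - 1, n_vars)]",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(p))
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(n))

  ss0 <- sum(X^2)
  scores <- matrix(0, n, K, dimnames = list(rownames(X), paste0("CC", 1:K)))
  t_unit <- scores
  loadings <- matrix(0, p, K, dimnames = list(colnames(X), paste0("CC", 1:K)))
  saliences <- loadings
  explained <- numeric(K)
  iterations <- integer(K)
  converged <- logical(K)

  Xw <- matrix(as.numeric(X), n, p, dimnames = dimnames(X))
  X_in <- Xw
  for (k in seq_len(K)) {
    ss_before <- sum(Xw^2)
    if (ss_before <= ss0 * 1e-14 || ss0 == 0) {
      # working matrix exhausted: remaining components carry no variation
      saliences[, k] <- 1 / p
      converged[k] <- TRUE
      next
    }
    lambda <- rep(1 / p, p)
    delta <- Inf
    for (it in seq_len(max_iter)) {
      W <- tcrossprod(Xw * rep(lambda, each = n), Xw)
      es <- eigen(W, symmetric = TRUE)
      tvec <- es$vectors[, 1L]
      cov2 <- as.vector(crossprod(Xw, tvec))^2
      tot <- sum(cov2)
      lambda_new <- if (tot > 0) cov2 / tot else rep(1 / p, p)
      delta <- max(abs(lambda_new - lambda))
      lambda <- lambda_new
      iterations[k] <- it
      if (delta < tol) {
        converged[k] <- TRUE
        break
      }
    }
    if (!converged[k]) {
      warning("component ", k, " did not converge within ", max_iter,
              " iterations (last salience change ", format(delta), ")",
              call. = FALSE)
    }
    # final eigen step at the converged saliences
    W <- tcrossprod(Xw * rep(lambda, each = n), Xw)
    es <- eigen(W, symmetric = TRUE)
    tvec <- es$vectors[, 1L]
    eigval <- max(es$values[1L], 0)

    load_k <- as.vector(crossprod(Xw, tvec))
    # sign convention: largest-magnitude loading positive, lowest index on ties
    j_star <- which.max(abs(load_k))
    if (load_k[j_star] < 0) {
      tvec <- -tvec
      load_k <- -load_k
    }
    t_unit[, k] <- tvec
    scores[, k] <- tvec * sqrt(eigval)
    loadings[, k] <- load_k
    saliences[, k] <- lambda
    Xw <- Xw - tcrossprod(tvec) %*% Xw
    explained[k] <- (ss_before - sum(Xw^2)) / ss0
  }
  structure(list(scores = scores, loadings = loadings, saliences = saliences,
                 explained = explained, iterations = iterations,
                 converged = converged, t_unit = t_unit, X = X_in,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  K <- ncol(x$scores)
  cat(sprintf("<cca_model> %d samples x %d variables, %d component(s)\n",
              nrow(x$scores), nrow(x$loadings), K))
  for (k in seq_len(K)) {
    cat(sprintf("  CC%d: %.1f%% of total variation, %d iteration(s)%s\n",
                k, 100 * x$explained[k], x$iterations[k],
                if (x$converged[k]) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

# Working matrix as it stood when component k was extracted (i.e. the input
# deflated by components 1..k-1).
working_matrix <- function(model, component) {
  X <- model$X
  if (component > 1L) {
    for (b in seq_len(component - 1L)) {
      u <- model$t_unit[, b]
      if (any(u != 0)) X <- X - tcrossprod(u) %*% X
    }
  }
  X
}
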