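#' Fit a Poisson log-linear model
#'
#' Maximum-likelihood fit of `y ~ Poisson(mu)`, `log(mu) = X beta`, by
#' iteratively reweighted least squares (convergence when the relative
#' deviance change drops below 1e-9, at most 50 iterations). Rows whose design
#' entries contain `NA` — e.g. the incomplete lag-history rows a cross-basis
#' flags — are dropped, and `n_used` reports the rows retained. In
#' `quasipoisson` mode the coefficient covariance is rescaled by the Pearson
#' dispersion estimate.
#'
#' @param y non-negative integer counts.
#' @param X design matrix (include the intercept column explicitly, e.g. via
#'   [assemble_design()]); an optional `block_index` attribute (named list of
#'   column positions) is carried into the result.
#' @param family `"poisson"` (default) or `"quasipoisson"`.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return a `poisson_fit` list: `beta`, `cov`, `deviance`, `aic` (Poisson
#'   log-likelihood based), `dispersion`, `n_used`, `converged`, `fitted`,
#'   `block_index`, `rows_used`.
#' @export
fit_poisson <- function(y, X, family = c("poisson", "quasipoisson"),
                        epsilon = 1e-9, maxit = 50) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (any(y < 0, na.rm = TRUE) || any(y != round(y), na.rm = TRUE)) {
    stop("y must be non-negative integer counts")
  }
  block_index <- attr(X, "block_index")
  keep <- stats::complete.cases(X) & !is.na(y)
  Xu <- X[keep, , drop = FALSE]
  yu <- y[keep]
  if (all(yu == 0)) stop("all-zero outcome: Poisson mean not identifiable")
  qrX <- qr(Xu)
  if (qrX$rank < ncol(Xu)) {
    dropped <- colnames(Xu)[qrX$pivot[(qrX$rank + 1):ncol(Xu)]]
    blocks <- if (!is.null(block_index)) {
      hit <- vapply(block_index, function(ix) {
        any(colnames(X)[ix] %in% dropped)
      }, logical(1))
      paste0(" (blocks involved: ", paste(names(block_index)[hit],
                                          collapse = ", "), ")")
    } else ""
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), blocks)
  }
  fit <- stats::glm.fit(Xu, yu, family = stats::poisson(),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = maxit))
  if (!fit$converged) {
    warning("IRLS did not converge within ", maxit, " iterations")
  }
  # covariance = (X' W X)^{-1}; for the log link the working weights equal the
  # fitted means, evaluated at the final coefficients (glm.fit's stored
  # weights lag one IRLS step behind)
  mu <- fit$fitted.values
  XtWX <- crossprod(Xu * sqrt(mu))
  cov <- chol2inv(chol(XtWX))
  pearson <- sum((yu - mu)^2 / mu)
  dfres <- length(yu) - ncol(Xu)
  dispersion <- if (family == "quasipoisson") pearson / dfres else 1
  cov <- cov * dispersion
  dimnames(cov) <- list(colnames(Xu), colnames(Xu))
  loglik <- sum(stats::dpois(yu, mu, log = TRUE))
  structure(list(
    beta = stats::setNames(fit$coefficients, colnames(Xu)),
    cov = cov,
    deviance = fit$deviance,
    aic = -2 * loglik + 2 * ncol(Xu),
    dispersion = dispersion,
    family = family,
    n_used = length(yu),
    converged = fit$converged,
    fitted = mu,
    rows_used = which(keep),
    block_index = block_index
  ), class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Poisson fit:", length(x$beta), "coefficients on", x$n_used, "days\n")
  cat("  deviance", format(x$deviance, digits = 6),
      " AIC", format(x$aic, digits = 6),
      " dispersion", format(x$dispersion, digits = 4),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Coefficient summary table
#'
#' @param fit a [fit_poisson()] result.
#' @return data frame with term, estimate, SE, z and p columns.
#' @export
fit_summary <- function(fit) {
  se <- sqrt(diag(fit$cov))
  z <- fit$beta / se
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(se), z = unname(z),
             p = 2 * stats::pnorm(-abs(unname(z))))
}

#' Rank candidate designs by AIC
#'
#' Fits each candidate design to the same outcome and sorts ascending by AIC;
#' ties break toward fewer coefficients. Candidates must retain the same rows
#' (AIC values are otherwise not comparable), so pre-align lag trimming before
#' calling.
#'
#' @param y counts.
#' @param designs named list of design matrices.
#' @param ... passed to [fit_poisson()].
#' @return data frame (candidate, aic, n_coef, n_used) sorted by AIC, with the
#'   fits in attribute `fits`.
#' @export
aic_scan <- function(y, designs, ...) {
  stopifnot(length(designs) >= 1)
  if (is.null(names(designs))) names(designs) <- paste0("m", seq_along(designs))
  fits <- lapply(designs, function(X) fit_poisson(y, X, ...))
  n_used <- vapply(fits, `[[`, numeric(1), "n_used")
  if (length(unique(n_used)) > 1) {
    stop("candidates retain different row counts (",
         paste(unique(n_used), collapse = ", "),
         "); AIC is not comparable across them")
  }
  tab <- data.frame(candidate = names(designs),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    n_coef = vapply(fits, function(f) length(f$beta),
                                    numeric(1)),
                    n_used = n_used, row.names = NULL)
  ord <- order(tab$aic, tab$n_coef)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
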