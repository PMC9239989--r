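# Phylogenetic generalized least squares with Pagel's lambda.

#' Brownian-motion phylogenetic covariance matrix
#'
#' Expected-shared-path-length matrix: `V[i, j]` is the path length from the
#' root to the most recent common ancestor of tips i and j, and the diagonal
#' holds root-to-tip distances.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param species Optional subset/order of tip labels.
#' @return Symmetric positive-semidefinite matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL) {
  if (is.null(species)) species <- tree$tip.label
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  if (length(setdiff(tree$tip.label, species)))
    tree <- ape::keep.tip(tree, species)
  V <- ape::vcv.phylo(tree)
  V[species, species]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` is pure Brownian motion, `lambda = 0` removes all
#' phylogenetic covariance (ordinary least squares).
#'
#' @param V Covariance matrix from [phylo_covariance()].
#' @param lambda Scaling factor in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

#' Generalized least squares under a fixed covariance
#'
#' Closed-form GLS: coefficients `(X' V^-1 X)^-1 X' V^-1 y`, coefficient
#' covariance `sigma2 * (X' V^-1 X)^-1` with `sigma2` estimated from the GLS
#' residuals at `n - p` degrees of freedom, two-sided t tests, and the
#' maximum-likelihood log-likelihood used for lambda profiling.
#'
#' @param y Response vector.
#' @param X Design matrix (including the intercept column).
#' @param V Error covariance (up to the scalar `sigma2`).
#' @return List with `coefficients` (estimate, se, t, p), `sigma2`,
#'   `logLik` (ML), `fitted`, `residuals`, `df_residual`.
#' @export
pgls_fit <- function(y, X, V) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  p <- ncol(X)
  if (n <= p) stop("need more species than coefficients")
  U <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is not positive definite"))
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  qr_ <- qr(XtX)
  if (qr_$rank < p) {
    bad <- colnames(X)[qr_$pivot[seq(qr_$rank + 1L, p)]]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- solve(qr_, crossprod(Xw, yw))
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  tval <- as.vector(beta) / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  sigma2_ml <- rss / n
  ldet <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + ldet + n)
  coefs <- data.frame(estimate = as.vector(beta), se = se, t = tval,
                      p = pval, row.names = colnames(X))
  list(coefficients = coefs, sigma2 = sigma2, sigma2_ml = sigma2_ml,
       logLik = ll, fitted = fitted, residuals = resid, df_residual = df_res)
}

#' Profile the likelihood of Pagel's lambda
#'
#' Evaluates the ML profile log-likelihood of the GLS model over a uniform
#' grid on `[0, 1]` plus a bounded one-dimensional optimization for the ML
#' value, and computes the likelihood-weighted average lambda
#' `sum(lambda_i w_i)` with `w_i` proportional to `exp(l_i - max l)`. A
#' profile whose total range is under 2 log-units is flagged flat (all
#' lambda values nearly equally supported, as happens at small sample sizes).
#'
#' @param y,X,V As in [pgls_fit()].
#' @param grid_n Number of grid points (default 101).
#' @return List with `lambda_ml`, `lambda_avg`, `grid`, `loglik`, `flat`.
#' @export
profile_lambda <- function(y, X, V, grid_n = 101L) {
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(l) pgls_fit(y, X, lambda_transform(V, l))$logLik, 0)
  opt <- stats::optimize(function(l)
    pgls_fit(y, X, lambda_transform(V, l))$logLik,
    c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                cbind(grid, ll)[which.max(ll), , drop = TRUE])
  lambda_ml <- cand[which.max(cand[, 2]), 1]
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(lambda_ml = unname(lambda_ml), lambda_avg = sum(grid * w),
       grid = grid, loglik = ll, weights = w,
       flat = (max(ll) - min(ll)) < 2)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits a linear model whose error covariance is the lambda-scaled
#' Brownian-motion covariance of a phylogeny. `lambda` may be the ML value,
#' the likelihood-weighted grid average, a fixed numeric value in `[0, 1]`,
#' or `"auto"`: ML, falling back to the weighted average when the ML estimate
#' is zero on an essentially flat profile (small samples often carry almost
#' no information about lambda).
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data Data frame with one row per species.
#' @param tree Rooted `phylo` with branch lengths covering all species.
#' @param species Species labels matching tree tips; defaults to
#'   `data$species`, else `rownames(data)`.
#' @param lambda `"ML"`, `"average"`, `"auto"`, or a number in `[0, 1]`.
#' @return An object of class `pgls`: coefficients with standard errors and
#'   t tests, the lambda used and how it was chosen, the lambda profile, the
#'   ML log-likelihood, fitted values and residuals.
#' @examples
#' tr <- ape::rcoal(8)
#' d <- data.frame(species = tr$tip.label, x = rnorm(8))
#' d$y <- 1 + 2 * d$x + rnorm(8, sd = 0.1)
#' fit <- pgls(y ~ x, d, tr, lambda = 1)
#' coef(fit)
#' @export
pgls <- function(formula, data, tree, species = NULL,
                 lambda = c("auto", "ML", "average")) {
  if (is.null(species)) {
    species <- if (!is.null(data$species)) as.character(data$species)
               else rownames(data)
  }
  if (is.null(species) || anyDuplicated(species))
    stop("species labels are required and must be unique")
  if (length(species) != nrow(data))
    stop("species labels must match the rows of `data`")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  sp <- species
  V <- phylo_covariance(tree, sp)
  prof <- profile_lambda(y, X, V)
  if (is.numeric(lambda)) {
    lam <- lambda
    mode <- paste0("fixed-", format(lambda))
  } else {
    lambda <- match.arg(lambda)
    lam <- switch(lambda,
      ML = prof$lambda_ml,
      average = prof$lambda_avg,
      auto = if (prof$flat && prof$lambda_ml < 1e-6) prof$lambda_avg
             else prof$lambda_ml)
    mode <- switch(lambda, ML = "ML", average = "averaged",
                   auto = if (prof$flat && prof$lambda_ml < 1e-6) "averaged"
                          else "ML")
  }
  fit <- pgls_fit(y, X, lambda_transform(V, lam))
  structure(c(fit,
              list(lambda = lam, lambda_mode = mode, lambda_profile = prof,
                   formula = formula, species = sp, n = length(y),
                   V = V, X = X, y = y, tree = tree,
                   call = match.call())),
            class = "pgls")
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("PGLS: ", deparse(x$formula), "  (n = ", x$n, ")\n", sep = "")
  cat("lambda = ", round(x$lambda, 4), " (", x$lambda_mode, ")",
      if (x$lambda_profile$flat) "  [flat profile]", "\n", sep = "")
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  structure(list(fit = object), class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  print(x$fit)
  cat("residual sigma2 = ", format(x$fit$sigma2, digits = 4),
      ", ML log-likelihood = ", format(x$fit$logLik, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...)
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))

#' @export
logLik.pgls <- function(object, ...)
  structure(object$logLik, df = nrow(object$coefficients) + 2,
            nobs = object$n, class = "logLik")

#' @export
residuals.pgls <- function(object, ...) {
  stats::setNames(object$residuals, object$species)
}

#' @export
fitted.pgls <- function(object, ...)
  stats::setNames(object$fitted, object$species)

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  as.vector(X %*% object$coefficients$estimate)
}

#' @export
plot.pgls <- function(x, ...) {
  pred_names <- setdiff(colnames(x$X), "(Intercept)")
  if (length(pred_names) == 0L) stop("no predictor to plot")
  xv <- x$X[, pred_names[1L]]
  plot(xv, x$y, xlab = pred_names[1L],
       ylab = deparse(x$formula[[2L]]),
       pch = 19, ...)
  b <- coef(x)
  others <- setdiff(pred_names, pred_names[1L])
  off <- b[["(Intercept)"]] +
    if (length(others)) sum(b[others] * colMeans(x$X[, others, drop = FALSE])) else 0
  graphics::abline(a = off, b = b[[pred_names[1L]]], lwd = 2)
  invisible(x)
}

#' Simulate responses from a fitted PGLS model
#'
#' @param object A `pgls` fit.
#' @param nsim Number of replicate response vectors.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses (rows in
#'   `object$species` order), drawn from the fitted multivariate normal
#'   `N(X beta, sigma2 * V_lambda)`.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = 1L, ...) {
  with_local_seed(seed, {
    Vl <- lambda_transform(object$V, object$lambda)
    L <- t(chol(object$sigma2 * Vl))
    mu <- object$fitted
    out <- vapply(seq_len(nsim), function(i)
      mu + as.vector(L %*% stats::rnorm(object$n)), numeric(object$n))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    rownames(out) <- object$species
    out
  })
}
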