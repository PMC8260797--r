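# GLS machinery shared by the PGLS models. V is a correlation-structure
# matrix (the lambda-transformed phylogenetic covariance, or identity);
# the scalar rate sigma2 is profiled out by ML.
gls_profile <- function(y, X, V) {
  ch <- chol_ridge(V)
  n <- length(y)
  Ly <- backsolve(ch, y, transpose = TRUE)
  LX <- backsolve(ch, X, transpose = TRUE)
  qr_ <- qr(LX)
  if (qr_$rank < ncol(X))
    stop("predictors are collinear (rank ", qr_$rank, " < ", ncol(X), ")")
  beta <- qr.coef(qr_, Ly)
  res <- Ly - LX %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + 2 * sum(log(diag(ch))) + n)
  XtX_inv <- chol2inv(qr.R(qr_))
  list(beta = drop(beta), rss = rss, sigma2_ml = sigma2_ml, loglik = ll,
       XtX_inv = XtX_inv)
}

#' Phylogenetic generalized least squares
#'
#' Regresses a continuous species trait on predictors with residual
#' covariance proportional to a branch-length-transformed phylogenetic
#' covariance. Three transformation models are supported: `OLS_star`
#' (identity covariance, i.e. a star phylogeny: ordinary least squares),
#' `BM` (full Brownian covariance, lambda = 1) and `lambda_ML` (Pagel's
#' lambda estimated jointly with the coefficients by maximum likelihood).
#'
#' @param y Named numeric response by species.
#' @param X Predictor matrix or data frame with species rownames (an
#'   intercept column is added automatically), or a named vector for a
#'   single predictor.
#' @param tree A `"phylo"` object or covariance matrix.
#' @param model `"OLS_star"`, `"BM"`, or `"lambda_ML"`.
#' @return An object of class `"pgls_fit"`: `beta`, `se`, `t`, `p_values`
#'   (t tests on n - p residual df with the unbiased variance), `model_id`,
#'   `lambda_hat` (NA unless estimated), `loglik` (ML), `BIC`
#'   (`k*log(n) - 2*loglik` with k counting beta, sigma2, and lambda when
#'   estimated), `n`, `k`.
#' @export
pgls_fit <- function(y, X, tree, model = c("OLS_star", "BM", "lambda_ML")) {
  model <- match.arg(model)
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  y <- align_traits(y, rownames(C))
  X <- as_predictor_matrix(X, rownames(C))
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more species than coefficients")

  lambda_hat <- NA_real_
  if (model == "OLS_star") {
    V <- diag(n)
    k <- p + 1
  } else if (model == "BM") {
    V <- C
    k <- p + 1
  } else {
    obj <- function(lam) gls_profile(y, X, lambda_transform(C, lam))$loglik
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-6)
    lambda_hat <- opt$maximum
    for (b in c(0, 1)) if (obj(b) >= opt$objective) lambda_hat <- b
    V <- lambda_transform(C, lambda_hat)
    k <- p + 2
  }
  g <- gls_profile(y, X, V)
  sigma2_unb <- g$rss / (n - p)
  se <- sqrt(diag(g$XtX_inv) * sigma2_unb)
  tval <- g$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  structure(list(beta = g$beta, se = se, t = tval, p_values = pval,
                 model_id = model, lambda_hat = lambda_hat,
                 sigma2_hat = g$sigma2_ml, loglik = g$loglik,
                 BIC = k * log(n) - 2 * g$loglik,
                 n = n, k = k, residual_df = n - p),
            class = "pgls_fit")
}

as_predictor_matrix <- function(X, labels) {
  if (is.null(dim(X))) {
    if (is.null(names(X))) stop("predictor vector must be named by species")
    X <- matrix(X[labels], ncol = 1,
                dimnames = list(labels, "x"))
    if (anyNA(X)) stop("predictor values missing for species: ",
                       paste(labels[is.na(X[, 1])], collapse = ", "))
  } else {
    X <- as.matrix(X)
    if (is.null(rownames(X))) stop("predictor matrix must have species rownames")
    missing <- setdiff(labels, rownames(X))
    if (length(missing))
      stop("predictor rows missing for species: ",
           paste(missing, collapse = ", "))
    X <- X[labels, , drop = FALSE]
  }
  cbind("(Intercept)" = 1, X)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit [", x$model_id, "]",
      if (!is.na(x$lambda_hat)) sprintf(" lambda = %.4f", x$lambda_hat),
      sprintf("  logLik = %.3f  BIC = %.3f  (n = %d)\n",
              x$loglik, x$BIC, x$n), sep = "")
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p_values))
  invisible(x)
}

#' Select the PGLS branch-transformation model by BIC
#'
#' @param fits List of `"pgls_fit"` objects fitted to the same data.
#' @return The fit with minimal BIC; ties go to the model with fewer
#'   parameters.
#' @export
select_model_bic <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  stopifnot(all(vapply(fits, inherits, logical(1), "pgls_fit")))
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  k <- vapply(fits, `[[`, numeric(1), "k")
  best <- order(bic, k)[1L]
  fits[[best]]
}

#' Fit all candidate PGLS models and pick the best by BIC
#'
#' Convenience wrapper fitting `OLS_star`, `BM` and `lambda_ML` and
#' returning the BIC-selected fit together with the full model table.
#'
#' @inheritParams pgls_fit
#' @return List with `best` (`pgls_fit`) and `table` (model, BIC, loglik,
#'   slope p-value per candidate).
#' @export
pgls_model_select <- function(y, X, tree) {
  models <- c("OLS_star", "BM", "lambda_ML")
  fits <- lapply(models, function(m) pgls_fit(y, X, tree, model = m))
  tab <- data.frame(
    model = models,
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    lambda_hat = vapply(fits, `[[`, numeric(1), "lambda_hat"))
  list(best = select_model_bic(fits), table = tab)
}

#' Chi-square test of a two-choice behavioral count against 50:50
#'
#' Pearson goodness-of-fit test on one degree of freedom, without
#' continuity correction, for counts such as copulations with the
#' compound-perfumed versus solvent-perfumed rival.
#'
#' @param n_option_a,n_option_b Non-negative integer counts (total > 0).
#' @return A `"stat_result"` with the chi-square statistic and upper-tail
#'   p-value.
#' @export
chisq_choice_test <- function(n_option_a, n_option_b) {
  if (n_option_a < 0 || n_option_b < 0) stop("counts must be >= 0")
  total <- n_option_a + n_option_b
  if (total <= 0) stop("total count must be > 0")
  ct <- suppressWarnings(
    stats::chisq.test(c(n_option_a, n_option_b), p = c(0.5, 0.5),
                      correct = FALSE))
  stat_result(ct$statistic, ct$p.value, "Chi-square goodness of fit (1 df)",
              total)
}
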