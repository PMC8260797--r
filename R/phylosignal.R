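#' Log-likelihood of a trait under lambda-transformed Brownian motion
#'
#' Evaluates the multivariate-normal log density of a species trait vector
#' with mean `mu * 1` and covariance `sigma2 * C(lambda)`, where `C(lambda)`
#' is the Pagel transform of the Brownian covariance.
#'
#' @param y Named numeric vector of species trait values; names must cover
#'   `rownames(C)`.
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @param lam Pagel's lambda in `[0, 1]`.
#' @param sigma2 Brownian rate (> 0), trait-units^2 per branch-length unit.
#' @param mu Root (ancestral) mean, trait units.
#' @return The log density (a single number).
#' @export
bm_loglik <- function(y, C, lam, sigma2, mu) {
  stopifnot(is.numeric(y), is.matrix(C))
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  y <- align_traits(y, rownames(C))
  V <- sigma2 * lambda_transform(C, lam)
  ch <- chol_ridge(V)
  r <- backsolve(ch, y - mu, transpose = TRUE)
  n <- length(y)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

# Align a named trait vector to a label order; error listing missing species.
align_traits <- function(y, labels) {
  if (is.null(names(y)))
    stop("trait vector must be named by species label")
  missing <- setdiff(labels, names(y))
  if (length(missing))
    stop("trait values missing for species: ",
         paste(missing, collapse = ", "))
  y[labels]
}

# Profile log-likelihood of lambda: mu and sigma2 maximized in closed form
# by GLS for the given lambda. Returns loglik, mu_hat, sigma2_hat.
# Uses the ML divisor n for sigma2 (profile likelihood).
profile_lambda <- function(y, C, lam) {
  V <- lambda_transform(C, lam)
  ch <- chol_ridge(V)
  n <- length(y)
  one <- rep(1, n)
  Li_y <- backsolve(ch, y, transpose = TRUE)
  Li_1 <- backsolve(ch, one, transpose = TRUE)
  mu <- sum(Li_1 * Li_y) / sum(Li_1^2)
  rss <- sum((Li_y - mu * Li_1)^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
  list(loglik = ll, mu_hat = mu, sigma2_hat = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' For each candidate lambda the root mean and Brownian rate are profiled
#' out in closed form by GLS; lambda itself is found by bounded 1-D
#' optimization on `[0, 1]` started from a coarse grid, so multimodal
#' profiles cannot trap the search in a local mode. Boundary values are
#' always evaluated and win ties.
#'
#' @param y Named numeric species trait vector (>= 3 finite values, not
#'   constant).
#' @param tree A `"phylo"` object, or a precomputed covariance matrix from
#'   [phylo_covariance()].
#' @param tol Convergence tolerance on lambda. Default 1e-6.
#' @return An object of class `"lambda_fit"`: list with `lambda_hat`,
#'   `sigma2_hat`, `mu_hat`, `loglik`, `converged`, `n_species`.
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' y <- simulate_bm_traits(tr, lam = 1, sigma2 = 1, mu = 0, n_traits = 1,
#'                         seed = 2)[, 1]
#' fit_lambda(y, tr)
#' @export
fit_lambda <- function(y, tree, tol = 1e-6) {
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  y <- align_traits(y, rownames(C))
  if (anyNA(y)) {
    keep <- !is.na(y)
    y <- y[keep]
    C <- C[keep, keep, drop = FALSE]
  }
  n <- length(y)
  if (n < 3L) stop("need >= 3 species with finite trait values")
  if (stats::sd(y) == 0)
    stop("trait is constant across species; lambda is unidentifiable")

  obj <- function(lam) profile_lambda(y, C, lam)$loglik
  starts <- c(0, 0.25, 0.5, 0.75, 1)
  best_lam <- 0
  best_ll <- -Inf
  for (s in seq_len(length(starts) - 1L)) {
    opt <- stats::optimize(obj, lower = starts[s], upper = starts[s + 1L],
                           maximum = TRUE, tol = tol)
    if (opt$objective > best_ll) {
      best_ll <- opt$objective
      best_lam <- opt$maximum
    }
  }
  # boundaries win ties (within tol of interior optimum)
  for (b in c(0, 1)) {
    llb <- obj(b)
    if (llb >= best_ll - 1e-8) {
      if (llb > best_ll || abs(best_lam - b) < 2 * tol) {
        best_ll <- max(llb, best_ll)
        best_lam <- b
      }
    }
  }
  prof <- profile_lambda(y, C, best_lam)
  structure(list(lambda_hat = best_lam,
                 sigma2_hat = prof$sigma2_hat,
                 mu_hat = prof$mu_hat,
                 loglik = prof$loglik,
                 converged = TRUE,
                 n_species = n),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda fit (", x$n_species, " species)\n", sep = "")
  cat(sprintf("  lambda = %.4f  sigma2 = %.4g  mu = %.4g  logLik = %.3f\n",
              x$lambda_hat, x$sigma2_hat, x$mu_hat, x$loglik))
  invisible(x)
}

#' Lambda estimates for every column of a trait matrix
#'
#' @param tm Species x feature matrix (rownames = species labels), e.g.
#'   from [standardize_profiles()].
#' @param tree `"phylo"` object or covariance matrix.
#' @return Data frame with one row per feature: `feature`, `lambda_hat`,
#'   `sigma2_hat`, `mu_hat`, `loglik`, `n`. Features whose fit fails
#'   (constant across species) are dropped with a message reporting the
#'   count.
#' @export
fit_lambda_profile <- function(tm, tree) {
  stopifnot(is.matrix(tm))
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  res <- vector("list", ncol(tm))
  dropped <- 0L
  for (j in seq_len(ncol(tm))) {
    fit <- tryCatch(fit_lambda(tm[, j], C), error = function(e) NULL)
    if (is.null(fit)) {
      dropped <- dropped + 1L
      next
    }
    res[[j]] <- data.frame(feature = colnames(tm)[j],
                           lambda_hat = fit$lambda_hat,
                           sigma2_hat = fit$sigma2_hat,
                           mu_hat = fit$mu_hat,
                           loglik = fit$loglik,
                           n = fit$n_species,
                           stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    message(dropped, " feature(s) dropped (constant across species)")
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

# Two-sided Mann-Whitney rank-sum test. For small samples (at most
# `exact_limit` group assignments) the permutation null of the rank-sum
# statistic is enumerated exactly, ties included via midranks; larger
# samples use the normal approximation with tie and continuity
# corrections (stats::wilcox.test).
rank_sum_test <- function(a, b, exact_limit = 50000) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  W <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(ranks[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(w_all <= W), mean(w_all >= W)))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         correct = TRUE, exact = FALSE))
    p <- wt$p.value
    # every observation tied: the tie-corrected variance is 0 and the
    # normal approximation returns NaN; the samples are indistinguishable
    if (is.na(p) && length(unique(c(a, b))) == 1L) p <- 1
  }
  list(statistic = W, p_value = p)
}

# Shared container for simple hypothesis-test results.
stat_result <- function(statistic, p_value, method, n1, n2 = NA_integer_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n1 = n1, n2 = n2),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), " (n1 = ", x$n1,
      if (!is.na(x$n2)) paste0(", n2 = ", x$n2), ")\n", sep = "")
  invisible(x)
}

#' Compare two distributions of lambda estimates between groups
#'
#' Two-sided unpaired Wilcoxon (Mann-Whitney) rank-sum test, as used to
#' contrast per-compound phylogenetic signal between the sexes. The exact
#' null distribution is used for small tie-free samples; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param lams_a,lams_b Numeric vectors of lambda estimates (non-empty).
#' @return A `"stat_result"` with the Mann-Whitney `W` statistic and
#'   two-sided p-value.
#' @export
compare_lambda_distributions <- function(lams_a, lams_b) {
  if (!length(lams_a) || !length(lams_b))
    stop("both samples must be non-empty")
  rs <- rank_sum_test(lams_a, lams_b)
  stat_result(rs$statistic, rs$p_value, "Wilcoxon rank sum",
              length(lams_a), length(lams_b))
}
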