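#' Select the top-ranked k-mers as model features
#'
#' Takes the first `top_n` rows of an association table (already sorted by
#' ascending p, ties by |t| then k-mer string).
#'
#' @param table an `association_table`.
#' @param top_n number of k-mers to keep (default 1000).
#' @return character vector of k-mer strings.
#' @export
select_top <- function(table, top_n = 1000L) {
  stopifnot(inherits(table, "association_table"))
  if (nrow(table) == 0L) stop("empty association table", call. = FALSE)
  table$kmer[seq_len(min(top_n, nrow(table)))]
}

#' Phenotype prediction from top k-mers by nested cross-validation
#'
#' Fits an L1-regularized (lasso) linear regression of the phenotype on the
#' binary presence of the top-ranked k-mers, and evaluates it by nested
#' cross-validation: a seeded random partition of strains into `outer_folds`
#' test folds (each strain tested exactly once), with the regularization
#' strength chosen per outer fold by inner cross-validation over a grid.
#' Mean squared error, out-of-sample R-squared and Spearman rank correlation
#' are computed per fold and averaged; R-squared compares residuals with
#' deviations from the training-fold mean, so it stays defined when a test
#' fold happens to contain one phenotype class (Spearman is NA there and
#' excluded from the average). A final model is refit on all strains with the
#' modal inner-selected strength.
#'
#' By default the feature ranking is computed once on all strains (global
#' top-N, as k-mer GWAS tools do); this leaks the test strains into feature
#' selection, so `rank_in_fold = TRUE` re-ranks k-mers within each training
#' fold for a leakage-free estimate.
#'
#' @param object a `kmer_gwas` fit, or a list with elements `association`,
#'   `kmers`, `phenotype`, `weights`.
#' @param top_n number of top k-mers used as features.
#' @param outer_folds,inner_folds fold counts (outer default 3).
#' @param lambda decreasing grid of L1 penalties (default 0.001 to 10,
#'   log-spaced).
#' @param seed integer seed for the fold assignments.
#' @param rank_in_fold re-rank features inside each training fold.
#' @return an object of class `kmer_cv_model`: list with `fold_metrics`
#'   (per-fold MSE, R2, Spearman and chosen lambda), `mean_metrics`, `folds`
#'   (outer assignment per strain), `features`, `final` (glmnet fit, chosen
#'   lambda, nonzero coefficients), `fitted` (cross-validated predictions)
#'   and `call`.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 11)
#' sim <- simulate_phenotype(simulate_genomes(cfg))
#' fit <- kmer_gwas(sim, sim$truth$true_phenotype)
#' mod <- fit_kmer_model(fit, seed = 1)
#' mod$mean_metrics
#' }
#' @export
fit_kmer_model <- function(object, top_n = 1000L, outer_folds = 3L,
                           inner_folds = 3L,
                           lambda = 10^seq(1, -3, length.out = 9L),
                           seed = 1L, rank_in_fold = FALSE) {
  cl <- match.call()
  assoc <- object$association
  km <- object$kmers
  y <- as.numeric(object$phenotype)
  strains <- rownames(km$counts)
  n <- length(strains)
  if (outer_folds < 2L) stop("outer_folds must be >= 2", call. = FALSE)
  if (n < outer_folds) stop("need at least one strain per fold",
                            call. = FALSE)
  lambda <- sort(lambda, decreasing = TRUE)
  if (stats::sd(y) == 0)
    warning("constant phenotype: R-squared undefined (NaN)", call. = FALSE)

  features <- select_top(assoc, top_n)
  X_all <- design_matrix(km, features)

  folds <- with_seed(seed, sample(rep_len(seq_len(outer_folds), n)))
  names(folds) <- strains

  fold_rows <- vector("list", outer_folds)
  fitted_cv <- rep(NA_real_, n)
  for (f in seq_len(outer_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (rank_in_fold) {
      km_tr <- km
      km_tr$counts <- km$counts[train, , drop = FALSE]
      km_tr <- filter_kmers(km_tr, 1L, 1L)
      assoc_tr <- run_association(km_tr, y[train],
                                  weights = object$weights[train],
                                  alpha = 1)
      feats <- select_top(assoc_tr, top_n)
      X <- design_matrix(km, feats)
    } else {
      X <- X_all
    }
    lam <- inner_cv_lambda(X[train, , drop = FALSE], y[train], inner_folds,
                           lambda, seed = seed * 1000L + f)
    fit <- lasso_fit_safe(X[train, , drop = FALSE], y[train], lambda)
    pred <- as.numeric(lasso_predict(fit, X[test, , drop = FALSE], s = lam))
    fitted_cv[test] <- pred
    yt <- y[test]
    mse <- mean((yt - pred)^2)
    # out-of-sample R2 against the training mean: stays defined when a test
    # fold happens to contain a single phenotype class
    r2 <- 1 - sum((yt - pred)^2) / sum((yt - mean(y[train]))^2)
    rho <- suppressWarnings(stats::cor(yt, pred, method = "spearman"))
    fold_rows[[f]] <- data.frame(fold = f, n_test = length(test),
                                 lambda = lam, mse = mse, r2 = r2,
                                 spearman = rho)
  }
  fm <- do.call(rbind, fold_rows)
  mean_metrics <- c(mse = mean(fm$mse), r2 = mean(fm$r2),
                    spearman = mean(fm$spearman, na.rm = TRUE))

  # final refit on all strains with the modal inner-selected strength
  tab <- table(fm$lambda)
  modal <- max(as.numeric(names(tab)[tab == max(tab)]))
  final_fit <- lasso_fit_safe(X_all, y, lambda)
  if (inherits(final_fit, "intercept_only")) {
    coefs <- c("(Intercept)" = final_fit$mu)
  } else {
    beta <- stats::coef(final_fit, s = modal)
    nz <- which(as.numeric(beta) != 0)
    coefs <- stats::setNames(as.numeric(beta)[nz], rownames(beta)[nz])
  }

  structure(list(
    fold_metrics = fm,
    mean_metrics = mean_metrics,
    folds = folds,
    features = features,
    fitted = stats::setNames(fitted_cv, strains),
    phenotype = stats::setNames(y, strains),
    final = list(fit = final_fit, lambda = modal, coefficients = coefs),
    rank_in_fold = rank_in_fold,
    call = cl
  ), class = "kmer_cv_model")
}

# binary strain x feature design matrix (at least two columns for glmnet;
# a zero dummy column is appended for single-feature sets and never reported)
design_matrix <- function(km, features) {
  X <- kmer_presence(km)[, features, drop = FALSE]
  storage.mode(X) <- "numeric"
  if (ncol(X) == 1L)
    X <- cbind(X, `.dummy` = 0)
  X
}

# lasso fit that degrades to an intercept-only model on constant response
lasso_fit_safe <- function(X, y, lambda) {
  colvar <- colMeans(X^2) - colMeans(X)^2
  if (stats::sd(y) == 0 || all(colvar == 0)) {
    return(structure(list(mu = mean(y)), class = "intercept_only"))
  }
  glmnet::glmnet(X, y, alpha = 1, lambda = lambda)
}

lasso_predict <- function(fit, X, s) {
  if (inherits(fit, "intercept_only"))
    return(matrix(fit$mu, nrow(X), length(s)))
  stats::predict(fit, X, s = s)
}

# inner CV: mean held-out MSE per lambda; ties go to the stronger penalty
inner_cv_lambda <- function(X, y, inner_folds, lambda, seed) {
  n <- nrow(X)
  kf <- min(inner_folds, n)
  assign <- with_seed(seed, sample(rep_len(seq_len(kf), n)))
  err <- matrix(NA_real_, kf, length(lambda))
  for (f in seq_len(kf)) {
    tr <- which(assign != f); te <- which(assign == f)
    if (length(tr) < 2L) next
    fit <- lasso_fit_safe(X[tr, , drop = FALSE], y[tr], lambda)
    pr <- lasso_predict(fit, X[te, , drop = FALSE], s = lambda)
    err[f, ] <- colMeans((pr - y[te])^2)
  }
  m <- colMeans(err, na.rm = TRUE)
  lambda[which(m <= min(m) + 1e-15)[1L]]   # grid is decreasing: first = largest
}

#' @export
print.kmer_cv_model <- function(x, ...) {
  cat("nested cross-validated k-mer lasso (",
      nrow(x$fold_metrics), " outer folds, ", length(x$features),
      " candidate k-mers)\n", sep = "")
  cat("  mean test MSE:      ", format(x$mean_metrics["mse"], digits = 4),
      "\n", sep = "")
  cat("  mean test R2:       ", format(x$mean_metrics["r2"], digits = 4),
      "\n", sep = "")
  cat("  mean test Spearman: ", format(x$mean_metrics["spearman"],
                                       digits = 4), "\n", sep = "")
  cat("  final lambda:       ", format(x$final$lambda, digits = 4),
      " (", sum(names(x$final$coefficients) != "(Intercept)"),
      " nonzero k-mer coefficients)\n", sep = "")
  invisible(x)
}

#' @export
summary.kmer_cv_model <- function(object, ...) {
  print(object)
  cat("\nper-fold metrics:\n")
  print(object$fold_metrics, digits = 4)
  cat("\nnonzero coefficients:\n")
  print(round(object$final$coefficients, 4))
  invisible(object)
}

#' @export
coef.kmer_cv_model <- function(object, ...) {
  object$final$coefficients
}

#' Predict phenotype for new genomes from a fitted k-mer model
#'
#' @param object a `kmer_cv_model`.
#' @param newdata a `kmer_matrix`, a `rhizo_sim`, a genome list (counted on
#'   the fly), or a binary strain x k-mer matrix. Features absent from
#'   `newdata` count as 0.
#' @param ... unused.
#' @return named numeric vector of predicted occupancies.
#' @export
predict.kmer_cv_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "rhizo_sim") || (is.list(newdata) &&
      !inherits(newdata, "kmer_matrix") && !is.matrix(newdata)))
    newdata <- count_kmers(newdata)
  P <- if (inherits(newdata, "kmer_matrix")) kmer_presence(newdata) else
    newdata >= 1
  X <- matrix(0, nrow(P), length(object$features),
              dimnames = list(rownames(P), object$features))
  have <- intersect(colnames(P), object$features)
  X[, have] <- P[, have] + 0
  if (ncol(X) == 1L) X <- cbind(X, `.dummy` = 0)
  drop(lasso_predict(object$final$fit, X, s = object$final$lambda))
}

#' Plot cross-validated predictions against observed phenotype
#'
#' @param x a `kmer_cv_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kmer_cv_model <- function(x, ...) {
  graphics::plot(x$phenotype, x$fitted,
                 xlab = "observed occupancy", ylab = "CV-predicted occupancy",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
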