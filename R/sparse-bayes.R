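#' Sparse Bayesian (relevance-vector) linear regression
#'
#' Linear-in-features model y = w0 + sum_j w_j x_j + eps with independent
#' zero-mean Gaussian priors w_j ~ N(0, 1/alpha_j) and type-II maximum
#' likelihood over the precisions alpha and the noise variance sigma^2.
#' Features whose precision diverges past the pruning ceiling carry no
#' evidence and are removed, giving automatic selection of an optimal
#' feature subset; the intercept is never pruned. The basis is the
#' (standardized) feature columns themselves, not a kernel over samples:
#' the model selects among LiDAR variables.
#'
#' @name sparse_bayes
NULL

#' Fitting controls
#'
#' @param max_iter outer iteration cap.
#' @param tol convergence tolerance on the largest |change of log alpha|.
#' @param prune_ceiling precisions above this are pruned. Both features and
#'   response are standardized internally, so the ceiling is scale-free;
#'   the default 1e4 removes weights below about 1% of the response sd.
#' @param alpha_init initial precision for every weight.
#' @param sigma2_init initial noise variance (default: 10% of var(y)).
#' @param prune prune high-precision features (TRUE) or keep all (FALSE).
#' @param fix_alpha if non-NULL, hold every alpha fixed at this value and
#'   only re-estimate the noise (the ridge/OLS limit used in checks).
#' @export
rvm_control <- function(max_iter = 500, tol = 1e-4, prune_ceiling = 1e4,
                        alpha_init = 1e-6, sigma2_init = NULL,
                        prune = TRUE, fix_alpha = NULL) {
  if (tol <= 0) stop("tolerance must be positive")
  if (prune_ceiling <= alpha_init) stop("ceiling must exceed initial alpha")
  list(max_iter = max_iter, tol = tol, prune_ceiling = prune_ceiling,
       alpha_init = alpha_init, sigma2_init = sigma2_init, prune = prune,
       fix_alpha = fix_alpha)
}

## Cholesky solve with escalating diagonal jitter
chol_safe <- function(C) {
  jit <- 0
  for (k in 0:6) {
    R <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-10 * mean(diag(C)) else jit * 100
  }
  stop("design matrix irreparably singular")
}

#' Fit the sparse Bayesian regression
#'
#' Iterates the posterior update Sigma = (sigma^-2 Phi' Phi + A)^-1,
#' mu = sigma^-2 Sigma Phi' y with the evidence updates
#' gamma_i = 1 - alpha_i Sigma_ii, alpha_i <- gamma_i / mu_i^2,
#' sigma^2 <- ||y - Phi mu||^2 / (n - sum gamma); prunes features whose
#' alpha exceeds the ceiling; stops when log-alpha changes fall below the
#' tolerance. Deterministic given inputs and control.
#'
#' @param X numeric feature matrix (n x p), named columns; standardized
#'   internally (constant columns are dropped and recorded).
#' @param y numeric response of length n >= 3.
#' @param control a [rvm_control()] list.
#' @return object of class `rvm_model`.
#' @export
rvm_fit <- function(X, y, control = rvm_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 3) stop("need at least 3 observations")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  n <- nrow(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  ctr <- colMeans(X[, keep, drop = FALSE])
  scl <- scl[keep]
  Xs <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)
  ## perfectly collinear duplicates make the weight split indeterminate;
  ## keep the first column of each such group
  dropped_collinear <- character(0)
  if (ncol(Xs) > 1) {
    cc <- abs(stats::cor(Xs))
    dup <- vapply(seq_len(ncol(Xs)), function(j)
      j > 1 && any(cc[seq_len(j - 1), j] > 1 - 1e-10), logical(1))
    if (any(dup)) {
      dropped_collinear <- colnames(Xs)[dup]
      Xs <- Xs[, !dup, drop = FALSE]
      ctr <- ctr[!dup]; scl <- scl[!dup]
    }
  }
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1           # constant response
  y <- (y - y_center) / y_scale
  Phi_full <- cbind(`(intercept)` = 1, Xs)
  p1 <- ncol(Phi_full)
  active <- seq_len(p1)                       # 1 = intercept
  alpha <- rep(if (is.null(control$fix_alpha)) control$alpha_init
               else control$fix_alpha, p1)
  sigma2 <- if (is.null(control$sigma2_init)) {
    max(0.1 * stats::var(y), 1e-8)
  } else control$sigma2_init
  fit_log <- list()
  logml <- -Inf
  for (it in seq_len(control$max_iter)) {
    Phi <- Phi_full[, active, drop = FALSE]
    A <- alpha[active]
    C <- crossprod(Phi) / sigma2 + diag(A, length(A))
    R <- chol_safe(C)
    Sigma <- chol2inv(R)
    mu <- drop(Sigma %*% crossprod(Phi, y)) / sigma2
    gamma <- 1 - A * diag(Sigma)
    resid <- y - drop(Phi %*% mu)
    ## marginal likelihood via determinant/quadratic identities
    logdetCy <- n * log(sigma2) - sum(log(A)) + 2 * sum(log(diag(R)))
    quad <- sum(y * resid) / sigma2
    logml_new <- -0.5 * (n * log(2 * pi) + logdetCy + quad)
    if (is.null(control$fix_alpha)) {
      alpha_new <- ifelse(mu^2 > 0, pmax(gamma, 1e-12) / mu^2,
                          control$prune_ceiling * 10)
      alpha_new[1] <- min(alpha_new[1], control$prune_ceiling / 10)  # intercept
    } else {
      alpha_new <- alpha[active]
    }
    dof <- max(n - sum(gamma), 1e-6)
    sigma2 <- max(sum(resid^2) / dof, 1e-12)
    delta <- max(abs(log(alpha_new) - log(alpha[active])))
    alpha[active] <- alpha_new
    pruned <- character(0)
    if (control$prune && is.null(control$fix_alpha)) {
      out <- active[alpha[active] > control$prune_ceiling & active != 1]
      if (length(out)) {
        pruned <- colnames(Phi_full)[out]
        active <- setdiff(active, out)
      }
    }
    fit_log[[it]] <- data.frame(iter = it, n_active = length(active),
                                n_pruned = length(pruned),
                                log_marginal = logml_new)
    logml <- logml_new
    if (delta < control$tol && length(pruned) == 0) break
  }
  ## final posterior on the surviving set
  Phi <- Phi_full[, active, drop = FALSE]
  A <- alpha[active]
  C <- crossprod(Phi) / sigma2 + diag(A, length(A))
  Sigma <- chol2inv(chol_safe(C))
  mu <- drop(Sigma %*% crossprod(Phi, y)) / sigma2
  structure(list(
    feature_names = colnames(Xs), retained = colnames(Phi_full)[active],
    active = active, weights = stats::setNames(mu, colnames(Phi_full)[active]),
    Sigma = Sigma, alpha = stats::setNames(alpha[active],
                                           colnames(Phi_full)[active]),
    sigma2 = sigma2, center = ctr, scale = scl,
    y_center = y_center, y_scale = y_scale,
    dropped_constant = colnames(X)[!keep],
    dropped_collinear = dropped_collinear,
    fit_log = do.call(rbind, fit_log), converged = it < control$max_iter,
    control = control), class = "rvm_model")
}

#' @export
print.rvm_model <- function(x, ...) {
  cat(sprintf(
    "<rvm_model> %d/%d features retained, sigma^2 = %.4g, %d iterations\n",
    length(x$retained) - 1, length(x$feature_names), x$sigma2,
    nrow(x$fit_log)))
  invisible(x)
}

## standardized design over the retained basis for new data
rvm_design <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)))
    colnames(X_new) <- paste0("x", seq_len(ncol(X_new)))
  miss <- setdiff(model$feature_names, colnames(X_new))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  Xs <- scale(X_new[, model$feature_names, drop = FALSE],
              center = model$center, scale = model$scale)
  cbind(`(intercept)` = 1, Xs)[, model$retained, drop = FALSE]
}

#' Predict from a fitted sparse Bayesian model
#'
#' Predictive mean Phi mu and predictive variance
#' sigma^2 + diag(Phi Sigma Phi') per row, in response units.
#'
#' @param model an `rvm_model`.
#' @param X_new matrix/data.frame with the model's feature columns.
#' @return data.frame with `mean` and `variance`.
#' @export
rvm_predict <- function(model, X_new) {
  Phi <- rvm_design(model, X_new)
  mean <- model$y_center + model$y_scale * drop(Phi %*% model$weights)
  var <- model$y_scale^2 *
    (model$sigma2 + rowSums((Phi %*% model$Sigma) * Phi))
  data.frame(mean = mean, variance = var)
}

#' Leave-one-out validation
#'
#' Refits the model n times, each fit excluding one observation and
#' predicting it; held-out pairs are scored with the package's RMSE%,
#' Bias% and R^2 statistics.
#'
#' @inheritParams rvm_fit
#' @return list: `predictions` (held-out predictive means), `measured`,
#'   `rmse`, `bias`, `r2` (each the corresponding statistic list),
#'   `n_fits`.
#' @export
loo_validate <- function(X, y, control = rvm_control()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out needs at least 4 observations")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- rvm_fit(X[-i, , drop = FALSE], y[-i], control)
    pred[i] <- rvm_predict(m, X[i, , drop = FALSE])$mean
  }
  list(predictions = pred, measured = y, rmse = rmse(y, pred),
       bias = bias(y, pred), r2 = r_squared(y, pred), n_fits = n)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model an `rvm_model`.
#' @param path file path.
#' @export
write_rvm_json <- function(model, path) {
  obj <- list(feature_names = model$feature_names, retained = model$retained,
              weights = as.list(model$weights),
              alpha = as.list(model$alpha), sigma2 = model$sigma2,
              Sigma = model$Sigma, center = as.list(model$center),
              scale = as.list(model$scale),
              y_center = model$y_center, y_scale = model$y_scale,
              dropped_constant = model$dropped_constant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rvm_json
#' @export
read_rvm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    feature_names = o$feature_names, retained = o$retained,
    weights = stats::setNames(unlist(o$weights), o$retained),
    Sigma = matrix(unlist(o$Sigma), length(o$retained)),
    alpha = stats::setNames(unlist(o$alpha), o$retained),
    sigma2 = o$sigma2,
    center = stats::setNames(unlist(o$center), o$feature_names),
    scale = stats::setNames(unlist(o$scale), o$feature_names),
    y_center = o$y_center, y_scale = o$y_scale,
    dropped_constant = o$dropped_constant,
    fit_log = NULL, converged = NA), class = "rvm_model")
}
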