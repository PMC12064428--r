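# Environment models: correlation pre-filter, beta regression of the
# introgression index (logit links for mean and dispersion), stepwise AIC
# selection, a variance-inflation loop and the Cox-Snell generalized R^2.

#' Squeeze boundary values of a (0,1) response
#'
#' `(y (n - 1) + 0.5)/n`: maps exact 0 and 1 into the open interval so the
#' beta likelihood is finite.
#' @param y numeric vector in [0, 1].
#' @param n sample size used for the squeeze (default `length(y)`).
#' @return squeezed vector.
#' @export
squeeze_unit <- function(y, n = length(y)) (y * (n - 1) + 0.5) / n

#' Correlation pre-filter for environmental covariates
#'
#' Pairwise Pearson correlations: derived variables correlated at
#' `|r| >= r_max` with any primary variable are dropped; among correlated
#' primary pairs the variable appearing earlier in `preferences` (falling
#' back to column order) is kept. Retention order is deterministic.
#'
#' @param env data.frame or matrix of covariates (numeric columns only are
#'   considered).
#' @param r_max correlation threshold (default 0.7).
#' @param primary character vector of primary-variable names; all others
#'   are treated as derived. Default: all primary.
#' @param preferences character vector ordering variables by biological
#'   preference; earlier wins within a correlated primary pair.
#' @return character vector of retained covariate names.
#' @export
correlation_filter <- function(env, r_max = 0.7, primary = NULL,
                               preferences = NULL) {
  X <- as.data.frame(env)
  num <- vapply(X, is.numeric, logical(1))
  vars <- names(X)[num]
  primary <- primary %||% vars
  R <- suppressWarnings(cor(X[vars], use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  dropped <- character(0)
  # 1. derived vs primary
  for (v in setdiff(vars, primary)) {
    prim_now <- setdiff(intersect(primary, setdiff(vars, dropped)), v)
    if (length(prim_now) && any(abs(R[v, prim_now]) >= r_max))
      dropped <- c(dropped, v)
  }
  # 2. correlated primary pairs: keep the preferred one
  pref_rank <- function(v) {
    i <- match(v, preferences %||% vars)
    ifelse(is.na(i), length(vars) + match(v, vars), i)
  }
  prim <- intersect(primary, setdiff(vars, dropped))
  prim <- prim[order(pref_rank(prim))]
  keep <- character(0)
  for (v in prim) {
    if (!length(keep) || all(abs(R[v, keep]) < r_max)) keep <- c(keep, v)
    else dropped <- c(dropped, v)
  }
  retained <- setdiff(vars, dropped)
  retained[order(match(retained, vars))]
}

#' Centre and scale covariates
#'
#' Retained covariates are centred (mean 0) and scaled (sd 1) before
#' modelling, so coefficients are comparable across variables.
#' @param env data.frame with `pop_id` and covariates.
#' @param vars covariates to standardize.
#' @return the data.frame with standardized columns.
#' @export
standardize_covariates <- function(env, vars) {
  for (v in vars) env[[v]] <- as.numeric(scale(env[[v]]))
  env
}

beta_loglik <- function(par, y, X) {
  k <- ncol(X)
  mu <- plogis(drop(X %*% par[seq_len(k)]))
  sig <- plogis(par[k + 1L])
  phi <- (1 - sig^2) / sig^2
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Beta regression with logit mean and logit dispersion links
#'
#' Maximum likelihood for the beta family parameterized by mean mu (logit
#' link on the linear predictor) and dispersion sigma in (0,1) (logit link,
#' intercept-only): the shape parameters are `mu*phi` and `(1-mu)*phi` with
#' `phi = (1 - sigma^2)/sigma^2`, so `var(y) = sigma^2 mu (1 - mu)`.
#' Optimization is deterministic from a least-squares start on the
#' logit-transformed response; standard errors come from the observed
#' information (numerical Hessian).
#'
#' @param y response strictly inside (0,1); exact 0/1 raise an error unless
#'   `squeeze = TRUE` applies [squeeze_unit()].
#' @param X design matrix or data.frame of covariates; an intercept column
#'   is added when absent.
#' @param squeeze apply the boundary squeeze (default FALSE).
#' @return a `beta_fit`: list with `coefficients` (data.frame term,
#'   estimate, se, z, p_value), `sigma`, `phi`, `loglik`, `aic`, `n`,
#'   `terms`, `converged`, `vcov`.
#' @export
fit_beta <- function(y, X = NULL, squeeze = FALSE) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("non-finite response")
  if (any(y <= 0 | y >= 1)) {
    if (squeeze) y <- squeeze_unit(y)
    else stop("response must lie strictly in (0,1); enable squeeze = TRUE")
  }
  if (var(y) == 0) stop("constant response cannot be fit")
  if (is.null(X)) {
    Xm <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xm <- as.matrix(as.data.frame(X))
    if (!"(Intercept)" %in% colnames(Xm))
      Xm <- cbind(`(Intercept)` = 1, Xm)
  }
  if (nrow(Xm) != length(y)) stop("dimension mismatch between y and X")
  if (qr(Xm)$rank < ncol(Xm)) stop("design matrix is rank deficient")
  k <- ncol(Xm)
  start_beta <- qr.solve(Xm, qlogis(y))
  start <- c(start_beta, 0)  # sigma = 0.5
  fit <- optim(start, beta_loglik, y = y, X = Xm, method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12),
               hessian = TRUE)
  est <- fit$par
  vc <- tryCatch(solve(-fit$hessian), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  se <- sqrt(pmax(diag(vc), 0))[seq_len(k)]
  z <- est[seq_len(k)] / se
  coefs <- data.frame(term = colnames(Xm), estimate = est[seq_len(k)],
                      se = se, z = z,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE, row.names = NULL)
  ll <- fit$value
  npar <- k + 1L
  structure(list(coefficients = coefs,
                 sigma = plogis(est[k + 1L]),
                 phi = (1 - plogis(est[k + 1L])^2) / plogis(est[k + 1L])^2,
                 loglik = ll, aic = -2 * ll + 2 * npar, n = length(y),
                 terms = setdiff(colnames(Xm), "(Intercept)"),
                 converged = fit$convergence == 0, vcov = vc),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("beta regression: n = %d, logLik = %.3f, AIC = %.3f, sigma = %.3f\n",
              x$n, x$loglik, x$aic, x$sigma))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Stepwise AIC selection for the beta regression
#'
#' Greedy both-direction search: at each step every single-term addition
#' (from `scope`) and deletion is scored by AIC and the best improvement is
#' accepted; the search terminates when no move lowers the AIC. The
#' accepted trace is logged.
#'
#' @param env data.frame holding the covariates.
#' @param y response vector in (0,1).
#' @param scope character vector of candidate terms.
#' @param start_terms initial model terms (default: full scope, i.e.
#'   backward-leaning both-direction search).
#' @param squeeze passed to [fit_beta()].
#' @return list: `fit` (the selected `beta_fit`), `trace` (data.frame step,
#'   action, term, aic).
#' @export
stepwise_aic <- function(env, y, scope, start_terms = scope,
                         squeeze = FALSE) {
  env <- as.data.frame(env)
  fit_terms <- function(terms) {
    X <- if (length(terms)) env[, terms, drop = FALSE] else NULL
    fit_beta(y, X, squeeze = squeeze)
  }
  current <- start_terms
  fit <- tryCatch(fit_terms(current), error = function(e) NULL)
  if (is.null(fit)) {
    # full start infeasible (e.g. more terms than observations):
    # fall back to a forward search from the intercept-only model
    current <- character(0)
    fit <- fit_terms(current)
  }
  trace <- data.frame(step = 0L, action = "start",
                      term = paste(current, collapse = "+"),
                      aic = fit$aic, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- list()
    for (tm in setdiff(scope, current))
      moves[[paste0("+", tm)]] <- c(current, tm)
    for (tm in current)
      moves[[paste0("-", tm)]] <- setdiff(current, tm)
    if (!length(moves)) break
    aics <- vapply(moves, function(tms)
      tryCatch(fit_terms(tms)$aic, error = function(e) Inf), numeric(1))
    if (min(aics) >= fit$aic - 1e-8) break
    best <- names(aics)[which.min(aics)]
    current <- moves[[best]]
    fit <- fit_terms(current)
    trace <- rbind(trace, data.frame(step = step,
                                     action = substr(best, 1, 1),
                                     term = substring(best, 2),
                                     aic = fit$aic))
  }
  list(fit = fit, trace = trace)
}

#' Variance inflation factors and the VIF exclusion loop
#'
#' `VIF_j = 1/(1 - R^2_j)` from the ordinary least-squares regression of
#' covariate j on the remaining covariates. `vif_loop` repeatedly drops the
#' covariate with the largest VIF until all values are at most `vif_max`.
#'
#' @param X data.frame or matrix of covariates.
#' @return `vif` returns a named vector; `vif_loop` a list with `retained`
#'   (column names) and `dropped`.
#' @export
vif <- function(X) {
  X <- as.matrix(as.data.frame(X))
  p <- ncol(X)
  if (p < 2) return(setNames(rep(1, p), colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    fitj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fitj$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' @rdname vif
#' @param vif_max threshold (default 3).
#' @export
vif_loop <- function(X, vif_max = 3) {
  X <- as.data.frame(X)
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2) break
    v <- vif(X)
    if (max(v) <= vif_max) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
  list(retained = names(X), dropped = dropped)
}

#' Cox-Snell generalized R-squared
#'
#' `1 - (L0/L1)^(2/n)` from the log-likelihoods of the fitted and the
#' null (intercept-only) model; n is the number of observations entering
#' the model.
#'
#' @param model,null_model `beta_fit` objects (or any objects with
#'   `loglik` and `n`).
#' @return generalized R^2 in [0, 1).
#' @export
generalized_r2 <- function(model, null_model) {
  if (model$n != null_model$n) stop("models fit to different n")
  1 - exp(-2 / model$n * (model$loglik - null_model$loglik))
}

#' Full environment-model workflow
#'
#' Correlation pre-filter, standardization, VIF loop on the full design,
#' stepwise AIC selection, and the generalized R^2 against the
#' intercept-only model.
#'
#' @param env data.frame with `pop_id`, covariates and the response.
#' @param response response column name (default `introgression_index`).
#' @param covariates candidate covariate names (default: all numeric
#'   columns except the response).
#' @param r_max,vif_max thresholds of the pre-filter and VIF loop.
#' @param primary,preferences passed to [correlation_filter()].
#' @param squeeze passed to [fit_beta()].
#' @return list: `fit`, `null_fit`, `r2`, `retained_after_cor`,
#'   `retained_after_vif`, `trace`.
#' @export
env_model_workflow <- function(env, response = "introgression_index",
                               covariates = NULL, r_max = 0.7, vif_max = 3,
                               primary = NULL, preferences = NULL,
                               squeeze = FALSE) {
  env <- as.data.frame(env)
  if (!response %in% names(env)) stop("response column not found")
  covariates <- covariates %||%
    setdiff(names(env)[vapply(env, is.numeric, logical(1))], response)
  env <- env[stats::complete.cases(env[c(response, covariates)]), ]
  y <- env[[response]]
  keep1 <- correlation_filter(env[covariates], r_max, primary, preferences)
  env <- standardize_covariates(env, keep1)
  keep2 <- vif_loop(env[keep1], vif_max)$retained
  sel <- stepwise_aic(env, y, scope = keep2, squeeze = squeeze)
  null_fit <- fit_beta(y, NULL, squeeze = squeeze)
  list(fit = sel$fit, null_fit = null_fit,
       r2 = generalized_r2(sel$fit, null_fit),
       retained_after_cor = keep1, retained_after_vif = keep2,
       trace = sel$trace)
}
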