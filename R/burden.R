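#' Specify a burden regression
#'
#' Assembles outcome, exposure and covariates into a listwise-complete,
#' full-rank design for the logistic engines. Factor covariates are one-hot
#' encoded with the first level dropped; collinear columns are dropped with a
#' message. The exposure always enters as the first non-intercept column.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param exposure binary or real vector.
#' @param covariates data.frame of covariates, or NULL.
#' @param engine "ml" or "firth".
#' @param bonferroni_m number of comparisons for Bonferroni adjustment.
#' @return list of class \code{regression_spec} with the design matrix
#'   \code{X} (including intercept), outcome \code{y}, and bookkeeping.
#' @export
regression_spec <- function(outcome, exposure, covariates = NULL,
                            engine = c("ml", "firth"), bonferroni_m = 1) {
  engine <- match.arg(engine)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1) | is.na(y))) stop("outcome must be binary")
  x <- as.numeric(exposure)
  df <- data.frame(.exposure = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df) & !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("regression_spec: %d row(s) dropped by listwise deletion",
                    n_dropped))
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("outcome has a single class after deletion")
  # drop constant columns before model.matrix so contrasts don't fail
  const <- vapply(df, function(v) length(unique(v)) < 2, logical(1))
  if (const[1]) stop("exposure is constant (rank-deficient exposure)")
  if (any(const)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(names(df)[const], collapse = ", ")))
    df <- df[, !const, drop = FALSE]
  }
  X <- stats::model.matrix(~ ., data = df)
  # drop remaining collinear columns (never the intercept or exposure)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- q$pivot[seq(q$rank + 1L, ncol(X))]
    if (any(drop_cols <= 2))
      stop("exposure is collinear with covariates")
    warning(sprintf("dropping collinear column(s): %s",
                    paste(colnames(X)[drop_cols], collapse = ", ")))
    X <- X[, -drop_cols, drop = FALSE]
  }
  structure(list(X = X, y = y, engine = engine,
                 bonferroni_m = bonferroni_m, n_dropped = n_dropped),
            class = "regression_spec")
}

.burden_result <- function(beta, se, spec, engine, converged = TRUE,
                           low_information = FALSE) {
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  exposed <- spec$X[, 2] != 0
  data.frame(beta = beta, se = se, or_ = exp(beta),
             ci_lo = exp(ci[1]), ci_hi = exp(ci[2]),
             p_raw = p, p_adjusted = min(1, spec$bonferroni_m * p),
             n = length(spec$y),
             n_cases_exposed = sum(spec$y == 1 & exposed),
             n_controls_exposed = sum(spec$y == 0 & exposed),
             engine = engine, converged = converged,
             low_information = low_information,
             stringsAsFactors = FALSE)
}

#' Maximum-likelihood logistic burden fit
#'
#' IRLS (Fisher scoring) fit via \code{stats::glm}, reporting the Wald
#' estimate, 95\% CI and p-value for the exposure coefficient. Detected
#' separation (exposure |beta| > 15) or non-convergence is an error that
#' advises the Firth engine.
#'
#' @param spec a \code{\link{regression_spec}} with \code{engine = "ml"}.
#' @param max_abs_beta separation threshold on the exposure coefficient.
#' @return one-row data.frame (beta, or_, ci, p_raw, p_adjusted, counts).
#' @export
fit_logistic_ml <- function(spec, max_abs_beta = 15) {
  stopifnot(inherits(spec, "regression_spec"))
  fit <- suppressWarnings(
    stats::glm.fit(spec$X, spec$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  beta_hat <- fit$coefficients
  if (!fit$converged || anyNA(beta_hat) ||
      abs(beta_hat[2]) > max_abs_beta)
    stop("ML logistic fit did not converge or shows separation; use engine = 'firth'")
  # Wald covariance from the final weighted design
  w <- fit$weights
  V <- solve(crossprod(spec$X * sqrt(w)))
  .burden_result(unname(beta_hat[2]), sqrt(V[2, 2]), spec, "ml")
}

# Firth-penalized logistic fit on a design matrix.
# Maximizes l(beta) + 0.5 log det I(beta) by Newton steps on the modified
# score U*(beta) = X'(y - p + h (1/2 - p)), with step-halving on the
# penalized likelihood. Returns finite estimates under complete separation.
.firth_fit <- function(X, y, maxit = 50, tol = 1e-8) {
  k <- ncol(X)
  beta <- rep(0, k)
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    I <- crossprod(X * (p * (1 - p)), X)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  Iinv <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    I <- crossprod(X * w, X)
    Iinv <- solve(I)
    h <- w * rowSums((X %*% Iinv) * X)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(Iinv %*% U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (ll_new >= ll_old - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    beta <- beta + step * delta
    moved <- max(abs(step * delta))
    if (moved < tol || abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # covariance at the final iterate
  p <- stats::plogis(drop(X %*% beta))
  Iinv <- solve(crossprod(X * (p * (1 - p)), X))
  list(beta = beta, vcov = Iinv, converged = converged, pen_loglik = ll_old)
}

#' Firth bias-corrected logistic burden fit
#'
#' Maximizes the Jeffreys-prior-penalized log-likelihood
#' \eqn{\ell(\beta) + \frac12 \log \det I(\beta)} by modified-score Newton
#' iterations with step-halving, giving finite estimates even under complete
#' separation. Wald CI and p-value on the penalized estimate of the exposure
#' coefficient.
#'
#' @param spec a \code{\link{regression_spec}} with \code{engine = "firth"}.
#' @param maxit,tol Newton iteration controls.
#' @return one-row data.frame as \code{\link{fit_logistic_ml}}.
#' @export
fit_logistic_firth <- function(spec, maxit = 50, tol = 1e-8) {
  stopifnot(inherits(spec, "regression_spec"))
  fit <- .firth_fit(spec$X, spec$y, maxit = maxit, tol = tol)
  if (!fit$converged)
    stop(sprintf(
      "Firth fit did not converge in %d iterations (last exposure beta %.4f)",
      maxit, fit$beta[2]))
  .burden_result(fit$beta[2], sqrt(fit$vcov[2, 2]), spec, "firth")
}

#' Fit a burden regression with the requested engine
#'
#' Dispatches on \code{spec$engine}; with \code{firth_fallback} the ML engine
#' falls back to Firth (with a warning) when it errors on separation.
#'
#' @param spec a \code{\link{regression_spec}}.
#' @param firth_fallback fall back to Firth when ML detects separation.
#' @return one-row burden-result data.frame.
#' @export
fit_burden <- function(spec, firth_fallback = TRUE) {
  if (spec$engine == "firth") return(fit_logistic_firth(spec))
  tryCatch(fit_logistic_ml(spec), error = function(e) {
    if (!firth_fallback) stop(e)
    warning("ML engine failed (", conditionMessage(e),
            "); falling back to Firth", call. = FALSE)
    fit_logistic_firth(spec)
  })
}

#' Carrier burden across diagnostic subsets within cases
#'
#' For each subset flag, fits subset-membership on carrier status among cases
#' with sex, principal components and sequencing batch as covariates, and
#' applies Bonferroni correction for \code{m} comparisons. Subsets with fewer
#' than two exposed individuals are flagged low-information but still
#' reported.
#'
#' @param cases cohort data.frame restricted to cases (or with a
#'   \code{case_status} column, in which case controls are dropped).
#' @param subset_flags named list (or data.frame) of logical vectors over
#'   cases: the outcomes compared.
#' @param carrier logical vector: exposure (carrier status) per case.
#' @param covariates data.frame of adjustment covariates per case.
#' @param m Bonferroni comparison count (fourteen diagnostic phenotype
#'   comparisons by default).
#' @param engine regression engine; ML falls back to Firth on separation.
#' @return data.frame with one row per subset.
#' @export
subset_burden <- function(cases, subset_flags, carrier, covariates,
                          m = 14, engine = "ml") {
  if ("case_status" %in% names(cases)) {
    keep <- cases$case_status == "case"
    cases <- cases[keep, , drop = FALSE]
    carrier <- carrier[keep]
    covariates <- covariates[keep, , drop = FALSE]
    subset_flags <- lapply(subset_flags, function(f) f[keep])
  }
  out <- list()
  for (nm in names(subset_flags)) {
    flag <- subset_flags[[nm]]
    res <- tryCatch({
      spec <- regression_spec(flag, carrier, covariates,
                              engine = engine, bonferroni_m = m)
      fit_burden(spec)
    }, error = function(e) {
      warning(sprintf("subset '%s' failed: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    res$subset <- nm
    res$low_information <- res$n_cases_exposed + res$n_controls_exposed < 2 ||
      res$n_cases_exposed < 2
    out[[nm]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("subset", setdiff(names(res), "subset"))]
}

#' Severity-adjusted burden
#'
#' As \code{\link{subset_burden}} but with level of intellectual disability
#' added as a covariate, encoded binary: mild (0) vs
#' moderate/severe/profound (1). Individuals with unspecified severity are
#' excluded by default or kept as their own indicator level.
#'
#' @param cases cases cohort rows with a \code{severity} column.
#' @param subset_flags,carrier,covariates,m,engine as
#'   \code{\link{subset_burden}}.
#' @param unspecified "exclude" or "own_level".
#' @return data.frame as \code{\link{subset_burden}}.
#' @export
severity_adjusted_burden <- function(cases, subset_flags, carrier, covariates,
                                     m = 14, engine = "ml",
                                     unspecified = c("exclude", "own_level")) {
  unspecified <- match.arg(unspecified)
  sev <- as.character(cases$severity)
  if (unspecified == "exclude") {
    keep <- sev %in% c("mild", "moderate_severe_profound")
    cases <- cases[keep, , drop = FALSE]
    carrier <- carrier[keep]
    covariates <- covariates[keep, , drop = FALSE]
    subset_flags <- lapply(subset_flags, function(f) f[keep])
    sev <- sev[keep]
    covariates$severity_severe <- as.integer(sev == "moderate_severe_profound")
  } else {
    covariates$severity_severe <- as.integer(sev == "moderate_severe_profound")
    covariates$severity_unspecified <- as.integer(sev == "unspecified")
  }
  subset_burden(cases, subset_flags, carrier, covariates, m = m,
                engine = engine)
}
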