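#' Test the rare-by-common interaction
#'
#' Logistic regression of case status on rare-variant carrier status, the
#' normalized polygenic score, and their interaction, adjusted for the
#' supplied covariates. Fit with the maximum-likelihood engine; if
#' separation is detected the Firth engine takes over with a warning. All
#' three exposure coefficients are reported with raw and
#' Bonferroni-adjusted p-values (default m = 11, the number of polygenic
#' score and rare-variant interaction models considered).
#'
#' @param outcome binary case indicator.
#' @param carrier logical/0-1 rare-variant carrier status.
#' @param pgs normalized polygenic score.
#' @param covariates data.frame of covariates.
#' @param m Bonferroni comparison count.
#' @return data.frame with rows carrier, pgs, carrier:pgs (estimate, se, z,
#'   p_raw, p_adjusted, engine).
#' @export
interaction_test <- function(outcome, carrier, pgs, covariates = NULL, m = 11) {
  df <- data.frame(.y = as.numeric(outcome), .carrier = as.numeric(carrier),
                   .pgs = as.numeric(pgs))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  X <- stats::model.matrix(~ .carrier * .pgs + ., data = df[, -1, drop = FALSE])
  y <- df$.y
  engine <- "ml"
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  terms <- c(".carrier", ".pgs", ".carrier:.pgs")
  if (!fit$converged || anyNA(fit$coefficients) ||
      any(abs(fit$coefficients[terms]) > 15, na.rm = TRUE)) {
    warning("ML interaction fit unstable; using Firth engine", call. = FALSE)
    engine <- "firth"
    ff <- .firth_fit(X, y)
    beta <- ff$beta; names(beta) <- colnames(X)
    V <- ff$vcov
  } else {
    beta <- fit$coefficients
    w <- fit$weights
    V <- solve(crossprod(X * sqrt(w)))
  }
  idx <- match(terms, colnames(X))
  se <- sqrt(diag(V))[idx]
  est <- beta[idx]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = c("carrier", "pgs", "carrier:pgs"),
             estimate = unname(est), se = unname(se), z = unname(z),
             p_raw = unname(p), p_adjusted = pmin(1, m * unname(p)),
             engine = engine, stringsAsFactors = FALSE)
}

.ic_row <- function(name, loglik, k, n) {
  aic <- 2 * k - 2 * loglik
  data.frame(model = name, k = k, loglik = loglik, aic = aic,
             aicc = aic + 2 * k * (k + 1) / (n - k - 1),
             bic = k * log(n) - 2 * loglik, stringsAsFactors = FALSE)
}

#' Multimodel inference over the four nested case-status models
#'
#' Fits logistic regressions of case status on (1) covariates only, (2)
#' covariates + polygenic score, (3) covariates + rare-variant carrier
#' status, (4) covariates + both, all on the same listwise-complete
#' individuals, and compares them by AIC, AICc and BIC with deltas relative
#' to each criterion's minimum. The parameter count k includes the intercept
#' and every covariate coefficient.
#'
#' @param outcome binary case indicator.
#' @param carrier rare-variant carrier status.
#' @param pgs normalized polygenic score.
#' @param covariates data.frame of covariates.
#' @return data.frame with one row per model: k, loglik, aic, aicc, bic,
#'   delta_aic, delta_aicc, delta_bic, and \code{best_*} flags; attribute
#'   \code{ranking} names the winner per criterion.
#' @export
multimodel_inference <- function(outcome, carrier, pgs, covariates = NULL) {
  df <- data.frame(.y = as.numeric(outcome), .carrier = as.numeric(carrier),
                   .pgs = as.numeric(pgs))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  base <- stats::model.matrix(
    ~ ., data = df[, setdiff(names(df), c(".y", ".carrier", ".pgs")),
                   drop = FALSE])
  designs <- list(
    covariates_only = base,
    pgs_only = cbind(base, pgs = df$.pgs),
    rare_only = cbind(base, carrier = df$.carrier),
    rare_plus_pgs = cbind(base, pgs = df$.pgs, carrier = df$.carrier))
  rows <- lapply(names(designs), function(nm) {
    X <- designs[[nm]]
    fit <- suppressWarnings(
      stats::glm.fit(X, df$.y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100)))
    if (!fit$converged || anyNA(fit$coefficients))
      stop(sprintf("model '%s' did not converge; comparison aborted", nm))
    ll <- -fit$deviance / 2
    .ic_row(nm, ll, ncol(X), n)
  })
  out <- do.call(rbind, rows)
  for (crit in c("aic", "aicc", "bic"))
    out[[paste0("delta_", crit)]] <- out[[crit]] - min(out[[crit]])
  ranking <- vapply(c("aic", "aicc", "bic"),
                    function(crit) out$model[which.min(out[[crit]])],
                    character(1))
  attr(out, "ranking") <- ranking
  out
}

#' Choose the polygenic score to report from candidate traits
#'
#' For each candidate trait, fits the covariates + carrier + score model and
#' ranks traits by information criterion; the best (lowest-criterion) trait
#' is returned per criterion, with ties broken by trait-name order (logged).
#'
#' @param outcome binary case indicator.
#' @param carrier rare-variant carrier status.
#' @param scores named list (or data.frame) of normalized candidate scores.
#' @param covariates data.frame of covariates.
#' @return list with \code{table} (per-trait aic/bic) and \code{best}
#'   (named character: trait chosen by aic and by bic).
#' @export
select_reporting_score <- function(outcome, carrier, scores,
                                   covariates = NULL) {
  traits <- names(scores)
  if (is.null(traits) || !length(traits)) stop("need at least one named trait")
  traits <- sort(traits)
  rows <- lapply(traits, function(tr) {
    mm <- multimodel_inference(outcome, carrier, scores[[tr]], covariates)
    full <- mm[mm$model == "rare_plus_pgs", ]
    data.frame(trait = tr, k = full$k, loglik = full$loglik,
               aic = full$aic, bic = full$bic, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- vapply(c("aic", "bic"), function(crit) {
    v <- tab[[crit]]
    winners <- tab$trait[v == min(v)]
    if (length(winners) > 1)
      message(sprintf("tie on %s between %s; keeping '%s' (name order)",
                      crit, paste(winners, collapse = ", "), winners[1]))
    winners[1]
  }, character(1))
  list(table = tab, best = best)
}
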