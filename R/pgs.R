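#' Normalize polygenic scores against controls
#'
#' Control-referenced z-scoring: subtract the control mean and divide by the
#' control standard deviation (n - 1 denominator). With
#' \code{center_only = TRUE} only the control mean is subtracted; both forms
#' are affine and order-preserving, and controls re-normalize to themselves.
#'
#' @param raw numeric vector of raw scores.
#' @param is_control logical vector marking control individuals.
#' @param center_only subtract the control mean without scaling.
#' @return numeric vector of normalized scores.
#' @export
normalize_scores <- function(raw, is_control, center_only = FALSE) {
  stopifnot(length(raw) == length(is_control))
  ctrl <- raw[is_control & is.finite(raw)]
  if (length(ctrl) < 2) stop("need at least 2 controls with finite scores")
  s <- stats::sd(ctrl)
  if (center_only) return(raw - mean(ctrl))
  if (s == 0) stop("control scores have zero variance")
  (raw - mean(ctrl)) / s
}

# marginal means from a linear model: prediction at the column means of the
# model matrix (continuous covariates at their grand mean, factor levels at
# their observed proportions), with the group variable toggled to each level.
.marginal_means <- function(fit, mm, group, level = stats::qnorm(0.975)) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  groups <- sort(unique(group))
  x0 <- colMeans(mm)
  gcols <- grep("^\\.group", colnames(mm), value = TRUE)
  rows <- lapply(groups, function(g) {
    x <- x0
    for (cn in gcols) x[cn] <- as.numeric(cn == paste0(".group", g))
    est <- sum(x * b)
    se <- sqrt(drop(t(x) %*% V %*% x))
    data.frame(group = g, emm = est, se = se,
               ci_lo = est - level * se, ci_hi = est + level * se,
               n = sum(group == g), stringsAsFactors = FALSE)
  })
  means <- do.call(rbind, rows)
  # pairwise contrast of the first level vs the second (e.g. case - control)
  x1 <- x0; x2 <- x0
  for (cn in gcols) {
    x1[cn] <- as.numeric(cn == paste0(".group", groups[1]))
    x2[cn] <- as.numeric(cn == paste0(".group", groups[2]))
  }
  d <- x1 - x2
  est <- sum(d * b)
  se <- sqrt(drop(t(d) %*% V %*% d))
  contrast <- data.frame(
    contrast = paste(groups[1], "-", groups[2]),
    estimate = est, se = se,
    ci_lo = est - level * se, ci_hi = est + level * se,
    p = 2 * stats::pnorm(-abs(est / se)), stringsAsFactors = FALSE)
  list(means = means, contrast = contrast)
}

#' Covariate-adjusted polygenic-score contrast between cases and controls
#'
#' Fits a linear model of the normalized score on group status, sex and
#' principal components, and reports the marginal mean and 95\% confidence
#' interval per group (prediction at covariate means, normal quantiles) plus
#' the adjusted group contrast.
#'
#' @param score normalized score vector.
#' @param group group labels (e.g. case/control), 2 or more levels.
#' @param covariates data.frame of covariates (may be NULL: marginal means
#'   then equal group means).
#' @return list with \code{means} (per-group marginal means and CI),
#'   \code{contrast} (last level minus first), and \code{low_information}
#'   flag (a group with fewer than 2 members).
#' @export
case_control_contrast <- function(score, group, covariates = NULL) {
  group <- as.character(group)
  keep <- is.finite(score) & !is.na(group)
  df <- data.frame(.score = score, .group = factor(group))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  keep <- keep & stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$.group)) < 2)
    stop("need at least two group levels")
  fit <- stats::lm(.score ~ ., data = df)
  mm <- stats::model.matrix(fit)
  res <- .marginal_means(fit, mm, as.character(df$.group))
  res$low_information <- min(table(df$.group)) < 2
  res
}

#' Polygenic-score contrast between case subsets
#'
#' As \code{\link{case_control_contrast}} restricted to cases: contrasts a
#' binary subset flag (e.g. mild vs moderate/severe/profound) on the
#' normalized score with covariate adjustment. One-individual subsets are
#' reported with their (wide) CI and flagged low-information.
#'
#' @param score normalized score vector over cases.
#' @param subset_flag logical vector over cases.
#' @param covariates covariate data.frame over cases.
#' @param labels length-2 labels for FALSE/TRUE subset levels.
#' @return as \code{\link{case_control_contrast}}.
#' @export
subset_contrast <- function(score, subset_flag, covariates = NULL,
                            labels = c("outside", "inside")) {
  if (!any(subset_flag) || all(subset_flag))
    stop("both subset levels must be present")
  case_control_contrast(score, ifelse(subset_flag, labels[2], labels[1]),
                        covariates)
}
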