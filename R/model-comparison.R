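#' Build the design matrix for grouped reciprocity models
#'
#' Columns: intercept, a dataset dummy (card = 1, case investigation = 0),
#' polynomial terms in trial day of the requested degree, and optionally
#' dataset-by-day interactions. The day terms use either the raw powers
#' (`day`, `day^2`) or orthonormal polynomial contrasts built over the
#' observed rows (`stats::poly`); both span the same column space, so
#' deviances, likelihood-ratio statistics and the dataset coefficient are
#' identical between bases.
#'
#' @param observations Tibble with columns `dataset` (`"card"` or
#'   `"case_investigation"`), `day`, `successes`, `trials`.
#' @param degree Day-polynomial degree, 1 or 2.
#' @param interaction Include dataset-by-day-polynomial interactions
#'   (requires `degree = 2`).
#' @param basis `"orthonormal"` (default) or `"raw"`.
#' @return A numeric design matrix with one row per observation.
#' @export
build_model_matrix <- function(observations, degree = 2, interaction = FALSE,
                               basis = c("orthonormal", "raw")) {
  basis <- match.arg(basis)
  stopifnot(degree %in% 1:2)
  if (interaction && degree != 2) {
    stop("Interaction models require the quadratic day polynomial.", call. = FALSE)
  }
  day <- observations$day
  if (length(unique(day)) <= degree) {
    stop("Too few distinct days for the requested polynomial degree.", call. = FALSE)
  }
  dataset <- as.integer(observations$dataset == "card")
  day_terms <- if (basis == "raw") {
    m <- cbind(day = day, `day^2` = day^2)
    m[, seq_len(degree), drop = FALSE]
  } else {
    m <- stats::poly(day, degree)
    colnames(m) <- paste0("day_poly", seq_len(degree))
    m
  }
  X <- cbind(`(Intercept)` = 1, dataset = dataset, day_terms)
  if (interaction) {
    inter <- day_terms * dataset
    colnames(inter) <- paste0("dataset:", colnames(day_terms))
    X <- cbind(X, inter)
  }
  if (qr(X)$rank < ncol(X)) stop("Design matrix is rank deficient.", call. = FALSE)
  X
}

#' Fit a grouped binomial logistic regression
#'
#' Maximum-likelihood logistic fit of reciprocated/total counts on the
#' supplied design, via iteratively reweighted least squares, with the
#' binomial deviance measured against the saturated (one probability per
#' row) model.
#'
#' @param design Design matrix from [build_model_matrix()].
#' @param observations The matching observations tibble.
#' @return An object of class `grouped_logit_fit`: coefficients, standard
#'   errors, deviance, residual df, log-likelihood, fitted probabilities,
#'   and the design column names.
#' @export
fit_grouped_logistic <- function(design, observations) {
  y <- observations$successes / observations$trials
  fit <- stats::glm.fit(x = design, y = y, weights = observations$trials,
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in 100 iterations (possible separation).",
         call. = FALSE)
  }
  p <- fit$fitted.values
  if (any(p <= 0 | p >= 1)) {
    stop("Fitted probabilities on the boundary: separation suspected.", call. = FALSE)
  }
  # observed information on the IRLS weights
  w <- observations$trials * p * (1 - p)
  vcov <- solve(crossprod(design * sqrt(w)))
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(design)),
    se = stats::setNames(sqrt(diag(vcov)), colnames(design)),
    vcov = vcov,
    deviance = fit$deviance,
    df_residual = nrow(design) - ncol(design),
    log_likelihood = sum(dbinom(observations$successes, observations$trials,
                                p, log = TRUE)),
    fitted = p,
    n_obs = nrow(design),
    basis = colnames(design)
  ), class = "grouped_logit_fit")
}

#' @export
print.grouped_logit_fit <- function(x, ...) {
  cat("<grouped_logit_fit>\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               z = x$coefficients / x$se)
  print(round(tab, 4))
  cat(sprintf("Residual deviance %.3f on %d df; logLik %.3f\n",
              x$deviance, x$df_residual, x$log_likelihood))
  invisible(x)
}

#' Fit one of the three nested reciprocity-trend models
#'
#' Model 1: dataset + day; Model 2: dataset + day + day^2; Model 3: adds
#' dataset-by-day and dataset-by-day^2 interactions.
#'
#' @param observations Grouped observations tibble (see
#'   [build_model_matrix()]).
#' @param model 1, 2 or 3.
#' @inheritParams build_model_matrix
#' @return A `grouped_logit_fit`.
#' @export
fit_reciprocity_model <- function(observations, model = 2,
                                  basis = c("orthonormal", "raw")) {
  stopifnot(model %in% 1:3)
  design <- build_model_matrix(observations,
                               degree = if (model == 1) 1 else 2,
                               interaction = model == 3,
                               basis = match.arg(basis))
  fit_grouped_logistic(design, observations)
}

#' Likelihood-ratio test of two nested fits
#'
#' `G^2 = deviance(small) - deviance(large)`, chi-square with df equal to
#' the parameter difference under the smaller model.
#'
#' @param model_small,model_large `grouped_logit_fit` objects fitted on the
#'   same observations, with `model_small` nested in `model_large`.
#' @return A named list: `G2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(model_small, model_large) {
  stopifnot(inherits(model_small, "grouped_logit_fit"),
            inherits(model_large, "grouped_logit_fit"))
  if (model_small$n_obs != model_large$n_obs) {
    stop("Models were fitted on different observation sets.", call. = FALSE)
  }
  df <- model_small$df_residual - model_large$df_residual
  if (df < 0) stop("Models are not nested (small model has no fewer parameters).",
                   call. = FALSE)
  G2 <- model_small$deviance - model_large$deviance
  if (G2 < -1e-8) stop("Larger model fits worse: models are not nested.",
                       call. = FALSE)
  G2 <- max(G2, 0)
  p <- if (df == 0) {
    if (G2 > 1e-6) stop("Equal parameter counts but different deviances: not nested.",
                        call. = FALSE)
    1
  } else {
    pchisq(G2, df, lower.tail = FALSE)
  }
  list(G2 = G2, df = df, p_value = p)
}

#' Dataset odds ratio with Wald inference
#'
#' Exponentiates the dataset (card vs case-investigation) coefficient: the
#' multiplicative change in the odds that a contact event is reciprocated
#' when detected by cards rather than reported in interviews. Invariant to
#' the day-polynomial basis.
#'
#' @param fit A `grouped_logit_fit` whose design includes the `dataset`
#'   dummy.
#' @param conf_level Confidence level (default 0.95).
#' @return A named list: `or`, `ci` (length 2), `z`, `p_value`.
#' @export
dataset_odds_ratio <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "grouped_logit_fit"))
  if (!"dataset" %in% names(fit$coefficients)) {
    stop("The fit does not include the dataset dummy.", call. = FALSE)
  }
  b <- fit$coefficients[["dataset"]]
  se <- fit$se[["dataset"]]
  z_crit <- qnorm(1 - (1 - conf_level) / 2)
  z <- b / se
  list(or = exp(b), ci = exp(b + c(-1, 1) * z_crit * se),
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
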