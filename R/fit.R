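#' Term sets for seasonal suitability models
#'
#' A term set is a named character vector over covariates with values
#' `"linear"` (linear term only) or `"quadratic"` (linear plus quadratic;
#' the quadratic term is never present without its linear term).
#'
#' @param variables character vector of covariate names.
#' @return Named character vector with every variable set to `"quadratic"`.
#' @export
full_quadratic_terms <- function(variables) {
  setNames(rep("quadratic", length(variables)), variables)
}

terms_formula <- function(terms, mixed) {
  rhs <- "1"
  for (v in names(terms)) {
    rhs <- paste(rhs, "+", v)
    if (terms[[v]] == "quadratic") rhs <- paste0(rhs, " + I(", v, "^2)")
  }
  if (mixed) rhs <- paste(rhs, "+ (1 | year)")
  as.formula(paste("label ~", rhs))
}

#' Fit a per-season binomial suitability model
#'
#' Fits a logit-link binomial model of presence/pseudo-absence labels on the
#' linear and (optionally) quadratic terms of each covariate, with a year
#' random intercept estimated by Laplace-approximated maximum likelihood.
#' Covariates are z-standardized internally; coefficients are reported both
#' on the standardized scale (used for prediction) and back-transformed to
#' the data scale.  When the year variance is estimated at the zero
#' boundary, when the data hold a single year, or when the mixed fit fails,
#' the model falls back to a plain logistic regression (identical likelihood
#' at the boundary) and the `fallback` flag is set.
#'
#' @param data model dataset: data.frame with `label` (0/1), `year` and
#'   covariate columns (see [make_model_dataset()]).
#' @param terms term set (see [full_quadratic_terms()]); may be empty for an
#'   intercept-only model.
#' @param use_mixed `"auto"` (mixed with boundary fallback), `"always"`
#'   (keep the mixed fit even when singular) or `"never"` (plain logistic).
#' @return A `fitted_sdm` object with elements `terms` (constant covariates
#'   are removed up front and listed in `dropped_constant`), `coef_std`,
#'   `coef_data`, `ranef_var`, `loglik`, `aic`, `converged`, `fallback`,
#'   `engine`, `scaling` and training `ranges`.
#' @export
fit_sdm <- function(data, terms = full_quadratic_terms(covariate_names(data)),
                    use_mixed = c("auto", "always", "never")) {
  use_mixed <- match.arg(use_mixed)
  stop_if_missing_cols(data, c("label", names(terms)), "model dataset")
  if (length(unique(data$label)) < 2)
    stop("model dataset needs both labels present")
  vars <- names(terms)
  if (length(vars) && anyNA(data[, vars]))
    stop("missing covariate values in model dataset")
  ## constant covariates (e.g. a crop layer that is zero all season) carry
  ## no information and make the design rank-deficient: drop them up front
  const <- vapply(vars, function(v) sd(data[[v]]) == 0, logical(1))
  dropped_constant <- vars[const]
  terms <- terms[!const]
  vars <- names(terms)
  ctr <- vapply(vars, function(v) mean(data[[v]]), numeric(1))
  scl <- vapply(vars, function(v) sd(data[[v]]), numeric(1))
  rng <- lapply(vars, function(v) range(data[[v]]))
  names(rng) <- vars
  mf <- data.frame(label = data$label)
  for (v in vars) mf[[v]] <- (data[[v]] - ctr[[v]]) / scl[[v]]
  n_years <- if (!is.null(data$year)) length(unique(data$year)) else 1L
  if (n_years >= 2) mf$year <- factor(data$year)

  want_mixed <- use_mixed != "never" && n_years >= 2
  fit <- NULL; engine <- "glm"; converged <- TRUE; fallback <- FALSE
  ranef_var <- NA_real_
  if (want_mixed) {
    ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                               check.conv.singular = "ignore")
    fit <- tryCatch(
      withCallingHandlers(
        lme4::glmer(terms_formula(terms, TRUE), data = mf,
                    family = binomial(), control = ctrl),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit)) {
      engine <- "glmer"
      ranef_var <- unname(unlist(lme4::VarCorr(fit)))
      if (use_mixed == "auto" && ranef_var < 1e-8) fit <- NULL  # boundary
    }
    if (is.null(fit)) fallback <- TRUE
  } else if (use_mixed != "never") {
    fallback <- TRUE   # single year level: mixed model not identifiable
  }
  if (is.null(fit)) {
    engine <- "glm"; converged <- TRUE; ranef_var <- NA_real_
    ## profiled pseudo-absences can separate near-perfectly; the resulting
    ## fitted-probability warning is expected and not a failure
    fit <- withCallingHandlers(
      glm(terms_formula(terms, FALSE), data = mf, family = binomial()),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("did not converge", msg)) converged <<- FALSE
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  msg))
          invokeRestart("muffleWarning")
      })
    converged <- converged && fit$converged
  }
  b <- if (engine == "glmer") lme4::fixef(fit) else coef(fit)
  names(b) <- sub("^I\\((.+)\\^2\\)$", "\\1^2", names(b))
  structure(list(
    terms = terms, coef_std = b,
    coef_data = destandardize_coefs(b, terms, ctr, scl),
    ranef_var = ranef_var,
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    converged = converged, fallback = fallback, engine = engine,
    dropped_constant = dropped_constant,
    scaling = list(center = ctr, scale = scl), ranges = rng,
    n = nrow(mf), years = if (n_years >= 2) sort(unique(data$year)) else
      unique(data$year %||% NA)
  ), class = "fitted_sdm")
}

## map standardized-scale coefficients b0 + b1 z + b2 z^2, z = (x - m)/s,
## to data-scale a0 + a1 x + a2 x^2
destandardize_coefs <- function(b, terms, ctr, scl) {
  a <- c("(Intercept)" = unname(b["(Intercept)"]))
  for (v in names(terms)) {
    m <- ctr[[v]]; s <- scl[[v]]
    b1 <- unname(b[v])
    b2 <- if (terms[[v]] == "quadratic") unname(b[paste0(v, "^2")]) else 0
    a[v] <- b1 / s - 2 * b2 * m / s^2
    if (terms[[v]] == "quadratic") a[paste0(v, "^2")] <- b2 / s^2
    a["(Intercept)"] <- a["(Intercept)"] - b1 * m / s + b2 * m^2 / s^2
  }
  a
}

#' @exportS3Method base::print
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("fitted_sdm (%s%s): AIC %.2f, logLik %.2f, n = %d\n",
              x$engine, if (x$fallback) ", fallback" else "", x$aic,
              x$loglik, x$n))
  if (length(x$terms))
    cat("  terms:", paste(names(x$terms), x$terms, sep = ":",
                          collapse = ", "), "\n")
  else cat("  intercept-only\n")
  if (!is.na(x$ranef_var))
    cat(sprintf("  year random-intercept variance: %.4g\n", x$ranef_var))
  invisible(x)
}

#' Population-level predictions from a fitted seasonal model
#'
#' The year random intercept is set to its mean (zero), so predictions are
#' valid for years unseen in training.
#'
#' @param object a `fitted_sdm`.
#' @param newdata data.frame with the model's covariate columns (data
#'   scale).
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fitted_sdm <- function(object, newdata, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  eta <- rep(unname(object$coef_std["(Intercept)"]), nrow(newdata))
  for (v in names(object$terms)) {
    z <- (newdata[[v]] - object$scaling$center[[v]]) /
      object$scaling$scale[[v]]
    eta <- eta + unname(object$coef_std[v]) * z
    if (object$terms[[v]] == "quadratic")
      eta <- eta + unname(object$coef_std[paste0(v, "^2")]) * z^2
  }
  if (type == "link") eta else plogis(eta)
}

#' Backward AIC term selection
#'
#' Starting from the full term set, repeatedly evaluates every
#' marginality-respecting single-term removal (a quadratic term before its
#' linear term; a linear term only once its quadratic is gone) and applies
#' the removal giving the lowest AIC, stopping when no removal lowers the
#' AIC.  The random-effect flavour (mixed vs boundary fallback) is decided
#' on the full model and held fixed along the path so all AIC comparisons
#' count the same parameters.
#'
#' @inheritParams fit_sdm
#' @param full_terms the starting term set.
#' @param trace logical; print the selection path.
#' @return The selected `fitted_sdm`, with the selection path in attribute
#'   `"path"`.  Its AIC never exceeds the full model's.
#' @export
stepwise_aic <- function(data, full_terms, use_mixed = c("auto", "always",
                                                         "never"),
                         trace = FALSE) {
  use_mixed <- match.arg(use_mixed)
  current <- fit_sdm(data, full_terms, use_mixed)
  flavor <- if (current$engine == "glm") "never" else "always"
  path <- data.frame(step = 0L, action = "<full>", aic = current$aic)
  repeat {
    cands <- list()
    for (v in names(current$terms)) {
      t2 <- current$terms
      if (t2[[v]] == "quadratic") {
        t2[[v]] <- "linear"
        cands[[paste0("- ", v, "^2")]] <- t2
      } else {
        t2 <- t2[names(t2) != v]
        cands[[paste0("- ", v)]] <- t2
      }
    }
    if (!length(cands)) break
    fits <- lapply(cands, function(tt) fit_sdm(data, tt, flavor))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    if (aics[best] >= current$aic - 1e-8) break
    current <- fits[[best]]
    path <- rbind(path, data.frame(step = nrow(path),
                                   action = names(cands)[best],
                                   aic = current$aic))
    if (trace) message(sprintf("%s -> AIC %.3f", names(cands)[best],
                               current$aic))
  }
  if (flavor == "never" && use_mixed != "never") current$fallback <- TRUE
  attr(current, "path") <- path
  current
}
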