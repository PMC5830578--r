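# Probit models of fixation selection: plain GLM, mixed model with crossed
# random intercepts, the incremental model series, bootstrap over control
# redraws, and the squared-correlation R^2.

MODEL_TERMS <- c("centrality", "saliency", "roi", "valence",
                 "saliency:roi", "saliency:valence")

## model term -> column expression in the observation matrix
term_to_col <- function(term) {
  switch(term,
         "centrality" = "centrality_z",
         "saliency" = "saliency_z",
         "roi" = "roi_z",
         "valence" = "valence_z",
         "saliency:roi" = "saliency_z:roi_z",
         "saliency:valence" = "saliency_z:valence_z",
         stop(sprintf("unknown model term '%s'", term)))
}

## The five nested models: centrality -> +saliency -> +ROI ->
## +saliency x ROI -> +saliency x valence (no valence main effect).
INCREMENTAL_MODELS <- list(
  c("centrality"),
  c("centrality", "saliency"),
  c("centrality", "saliency", "roi"),
  c("centrality", "saliency", "roi", "saliency:roi"),
  c("centrality", "saliency", "roi", "saliency:roi", "saliency:valence"))

build_formula <- function(terms, random = NULL) {
  rhs <- paste(vapply(terms, term_to_col, character(1)), collapse = " + ")
  if (length(random))
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", random), collapse = " + "),
                 sep = " + ")
  stats::as.formula(paste("fixated ~", rhs))
}

new_fit_result <- function(coefficients, intercept, converged, fitted,
                           loglik, variances = NULL, dropped = character(0),
                           method = "glm") {
  structure(list(coefficients = coefficients, intercept = intercept,
                 converged = converged, fitted = fitted, loglik = loglik,
                 variances = variances, dropped = dropped, method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s, probit)%s\n", x$method,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  if (length(x$coefficients)) {
    cat("  weights:\n")
    for (nm in names(x$coefficients))
      cat(sprintf("    %-18s %s\n", nm, format(x$coefficients[[nm]], digits = 4)))
  }
  if (!is.null(x$variances)) {
    cat("  random-intercept variances:\n")
    for (nm in names(x$variances))
      cat(sprintf("    %-18s %s\n", nm, format(x$variances[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Probit GLM of fixation selection
#'
#' Maximum-likelihood probit regression of the binary fixated/control response
#' on standardized predictors (no random effects), used for the per-unit
#' consistency fits. Estimation is iteratively reweighted least squares
#' (stats::glm, epsilon 1e-10, at most 100 iterations). Fits showing signs of
#' separation (|beta| > 10 on standardized predictors) or failed IRLS are
#' returned with `converged = FALSE` and the last iterate. Rank-deficient
#' columns are dropped and recorded in `$dropped`.
#'
#' @param rows observation-matrix rows (see [build_observation_matrix()]).
#' @param terms character vector of model terms, a subset of
#'   `c("centrality", "saliency", "roi", "valence", "saliency:roi",
#'   "saliency:valence")`.
#' @param beta_max separation threshold on |beta| (default 10).
#' @return A `fit_result` with elements `coefficients` (named per term),
#'   `intercept`, `converged`, `fitted` (probabilities), `loglik`, `dropped`.
#' @export
fit_probit_glm <- function(rows, terms = c("centrality", "saliency", "roi"),
                           beta_max = 10) {
  if (length(unique(rows$fixated)) < 2L)
    stop("need at least one row per response level")
  fml <- build_formula(terms)
  fit <- suppressWarnings(
    stats::glm(fml, data = rows, family = stats::binomial(link = "probit"),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  cf[is.na(cf)] <- 0
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(abs(cf) <= beta_max)
  beta <- cf[-1]
  names(beta) <- terms  # coefficient order follows the constructed formula
  new_fit_result(beta, unname(cf[1]), converged,
                 as.numeric(stats::fitted(fit)),
                 as.numeric(stats::logLik(fit)), dropped = dropped,
                 method = "glm")
}

#' Probit GLMM with crossed random intercepts
#'
#' Probit mixed model of fixation selection with crossed random intercepts
#' for participant and video, fitted by Laplace-approximated maximum
#' likelihood (lme4::glmer, bobyqa optimizer). `nAGQ = 0` selects the faster
#' penalized-least-squares-only approximation and is flagged in `$method`.
#' Fitted probabilities are population-level (random effects at zero).
#'
#' @inheritParams fit_probit_glm
#' @param random character vector of random-intercept factors (default both
#'   `"participant"` and `"video"`; each needs >= 2 levels).
#' @param nAGQ integer, 1 = Laplace (default), 0 = PIRLS-only approximation.
#' @return A `fit_result`; `$variances` holds the random-intercept variance
#'   per factor (a 0 estimate indicates a boundary fit, `converged` stays
#'   TRUE but the boundary is recorded in `$boundary`).
#' @export
fit_probit_glmm <- function(rows, terms = c("centrality", "saliency", "roi"),
                            random = c("participant", "video"), nAGQ = 1,
                            beta_max = 10) {
  for (r in random) {
    if (length(unique(rows[[r]])) < 2L)
      stop(sprintf("random factor '%s' needs >= 2 levels; use fit_probit_glm()", r))
    rows[[r]] <- factor(rows[[r]])
  }
  fml <- build_formula(terms, random)
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(fml, data = rows, family = stats::binomial(link = "probit"),
                nAGQ = nAGQ,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))))
  cf <- lme4::fixef(fit)
  beta <- cf[-1]
  names(beta) <- terms
  vc <- lme4::VarCorr(fit)
  variances <- vapply(random, function(r) as.numeric(vc[[r]]), numeric(1))
  boundary <- any(variances < 1e-8)
  conv_ok <- length(fit@optinfo$conv$lme4) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  converged <- conv_ok && all(abs(cf) <= beta_max)
  res <- new_fit_result(beta, unname(cf[1]), converged,
                        as.numeric(stats::predict(fit, re.form = NA,
                                                  type = "response")),
                        as.numeric(stats::logLik(fit)),
                        variances = variances,
                        method = if (nAGQ == 0) "glmm-nAGQ0" else "glmm-laplace")
  res$boundary <- boundary
  res
}

#' Incremental series of five nested probit GLMMs
#'
#' Fits, in order: centrality; + saliency; + social ROI; + saliency x ROI;
#' + saliency x valence (no valence main effect), each with crossed random
#' intercepts for participant and video.
#'
#' @inheritParams fit_probit_glmm
#' @param models integer subset of 1:5 (default all five).
#' @return Named list (`model1` ... `model5`) of `fit_result`s, each with an
#'   `r_squared` element (squared correlation between response and
#'   population-level fitted probabilities).
#' @export
incremental_series <- function(rows, models = 1:5, nAGQ = 1,
                               random = c("participant", "video")) {
  out <- list()
  for (m in models) {
    fit <- fit_probit_glmm(rows, INCREMENTAL_MODELS[[m]], random = random,
                           nAGQ = nAGQ)
    fit$r_squared <- r_squared(rows$fixated, fit$fitted)
    out[[paste0("model", m)]] <- fit
  }
  out
}

#' Squared-correlation analogue of R^2
#'
#' The square of the Pearson correlation between the observed binary
#' responses and the model-predicted probabilities. Zero variance in the
#' predictions gives 0 with a warning.
#'
#' @param observed 0/1 responses.
#' @param predicted fitted probabilities (same length).
#' @return Value in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have the same length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance; R^2 undefined, returning 0")
    return(0)
  }
  stats::cor(observed, predicted)^2
}

#' Bootstrap of the model series over control-cell redraws
#'
#' Because each observation matrix uses one random non-fixated control cell
#' per frame, the whole procedure (control redraw, matrix rebuild, model
#' refits) is repeated `n_iter` times; the summary reports the per-term mean
#' weight and the empirical 2.5th/97.5th percentile interval (linear
#' interpolation) across iterations, and likewise for R^2.
#'
#' @inheritParams build_observation_matrix
#' @param n_iter number of redraw iterations (>= 2; the source analysis
#'   uses 100).
#' @param seed master seed; iteration `i` uses a derived stream.
#' @param models integer subset of 1:5.
#' @param nAGQ passed to [fit_probit_glmm()].
#' @return A `bootstrap_summary`: list with `weights` (data.frame model,
#'   term, mean, lower, upper), `r2` (data.frame model, mean, lower, upper),
#'   `n_iterations`, `n_failed`.
#' @export
bootstrap_series <- function(cells, labels, ratings = NULL, n_iter = 100,
                             seed = 1L, grid = grid_spec(), models = 1:5,
                             nAGQ = 1) {
  if (n_iter < 2) stop("'n_iter' must be >= 2")
  draws <- vector("list", n_iter)
  failed <- 0L
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, "boot", i)
    res <- tryCatch({
      obs <- build_observation_matrix(cells, labels, ratings,
                                      seed = it_seed, grid = grid)
      incremental_series(obs, models = models, nAGQ = nAGQ)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else draws[[i]] <- res
  }
  draws <- draws[!vapply(draws, is.null, logical(1))]
  if (length(draws) == 0L) stop("all bootstrap iterations failed")
  wrows <- list()
  r2rows <- list()
  for (m in models) {
    key <- paste0("model", m)
    terms <- INCREMENTAL_MODELS[[m]]
    for (term in terms) {
      est <- vapply(draws, function(d) d[[key]]$coefficients[[term]], numeric(1))
      ci <- stats::quantile(est, c(0.025, 0.975), names = FALSE, type = 6)
      wrows[[length(wrows) + 1L]] <-
        data.frame(model = m, term = term, mean = mean(est),
                   lower = ci[1], upper = ci[2])
    }
    r2 <- vapply(draws, function(d) d[[key]]$r_squared, numeric(1))
    ci <- stats::quantile(r2, c(0.025, 0.975), names = FALSE, type = 6)
    r2rows[[length(r2rows) + 1L]] <-
      data.frame(model = m, mean = mean(r2), lower = ci[1], upper = ci[2])
  }
  structure(list(weights = do.call(rbind, wrows),
                 r2 = do.call(rbind, r2rows),
                 n_iterations = length(draws), n_failed = failed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary over %d iteration(s) (%d failed)\n",
              x$n_iterations, x$n_failed))
  w <- x$weights
  for (m in unique(w$model)) {
    r2 <- x$r2[x$r2$model == m, ]
    cat(sprintf("model %d:  R^2 = %.3f [%.3f, %.3f]\n",
                m, r2$mean, r2$lower, r2$upper))
    wm <- w[w$model == m, ]
    for (i in seq_len(nrow(wm)))
      cat(sprintf("    %-18s %6.3f [%6.3f, %6.3f]\n",
                  wm$term[i], wm$mean[i], wm$lower[i], wm$upper[i]))
  }
  invisible(x)
}

#' Table-shaped summary of a bootstrap run
#'
#' Flattens a [bootstrap_series()] result into one row per model x term with
#' the mean weight and percentile interval, plus R^2 columns — the
#' machine-readable twin of the usual incremental-model results table.
#'
#' @param summary a `bootstrap_summary`.
#' @return data.frame with columns `model`, `term`, `mean`, `lower`, `upper`,
#'   `r2_mean`, `r2_lower`, `r2_upper`.
#' @export
summary_table <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  w <- summary$weights
  r2 <- summary$r2
  idx <- match(w$model, r2$model)
  data.frame(w, r2_mean = r2$mean[idx], r2_lower = r2$lower[idx],
             r2_upper = r2$upper[idx])
}
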