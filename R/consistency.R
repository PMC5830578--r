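# Intra-individual consistency of predictor weights: per-unit probit fits,
# predictive-mean-matching imputation of non-converged units, video-wise
# z-standardization, Cronbach's alpha, and the ratings ICC.

#' Per-unit probit fits (one per participant x video)
#'
#' Fits a plain probit GLM (terms centrality, saliency, ROI; random
#' intercepts are unidentifiable with a single participant and video) to the
#' observation rows of every participant x video unit. Non-converged units
#' are recorded with missing weights.
#'
#' @param obs observation matrix (typically restricted to social videos).
#' @param terms model terms (default `c("centrality", "saliency", "roi")`).
#' @return A `weight_table`: data.frame with columns `participant`, `video`,
#'   `term`, `weight` (NA iff the unit's fit did not converge), `converged`.
#' @export
per_unit_fits <- function(obs, terms = c("centrality", "saliency", "roi")) {
  units <- unique(obs[c("participant", "video")])
  rows <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- obs[obs$participant == units$participant[i] &
               obs$video == units$video[i], , drop = FALSE]
    fit <- tryCatch(fit_probit_glm(u, terms), error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    w <- if (ok) unlist(fit$coefficients[terms]) else rep(NA_real_, length(terms))
    rows[[i]] <- data.frame(participant = units$participant[i],
                            video = units$video[i], term = terms,
                            weight = as.numeric(w), converged = ok)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

## predicted values for one term of a weight table: linear model of the
## target weight from the unit's other observed terms plus the participant-
## and video-mean weight of the target term. Units whose other terms are
## missing (the usual case: non-convergence removes the whole unit) fall
## back to the means-only model.
pmm_predict <- function(tab, term, terms) {
  sub <- tab[tab$term == term, ]
  others <- setdiff(terms, term)
  wide <- sub[c("participant", "video", "weight")]
  for (o in others) {
    ot <- tab[tab$term == o, ]
    wide[[paste0("w_", o)]] <-
      ot$weight[match(paste(wide$participant, wide$video),
                      paste(ot$participant, ot$video))]
  }
  pm <- tapply(wide$weight, wide$participant, mean, na.rm = TRUE)
  vm <- tapply(wide$weight, wide$video, mean, na.rm = TRUE)
  grand <- mean(wide$weight, na.rm = TRUE)
  wide$pmean <- as.numeric(pm[as.character(wide$participant)])
  wide$vmean <- as.numeric(vm[as.character(wide$video)])
  wide$pmean[!is.finite(wide$pmean)] <- grand
  wide$vmean[!is.finite(wide$vmean)] <- grand
  ocols <- if (length(others)) paste0("w_", others) else character(0)
  full_ok <- if (length(ocols)) stats::complete.cases(wide[ocols])
             else rep(FALSE, nrow(wide))
  obs_i <- !is.na(wide$weight)
  pred <- rep(NA_real_, nrow(wide))
  fit_predict <- function(fml, train, newdata) {
    fit <- tryCatch(stats::lm(fml, data = train), error = function(e) NULL)
    if (is.null(fit)) return(rep(NA_real_, nrow(newdata)))
    as.numeric(stats::predict(fit, newdata = newdata))
  }
  if (length(ocols) && any(obs_i & full_ok)) {
    fml <- stats::as.formula(paste("weight ~ pmean + vmean",
                                   paste(c("", ocols), collapse = " + ")))
    p <- fit_predict(fml, wide[obs_i & full_ok, ], wide)
    pred[full_ok] <- p[full_ok]
  }
  if (any(is.na(pred))) {
    p <- fit_predict(weight ~ pmean + vmean, wide[obs_i, ], wide)
    pred[is.na(pred)] <- p[is.na(pred)]
  }
  pred[is.na(pred)] <- grand
  list(wide = wide, pred = pred)
}

## draw one donor among the k observed entries nearest in predicted value
pmm_draw <- function(pred_target, pred_obs, w_obs, k) {
  ord <- order(abs(pred_obs - pred_target), seq_along(pred_obs))
  pool <- w_obs[ord[seq_len(min(k, length(ord)))]]
  pool[sample.int(length(pool), 1L)]
}

#' Predictive mean matching imputation of missing weights
#'
#' For every missing (non-converged) entry, a linear model predicts the
#' target weight from the unit's other observed terms plus the participant
#' and video mean weights; the imputed value is drawn uniformly from the
#' `k_donors` observed entries with the closest predicted values. Every
#' imputed value is therefore an element of the observed-weight pool.
#' Repeating the draw `m` times yields `m` completed tables; observed entries
#' are never altered.
#'
#' @param table a `weight_table` from [per_unit_fits()].
#' @param m number of imputed datasets (default 5).
#' @param k_donors donor pool size (default 5).
#' @param seed integer seed.
#' @return List of `m` completed weight tables.
#' @export
pmm_impute <- function(table, m = 5, k_donors = 5, seed = 1L) {
  terms <- unique(table$term)
  for (term in terms) {
    n_obs <- sum(!is.na(table$weight[table$term == term]))
    if (n_obs == 0L) stop(sprintf("no observed weights for term '%s'", term))
    if (n_obs < k_donors)
      stop(sprintf("need >= %d observed weights for term '%s'", k_donors, term))
  }
  if (!anyNA(table$weight)) return(replicate(m, table, simplify = FALSE))
  preds <- lapply(terms, function(tr) pmm_predict(table, tr, terms))
  names(preds) <- terms
  out <- vector("list", m)
  for (j in seq_len(m)) {
    completed <- table
    with_seed(derive_seed(seed, "pmm", j), {
      for (term in terms) {
        p <- preds[[term]]
        idx_all <- which(table$term == term)
        miss <- is.na(p$wide$weight)
        for (i in which(miss)) {
          completed$weight[idx_all[i]] <-
            pmm_draw(p$pred[i], p$pred[!miss], p$wide$weight[!miss], k_donors)
        }
      }
    })
    out[[j]] <- completed
  }
  out
}

#' Cronbach's alpha of video-wise standardized weights
#'
#' For each completed weight table and term: the participant x video weight
#' matrix is z-standardized within each video (across participants), videos
#' are treated as items and participants as cases, and
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(case sums))`. The
#' result per term is the mean alpha across tables with the empirical
#' 2.5th/97.5th percentile interval.
#'
#' @param tables list of completed weight tables (e.g. from [pmm_impute()],
#'   possibly concatenated across bootstrap iterations).
#' @return data.frame with columns `term`, `alpha`, `lower`, `upper`,
#'   `n_datasets`. `NA` alpha indicates zero total variance.
#' @export
consistency_alpha <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  terms <- unique(tables[[1]]$term)
  rows <- lapply(terms, function(term) {
    a <- vapply(tables, function(tab) {
      sub <- tab[tab$term == term, ]
      m <- stats::xtabs(weight ~ participant + video, data = sub)
      cronbach_alpha(scale(unclass(m)))
    }, numeric(1))
    a_ok <- a[is.finite(a)]
    if (length(a_ok) == 0L)
      return(data.frame(term = term, alpha = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_datasets = length(a)))
    ci <- stats::quantile(a_ok, c(0.025, 0.975), names = FALSE, type = 6)
    data.frame(term = term, alpha = mean(a_ok), lower = ci[1], upper = ci[2],
               n_datasets = length(a))
  })
  do.call(rbind, rows)
}

#' Cronbach's alpha of a cases x items matrix
#'
#' `alpha = k/(k-1) * (1 - sum_i var(item_i) / var(rowSums))` with sample
#' variances; `NA` when the total variance is zero. At least 2 items and 2
#' cases are required.
#'
#' @param x numeric matrix, rows = cases (participants), columns = items
#'   (videos).
#' @return Scalar alpha (<= 1, possibly negative).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 cases and >= 2 items")
  k <- ncol(x)
  total <- stats::var(rowSums(x))
  if (!is.finite(total) || total == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total)
}

#' Intraclass correlation of a ratings table
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC (often
#' written ICC(2,1) or ICC(A,1)) computed from the ANOVA mean squares of a
#' complete videos x raters table, with the standard F-based 95% confidence
#' interval.
#'
#' @param ratings numeric matrix or data.frame, rows = targets (videos),
#'   columns = raters (participants); or a long data.frame with columns
#'   `participant`, `video` and the rating column named by `value`.
#' @param value rating column name for long input (default `"valence"`).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `lower`, `upper`, and the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`). `icc` is `NA` when the variance is
#'   degenerate.
#' @export
icc <- function(ratings, value = "valence", conf = 0.95) {
  if (is.data.frame(ratings) && all(c("participant", "video") %in% names(ratings))) {
    m <- stats::xtabs(stats::as.formula(paste(value, "~ video + participant")),
                      data = ratings)
    ratings <- unclass(m)
  }
  x <- as.matrix(ratings)
  n <- nrow(x)  # targets
  k <- ncol(x)  # raters
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || denom <= 0)
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                ms_rows = msr, ms_cols = msc, ms_error = mse))
  est <- (msr - mse) / denom
  ## F-based interval for ICC(A,1) (McGraw & Wong)
  alpha <- 1 - conf
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = est, lower = lower, upper = upper,
       ms_rows = msr, ms_cols = msc, ms_error = mse)
}

#' Consistency analysis over bootstrap control redraws
#'
#' The per-unit fitting is repeated over `n_iter` control-cell redraws; for
#' each iteration the weight table is completed with `m` PMM imputations, so
#' alpha is summarized over `n_iter * m` datasets (the source analysis uses
#' 100 x 5 = 500).
#'
#' @inheritParams build_observation_matrix
#' @param n_iter control-redraw iterations.
#' @param m imputations per iteration.
#' @param k_donors PMM donor pool size.
#' @param terms per-unit model terms.
#' @return List with `alpha` (data.frame from [consistency_alpha()]),
#'   `n_nonconverged` (per-iteration counts of non-converged units) and
#'   `n_units`.
#' @export
consistency_analysis <- function(cells, labels, ratings = NULL, n_iter = 10,
                                 m = 5, k_donors = 5, seed = 1L,
                                 grid = grid_spec(),
                                 terms = c("centrality", "saliency", "roi")) {
  tables <- list()
  nonconv <- integer(n_iter)
  n_units <- NA_integer_
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, "consistency", i)
    obs <- build_observation_matrix(cells, labels, ratings, seed = it_seed,
                                    grid = grid)
    wt <- per_unit_fits(obs, terms)
    n_units <- nrow(unique(wt[c("participant", "video")]))
    nonconv[i] <- sum(!wt$converged[wt$term == terms[1]])
    tables <- c(tables, pmm_impute(wt, m = m, k_donors = k_donors,
                                   seed = it_seed))
  }
  list(alpha = consistency_alpha(tables), n_nonconverged = nonconv,
       n_units = n_units)
}
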