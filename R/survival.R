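# ---------------------------------------------------------------------------
# Outcome association stages: Kaplan-Meier + log-rank by attractor, bootstrap
# Spearman for the stability-survival link, and ridge-penalized Cox models
# with cross-validated concordance. The survival package does the fitting;
# hand-computed product-limit and O-E/V oracles live in the test suite.
# ---------------------------------------------------------------------------

#' Kaplan-Meier curves by group
#'
#' Product-limit estimator per group with median survival (first time the
#' survival curve drops to 0.5 or below; `NA` = not reached).
#'
#' @param records tibble with `time` (days) and `event` (1 = death,
#'   0 = censored).
#' @param groups group label per record (attractor index, morphotype, ...).
#' @return object of class `morpho_km`: `curves` tibble (group, time,
#'   n_risk, n_event, surv) and `medians` tibble (group, n, median).
#' @export
km_curve <- function(records, groups) {
  stopifnot(all(c("time", "event") %in% names(records)),
            nrow(records) == length(groups))
  if (any(records$time < 0)) stop("km_curve: negative times")
  d <- data.frame(time = records$time, event = records$event,
                  group = factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(d$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                           n_event = sm$n.event, surv = sm$surv)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  medians <- tibble::tibble(group = sub("^group=", "", rownames(tab)),
                            n = unname(tab[, "records"]),
                            median = unname(tab[, "median"]))
  structure(list(curves = curves, medians = medians, fit = fit),
            class = "morpho_km")
}

#' Multigroup log-rank test with pairwise follow-up
#'
#' Observed-vs-expected chi-square across event times (hypergeometric
#' variance); pairwise two-group tests are Benjamini-Hochberg adjusted.
#'
#' @param records tibble with `time`, `event`.
#' @param groups group label per record.
#' @return object of class `morpho_logrank`: `chi2`, `df`, `p`,
#'   `group_sizes`, `pairwise` tibble (group1, group2, chi2, p, p_adj).
#' @export
logrank <- function(records, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("logrank: need at least 2 non-empty groups")
  d <- data.frame(time = records$time, event = records$event, group = g)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE)
  pw <- NULL
  if (nlevels(g) > 2) {
    combs <- utils::combn(levels(g), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      dd <- d[d$group %in% combs[, j], ]
      dd$group <- droplevels(dd$group)
      f <- survival::survdiff(survival::Surv(time, event) ~ group, data = dd)
      data.frame(group1 = combs[1, j], group2 = combs[2, j], chi2 = f$chisq,
                 p = stats::pchisq(f$chisq, 1, lower.tail = FALSE))
    }))
    pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
    pw <- tibble::as_tibble(pw)
  }
  structure(list(chi2 = unname(sd_fit$chisq), df = df, p = p,
                 group_sizes = table(g), pairwise = pw),
            class = "morpho_logrank")
}

#' Bootstrap Spearman correlation
#'
#' Case-level resampling with replacement; percentile 2.5/97.5 interval for
#' rho, plus the point estimate's two-sided p-value from the large-sample
#' t approximation.
#'
#' @param x,y paired numeric vectors (e.g. stability and survival days).
#' @param B bootstrap resamples (default 2000).
#' @param seed RNG seed (resampling is deterministic under it).
#' @return tibble: `rho`, `rho_median`, `ci_low`, `ci_high`, `p`, `n`, `B`.
#' @export
bootstrap_spearman <- function(x, y, B = 2000L, seed = 42L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10) stop("bootstrap_spearman: need n >= 10")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("bootstrap_spearman: constant input")
  rho <- stats::cor(x, y, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(rho = rho, rho_median = stats::median(boots),
                 ci_low = ci[1], ci_high = ci[2], p = p, n = n,
                 B = length(boots))
}

#' Ridge-penalized Cox proportional hazards model
#'
#' L2-penalized partial-likelihood fit (Efron ties). Numeric covariates are
#' z-scored internally by default, so hazard ratios are per covariate
#' standard deviation; `standardize = FALSE` keeps the native units (e.g.
#' per year of age). Harrell's C is reported on the training data and as
#' mean +/- sd over `cv_folds` cross-validation folds (fit on the training
#' fold, concordance of its linear predictor on the held-out fold).
#'
#' @param records tibble with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param penalizer ridge penalty theta (default 0.5).
#' @param cv_folds folds for cross-validated concordance (default 5;
#'   0 skips CV).
#' @param standardize z-score covariates internally (default TRUE).
#' @param seed RNG seed for fold assignment.
#' @return object of class `morpho_ridge_cox` with `coefs` tibble
#'   (variable, coef, hr, ci_low, ci_high, p), `c_index`, `c_index_cv`,
#'   `c_index_cv_sd`, `scale` ("sd" or "native").
#' @export
ridge_cox <- function(records, covariates, penalizer = 0.5, cv_folds = 5L,
                      standardize = TRUE, seed = 42L) {
  stopifnot(all(c("time", "event") %in% names(records)),
            all(covariates %in% names(records)))
  X <- as.matrix(records[, covariates, drop = FALSE])
  if (anyNA(X)) stop("ridge_cox: missing covariate values")
  keep <- apply(X, 2, stats::sd) > 0
  Xs <- X
  if (standardize)
    Xs[, keep] <- scale(X[, keep, drop = FALSE])
  Xs[, !keep] <- 0
  d <- data.frame(time = records$time, event = records$event, Xs)
  colnames(d) <- c("time", "event", covariates)
  if (sum(d$event) < length(covariates))
    warning("ridge_cox: fewer events than covariates")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ survival::ridge(",
    paste(covariates, collapse = ", "), ", theta = ", penalizer,
    ", scale = FALSE)"))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- beta / se
  coefs <- tibble::tibble(
    variable = covariates,
    coef = unname(beta), hr = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))))
  # zero-variance covariates contribute nothing: HR pinned to 1
  coefs$hr[!keep] <- 1
  coefs$ci_low[!keep] <- 1
  coefs$ci_high[!keep] <- 1
  coefs$p[!keep] <- 1
  cidx <- unname(survival::concordance(fit)$concordance)
  cv_mean <- cv_sd <- NA_real_
  if (cv_folds >= 2) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(cv_folds), nrow(d)))
    cs <- vapply(seq_len(cv_folds), function(f) {
      tr <- d[fold != f, ]
      te <- d[fold == f, ]
      ft <- tryCatch(survival::coxph(fml, data = tr, ties = "efron"),
                     error = function(e) NULL)
      if (is.null(ft) || sum(te$event) == 0) return(NA_real_)
      lp <- as.matrix(te[, covariates, drop = FALSE]) %*% stats::coef(ft)
      unname(survival::concordance(
        survival::Surv(te$time, te$event) ~ lp, reverse = TRUE)$concordance)
    }, numeric(1))
    cs <- cs[!is.na(cs)]
    cv_mean <- mean(cs)
    cv_sd <- stats::sd(cs)
  }
  structure(list(coefs = coefs, c_index = cidx, c_index_cv = cv_mean,
                 c_index_cv_sd = cv_sd, penalizer = penalizer,
                 scale = if (standardize) "sd" else "native",
                 n = nrow(d), n_events = sum(d$event), fit = fit),
            class = "morpho_ridge_cox")
}
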