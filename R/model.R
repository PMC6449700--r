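#' Fit an interactive mixed-effects reaction-time model
#'
#' Fits `rt ~ (p1 + ... + pk)^order + (1 | participant) + (1 | trial)` with
#' lme4: crossed random intercepts for participant and for trial position
#' (1..10 within each period), fixed effects expanded to all interactions
#' up to `order`. Continuous predictors are z-scored before the
#' interaction expansion (interaction coefficients are otherwise
#' scale-dependent); `period` enters as a numeric covariate centered at
#' its midpoint. Rows with any missing model variable are excluded
#' listwise. Estimation is maximum likelihood by default, as required for
#' likelihood-ratio tests of fixed effects; set `ml = FALSE` for REML
#' variance reporting.
#'
#' @param data Feature tibble with columns `rt`, `participant`, `trial`
#'   and the requested predictors (see [build_trial_features()]).
#' @param predictors Fixed-effect terms; any of `"alpha_db"`, `"mean_rr"`,
#'   `"rmssd"`, `"ln_x"`, `"period"`.
#' @param order Maximum interaction order (1, 2 or 3).
#' @param standardize Z-score continuous predictors (and center `period`)
#'   before expansion.
#' @param ml Fit by maximum likelihood (`TRUE`) or REML.
#' @param random_slopes Optional character vector of predictors given
#'   random slopes over participants (off by default; the random-intercept
#'   structure is the reference model family).
#' @param add_terms Optional explicit interaction terms (e.g.
#'   `"alpha_db:rmssd"`) appended to the expansion; useful for testing one
#'   interaction against an otherwise additive model.
#' @return An object of class `rt_lme` wrapping the lme4 fit, with
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot] methods.
#' @export
fit_rt_model <- function(data, predictors = c("alpha_db", "mean_rr", "rmssd",
                                              "ln_x", "period"),
                         order = 3, standardize = TRUE, ml = TRUE,
                         random_slopes = NULL, add_terms = NULL) {
  stopifnot(order %in% 1:3)
  missing_terms <- setdiff(predictors, names(data))
  if (length(missing_terms)) {
    stop("predictor(s) not in data: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  use <- stats::complete.cases(data[c("rt", "participant", "trial", predictors)])
  d <- data[use, , drop = FALSE]
  if (length(unique(d$participant)) < 2 || length(unique(d$trial)) < 2) {
    stop("need at least 2 participants and 2 trial positions", call. = FALSE)
  }
  scaling <- list()
  if (standardize) {
    for (p in predictors) {
      if (p == "period") {
        mu <- mean(range(d$period)); sdv <- 1
      } else {
        mu <- mean(d[[p]]); sdv <- stats::sd(d[[p]])
        if (!is.finite(sdv) || sdv == 0) sdv <- 1
      }
      scaling[[p]] <- c(center = mu, scale = sdv)
      d[[p]] <- (d[[p]] - mu) / sdv
    }
  }
  d$participant <- factor(d$participant)
  d$trial <- factor(d$trial)
  fixed <- if (length(predictors) == 1 || order == 1) {
    paste(predictors, collapse = " + ")
  } else {
    sprintf("(%s)^%d", paste(predictors, collapse = " + "), order)
  }
  if (length(add_terms)) {
    fixed <- paste(c(fixed, add_terms), collapse = " + ")
  }
  re <- "(1 | participant) + (1 | trial)"
  if (length(random_slopes)) {
    re <- sprintf("(1 + %s | participant) + (1 | trial)",
                  paste(random_slopes, collapse = " + "))
  }
  form <- stats::as.formula(paste("rt ~ 1 +", fixed, "+", re))
  fit <- lme4::lmer(form, data = d, REML = !ml,
                    control = lme4::lmerControl(
                      optimizer = "bobyqa",
                      check.conv.singular = "ignore"))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(
    list(fit = fit, formula = form, predictors = predictors, order = order,
         ml = ml, scaling = scaling, n_obs = nrow(d), converged = conv,
         data = d),
    class = "rt_lme")
}

#' @export
print.rt_lme <- function(x, ...) {
  cat("Interactive mixed-effects RT model\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  g <- generics::glance(x)
  cat(sprintf("  n = %d, logLik = %.1f, AIC = %.1f, BIC = %.1f (%s)\n",
              g$nobs, g$logLik, g$AIC, g$BIC, if (x$ml) "ML" else "REML"))
  invisible(x)
}

#' Tidy and summarize fitted RT models
#'
#' `tidy()` returns one row per fixed effect (estimate, SE, t); `glance()`
#' returns one row of fit summaries, including the three variance
#' components.
#'
#' @param x An `rt_lme` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rt_lme
#' @export
tidy.rt_lme <- function(x, ...) {
  cc <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = rownames(cc),
    estimate = cc[, "Estimate"],
    std_error = cc[, "Std. Error"],
    statistic = cc[, "t value"]
  )
}

#' @rdname tidy.rt_lme
#' @method glance rt_lme
#' @export
glance.rt_lme <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  vc <- varcomps(x)
  tibble::tibble(
    nobs = x$n_obs,
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    AIC = stats::AIC(x$fit),
    BIC = stats::BIC(x$fit),
    sigma2_participant = vc[["participant"]],
    sigma2_trial = vc[["trial"]],
    sigma2_residual = vc[["residual"]],
    converged = x$converged
  )
}

varcomps <- function(x) {
  vc <- lme4::VarCorr(x$fit)
  c(participant = unname(attr(vc$participant, "stddev"))^2,
    trial = unname(attr(vc$trial, "stddev"))^2,
    residual = attr(vc, "sc")^2)
}

n_fixed <- function(x) length(lme4::fixef(x$fit))

#' Likelihood-ratio test of nested RT models
#'
#' Chi-square = 2 * (logLik_full - logLik_null) clipped at zero, with
#' degrees of freedom equal to the difference in fixed-effect parameter
#' counts, referred to the upper chi-square tail. Both models must be fit
#' by ML on the same rows with the null's fixed terms nested in the
#' full's; violating either is a misuse error, not a warning.
#'
#' @param full,null `rt_lme` fits.
#' @return A one-row tibble: `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, null) {
  if (!full$ml || !null$ml) {
    stop("LRTs of fixed effects require ML fits (ml = TRUE)", call. = FALSE)
  }
  if (!full$converged || !null$converged) {
    stop("refusing LRT on a non-converged fit", call. = FALSE)
  }
  if (full$n_obs != null$n_obs) {
    stop("models were fit to different rows; refit on common data",
         call. = FALSE)
  }
  tf <- names(lme4::fixef(full$fit))
  tn <- names(lme4::fixef(null$fit))
  if (!all(tn %in% tf)) {
    stop("null model fixed effects are not nested within the full model",
         call. = FALSE)
  }
  chi <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                       as.numeric(stats::logLik(null$fit))))
  df <- n_fixed(full) - n_fixed(null)
  if (df == 0) {
    # self-comparison: no evidence either way
    return(tibble::tibble(chi_square = chi, df = 0L, p_value = 1))
  }
  tibble::tibble(
    chi_square = chi, df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE)
  )
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional): with `var_f` the variance of the
#' fixed-effect linear predictor over the fitted rows and the participant,
#' trial and residual variance components, marginal = var_f / total and
#' conditional = (var_f + var_participant + var_trial) / total, where
#' total is the sum of all four.
#'
#' @param x An `rt_lme` fit.
#' @return A one-row tibble: `marginal`, `conditional`.
#' @export
nakagawa_r2 <- function(x) {
  if (!x$converged) stop("fit did not converge", call. = FALSE)
  eta <- as.numeric(stats::model.matrix(x$fit) %*% lme4::fixef(x$fit))
  vc <- varcomps(x)
  r2_from_components(stats::var(eta), vc[["participant"]], vc[["trial"]],
                     vc[["residual"]])
}

# the variance-partition arithmetic, shared with tests
r2_from_components <- function(var_f, var_participant, var_trial, var_resid) {
  total <- var_f + var_participant + var_trial + var_resid
  if (total <= 0) {
    warning("zero total variance; R2 undefined", call. = FALSE)
    return(tibble::tibble(marginal = NA_real_, conditional = NA_real_))
  }
  tibble::tibble(
    marginal = var_f / total,
    conditional = (var_f + var_participant + var_trial) / total
  )
}

#' Run the staged model sequence for a feature table
#'
#' Reproduces the reference modeling sequence on a per-trial feature
#' table:
#' \enumerate{
#'   \item four single-predictor-by-period interactive models (alpha,
#'     meanRR, RMSSD, lnX; each with its period interaction), each
#'     LRT-compared with its additive null;
#'   \item the full five-term interactive model (interactions to order 3);
#'   \item the reduced four-term model with lnX dropped, LRT-compared with
#'     its additive null, plus Nakagawa R-squared;
#'   \item three follow-up LRTs probing the alpha-by-HRV, alpha-by-period
#'     and HRV-by-period two-way interactions: each compares the full
#'     reduced interactive model against "additive + that single two-way
#'     term".
#' }
#'
#' @param data Feature tibble (see [build_trial_features()]).
#' @param rt_cap Winsorization ceiling applied to `rt` before fitting, ms.
#' @return A list of class `rt_model_report` with elements
#'   `single_predictor` (named list of fits), `single_lrt` (tibble),
#'   `full`, `reduced` (fits), `reduced_lrt`, `pairwise_lrt` (tibble),
#'   `r2` (tibble), and `fits_glance` (tibble of all fit summaries).
#' @export
model_search <- function(data, rt_cap = 2600) {
  data$rt <- pmin(data$rt, rt_cap)
  singles <- c("alpha_db", "mean_rr", "rmssd", "ln_x")
  avail <- intersect(singles, names(data))

  single_fits <- list()
  single_lrt <- purrr::map_dfr(avail, function(p) {
    # fit both on the rows complete for this predictor pair
    full <- fit_rt_model(data, c(p, "period"), order = 2)
    null <- fit_rt_model(data, c(p, "period"), order = 1)
    single_fits[[p]] <<- full
    dplyr::mutate(likelihood_ratio_test(full, null),
                  comparison = paste0(p, " x period vs additive"),
                  .before = 1)
  })

  full5 <- fit_rt_model(data, c("alpha_db", "mean_rr", "rmssd", "ln_x",
                                "period"), order = 3)
  # reduced model: lnX dropped; restrict to the same listwise-complete rows
  reduced_terms <- c("alpha_db", "mean_rr", "rmssd", "period")
  reduced <- fit_rt_model(data, reduced_terms, order = 3)
  reduced_null <- fit_rt_model(data, reduced_terms, order = 1)
  reduced_lrt <- dplyr::mutate(
    likelihood_ratio_test(reduced, reduced_null),
    comparison = "reduced interactive vs additive", .before = 1)

  pairs <- list(
    c("alpha_db", "rmssd"),
    c("alpha_db", "period"),
    c("rmssd", "period")
  )
  pairwise_lrt <- purrr::map_dfr(pairs, function(pr) {
    null <- fit_rt_model(data, reduced_terms, order = 1,
                         add_terms = paste(pr, collapse = ":"))
    dplyr::mutate(likelihood_ratio_test(reduced, null),
                  comparison = sprintf("full vs additive + %s:%s",
                                       pr[1], pr[2]),
                  .before = 1)
  })

  all_fits <- c(single_fits, list(full = full5, reduced = reduced,
                                  reduced_additive = reduced_null))
  report <- list(
    single_predictor = single_fits,
    single_lrt = single_lrt,
    full = full5,
    reduced = reduced,
    reduced_lrt = reduced_lrt,
    pairwise_lrt = pairwise_lrt,
    r2 = nakagawa_r2(reduced),
    fits_glance = purrr::map_dfr(all_fits, generics::glance, .id = "model")
  )
  class(report) <- "rt_model_report"
  report
}

#' @export
print.rt_model_report <- function(x, ...) {
  cat("RT model search report\n\n")
  cat("Single-predictor interaction LRTs:\n")
  print(as.data.frame(x$single_lrt), row.names = FALSE)
  cat("\nReduced interactive vs additive:\n")
  print(as.data.frame(x$reduced_lrt), row.names = FALSE)
  cat("\nFollow-up interaction LRTs:\n")
  print(as.data.frame(x$pairwise_lrt), row.names = FALSE)
  cat(sprintf("\nNakagawa R2: marginal %.3f, conditional %.3f\n",
              x$r2$marginal, x$r2$conditional))
  invisible(x)
}

#' Serialize a model report to JSON
#'
#' @param report An `rt_model_report` from [model_search()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_model_report <- function(report, path = NULL) {
  payload <- list(
    fixed_effects = lapply(
      c(list(full = report$full, reduced = report$reduced),
        report$single_predictor),
      function(f) as.list(stats::setNames(tidy.rt_lme(f)$estimate,
                                          tidy.rt_lme(f)$term))),
    variance_components = lapply(
      list(full = report$full, reduced = report$reduced),
      function(f) as.list(varcomps(f))),
    fits = report$fits_glance,
    lrt = dplyr::bind_rows(report$single_lrt, report$reduced_lrt,
                           report$pairwise_lrt),
    r2 = report$r2
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                           dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
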