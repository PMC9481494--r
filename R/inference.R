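#' Prepare a cone-width table for mixed modelling
#'
#' Keeps rows with a defined cone width, orders the condition factor
#' baseline < eyes closed < direct gaze (so treatment contrasts measure
#' widening relative to the least-capturing condition present), and
#' factors ethnicity when it is informative.
#'
#' @param widths A tibble with columns `participant_id`, `condition`,
#'   `width` and optionally `ethnicity` and `fit_ok`.
#' @return A tibble ready for [fit_cone_lmm()].
#' @export
prepare_width_data <- function(widths) {
  d <- widths
  if ("fit_ok" %in% names(d)) d <- dplyr::filter(d, .data$fit_ok)
  d <- dplyr::filter(d, !is.na(.data$width))
  d$condition <- factor(d$condition,
                        levels = intersect(CONDITIONS, unique(d$condition)))
  if (!"ethnicity" %in% names(d)) d$ethnicity <- NA_character_
  if (dplyr::n_distinct(d$ethnicity, na.rm = TRUE) >= 2) {
    d$ethnicity <- factor(d$ethnicity,
                          levels = intersect(ETHNICITIES, unique(d$ethnicity)))
  }
  d$participant_id <- factor(d$participant_id)
  d
}

lmm_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    calc.derivs = FALSE)
}

#' Fit the random-intercept mixed model for cone widths
#'
#' Fits `width ~ condition (* ethnicity) + (1 | participant_id)` by
#' maximum likelihood (not REML), so that log-likelihoods are comparable
#' across fixed-effect specifications in likelihood-ratio tests. No random
#' slopes are included.
#'
#' @param widths Cone-width table (see [prepare_width_data()]).
#' @param formula Optional model formula overriding the default; must
#'   contain a `(1 | participant_id)` term.
#' @param include_ethnicity Force ethnicity (and its interaction with
#'   condition) in or out; default `NULL` includes it when two ethnicity
#'   labels are present.
#' @return A fitted `lmerMod` (ML).
#' @export
fit_cone_lmm <- function(widths, formula = NULL, include_ethnicity = NULL) {
  d <- prepare_width_data(widths)
  if (nlevels(d$condition) < 2) {
    abort("need at least two conditions to model a condition effect",
          class = "gazecone_spec_error")
  }
  if (is.null(formula)) {
    use_eth <- include_ethnicity %||% is.factor(d$ethnicity)
    formula <- if (use_eth) {
      width ~ condition * ethnicity + (1 | participant_id)
    } else {
      width ~ condition + (1 | participant_id)
    }
  }
  lme4::lmer(formula, data = d, REML = FALSE, control = lmm_control())
}

fixed_terms <- function(formula) {
  attr(terms(lme4::nobars(formula)), "term.labels")
}

#' Likelihood-ratio test by dropping an effect
#'
#' Fits the full and the reduced model by maximum likelihood and compares
#' them: the statistic is twice the log-likelihood difference (truncated
#' at zero), the degrees of freedom the difference in fixed-effect
#' coefficient counts, and the p-value comes from the chi-square reference
#' distribution. The reduced model's fixed terms must be a subset of the
#' full model's.
#'
#' @param widths Cone-width table.
#' @param full,reduced Model formulas, each with a `(1 | participant_id)`
#'   random intercept, the reduced nested in the full.
#' @return One-row tibble: `chi2`, `df`, `p_value`, `logLik_full`,
#'   `logLik_reduced`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = 12, seed = 3))
#' w <- cone_widths(aggregate_counts(cohort$trials))
#' lrt_drop_effect(w, width ~ condition + (1 | participant_id),
#'                 width ~ 1 + (1 | participant_id))
lrt_drop_effect <- function(widths, full, reduced) {
  t_full <- fixed_terms(full)
  t_red <- fixed_terms(reduced)
  if (!all(t_red %in% t_full)) {
    abort("reduced model is not nested in the full model",
          class = "gazecone_spec_error")
  }
  m_full <- fit_cone_lmm(widths, formula = full)
  m_red <- fit_cone_lmm(widths, formula = reduced)
  ll_f <- as.numeric(logLik(m_full))
  ll_r <- as.numeric(logLik(m_red))
  df <- length(lme4::fixef(m_full)) - length(lme4::fixef(m_red))
  chi2 <- max(0, 2 * (ll_f - ll_r))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, df = df, p_value = p,
                 logLik_full = ll_f, logLik_reduced = ll_r)
}

#' Pairwise condition contrasts of estimated marginal means
#'
#' Computes all pairwise differences in model-estimated marginal mean cone
#' width between conditions, averaging over the levels of any other fixed
#' factor with equal weight. Standard errors come from the fixed-effect
#' covariance of the fitted model; t statistics use the residual degrees
#' of freedom (observations minus fixed-effect coefficients minus
#' participants) and p-values are unadjusted. Contrasts are oriented so
#' that the condition expected to be wider (later in the order baseline <
#' eyes closed < direct gaze) comes first.
#'
#' @param model A fitted `lmerMod` from [fit_cone_lmm()].
#' @param level Confidence level for the Wald-t intervals.
#' @return Tibble: `contrast`, `estimate`, `se`, `df`, `t`, `p_value`,
#'   `ci_low`, `ci_high`.
#' @export
pairwise_contrasts <- function(model, level = 0.95) {
  mf <- stats::model.frame(model)
  if (!"condition" %in% names(mf)) {
    abort("model has no condition factor", class = "gazecone_spec_error")
  }
  fe_form <- lme4::nobars(stats::formula(model, fixed.only = TRUE))
  tt <- stats::delete.response(terms(fe_form))
  vars <- setdiff(all.vars(tt), "width")
  lv <- lapply(vars, function(v) levels(mf[[v]]) %||% unique(mf[[v]]))
  names(lv) <- vars
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  for (v in vars) {
    if (is.factor(mf[[v]])) grid[[v]] <- factor(grid[[v]], levels(mf[[v]]))
  }
  X <- model.matrix(tt, grid)

  b <- lme4::fixef(model)
  # a rank-deficient design drops coefficients; align X with the kept ones
  X <- X[, names(b), drop = FALSE]
  V <- as.matrix(vcov(model))
  conds <- levels(mf$condition)
  emm_rows <- vapply(conds, function(cc) {
    colMeans(X[grid$condition == cc, , drop = FALSE])
  }, numeric(ncol(X)))

  n_obs <- nrow(mf)
  n_part <- nlevels(droplevels(mf[["participant_id"]]))
  df <- n_obs - length(b) - n_part

  pairs <- utils::combn(seq_along(conds), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    # orient wider-expected minus narrower-expected (later level first)
    L <- emm_rows[, pr[2]] - emm_rows[, pr[1]]
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tstat <- est / se
    crit <- qt(1 - (1 - level) / 2, df)
    tibble::tibble(
      contrast = paste(conds[pr[2]], "-", conds[pr[1]]),
      estimate = est, se = se, df = df, t = tstat,
      p_value = 2 * pt(-abs(tstat), df),
      ci_low = est - crit * se, ci_high = est + crit * se
    )
  })
  rows
}

#' Full group-level analysis of cone widths
#'
#' Fits the random-intercept mixed model, runs likelihood-ratio tests by
#' dropping each effect of interest from the appropriate model (the
#' interaction from the full model; each main effect from the additive
#' model), and computes pairwise condition contrasts with Wald-t
#' intervals.
#'
#' @inheritParams fit_cone_lmm
#' @param level Confidence level for contrast intervals.
#' @return An object of class `cone_inference`: the fitted model, an
#'   `lrt` tibble (one row per dropped effect), a `contrasts` tibble, and
#'   sample sizes.
#' @export
analyze_cone_widths <- function(widths, include_ethnicity = NULL,
                                level = 0.95) {
  d <- prepare_width_data(widths)
  use_eth <- include_ethnicity %||% is.factor(d$ethnicity)
  model <- fit_cone_lmm(d, include_ethnicity = use_eth)

  lrt <- if (use_eth) {
    dplyr::bind_rows(
      condition = lrt_drop_effect(
        d, width ~ condition + ethnicity + (1 | participant_id),
        width ~ ethnicity + (1 | participant_id)),
      ethnicity = lrt_drop_effect(
        d, width ~ condition + ethnicity + (1 | participant_id),
        width ~ condition + (1 | participant_id)),
      `condition:ethnicity` = lrt_drop_effect(
        d, width ~ condition * ethnicity + (1 | participant_id),
        width ~ condition + ethnicity + (1 | participant_id)),
      .id = "effect"
    )
  } else {
    dplyr::bind_rows(
      condition = lrt_drop_effect(
        d, width ~ condition + (1 | participant_id),
        width ~ 1 + (1 | participant_id)),
      .id = "effect"
    )
  }

  structure(
    list(model = model, lrt = lrt,
         contrasts = pairwise_contrasts(model, level = level),
         n_participants = nlevels(d$participant_id),
         n_obs = nrow(d),
         conditions = levels(d$condition),
         include_ethnicity = use_eth,
         level = level),
    class = "cone_inference"
  )
}

#' @export
print.cone_inference <- function(x, ...) {
  cat("Cone-width mixed-model analysis\n")
  cat(sprintf("  %d participants, %d observations, conditions: %s\n",
              x$n_participants, x$n_obs, paste(x$conditions, collapse = ", ")))
  cat("\nLikelihood-ratio tests (effect dropped from its model):\n")
  print(as.data.frame(x$lrt), digits = 4, row.names = FALSE)
  cat("\nPairwise condition contrasts (degrees, unadjusted p):\n")
  print(as.data.frame(x$contrasts), digits = 4, row.names = FALSE)
  invisible(x)
}
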