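#' Predicted category proportions from joint logistic parameters
#'
#' The fitted model: a decreasing logistic for "left" responses with
#' midpoint `mu_left` and steepness `beta_left`,
#' \eqn{p_L(x) = 1 / (1 + e^{\beta_L (x - \mu_L)})}; an increasing logistic
#' for "right" responses, \eqn{p_R(x) = 1 / (1 + e^{-\beta_R (x - \mu_R)})};
#' and the "middle" proportion as their complement
#' \eqn{p_M(x) = 1 - p_L(x) - p_R(x)}, so the three proportions sum to one
#' identically. Slopes are strictly positive by construction; the signs of
#' the transitions live in the functional forms.
#'
#' @param params A `cone_fit` object or any list/vector with elements
#'   `mu_left`, `beta_left`, `mu_right`, `beta_right`.
#' @param azimuth_deg Numeric vector of azimuths (degrees).
#' @return Tibble with columns `azimuth_deg`, `p_left`, `p_middle`,
#'   `p_right`.
#' @export
#' @examples
#' predict_proportions(list(mu_left = -15, beta_left = 0.3,
#'                          mu_right = 15, beta_right = 0.3), -40:40)
predict_proportions <- function(params, azimuth_deg) {
  p <- as.list(params[c("mu_left", "beta_left", "mu_right", "beta_right")])
  pm <- predict_mat(p$mu_left, p$beta_left, p$mu_right, p$beta_right,
                    azimuth_deg)
  tibble::tibble(azimuth_deg = azimuth_deg,
                 p_left = as.numeric(pm[, 1]),
                 p_middle = as.numeric(pm[, 2]),
                 p_right = as.numeric(pm[, 3]))
}

# Matrix version used in optimizer inner loops: cols left, middle, right.
predict_mat <- function(mu_l, beta_l, mu_r, beta_r, x) {
  p_left <- plogis(-beta_l * (x - mu_l))
  p_right <- plogis(beta_r * (x - mu_r))
  cbind(p_left, 1 - p_left - p_right, p_right)
}

#' Control parameters for the joint logistic fit
#'
#' @param n_restarts Number of simplex starts: one data-driven start
#'   (midpoints where the empirical left/right proportions cross 0.5 by
#'   linear interpolation, slope 0.2 per degree) plus deterministic
#'   perturbations of it. Default 5.
#' @param maxit Maximum simplex iterations per restart.
#' @param abstol,reltol Loss tolerances passed to the simplex optimizer.
#' @param search_range Azimuth interval (degrees) scanned for curve
#'   crossings; wider than the stimulus range because fitted crossings may
#'   fall outside it.
#' @param check_middle If `TRUE` (default) a fit is only accepted when the
#'   predicted middle proportion is non-negative, within `middle_tol`, at
#'   every design azimuth present in the data.
#' @param middle_tol How far below zero the predicted middle proportion
#'   may dip at a design azimuth before the fit is rejected. The two
#'   fitted logistics are free curves, so the tail of one routinely leaks
#'   a proportion of order 1e-6 past the complement of the other at the
#'   extreme azimuths; only a materially negative middle curve (default
#'   more than 0.01, i.e. one percentage point) marks a meaningless fit.
#' @return A list of class `cone_fit_control`.
#' @export
fit_control <- function(n_restarts = 5, maxit = 2000, abstol = 1e-10,
                        reltol = 1e-10, search_range = c(-90, 90),
                        check_middle = TRUE, middle_tol = 0.01) {
  structure(list(n_restarts = n_restarts, maxit = maxit, abstol = abstol,
                 reltol = reltol, search_range = search_range,
                 check_middle = check_middle, middle_tol = middle_tol),
            class = "cone_fit_control")
}

# Data-driven start: interpolate where empirical p_left falls through 0.5
# (and p_right rises through 0.5); with several crossings the one nearest
# 0 is used, which keeps the start mirror-consistent. Fall back to the
# inner quartile azimuths.
start_values <- function(obs, x) {
  cross_of <- function(p, rising) {
    s <- if (rising) p else 1 - p
    idx <- which(diff(sign(s - 0.5 + 1e-12)) > 0)
    if (length(idx) == 0) return(NA_real_)
    x0 <- vapply(idx, function(i) {
      x[i] + (0.5 - s[i]) / (s[i + 1] - s[i]) * (x[i + 1] - x[i])
    }, numeric(1))
    x0[which.min(abs(x0))]
  }
  mu_l <- cross_of(obs[, 1], rising = FALSE)
  mu_r <- cross_of(obs[, 3], rising = TRUE)
  rng <- range(x)
  if (is.na(mu_l)) mu_l <- rng[1] + diff(rng) / 4
  if (is.na(mu_r)) mu_r <- rng[2] - diff(rng) / 4
  if (mu_l > mu_r) { tmp <- mu_l; mu_l <- mu_r; mu_r <- tmp }
  c(mu_l = mu_l, mu_r = mu_r, slope = 0.2)
}

# Deterministic perturbations of the data-driven start. The set is
# mirror-symmetric in (mu_l, mu_r) so that reflected datasets explore
# reflected start points.
start_grid <- function(s0, n_restarts) {
  jitters <- list(
    c(0, 0, 1),
    c(-6, -6, 1),
    c(6, 6, 1),
    c(0, 0, 0.4),
    c(0, 0, 2.5),
    c(-4, 4, 1),
    c(4, -4, 1)
  )
  jitters <- jitters[seq_len(min(n_restarts, length(jitters)))]
  lapply(jitters, function(j) {
    mu_l <- s0[["mu_l"]] + j[1]
    mu_r <- s0[["mu_r"]] + j[2]
    if (mu_l > mu_r) { mid <- (mu_l + mu_r) / 2; mu_l <- mid - 1; mu_r <- mid + 1 }
    c(mu_l, mu_r, log(s0[["slope"]] * j[3]), log(s0[["slope"]] * j[3]))
  })
}

#' Jointly fit the three category response functions
#'
#' Fits the two logistic curves (and hence the complementary middle curve)
#' of [predict_proportions()] to one participant-condition response-count
#' table by minimizing the sum of squared differences between observed and
#' predicted proportions over all azimuths and all three categories — the
#' residual variance up to a constant factor — with the Nelder–Mead simplex
#' method. All three curves are fitted simultaneously, which respects the
#' non-independence of the categories. Slopes are optimized on the log
#' scale so they are positive by construction; several starts are tried and
#' the best kept.
#'
#' A fit is accepted only if the optimizer converged, (by default) the
#' predicted middle proportion is non-negative within tolerance at every
#' design azimuth in the data, and both curve crossings defining the cone
#' exist with positive width inside the search range (see
#' [find_crossings()]). An unacceptable fit is the "unable to fit"
#' exclusion trigger:
#' with `on_failure = "error"` (default) a classed condition
#' `gazecone_fit_failure` carrying the diagnostics is raised; with
#' `"return"` the non-converged `cone_fit` object is returned for the
#' caller to flag.
#'
#' @param counts One participant-condition slice of [aggregate_counts()]
#'   output: columns `azimuth_deg`, `n_left`, `n_middle`, `n_right`,
#'   `n_total`. At least four azimuths with trials are required.
#' @param control A [fit_control()] list.
#' @param on_failure `"error"` or `"return"`.
#' @return A `cone_fit` object: fitted parameters, `loss` (SSE),
#'   `converged`, `n_restarts_used`, failure `reasons`, and the data.
#' @export
fit_joint <- function(counts, control = fit_control(),
                      on_failure = c("error", "return")) {
  on_failure <- match.arg(on_failure)
  counts <- dplyr::filter(counts, .data$n_total > 0)
  x <- counts$azimuth_deg
  if (length(x) < 4) {
    abort("joint fit needs at least 4 azimuths with observations",
          class = "gazecone_data_error")
  }
  obs <- cbind(counts$n_left, counts$n_middle, counts$n_right) / counts$n_total
  oL <- obs[, 1]; oM <- obs[, 2]; oR <- obs[, 3]

  # hot path: called ~10^3 times per fit, so no matrix or tibble building
  objective <- function(th) {
    pL <- 1 / (1 + exp(exp(th[3]) * (x - th[1])))
    pR <- 1 / (1 + exp(-exp(th[4]) * (x - th[2])))
    dM <- oM - 1 + pL + pR
    sum((oL - pL)^2) + sum(dM * dM) + sum((oR - pR)^2)
  }

  starts <- start_grid(start_values(obs, x), control$n_restarts)
  best <- NULL
  for (s in starts) {
    o <- suppressWarnings(optim(
      s, objective, method = "Nelder-Mead",
      control = list(maxit = control$maxit, abstol = control$abstol,
                     reltol = control$reltol)
    ))
    if (is.null(best) ||
        (o$convergence == 0 && best$convergence != 0) ||
        (o$convergence == best$convergence && o$value < best$value)) {
      best <- o
    }
  }

  params <- c(mu_left = best$par[[1]], beta_left = exp(best$par[[3]]),
              mu_right = best$par[[2]], beta_right = exp(best$par[[4]]))
  reasons <- character()
  if (best$convergence != 0) reasons <- c(reasons, "non_convergence")
  if (control$check_middle) {
    pm <- predict_mat(params[["mu_left"]], params[["beta_left"]],
                      params[["mu_right"]], params[["beta_right"]], x)
    if (any(pm[, 2] < -control$middle_tol)) {
      reasons <- c(reasons, "negative_middle")
    }
  }
  crossings <- find_crossings(as.list(params),
                              search_range = control$search_range)
  if (crossings$status != "ok") reasons <- c(reasons, crossings$status)

  fit <- structure(
    list(params = params, loss = best$value,
         converged = length(reasons) == 0,
         n_restarts_used = length(starts),
         reasons = reasons,
         crossings = crossings,
         counts = counts),
    class = "cone_fit"
  )
  if (!fit$converged && on_failure == "error") {
    abort(paste0("unable to fit logistic functions (",
                 paste(reasons, collapse = ", "), ")"),
          class = "gazecone_fit_failure", fit = fit)
  }
  fit
}

#' @export
print.cone_fit <- function(x, ...) {
  cat("Joint 3-category logistic fit\n")
  cat(sprintf("  mu_left = %.2f deg, beta_left = %.3f /deg\n",
              x$params[["mu_left"]], x$params[["beta_left"]]))
  cat(sprintf("  mu_right = %.2f deg, beta_right = %.3f /deg\n",
              x$params[["mu_right"]], x$params[["beta_right"]]))
  cat(sprintf("  SSE = %.5g; converged: %s (%d restarts)\n", x$loss,
              x$converged, x$n_restarts_used))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Locate the crossings of the side curves with the middle curve
#'
#' The cone width is the distance between the azimuth where the fitted
#' "left" curve intersects the "middle" curve and the azimuth where the
#' "right" curve does. Each crossing is located by scanning for a sign
#' change of the difference function on a 0.1-degree grid over
#' `search_range` and refining it by bisection to better than 1e-4
#' degrees. If several sign changes exist the one nearest 0 degrees is
#' used; a missing crossing or a non-positive width is recorded in
#' `status` rather than raised.
#'
#' @param params A `cone_fit` or a list with `mu_left`, `beta_left`,
#'   `mu_right`, `beta_right`.
#' @param search_range Length-2 numeric, degrees.
#' @return A one-row tibble: `x_left_cross`, `x_right_cross`, `width`,
#'   `status` (one of `"ok"`, `"no_left_cross"`, `"no_right_cross"`,
#'   `"nonpositive_width"`).
#' @export
#' @examples
#' find_crossings(list(mu_left = -15, beta_left = 0.3,
#'                     mu_right = 15, beta_right = 0.3))
find_crossings <- function(params, search_range = c(-90, 90)) {
  p <- if (inherits(params, "cone_fit")) as.list(params$params) else
    as.list(params)
  grid <- seq(search_range[1], search_range[2], by = 0.1)

  # The relevant crossing has a direction: at the cone's left edge "left"
  # responses fall through the middle curve (descending difference), at its
  # right edge "right" responses rise through it (ascending). Tail leakage
  # of the opposite curve can create a second, oppositely-signed crossing,
  # which is ignored. Among admissible crossings the one nearest 0 is used.
  pm_grid <- predict_mat(p$mu_left, p$beta_left, p$mu_right, p$beta_right,
                         grid)

  locate <- function(v, diff_fun, direction) {
    s <- sign(v)
    step <- s[-1] - s[-length(s)]
    hits <- if (direction > 0) which(step > 0) else which(step < 0)
    if (length(hits) == 0) return(NA_real_)
    mids <- (grid[hits] + grid[hits + 1]) / 2
    i <- hits[which.min(abs(mids))]
    uniroot(diff_fun, c(grid[i], grid[i + 1]), tol = 1e-6)$root
  }

  pl_minus_pm <- function(x) {
    pm <- predict_mat(p$mu_left, p$beta_left, p$mu_right, p$beta_right, x)
    pm[, 1] - pm[, 2]
  }
  pr_minus_pm <- function(x) {
    pm <- predict_mat(p$mu_left, p$beta_left, p$mu_right, p$beta_right, x)
    pm[, 3] - pm[, 2]
  }

  x_l <- locate(pm_grid[, 1] - pm_grid[, 2], pl_minus_pm, direction = -1)
  x_r <- locate(pm_grid[, 3] - pm_grid[, 2], pr_minus_pm, direction = 1)
  status <- if (is.na(x_l)) "no_left_cross" else if (is.na(x_r))
    "no_right_cross" else if (x_r - x_l <= 0) "nonpositive_width" else "ok"
  tibble::tibble(
    x_left_cross = x_l, x_right_cross = x_r,
    width = if (status == "ok") x_r - x_l else NA_real_,
    status = status
  )
}

#' Cone widths for every participant and condition
#'
#' Runs the joint logistic fit and the crossing solver on each
#' participant-condition block of an aggregated count table. A block whose
#' fit is rejected, or whose crossings are missing or yield a non-positive
#' width, is marked `fit_ok = FALSE`; because the cone-width statistic is
#' then undefined for that participant, `participant_fit_ok` flags the
#' whole participant for exclusion in every condition.
#'
#' @param counts Output of [aggregate_counts()] (any number of
#'   participants and conditions).
#' @param control A [fit_control()].
#' @return A tibble with one row per participant and condition:
#'   `width`, crossing azimuths, fitted parameters, `loss`,
#'   `n_restarts_used`, `status`, `fit_ok`, `participant_fit_ok`.
#' @export
cone_widths <- function(counts, control = fit_control()) {
  if (nrow(counts) == 0) {
    return(tibble::tibble(
      participant_id = character(), ethnicity = character(),
      condition = character(), width = numeric(),
      x_left_cross = numeric(), x_right_cross = numeric(),
      mu_left = numeric(), beta_left = numeric(),
      mu_right = numeric(), beta_right = numeric(),
      loss = numeric(), n_restarts_used = integer(),
      status = character(), fit_ok = logical(),
      participant_fit_ok = logical()
    ))
  }
  groups <- split(
    counts,
    list(counts$participant_id, counts$condition),
    drop = TRUE
  )
  rows <- lapply(groups, function(tbl) {
    fit <- tryCatch(
      fit_joint(tbl, control = control, on_failure = "return"),
      gazecone_data_error = function(e) NULL
    )
    base <- tibble::tibble(
      participant_id = tbl$participant_id[1],
      ethnicity = tbl$ethnicity[1],
      condition = tbl$condition[1]
    )
    if (is.null(fit)) {
      return(dplyr::bind_cols(base, tibble::tibble(
        width = NA_real_, x_left_cross = NA_real_, x_right_cross = NA_real_,
        mu_left = NA_real_, beta_left = NA_real_, mu_right = NA_real_,
        beta_right = NA_real_, loss = NA_real_, n_restarts_used = 0L,
        status = "insufficient_data", fit_ok = FALSE
      )))
    }
    cr <- fit$crossings
    dplyr::bind_cols(base, tibble::tibble(
      width = cr$width, x_left_cross = cr$x_left_cross,
      x_right_cross = cr$x_right_cross,
      mu_left = fit$params[["mu_left"]], beta_left = fit$params[["beta_left"]],
      mu_right = fit$params[["mu_right"]],
      beta_right = fit$params[["beta_right"]],
      loss = fit$loss, n_restarts_used = fit$n_restarts_used,
      status = if (fit$converged) "ok" else
        paste(fit$reasons, collapse = ","),
      fit_ok = fit$converged
    ))
  })
  res <- dplyr::arrange(dplyr::bind_rows(rows), .data$participant_id,
                        .data$condition)
  res |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(participant_fit_ok = all(.data$fit_ok)) |>
    dplyr::ungroup()
}
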