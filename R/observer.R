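#' Generative observer parameters
#'
#' Defines the synthetic 3AFC observer used by [simulate_cohort()]. The
#' observer carries two category boundaries (degrees azimuth): below
#' `boundary_left` the "left" response dominates, above `boundary_right`
#' the "right" response does, and the middle category is the complement.
#' Category probabilities follow the same opposed-logistic family the
#' analysis fits, mixed with a small lapse rate (stimulus-independent
#' uniform responding) as deliberate mild misspecification.
#'
#' Visual conditions widen the boundaries symmetrically, moving each
#' outward: any face (versus the audio-only baseline) adds `face_widening`
#' degrees per boundary, and a face with direct gaze additionally adds
#' `capture_widening` degrees per boundary. With the defaults the implied
#' cone-width difference between direct-gaze and eyes-closed conditions is
#' about 3 degrees, and between eyes-closed and baseline about 4 degrees,
#' the magnitudes typical of visual-capture effects on central sound
#' localization.
#'
#' @param boundary_left,boundary_right Category boundaries in degrees,
#'   `boundary_left < boundary_right`. Defaults -10 and +10.
#' @param slope Steepness of the category transitions, per degree (> 0).
#' @param lapse_rate Probability in \[0, 0.1\] of a uniformly random
#'   response.
#' @param capture_widening Extra widening (degrees per boundary) for the
#'   direct-gaze condition relative to eyes closed.
#' @param face_widening Widening (degrees per boundary) of either face
#'   condition relative to the audio-only baseline.
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params()
observer_params <- function(boundary_left = -10, boundary_right = 10,
                            slope = 0.25, lapse_rate = 0.02,
                            capture_widening = 1.5, face_widening = 2) {
  if (!is.numeric(boundary_left) || !is.numeric(boundary_right) ||
      boundary_left >= boundary_right) {
    abort("boundary_left must be strictly less than boundary_right",
          class = "gazecone_parameter_error")
  }
  if (slope <= 0) {
    abort("slope must be positive", class = "gazecone_parameter_error")
  }
  if (lapse_rate < 0 || lapse_rate > 0.1) {
    abort("lapse_rate must lie in [0, 0.1]", class = "gazecone_parameter_error")
  }
  if (capture_widening < 0 || face_widening < 0) {
    abort("condition widenings must be non-negative",
          class = "gazecone_parameter_error")
  }
  structure(
    list(boundary_left = boundary_left, boundary_right = boundary_right,
         slope = slope, lapse_rate = lapse_rate,
         capture_widening = capture_widening, face_widening = face_widening),
    class = "observer_params"
  )
}

# Condition-adjusted boundaries: faces widen both boundaries outward.
condition_boundaries <- function(params, condition) {
  widen <- params$face_widening * (condition != "baseline") +
    params$capture_widening * (condition == "direct_gaze")
  list(left = params$boundary_left - widen,
       right = params$boundary_right + widen)
}

# Lapse-free category probability matrix (cols left, middle, right) for
# boundaries (bl, br) and common slope; shared by the generator and the
# ground-truth oracle.
category_prob_matrix <- function(bl, br, slope, azimuth_deg) {
  p_left <- plogis(-slope * (azimuth_deg - bl))
  p_right <- plogis(slope * (azimuth_deg - br))
  p_middle <- 1 - p_left - p_right
  cbind(left = p_left, middle = p_middle, right = p_right)
}

#' Category response probabilities of the synthetic observer
#'
#' Evaluates the generative model at given azimuths: the probability of a
#' "left", "middle" and "right" response under one visual condition,
#' including the observer's lapse rate, which mixes in a uniform
#' (1/3, 1/3, 1/3) component.
#'
#' @param params An [observer_params()] object.
#' @param condition One of `"baseline"`, `"eyes_closed"`, `"direct_gaze"`.
#' @param azimuth_deg Numeric vector of azimuths in degrees.
#' @return A tibble with columns `azimuth_deg`, `p_left`, `p_middle`,
#'   `p_right`; rows sum to 1.
#' @export
#' @examples
#' category_probabilities(observer_params(), "direct_gaze", design_azimuths())
category_probabilities <- function(params, condition, azimuth_deg) {
  stopifnot(inherits(params, "observer_params"))
  condition <- match.arg(condition, CONDITIONS)
  b <- condition_boundaries(params, condition)
  pm <- category_prob_matrix(b$left, b$right, params$slope, azimuth_deg)
  if (any(pm[, "middle"] < -1e-12)) {
    abort(paste0("observer parameters imply a negative middle-response ",
                 "probability at azimuth ",
                 azimuth_deg[which(pm[, "middle"] < -1e-12)[1]]),
          class = "gazecone_parameter_error")
  }
  pm[, "middle"] <- pmax(pm[, "middle"], 0)
  lam <- params$lapse_rate
  pm <- (1 - lam) * pm + lam / 3
  tibble::tibble(azimuth_deg = azimuth_deg,
                 p_left = as.numeric(pm[, "left"]),
                 p_middle = as.numeric(pm[, "middle"]),
                 p_right = as.numeric(pm[, "right"]))
}

# True cone width of an observer in one condition, via the same crossing
# solver used on fitted curves. The lapse mixes the same constant into
# every category, so p_left = p_middle crossings are unaffected by it.
true_cone_width <- function(params, condition, search_range = c(-90, 90)) {
  b <- condition_boundaries(params, condition)
  fp <- list(mu_left = b$left, beta_left = params$slope,
             mu_right = b$right, beta_right = params$slope)
  cr <- find_crossings(fp, search_range = search_range)
  if (cr$status != "ok") return(NA_real_)
  cr$width
}
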