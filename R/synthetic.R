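# Treatment presets: generating parameters for the three acclimation regimes
# (well-watered WW, transient deficit TD, sustained deficit SD). These carry
# the study's reported per-treatment values for convenience as generator
# presets — they are parameter sets, not data.
VC_PRESETS <- list(
  WW = list(alpha = 4.32, plc50 = -1.31),  # slope 108 %/MPa
  TD = list(alpha = 4.12, plc50 = -1.18),  # slope 103 %/MPa
  SD = list(alpha = 4.64, plc50 = -1.09)   # slope 116 %/MPa
)
PV_PRESETS <- list(
  WW = list(pi100 = -1.02, epsilon = 6.07),
  TD = list(pi100 = -1.07, epsilon = 8.16),
  SD = list(pi100 = -1.10, epsilon = 7.17)
)
VESSEL_PRESETS <- list(
  # log-normal diameter parameters chosen so the arithmetic mean diameter
  # matches the reported per-treatment means at a realistic spread
  WW = list(mean_diameter = 20.6, log_sd = 0.35, n = 424, leaf_area = 168.9,
            petiole_area = 5.58),
  TD = list(mean_diameter = 18.3, log_sd = 0.35, n = 468, leaf_area = 155.9,
            petiole_area = 5.47),
  SD = list(mean_diameter = 20.0, log_sd = 0.35, n = 336, leaf_area = 119.4,
            petiole_area = 4.33)
)

#' Generator presets for the three acclimation treatments
#'
#' Returns the per-treatment generating parameters used by the synthetic-data
#' module: vulnerability-curve (`alpha`, `plc50`), pressure-volume (`pi100`,
#' `epsilon`) and vessel-population settings for the well-watered (WW),
#' transient-deficit (TD) and sustained-deficit (SD) regimes.
#'
#' @param treatment One of `"WW"`, `"TD"`, `"SD"`.
#' @return Named list with elements `vc`, `pv`, `vessels`.
#' @export
treatment_preset <- function(treatment = c("WW", "TD", "SD")) {
  treatment <- match.arg(treatment)
  list(vc = VC_PRESETS[[treatment]], pv = PV_PRESETS[[treatment]],
       vessels = VESSEL_PRESETS[[treatment]])
}

#' Simulate vulnerability-curve observations
#'
#' Forward model: stem water potentials drawn uniformly over `psi_range`,
#' PLC from the sigmoid \eqn{100/(1 + e^{\alpha(\Psi_s - PLC_{50})})} plus
#' additive Gaussian noise (SD `noise_sd` PLC points), clamped to \[0, 100\].
#'
#' @param alpha Sigmoid steepness, MPa-1 (> 0).
#' @param plc50 Midpoint, MPa (< 0).
#' @param psi_range Range of stem water potentials sampled, MPa (length 2).
#' @param n Number of observations.
#' @param noise_sd Gaussian noise SD in PLC points (>= 0).
#' @param seed Integer seed (optional); identical inputs give identical data.
#' @param treatment Label attached to the observations.
#' @return Data frame with columns `psi_stem`, `plc`, `treatment`, `shoot_id`
#'   and a `"truth"` attribute carrying the generating parameters.
#' @export
simulate_vc <- function(alpha, plc50, psi_range = c(-2.2, -0.2), n = 36,
                        noise_sd = 5, seed = NULL, treatment = "synthetic") {
  stopifnot(alpha > 0, length(psi_range) == 2, noise_sd >= 0, n >= 1)
  psi_range <- sort(psi_range)
  if (!is.null(seed)) set.seed(seed)
  psi <- stats::runif(n, psi_range[1], psi_range[2])
  plc_true <- vc_sigmoid(psi, alpha, plc50)
  plc_obs <- pmin(pmax(plc_true + stats::rnorm(n, 0, noise_sd), 0), 100)
  out <- data.frame(psi_stem = psi, plc = plc_obs, treatment = treatment,
                    shoot_id = sprintf("shoot%02d", seq_len(n)))
  attr(out, "truth") <- list(alpha = alpha, plc50 = plc50,
                             slope_at_p50 = 25 * alpha, noise_sd = noise_sd)
  out
}

#' Simulate a pressure-volume dehydration curve
#'
#' Forward model with constant bulk modulus and Boyle-van't Hoff osmotic
#' dilution, on a descending RWC grid:
#' \deqn{R_s = (RWC/100 - a_f)/(1 - a_f), \quad \pi = \pi_{100}/R_s,}
#' \deqn{P = \max(0,\, -\pi_{100} - \epsilon (1 - R_s)), \quad \Psi = P + \pi.}
#' Fresh weights follow from the RWC definition; multiplicative Gaussian
#' noise of relative SD `noise_rel` is applied to the series fresh weights
#' and to \eqn{\Psi}. The analytic turgor loss point of this model,
#' \eqn{\Psi_{TLP} = \pi_{100}\,\epsilon/(\epsilon + \pi_{100})}, is recorded
#' as ground truth.
#'
#' @param pi100 Osmotic potential at full turgor, MPa (< 0).
#' @param epsilon Bulk modulus of elasticity, MPa (> 0).
#' @param apoplastic_fraction Apoplastic water fraction in \[0, 1).
#' @param turgid_weight,dry_weight Leaf weights, g.
#' @param n Number of observations on the RWC grid.
#' @param rwc_min Driest RWC on the grid (percent).
#' @param noise_rel Relative (multiplicative) noise SD (>= 0).
#' @param seed Integer seed (optional).
#' @param leaf_id,treatment Labels.
#' @return A [pv_curve()] whose `"truth"` attribute carries the generating
#'   parameters and the analytic `psi_tlp` / `rwc_tlp`.
#' @export
simulate_pv <- function(pi100, epsilon, apoplastic_fraction = 0,
                        turgid_weight = 2, dry_weight = 0.5, n = 15,
                        rwc_min = 78, noise_rel = 0, seed = NULL,
                        leaf_id = "synthetic", treatment = "synthetic") {
  stopifnot(pi100 < 0, epsilon > 0, apoplastic_fraction >= 0,
            apoplastic_fraction < 1, noise_rel >= 0, n >= 4)
  af <- apoplastic_fraction
  rs_tlp <- 1 + pi100 / epsilon
  if (rs_tlp <= 0 || 100 * (af + rs_tlp * (1 - af)) <= rwc_min) {
    warning("no turgor phase on the RWC grid (epsilon <= -pi100 or TLP below grid)",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rwc <- seq(100, rwc_min, length.out = n)
  rs <- (rwc / 100 - af) / (1 - af)
  osmotic <- pi100 / rs
  turgor <- pmax(0, -pi100 - epsilon * (1 - rs))
  psi <- turgor + osmotic
  fresh <- dry_weight + (turgid_weight - dry_weight) * rwc / 100
  if (noise_rel > 0) {
    fresh <- fresh * (1 + stats::rnorm(n, 0, noise_rel))
    psi <- psi * (1 + stats::rnorm(n, 0, noise_rel))
    psi <- pmin(psi, 0)
  }
  curve <- suppressWarnings(
    pv_curve(data.frame(fresh_weight = fresh, psi_leaf = psi),
             turgid_weight = turgid_weight, dry_weight = dry_weight,
             leaf_id = leaf_id, treatment = treatment))
  attr(curve, "truth") <- list(
    pi100 = pi100, epsilon = epsilon, apoplastic_fraction = af,
    psi_tlp = pi100 * epsilon / (epsilon + pi100),
    rwc_tlp = 100 * (af + rs_tlp * (1 - af)), noise_rel = noise_rel)
  curve
}

#' Simulate a gas-exchange daily course with known conductances
#'
#' Inverts the Ohm's-law conductance definitions: for a transpiration
#' profile E(t),
#' \deqn{\Psi_l = \Psi_{PD} - E/k_{plant}, \qquad \Psi_s = \Psi_l + E/k_{leaf}.}
#' Multiplicative Gaussian noise of relative SD `noise_rel` is applied to the
#' observed E and to each water-potential drop (the plant-path and leaf
#' segments) — i.e. measurement error scales with the measured gradient
#' components. Stomatal conductance is E divided by a fixed nominal
#' vapor-pressure deficit (mole-fraction form), since no stomatal model is
#' needed for conductance recovery.
#'
#' @param k_leaf_true,k_plant_true Generating conductances,
#'   mmol m-2 s-1 MPa-1 (> 0; `k_leaf_true >= k_plant_true` keeps
#'   \eqn{\Psi_s \le \Psi_{PD}}).
#' @param psi_predawn Pre-dawn water potential, MPa.
#' @param E_profile Transpiration time series, mmol m-2 s-1. Default: a
#'   half-sine daily course peaking at `E_max` over `n` points.
#' @param times Time of day (hours) for the default profile.
#' @param E_max Peak transpiration for the default profile.
#' @param n Number of time points for the default profile.
#' @param noise_rel Relative noise SD (>= 0).
#' @param vpd Nominal vapor-pressure deficit, kPa, for the gs proxy.
#' @param seed Integer seed (optional).
#' @param treatment Label.
#' @return Data frame of gas-exchange records (`time`, `E`, `gs`, `psi_leaf`,
#'   `psi_stem`, `psi_predawn`, `treatment`, `theta`) with a `"truth"`
#'   attribute.
#' @export
simulate_daily_course <- function(k_leaf_true = 30, k_plant_true = 10,
                                  psi_predawn = -0.2, E_profile = NULL,
                                  times = NULL, E_max = 4, n = 13,
                                  noise_rel = 0, vpd = 1.5, seed = NULL,
                                  treatment = "synthetic") {
  stopifnot(k_leaf_true > 0, k_plant_true > 0, noise_rel >= 0)
  if (is.null(E_profile)) {
    if (is.null(times)) times <- seq(6, 18, length.out = n)
    E_profile <- E_max * sin(pi * (times - min(times)) /
                               (max(times) - min(times)))
    E_profile[E_profile < 1e-9 * E_max] <- 0  # exact zeros at the day edges
  } else if (is.null(times)) {
    times <- seq_along(E_profile)
  }
  m <- length(E_profile)
  if (!is.null(seed)) set.seed(seed)
  drop_plant <- E_profile / k_plant_true
  drop_leaf <- E_profile / k_leaf_true
  E_obs <- E_profile
  if (noise_rel > 0) {
    drop_plant <- drop_plant * (1 + stats::rnorm(m, 0, noise_rel))
    drop_leaf <- drop_leaf * (1 + stats::rnorm(m, 0, noise_rel))
    E_obs <- E_obs * (1 + stats::rnorm(m, 0, noise_rel))
  }
  psi_leaf <- psi_predawn - drop_plant
  psi_stem <- psi_leaf + drop_leaf
  gs <- (E_obs / 1000) / (vpd / 101.325)
  out <- data.frame(time = times, E = E_obs, gs = gs, psi_leaf = psi_leaf,
                    psi_stem = psi_stem, psi_predawn = psi_predawn,
                    treatment = treatment, theta = NA_real_)
  attr(out, "truth") <- list(k_leaf = k_leaf_true, k_plant = k_plant_true,
                             psi_predawn = psi_predawn, noise_rel = noise_rel)
  out
}

#' Simulate a vessel population
#'
#' Diameters are drawn log-normal (the canonical right-skewed conduit-size
#' distribution); lumen areas are back-computed from the diameters.
#'
#' @param log_mean,log_sd Mean and SD of log-diameter (um on the log scale).
#' @param n Number of vessels (>= 1).
#' @param seed Integer seed (optional).
#' @param mean_diameter Convenience alternative to `log_mean`: the target
#'   arithmetic mean diameter, um; `log_mean` is then
#'   `log(mean_diameter) - log_sd^2/2`.
#' @return Data frame with `diameter_um`, `lumen_area_um2`, `bundle_id` and a
#'   `"truth"` attribute.
#' @export
simulate_vessels <- function(log_mean = NULL, log_sd = 0.35, n = 400,
                             seed = NULL, mean_diameter = NULL) {
  stopifnot(n >= 1, log_sd >= 0)
  if (is.null(log_mean)) {
    if (is.null(mean_diameter)) {
      stop("provide `log_mean` or `mean_diameter`", call. = FALSE)
    }
    log_mean <- log(mean_diameter) - log_sd^2 / 2
  }
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rlnorm(n, log_mean, log_sd)
  out <- data.frame(diameter_um = d, lumen_area_um2 = pi * (d / 2)^2,
                    bundle_id = sprintf("b%02d", 1 + (seq_len(n) - 1) %% 25))
  attr(out, "truth") <- list(log_mean = log_mean, log_sd = log_sd,
                             mean_diameter = exp(log_mean + log_sd^2 / 2))
  out
}

#' Simulate a drought-response study with a known leaf-conductance decline
#'
#' Builds gas-exchange records across a range of stem water potentials in
#' which the underlying leaf conductance declines sigmoidally,
#' \eqn{k_{leaf}(\Psi_s) = k_{max}(1 - L(\Psi_s)/100)} with
#' \eqn{L(\Psi_s) = 100/(1 + e^{\alpha_k(\Psi_s - \Psi_{50,k})})}. Together
#' with vulnerability-curve data generated at a drier `plc50`, this
#' constructs a study whose leaf-conductance decline midpoint is wetter than
#' its embolism midpoint by a known margin — the decoupling scenario the
#' pipeline quantifies.
#'
#' @param k_leaf_max Leaf conductance in the absence of decline,
#'   mmol m-2 s-1 MPa-1.
#' @param alpha_k,psi50_k Decline-sigmoid steepness (MPa-1) and midpoint (MPa).
#' @param psi_range Stem water-potential range sampled, MPa.
#' @param n Number of records.
#' @param E Transpiration assigned to each record, mmol m-2 s-1.
#' @param noise_rel Relative noise SD applied to the leaf-segment drop.
#' @param vpd Nominal vapor-pressure deficit, kPa, for the gs proxy.
#' @param seed Integer seed (optional).
#' @param treatment Label.
#' @return Data frame of gas-exchange records with a `"truth"` attribute
#'   (`k_leaf_max`, `alpha_k`, `psi50_k`).
#' @export
simulate_decline_study <- function(k_leaf_max = 30, alpha_k = 6,
                                   psi50_k = -0.5, psi_range = c(-1.2, -0.05),
                                   n = 120, E = 2, noise_rel = 0, vpd = 1.5,
                                   seed = NULL, treatment = "synthetic") {
  stopifnot(k_leaf_max > 0, alpha_k > 0, noise_rel >= 0)
  psi_range <- sort(psi_range)
  if (!is.null(seed)) set.seed(seed)
  psi_stem <- stats::runif(n, psi_range[1], psi_range[2])
  loss <- vc_sigmoid(psi_stem, alpha_k, psi50_k)
  k <- k_leaf_max * (1 - loss / 100)
  drop_leaf <- E / k
  if (noise_rel > 0) drop_leaf <- drop_leaf * (1 + stats::rnorm(n, 0, noise_rel))
  psi_leaf <- psi_stem - drop_leaf
  out <- data.frame(time = NA_real_, E = E, gs = (E / 1000) / (vpd / 101.325),
                    psi_leaf = psi_leaf, psi_stem = psi_stem,
                    psi_predawn = NA_real_, treatment = treatment,
                    theta = NA_real_)
  attr(out, "truth") <- list(k_leaf_max = k_leaf_max, alpha_k = alpha_k,
                             psi50_k = psi50_k, noise_rel = noise_rel)
  out
}
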