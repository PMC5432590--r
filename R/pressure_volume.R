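#' Construct a pressure-volume curve
#'
#' Bundles a bench-dehydration series (fresh weight, leaf water potential)
#' with the turgid and dry weights needed to express it on a relative water
#' content scale.
#'
#' @param observations Data frame with columns `fresh_weight` (g, > 0) and
#'   `psi_leaf` (MPa, <= 0), ordered along dehydration.
#' @param turgid_weight Fully rehydrated leaf weight, g.
#' @param dry_weight Oven-dry weight, g. Must satisfy
#'   `turgid_weight > dry_weight > 0`.
#' @param leaf_id,treatment Optional labels.
#' @return Object of class `pv_curve`.
#' @export
pv_curve <- function(observations, turgid_weight, dry_weight,
                     leaf_id = NA_character_, treatment = NA_character_) {
  stopifnot(is.data.frame(observations),
            all(c("fresh_weight", "psi_leaf") %in% names(observations)))
  if (!is.finite(turgid_weight) || !is.finite(dry_weight) ||
      dry_weight <= 0 || turgid_weight <= dry_weight) {
    stop("need turgid_weight > dry_weight > 0", call. = FALSE)
  }
  if (any(observations$fresh_weight <= 0)) {
    stop("fresh weights must be positive", call. = FALSE)
  }
  if (any(observations$psi_leaf > 0)) {
    stop("leaf water potentials must be <= 0 MPa", call. = FALSE)
  }
  over <- observations$fresh_weight > turgid_weight
  if (any(over)) {
    warning(sprintf("%d observation(s) with fresh weight above turgid weight",
                    sum(over)), call. = FALSE)
  }
  if (is.unsorted(rev(observations$fresh_weight), strictly = FALSE)) {
    # noise can produce local weight increases during dehydration; flag only
    warning("fresh weights are not monotonically non-increasing", call. = FALSE)
  }
  structure(list(observations = observations, turgid_weight = turgid_weight,
                 dry_weight = dry_weight, leaf_id = leaf_id,
                 treatment = treatment),
            class = "pv_curve")
}

#' Relative water content of a pressure-volume series
#'
#' \deqn{RWC_i = 100 (FW_i - DW) / (TW - DW)} for each observation of the
#' curve. Values above 100 (over-rehydration or weighing noise) are clipped
#' to 100 and flagged via the `"clipped"` attribute.
#'
#' @param curve A [pv_curve()].
#' @return Numeric vector of RWC (percent), same order as the observations.
#' @export
compute_rwc <- function(curve) {
  stopifnot(inherits(curve, "pv_curve"))
  rwc <- 100 * (curve$observations$fresh_weight - curve$dry_weight) /
    (curve$turgid_weight - curve$dry_weight)
  clipped <- rwc > 100
  if (any(clipped)) {
    warning(sprintf("%d RWC value(s) above 100 clipped", sum(clipped)),
            call. = FALSE)
  }
  out <- pmin(rwc, 100)
  attr(out, "clipped") <- clipped
  out
}

# Longest qualifying driest-end run in (x = 100 - RWC, y = -1/psi) space.
# Runs grow from the `min_points` driest points toward wetter ones; a run of
# m > min_points points qualifies when its refitted line has R^2 >= r2_min and
# the wettest (incremental) point's residual is within resid_mult x the line's
# residual SD (plus a small absolute floor so exact, zero-noise lines pass).
find_osmotic_run <- function(x, y, min_points = 4, r2_min = 0.99,
                             resid_mult = 2) {
  n <- length(x)
  best <- NULL
  for (m in min_points:n) {
    i <- seq_len(m)
    fit <- stats::lm(y[i] ~ x[i])
    res <- stats::resid(fit)
    sst <- sum((y[i] - mean(y[i]))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    sdr <- stats::sd(res)
    tol <- resid_mult * sdr + 1e-8 * max(abs(y[i]))
    qualifies <- if (m == min_points) TRUE else
      (is.finite(r2) && r2 >= r2_min && abs(res[m]) <= tol)
    if (qualifies) {
      best <- list(m = m, coef = stats::coef(fit), r2 = r2)
    }
  }
  best
}

#' Extract pressure-volume parameters from a dehydration curve
#'
#' Turner-style analysis of a leaf pressure-volume curve. The series is
#' transformed to \eqn{x = 100 - RWC}, \eqn{y = -1/\Psi}; beyond the turgor
#' loss point the osmotic relation \eqn{\Psi = \pi_{100}/R_s} is a straight
#' line in this space. The algorithm:
#' \enumerate{
#'   \item finds the maximal driest-end run of points that is linear (run
#'     detection rule documented under Details);
#'   \item reads \eqn{\pi_{100}} off the osmotic line at RWC = 100
#'     (\eqn{\pi_{100} = -1/c_0});
#'   \item places the turgor loss point at the wettest point accepted into
#'     the osmotic line, evaluated on the line;
#'   \item estimates the apoplastic water fraction from the RWC at which the
#'     osmotic line extrapolates to \eqn{1/\Psi = 0}, clamped at 0;
#'   \item computes turgor pressure \eqn{P_i = \Psi_i - \pi_i} (osmotic
#'     component from the line) for points wetter than the turgor loss point
#'     and takes \eqn{\epsilon} as the slope of \eqn{P} against symplastic
#'     relative water content \eqn{R_s = (RWC/100 - a_f)/(1 - a_f)} — a
#'     single mean bulk modulus over the turgor phase.
#' }
#'
#' @details The linear region rule: starting from the `min_line_points`
#' driest points, runs are extended toward wetter points; an extended run
#' qualifies while its refitted line keeps \eqn{R^2 \ge} `r2_min` and the
#' incremental point's residual stays within `resid_mult` times the line's
#' residual SD. The longest qualifying run wins. Observations with
#' \eqn{\Psi = 0} (full turgor) are unusable in the transform and are set
#' aside, but still contribute to the turgor-phase regression. Because the
#' transform \eqn{y = -1/\Psi} weights wet-end points heavily, no
#' reweighting is applied (standard practice; see the package vignette for
#' the implied limitation).
#'
#' @param curve A [pv_curve()].
#' @param min_line_points Minimum number of points in the osmotic line.
#' @param r2_min Minimum R-squared for an extended osmotic run.
#' @param resid_mult Residual tolerance multiplier for the incremental point.
#' @return Object of class `pv_fit`: list with `pi100` (MPa), `epsilon`
#'   (MPa; NA when fewer than 3 turgor-phase points), `psi_tlp` (MPa),
#'   `rwc_tlp` (percent), `apoplastic_fraction`, `n_points_osmotic_line`,
#'   `r_squared_osmotic_line`, plus diagnostics (`osmotic_intercept`,
#'   `osmotic_slope`, `n_turgor_points`, `leaf_id`, `treatment`).
#' @export
fit_pv <- function(curve, min_line_points = 4, r2_min = 0.99, resid_mult = 2) {
  stopifnot(inherits(curve, "pv_curve"))
  rwc <- as.numeric(compute_rwc(curve))
  psi <- curve$observations$psi_leaf
  usable <- is.finite(rwc) & is.finite(psi)
  if (sum(usable) < 8) {
    stop("at least 8 finite observations are required for a PV fit",
         call. = FALSE)
  }
  rwc <- rwc[usable]; psi <- psi[usable]
  transformable <- psi < 0
  x_all <- 100 - rwc
  y_all <- -1 / psi

  ord <- order(x_all[transformable], decreasing = TRUE)  # driest first
  x <- x_all[transformable][ord]
  y <- y_all[transformable][ord]
  if (length(x) < min_line_points + 1) {
    stop("too few transformable points (Psi < 0) for osmotic-line detection",
         call. = FALSE)
  }
  run <- find_osmotic_run(x, y, min_line_points, r2_min, resid_mult)
  if (is.null(run)) {
    stop(sprintf(
      "no linear osmotic region found (n = %d, R^2 threshold %.3f); driest-end R^2 too low",
      length(x), r2_min), call. = FALSE)
  }
  c0 <- unname(run$coef[1])   # y at RWC = 100
  c1 <- unname(run$coef[2])   # dy/dx, negative along dehydration
  if (!is.finite(c0) || c0 <= 0 || c1 >= 0) {
    stop("degenerate osmotic line (non-positive intercept or non-negative slope)",
         call. = FALSE)
  }
  pi100 <- -1 / c0

  # apoplastic fraction: RWC at which the osmotic line extrapolates to
  # 1/Psi = 0 (x-intercept x0 = -c0/c1), as a fraction; clamped at 0
  x0 <- -c0 / c1
  af <- max(0, (100 - x0) / 100)

  # turgor loss point: wettest point accepted into the osmotic line,
  # evaluated on the line
  x_w <- x[run$m]
  y_w <- c0 + c1 * x_w
  psi_tlp <- -1 / y_w
  rwc_tlp <- 100 - x_w

  # turgor phase: all points wetter than the TLP point (including Psi = 0)
  turgor <- x_all < x_w
  epsilon <- NA_real_
  n_turgor <- sum(turgor)
  if (n_turgor >= 3) {
    pi_line <- -1 / (c0 + c1 * x_all[turgor])
    P <- psi[turgor] - pi_line
    rs <- (rwc[turgor] / 100 - af) / (1 - af)
    epsilon <- unname(stats::coef(stats::lm(P ~ rs))[2])
  } else {
    warning("fewer than 3 points in the turgor phase; epsilon not estimated",
            call. = FALSE)
  }

  structure(list(
    pi100 = pi100, epsilon = epsilon, psi_tlp = psi_tlp, rwc_tlp = rwc_tlp,
    apoplastic_fraction = af,
    n_points_osmotic_line = run$m,
    r_squared_osmotic_line = run$r2,
    osmotic_intercept = c0, osmotic_slope = c1, n_turgor_points = n_turgor,
    leaf_id = curve$leaf_id, treatment = curve$treatment
  ), class = "pv_fit")
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("Pressure-volume parameters\n")
  cat(sprintf("  pi100 = %.3f MPa   epsilon = %s MPa   Psi_TLP = %.3f MPa\n",
              x$pi100,
              if (is.na(x$epsilon)) "NA" else sprintf("%.2f", x$epsilon),
              x$psi_tlp))
  cat(sprintf("  RWC_TLP = %.1f %%   apoplastic fraction = %.3f\n",
              x$rwc_tlp, x$apoplastic_fraction))
  cat(sprintf("  osmotic line: %d points, R^2 = %.4f\n",
              x$n_points_osmotic_line, x$r_squared_osmotic_line))
  invisible(x)
}

#' Summarize PV fits as a per-treatment table
#'
#' Means and standard errors of the pressure-volume parameters by treatment,
#' in the shape of a standard PV-parameter table (pi100, epsilon, Psi_TLP,
#' RWC_TLP).
#'
#' @param fits List of [fit_pv()] results.
#' @return Data frame with one row per treatment.
#' @export
pv_parameter_table <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "pv_fit")))
  d <- do.call(rbind, lapply(fits, function(f) {
    data.frame(treatment = f$treatment, pi100 = f$pi100, epsilon = f$epsilon,
               psi_tlp = f$psi_tlp, rwc_tlp = f$rwc_tlp,
               apoplastic_fraction = f$apoplastic_fraction)
  }))
  se <- function(v) if (sum(is.finite(v)) < 2) NA_real_ else
    stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  out <- do.call(rbind, lapply(split(d, d$treatment), function(g) {
    num <- g[, -1]
    data.frame(treatment = g$treatment[1], n = nrow(g),
               as.list(setNames(colMeans(num, na.rm = TRUE),
                                paste0(names(num), "_mean"))),
               as.list(setNames(vapply(num, se, 0), paste0(names(num), "_se"))))
  }))
  rownames(out) <- NULL
  out
}

#' Read pressure-volume curves from a long-format CSV
#'
#' Expects columns `leaf_id`, `fresh_weight`, `psi_leaf`, `turgid_weight`,
#' `dry_weight` and optionally `treatment`; one row per dehydration
#' observation, metadata repeated within a leaf.
#'
#' @param file Path to a CSV file.
#' @return List of [pv_curve()] objects, one per `leaf_id`.
#' @export
read_pv_curves <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("leaf_id", "fresh_weight", "psi_leaf", "turgid_weight", "dry_weight")
  if (!all(req %in% names(x))) {
    stop("PV file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(x, x$leaf_id), function(d) {
    pv_curve(d[, c("fresh_weight", "psi_leaf")],
             turgid_weight = d$turgid_weight[1], dry_weight = d$dry_weight[1],
             leaf_id = d$leaf_id[1],
             treatment = if ("treatment" %in% names(d)) d$treatment[1] else NA)
  })
}
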