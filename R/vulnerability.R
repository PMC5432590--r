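#' @keywords internal
vc_sigmoid <- function(psi_stem, alpha, plc50, plc_max = 100) {
  plc_max / (1 + exp(alpha * (psi_stem - plc50)))
}

vc_params <- function(model) {
  if (inherits(model, "vc_fit")) {
    list(alpha = model$alpha, plc50 = model$plc50, plc_max = model$plc_max)
  } else if (is.list(model) && all(c("alpha", "plc50") %in% names(model))) {
    list(alpha = model$alpha, plc50 = model$plc50,
         plc_max = if (is.null(model$plc_max)) 100 else model$plc_max)
  } else {
    stop("`model` must be a vc_fit or a list with elements alpha and plc50",
         call. = FALSE)
  }
}

#' Predict PLC from a fitted vulnerability curve
#'
#' Evaluates the sigmoidal vulnerability curve
#' \deqn{PLC(\Psi_s) = PLC_{max} / (1 + e^{\alpha(\Psi_s - PLC_{50})})}
#' (default \eqn{PLC_{max} = 100}). PLC increases strictly as the stem water
#' potential becomes more negative and is bounded in (0, `plc_max`).
#'
#' @param model A [fit_vc()] result, or a list with elements `alpha`
#'   (MPa-1, > 0) and `plc50` (MPa, < 0) and optionally `plc_max`.
#' @param psi_stem Stem water potential(s), MPa.
#' @return Predicted PLC (percent).
#' @examples
#' predict_plc(list(alpha = 4.32, plc50 = -1.31), -1.31)  # 50
#' @export
predict_plc <- function(model, psi_stem) {
  p <- vc_params(model)
  vc_sigmoid(psi_stem, p$alpha, p$plc50, p$plc_max)
}

#' Stem water potential at a given PLC level
#'
#' Closed-form inversion of the sigmoidal vulnerability curve:
#' \deqn{\Psi(L) = PLC_{50} + \ln((PLC_{max} - L)/L)/\alpha.}
#' `psi_at_plc(model, 50)` returns `plc50` exactly; levels 12 and 88 give the
#' conventional \eqn{\Psi_{12}} (air-entry proxy) and \eqn{\Psi_{88}}.
#'
#' @inheritParams predict_plc
#' @param level PLC level, strictly inside (0, `plc_max`).
#' @return Stem water potential, MPa.
#' @export
psi_at_plc <- function(model, level) {
  p <- vc_params(model)
  if (any(level <= 0 | level >= p$plc_max)) {
    stop("`level` must lie strictly inside (0, plc_max)", call. = FALSE)
  }
  p$plc50 + log((p$plc_max - level) / level) / p$alpha
}

#' Linearize PLC observations for regression analysis
#'
#' Applies the logit-type transform \eqn{y = \ln(100/PLC - 1)}, under which
#' the sigmoidal vulnerability curve becomes the line
#' \eqn{y = \alpha(\Psi_s - PLC_{50})}. The transform is undefined at PLC = 0
#' and 100; such observations are excluded (not winsorized) and the exclusion
#' count is reported via the `"n_excluded"` attribute.
#'
#' @param observations Data frame with at least columns `psi_stem` and `plc`.
#' @return The transformable rows with an added column `y`, and attribute
#'   `"n_excluded"` giving the number of rows dropped.
#' @export
linearize <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("psi_stem", "plc") %in% names(observations)))
  ok <- is.finite(observations$plc) & observations$plc > 0 &
    observations$plc < 100 & is.finite(observations$psi_stem)
  out <- observations[ok, , drop = FALSE]
  out$y <- log(100 / out$plc - 1)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

vc_start_values <- function(psi, plcv) {
  span <- diff(range(psi))
  if (span <= 0) span <- 1
  list(alpha = 4 / span, plc50 = psi[which.min(abs(plcv - 50))])
}

fit_vc_once <- function(psi, plcv, start, free_max = FALSE) {
  dat <- data.frame(psi = psi, plc = plcv)
  if (free_max) {
    minpack.lm::nlsLM(
      plc ~ pmax_ * 1 / (1 + exp(alpha * (psi - plc50))), data = dat,
      start = c(start, list(pmax_ = max(100, max(plcv)))),
      lower = c(alpha = 1e-6, plc50 = -Inf, pmax_ = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      plc ~ 100 / (1 + exp(alpha * (psi - plc50))), data = dat,
      start = start, lower = c(alpha = 1e-6, plc50 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
}

#' Fit a sigmoidal xylem vulnerability curve
#'
#' Nonlinear least-squares fit of
#' \deqn{PLC = 100 / (1 + e^{\alpha(\Psi_s - PLC_{50})})}
#' to (stem water potential, PLC) observations, with seeded case-resampling
#' bootstrap confidence intervals and the derived quantities
#' \eqn{\Psi_{12}}, \eqn{\Psi_{88}} and the absolute midpoint slope
#' (\eqn{25\alpha} %/MPa for the fixed-asymptote form). Starting values are
#' deterministic and data-driven: `plc50` starts at the observed
#' \eqn{\Psi_s} nearest PLC 50 and `alpha` at 4 / range(\eqn{\Psi_s}).
#'
#' With `free_max = TRUE` the upper asymptote is a third free parameter
#' (`plc_max`); the default keeps it fixed at 100, the form on which the
#' linearized treatment comparison ([compare_treatments()]) is defined.
#'
#' @param observations Data frame with columns `psi_stem` (MPa, <= 0) and
#'   `plc` (percent in \[0, 100\]).
#' @param n_bootstrap Number of bootstrap resamples for percentile confidence
#'   intervals (default 1000; 0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap resampling (optional).
#' @param free_max Free the upper asymptote instead of fixing it at 100.
#' @param conf_level Confidence level for percentile intervals.
#' @return An object of class `vc_fit`: a list with `alpha`, `plc50`,
#'   `plc_max`, `slope_at_p50`, `psi12`, `psi88`, `vcov` (of alpha, plc50),
#'   `ci` (percentile bootstrap matrix or NULL), `n_boot_ok`, `degenerate`
#'   (TRUE when all observations fall on one side of PLC 50), `n_obs`, and
#'   the fitted `model`.
#' @export
fit_vc <- function(observations, n_bootstrap = 1000, seed = NULL,
                   free_max = FALSE, conf_level = 0.95) {
  stopifnot(is.data.frame(observations),
            all(c("psi_stem", "plc") %in% names(observations)))
  obs <- observations[is.finite(observations$psi_stem) &
                        is.finite(observations$plc), , drop = FALSE]
  if (nrow(obs) < 4) {
    stop("at least 4 finite observations are required to fit a vulnerability curve",
         call. = FALSE)
  }
  if (any(obs$plc < 0 | obs$plc > 100)) {
    stop("`plc` must lie in [0, 100]", call. = FALSE)
  }
  psi <- obs$psi_stem
  plcv <- obs$plc
  degenerate <- all(plcv <= 50) || all(plcv >= 50)
  if (degenerate) {
    warning("all PLC observations lie on one side of 50; fit is poorly constrained",
            call. = FALSE)
  }
  start <- vc_start_values(psi, plcv)
  fit <- tryCatch(fit_vc_once(psi, plcv, start, free_max), error = function(e) {
    stop(sprintf(
      "vulnerability-curve fit failed (%s); starts: alpha = %.4g, plc50 = %.4g; n = %d, PLC range [%.1f, %.1f]",
      conditionMessage(e), start$alpha, start$plc50, length(psi),
      min(plcv), max(plcv)), call. = FALSE)
  })
  cf <- stats::coef(fit)
  alpha <- unname(cf["alpha"])
  plc50 <- unname(cf["plc50"])
  plc_max <- if (free_max) unname(cf["pmax_"]) else 100
  if (degenerate && (plc50 < min(psi) || plc50 > max(psi))) {
    # flat data leave the midpoint unidentified; report the deterministic
    # start (psi nearest PLC 50) rather than an arbitrary drift value
    plc50 <- start$plc50
  }
  derived <- function(a, p50, pm) {
    c(alpha = a, plc50 = p50,
      slope_at_p50 = pm * a / 4,
      psi12 = p50 + log((pm - 12) / 12) / a,
      psi88 = if (pm > 88) p50 + log((pm - 88) / 88) / a else NA_real_)
  }
  est <- derived(alpha, plc50, plc_max)

  ci <- NULL
  n_boot_ok <- 0L
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, nrow = n_bootstrap, ncol = 5,
                   dimnames = list(NULL, names(est)))
    bstart <- list(alpha = alpha, plc50 = plc50)
    n <- length(psi)
    for (b in seq_len(n_bootstrap)) {
      i <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(fit_vc_once(psi[i], plcv[i], bstart, free_max),
                     error = function(e) NULL)
      if (is.null(bf)) next
      bc <- stats::coef(bf)
      bm <- if (free_max) unname(bc["pmax_"]) else 100
      boot[b, ] <- derived(unname(bc["alpha"]), unname(bc["plc50"]), bm)
    }
    ok <- stats::complete.cases(boot)
    n_boot_ok <- sum(ok)
    if (n_boot_ok >= 10) {
      pr <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
      ci <- apply(boot[ok, , drop = FALSE], 2, stats::quantile, probs = pr)
    } else {
      warning("fewer than 10 successful bootstrap refits; no confidence intervals",
              call. = FALSE)
    }
  }

  vc <- tryCatch(stats::vcov(fit)[c("alpha", "plc50"), c("alpha", "plc50")],
                 error = function(e) matrix(NA_real_, 2, 2,
                   dimnames = list(c("alpha", "plc50"), c("alpha", "plc50"))))
  structure(list(
    alpha = alpha, plc50 = plc50, plc_max = plc_max,
    slope_at_p50 = unname(est["slope_at_p50"]),
    psi12 = unname(est["psi12"]), psi88 = unname(est["psi88"]),
    vcov = vc, ci = ci, n_boot_ok = n_boot_ok, degenerate = degenerate,
    n_obs = length(psi), residual_sd = stats::sigma(fit), model = fit
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Sigmoidal vulnerability curve",
      if (x$plc_max != 100) sprintf("(free asymptote PLC_max = %.1f)", x$plc_max),
      "\n")
  cat(sprintf("  PLC50 = %.3f MPa   alpha = %.3f MPa^-1   slope at P50 = %.1f %%/MPa\n",
              x$plc50, x$alpha, x$slope_at_p50))
  cat(sprintf("  Psi12 = %.3f MPa   Psi88 = %.3f MPa   n = %d\n",
              x$psi12, x$psi88, x$n_obs))
  if (!is.null(x$ci)) {
    cat(sprintf("  PLC50 95%% CI: [%.3f, %.3f] (%d bootstrap refits)\n",
                x$ci[1, "plc50"], x$ci[2, "plc50"], x$n_boot_ok))
  }
  if (x$degenerate) cat("  warning: degenerate data (all PLC on one side of 50)\n")
  invisible(x)
}

#' Write a fitted vulnerability curve to JSON
#'
#' @param fit A [fit_vc()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vc_json <- function(fit, path) {
  stopifnot(inherits(fit, "vc_fit"))
  out <- fit[c("alpha", "plc50", "plc_max", "slope_at_p50", "psi12", "psi88",
               "n_obs", "n_boot_ok", "degenerate")]
  if (!is.null(fit$ci)) {
    out$ci <- as.data.frame(t(fit$ci))
    out$ci$parameter <- rownames(out$ci)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare vulnerability curves between treatments
#'
#' Fits the linearized vulnerability-curve model by ordinary least squares,
#' \eqn{\ln(100/PLC - 1) = a\,\Psi_s + b}, with stem water potential,
#' treatment, and their interaction as model effects, and tests jointly
#' whether any treatment term (main effect or interaction) is non-zero.
#' Observations at PLC exactly 0 or 100 are excluded by the transform and
#' counted. Per-treatment parameters are back-solved from each treatment's
#' own line as \eqn{\alpha = a} and \eqn{PLC_{50} = -b/a}.
#'
#' @param observations Data frame with columns `psi_stem`, `plc`, `treatment`.
#' @return Object of class `vc_comparison`: list with `coefficients` (one row
#'   per treatment: `alpha`, `plc50`, `n`), `joint_test` (F statistic, df,
#'   p-value for all treatment terms), `interaction_test` (the
#'   \eqn{\Psi_s \times} treatment interaction alone), `n_excluded`, and the
#'   full `model`.
#' @export
compare_treatments <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("psi_stem", "plc", "treatment") %in% names(observations)))
  lin <- linearize(observations)
  n_excluded <- attr(lin, "n_excluded")
  lin$treatment <- factor(lin$treatment)
  counts <- table(lin$treatment)
  if (length(counts) < 2) {
    stop("at least 2 treatments are required", call. = FALSE)
  }
  if (any(counts < 3)) {
    stop("each treatment needs at least 3 transformable observations; short: ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  }
  full <- stats::lm(y ~ psi_stem * treatment, data = lin)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  base <- stats::lm(y ~ psi_stem, data = lin)
  no_int <- stats::lm(y ~ psi_stem + treatment, data = lin)
  joint <- stats::anova(base, full)
  inter <- stats::anova(no_int, full)

  coefs <- do.call(rbind, lapply(levels(lin$treatment), function(tr) {
    d <- lin[lin$treatment == tr, ]
    cf <- stats::coef(stats::lm(y ~ psi_stem, data = d))
    a <- unname(cf["psi_stem"]); b <- unname(cf["(Intercept)"])
    data.frame(treatment = tr, alpha = a, plc50 = -b / a, n = nrow(d))
  }))

  structure(list(
    coefficients = coefs,
    joint_test = list(F = joint$F[2], df = c(joint$Df[2], joint$Res.Df[2]),
                      p_value = joint$`Pr(>F)`[2]),
    interaction_test = list(F = inter$F[2], df = c(inter$Df[2], inter$Res.Df[2]),
                            p_value = inter$`Pr(>F)`[2]),
    n_excluded = n_excluded, model = full
  ), class = "vc_comparison")
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat("Linearized vulnerability-curve comparison\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("  joint treatment test: F(%d, %d) = %.3f, p = %.4g\n",
              x$joint_test$df[1], x$joint_test$df[2], x$joint_test$F,
              x$joint_test$p_value))
  cat(sprintf("  interaction test:     F(%d, %d) = %.3f, p = %.4g\n",
              x$interaction_test$df[1], x$interaction_test$df[2],
              x$interaction_test$F, x$interaction_test$p_value))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d observation(s) at PLC 0 or 100 excluded by the transform\n",
                x$n_excluded))
  }
  invisible(x)
}

#' Read PLC observations from CSV
#'
#' Expects columns `psi_stem` and `plc`, optionally `treatment` and
#' `shoot_id`.
#'
#' @param file Path to a CSV file.
#' @return Data frame of PLC observations.
#' @export
read_plc_observations <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("psi_stem", "plc") %in% names(x))) {
    stop("PLC file must have columns psi_stem and plc", call. = FALSE)
  }
  x
}
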