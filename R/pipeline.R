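#' Configuration for an end-to-end study analysis
#'
#' Collects the inputs and settings consumed by [run_study()]. Every data
#' kind is optional; stages without data are skipped with a logged notice.
#' All stochastic steps (bootstraps) derive their seeds deterministically
#' from the single top-level `seed`.
#'
#' @param vc PLC observations: data frame (`psi_stem`, `plc`, `treatment`) or
#'   a CSV path for [read_plc_observations()].
#' @param pv Pressure-volume data: list of [pv_curve()] objects or a CSV path
#'   for [read_pv_curves()].
#' @param sections Petiole anatomy: list of [petiole_section()] objects.
#' @param course Gas-exchange records: data frame or a CSV path for
#'   [read_gas_exchange()].
#' @param bin_width Stem water-potential class width, MPa.
#' @param bin_edges Vessel diameter class edges, um.
#' @param n_bootstrap Bootstrap replicates for curve fits.
#' @param seed Top-level integer seed.
#' @param out_dir Output directory for CSV/JSON tables (optional; no files
#'   are written when NULL).
#' @return Object of class `study_config`.
#' @export
study_config <- function(vc = NULL, pv = NULL, sections = NULL, course = NULL,
                         bin_width = 0.2, bin_edges = c(10, 15, 20, 25, 30),
                         n_bootstrap = 200, seed = 1, out_dir = NULL) {
  if (is.character(vc)) vc <- read_plc_observations(vc)
  if (is.character(pv)) pv <- read_pv_curves(pv)
  if (is.character(course)) course <- read_gas_exchange(course)
  if (is.null(vc) && is.null(pv) && is.null(sections) && is.null(course)) {
    stop("at least one data kind (vc, pv, sections, course) is required",
         call. = FALSE)
  }
  structure(list(vc = vc, pv = pv, sections = sections, course = course,
                 bin_width = bin_width, bin_edges = bin_edges,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

#' Sigmoidal fit to the decline of binned leaf conductance
#'
#' Converts binned leaf-conductance points to percent loss relative to the
#' mean of the wettest (least negative) class and fits the same sigmoid used
#' for vulnerability curves, so that the stem water potential at 50% leaf
#' conductance loss is directly comparable to the embolism PLC50. Losses
#' outside \[0, 100\] (classes wetter-but-higher than the reference, or
#' negative conductances) are clamped. A series whose losses never cross 50%
#' is flagged degenerate by the underlying fit.
#'
#' @param points Binned conductance points from [bin_by_psi()] (needs
#'   `psi_class_center`, `k_leaf_mean`).
#' @param n_bootstrap,seed Passed to [fit_vc()].
#' @param reference Baseline conductance; default the wettest class mean.
#' @return A `vc_fit` on percent k_leaf loss, with extra fields
#'   `reference_k` and `psi50_kleaf` (= its `plc50`).
#' @export
kleaf_decline_fit <- function(points, n_bootstrap = 200, seed = NULL,
                              reference = NULL) {
  stopifnot(is.data.frame(points),
            all(c("psi_class_center", "k_leaf_mean") %in% names(points)))
  pts <- points[is.finite(points$k_leaf_mean), , drop = FALSE]
  if (nrow(pts) < 4) {
    stop("at least 4 binned conductance points are required", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- pts$k_leaf_mean[which.max(pts$psi_class_center)]
  }
  if (!is.finite(reference) || reference <= 0) {
    stop("reference (wettest-class) leaf conductance must be positive",
         call. = FALSE)
  }
  loss <- 100 * (1 - pts$k_leaf_mean / reference)
  loss <- pmin(pmax(loss, 0), 100)
  fit <- fit_vc(data.frame(psi_stem = pts$psi_class_center, plc = loss),
                n_bootstrap = n_bootstrap, seed = seed)
  fit$reference_k <- reference
  fit$psi50_kleaf <- fit$plc50
  fit
}

write_stage <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}

#' Run the end-to-end study analysis
#'
#' Executes every stage for which the configuration supplies data:
#' per-treatment vulnerability-curve fits and the linearized treatment
#' comparison; per-leaf pressure-volume fits and the per-treatment parameter
#' table; per-section anatomy (Hagen-Poiseuille) table and vessel-class
#' distributions; water-potential-binned conductance points; and — when both
#' conductance and vulnerability data are present — a decoupling summary
#' giving, per treatment, the stem water potential at 50% leaf-conductance
#' loss, the PLC50, and their difference in MPa (positive when leaf
#' conductance declines at wetter potentials than embolism develops).
#' Deterministic given (inputs, config, seed): stage seeds are fanned out
#' from the top-level seed.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`: list with any of `vc_fits`,
#'   `vc_comparison`, `pv_fits`, `pv_table`, `anatomy_table`,
#'   `vessel_classes`, `conductance_bins`, `kleaf_fits`, `decoupling`, plus
#'   `seed` and `skipped` (character vector of stages without data).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  report <- list(seed = seed, skipped = character(0))

  # vulnerability stage
  if (!is.null(config$vc)) {
    vc <- config$vc
    if (!"treatment" %in% names(vc)) vc$treatment <- "all"
    groups <- split(vc, vc$treatment)
    report$vc_fits <- lapply(seq_along(groups), function(i) {
      fit_vc(groups[[i]], n_bootstrap = config$n_bootstrap,
             seed = seed + 101L * i)
    })
    names(report$vc_fits) <- names(groups)
    if (length(groups) >= 2) {
      report$vc_comparison <- compare_treatments(vc)
    }
    vc_table <- do.call(rbind, lapply(names(report$vc_fits), function(tr) {
      f <- report$vc_fits[[tr]]
      data.frame(treatment = tr, alpha = f$alpha, plc50 = f$plc50,
                 slope_at_p50 = f$slope_at_p50, psi12 = f$psi12,
                 psi88 = f$psi88, n = f$n_obs)
    }))
    report$vc_table <- vc_table
    write_stage(vc_table, config$out_dir, "vc_parameters.csv")
  } else {
    report$skipped <- c(report$skipped, "vulnerability")
    message("no vulnerability-curve data; stage skipped")
  }

  # pressure-volume stage
  if (!is.null(config$pv)) {
    report$pv_fits <- lapply(config$pv, fit_pv)
    report$pv_table <- pv_parameter_table(report$pv_fits)
    write_stage(report$pv_table, config$out_dir, "pv_parameters.csv")
  } else {
    report$skipped <- c(report$skipped, "pressure_volume")
    message("no pressure-volume data; stage skipped")
  }

  # anatomy stage
  if (!is.null(config$sections)) {
    report$anatomy_table <- do.call(rbind, lapply(config$sections,
                                                  section_conductivity))
    rownames(report$anatomy_table) <- NULL
    report$vessel_classes <- do.call(rbind, lapply(config$sections, function(s) {
      cbind(section_id = s$section_id, treatment = s$treatment,
            vessel_class_distribution(s$vessels$diameter_um, config$bin_edges))
    }))
    rownames(report$vessel_classes) <- NULL
    write_stage(report$anatomy_table, config$out_dir, "anatomy_table.csv")
    write_stage(report$vessel_classes, config$out_dir, "vessel_classes.csv")
  } else {
    report$skipped <- c(report$skipped, "anatomy")
    message("no anatomy data; stage skipped")
  }

  # conductance stage
  if (!is.null(config$course)) {
    course <- config$course
    if (!"treatment" %in% names(course)) course$treatment <- "all"
    groups <- split(course, course$treatment)
    bins <- lapply(groups, bin_by_psi, bin_width = config$bin_width)
    report$conductance_bins <- do.call(rbind, lapply(names(bins), function(tr) {
      cbind(treatment = tr, bins[[tr]])
    }))
    rownames(report$conductance_bins) <- NULL
    write_stage(report$conductance_bins, config$out_dir,
                "conductance_bins.csv")

    # decoupling summary needs both a k_leaf decline and a vulnerability fit
    if (!is.null(report$vc_fits)) {
      shared <- intersect(names(bins), names(report$vc_fits))
      kleaf_fits <- list()
      rows <- list()
      for (tr in shared) {
        kf <- tryCatch(
          kleaf_decline_fit(bins[[tr]], n_bootstrap = config$n_bootstrap,
                            seed = seed + 977L * match(tr, shared)),
          error = function(e) {
            message("k_leaf decline fit failed for ", tr, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(kf)) next
        kleaf_fits[[tr]] <- kf
        plc50 <- report$vc_fits[[tr]]$plc50
        rows[[tr]] <- data.frame(
          treatment = tr,
          psi50_kleaf = kf$psi50_kleaf,
          plc50 = plc50,
          gap = kf$psi50_kleaf - plc50,
          kleaf_degenerate = kf$degenerate
        )
      }
      if (length(rows)) {
        report$kleaf_fits <- kleaf_fits
        report$decoupling <- do.call(rbind, rows)
        rownames(report$decoupling) <- NULL
        write_stage(report$decoupling, config$out_dir, "decoupling.csv")
      }
    }
  } else {
    report$skipped <- c(report$skipped, "conductance")
    message("no gas-exchange data; stage skipped")
  }

  if (!is.null(config$out_dir) && !is.null(report$vc_fits)) {
    for (tr in names(report$vc_fits)) {
      write_vc_json(report$vc_fits[[tr]],
                    file.path(config$out_dir, paste0("vc_", tr, ".json")))
    }
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed ", x$seed, ")\n", sep = "")
  ran <- setdiff(c("vulnerability", "pressure_volume", "anatomy", "conductance"),
                 x$skipped)
  cat("  stages run:", paste(ran, collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("  stages skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  if (!is.null(x$decoupling)) {
    cat("  decoupling summary (MPa):\n")
    print(x$decoupling, row.names = FALSE)
  }
  invisible(x)
}
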