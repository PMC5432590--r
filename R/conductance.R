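#' Percent loss of hydraulic conductivity
#'
#' Computes PLC of a xylem segment from its initial (native) conductance and
#' its maximum conductance after flushing:
#' \deqn{PLC = 100 (1 - k_i / k_{max}).}
#' Measurement noise can produce `k_initial > k_max` (nominally negative PLC);
#' such values are clamped into \[0, 100\] and flagged rather than rejected,
#' which preserves sample size and mirrors field practice.
#'
#' @param k_initial Initial hydraulic conductance, any consistent flow units.
#'   Must be non-negative.
#' @param k_max Maximum (flushed) conductance in the same units. Must be
#'   strictly positive.
#' @return Numeric vector of PLC values in \[0, 100\]. The attribute
#'   `"clamped"` is a logical vector marking observations whose raw value fell
#'   outside \[0, 100\]; a warning is emitted when any were clamped.
#' @examples
#' plc(k_initial = 1, k_max = 4)  # 75
#' @export
plc <- function(k_initial, k_max) {
  if (any(!is.finite(k_max)) || any(k_max <= 0)) {
    stop("`k_max` must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(k_initial)) || any(k_initial < 0)) {
    stop("`k_initial` must be finite and non-negative", call. = FALSE)
  }
  raw <- 100 * (1 - k_initial / k_max)
  clamped <- raw < 0 | raw > 100
  if (any(clamped)) {
    warning(sprintf("%d PLC value(s) outside [0, 100] (k_initial > k_max); clamped",
                    sum(clamped)), call. = FALSE)
  }
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- clamped
  out
}

k_from_gradient <- function(E, psi_upstream, psi_downstream, label) {
  grad <- psi_upstream - psi_downstream
  if (any(!is.finite(grad))) {
    stop("non-finite water potentials in ", label, call. = FALSE)
  }
  if (any(grad == 0)) {
    stop("zero water-potential gradient: ", label, " undefined", call. = FALSE)
  }
  k <- E / grad
  reversed <- grad < 0
  if (any(reversed)) {
    warning(sprintf("%d record(s) with reversed water-potential gradient in %s; signed values returned",
                    sum(reversed), label), call. = FALSE)
  }
  attr(k, "reversed") <- reversed
  k
}

#' Leaf hydraulic conductance (Ohm's-law analogy)
#'
#' \deqn{k_{leaf} = E / (\Psi_s - \Psi_l)}
#' with transpiration `E` in mmol m-2 s-1 and water potentials in MPa, giving
#' a leaf-area-specific conductance in mmol m-2 s-1 MPa-1. A reversed gradient
#' (leaf wetter than stem) yields a signed negative value and a flag; the
#' decision to exclude such records is left to the pipeline, never applied
#' silently here.
#'
#' @param E Transpiration, mmol H2O m-2 s-1.
#' @param psi_stem Stem water potential, MPa (<= 0 by convention).
#' @param psi_leaf Leaf water potential, MPa.
#' @return Numeric vector of conductances with a logical `"reversed"`
#'   attribute flagging negative driving gradients.
#' @examples
#' leaf_conductance(E = 2, psi_stem = -0.5, psi_leaf = -0.9)  # 5
#' @export
leaf_conductance <- function(E, psi_stem, psi_leaf) {
  k_from_gradient(E, psi_stem, psi_leaf, "k_leaf")
}

#' Whole-plant hydraulic conductance
#'
#' \deqn{k_{plant} = E / (\Psi_{PD} - \Psi_l)} — as [leaf_conductance()] but
#' driven by the pre-dawn-to-leaf gradient.
#'
#' @inheritParams leaf_conductance
#' @param psi_predawn Pre-dawn (soil-equilibrated) water potential, MPa.
#' @return Numeric vector of conductances with a `"reversed"` attribute.
#' @examples
#' plant_conductance(E = 3, psi_predawn = -0.2, psi_leaf = -1.2)  # 3
#' @export
plant_conductance <- function(E, psi_predawn, psi_leaf) {
  k_from_gradient(E, psi_predawn, psi_leaf, "k_plant")
}

psi_class_index <- function(psi_stem, bin_width) {
  # half-open classes (-(i+1)w, -i*w] anchored at 0; the epsilon keeps
  # boundary values (psi = -i*w) in class i despite floating-point division
  floor(-psi_stem / bin_width + 1e-9)
}

#' Bin a daily course by stem water-potential class
#'
#' Groups gas-exchange records into contiguous stem water-potential classes of
#' width `bin_width` anchored at 0 MPa (half-open intervals `(-(i+1)w, -i*w]`),
#' computes per-record `k_leaf` (and `k_plant` when `psi_predawn` is present)
#' via the Ohm's-law analogy, and returns per-class means and standard errors.
#' Records with a zero stem-to-leaf gradient or non-finite stem water potential
#' are dropped with a message; empty classes are omitted.
#'
#' @param records Data frame with columns `E`, `gs`, `psi_stem`, `psi_leaf`
#'   and optionally `psi_predawn` (see [read_gas_exchange()]).
#' @param bin_width Class width in MPa (> 0). Default 0.2 MPa.
#' @return Data frame of conductance points, one row per non-empty class:
#'   `psi_class_center`, `n`, `k_leaf_mean`, `k_leaf_se`, `k_plant_mean`,
#'   `k_plant_se` (NA when `psi_predawn` is absent), `gs_mean`, `gs_se`.
#'   Ordered from the wettest (least negative) class down.
#' @export
bin_by_psi <- function(records, bin_width = 0.2) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive number", call. = FALSE)
  }
  req <- c("E", "gs", "psi_stem", "psi_leaf")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(records$psi_stem) & is.finite(records$psi_leaf) &
    is.finite(records$E)
  grad <- records$psi_stem - records$psi_leaf
  ok <- ok & grad != 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped (non-finite values or zero gradient)")
  }
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0) stop("no usable records after filtering", call. = FALSE)

  k_leaf <- rec$E / (rec$psi_stem - rec$psi_leaf)
  has_pd <- "psi_predawn" %in% names(rec) && any(is.finite(rec$psi_predawn))
  k_plant <- if (has_pd) rec$E / (rec$psi_predawn - rec$psi_leaf) else rep(NA_real_, nrow(rec))

  idx <- psi_class_index(rec$psi_stem, bin_width)
  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  mean_f <- function(x) if (all(!is.finite(x))) NA_real_ else mean(x[is.finite(x)])
  groups <- split(seq_len(nrow(rec)), idx)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(
      psi_class_center = -(as.numeric(g) + 0.5) * bin_width,
      n = length(i),
      k_leaf_mean = mean_f(k_leaf[i]), k_leaf_se = se(k_leaf[i]),
      k_plant_mean = mean_f(k_plant[i]), k_plant_se = se(k_plant[i]),
      gs_mean = mean_f(rec$gs[i]), gs_se = se(rec$gs[i])
    )
  }))
  out <- out[order(-out$psi_class_center), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gas-exchange daily-course table
#'
#' Reads a CSV with the named columns `time`, `E`, `gs`, `psi_leaf`,
#' `psi_stem`, `psi_predawn`, `treatment`, `theta`. `psi_predawn` (and
#' `theta`) may be absent, in which case whole-plant conductance cannot be
#' derived downstream.
#'
#' @param file Path to a CSV file.
#' @return Data frame of gas-exchange records.
#' @export
read_gas_exchange <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("time", "E", "gs", "psi_leaf", "psi_stem", "treatment")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("gas-exchange file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(x$E < 0, na.rm = TRUE) || any(x$gs < 0, na.rm = TRUE)) {
    warning("negative E or gs values present", call. = FALSE)
  }
  x
}
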