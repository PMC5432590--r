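# Physical constants for the Hagen-Poiseuille conversion.
# Density and viscosity of xylem sap are taken as those of water; the molar
# mass converts the mass-flow form of the law to molar flow units.
HP_DENSITY_KG_M3 <- 1000        # rho, kg m^-3
HP_VISCOSITY_MPA_S <- 1e-9      # eta, MPa s (= 1e-3 Pa s)
WATER_MOLAR_MASS_KG <- 0.018015 # kg mol^-1

#' Equivalent-circle diameter of a vessel lumen
#'
#' Converts a measured lumen cross-sectional area to the diameter of the
#' circle of equal area, \eqn{d = 2\sqrt{A/\pi}} — the quantity the
#' Hagen-Poiseuille law consumes when vessels are digitized as areas.
#'
#' @param lumen_area Lumen area(s), um^2 (> 0).
#' @return Diameter(s), um.
#' @examples
#' equivalent_diameter(100 * pi)  # 20
#' @export
equivalent_diameter <- function(lumen_area) {
  if (any(!is.finite(lumen_area)) || any(lumen_area <= 0)) {
    stop("`lumen_area` must be finite and positive", call. = FALSE)
  }
  2 * sqrt(lumen_area / pi)
}

#' Theoretical hydraulic conductivity of a vessel population
#'
#' Modified Hagen-Poiseuille law:
#' \deqn{k_t = \frac{\pi \rho}{128 \eta} \sum_i d_i^4}
#' with \eqn{\rho} = 1000 kg m-3, \eqn{\eta} = 1e-9 MPa s and diameters in
#' meters, giving a mass-flow conductivity (kg m s-1 MPa-1) that is converted
#' to molar units through the molar mass of water (18.015 g mol-1) and
#' reported in mmol m s-1 MPa-1. When only half of a (nearly symmetrical)
#' petiole cross-section was digitized, `extrapolate_half = TRUE` doubles the
#' sum to represent the whole petiole.
#'
#' @param diameters Vessel lumen diameters, um (all > 0).
#' @param extrapolate_half Double the sum of d^4 (half-section digitization).
#' @return Theoretical conductivity `k_t`, mmol m s-1 MPa-1. Zero (with a
#'   warning) for an empty vessel set.
#' @examples
#' theoretical_conductivity(20)  # single 20-um vessel
#' @export
theoretical_conductivity <- function(diameters, extrapolate_half = FALSE) {
  if (length(diameters) == 0) {
    warning("empty vessel set; k_t = 0", call. = FALSE)
    return(0)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("`diameters` must be finite and positive", call. = FALSE)
  }
  d_m <- diameters * 1e-6
  sum_d4 <- sum(d_m^4)
  if (extrapolate_half) sum_d4 <- 2 * sum_d4
  kt_kg <- pi * HP_DENSITY_KG_M3 / (128 * HP_VISCOSITY_MPA_S) * sum_d4
  kt_kg / WATER_MOLAR_MASS_KG * 1000  # kg -> mol -> mmol
}

#' Leaf-area-specific theoretical conductivity
#'
#' \eqn{k_{ts} = k_t / LA}: the Hagen-Poiseuille conductivity of the petiole
#' normalized to the leaf area it subtends, in mmol m-1 s-1 MPa-1.
#'
#' @param k_t Theoretical conductivity, mmol m s-1 MPa-1.
#' @param leaf_area Subtended leaf area, cm^2 (> 0).
#' @return `k_ts`, mmol m-1 s-1 MPa-1.
#' @export
specific_conductivity <- function(k_t, leaf_area) {
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0)) {
    stop("`leaf_area` must be finite and positive (cm^2)", call. = FALSE)
  }
  k_t / (leaf_area * 1e-4)
}

#' Vessel size-class frequency and conductivity contribution
#'
#' Splits a vessel population into diameter classes and reports, per class,
#' the relative frequency of vessel counts and the relative contribution to
#' theoretical conductivity (proportional to \eqn{\sum d^4}), each summing to
#' 100%. Underflow and overflow classes are always included.
#'
#' @param diameters Vessel diameters, um.
#' @param bin_edges Strictly increasing interior class edges, um. The default
#'   gives classes <10, 10-15, 15-20, 20-25, 25-30, >30.
#' @return Data frame with `class` (label), `lower`, `upper` (um), `count`,
#'   `freq_pct` and `kt_pct`.
#' @export
vessel_class_distribution <- function(diameters, bin_edges = c(10, 15, 20, 25, 30)) {
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("`diameters` must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  breaks <- c(-Inf, bin_edges, Inf)
  cls <- cut(diameters, breaks = breaks, right = FALSE)
  labels <- c(paste0("<", bin_edges[1]),
              if (length(bin_edges) > 1)
                paste(bin_edges[-length(bin_edges)], bin_edges[-1], sep = "-"),
              paste0(">", bin_edges[length(bin_edges)]))
  counts <- as.integer(table(cls))
  d4 <- tapply(diameters^4, cls, sum, default = 0)
  data.frame(
    class = labels,
    lower = c(-Inf, bin_edges),
    upper = c(bin_edges, Inf),
    count = counts,
    freq_pct = 100 * counts / sum(counts),
    kt_pct = 100 * as.numeric(d4) / sum(diameters^4)
  )
}

#' Construct a petiole cross-section record
#'
#' @param vessels Data frame of vessel records with column `diameter_um`
#'   and/or `lumen_area_um2` (at least one; diameters are derived from areas
#'   by [equivalent_diameter()] when absent) and optionally `bundle_id`.
#' @param petiole_area Petiole cross-section area, mm^2.
#' @param leaf_area Subtended leaf area, cm^2 (> 0).
#' @param n_bundles Number of vascular bundles (optional).
#' @param half_section TRUE when only half the cross-section was digitized;
#'   totals are then extrapolated (doubled) to the whole petiole.
#' @param section_id,treatment Optional labels.
#' @return Object of class `petiole_section`.
#' @export
petiole_section <- function(vessels, petiole_area = NA_real_, leaf_area,
                            n_bundles = NA_integer_, half_section = FALSE,
                            section_id = NA_character_,
                            treatment = NA_character_) {
  stopifnot(is.data.frame(vessels))
  if (!any(c("diameter_um", "lumen_area_um2") %in% names(vessels))) {
    stop("vessels need a `diameter_um` or `lumen_area_um2` column", call. = FALSE)
  }
  if (!"diameter_um" %in% names(vessels)) {
    vessels$diameter_um <- equivalent_diameter(vessels$lumen_area_um2)
  }
  if (!"lumen_area_um2" %in% names(vessels)) {
    vessels$lumen_area_um2 <- pi * (vessels$diameter_um / 2)^2
  }
  if (nrow(vessels) == 0) stop("vessel set is empty", call. = FALSE)
  if (!is.finite(leaf_area) || leaf_area <= 0) {
    stop("`leaf_area` must be positive (cm^2)", call. = FALSE)
  }
  structure(list(vessels = vessels, petiole_area = petiole_area,
                 leaf_area = leaf_area, n_bundles = n_bundles,
                 half_section = isTRUE(half_section), section_id = section_id,
                 treatment = treatment),
            class = "petiole_section")
}

#' Conductivity summary of a petiole section
#'
#' Computes the per-section quantities of a xylem-architecture table:
#' theoretical conductivity `k_t`, leaf-area-specific `k_ts`, mean vessel
#' diameter, total vessel lumen area and vessel count. For half-section
#' digitizations, `k_t`, the vessel count and the total lumen area are
#' extrapolated (doubled) to the whole petiole; the mean diameter is
#' unaffected.
#'
#' @param section A [petiole_section()].
#' @return Data frame with one row: `section_id`, `treatment`,
#'   `petiole_area_mm2`, `leaf_area_cm2`, `n_bundles`, `n_vessels`,
#'   `mean_diameter_um`, `total_vessel_area_mm2`, `k_t` (mmol m s-1 MPa-1)
#'   and `k_ts` (mmol m-1 s-1 MPa-1).
#' @export
section_conductivity <- function(section) {
  stopifnot(inherits(section, "petiole_section"))
  d <- section$vessels$diameter_um
  mult <- if (section$half_section) 2 else 1
  k_t <- theoretical_conductivity(d, extrapolate_half = section$half_section)
  data.frame(
    section_id = section$section_id,
    treatment = section$treatment,
    petiole_area_mm2 = section$petiole_area,
    leaf_area_cm2 = section$leaf_area,
    n_bundles = section$n_bundles,
    n_vessels = mult * length(d),
    mean_diameter_um = mean(d),
    total_vessel_area_mm2 = mult * sum(section$vessels$lumen_area_um2) * 1e-6,
    k_t = k_t,
    k_ts = specific_conductivity(k_t, section$leaf_area)
  )
}

#' Read vessel records and section metadata from CSV
#'
#' `vessel_file` needs `section_id` plus `diameter_um` or `lumen_area_um2`
#' (optionally `bundle_id`); `section_file` needs `section_id`,
#' `leaf_area_cm2` and optionally `petiole_area_mm2`, `n_bundles`,
#' `half_section`, `treatment`.
#'
#' @param vessel_file,section_file CSV paths.
#' @return List of [petiole_section()] objects keyed by `section_id`.
#' @export
read_petiole_sections <- function(vessel_file, section_file) {
  v <- utils::read.csv(vessel_file, stringsAsFactors = FALSE)
  s <- utils::read.csv(section_file, stringsAsFactors = FALSE)
  if (!"section_id" %in% names(v) || !"section_id" %in% names(s)) {
    stop("both files need a `section_id` column", call. = FALSE)
  }
  get <- function(df, col, default) if (col %in% names(df)) df[[col]] else default
  out <- lapply(seq_len(nrow(s)), function(i) {
    vi <- v[v$section_id == s$section_id[i], , drop = FALSE]
    petiole_section(
      vessels = vi,
      petiole_area = get(s, "petiole_area_mm2", NA_real_)[i],
      leaf_area = s$leaf_area_cm2[i],
      n_bundles = get(s, "n_bundles", NA_integer_)[i],
      half_section = isTRUE(as.logical(get(s, "half_section", FALSE)[i])),
      section_id = s$section_id[i],
      treatment = get(s, "treatment", NA_character_)[i]
    )
  })
  names(out) <- s$section_id
  out
}
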