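# Pattern taxonomy and density criteria. Emergent polar patterns of gliding
# filaments on a vesicle fall into five classes: streams, vortices, bands,
# partially jammed and globally jammed states; which occur is concentration
# dependent, and the Onsager hard-rod criterion shows the observed densities
# sit well below the passive isotropic-nematic transition, so the patterns
# are activity induced.

#' Parameters for filament surface-density conversions
#'
#' @param c_A_nM Encapsulated actin monomer concentration in nanomolar.
#' @param R_um Vesicle radius in micrometres.
#' @param L_mode_um Mode of the log-normal filament length distribution
#'   (micrometres, default 0.6).
#' @param L_eff_um Effective filament length used in density conversions
#'   (default 0.55; reconciles the printed density, packing-fraction and
#'   critical-density values, see the methods vignette).
#' @param monomers_per_um Actin monomers per micrometre of filament
#'   (default 370).
#' @param width_nm Filament width in nanometres (default 7).
#' @return Object of class `density_params`.
#' @export
density_params <- function(c_A_nM, R_um = 18, L_mode_um = 0.6, L_eff_um = 0.55,
                           monomers_per_um = 370, width_nm = 7) {
  vals <- c(c_A_nM = c_A_nM, R_um = R_um, L_mode_um = L_mode_um,
            L_eff_um = L_eff_um, monomers_per_um = monomers_per_um,
            width_nm = width_nm)
  if (any(!is.finite(vals)) || any(vals[-1L] <= 0) || c_A_nM < 0)
    stop("density parameters must be positive (c_A may be zero)")
  structure(as.list(vals), class = "density_params")
}

AVOGADRO <- 6.02214076e23

#' Filament surface density from encapsulated concentration
#'
#' Assuming all encapsulated monomers polymerize into filaments of effective
#' length `L_eff` that bind the membrane, the surface density is
#' `rho = c_A * N_A * (4/3 pi R^3) / (monomers_per_um * L_eff) / (4 pi R^2)
#'      = c_A * N_A * R / (3 * monomers_per_um * L_eff)`
#' (with nM and um unit conversions). 100-600 nM in an 18 um vesicle gives
#' about 1.8-10.7 filaments per square micrometre.
#'
#' @param p A [density_params()].
#' @return Surface density in filaments per square micrometre.
#' @export
surface_density <- function(p) {
  if (!inherits(p, "density_params")) stop("p must be density_params")
  monomers_per_um3 <- p$c_A_nM * 1e-9 * AVOGADRO / 1e15  # per um^3
  filaments_per_um3 <- monomers_per_um3 / (p$monomers_per_um * p$L_eff_um)
  filaments_per_um3 * p$R_um / 3
}

#' Surface packing fraction of filaments
#'
#' Rectangle approximation `phi = rho * L * w`: the fraction of membrane
#' area occupied by filaments of length `L` and width `w`.
#'
#' @param rho Surface density, filaments per square micrometre (> 0 unless 0).
#' @param L_um Filament length in micrometres.
#' @param w_nm Filament width in nanometres.
#' @return Dimensionless packing fraction.
#' @export
packing_fraction <- function(rho, L_um = 0.55, w_nm = 7) {
  if (rho < 0 || L_um <= 0 || w_nm <= 0) stop("inputs must be non-negative (rho) / positive")
  rho * L_um * (w_nm * 1e-3)
}

#' Onsager critical surface density for hard rods
#'
#' The passive isotropic-nematic transition of two-dimensional hard rods of
#' length `L` occurs at `rho* = 3*pi / (2*L^2)`. For L = 0.55 um this is
#' about 15.6 filaments per square micrometre.
#'
#' @param L_um Rod length in micrometres (> 0).
#' @return Critical density in filaments per square micrometre.
#' @export
onsager_critical_density <- function(L_um) {
  if (!is.numeric(L_um) || length(L_um) != 1L || !is.finite(L_um) || L_um <= 0)
    stop("L_um must be a single positive length in micrometres")
  3 * pi / (2 * L_um^2)
}

#' Classifier thresholds for the pattern taxonomy
#'
#' Defaults are motivated by the observed speed scales (moving structures
#' 40-50 nm/s versus jammed defects below 5-10 nm/s) and coverage geometry;
#' all are exposed here because the original pattern assignment was by eye.
#'
#' @param c0 Coverage below which a vesicle is called empty.
#' @param c_full Coverage at or above which a pattern counts as covering the
#'   full surface.
#' @param v_jam Speed (nm/s) below which motion counts as jammed.
#' @param v_move Speed (nm/s) at or above which structures count as moving.
#' @param beta0_deg Maximum distance of the latitude-profile peak from the
#'   equator for a band call without defect input (degrees).
#' @param rel_threshold Coverage threshold as a fraction of the mean-map
#'   maximum.
#' @param min_threshold Absolute floor on the coverage threshold (intensity
#'   units of the rendered maps).
#' @param ridge_occupancy Fraction of azimuth columns that must contain
#'   high-intensity signal for a ridge to count as closed.
#' @return List of class `pattern_config`.
#' @export
pattern_config <- function(c0 = 0.005, c_full = 0.8, v_jam = 15, v_move = 25,
                           beta0_deg = 15, rel_threshold = 0.05,
                           min_threshold = 0.1, ridge_occupancy = 0.9) {
  structure(list(c0 = c0, c_full = c_full, v_jam = v_jam, v_move = v_move,
                 beta0_deg = beta0_deg, rel_threshold = rel_threshold,
                 min_threshold = min_threshold, ridge_occupancy = ridge_occupancy),
            class = "pattern_config")
}

#' Classify the polar pattern of a vesicle
#'
#' Decision-rule operationalization of the five-pattern taxonomy (stream,
#' vortex, band, partially jammed, globally jammed, plus empty) from map
#' morphology (coverage, latitude profile, ridge closure), structure and
#' defect speeds, and defect charges. The feature vector is always returned
#' for auditability. Missing speed or defect inputs relax the corresponding
#' conditions (classification then rests on morphology alone).
#'
#' @param maps An [equirect_seq()] or a single [equirect_map()].
#' @param structure_speeds Speeds of moving structures in nm/s (vector), or
#'   NULL.
#' @param defects A [defect_configuration()] (representative frame) or NULL
#'   when no defect annotation exists.
#' @param defect_speeds Instantaneous defect speeds in nm/s, or NULL.
#' @param config A [pattern_config()].
#' @return List of class `pattern_classification` with `label` (one of
#'   `"stream"`, `"vortex"`, `"band"`, `"partially_jammed"`,
#'   `"globally_jammed"`, `"empty"`) and `features`.
#' @export
classify_pattern <- function(maps, structure_speeds = NULL, defects = NULL,
                             defect_speeds = NULL, config = pattern_config()) {
  if (inherits(maps, "equirect_map")) maps <- equirect_seq(list(maps), 0)
  if (!inherits(maps, "equirect_seq")) stop("maps must be an equirect_seq or equirect_map")
  g <- maps$geometry
  mean_map <- equirect_map(Reduce(`+`, lapply(maps$maps, unclass)) / length(maps$maps), g)
  M <- unclass(mean_map)
  mx <- max(M)
  thr <- max(config$rel_threshold * mx, config$min_threshold)
  cov <- coverage_fraction(mean_map, thr)

  # latitude profile peak (degrees of colatitude)
  peak_theta_deg <- if (mx > 0) {
    prof <- rowMeans(M)
    map_theta_centers(mean_map)[which.max(prof)] * 180 / pi
  } else NA_real_
  # ridge: columns holding high-intensity signal; closure and latitude spread
  high <- M >= 0.5 * mx & mx > 0
  col_occ <- colSums(high) > 0
  ridge_occ <- mean(col_occ)
  ridge_theta <- apply(M, 2L, which.max)
  ridge_sd_deg <- if (any(col_occ))
    stats::sd(map_theta_centers(mean_map)[ridge_theta[col_occ]]) * 180 / pi else NA_real_
  ridge_closed <- ridge_occ >= config$ridge_occupancy

  n_half <- n_plus1 <- 0L; q_total <- NA_real_
  if (!is.null(defects)) {
    n_half <- sum(abs(defects$charge_half) == 1L)
    n_plus1 <- sum(defects$charge_half == 2L)
    q_total <- total_charge(defects)
  }
  med_speed <- if (length(structure_speeds)) stats::median(structure_speeds) else NA_real_
  med_defect_speed <- if (length(defect_speeds)) stats::median(defect_speeds) else NA_real_
  # speed predicates default permissive when the input is absent
  moving <- is.na(med_speed) || med_speed >= config$v_move
  jam_speed <- stats::median(c(defect_speeds, if (!length(defect_speeds)) structure_speeds))
  jammed_slow <- if (length(c(defect_speeds, structure_speeds))) jam_speed < config$v_jam else TRUE

  warn <- NULL
  if (!is.null(defects) && cov >= config$c_full && !is.na(q_total) && q_total != 2) {
    warn <- sprintf("full coverage (%.2f) with total charge %+g violates Poincare-Hopf", cov, q_total)
    warning(warn)
  }

  label <- if (cov < config$c0) {
    "empty"
  } else if (!is.null(defects) && n_half >= 4L && cov >= config$c_full && jammed_slow) {
    "globally_jammed"
  } else if (cov >= config$c_full && moving &&
             (n_plus1 == 2L ||
              (is.null(defects) && !is.na(peak_theta_deg) &&
               abs(peak_theta_deg - 90) <= config$beta0_deg && ridge_closed))) {
    "band"
  } else if (!is.null(defects) && n_half >= 1L && !is.na(med_defect_speed) &&
             med_defect_speed < config$v_jam &&
             length(structure_speeds) && max(structure_speeds) >= config$v_move) {
    "partially_jammed"
  } else if (ridge_closed && cov < config$c_full && moving) {
    "vortex"
  } else {
    "stream"
  }
  structure(list(label = label,
                 features = list(coverage = cov, threshold = thr,
                                 peak_theta_deg = peak_theta_deg,
                                 ridge_occupancy = ridge_occ,
                                 ridge_theta_sd_deg = ridge_sd_deg,
                                 median_structure_speed_nm_s = med_speed,
                                 median_defect_speed_nm_s = med_defect_speed,
                                 n_half_defects = n_half, n_plus1_defects = n_plus1,
                                 total_charge = q_total),
                 warning = warn),
            class = "pattern_classification")
}

#' @export
print.pattern_classification <- function(x, ...) {
  f <- x$features
  cat(sprintf("pattern: %s (coverage %.3f, peak theta %.1f deg, ridge occupancy %.2f)\n",
              x$label, f$coverage, f$peak_theta_deg, f$ridge_occupancy))
  invisible(x)
}
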