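#' Concentration-time profile for one subject in one matrix
#'
#' The basic unit of pharmacokinetic data: an ordered concentration-time
#' series for a single subject (or a composite of group means under
#' destructive sampling) in a single biological matrix, together with dose
#' and treatment metadata. Concentrations are ng/mL for plasma and ng/g for
#' tissue; tissue density is taken as 1 g/mL so brain-to-plasma ratios are
#' dimensionless.
#'
#' @param subject_id Subject (or composite) identifier.
#' @param group Group label, e.g. genotype and/or treatment
#'   (`"WT"`, `"Mdr1a/b-KO"`, `"triple-KO"`, `"WT+elacridar"`, ...).
#' @param matrix One of `"plasma"`, `"brain"`, `"tumor_core"`,
#'   `"tumor_rim"`, `"normal_brain"`.
#' @param times Sampling times in hours, strictly increasing, all >= 0.
#' @param concentrations Concentrations (ng/mL plasma, ng/g tissue), >= 0,
#'   same length as `times`.
#' @param dose_amount Dose in mg per kg body weight.
#' @param route Administration route, `"iv"` or `"ip"`.
#' @param conc_sd Optional per-time-point standard deviations (composite
#'   profiles from destructive sampling).
#' @param n_per_time Optional per-time-point sample sizes.
#' @return An object of class `pk_profile`.
#' @export
pk_profile <- function(subject_id, group, matrix, times, concentrations,
                       dose_amount = NA_real_, route = c("iv", "ip"),
                       conc_sd = NULL, n_per_time = NULL) {
  route <- match.arg(route)
  matrix <- match.arg(matrix, pk_matrices())
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  x <- structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         matrix = matrix, times = times, concentrations = concentrations,
         dose_amount = as.numeric(dose_amount), route = route,
         conc_sd = if (!is.null(conc_sd)) as.numeric(conc_sd),
         n_per_time = if (!is.null(n_per_time)) as.integer(n_per_time)),
    class = "pk_profile")
  validate_pk_profile(x)
}

pk_matrices <- function() {
  c("plasma", "brain", "tumor_core", "tumor_rim", "normal_brain")
}

validate_pk_profile <- function(x) {
  stopifnot(inherits(x, "pk_profile"))
  if (length(x$times) != length(x$concentrations)) {
    stop("times and concentrations must have the same length", call. = FALSE)
  }
  if (length(x$times) > 0) {
    if (any(!is.finite(x$times)) || any(x$times < 0)) {
      stop("times must be finite and non-negative", call. = FALSE)
    }
    if (any(diff(x$times) <= 0)) {
      stop("times must be strictly increasing", call. = FALSE)
    }
    if (any(!is.finite(x$concentrations)) || any(x$concentrations < 0)) {
      stop("concentrations must be finite and non-negative", call. = FALSE)
    }
  }
  if (!is.null(x$conc_sd) && length(x$conc_sd) != length(x$times)) {
    stop("conc_sd must match times in length", call. = FALSE)
  }
  x
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> subject %s | group %s | %s | %d points (%g-%g h)\n",
              x$subject_id, x$group, x$matrix, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Rapid-equilibrium-dialysis measurement
#'
#' One donor/receiver concentration pair from a RED assay. Brain is dialysed
#' as a homogenate diluted in buffer; `dilution_factor` is the total-volume
#' to tissue-volume ratio (tissue in 3 volumes PBS gives D = 4). Plasma is
#' dialysed neat (D = 1).
#'
#' @param matrix `"plasma"` or `"brain_homogenate"`.
#' @param donor_conc Donor-chamber concentration at equilibrium (uM), > 0.
#' @param receiver_conc Receiver-chamber (buffer) concentration (uM), >= 0
#'   and <= `donor_conc`.
#' @param dilution_factor Homogenate dilution factor D >= 1.
#' @return An object of class `dialysis_measurement`.
#' @export
dialysis_measurement <- function(matrix = c("plasma", "brain_homogenate"),
                                 donor_conc, receiver_conc,
                                 dilution_factor = 1) {
  matrix <- match.arg(matrix)
  if (!is.finite(donor_conc) || donor_conc <= 0) {
    stop("donor_conc must be positive", call. = FALSE)
  }
  if (!is.finite(receiver_conc) || receiver_conc < 0) {
    stop("receiver_conc must be non-negative", call. = FALSE)
  }
  if (receiver_conc > donor_conc) {
    stop("receiver_conc cannot exceed donor_conc", call. = FALSE)
  }
  if (!is.finite(dilution_factor) || dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  structure(list(matrix = matrix, donor_conc = donor_conc,
                 receiver_conc = receiver_conc,
                 dilution_factor = dilution_factor),
            class = "dialysis_measurement")
}

#' In-vitro viability table
#'
#' Replicate-resolved cell-viability measurements (percent of untreated
#' control) over a concentration grid, as produced by an ATP-based
#' cytotoxicity assay.
#'
#' @param cell_line Cell-line label.
#' @param concentrations Drug concentrations in nM, > 0 (one per row).
#' @param viability Percent-of-control viability, >= 0, same length.
#' @param replicate Optional replicate index per row.
#' @param co_treatment Optional co-treatment label (e.g. "elacridar 500 nM").
#' @return A data.frame of class `viability_table` with columns
#'   `concentration`, `viability`, `replicate`.
#' @export
viability_table <- function(cell_line, concentrations, viability,
                            replicate = NULL, co_treatment = NA_character_) {
  concentrations <- as.numeric(concentrations)
  viability <- as.numeric(viability)
  if (length(concentrations) != length(viability)) {
    stop("concentrations and viability must have the same length",
         call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(!is.finite(viability)) || any(viability < 0)) {
    stop("viability must be non-negative", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- seq_along(concentrations) * 0L + 1L
  out <- data.frame(concentration = concentrations, viability = viability,
                    replicate = as.integer(replicate))
  structure(out, class = c("viability_table", "data.frame"),
            cell_line = as.character(cell_line),
            co_treatment = as.character(co_treatment))
}

#' Bioluminescence time series for one animal
#'
#' Photon flux of a luciferase-expressing intracranial tumor over time,
#' a proxy for tumor burden.
#'
#' @param animal_id Animal identifier.
#' @param group Treatment group.
#' @param times Days post tumor inoculation, strictly increasing.
#' @param flux Photon flux (photons/s), > 0.
#' @return An object of class `bli_series`.
#' @export
bli_series <- function(animal_id, group, times, flux) {
  times <- as.numeric(times); flux <- as.numeric(flux)
  if (length(times) != length(flux)) {
    stop("times and flux must have the same length", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(flux)) || any(flux <= 0)) {
    stop("flux must be positive", call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id),
                 group = as.character(group), times = times, flux = flux),
            class = "bli_series")
}

#' Survival records
#'
#' Time-to-event data for one or more animals; `event = 1` marks an observed
#' death, `event = 0` right-censoring at the recorded time.
#'
#' @param animal_id Animal identifiers.
#' @param group Group labels.
#' @param time Days, > 0.
#' @param event Event indicator (1 death, 0 censored).
#' @return A data.frame of class `survival_records`.
#' @export
survival_records <- function(animal_id, group, time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("time must be positive", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  out <- data.frame(animal_id = as.character(animal_id),
                    group = as.character(group), time = time, event = event)
  structure(out, class = c("survival_records", "data.frame"))
}

#' Analysis configuration
#'
#' Bundles the enumerated analysis choices so that every stage is
#' deterministic and reportable: AUC method, terminal-slope point selection,
#' threshold-crossing interpolation, and the global random seed.
#'
#' @param auc_method `"linear"` (default) or `"linlog"`
#'   (linear-up/log-down).
#' @param lambda_z_min_points Minimum terminal points for the log-linear
#'   terminal fit (default 3).
#' @param lambda_z_r2 r-squared threshold for extending the terminal window
#'   backwards (default 0.90).
#' @param interp Threshold-crossing interpolation: `"loglinear"` (default,
#'   log-linear on declining positive segments) or `"linear"`.
#' @param seed Global random seed; per-stage seeds are derived from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(auc_method = c("linear", "linlog"),
                         lambda_z_min_points = 3L, lambda_z_r2 = 0.90,
                         interp = c("loglinear", "linear"), seed = 1L) {
  auc_method <- match.arg(auc_method)
  interp <- match.arg(interp)
  stopifnot(lambda_z_min_points >= 3L, lambda_z_r2 > 0, lambda_z_r2 <= 1)
  structure(list(auc_method = auc_method,
                 lambda_z_min_points = as.integer(lambda_z_min_points),
                 lambda_z_r2 = lambda_z_r2, interp = interp,
                 seed = as.integer(seed)),
            class = "study_config")
}
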