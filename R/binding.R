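#' Apparent unbound fraction from an equilibrium-dialysis pair
#'
#' At dialysis equilibrium the receiver (buffer) chamber holds only free
#' drug, so the apparent unbound fraction of the dialysed matrix is the
#' receiver-to-donor concentration ratio.
#'
#' @param m A [dialysis_measurement].
#' @param zero_receiver `"error"` (default) or `"floor"`; with `"floor"` a
#'   zero receiver concentration returns the smallest representable positive
#'   fraction with a warning instead of failing.
#' @return Apparent unbound fraction in (0, 1].
#' @export
fu_from_red <- function(m, zero_receiver = c("error", "floor")) {
  zero_receiver <- match.arg(zero_receiver)
  stopifnot(inherits(m, "dialysis_measurement"))
  if (m$receiver_conc == 0) {
    if (zero_receiver == "error") {
      stop("receiver concentration is zero: unbound fraction indeterminate",
           call. = FALSE)
    }
    warning("receiver concentration is zero: flooring fu at machine epsilon")
    return(.Machine$double.eps)
  }
  min(m$receiver_conc / m$donor_conc, 1)
}

#' Correct an apparent unbound fraction for homogenate dilution
#'
#' Dialysing tissue as a homogenate diluted D-fold in buffer dilutes the
#' binding constituents, inflating the measured unbound fraction. With the
#' usual assumption of linear (non-saturable) binding the apparent fraction
#' relates to the undiluted-tissue fraction by
#' fu_app = D.fu / (1 + (D - 1).fu), and this function applies the exact
#' inverse:
#' fu = (1/D).fu_app / (1 - fu_app + (1/D).fu_app).
#' D = 1 is the identity, and fu_app = 1 maps to 1 for any D.
#'
#' @param fu_apparent Apparent unbound fraction in (0, 1].
#' @param dilution_factor Dilution factor D >= 1 (tissue in 3 volumes of
#'   buffer gives D = 4).
#' @return Undiluted-matrix unbound fraction in (0, 1].
#' @export
correct_fu_dilution <- function(fu_apparent, dilution_factor) {
  stopifnot(all(fu_apparent > 0), all(fu_apparent <= 1),
            all(dilution_factor >= 1))
  d_inv <- 1 / dilution_factor
  d_inv * fu_apparent / (1 - fu_apparent + d_inv * fu_apparent)
}

#' Unbound-fraction estimation for a set of dialysis measurements
#'
#' Applies [fu_from_red] and [correct_fu_dilution] to each measurement.
#' Plasma is dialysed neat (D = 1), so its apparent and corrected fractions
#' coincide.
#'
#' @param measurements A list of [dialysis_measurement] objects.
#' @return A data.frame of class `binding_result` with columns `matrix`,
#'   `fu_apparent`, `fu_corrected`, `dilution_factor`.
#' @export
estimate_binding <- function(measurements) {
  if (inherits(measurements, "dialysis_measurement")) {
    measurements <- list(measurements)
  }
  rows <- lapply(measurements, function(m) {
    fa <- fu_from_red(m)
    data.frame(matrix = m$matrix, fu_apparent = fa,
               fu_corrected = correct_fu_dilution(fa, m$dilution_factor),
               dilution_factor = m$dilution_factor)
  })
  structure(do.call(rbind, rows),
            class = c("binding_result", "data.frame"))
}

#' Total-drug partition coefficient Kp
#'
#' Ratio of tissue to plasma exposure: either an AUC ratio (study-level Kp,
#' as over a full concentration-time course) or a single-time-point
#' concentration ratio. The result is labelled with which basis was used.
#'
#' @param auc_brain Brain (tissue) AUC or concentration.
#' @param auc_plasma Plasma AUC or concentration, > 0.
#' @param basis Label recorded on the result: `"auc_0t"`, `"auc_0inf"` or
#'   `"timepoint"`.
#' @return Kp (dimensionless) with a `basis` attribute.
#' @export
compute_kp <- function(auc_brain, auc_plasma,
                       basis = c("auc_0t", "auc_0inf", "timepoint")) {
  basis <- match.arg(basis)
  if (any(auc_plasma <= 0)) stop("plasma exposure must be positive",
                                 call. = FALSE)
  structure(auc_brain / auc_plasma, basis = basis)
}

#' Unbound partition coefficient Kp,uu
#'
#' Kp corrected to free drug: Kp,uu = Kp . fu_tissue / fu_plasma. A value
#' near 1 indicates passive distributional equilibrium across the BBB;
#' values far below 1 indicate active efflux.
#'
#' @param kp Total-drug partition coefficient, > 0.
#' @param fu_tissue Tissue (brain) unbound fraction, > 0.
#' @param fu_plasma Plasma unbound fraction, > 0.
#' @return Kp,uu (dimensionless).
#' @export
compute_kpuu <- function(kp, fu_tissue, fu_plasma) {
  stopifnot(all(kp > 0), all(fu_tissue > 0), all(fu_plasma > 0))
  kp * fu_tissue / fu_plasma
}

#' Distribution advantage
#'
#' Ratio of the transporter-deficient (or efflux-inhibited) Kp to the
#' wild-type Kp, quantifying the total effect of efflux transport on tissue
#' exposure.
#'
#' @param kp_knockout Kp in the efflux-deficient condition, > 0.
#' @param kp_wildtype Kp in the wild-type condition, > 0.
#' @return DA (dimensionless).
#' @export
compute_da <- function(kp_knockout, kp_wildtype) {
  stopifnot(all(kp_wildtype > 0))
  kp_knockout / kp_wildtype
}

#' Regional tumor partition table
#'
#' Computes single-time-point tissue-to-plasma ratios (Kp) per brain region
#' and treatment group, and the fold increase of each Kp over a reference
#' region/group (conventionally normal brain of the drug-alone arm).
#'
#' @param regional A data.frame with columns `subject_id`, `group`,
#'   `region` (one of `tumor_core`, `tumor_rim`, `normal_brain`) and
#'   `concentration` (ng/g).
#' @param plasma A data.frame with columns `subject_id`, `group`,
#'   `concentration` (ng/mL), one row per subject.
#' @param reference_region Region of the fold-increase denominator
#'   (default `"normal_brain"`).
#' @param reference_group Group of the fold-increase denominator.
#' @return A data.frame of class `partition_summary` with per (group,
#'   region) mean Kp, its SD over subjects, n, and `fold_increase`.
#' @export
regional_partition_table <- function(regional, plasma,
                                     reference_region = "normal_brain",
                                     reference_group) {
  need <- c("subject_id", "group", "region", "concentration")
  stopifnot(all(need %in% names(regional)),
            all(c("subject_id", "concentration") %in% names(plasma)))
  ip <- match(regional$subject_id, plasma$subject_id)
  if (anyNA(ip)) {
    stop(sprintf("no plasma concentration for subject %s",
                 regional$subject_id[which(is.na(ip))[1]]), call. = FALSE)
  }
  regional$kp <- timepoint_ratio(regional$concentration,
                                 plasma$concentration[ip])
  agg <- stats::aggregate(kp ~ group + region, data = regional,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, region = agg$region,
                    kp = agg$kp[, "mean"], kp_sd = agg$kp[, "sd"],
                    n = agg$kp[, "n"])
  ref <- out$kp[out$region == reference_region &
                  out$group == reference_group]
  if (length(ref) != 1) {
    stop(sprintf("reference %s / %s not present", reference_region,
                 reference_group), call. = FALSE)
  }
  out$fold_increase <- out$kp / ref
  structure(out, class = c("partition_summary", "data.frame"),
            basis = "timepoint",
            reference = c(region = reference_region, group = reference_group))
}

#' Group-level partition summary from NCA results
#'
#' Combines brain and plasma AUCs into Kp per group, applies the unbound
#' fractions for Kp,uu, and expresses each group's distribution advantage
#' relative to a reference (wild-type) group.
#'
#' @param nca_results A list of `nca_result` objects covering a plasma and a
#'   brain profile per group.
#' @param fu_brain,fu_plasma Corrected unbound fractions, in (0, 1].
#' @param reference_group Group used as the DA denominator.
#' @param basis `"auc_0t"` (default, matching reporting on the observed
#'   interval) or `"auc_0inf"`.
#' @return A data.frame of class `partition_summary` with columns `group`,
#'   `kp`, `kp_uu`, `da`.
#' @export
partition_summary <- function(nca_results, fu_brain, fu_plasma,
                              reference_group,
                              basis = c("auc_0t", "auc_0inf")) {
  basis <- match.arg(basis)
  df <- do.call(rbind, lapply(nca_results, as.data.frame))
  auc_col <- basis
  groups <- unique(df$group)
  rows <- lapply(groups, function(g) {
    pl <- df[df$group == g & df$matrix == "plasma", auc_col]
    br <- df[df$group == g & df$matrix == "brain", auc_col]
    if (length(pl) != 1 || length(br) != 1) {
      stop(sprintf("group %s needs exactly one plasma and one brain result",
                   g), call. = FALSE)
    }
    kp <- as.numeric(compute_kp(br, pl, basis = basis))
    data.frame(group = g, kp = kp,
               kp_uu = compute_kpuu(kp, fu_brain, fu_plasma))
  })
  out <- do.call(rbind, rows)
  if (!reference_group %in% out$group) {
    stop(sprintf("reference group %s absent", reference_group),
         call. = FALSE)
  }
  out$da <- compute_da(out$kp, out$kp[out$group == reference_group])
  structure(out, class = c("partition_summary", "data.frame"), basis = basis)
}
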