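#' Area under the concentration-time curve to the last observation
#'
#' Trapezoidal AUC(0-t) from the first to the last observed time. With
#' `method = "linlog"` (linear-up/log-down) the logarithmic trapezoid is
#' used on segments where both concentrations are positive and declining;
#' all other segments use the linear trapezoid.
#'
#' @param profile A [pk_profile].
#' @param method `"linear"` (default) or `"linlog"`.
#' @return AUC in h x concentration units of the profile.
#' @export
compute_auc_0t <- function(profile, method = c("linear", "linlog")) {
  method <- match.arg(method)
  validate_pk_profile(profile)
  t <- profile$times; c <- profile$concentrations
  if (length(t) < 2) stop("AUC requires at least 2 points", call. = FALSE)
  if (all(c == 0)) {
    warning("all-zero profile: AUC = 0")
    return(0)
  }
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1]
  seg <- dt * (c1 + c2) / 2
  if (method == "linlog") {
    logdown <- c2 < c1 & c2 > 0
    seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown])
  }
  sum(seg)
}

#' Terminal-slope estimation by log-linear regression
#'
#' Fits ln(C) vs t over terminal points after the observed peak (the peak
#' itself is excluded when an absorption phase precedes it; iv-bolus
#' profiles declining from the first sample keep all points eligible).
#' The default rule takes the last `min_points` positive
#' concentrations and extends the window backwards one point at a time while
#' the regression r-squared stays at or above `r2_threshold`; the rule is
#' deterministic. The negated slope is the terminal rate constant
#' lambda_z; half-life is ln(2)/lambda_z.
#'
#' @param profile A [pk_profile].
#' @param min_points Minimum terminal points (default 3).
#' @param r2_threshold r-squared required to extend the window (default 0.90).
#' @return A list with `lambda_z` (1/h), `half_life` (h), `r_squared`,
#'   `n_points`, `intercept` (ln concentration at t = 0) and a `flag`
#'   (`NA` when clean, `"no terminal decline"` when the slope is
#'   non-negative).
#' @export
fit_lambda_z <- function(profile, min_points = 3L, r2_threshold = 0.90) {
  validate_pk_profile(profile)
  t <- profile$times; c <- profile$concentrations
  i_max <- which.max(c)
  # exclude the peak only when an absorption phase precedes it; on iv-bolus
  # profiles declining from the first sample every point is eligible
  keep <- if (i_max > 1) seq_along(t) > i_max & c > 0 else c > 0
  if (i_max == length(t)) {
    # concentrations still rising at the last sample: no terminal phase
    return(list(lambda_z = NA_real_, half_life = NA_real_,
                r_squared = NA_real_, n_points = NA_integer_,
                intercept = NA_real_, flag = "no terminal decline"))
  }
  t <- t[keep]; c <- c[keep]
  if (length(t) < min_points) {
    stop(sprintf("terminal fit requires >= %d positive points after t_max",
                 min_points), call. = FALSE)
  }
  fit_n <- function(n) {
    idx <- seq(length(t) - n + 1, length(t))
    fit <- stats::lm(log(c[idx]) ~ t[idx])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = if (is.nan(r2)) 0 else r2, n = n)
  }
  best <- fit_n(min_points)
  n <- min_points
  while (n < length(t)) {
    cand <- fit_n(n + 1)
    if (cand$r2 < r2_threshold) break
    best <- cand
    n <- n + 1
  }
  if (best$slope >= 0) {
    return(list(lambda_z = NA_real_, half_life = NA_real_,
                r_squared = best$r2, n_points = best$n,
                intercept = best$intercept, flag = "no terminal decline"))
  }
  lz <- -best$slope
  list(lambda_z = lz, half_life = log(2) / lz, r_squared = best$r2,
       n_points = best$n, intercept = best$intercept, flag = NA_character_)
}

#' Extrapolated AUC to infinity
#'
#' AUC(0-inf) = AUC(0-t) + C_last / lambda_z. When `lambda_z` is missing
#' the unextrapolated AUC(0-t) is returned with a flag.
#'
#' @param auc_0t AUC to the last observation.
#' @param c_last Last measured concentration, >= 0.
#' @param lambda_z Terminal rate constant (1/h), or `NA`.
#' @return A list with `auc_0inf`, `pct_extrapolated` and `flag`.
#' @export
compute_auc_inf <- function(auc_0t, c_last, lambda_z) {
  stopifnot(auc_0t > 0, c_last >= 0)
  if (is.na(lambda_z)) {
    return(list(auc_0inf = auc_0t, pct_extrapolated = NA_real_,
                flag = "no lambda_z: AUC not extrapolated"))
  }
  stopifnot(lambda_z > 0)
  auc_inf <- auc_0t + c_last / lambda_z
  list(auc_0inf = auc_inf,
       pct_extrapolated = 100 * (auc_inf - auc_0t) / auc_inf,
       flag = NA_character_)
}

#' Clearance and volume of distribution
#'
#' CL = dose / AUC(0-inf) with the dose converted from mg/kg to ng/kg so
#' that CL is in mL/h/kg against an AUC in h.ng/mL; Vd = CL / lambda_z
#' (mL/kg).
#'
#' @param dose Dose in mg/kg, > 0.
#' @param auc_0inf AUC(0-inf) in h.ng/mL, > 0.
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return A list with `cl` (mL/h/kg) and `vd` (mL/kg).
#' @export
compute_cl_vd <- function(dose, auc_0inf, lambda_z) {
  stopifnot(dose > 0, auc_0inf > 0, lambda_z > 0)
  cl <- dose * 1e6 / auc_0inf
  list(cl = cl, vd = cl / lambda_z)
}

#' Single-time-point brain-to-plasma concentration ratio
#'
#' @param brain Brain (or tumor-region) concentration, ng/g.
#' @param plasma Plasma concentration, ng/mL, > 0.
#' @return The dimensionless ratio; `NA` with a warning when plasma is zero.
#' @export
timepoint_ratio <- function(brain, plasma) {
  if (any(plasma == 0)) {
    warning("zero plasma concentration: ratio undefined")
    return(ifelse(plasma == 0, NA_real_, brain / plasma))
  }
  brain / plasma
}

#' Average replicate subjects into a composite group-mean profile
#'
#' Destructive sampling yields one animal per time point; NCA is then run
#' on the composite profile of per-time-point group means. Per-time-point
#' SDs and n are retained for the sparse-sampling AUC standard error.
#'
#' @param profiles A list of [pk_profile] objects from one group and matrix,
#'   sharing a common nominal time grid.
#' @return A composite [pk_profile] with `conc_sd` and `n_per_time` set.
#' @export
composite_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  mats <- unique(vapply(profiles, `[[`, "", "matrix"))
  grps <- unique(vapply(profiles, `[[`, "", "group"))
  if (length(mats) != 1 || length(grps) != 1) {
    stop("profiles must share one group and one matrix", call. = FALSE)
  }
  times <- sort(unique(unlist(lapply(profiles, `[[`, "times"))))
  conc_at <- function(p, tt) {
    i <- match(tt, p$times)
    if (is.na(i)) NA_real_ else p$concentrations[i]
  }
  mat <- vapply(times, function(tt)
    vapply(profiles, conc_at, numeric(1), tt = tt), numeric(length(profiles)))
  mat <- matrix(mat, nrow = length(profiles))
  means <- colMeans(mat, na.rm = TRUE)
  sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
  ns <- colSums(!is.na(mat))
  pk_profile(subject_id = paste0(grps, "_composite"), group = grps,
             matrix = mats, times = times, concentrations = means,
             dose_amount = profiles[[1]]$dose_amount,
             route = profiles[[1]]$route, conc_sd = sds, n_per_time = ns)
}

# Bailer sparse-sampling variance of the linear-trapezoid AUC:
# AUC = sum(w_i * ybar_i), Var(AUC) = sum(w_i^2 * s_i^2 / n_i).
auc_sparse_se <- function(times, sd, n) {
  k <- length(times)
  w <- numeric(k)
  w[1] <- (times[2] - times[1]) / 2
  w[k] <- (times[k] - times[k - 1]) / 2
  if (k > 2) w[2:(k - 1)] <- (times[3:k] - times[1:(k - 2)]) / 2
  sqrt(sum(w^2 * sd^2 / n))
}

#' Full non-compartmental analysis of one profile
#'
#' Computes AUC(0-t), the terminal slope, AUC(0-inf), half-life and - when
#' the profile carries a dose - clearance and volume of distribution.
#' Concentrations below the quantification limit are dropped with a logged
#' count before analysis. On composite profiles carrying per-time-point SDs
#' the sparse-sampling (Bailer) standard error of AUC(0-t) is reported.
#'
#' @param profile A [pk_profile].
#' @param config A [study_config] (AUC method, terminal-fit rule).
#' @param loq Lower limit of quantification in concentration units;
#'   observations strictly below it are dropped (default 0: keep all).
#' @return A list of class `nca_result`.
#' @export
run_nca <- function(profile, config = study_config(), loq = 0) {
  validate_pk_profile(profile)
  if (loq > 0) {
    drop <- profile$concentrations < loq
    if (any(drop)) {
      message(sprintf("dropping %d observation(s) below LOQ", sum(drop)))
      profile$times <- profile$times[!drop]
      profile$concentrations <- profile$concentrations[!drop]
      if (!is.null(profile$conc_sd)) profile$conc_sd <- profile$conc_sd[!drop]
      if (!is.null(profile$n_per_time))
        profile$n_per_time <- profile$n_per_time[!drop]
    }
  }
  auc_0t <- compute_auc_0t(profile,
                           method = if (config$auc_method == "linlog")
                             "linlog" else "linear")
  auc_se <- if (!is.null(profile$conc_sd) && !is.null(profile$n_per_time) &&
                all(profile$n_per_time > 0)) {
    auc_sparse_se(profile$times, profile$conc_sd, profile$n_per_time)
  } else NA_real_
  lz <- tryCatch(fit_lambda_z(profile, config$lambda_z_min_points,
                              config$lambda_z_r2),
                 error = function(e) list(lambda_z = NA_real_,
                                          half_life = NA_real_,
                                          r_squared = NA_real_,
                                          n_points = NA_integer_,
                                          flag = conditionMessage(e)))
  c_last <- profile$concentrations[length(profile$concentrations)]
  ext <- compute_auc_inf(auc_0t, c_last, lz$lambda_z)
  cl <- vd <- NA_real_
  if (!is.na(profile$dose_amount) && !is.na(lz$lambda_z)) {
    cv <- compute_cl_vd(profile$dose_amount, ext$auc_0inf, lz$lambda_z)
    cl <- cv$cl; vd <- cv$vd
  }
  structure(list(subject_id = profile$subject_id, group = profile$group,
                 matrix = profile$matrix, auc_0t = auc_0t, auc_se = auc_se,
                 auc_0inf = ext$auc_0inf,
                 pct_extrapolated = ext$pct_extrapolated,
                 lambda_z = lz$lambda_z, half_life = lz$half_life,
                 r_squared_lambda_z = lz$r_squared,
                 n_points_lambda_z = lz$n_points, cl = cl, vd = vd,
                 flags = stats::na.omit(c(lz$flag, ext$flag))),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s | %s | %s\n", x$subject_id, x$group, x$matrix))
  cat(sprintf("  AUC(0-t) %.4g  AUC(0-inf) %.4g  lambda_z %.4g /h  t1/2 %.4g h\n",
              x$auc_0t, x$auc_0inf, x$lambda_z, x$half_life))
  if (!is.na(x$cl)) cat(sprintf("  CL %.4g mL/h/kg  Vd %.4g mL/kg\n", x$cl, x$vd))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, matrix = x$matrix,
             auc_0t = x$auc_0t, auc_se = x$auc_se, auc_0inf = x$auc_0inf,
             pct_extrapolated = x$pct_extrapolated, lambda_z = x$lambda_z,
             half_life = x$half_life,
             r_squared_lambda_z = x$r_squared_lambda_z,
             n_points_lambda_z = x$n_points_lambda_z, cl = x$cl, vd = x$vd,
             flags = paste(x$flags, collapse = "; "))
}
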