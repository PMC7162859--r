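#' Fit the Hill equation to a viability table
#'
#' Least-squares fit of
#' E(C) = bottom + (top - bottom) / (1 + (C/EC50)^h)
#' on log10 concentration, describing viability falling from `top` toward
#' `bottom` with increasing drug concentration. By default the top asymptote
#' is fixed at 100% of control and the bottom is free in [0, 100]. The
#' starting EC50 is the tested concentration whose mean response is nearest
#' the asymptote midpoint and the starting Hill coefficient is 1, so fits
#' are reproducible.
#'
#' @param table A [viability_table].
#' @param top_policy `"fixed100"` (default) or `"free"`.
#' @return A list of class `dose_response_fit` with `ec50` (nM),
#'   `hill_coefficient`, `top`, `bottom`, `se_ec50`, `se_hill`,
#'   `residual_sd` (percent), `converged`, and `flag` (`"no inhibition"`
#'   when viability rises with concentration, `"extrapolated"` when the
#'   EC50 falls outside the tested range).
#' @export
fit_hill <- function(table, top_policy = c("fixed100", "free")) {
  top_policy <- match.arg(top_policy)
  stopifnot(inherits(table, "viability_table"))
  conc <- table$concentration; viab <- table$viability
  if (length(unique(conc)) < 4) {
    stop("Hill fit requires >= 4 distinct concentrations", call. = FALSE)
  }
  means <- tapply(viab, conc, mean)
  cgrid <- as.numeric(names(means))
  o <- order(cgrid); cgrid <- cgrid[o]; means <- as.numeric(means)[o]
  if (stats::cor(log10(cgrid), means, method = "spearman") > 0) {
    return(structure(list(ec50 = NA_real_, hill_coefficient = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          se_ec50 = NA_real_, se_hill = NA_real_,
                          residual_sd = NA_real_, converged = FALSE,
                          flag = "no inhibition",
                          cell_line = attr(table, "cell_line")),
                     class = "dose_response_fit"))
  }
  x <- log10(conc)
  top0 <- if (top_policy == "fixed100") 100 else max(means)
  bot0 <- max(min(means), 0)
  mid <- (top0 + bot0) / 2
  p0 <- log10(cgrid[which.min(abs(means - mid))])
  model <- function(par) {
    top <- if (top_policy == "fixed100") 100 else par[["top"]]
    par[["bottom"]] + (top - par[["bottom"]]) /
      (1 + 10^(par[["h"]] * (x - par[["logec50"]])))
  }
  start <- c(logec50 = p0, h = 1, bottom = bot0)
  lower <- c(-12, 1e-3, 0); upper <- c(12, 20, 100)
  if (top_policy == "free") {
    start <- c(start, top = top0)
    lower <- c(lower, 0); upper <- c(upper, 200)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(par) viab - model(par),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$info %in% 1:4) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(ec50 = NA_real_, hill_coefficient = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          se_ec50 = NA_real_, se_hill = NA_real_,
                          residual_sd = NA_real_, converged = FALSE,
                          flag = paste("non-convergence:", msg),
                          cell_line = attr(table, "cell_line")),
                     class = "dose_response_fit"))
  }
  cf <- fit$par
  dof <- length(viab) - length(cf)
  sigma <- sqrt(fit$deviance / dof)
  se <- tryCatch(sigma * sqrt(diag(solve(fit$hessian))),
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  ec50 <- 10^cf[["logec50"]]
  flag <- if (ec50 < min(cgrid) || ec50 > max(cgrid)) "extrapolated"
          else NA_character_
  structure(list(
    ec50 = ec50, hill_coefficient = cf[["h"]],
    top = if (top_policy == "fixed100") 100 else cf[["top"]],
    bottom = cf[["bottom"]],
    se_ec50 = log(10) * ec50 * unname(se["logec50"]),
    se_hill = unname(se["h"]),
    residual_sd = sigma, converged = TRUE, flag = flag,
    cell_line = attr(table, "cell_line")),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s\n",
              if (is.na(x$cell_line)) "" else x$cell_line))
  if (x$converged) {
    cat(sprintf("  EC50 %.4g nM (SE %.3g)  Hill %.3g  top %.3g  bottom %.3g\n",
                x$ec50, x$se_ec50, x$hill_coefficient, x$top, x$bottom))
  }
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Unbound (free) molar concentration-time profile
#'
#' Converts a total-drug tissue or plasma profile to unbound molar units:
#' C_u (nM) = C_total . fu . 1000 / molar_mass, with C_total in ng/mL (or
#' ng/g at unit tissue density) and molar_mass in g/mol.
#'
#' @param profile A [pk_profile] of total concentrations.
#' @param fu Unbound fraction in (0, 1].
#' @param molar_mass Molar mass of the drug in g/mol, > 0.
#' @return A list of class `unbound_profile` with `times` (h) and
#'   `conc_nM`.
#' @export
unbound_profile <- function(profile, fu, molar_mass) {
  validate_pk_profile(profile)
  stopifnot(fu > 0, fu <= 1)
  if (missing(molar_mass) || !is.finite(molar_mass) || molar_mass <= 0) {
    stop("a positive molar mass (g/mol) is required", call. = FALSE)
  }
  structure(list(times = profile$times,
                 conc_nM = profile$concentrations * fu * 1000 / molar_mass,
                 matrix = profile$matrix, group = profile$group,
                 fold = 1),
            class = "unbound_profile")
}

#' Scale an unbound profile by a fold change
#'
#' Pointwise multiplication of the unbound concentrations, used to predict
#' exposure under efflux inhibition (e.g. 10-fold as with a dual P-gp/Bcrp
#' inhibitor) or transporter deficiency (e.g. 50-fold).
#'
#' @param profile An `unbound_profile`.
#' @param fold Multiplier >= 0.
#' @return The scaled `unbound_profile`; the cumulative fold applied is
#'   tracked in `$fold`.
#' @export
apply_fold <- function(profile, fold) {
  stopifnot(inherits(profile, "unbound_profile"), fold >= 0)
  profile$conc_nM <- profile$conc_nM * fold
  profile$fold <- profile$fold * fold
  profile
}

#' Time spent above a potency threshold
#'
#' Measures the total time within the observed span during which the
#' (unbound) concentration exceeds a threshold such as an in-vitro EC50.
#' Crossings between adjacent samples are located by interpolation:
#' log-linear on declining positive segments (consistent with first-order
#' elimination) and linear otherwise by default, or purely linear.
#'
#' @param profile An `unbound_profile` with >= 2 points.
#' @param threshold Threshold in nM, > 0.
#' @param interp `"loglinear"` (default) or `"linear"`.
#' @return A list with `hours` above the threshold and
#'   `fraction_of_interval` of the observed span.
#' @export
time_above_threshold <- function(profile, threshold,
                                 interp = c("loglinear", "linear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(profile, "unbound_profile"))
  t <- profile$times; c <- profile$conc_nM
  if (length(t) < 2) stop("need >= 2 points", call. = FALSE)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    t1 <- t[i]; t2 <- t[i + 1]; c1 <- c[i]; c2 <- c[i + 1]
    above1 <- c1 > threshold; above2 <- c2 > threshold
    if (above1 && above2) {
      total <- total + (t2 - t1)
    } else if (above1 || above2) {
      use_log <- interp == "loglinear" && c1 > 0 && c2 > 0 && c2 < c1
      tc <- if (use_log) {
        t1 + (t2 - t1) * log(threshold / c1) / log(c2 / c1)
      } else {
        t1 + (t2 - t1) * (threshold - c1) / (c2 - c1)
      }
      total <- total + if (above1) tc - t1 else t2 - tc
    }
  }
  list(hours = total, fraction_of_interval = total / (t[length(t)] - t[1]))
}

#' Exposure-scenario table
#'
#' For each fold change, scales the unbound profile and reports the time
#' above the threshold, reproducing the usual what-if comparison of
#' baseline, efflux-inhibited and efflux-deficient brain exposure against an
#' in-vitro potency threshold.
#'
#' @param profile An `unbound_profile`.
#' @param folds Numeric vector of fold changes (default `c(1, 10, 50)`).
#' @param threshold Threshold in nM (e.g. an EC50).
#' @param interp Passed to [time_above_threshold].
#' @return A data.frame with columns `fold`, `threshold_nM`, `time_above_h`,
#'   `fraction_of_interval`.
#' @export
exposure_scenarios <- function(profile, folds = c(1, 10, 50), threshold,
                               interp = c("loglinear", "linear")) {
  interp <- match.arg(interp)
  rows <- lapply(folds, function(f) {
    ta <- time_above_threshold(apply_fold(profile, f), threshold, interp)
    data.frame(fold = f, threshold_nM = threshold,
               time_above_h = ta$hours,
               fraction_of_interval = ta$fraction_of_interval)
  })
  do.call(rbind, rows)
}
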