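#' Simulation parameters for the plasma-brain PK model
#'
#' Plasma follows a bi-exponential disposition after an iv bolus:
#' Cp(t) = A.exp(-alpha.t) + B.exp(-beta.t), with A + B = dose/v_central,
#' A = dist_frac x C0, and beta chosen so total plasma clearance equals
#' `cl_plasma`. The brain compartment obeys
#' dCb/dt = kin.Cp - (kout_passive + efflux_factor.k_efflux).Cb,
#' with brain mass transfer assumed too small to perturb plasma. At the
#' AUC(0-inf) level the model's true partition coefficient is
#' Kp = kin / (kout_passive + efflux_factor.k_efflux).
#'
#' Defaults represent a highly bound, heavily effluxed small molecule after
#' a 5 mg/kg iv bolus: the wild-type configuration (efflux_factor = 1)
#' gives Kp = 0.23 and the efflux-deficient configuration
#' (efflux_factor = 0) Kp = 12.12, with fu_plasma = 0.006 and
#' fu_brain = 0.0005.
#'
#' @param dose Dose, mg/kg.
#' @param cl_plasma Plasma clearance, mL/h/kg.
#' @param v_central Central volume, mL/kg.
#' @param dist_alpha Distribution-phase rate, 1/h.
#' @param dist_frac Fraction of the initial concentration in the
#'   distribution phase, in [0, 1).
#' @param kin_brain Plasma-to-brain uptake rate, 1/h.
#' @param kout_passive Passive brain efflux rate, 1/h.
#' @param k_efflux Active (transporter-mediated) efflux rate at full
#'   activity, 1/h.
#' @param efflux_factor Scale on active efflux: 1 wild-type, 0 knockout /
#'   complete inhibition, intermediate for partial inhibition.
#' @param fu_plasma,fu_brain Unbound fractions.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise.
#' @return A list of class `pk_sim_params`.
#' @export
pk_sim_params <- function(dose = 5, cl_plasma = 600, v_central = 2000,
                          dist_alpha = 2, dist_frac = 0.7,
                          kin_brain = 1.818, kout_passive = 0.15,
                          k_efflux = 7.754, efflux_factor = 1,
                          fu_plasma = 0.006, fu_brain = 0.0005,
                          noise_cv = 0.2) {
  stopifnot(dose > 0, cl_plasma > 0, v_central > 0, dist_alpha > 0,
            dist_frac >= 0, dist_frac < 1, kin_brain > 0, kout_passive > 0,
            k_efflux >= 0, efflux_factor >= 0,
            fu_plasma > 0, fu_plasma <= 1, fu_brain > 0, fu_brain <= 1,
            noise_cv >= 0)
  if (v_central / cl_plasma <= dist_frac / dist_alpha) {
    stop("inconsistent disposition: v_central/cl_plasma must exceed dist_frac/dist_alpha",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pk_sim_params")
}

#' Named parameter presets for the study arms
#'
#' `"wildtype"` (full efflux), `"tko"` (transporter triple-knockout, no
#' active efflux) and `"elacridar"` (co-dosed dual inhibitor, modelled as
#' 90% efflux inhibition, giving the roughly 10-fold brain-exposure gain
#' seen with pharmacologic inhibition versus the roughly 50-fold gain of
#' genetic deletion).
#'
#' @param preset One of `"wildtype"`, `"tko"`, `"elacridar"`.
#' @param ... Overrides passed to [pk_sim_params].
#' @return A `pk_sim_params` object.
#' @export
pk_preset <- function(preset = c("wildtype", "tko", "elacridar"), ...) {
  preset <- match.arg(preset)
  ef <- switch(preset, wildtype = 1, tko = 0, elacridar = 0.1)
  pk_sim_params(efflux_factor = ef, ...)
}

#' Noiseless model concentrations on a time grid
#'
#' @param params A [pk_sim_params].
#' @param times Hours, >= 0.
#' @return A data.frame with `time`, `plasma` (ng/mL), `brain` (ng/g).
#' @export
pk_curve <- function(params, times) {
  stopifnot(inherits(params, "pk_sim_params"), all(times >= 0))
  c0 <- params$dose * 1e6 / params$v_central
  a_coef <- params$dist_frac * c0
  b_coef <- (1 - params$dist_frac) * c0
  beta <- (1 - params$dist_frac) /
    (params$v_central / params$cl_plasma -
       params$dist_frac / params$dist_alpha)
  rates <- c(params$dist_alpha, beta)
  coefs <- c(a_coef, b_coef)
  plasma <- coefs[1] * exp(-rates[1] * times) +
    coefs[2] * exp(-rates[2] * times)
  kout <- params$kout_passive + params$efflux_factor * params$k_efflux
  brain <- numeric(length(times))
  for (j in 1:2) {
    if (abs(kout - rates[j]) < 1e-8) {
      brain <- brain + params$kin_brain * coefs[j] * times *
        exp(-kout * times)
    } else {
      brain <- brain + params$kin_brain * coefs[j] / (kout - rates[j]) *
        (exp(-rates[j] * times) - exp(-kout * times))
    }
  }
  data.frame(time = times, plasma = plasma, brain = brain)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate plasma and brain concentration-time profiles
#'
#' Draws `n_subjects` replicate animals, each observed on `sample_times`
#' with multiplicative lognormal measurement noise around the model curve.
#' Output is seed-reproducible.
#'
#' @param params A [pk_sim_params].
#' @param sample_times Sampling times, hours (default the study design
#'   0.17-15 h).
#' @param n_subjects Animals per arm (default 4).
#' @param group Group label stamped on the profiles.
#' @param seed Integer seed.
#' @return A list of [pk_profile] objects (plasma and brain per subject).
#' @export
simulate_pk <- function(params,
                        sample_times = c(0.17, 0.5, 1, 2, 4, 8, 15),
                        n_subjects = 4, group = "sim", seed = 1L) {
  stopifnot(inherits(params, "pk_sim_params"), n_subjects >= 1)
  curve <- pk_curve(params, sample_times)
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", group, i)
      pl <- curve$plasma * lognormal_noise(nrow(curve), params$noise_cv)
      br <- curve$brain * lognormal_noise(nrow(curve), params$noise_cv)
      out[[length(out) + 1]] <- pk_profile(sid, group, "plasma",
                                           curve$time, pl,
                                           dose_amount = params$dose,
                                           route = "iv")
      out[[length(out) + 1]] <- pk_profile(sid, group, "brain",
                                           curve$time, br,
                                           dose_amount = params$dose,
                                           route = "iv")
    }
    out
  })
}

#' Simulate a rapid-equilibrium-dialysis measurement
#'
#' Forward model of the homogenate-dilution effect: a matrix with true
#' unbound fraction `fu_true` dialysed at dilution D shows an apparent
#' fraction fu_app = D.fu_true / (1 + (D - 1).fu_true). The donor is spiked
#' to 1 uM; multiplicative lognormal noise is applied to both chambers.
#'
#' @param fu_true True undiluted unbound fraction in (0, 1].
#' @param dilution_factor D >= 1.
#' @param noise_cv CV of lognormal assay noise (0 for exact).
#' @param matrix `"plasma"` or `"brain_homogenate"`.
#' @param seed Integer seed.
#' @return A [dialysis_measurement].
#' @export
simulate_red <- function(fu_true, dilution_factor = 1, noise_cv = 0,
                         matrix = c("plasma", "brain_homogenate"),
                         seed = 1L) {
  matrix <- match.arg(matrix)
  stopifnot(fu_true > 0, fu_true <= 1, dilution_factor >= 1, noise_cv >= 0)
  fu_app <- dilution_factor * fu_true /
    (1 + (dilution_factor - 1) * fu_true)
  withr::with_seed(seed, {
    donor <- 1 * lognormal_noise(1, noise_cv)
    receiver <- min(fu_app * donor * lognormal_noise(1, noise_cv), donor)
  })
  dialysis_measurement(matrix = matrix, donor_conc = donor,
                       receiver_conc = receiver,
                       dilution_factor = dilution_factor)
}

#' Simulate a replicate-resolved viability table
#'
#' Hill-model mean response with additive Gaussian noise, clipped at 0
#' (viability percentages cannot be negative).
#'
#' @param ec50 True EC50, nM.
#' @param hill True Hill coefficient.
#' @param top,bottom Asymptotes, percent of control.
#' @param conc_grid Concentrations in nM (default an 8-point log grid over
#'   0.025-1000 nM, the assay's tested range).
#' @param n_reps Replicates per concentration (default 10 wells).
#' @param noise_sd SD of Gaussian noise, percent.
#' @param cell_line Label.
#' @param seed Integer seed.
#' @return A [viability_table].
#' @export
simulate_viability <- function(ec50, hill = 1, top = 100, bottom = 0,
                               conc_grid = exp(seq(log(0.025), log(1000),
                                                   length.out = 8)),
                               n_reps = 10, noise_sd = 5,
                               cell_line = "sim", seed = 1L) {
  stopifnot(ec50 > 0, hill > 0, bottom <= top, n_reps >= 1, noise_sd >= 0)
  conc <- rep(conc_grid, each = n_reps)
  mu <- bottom + (top - bottom) / (1 + (conc / ec50)^hill)
  withr::with_seed(seed, {
    v <- pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0)
  })
  viability_table(cell_line = cell_line, concentrations = conc,
                  viability = v,
                  replicate = rep(seq_len(n_reps), times = length(conc_grid)))
}

#' Simulate bioluminescence growth series
#'
#' Exponential tumor growth: flux = t0_flux . 2^(t/doubling_time) with
#' multiplicative lognormal noise per observation. `doubling_time = Inf`
#' yields a constant (non-growing) series.
#'
#' @param doubling_time Days (may be `Inf`).
#' @param t0_flux Flux at t = 0, photons/s.
#' @param times Observation days (default 8 points over the treatment
#'   period, days 7-37).
#' @param noise_cv CV of lognormal noise.
#' @param n_animals Animals (default 10).
#' @param group Group label.
#' @param seed Integer seed.
#' @return A list of [bli_series].
#' @export
simulate_bli <- function(doubling_time, t0_flux = 2e9,
                         times = seq(7, 37, length.out = 8),
                         noise_cv = 0.2, n_animals = 10, group = "sim",
                         seed = 1L) {
  stopifnot(doubling_time > 0, t0_flux > 0, noise_cv >= 0, n_animals >= 1)
  mu <- if (is.infinite(doubling_time)) rep(t0_flux, length(times))
        else t0_flux * 2^(times / doubling_time)
  withr::with_seed(seed, {
    lapply(seq_len(n_animals), function(i) {
      bli_series(sprintf("%s_%02d", group, i), group, times,
                 mu * lognormal_noise(length(times), noise_cv))
    })
  })
}

#' Simulate survival times
#'
#' Weibull event times with the scale set so the distribution median equals
#' `median` (scale = median / ln(2)^(1/shape)); animals alive at
#' `censor_day` are right-censored there. Shape 1 reduces to the
#' exponential distribution.
#'
#' @param median Target distribution median, days.
#' @param shape Weibull shape, > 0.
#' @param n Animals.
#' @param censor_day Administrative censoring day (default `Inf`: none).
#' @param group Group label.
#' @param seed Integer seed.
#' @return A [survival_records] data.frame.
#' @export
simulate_survival <- function(median, shape = 4, n = 10, censor_day = Inf,
                              group = "sim", seed = 1L) {
  stopifnot(median > 0, shape > 0, n >= 1, censor_day > 0)
  scale <- median / log(2)^(1 / shape)
  withr::with_seed(seed, {
    tt <- stats::rweibull(n, shape = shape, scale = scale)
  })
  event <- as.integer(tt <= censor_day)
  survival_records(sprintf("%s_%02d", group, seq_len(n)), group,
                   pmin(tt, censor_day), event)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic mixing of a global seed with a stage label so that the
#' stages of one simulated study draw independent but reproducible streams.
#' The result stays below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
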