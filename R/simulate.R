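#' Specify a ground-truth pathway kernel
#'
#' A true kernel for one input->output pathway of the two-input linear
#' dynamic model, parameterized by Laguerre coefficients so that the
#' generating dynamics live in the same model class the estimator fits.
#' The kernel (in output units per input unit per lag) is
#' `gain_scale * laguerre_basis(alpha, length(coeffs), M)$B %*% coeffs`.
#'
#' @param pathway One of `"ABP->CBV"`, `"CO2->CBV"`, `"ABP->OXY"`,
#'   `"CO2->OXY"`.
#' @param coeffs Numeric vector of Laguerre coefficients (dimensionless).
#' @param alpha Laguerre decay parameter in (0, 1).
#' @param gain_scale Overall scale in output units per input unit
#'   (e.g. cm/s per mmHg for the velocity pathways).
#' @param M Kernel memory in lags.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(pathway, coeffs, alpha = 0.5, gain_scale = 1, M = 60) {
  pathway <- match.arg(pathway, .pathways)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (length(coeffs) < 1 || length(coeffs) > 9) {
    abort("`coeffs` must have between 1 and 9 elements.")
  }
  structure(
    list(pathway = pathway, coeffs = as.numeric(coeffs), alpha = alpha,
         gain_scale = gain_scale, M = as.integer(M)),
    class = "kernel_spec"
  )
}

#' Reconstruct the kernel vector of a [kernel_spec()]
#' @param spec A `kernel_spec`.
#' @return Numeric vector of length `spec$M`.
#' @export
true_kernel <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  b <- laguerre_basis(spec$alpha, length(spec$coeffs), spec$M)
  as.vector(b$B %*% spec$coeffs) * spec$gain_scale
}

# Default pathway dynamics: plausible resting-state magnitudes
# (autoregulation ~0.2 cm/s per mmHg at steady state, CO2 reactivity
# ~1-2 cm/s per mmHg, oxygenation responses two orders smaller in %/mmHg).
default_kernel_specs <- function(M = 60) {
  list(
    "ABP->CBV" = kernel_spec("ABP->CBV", c(0.60, -0.25, 0.08), 0.45, 0.30, M),
    "CO2->CBV" = kernel_spec("CO2->CBV", c(0.50, 0.30, -0.10), 0.55, 1.50, M),
    "ABP->OXY" = kernel_spec("ABP->OXY", c(0.50, -0.20, 0.05), 0.50, 0.03, M),
    "CO2->OXY" = kernel_spec("CO2->OXY", c(0.50, 0.25, -0.08), 0.55, 0.15, M)
  )
}

#' Specify one synthetic subject
#'
#' @param subject_id Character id.
#' @param group `"CN"`, `"MCI"` or `"dementia"`.
#' @param apoe_e4 Logical, APOE epsilon-4 carrier.
#' @param kernel_specs Named list with exactly one [kernel_spec()] per
#'   pathway.
#' @param noise_sd Output measurement-noise SD, a single value or a vector
#'   named by channel (`CBV`, `OXY`), in output units.
#' @param artifact_rate Expected artifact spikes per minute per output
#'   channel.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id, group = "CN", apoe_e4 = FALSE,
                         kernel_specs = default_kernel_specs(),
                         noise_sd = c(CBV = 0.6, OXY = 0.15),
                         artifact_rate = 0) {
  group <- match.arg(group, c("CN", "MCI", "dementia"))
  if (!setequal(names(kernel_specs), .pathways)) {
    abort("`kernel_specs` must contain exactly one spec per pathway.")
  }
  if (any(noise_sd < 0)) abort("`noise_sd` must be non-negative.")
  if (length(noise_sd) == 1) noise_sd <- c(CBV = unname(noise_sd), OXY = unname(noise_sd))
  structure(
    list(subject_id = as.character(subject_id), group = group,
         apoe_e4 = isTRUE(apoe_e4), kernel_specs = kernel_specs[.pathways],
         noise_sd = noise_sd, artifact_rate = artifact_rate),
    class = "subject_spec"
  )
}

# Band-limited spontaneous fluctuation as random-phase harmonic synthesis:
# a sum of sinusoids with frequencies in `band` and 1/f-weighted amplitudes
# scaled to the target SD. Being a closed-form function of continuous time,
# it can be evaluated exactly at irregular beat/breath times and at the
# lagged times the forward convolution needs.
band_signal <- function(mean, sd, band, n_components = 48) {
  f <- sort(runif(n_components, band[1], band[2]))
  phi <- runif(n_components, 0, 2 * pi)
  a <- 1 / sqrt(f / band[1]) # mildly red spectrum within the band
  if (sd > 0) a <- a * sd / sqrt(sum(a^2) / 2) else a <- a * 0
  w <- 2 * pi * f
  list(
    mean = mean, f = f, a = a, phi = phi,
    eval = function(t) {
      if (length(t) == 0) return(numeric(0))
      mean + as.vector(sin(outer(t, w) + rep(phi, each = length(t))) %*% a)
    }
  )
}

# Irregular event times: log-normal inter-event intervals clipped to a
# physiologic range, so the spline-resampling stage is genuinely exercised.
# `t_start` may be negative to cover the pre-record kernel memory.
event_times <- function(duration_s, meanlog, sdlog, lo, hi, t_start = 0) {
  n <- ceiling((duration_s - t_start) / lo) + 2
  iv <- pmin(pmax(rlnorm(n, meanlog, sdlog), lo), hi)
  t <- t_start + cumsum(c(0, iv))
  t[t <= duration_s]
}

#' Generate spontaneous arterial-pressure and end-tidal CO2 input series
#'
#' Simulates ~8 minutes of resting beat-to-beat arterial blood pressure and
#' breath-to-breath end-tidal CO2 with band-limited low-frequency
#' fluctuations around physiologic means. Beat intervals fall in
#' 0.6--1.3 s and breath intervals in 2.5--7 s.
#'
#' @param duration_s Recording duration in seconds (>= 120).
#' @param seed Optional integer seed for reproducibility.
#' @param abp_mean,abp_sd ABP mean and fluctuation SD (mmHg).
#' @param etco2_mean,etco2_sd ETCO2 mean and fluctuation SD (mmHg).
#' @param fluctuation_scale Multiplier on both fluctuation SDs (0 gives
#'   constant series at the means).
#' @return A list with tibbles `abp` and `etco2` (`time_s`, `value`).
#' @export
generate_input_signals <- function(duration_s = 480, seed = NULL,
                                   abp_mean = 90, abp_sd = 4,
                                   etco2_mean = 38, etco2_sd = 1.5,
                                   fluctuation_scale = 1) {
  sig <- input_generators(duration_s, seed, abp_mean, abp_sd * fluctuation_scale,
                          etco2_mean, etco2_sd * fluctuation_scale)
  list(
    abp = tibble::tibble(time_s = sig$beat_t, value = sig$abp$eval(sig$beat_t)),
    etco2 = tibble::tibble(time_s = sig$breath_t, value = sig$co2$eval(sig$breath_t))
  )
}

input_generators <- function(duration_s, seed = NULL, abp_mean = 90, abp_sd = 4,
                             etco2_mean = 38, etco2_sd = 1.5) {
  if (!is.numeric(duration_s) || duration_s < 120) {
    abort("`duration_s` must be at least 120 seconds.")
  }
  if (!is.null(seed)) set.seed(seed)
  # ABP fluctuations span the full very-low/low-frequency band; ETCO2
  # variability is physiologically slower and must stay well below the
  # breath Nyquist rate so breath-to-breath sampling can represent it.
  abp <- band_signal(abp_mean, abp_sd, c(0.018, 0.10))
  co2 <- band_signal(etco2_mean, etco2_sd, c(0.018, 0.035))
  beat_t <- event_times(duration_s, log(0.88), 0.09, 0.6, 1.3)
  breath_t <- event_times(duration_s, log(4.0), 0.18, 2.5, 7.0)
  list(abp = abp, co2 = co2, beat_t = beat_t, breath_t = breath_t)
}

# Evaluate the two-input convolution y(t) = k0 + sum_m k_abp(m) xa(t - m Ts)
# + sum_m k_co2(m) xc(t - m Ts) at arbitrary times, using the continuous
# input generators (demeaned).
convolve_at <- function(t, k_abp, k_co2, Ts, abp, co2, offset) {
  lags <- (seq_along(k_abp) - 1) * Ts
  y <- rep(offset, length(t))
  tl <- as.vector(outer(t, lags, `-`))
  Xa <- matrix(abp$eval(tl) - abp$mean, nrow = length(t))
  Xc <- matrix(co2$eval(tl) - co2$mean, nrow = length(t))
  y + as.vector(Xa %*% k_abp) + as.vector(Xc %*% k_co2)
}

inject_artifacts <- function(values, rate_per_min, duration_s) {
  n_spikes <- rpois(1, rate_per_min * duration_s / 60)
  idx <- integer(0)
  if (n_spikes > 0) {
    idx <- sort(sample(seq_along(values), min(n_spikes, length(values))))
    s <- sd(values)
    if (s == 0) s <- 1
    # A spike is a 4-6 channel-SD excursion from the channel mean, so it is
    # removable by the +/- 3 SD rule by construction.
    values[idx] <- mean(values) +
      sample(c(-1, 1), length(idx), replace = TRUE) * runif(length(idx), 4, 6) * s
  }
  list(values = values, idx = idx)
}

#' Generate a full synthetic subject recording
#'
#' Forward-simulates the two-input linear dynamic model: cerebral blood
#' velocity and tissue oxygenation equal the convolution of the demeaned
#' ABP/ETCO2 fluctuations with the subject's true kernels plus a constant
#' offset, Gaussian measurement noise, and Poisson-placed artifact spikes
#' of 4--6 channel-SDs. CBV is sampled at beat times; OXY at a regular
#' device rate.
#'
#' @param spec A [subject_spec()].
#' @param duration_s Recording length in seconds.
#' @param seed Optional integer seed.
#' @param Ts Lag step of the true kernels (s).
#' @param oxy_rate_s Sampling interval of the oxygenation device (s).
#' @param cbv_offset,oxy_offset Channel baselines (cm/s, %).
#' @return A [physio_recording()] whose `truth` metadata stores the true
#'   kernels, offsets and injected-artifact bookkeeping.
#' @export
generate_subject_recording <- function(spec, duration_s = 480, seed = NULL,
                                       Ts = 1, oxy_rate_s = 0.5,
                                       cbv_offset = 55, oxy_offset = 68) {
  stopifnot(inherits(spec, "subject_spec"))
  M <- spec$kernel_specs[[1]]$M
  if (M * Ts >= duration_s) {
    abort("Kernel memory exceeds the recording duration.")
  }
  if (!is.null(seed)) set.seed(seed)
  # Event times extend before t = 0 so the convolution has a full memory of
  # observed-like input at the start of the record.
  pre <- -(M * Ts + 10)
  beat_all <- event_times(duration_s, log(0.88), 0.09, 0.6, 1.3, t_start = pre)
  breath_all <- event_times(duration_s, log(4.0), 0.18, 2.5, 7.0, t_start = pre)
  abp_raw <- band_signal(90, 4, c(0.018, 0.10))
  co2_raw <- band_signal(38, 1.5, c(0.018, 0.035))
  # The effective stimulus seen by the model is the cubic-spline
  # interpolation of the event-sampled values: end-tidal CO2 only exists
  # per breath, and finger-pressure only per beat, so the smooth
  # interpolant is the natural continuous-time input.
  abp <- list(mean = abp_raw$mean,
              eval = splinefun(beat_all, abp_raw$eval(beat_all), method = "fmm"))
  co2 <- list(mean = co2_raw$mean,
              eval = splinefun(breath_all, co2_raw$eval(breath_all), method = "fmm"))
  beat_t <- beat_all[beat_all >= 0]
  breath_t <- breath_all[breath_all >= 0]

  k <- lapply(spec$kernel_specs, true_kernel)
  oxy_t <- seq(0, duration_s, by = oxy_rate_s)

  cbv <- convolve_at(beat_t, k[["ABP->CBV"]], k[["CO2->CBV"]], Ts,
                     abp, co2, cbv_offset)
  oxy <- convolve_at(oxy_t, k[["ABP->OXY"]], k[["CO2->OXY"]], Ts,
                     abp, co2, oxy_offset)
  cbv <- cbv + rnorm(length(cbv), 0, spec$noise_sd[["CBV"]])
  oxy <- oxy + rnorm(length(oxy), 0, spec$noise_sd[["OXY"]])
  art_cbv <- inject_artifacts(cbv, spec$artifact_rate, duration_s)
  art_oxy <- inject_artifacts(oxy, spec$artifact_rate, duration_s)

  physio_recording(
    subject_id = spec$subject_id,
    channels = list(
      ABP = tibble::tibble(time_s = beat_t, value = abp$eval(beat_t)),
      ETCO2 = tibble::tibble(time_s = breath_t, value = co2$eval(breath_t)),
      CBV = tibble::tibble(time_s = beat_t, value = art_cbv$values),
      OXY = tibble::tibble(time_s = oxy_t, value = art_oxy$values)
    ),
    duration_s = duration_s,
    metadata = list(
      group = spec$group, apoe_e4 = spec$apoe_e4,
      truth = list(
        kernels = k, Ts = Ts,
        offsets = c(CBV = cbv_offset, OXY = oxy_offset),
        artifacts = list(
          CBV = list(n = length(art_cbv$idx), idx = art_cbv$idx,
                     time_s = beat_t[art_cbv$idx]),
          OXY = list(n = length(art_oxy$idx), idx = art_oxy$idx,
                     time_s = oxy_t[art_oxy$idx])
        )
      )
    )
  )
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the study cohort: 61/45/27 CN/MCI/dementia subjects,
#' ~41% APOE epsilon-4 carriers, kernel gains shifted downward in the
#' impaired groups, and neuroimaging outcomes generated as standardized
#' linear functions of the true (latent) hemodynamic indices.
#'
#' @param n_per_group Named counts for CN/MCI/dementia.
#' @param group_gain_shifts Mean shift of the latent gain severity per
#'   group, in between-subject SD units (CN is the reference at 0).
#' @param outcome_effects Tibble with columns `outcome`, `index`, `beta`
#'   giving the standardized slope of each outcome on each true index.
#' @param apoe_p Carrier probability.
#' @param apoe_gain_shift Additive latent-gain shift for carriers.
#' @param gain_cv Coefficient of variation of kernel scale per 1 latent SD.
#' @param pathway_noise_sd SD of the pathway-specific part of the latent
#'   gain (shared severity has SD 1).
#' @param noise_sd,artifact_rate Passed to [subject_spec()].
#' @param duration_s Recording length when recordings are generated.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(CN = 61, MCI = 45, dementia = 27),
                          group_gain_shifts = c(CN = 0, MCI = -1.0, dementia = -1.25),
                          outcome_effects = default_outcome_effects(),
                          apoe_p = 0.413,
                          apoe_gain_shift = 0.3,
                          gain_cv = 0.25,
                          pathway_noise_sd = 0.5,
                          noise_sd = c(CBV = 0.6, OXY = 0.15),
                          artifact_rate = 0.5,
                          duration_s = 480,
                          seed = 20260101) {
  if (any(n_per_group <= 0)) abort("Group counts must be positive.")
  if (!all(c("CN", "MCI", "dementia") %in% names(n_per_group))) {
    abort("`n_per_group` must name CN, MCI and dementia counts.")
  }
  if (any(abs(outcome_effects$beta) >= 1)) {
    abort("Standardized slopes in `outcome_effects` must be < 1 in magnitude.")
  }
  structure(
    list(n_per_group = n_per_group, group_gain_shifts = group_gain_shifts,
         outcome_effects = outcome_effects, apoe_p = apoe_p,
         apoe_gain_shift = apoe_gain_shift, gain_cv = gain_cv,
         pathway_noise_sd = pathway_noise_sd, noise_sd = noise_sd,
         artifact_rate = artifact_rate, duration_s = duration_s, seed = seed),
    class = "cohort_config"
  )
}

#' Default standardized outcome effects
#'
#' One driving index per neuroimaging outcome, at the magnitudes of the
#' strongest cohort associations: composite-COR on hippocampal volume
#' (0.26) and amyloid burden (-0.25), DVR on white-matter-hyperintensity
#' volume (-0.20), COPR on AD-signature cortical thickness (0.20).
#' @return A tibble with columns `outcome`, `index`, `beta`.
#' @export
default_outcome_effects <- function() {
  tibble::tribble(
    ~outcome,              ~index,           ~beta,
    "hippocampal_volume",  "composite_COR",   0.26,
    "amyloid_suvr",        "composite_COR",  -0.25,
    "wmh_volume",          "DVR",            -0.20,
    "meta_roi_thickness",  "COPR",            0.20
  )
}

.true_index_cols <- c("true_DVR", "true_DCA", "true_COCR", "true_COPR",
                      "true_composite_COR")

#' Generate a synthetic cohort
#'
#' Draws per-subject covariates, latent hemodynamic severities, true
#' pathway kernels and neuroimaging outcomes, and (optionally) full
#' physiological recordings for every subject. True per-pathway indices
#' are stored in the cohort table (`true_*` columns) for recovery tests.
#'
#' Outcomes are generated as `sum(beta * true_index) + residual`, with the
#' residual scaled so the outcome is standardized and the configured
#' standardized slopes are recovered without attenuation; they are then
#' mapped to plausible raw units by a fixed affine transform.
#'
#' @param config A [cohort_config()].
#' @param make_recordings If `TRUE`, also forward-simulate a
#'   [physio_recording()] per subject (slower).
#' @return A list with `cohort` (tibble), `recordings` (named list or
#'   `NULL`) and `truth` (per-subject kernel specs and the config).
#' @export
generate_cohort <- function(config = cohort_config(), make_recordings = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_group[c("CN", "MCI", "dementia")]
  N <- sum(n)
  groups <- factor(rep(c("CN", "MCI", "dementia"), n),
                   levels = c("CN", "MCI", "dementia"))
  id <- sprintf("S%03d", seq_len(N))

  apoe <- rbinom(N, 1, config$apoe_p) == 1
  age <- rnorm(N, 73, 8)
  sex <- factor(ifelse(rbinom(N, 1, 0.47) == 1, "F", "M"), levels = c("F", "M"))
  site <- factor(sample(c("KUMC", "USC", "UTSW"), N, replace = TRUE,
                        prob = c(0.45, 0.38, 0.17)))
  moca_mu <- c(CN = 26.5, MCI = 22.5, dementia = 15.5)[as.character(groups)]
  moca_sd <- c(CN = 2.2, MCI = 3.0, dementia = 4.5)[as.character(groups)]
  moca <- pmin(pmax(round(rnorm(N, moca_mu, moca_sd)), 0), 30)
  icv <- rnorm(N, 1.45e6, 1.5e5)

  # Latent severity: shared component per subject plus a pathway-specific
  # component; group and APOE shift the shared mean.
  shift <- config$group_gain_shifts[as.character(groups)]
  s <- rnorm(N, shift + config$apoe_gain_shift * (apoe - mean(apoe)), 1)
  latent <- sapply(.pathways, function(p) {
    s + rnorm(N, 0, config$pathway_noise_sd)
  })
  colnames(latent) <- .pathways

  true_idx <- tibble::tibble(
    true_DVR = as.numeric(scale(latent[, "CO2->CBV"])),
    true_DCA = as.numeric(scale(latent[, "ABP->CBV"])),
    true_COCR = as.numeric(scale(latent[, "CO2->OXY"])),
    true_COPR = as.numeric(scale(latent[, "ABP->OXY"])),
    true_composite_COR = as.numeric(
      scale(latent[, "CO2->OXY"] + latent[, "ABP->OXY"])
    )
  )

  # Outcomes: standardized linear combination of true indices plus a
  # residual scaled so the generated outcome has unit variance.
  outcomes <- c("hippocampal_volume", "wmh_volume", "meta_roi_thickness",
                "amyloid_suvr")
  z_out <- sapply(outcomes, function(o) {
    eff <- config$outcome_effects[config$outcome_effects$outcome == o, ]
    lp <- rep(0, N)
    for (i in seq_len(nrow(eff))) {
      lp <- lp + eff$beta[i] * true_idx[[paste0("true_", eff$index[i])]]
    }
    res_var <- max(1 - stats::var(lp), 0.05)
    lp + rnorm(N, 0, sqrt(res_var))
  })
  raw <- tibble::tibble(
    hippocampal_volume = 3400 + 450 * z_out[, "hippocampal_volume"],
    wmh_volume = 6000 + 2500 * z_out[, "wmh_volume"],
    meta_roi_thickness = 2.7 + 0.15 * z_out[, "meta_roi_thickness"],
    amyloid_suvr = 1.35 + 0.25 * z_out[, "amyloid_suvr"]
  )

  cohort <- dplyr::bind_cols(
    tibble::tibble(subject_id = id, diagnosis = groups, apoe_e4 = apoe,
                   age = age, sex = sex, site = site, moca = moca, icv = icv),
    raw, true_idx
  )

  # Per-subject true kernels: base shapes scaled by the latent severity.
  base <- default_kernel_specs()
  subj_specs <- vector("list", N)
  subj_seeds <- sample.int(2^31 - 1, N)
  for (i in seq_len(N)) {
    ks <- lapply(.pathways, function(p) {
      sc <- base[[p]]
      kernel_spec(p, sc$coeffs, sc$alpha,
                  sc$gain_scale * (1 + config$gain_cv * latent[i, p]), sc$M)
    })
    names(ks) <- .pathways
    subj_specs[[i]] <- subject_spec(
      id[i], as.character(groups[i]), apoe[i], ks,
      noise_sd = config$noise_sd, artifact_rate = config$artifact_rate
    )
  }

  recordings <- NULL
  if (make_recordings) {
    recordings <- lapply(seq_len(N), function(i) {
      generate_subject_recording(subj_specs[[i]], config$duration_s,
                                 seed = subj_seeds[i])
    })
    names(recordings) <- id
  }

  list(
    cohort = cohort,
    recordings = recordings,
    truth = list(subject_specs = setNames(subj_specs, id),
                 latent = latent, config = config,
                 subject_seeds = subj_seeds)
  )
}
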