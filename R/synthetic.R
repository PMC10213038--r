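#' Library of planted spectral phenotype archetypes
#'
#' Four archetypes of resting-state (eyes-closed) spectral profiles over the
#' 32-channel montage:
#'
#' 1. *Neurotypical*: posterior-dominant alpha with a clear occipito-parietal
#'    vs frontal gradient.
#' 2. *Slowed*: dominant power shifted from alpha toward theta, with a low
#'    alpha peak frequency.
#' 3. *Low-alpha / high-beta*: weak 10 Hz activity, elevated beta and gamma.
#' 4. *High-alpha with 20 Hz peak*: strong alpha with a reduced
#'    frontal-parietal alpha gradient plus a narrowband beta (20 Hz) peak.
#'
#' Each archetype is a per-channel, per-band relative power target. The
#' `separation` dial linearly scales every archetype's contrast around the
#' archetype-average profile: 1 keeps the library as defined, 0 collapses all
#' phenotypes onto their mean (no separation).
#'
#' @param separation nonnegative scalar contrast multiplier.
#' @return List of 4 objects of class `phenotype_spec`, each with fields
#'   `phenotype_id`, `band_topography` (5 bands x 32 channels, columns
#'   normalized to sum 1), `alpha_peak_hz`, `beta_peak_hz` (NA if none) and
#'   `background_exponent` (1/f slope of the broadband background).
#' @export
phenotype_library <- function(separation = 1) {
  stopifnot(is.numeric(separation), length(separation) == 1, separation >= 0)
  ch <- eeg_montage()
  posterior <- c("O1", "Oz", "O2", "PO3", "PO4", "Pz", "P3", "P4", "P7", "P8")
  frontal   <- c("F3", "F4", "Fz", "F7", "F8", "AF7", "AF8", "Fpz",
                 "AF4", "Fp2", "Fp1", "AF3")
  topo <- function(post, front, rest) {
    v <- rep(rest, length(ch))
    v[ch %in% posterior] <- post
    v[ch %in% frontal] <- front
    v
  }
  flat <- function(x) rep(x, length(ch))
  mk <- function(id, delta, theta, alpha, beta, gamma,
                 alpha_peak, beta_peak, exponent) {
    w <- rbind(delta = delta, theta = theta, alpha = alpha,
               beta = beta, gamma = gamma)
    colnames(w) <- ch
    structure(list(phenotype_id = id, band_topography = w,
                   alpha_peak_hz = alpha_peak, beta_peak_hz = beta_peak,
                   background_exponent = exponent),
              class = "phenotype_spec")
  }
  lib <- list(
    mk(1L, flat(0.15), flat(0.15), topo(0.55, 0.22, 0.35), flat(0.12),
       flat(0.04), alpha_peak = 10, beta_peak = NA_real_, exponent = 1.2),
    mk(2L, flat(0.22), topo(0.45, 0.35, 0.40), flat(0.14), flat(0.12),
       flat(0.04), alpha_peak = 8.5, beta_peak = NA_real_, exponent = 1.4),
    mk(3L, flat(0.18), flat(0.14), flat(0.12), topo(0.38, 0.42, 0.40),
       flat(0.12), alpha_peak = 10, beta_peak = NA_real_, exponent = 1.0),
    mk(4L, flat(0.10), flat(0.10), topo(0.48, 0.42, 0.45), flat(0.28),
       flat(0.05), alpha_peak = 10, beta_peak = 20, exponent = 1.1)
  )
  lib <- lapply(lib, function(p) {
    p$band_topography <- normalize_columns(p$band_topography)
    p
  })
  if (separation != 1) {
    wbar <- Reduce(`+`, lapply(lib, `[[`, "band_topography")) / length(lib)
    lib <- lapply(lib, function(p) {
      w <- wbar + separation * (p$band_topography - wbar)
      p$band_topography <- normalize_columns(pmax(w, 0))
      p
    })
  }
  for (p in lib) validate_phenotype_spec(p)
  lib
}

normalize_columns <- function(w) {
  s <- colSums(w)
  s[s == 0] <- 1
  sweep(w, 2, s, "/")
}

validate_phenotype_spec <- function(p) {
  w <- p$band_topography
  stopifnot(inherits(p, "phenotype_spec"), is.matrix(w), nrow(w) == 5)
  if (any(w < 0)) stop("band_topography weights must be nonnegative")
  if (!any(w > 0)) stop("band_topography must have a positive weight somewhere")
  if (p$alpha_peak_hz < 8 || p$alpha_peak_hz > 13)
    stop("alpha_peak_hz must lie within the alpha band (8-13 Hz)")
  if (p$background_exponent <= 0) stop("background_exponent must be > 0")
  invisible(p)
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study design this package targets: 56 subjects, 4
#' sessions each (one pre-stimulation eyes-closed resting recording per
#' session), 4 spectral phenotypes in equal proportion, small within-subject
#' session-to-session variability, and behavioral active-sham differences
#' whose magnitude is tied to planted cluster membership.
#'
#' @param n_subjects number of subjects (default 56).
#' @param n_sessions sessions per subject (default 4).
#' @param proportions mixing proportions over the phenotype library.
#' @param separation phenotype contrast dial passed to [phenotype_library()].
#' @param subject_cv coefficient of variation of subject-level weight
#'   perturbation around the phenotype archetype (default 0.10).
#' @param session_cv coefficient of variation of session-to-session weight
#'   jitter around the subject profile (default 0.05), chosen so that the four
#'   sessions of a subject stay mutually closer than any other phenotype.
#' @param measurement_sd additive noise on feature-level relative band powers,
#'   emulating PSD estimation error after median aggregation (default 0.005).
#' @param effect_size standardized planted active-sham behavioral shift for
#'   responder phenotypes (default 1).
#' @param responder_classes character vector, one of
#'   `"positive"`, `"negative"`, `"non"` per phenotype.
#' @param accuracy_scale accuracy shift (fraction correct) per unit effect
#'   size (default 0.05).
#' @param rt_scale reaction-time shift in ms per unit effect size (default 40).
#' @param accuracy_noise_sd,rt_noise_sd per-record measurement noise
#'   (accuracy fraction / ms).
#' @param age_delta_slope weak age confound on the active-sham RT difference,
#'   in ms per year of age (default 2); exercises covariate adjustment.
#' @param fs,duration sampling rate (Hz) and recording length (s).
#' @param channel_rms target per-channel RMS amplitude in microvolts.
#' @param cz_gain relative amplitude of the Cz reference channel; kept below 1
#'   so that reference subtraction perturbs relative band powers little.
#' @param background_frac fraction of channel power given to the 1/f
#'   broadband background.
#' @param osc_frac fraction of alpha (and peaked beta) band power concentrated
#'   in the narrowband oscillation at the peak frequency.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 56, n_sessions = 4,
                          proportions = c(0.25, 0.25, 0.25, 0.25),
                          separation = 1,
                          subject_cv = 0.10, session_cv = 0.05,
                          measurement_sd = 0.005,
                          effect_size = 1,
                          responder_classes = c("non", "positive", "negative", "non"),
                          accuracy_scale = 0.05, rt_scale = 40,
                          accuracy_noise_sd = 0.03, rt_noise_sd = 20,
                          age_delta_slope = 2,
                          fs = 500, duration = 120,
                          channel_rms = 15, cz_gain = 0.3,
                          background_frac = 0.05, osc_frac = 0.5) {
  cfg <- as.list(environment())
  n_pheno <- sum(proportions > 0)
  if (n_subjects < n_pheno)
    stop("n_subjects must be at least the number of planted phenotypes")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(c(subject_cv, session_cv, measurement_sd, accuracy_noise_sd,
            rt_noise_sd) < 0))
    stop("noise scales must be nonnegative")
  if (!all(responder_classes %in% c("positive", "negative", "non")))
    stop("responder_classes must be 'positive', 'negative' or 'non'")
  if (length(responder_classes) != length(proportions))
    stop("one responder class per phenotype is required")
  structure(cfg, class = "cohort_config")
}

# Session-level band topography for one subject-session: archetype weights,
# perturbed once at the subject level and once per session, deterministically
# from (seed, subject, session).
session_topography <- function(pheno, subject_id, session_index, seed,
                               subject_cv, session_cv) {
  w <- pheno$band_topography
  set.seed(derive_seed(seed, "subjweights", subject_id))
  w <- pmax(w * (1 + subject_cv * matrix(stats::rnorm(length(w)), nrow(w))), 0)
  set.seed(derive_seed(seed, "sessweights", subject_id, session_index))
  w <- pmax(w * (1 + session_cv * matrix(stats::rnorm(length(w)), nrow(w))), 0)
  normalize_columns(w)
}

#' Generate a synthetic cohort with planted phenotypes and effects
#'
#' Draws subject ground truth (phenotype, group, covariates, responder class),
#' per-session relative-band-power feature vectors, and a behavioral table
#' with planted cluster-linked active-sham effects. Raw multichannel EEG for
#' any subject-session can be synthesized on demand with [cohort_recording()]
#' (or all at once via `include_recordings = TRUE`, intended for small
#' cohorts: a full-size cohort of raw EEG occupies gigabytes).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds yield identical cohorts.
#' @param include_recordings if TRUE, also synthesize every session's raw EEG.
#' @return List of class `eeg_cohort` with elements `truths` (data.frame),
#'   `features` (data.frame: subject_id, session_index, 135 feature columns),
#'   `behavior` (data.frame), `covariates` (data.frame), `phenotypes`
#'   (the archetype library used), `config`, `seed`, and optionally
#'   `recordings` (list of `session_recording`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            include_recordings = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  lib <- phenotype_library(config$separation)
  n <- config$n_subjects

  # phenotype counts by largest remainder, then covariates
  raw <- config$proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  set.seed(derive_seed(seed, "truths"))
  phenotype_id <- sample(rep(seq_along(counts), counts))
  truths <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    phenotype_id = phenotype_id,
    group = sample(rep(c("A", "B"), length.out = n)),
    age = round(pmin(pmax(stats::rnorm(n, 14.09, 2.1), 10), 17), 1),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(32, 24) / 56),
    iq = pmax(80L, as.integer(round(stats::rnorm(n, 105, 12)))),
    handedness = as.integer(pmax(-100, pmin(100, round(stats::rnorm(n, 60, 40))))),
    responder_class = config$responder_classes[phenotype_id],
    stringsAsFactors = FALSE
  )
  truths$effect_size <- ifelse(truths$responder_class == "non", 0,
                               config$effect_size)

  # session feature vectors drawn from the session topography on the
  # retained 27 channels, plus feature-level measurement noise
  keep <- retained_channels()
  feats <- vector("list", n * config$n_sessions)
  idx <- 1L
  for (i in seq_len(n)) {
    pheno <- lib[[truths$phenotype_id[i]]]
    for (s in seq_len(config$n_sessions)) {
      w <- session_topography(pheno, truths$subject_id[i], s, seed,
                              config$subject_cv, config$session_cv)
      f <- normalize_columns(w[, keep, drop = FALSE])
      set.seed(derive_seed(seed, "featnoise", truths$subject_id[i], s))
      f <- pmax(f + config$measurement_sd * matrix(stats::rnorm(length(f)), nrow(f)), 0)
      f <- normalize_columns(f)
      feats[[idx]] <- c(subject = truths$subject_id[i], session = s,
                        as.vector(f))
      idx <- idx + 1L
    }
  }
  fm <- do.call(rbind, lapply(feats, function(x) as.numeric(x[-(1:2)])))
  colnames(fm) <- feature_names(keep)
  features <- data.frame(
    subject_id = vapply(feats, `[[`, "", 1),
    session_index = as.integer(vapply(feats, `[[`, "", 2)),
    fm, check.names = FALSE, stringsAsFactors = FALSE
  )

  behavior <- do.call(rbind, lapply(seq_len(n), function(i)
    generate_behavior(truths[i, ], membership_target = 1,
                      seed = seed, config = config)))
  covariates <- truths[, c("subject_id", "group", "age", "sex", "iq",
                           "handedness", "phenotype_id", "responder_class")]

  cohort <- structure(
    list(truths = truths, features = features, behavior = behavior,
         covariates = covariates, phenotypes = lib, config = config,
         seed = seed),
    class = "eeg_cohort"
  )
  if (include_recordings) {
    cohort$recordings <- lapply(seq_len(nrow(features)), function(j)
      cohort_recording(cohort, features$subject_id[j], features$session_index[j]))
  }
  cohort
}

#' Synthesize the raw EEG of one cohort subject-session
#'
#' Deterministically re-derives the session's jittered topography and calls
#' [synthesize_eeg()]; equal `(cohort, subject, session)` always yields the
#' identical recording, so large cohorts can be streamed one session at a
#' time.
#'
#' @param cohort an `eeg_cohort`.
#' @param subject_id,session_index which session to synthesize.
#' @return A `session_recording`.
#' @export
cohort_recording <- function(cohort, subject_id, session_index) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  i <- match(subject_id, cohort$truths$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subject_id)
  cfg <- cohort$config
  pheno <- cohort$phenotypes[[cohort$truths$phenotype_id[i]]]
  w <- session_topography(pheno, subject_id, session_index, cohort$seed,
                          cfg$subject_cv, cfg$session_cv)
  spec <- pheno
  spec$band_topography <- w
  synthesize_eeg(spec, subject_id = subject_id, session_index = session_index,
                 seed = derive_seed(cohort$seed, "eeg", subject_id, session_index),
                 fs = cfg$fs, duration = cfg$duration,
                 channel_rms = cfg$channel_rms, cz_gain = cfg$cz_gain,
                 background_frac = cfg$background_frac, osc_frac = cfg$osc_frac)
}

#' Synthesize one multichannel resting-state EEG recording
#'
#' Gaussian signal realized in the frequency domain from a target spectrum
#' composed of (i) a 1/f^exponent broadband background, (ii) per-band
#' band-limited noise whose power follows the phenotype's band topography
#' channel-wise, and (iii) a narrowband oscillation at the alpha peak
#' frequency (and at the beta peak if the phenotype defines one). The Welch
#' spectrum of the output therefore reproduces the intended relative
#' band-power profile up to realization noise.
#'
#' @param pheno a `phenotype_spec` (channel weights may be jittered).
#' @param subject_id,session_index identifiers stored in the recording.
#' @param seed integer seed.
#' @param fs sampling rate (Hz); `duration` length in seconds.
#' @param channel_rms target RMS per channel in microvolts.
#' @param cz_gain relative RMS of the Cz channel.
#' @param background_frac fraction of power in the 1/f background.
#' @param osc_frac fraction of alpha/beta band power in the narrowband peak.
#' @return A `session_recording` (32 channels x `duration * fs` samples, in
#'   microvolts).
#' @export
synthesize_eeg <- function(pheno, subject_id = "S000", session_index = 1,
                           seed = 1, fs = 500, duration = 120,
                           channel_rms = 15, cz_gain = 0.3,
                           background_frac = 0.05, osc_frac = 0.5) {
  w <- pheno$band_topography
  if (any(w < 0)) stop("band_topography weights must be nonnegative")
  ch <- colnames(w)
  n <- as.integer(round(duration * fs))
  nf <- n %/% 2L
  freqs <- (1:(nf - 1)) * fs / n                 # positive bins below Nyquist
  bands <- eeg_bands()
  set.seed(seed)
  data <- matrix(0, nrow = length(ch), ncol = n)
  for (c_i in seq_along(ch)) {
    wc <- w[, c_i]
    p <- channel_bin_powers(freqs, wc, pheno, background_frac, osc_frac, bands)
    if (sum(p) == 0) next                        # silent channel
    # random-phase realization: spectral amplitudes are deterministic, so
    # every realization carries the target band powers exactly
    phase <- stats::runif(nf - 1, 0, 2 * pi)
    spec <- sqrt(p) * complex(modulus = 1, argument = phase)
    full <- complex(length.out = n)
    full[2:nf] <- spec
    full[(nf + 2):n] <- Conj(rev(spec))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    if (!all(is.finite(x))) stop("non-finite synthesized signal")
    rms <- sqrt(mean(x^2))
    gain <- if (ch[c_i] == "Cz") cz_gain else 1
    data[c_i, ] <- x * (channel_rms * gain / rms)
  }
  session_recording(subject_id, session_index, data, ch, fs)
}

# Target power per FFT bin for one channel: per-band flat noise plus optional
# narrowband peaks, plus the 1/f background, all confined to [2, 45) Hz.
channel_bin_powers <- function(freqs, wc, pheno, background_frac, osc_frac,
                               bands) {
  p <- numeric(length(freqs))
  if (sum(wc) == 0 && background_frac == 0) return(p)
  for (b in seq_len(nrow(bands))) {
    # realize band noise slightly inside the band edges: clear of the 2 and
    # 45 Hz acquisition-filter transitions and one 0.25 Hz analysis bin from
    # interior edges, so realized band powers are not clipped by filtering
    # or smeared across bands by spectral leakage
    lo_r <- if (bands$band[b] == "delta") 2.5 else bands$low_hz[b] + 0.25
    hi_r <- if (bands$band[b] == "gamma") 44 else bands$high_hz[b] - 0.25
    idx <- which(freqs >= lo_r & freqs < hi_r)
    if (!length(idx)) next
    pb <- (1 - background_frac) * wc[b]
    peak <- switch(bands$band[b],
                   alpha = pheno$alpha_peak_hz,
                   beta  = pheno$beta_peak_hz,
                   NA_real_)
    if (!is.na(peak) && osc_frac > 0) {
      bump <- stats::dnorm(freqs[idx], peak, 0.5)
      bump <- if (sum(bump) > 0) bump / sum(bump) else rep(1 / length(idx), length(idx))
      p[idx] <- p[idx] + pb * ((1 - osc_frac) / length(idx) + osc_frac * bump)
    } else {
      p[idx] <- p[idx] + pb / length(idx)
    }
  }
  bg_idx <- which(freqs >= 2 & freqs < 45)
  if (background_frac > 0 && sum(wc) > 0) {
    shape <- freqs[bg_idx]^(-pheno$background_exponent)
    p[bg_idx] <- p[bg_idx] + background_frac * shape / sum(shape)
  }
  p
}

#' Generate the behavioral table for one subject
#'
#' Task performance (Flanker, N-Back, CPT; accuracy and reaction time) under
#' active and sham stimulation, separately for concurrent and non-concurrent
#' task conditions, plus a pre-treatment baseline row per task and metric.
#' Sham values are drawn from a subject baseline (logistic-bounded Gaussian
#' accuracy, log-normal RT); active values add
#' `effect_size * membership_target * scale`, signed +accuracy/-RT for
#' positive responders and reversed for negative responders. A weak linear
#' age effect is added to the active-sham RT difference so that
#' covariate-adjusted correlation is exercised.
#'
#' @param truth one-row data.frame with `subject_id`, `responder_class`,
#'   `effect_size`, `age` (as produced by [generate_cohort()]).
#' @param membership_target weight of the subject's planted cluster used to
#'   scale the effect (1 = full membership).
#' @param seed integer seed (combined with the subject id).
#' @param config a [cohort_config()].
#' @return data.frame with columns `subject_id`, `task`, `metric`,
#'   `stimulation` (active/sham/baseline), `concurrency`, `value`.
#' @export
generate_behavior <- function(truth, membership_target = 1, seed = 1,
                              config = cohort_config()) {
  stopifnot(is.finite(truth$effect_size))
  set.seed(derive_seed(seed, "behavior", truth$subject_id))
  dir_acc <- switch(truth$responder_class, positive = 1, negative = -1, non = 0)
  s <- truth$effect_size * membership_target
  tasks <- c("Flanker", "N-Back", "CPT")
  rows <- list()
  for (task in tasks) {
    for (conc in c("concurrent", "non-concurrent")) {
      acc_base <- stats::plogis(stats::qlogis(0.8) + stats::rnorm(1, 0, 0.4))
      rt_base <- exp(log(450) + stats::rnorm(1, 0, 0.15))
      sham_acc <- clamp01(acc_base + stats::rnorm(1, 0, config$accuracy_noise_sd))
      act_acc <- clamp01(acc_base + dir_acc * s * config$accuracy_scale +
                           stats::rnorm(1, 0, config$accuracy_noise_sd))
      sham_rt <- max(100, rt_base + stats::rnorm(1, 0, config$rt_noise_sd))
      act_rt <- max(100, rt_base - dir_acc * s * config$rt_scale +
                      (truth$age - 13.5) * config$age_delta_slope +
                      stats::rnorm(1, 0, config$rt_noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = truth$subject_id, task = task,
        metric = rep(c("accuracy", "rt"), each = 2),
        stimulation = rep(c("active", "sham"), 2),
        concurrency = conc,
        value = c(act_acc, sham_acc, act_rt, sham_rt),
        stringsAsFactors = FALSE
      )
    }
    base_acc <- clamp01(stats::plogis(stats::qlogis(0.8) + stats::rnorm(1, 0, 0.4)) +
                          stats::rnorm(1, 0, config$accuracy_noise_sd))
    base_rt <- max(100, exp(log(450) + stats::rnorm(1, 0, 0.15)) +
                     stats::rnorm(1, 0, config$rt_noise_sd))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = truth$subject_id, task = task,
      metric = c("accuracy", "rt"), stimulation = "baseline",
      concurrency = "none", value = c(base_acc, base_rt),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Session feature matrix of a cohort
#'
#' @param cohort an `eeg_cohort`.
#' @return Numeric matrix (sessions x 135) of the cohort's feature vectors.
#' @export
feature_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  as.matrix(cohort$features[, feature_names(), drop = FALSE])
}
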