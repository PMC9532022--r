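# Synthetic tracing cohorts with the statistical structure the analysis is
# designed to detect: per-subject systematic bias fields, within-trial
# correlated wander, per-sample sensor jitter, age-dependent skill and
# occasional outlier subjects.

#' Configuration for the synthetic cohort generator
#'
#' The generative model: a subject traces the template at constant nominal
#' speed (covering `passes` full laps in `duration` seconds). At arc
#' position `s` the finger is displaced along the local curve normal by
#' `bias(s) + wander(S)` plus isotropic per-sample jitter, where
#' \itemize{
#'   \item `bias` is the subject's systematic bias field: a smooth periodic
#'     sum of `bias_modes` low-frequency sinusoids whose sine/cosine
#'     coefficients are zero-mean Gaussian. The field is a stationary
#'     Gaussian process on the closed curve with marginal standard
#'     deviation `bias_amplitude * g(age)`; its expectation across subjects
#'     is zero at every arc position, and the mean absolute bias — the
#'     error floor that self-aggregation cannot cancel — is analytically
#'     `bias_amplitude * g(age) * sqrt(2/pi)` (see [bias_error_floor()]).
#'   \item `wander` is stationary first-order autoregressive (Ornstein-
#'     Uhlenbeck) trial-to-trial noise in cumulative traversed arc length
#'     `S`, with standard deviation `trial_noise * g(age)` and correlation
#'     length `wander_correlation_length` mm; successive passes over the
#'     same template region are effectively independent.
#'   \item `g(age) = (age_reference / age) ^ age_exponent` makes younger
#'     subjects noisier and more biased, emulating motor-skill maturation;
#'     `age_exponent = 0` switches the age dependence off.
#' }
#' A fraction `outlier_fraction` of subjects draw their bias field with
#' amplitude `outlier_scale` instead (not age-scaled): subjects whose
#' traces deviate wildly from the template.
#'
#' @param n_subjects number of subjects; default 200.
#' @param age_range years, subjects drawn uniformly; default `c(6, 18)`.
#' @param bias_amplitude marginal sd of the bias field at the reference
#'   age, mm; default 2.5.
#' @param age_reference years at which the amplitudes apply; default 10.
#' @param age_exponent exponent of the age scaling; default 1.
#' @param bias_modes number of sinusoidal bias components; default 3.
#' @param trial_noise sd of the wander process at the reference age, mm;
#'   default 1.5.
#' @param wander_correlation_length correlation length of the wander in mm
#'   of arc; default 20.
#' @param jitter per-axis sd of isotropic sensor noise, mm; default 0.3.
#' @param passes nominal template laps per 30 s trace; default 8, matching
#'   one lap per raw individual trajectory at the default splicing.
#' @param speed mm/s; overrides `passes` when given.
#' @param sample_rate Hz; default 85, the tablet touch-event rate.
#' @param duration seconds per trace; default 30.
#' @param outlier_fraction fraction of outlier subjects; default 0.05.
#' @param outlier_scale bias-field sd for outlier subjects, mm; default 20.
#' @param templates template names to simulate; default all five.
#' @param seed integer seed fixing the entire cohort; default 1.
#' @return a list of class `woc_synth_config`.
#' @export
synthetic_config <- function(n_subjects = 200L, age_range = c(6, 18),
                             bias_amplitude = 2.5, age_reference = 10,
                             age_exponent = 1, bias_modes = 3L,
                             trial_noise = 1.5,
                             wander_correlation_length = 20, jitter = 0.3,
                             passes = 8, speed = NULL, sample_rate = 85,
                             duration = 30, outlier_fraction = 0.05,
                             outlier_scale = 20,
                             templates = c("ellipse", "thin_ellipse",
                                           "three_petal", "four_petal",
                                           "lemniscate"),
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
              bias_amplitude = bias_amplitude, age_reference = age_reference,
              age_exponent = age_exponent, bias_modes = as.integer(bias_modes),
              trial_noise = trial_noise,
              wander_correlation_length = wander_correlation_length,
              jitter = jitter, passes = passes, speed = speed,
              sample_rate = sample_rate, duration = duration,
              outlier_fraction = outlier_fraction,
              outlier_scale = outlier_scale, templates = templates,
              seed = as.integer(seed))
  scales <- c("bias_amplitude", "trial_noise", "jitter", "outlier_fraction",
              "outlier_scale", "wander_correlation_length")
  for (f in scales) if (any(cfg[[f]] < 0)) stop(f, " must be non-negative")
  if (cfg$sample_rate * cfg$duration < 8)
    stop("sample_rate * duration too small to splice")
  class(cfg) <- "woc_synth_config"
  cfg
}

# Age-skill scaling g(age).
age_scale <- function(age, config) {
  (config$age_reference / age)^config$age_exponent
}

#' Analytic bias-induced error floor
#'
#' The expected absolute value of the systematic bias field at any arc
#' position, `amplitude * sqrt(2/pi)` for a Gaussian field of marginal sd
#' `amplitude`. Aggregating many trials of one subject cancels trial noise
#' but not the bias, so within-subject aggregation curves plateau near this
#' value; it is the recovery target of the parameter-recovery checks.
#'
#' @param bias_amplitude marginal sd of the bias field, mm.
#' @return expected absolute bias, mm.
#' @export
bias_error_floor <- function(bias_amplitude) bias_amplitude * sqrt(2 / pi)

#' Draw a subject's systematic bias field
#'
#' The field is `sum_k A_k sin(2 pi k s / L + phi_k)` over
#' `k = 1..bias_modes`, with Rayleigh amplitudes and uniform phases —
#' equivalently, zero-mean Gaussian sine/cosine quadrature coefficients of
#' per-mode variance `sd^2 / bias_modes` — so the marginal distribution at
#' every arc position is exactly `N(0, sd^2)`. Uses the current RNG state.
#'
#' @param template a complete `woc_template` (for the curve length).
#' @param sd marginal standard deviation of the field, mm.
#' @param bias_modes number of sinusoidal components.
#' @return a function `offset(s)` mapping arc position (mm) to signed
#'   normal offset (mm), periodic over the curve; carries the coefficients
#'   as attribute `coef`.
#' @export
sample_bias_field <- function(template, sd, bias_modes = 3L) {
  L <- template$total_length
  m <- as.integer(bias_modes)
  a <- stats::rnorm(m, 0, sd / sqrt(m))
  b <- stats::rnorm(m, 0, sd / sqrt(m))
  if (sd == 0) a <- b <- numeric(m)
  f <- function(s) {
    w <- 2 * pi * outer(s / L, seq_len(m))
    drop(sin(w) %*% a + cos(w) %*% b)
  }
  attr(f, "coef") <- list(a = a, b = b, L = L)
  f
}

#' Simulate one 30 s tracing trial
#'
#' Constant-speed traversal of the template starting at a random arc
#' position, displaced along the local normal by the subject's bias field
#' plus the wander process, with isotropic jitter added to both
#' coordinates. Uses the current RNG state.
#'
#' @param subject_id subject identifier.
#' @param template a complete `woc_template`.
#' @param config a [synthetic_config()].
#' @param bias a bias field from [sample_bias_field()]; `NULL` for a fresh
#'   draw of marginal sd `bias_sd`.
#' @param bias_sd,wander_sd noise scales in mm (already age-scaled by the
#'   caller); default the config values unscaled.
#' @param details if `TRUE`, attach the arc positions and the individual
#'   displacement components as attributes (for diagnostics).
#' @return a [trace_record()].
#' @export
simulate_trace <- function(subject_id, template, config, bias = NULL,
                           bias_sd = config$bias_amplitude,
                           wander_sd = config$trial_noise,
                           details = FALSE) {
  L <- template$total_length
  v <- config$speed %||% (config$passes * L / config$duration)
  t <- seq(0, config$duration, by = 1 / config$sample_rate)
  s0 <- stats::runif(1, 0, L)
  S <- s0 + v * t                      # cumulative traversed arc
  s <- S %% L
  base <- template_point_at(template, s)
  nrm <- template_normal_at(template, s)
  if (is.null(bias)) bias <- sample_bias_field(template, bias_sd,
                                               config$bias_modes)
  offb <- bias(s)
  offw <- ou_process(length(t), v / config$sample_rate, wander_sd,
                     config$wander_correlation_length)
  jit <- matrix(stats::rnorm(2L * length(t), 0, config$jitter), ncol = 2L)
  xy <- base + nrm * (offb + offw) + jit
  tr <- trace_record(subject_id, template$name, t, xy)
  if (details)
    attr(tr, "details") <- list(s = s, base = base, normal = nrm,
                                bias = offb, wander = offw, jitter = jit)
  tr
}

# Stationary AR(1)/Ornstein-Uhlenbeck sequence of length n, step `delta`
# (mm of arc between samples), marginal sd `sd`, correlation length `ell`.
ou_process <- function(n, delta, sd, ell) {
  if (sd == 0) return(numeric(n))
  rho <- exp(-delta / ell)
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  e[1L] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

#' Generate a full synthetic tracing cohort
#'
#' Draws the subject table (ages uniform over `age_range`, 10% left-handed,
#' 56% female, emulating the composition of a school cohort), marks a
#' fraction of subjects as outliers, and simulates one trace per subject
#' and template. Fully deterministic under `config$seed`: per-subject
#' sub-seeds are derived from the master seed, so the cohort is
#' reproducible regardless of evaluation order.
#'
#' @param config a [synthetic_config()].
#' @param templates optional named list of prebuilt templates (to avoid
#'   rebuilding geometry across repeated cohorts).
#' @return a `woc_cohort` ready for [clean_cohort()] / [process_cohort()].
#' @export
generate_cohort <- function(config = synthetic_config(), templates = NULL) {
  stopifnot(inherits(config, "woc_synth_config"))
  templates <- templates %||% default_templates(config$templates)
  set.seed(config$seed)
  n <- config$n_subjects
  if (n == 0L)
    return(trace_cohort(data.frame(subject_id = character(0),
                                   age = numeric(0),
                                   handedness = character(0),
                                   gender = character(0)),
                        templates = templates))
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    handedness = sample(c("right", "left"), n, TRUE, c(0.9, 0.1)),
    gender = sample(c("female", "male"), n, TRUE, c(0.56, 0.44)))
  outlier <- stats::runif(n) < config$outlier_fraction
  sub_seeds <- derive_seed(config$seed, seq_len(n))
  traces <- vector("list", n * length(templates))
  idx <- 0L
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    g <- age_scale(subjects$age[i], config)
    bias_sd <- if (outlier[i]) config$outlier_scale else
      config$bias_amplitude * g
    wander_sd <- config$trial_noise * g
    for (tpl in templates) {
      bias <- sample_bias_field(tpl, bias_sd, config$bias_modes)
      idx <- idx + 1L
      traces[[idx]] <- simulate_trace(subjects$subject_id[i], tpl, config,
                                      bias = bias, wander_sd = wander_sd)
    }
  }
  out <- trace_cohort(subjects, traces, templates)
  attr(out, "outlier") <- outlier
  attr(out, "config") <- config
  out
}
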