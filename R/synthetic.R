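# Seeded generators emulating every input the pipeline consumes:
# Gaussian-peak chromatograms, an n-alkane reference ladder, calibration
# and control campaigns, replicated design-of-experiments response
# tables, and first-order fiber-uptake kinetics. Every generator is a
# pure function of its arguments including the seed.

# Derive a deterministic substream seed from a root seed and a stream
# index; kept within the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 10007 + stream * 1009) %% 2147483629)
}

#' Synthetic chromatogram of Gaussian peaks
#'
#' Sum of Gaussian peaks on a constant baseline with seeded white noise.
#' The default two-peak layout mimics a derivatized-analyte /
#' internal-standard pair eluting at 5.03 and 5.36 min.
#'
#' @param peaks data.frame with columns `center` (min), `width`
#'   (Gaussian sigma, min) and `area` (units x min).
#' @param span time span `c(from, to)` in minutes.
#' @param dt sampling interval, min.
#' @param baseline constant baseline intensity.
#' @param noise_sd SD of the additive white noise.
#' @param seed integer seed.
#' @return data.frame with columns `time` and `intensity`.
#' @export
gen_chromatogram <- function(peaks = data.frame(center = c(5.03, 5.36),
                                                width = c(0.015, 0.015),
                                                area = c(1e5, 1.2e5)),
                             span = c(4, 6.2), dt = 0.001,
                             baseline = 100, noise_sd = 5, seed = 1) {
  stopifnot(all(c("center", "width", "area") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak width must be > 0", call. = FALSE)
  if (any(peaks$center < span[1] | peaks$center > span[2])) {
    stop("peak centers must lie within the time span", call. = FALSE)
  }
  tt <- seq(span[1], span[2], by = dt)
  y <- rep(baseline, length(tt))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$area[i] * stats::dnorm(tt, peaks$center[i],
                                          peaks$width[i])
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 1L))
    y <- y + stats::rnorm(length(tt), 0, noise_sd)
  }
  data.frame(time = tt, intensity = y)
}

#' Synthetic n-alkane reference ladder
#'
#' Evenly spaced C8-C20 ladder anchored so that a 5.03-min analyte
#' brackets between C13 and C14 at retention index 1384: C13 elutes at
#' 4.78 min and the per-carbon spacing is 0.25/0.84 min. Optional seeded
#' jitter perturbs all times while preserving monotonicity.
#'
#' @param carbons integer carbon numbers (default 8:20).
#' @param anchor_time retention time of the anchor carbon, min.
#' @param anchor_carbon carbon number anchored at `anchor_time`.
#' @param spacing per-carbon retention-time increment, min.
#' @param jitter_sd SD of seeded Gaussian jitter on each time (min);
#'   0 (default) gives deterministic times.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return An [alkane_ladder()].
#' @export
gen_alkane_ladder <- function(carbons = 8:20, anchor_time = 4.78,
                              anchor_carbon = 13, spacing = 0.25 / 0.84,
                              jitter_sd = 0, seed = 1) {
  times <- anchor_time + (carbons - anchor_carbon) * spacing
  if (jitter_sd > 0) {
    set.seed(derive_seed(seed, 2L))
    jit <- stats::rnorm(length(times), 0, jitter_sd)
    # clamp so the ladder stays strictly increasing
    jit <- pmin(pmax(jit, -spacing / 4), spacing / 4)
    times <- times + jit
  }
  alkane_ladder(carbons, times)
}

#' Synthetic calibration/control validation campaign
#'
#' Emulates a multi-day validation: for each day and set, one
#' internal-standard-corrected response per calibration level drawn as
#' `slope * conc + intercept + N(0, noise_sd)`, plus control samples
#' whose measured concentration scatters around nominal with coefficient
#' of variation `control_cv` (unbiased) before being mapped back to a
#' response through the true curve. The default layout is 6 inter-day
#' days of 3 sets plus one intra-day day of 6 sets; default noise is
#' calibrated so a single fitted curve has R^2 near 0.991.
#'
#' @param interday_days number of inter-day days.
#' @param interday_sets calibration/control sets per inter-day day.
#' @param intraday_sets sequential sets on the single intra-day day.
#' @param levels calibration concentrations, mg/L.
#' @param control_levels control concentrations, mg/L.
#' @param slope,intercept true calibration line (response units).
#' @param noise_sd SD of the response noise on calibrants.
#' @param control_cv relative SD of control measured concentrations.
#' @param day_slope_sd SD of a per-day multiplicative slope drift
#'   (0 = none).
#' @param is_area internal-standard area emitted for every row.
#' @param seed integer seed.
#' @return data.frame in the campaign schema of [assemble_report()]:
#'   `scope`, `day`, `set`, `level_mg_L`, `analyte_area`, `is_area`,
#'   `role`.
#' @export
gen_calibration_campaign <- function(interday_days = 6, interday_sets = 3,
                                     intraday_sets = 6,
                                     levels = c(0.3, 0.5, 1, 5, 10),
                                     control_levels = c(0.3, 1),
                                     slope = 210501, intercept = 151459,
                                     noise_sd = 97000, control_cv = 0.044,
                                     day_slope_sd = 0, is_area = 1000,
                                     seed = 1) {
  stopifnot(interday_days >= 1, interday_sets >= 1, intraday_sets >= 1,
            noise_sd >= 0, control_cv >= 0)
  set.seed(derive_seed(seed, 3L))
  emit_day <- function(scope, day, n_sets) {
    day_slope <- slope * (1 + if (day_slope_sd > 0) {
      stats::rnorm(1, 0, day_slope_sd)
    } else 0)
    rows <- list()
    for (s in seq_len(n_sets)) {
      resp <- day_slope * levels + intercept +
        stats::rnorm(length(levels), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        scope = scope, day = day, set = s, level_mg_L = levels,
        analyte_area = resp * is_area, is_area = is_area,
        role = "calibrant"
      )
      c_meas <- control_levels *
        (1 + stats::rnorm(length(control_levels), 0, control_cv))
      rows[[length(rows) + 1]] <- data.frame(
        scope = scope, day = day, set = s, level_mg_L = control_levels,
        analyte_area = (day_slope * c_meas + intercept) * is_area,
        is_area = is_area, role = "control"
      )
    }
    do.call(rbind, rows)
  }
  out <- list()
  for (d in seq_len(interday_days)) {
    out[[length(out) + 1]] <- emit_day("interday", d, interday_sets)
  }
  out[[length(out) + 1]] <- emit_day("intraday", interday_days + 1,
                                     intraday_sets)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default true response surfaces for the design-of-experiments generator
#'
#' Coefficient vectors over the saturated model terms
#' (1, x1, x2, x1^2, x1:x2) for the four monitored responses: peak area
#' (Y1, maximized), signal-to-noise (Y2), limit of quantification
#' (Y3, minimized) and RSD (Y4, minimized). The defaults place the joint
#' optimum at the 30-um fiber in the cooled setting, i.e. (x1, x2) =
#' (0, 1).
#'
#' @return Named list of length-5 coefficient vectors.
#' @export
default_doe_truth <- function() {
  list(
    peak_area = c(100, 0, 20, -30, 0),
    s_to_n = c(50, 0, 10, -12, 0),
    loq = c(0.3, 0, -0.1, 0.1, 0),
    rsd = c(6, 0, -1, 1, 0)
  )
}

#' Synthetic replicated design-of-experiments responses
#'
#' Draws `n_rep` replicate responses per candidate grid point for each
#' response surface: model value plus Gaussian replicate noise. Default
#' truth is [default_doe_truth()] with noise 2% of each surface's grid
#' range.
#'
#' @param candidates coded candidate grid (default the 3x2 fiber
#'   thickness x sampling temperature grid).
#' @param model model formula; defaults to the saturated 5-term model.
#' @param truth named list of true coefficient vectors over the model
#'   terms.
#' @param n_rep replicates per run (default 5).
#' @param noise_sd named numeric vector of replicate SDs per response;
#'   `NULL` scales each to 2% of the surface's range over the grid.
#' @param seed integer seed.
#' @return List with `candidates`, `model`, `truth`, `noise_sd` and
#'   `responses` — a named list of `n_runs x n_rep` matrices.
#' @export
gen_doe_responses <- function(candidates = NULL, model = saturated_model(),
                              truth = default_doe_truth(), n_rep = 5,
                              noise_sd = NULL, seed = 1) {
  if (is.null(candidates)) {
    candidates <- build_candidates(list(
      factor_spec("x1", c(-1, 0, 1), c("7 um", "30 um", "100 um")),
      factor_spec("x2", c(-1, 1), c("60 C", "10 C"))
    ))
  }
  X <- expand_model(model, candidates)
  stopifnot(all(vapply(truth, length, integer(1)) == ncol(X)), n_rep >= 2)
  if (is.null(noise_sd)) {
    noise_sd <- vapply(truth, function(b) {
      mu <- drop(X %*% b)
      0.02 * diff(range(mu))
    }, numeric(1))
  }
  stopifnot(all(names(truth) %in% names(noise_sd)) ||
              length(noise_sd) == length(truth))
  if (is.null(names(noise_sd))) names(noise_sd) <- names(truth)
  set.seed(derive_seed(seed, 4L))
  responses <- lapply(names(truth), function(r) {
    mu <- drop(X %*% truth[[r]])
    mu + matrix(stats::rnorm(length(mu) * n_rep, 0, noise_sd[[r]]),
                nrow = length(mu))
  })
  names(responses) <- names(truth)
  list(candidates = candidates, model = model, truth = truth,
       noise_sd = noise_sd, responses = responses)
}

#' Synthetic fiber-uptake kinetic series
#'
#' Exponential approach to the equilibrium mass with seeded Gaussian
#' noise; the rate constant is set so the curve reaches
#' `equilibrium_fraction` of `n_eq` at `t_eq` (the operational
#' equilibrium-time convention). Defaults reflect uptake at the heated
#' (60 C) condition, t_eq = 38 min; the cooled condition equilibrates at
#' 14 min.
#'
#' @param n_eq equilibrium mass, ng.
#' @param t_eq equilibrium time, min.
#' @param times sampling times, min; default a grid to 2 x t_eq.
#' @param noise_sd SD of additive mass noise, ng.
#' @param equilibrium_fraction fraction of n_eq defining t_eq.
#' @param seed integer seed.
#' @return data.frame with columns `time` and `mass`.
#' @export
gen_uptake_series <- function(n_eq = 120, t_eq = 38, times = NULL,
                              noise_sd = 0, equilibrium_fraction = 0.95,
                              seed = 1) {
  stopifnot(n_eq > 0, t_eq > 0)
  if (is.null(times)) times <- seq(0, 2 * t_eq, length.out = 40)
  pred <- uptake_prediction(n_eq, t_eq, equilibrium_fraction)
  mass <- uptake_at_time(pred, times)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 5L))
    mass <- mass + stats::rnorm(length(times), 0, noise_sd)
  }
  data.frame(time = times, mass = mass)
}
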