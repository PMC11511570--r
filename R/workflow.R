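# Workflow layer: overlapped sample-preparation throughput modelling and
# a one-call pipeline runner that exercises generation, partition
# modelling, retention indexing, design optimization and validation
# statistics, writing delimited tables and a structured run summary.

#' Stage schedule for an overlapped automated prep workflow
#'
#' Each stage has a duration and a resource count (parallel slots). The
#' defaults mirror an automated urine workflow: 60 min hydrolysis and
#' 50 min cooling/neutralization/derivatization on a multi-position
#' agitator, 5 min cooled SPME sampling, and a 17 min
#' sampling-to-end-of-run GC cycle on a single instrument.
#'
#' @param stages data.frame with columns `name`, `duration` (min) and
#'   `resources` (integer slot count).
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(stages = data.frame(
                             name = c("hydrolysis", "derivatization",
                                      "spme_sampling", "gc_run"),
                             duration = c(60, 50, 5, 17),
                             resources = c(6, 6, 1, 1))) {
  stopifnot(is.data.frame(stages),
            all(c("name", "duration", "resources") %in% names(stages)))
  if (any(stages$duration <= 0)) {
    stop("stage durations must be > 0", call. = FALSE)
  }
  if (any(stages$resources < 1)) {
    stop("every stage needs >= 1 resource", call. = FALSE)
  }
  structure(list(stages = stages), class = "stage_schedule")
}

#' Steady-state cycle time and first-sample lead time
#'
#' The lead time is the sum of stage durations (the first sample's
#' flow time); the steady-state cycle is the bottleneck rate
#' `max(duration / resources)`.
#'
#' @param schedule a [stage_schedule()].
#' @return List with `lead_time` and `cycle` in minutes.
#' @export
schedule_bottleneck <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  st <- schedule$stages
  list(lead_time = sum(st$duration),
       cycle = max(st$duration / st$resources))
}

#' Throughput of an overlapped prep schedule by discrete-event simulation
#'
#' Samples are released as early as possible (prep-ahead overlap) into a
#' tandem line of stages, each with a fixed number of parallel slots and
#' deterministic durations. Returns the number of samples completed
#' within the horizon and a per-sample stage timeline. For
#' single-bottleneck schedules this equals the closed-form
#' `floor((horizon - lead_time) / cycle) + 1`.
#'
#' @param schedule a [stage_schedule()].
#' @param horizon minutes of available run time (> 0).
#' @return List with `completed`, `timeline` (data.frame: sample, stage,
#'   start, end), `lead_time` and `cycle`.
#' @export
throughput <- function(schedule, horizon) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  st <- schedule$stages
  bn <- schedule_bottleneck(schedule)
  if (horizon < bn$lead_time) {
    return(list(completed = 0L,
                timeline = data.frame(sample = integer(), stage = character(),
                                      start = numeric(), end = numeric()),
                lead_time = bn$lead_time, cycle = bn$cycle))
  }
  n_max <- floor((horizon - bn$lead_time) / bn$cycle) + 2L
  servers <- lapply(st$resources, function(r) numeric(r))
  timeline <- vector("list", n_max)
  completed <- 0L
  for (j in seq_len(n_max)) {
    prev_finish <- 0
    rows <- data.frame(sample = integer(), stage = character(),
                       start = numeric(), end = numeric())
    for (i in seq_len(nrow(st))) {
      k <- which.min(servers[[i]])
      start <- max(prev_finish, servers[[i]][k])
      end <- start + st$duration[i]
      servers[[i]][k] <- end
      prev_finish <- end
      rows <- rbind(rows, data.frame(sample = j, stage = st$name[i],
                                     start = start, end = end))
    }
    if (prev_finish <= horizon) {
      completed <- j
      timeline[[j]] <- rows
    } else {
      break
    }
  }
  list(completed = completed,
       timeline = do.call(rbind, timeline[seq_len(completed)]),
       lead_time = bn$lead_time, cycle = bn$cycle)
}

#' Default configuration for the end-to-end pipeline run
#'
#' @param seed root integer seed for every generator substream.
#' @return Named list of pipeline settings.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    analyte_config = system.file("extdata", "bmda.yaml",
                                 package = "hsspme"),
    spike_concentration = 0.3,
    fiber_thickness_um = 30,
    calibration = list(),
    horizon_min = 527
  )
}

#' Run the full synthetic pipeline and write a report bundle
#'
#' Generates every input, then runs partition/uptake prediction at both
#' sampling temperatures, retention indexing of the synthetic
#' chromatogram, D-optimal design construction, surface fitting with
#' test-point validation and optimum selection, and the calibration
#' performance report. All tables are written as CSV next to a
#' `summary.json` and a plain-text log; identical config and seed give
#' identical outputs.
#'
#' @param config list from [default_pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("hsspme_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), "|", sprintf(...), "\n",
        file = log_path, append = TRUE)
  }
  logf("hsspme %s | seed %d", as.character(utils::packageVersion("hsspme")),
       config$seed)

  # --- physchem: partition coefficients and uptake at both temperatures
  analyte <- read_analyte_properties(config$analyte_config)
  protocol <- default_prep_protocol()
  v1 <- pdms_coating_volume(config$fiber_thickness_um)
  c0 <- effective_c0(protocol, config$spike_concentration,
                     analyte_mw = formula_weight("C9H12O"),
                     derivative_mw = analyte[[1]]$molecular_weight)
  part_rows <- lapply(analyte, function(a) {
    k2 <- k2_from_henry(a$henry_constant, a$temperature)
    k1 <- k1_from_kow_k2(a$log_kow, k2)
    sys <- phase_system(v1, liquid_volume(protocol),
                        headspace_volume(protocol), a$temperature)
    n_eq <- equilibrium_uptake(sys, c0, partition_set(k1, k2, "from_kow"))
    data.frame(temperature_K = a$temperature, k1 = k1, k2 = k2,
               k = k1 * k2, c0_mg_L = c0, n_eq_ng = n_eq)
  })
  partitions <- do.call(rbind, part_rows)
  utils::write.csv(partitions, file.path(out_dir, "partitions.csv"),
                   row.names = FALSE)
  logf("physchem: %d temperature conditions", nrow(partitions))

  # --- retention: synthetic chromatogram -> peaks -> retention index
  chrom <- gen_chromatogram(seed = config$seed)
  ladder <- gen_alkane_ladder()
  analyte_peak <- detect_and_integrate(chrom, c(4.9, 5.16), label = "analyte")
  is_peak <- detect_and_integrate(chrom, c(5.23, 5.49), label = "IS")
  peaks <- peak_table(analyte_peak, is_peak, source = "synthetic")
  peaks$ltpri <- vapply(peaks$retention_time, function(t) {
    ltpri_from_ladder(ladder, t)
  }, numeric(1))
  write_peak_table(peaks, file.path(out_dir, "peak_table.csv"))
  logf("retention: analyte index %.1f", peaks$ltpri[peaks$label == "analyte"])

  # --- doe: design, fits, validation, optimum
  doe_data <- gen_doe_responses(seed = config$seed)
  design <- d_optimal_subset(doe_data$candidates, doe_data$model, k = 5)
  fits <- lapply(doe_data$responses, function(Y) {
    fit_model(design, Y[design$indices, , drop = FALSE])
  })
  test_point <- design$excluded[1, , drop = FALSE]
  test_idx <- setdiff(seq_len(nrow(doe_data$candidates)), design$indices)[1]
  validations <- lapply(names(fits), function(r) {
    validate_test_point(fits[[r]], test_point,
                        doe_data$responses[[r]][test_idx, ])
  })
  names(validations) <- names(fits)
  opt <- select_optimum(
    fits[c("peak_area", "loq", "rsd")],
    c(peak_area = "maximize", loq = "minimize", rsd = "minimize")
  )
  utils::write.csv(cbind(run = design$indices, design$runs),
                   file.path(out_dir, "doe_design.csv"), row.names = FALSE)
  utils::write.csv(opt$evaluation, file.path(out_dir, "doe_evaluation.csv"),
                   row.names = FALSE)
  logf("doe: det(X'X) = %.0f, optimum (%s)", design$det,
       paste(unlist(opt$optimum), collapse = ", "))

  # --- validation: calibration campaign -> performance report
  campaign <- do.call(gen_calibration_campaign,
                      c(list(seed = config$seed), config$calibration))
  report <- assemble_report(campaign)
  utils::write.csv(report$daily, file.path(out_dir, "performance_daily.csv"),
                   row.names = FALSE)
  logf("validation: overall LOD %.3g mg/L", report$overall$lod)

  # --- workflow: throughput scenario
  tp <- throughput(stage_schedule(), config$horizon_min)

  summary <- list(
    seed = config$seed,
    partitions = partitions,
    analyte_ltpri = peaks$ltpri[peaks$label == "analyte"],
    doe = list(det = design$det,
               excluded = lapply(as.list(design$excluded[1, ]), as.numeric),
               optimum = lapply(as.list(opt$optimum), as.numeric),
               validated = vapply(validations, `[[`, logical(1),
                                  "validated")),
    performance = as.list(format_report(report)),
    throughput = list(horizon_min = config$horizon_min,
                      completed = tp$completed, cycle_min = tp$cycle)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(summary)
}
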