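#' Run configuration
#'
#' Bundles everything a pipeline run needs: preset name, seed, acquisition
#' and fission parameters, output directory. Fully serializable to YAML;
#' every run writes its resolved configuration beside its outputs.
#'
#' @param preset One of `"fig1"`, `"fig2"`, `"fig3-23C"`, `"fig3-37C"`,
#'   `"fig4"`.
#' @param seed Integer seed driving every random stage.
#' @param outdir Output directory.
#' @param acquisition A `bas_acquisition`.
#' @param fission A `bas_fission_params` (ignored by fig1).
#' @return A `bas_config`.
#' @export
bas_config <- function(preset = c("fig1", "fig2", "fig3-23C", "fig3-37C",
                                  "fig4"),
                       seed = 1, outdir = tempfile("bas_run_"),
                       acquisition = acquisition_params(),
                       fission = fission_params(0.1)) {
  preset <- match.arg(preset)
  stopifnot(inherits(acquisition, "bas_acquisition"),
            inherits(fission, "bas_fission_params"))
  structure(list(preset = preset, seed = as.integer(seed), outdir = outdir,
                 acquisition = acquisition, fission = fission),
            class = "bas_config")
}

#' @rdname bas_config
#' @param path YAML file path.
#' @param config A `bas_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bas_config"))
  yaml::write_yaml(list(preset = config$preset, seed = config$seed,
                        outdir = config$outdir,
                        acquisition = acq_to_list(config$acquisition),
                        fission = unclass(config$fission)), path)
  invisible(path)
}

#' @rdname bas_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  bas_config(preset = l$preset, seed = l$seed, outdir = l$outdir,
             acquisition = acq_from_list(l$acquisition),
             fission = do.call(fission_params, l$fission))
}

#' Preset end-to-end scenario configurations
#'
#' Scenario parameters follow the standard BAS fission experiment design:
#' extruded liposome standards
#' at 50/100/200 nm and ~35% CV; a 0.01 mg/mL working stock of 200 nm
#' liposomes taken as ~100 pM particles; complete fission of 200 nm parents
#' into 20 nm (30% CV) products; and kinetics presets whose first-order
#' rate constants (0.05/min at 23 C, 0.10/min at 37 C) put the small-product
#' plateau at ~60 and ~30 min respectively.
#'
#' @param preset Preset name (see [bas_config()]).
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param duration Trace duration per measurement, s.
#' @return A `bas_config`.
#' @export
bas_preset <- function(preset, seed = 1, outdir = tempfile("bas_run_"),
                       duration = 60) {
  acq <- acquisition_params(duration = duration)
  fis <- switch(preset,
    "fig1" = fission_params(0),
    "fig2" = fission_params(0.1, 20, 0.3, "direct"),
    "fig3-23C" = fission_params(log(20) / 60, 20, 0.3, "direct"),
    "fig3-37C" = fission_params(2 * log(20) / 60, 20, 0.3, "direct"),
    "fig4" = fission_params(0.1, 20, 0.3, "direct"),
    stop("unknown preset: ", preset))
  if (preset == "fig3-37C")
    acq$temperature <- 310
  bas_config(preset, seed = seed, outdir = outdir, acquisition = acq,
             fission = fis)
}

# Shared log-spaced edges wide enough for parents and dim products.
default_edges <- function(acq, d_min = 8, d_max = 500, n_per_decade = 24) {
  base <- acq$brightness_scale * acq$transit_time
  log_edges(brightness_of(d_min) * base * exp(-4.5) * 0.5,
            brightness_of(d_max) * base * 1.5, n_per_decade)
}

# One measurement: population -> trace -> bursts -> histogram.
measure_sample <- function(pop, acq, edges, dilution = 1, seed = NULL) {
  if (dilution != 1) {
    pop$particle_conc <- pop$particle_conc / dilution
    pop$species$concentration <- pop$species$concentration / dilution
  }
  trace <- simulate_trace(pop, acq, seed = seed)
  bursts <- detect_bursts(trace)
  h <- build_histogram(bursts, acq, edges = edges,
                       dilution_factor = dilution)
  list(trace = trace, bursts = bursts, histogram = h)
}

# Simulate a fission time course: evolve parents, dilute each aliquot into
# the single-particle regime, measure, histogram on shared edges.
kinetics_course <- function(k_per_min, times_min, acq, fp,
                            parent_conc = 100, parent_diameter = 200,
                            parent_cv = 0.35, dilution = 22,
                            n_parents = 1000, seed = 1,
                            temperature = NULL) {
  fp$rate_constant <- k_per_min
  pop0 <- sample_population(
    liposome_species(parent_diameter, parent_cv, parent_conc),
    n_parents, seed = derive_seed(seed, 1))
  edges <- default_edges(acq)
  hists <- lapply(seq_along(times_min), function(i) {
    pt <- evolve_fission(pop0, fp, times_min[i],
                         seed = derive_seed(seed, 100 + i))
    measure_sample(pt, acq, edges, dilution = dilution,
                   seed = derive_seed(seed, 200 + i))$histogram
  })
  fission_time_course(times_min, hists, temperature = temperature)
}

#' Run an end-to-end preset pipeline
#'
#' Executes the preset scenario (simulate, detect, histogram, plus
#' merging, CV inference, kinetics or dose response as appropriate), writes
#' every artifact (traces, burst tables, histogram CSVs, heat-map matrix,
#' resolved config) under `config$outdir`, and writes a `summary.json`
#' containing the scenario's scaling checks with pass/fail against their
#' tolerances. Deterministic under a fixed seed.
#'
#' @param config A `bas_config` (see [bas_preset()]).
#' @param write_traces Write full trace CSVs (large); burst tables and
#'   histograms are always written.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, write_traces = FALSE) {
  stopifnot(inherits(config, "bas_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(config$outdir, "config.yaml"))
  acq <- config$acquisition
  seed <- config$seed
  summary <- switch(config$preset,
    "fig1" = pipeline_fig1(config, acq, seed, write_traces),
    "fig2" = pipeline_fig2(config, acq, seed, write_traces),
    "fig3-23C" = pipeline_fig3(config, acq, seed, 23),
    "fig3-37C" = pipeline_fig3(config, acq, seed, 37),
    "fig4" = pipeline_fig4(config, acq, seed))
  summary$preset <- config$preset
  summary$seed <- seed
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

pipeline_fig1 <- function(config, acq, seed, write_traces) {
  sizes <- c(200, 100, 50)
  edges <- default_edges(acq, d_min = 15, d_max = 400)
  runs <- lapply(seq_along(sizes), function(i) {
    pop <- sample_population(liposome_species(sizes[i], 0.35, 100), 20000L,
                             seed = derive_seed(seed, i))
    m <- measure_sample(pop, acq, edges, seed = derive_seed(seed, 10 + i))
    write_bursts(m$bursts,
                 file.path(config$outdir, sprintf("bursts_%dnm.csv", sizes[i])))
    write_histogram(m$histogram,
                    file.path(config$outdir,
                              sprintf("histogram_%dnm.csv", sizes[i])))
    if (write_traces)
      write_trace(m$trace,
                  file.path(config$outdir, sprintf("trace_%dnm.csv", sizes[i])))
    m
  })
  r41 <- mean_intensity_ratio(runs[[1]]$histogram, runs[[2]]$histogram)$fold
  r16 <- mean_intensity_ratio(runs[[1]]$histogram, runs[[3]]$histogram)$fold
  list(checks = list(
    fold_200_vs_100 = list(value = r41, expected = 4, tol = 0.10,
                           pass = abs(r41 / 4 - 1) < 0.10),
    fold_200_vs_50 = list(value = r16, expected = 16, tol = 0.10,
                          pass = abs(r16 / 16 - 1) < 0.10)))
}

pipeline_fig2 <- function(config, acq, seed, write_traces) {
  edges <- default_edges(acq)
  pop0 <- sample_population(liposome_species(200, 0.35, 100), 2000L,
                            seed = derive_seed(seed, 1))
  m0 <- measure_sample(pop0, acq, edges, seed = derive_seed(seed, 2))
  fp <- config$fission
  done <- evolve_fission(pop0, fp, t = 60 / fp$rate_constant,
                         seed = derive_seed(seed, 3))
  series <- lapply(c(25, 100), function(d)
    measure_sample(done, acq, edges, dilution = d,
                   seed = derive_seed(seed, 4 + d))$histogram)
  merged <- merge_dilution_series(series)
  write_histogram(m0$histogram, file.path(config$outdir, "histogram_start.csv"))
  write_histogram(merged, file.path(config$outdir, "histogram_merged.csv"))
  start_total <- sum(undiluted_concentration(m0$histogram))
  prod_total <- sum(merged$concentration)
  fold_count <- prod_total / start_total
  fold_amp <- mean_intensity_ratio(m0$histogram, merged)$fold
  cvfit <- estimate_cv(series[[1]], mean_diameter_grid = 20,
                       cv_grid = seq(0.10, 0.50, 0.05),
                       seed = derive_seed(seed, 7))
  list(checks = list(
    product_count_fold = list(value = fold_count, expected = 100,
                              pass = fold_count >= 100 * 0.85),
    burst_size_fold = list(value = fold_amp, expected = 100, tol = 0.15,
                           pass = abs(fold_amp / 100 - 1) < 0.15),
    product_cv = list(value = cvfit$cv, expected = fp$product_cv,
                      # measured (coincidence-contaminated) histograms at
                      # a few thousand events resolve the CV to about one
                      # 5% grid step
                      pass = abs(cvfit$cv - fp$product_cv) < 0.076)))
}

pipeline_fig3 <- function(config, acq, seed, temp_c) {
  fp <- config$fission
  times <- c(0, 7.5, 15, 26, 34, 52, 68, 180)
  tc <- kinetics_course(fp$rate_constant, times, acq, fp, seed = seed,
                        temperature = temp_c)
  write_time_course(tc, file.path(config$outdir, "time_course"))
  hm <- heat_map(tc)
  utils::write.csv(hm, file.path(config$outdir, "heat_map.csv"))
  tp <- time_to_plateau(tc, product_region(tc))
  ts <- total_signal_series(tc)
  list(checks = list(
    plateau_time_min = list(value = tp,
                            expected = log(20) / fp$rate_constant,
                            tol = 0.15,
                            pass = abs(tp * fp$rate_constant / log(20) - 1)
                              < 0.15),
    total_signal_band = list(value = range(ts), expected = c(0.8, 1),
                             pass = min(ts) > 0.8)))
}

pipeline_fig4 <- function(config, acq, seed) {
  edges <- default_edges(acq)
  doses <- c(0.5, 1, 5, 10)   # uM
  k_of_dose <- function(d) 0.15 * d / (d + 2)  # per min, saturating
  pop0 <- sample_population(liposome_species(200, 0.35, 100), 2000L,
                            seed = derive_seed(seed, 1))
  ref <- measure_sample(pop0, acq, edges, seed = derive_seed(seed, 2))$histogram
  histos <- lapply(seq_along(doses), function(i) {
    fp <- config$fission
    fp$rate_constant <- k_of_dose(doses[i])
    pt <- evolve_fission(pop0, fp, t = 20, seed = derive_seed(seed, 10 + i))
    h <- measure_sample(pt, acq, edges, dilution = 25,
                        seed = derive_seed(seed, 20 + i))$histogram
    list(doses[i], h)
  })
  dr <- dose_response(histos, ref)
  utils::write.csv(dr, file.path(config$outdir, "dose_response.csv"),
                   row.names = FALSE)
  write_histogram(ref, file.path(config$outdir, "histogram_reference.csv"))
  list(checks = list(
    monotone_dose = list(value = dr$remaining,
                         pass = all(diff(dr$remaining) < 0))))
}
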