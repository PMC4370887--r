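# Plain-text readers/writers for every artifact type. Traces are two-column
# CSV (time_s, counts) with a JSON sidecar of acquisition parameters; burst
# tables and histograms are CSV with documented columns; populations,
# ground truth and run configuration are JSON/YAML.

acq_to_list <- function(acq) unclass(acq)

acq_from_list <- function(l) {
  l <- l[!vapply(l, is.null, logical(1))]
  do.call(acquisition_params, l)
}

#' Write / read a photon-count trace
#'
#' CSV with columns `time_s`, `counts`, plus a `<path>.json` sidecar of the
#' acquisition parameters (and ground-truth bursts, when present).
#'
#' @param trace A `bas_trace`.
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `bas_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bas_trace"))
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              counts = trace$counts),
                   path, row.names = FALSE)
  side <- list(acquisition = acq_to_list(trace$acq))
  if (!is.null(trace$ground_truth)) side$ground_truth <- trace$ground_truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df)))
    stop("trace CSV must have columns time_s, counts: ", path)
  if (any(df$counts < 0) || any(df$counts != round(df$counts)))
    stop("counts must be non-negative integers: ", path)
  dt <- diff(df$time_s)
  if (nrow(df) > 1 && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("trace bins must be uniformly spaced: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  acq <- acq_from_list(side$acquisition)
  tr <- new_trace(df$counts, acq,
                  ground_truth = if (!is.null(side$ground_truth))
                    as.data.frame(side$ground_truth))
  tr
}

#' Write / read a burst table
#'
#' CSV with columns `start_s`, `end_s`, `amplitude`, `peak`, `n_bins`, plus
#' a JSON run log (background, threshold) beside it.
#'
#' @param bursts A `bas_bursts` table.
#' @param path CSV file path.
#' @export
write_bursts <- function(bursts, path) {
  stopifnot(inherits(bursts, "bas_bursts"))
  utils::write.csv(data.frame(start_s = bursts$start, end_s = bursts$end,
                              amplitude = bursts$amplitude,
                              peak = bursts$peak, n_bins = bursts$n_bins),
                   path, row.names = FALSE)
  jsonlite::write_json(list(background_rate = attr(bursts, "background_rate"),
                            sigma = attr(bursts, "sigma"),
                            threshold = attr(bursts, "threshold"),
                            k_sigma = attr(bursts, "k_sigma")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("start_s", "end_s", "amplitude", "peak", "n_bins")
  if (!all(need %in% names(df)))
    stop("burst CSV must have columns ", paste(need, collapse = ", "),
         ": ", path)
  if (any(df$end_s <= df$start_s)) stop("burst end must exceed start: ", path)
  out <- data.frame(start = df$start_s, end = df$end_s,
                    amplitude = df$amplitude, peak = df$peak,
                    n_bins = df$n_bins)
  log_path <- paste0(path, ".json")
  lg <- if (file.exists(log_path))
    jsonlite::read_json(log_path, simplifyVector = TRUE) else list()
  structure(out, class = c("bas_bursts", "data.frame"),
            background_rate = lg$background_rate, sigma = lg$sigma,
            threshold = lg$threshold, k_sigma = lg$k_sigma)
}

#' Write / read a BAS histogram
#'
#' CSV with columns `bin_lo`, `bin_hi`, `mean_intensity`,
#' `concentration_pM`, `n_events`, `valid`, plus a JSON metadata sidecar
#' (dilution factor, acquisition).
#'
#' @param h A `bas_histogram`.
#' @param path CSV file path.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "bas_histogram"))
  utils::write.csv(data.frame(bin_lo = h$bin_lo, bin_hi = h$bin_hi,
                              mean_intensity = h$mean_intensity,
                              concentration_pM = h$concentration,
                              n_events = h$n_events, valid = h$valid),
                   path, row.names = FALSE)
  jsonlite::write_json(list(dilution_factor = attr(h, "dilution_factor"),
                            acquisition = acq_to_list(attr(h, "acq"))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_lo", "bin_hi", "mean_intensity", "concentration_pM",
            "n_events", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("histogram CSV missing column(s) ", paste(miss, collapse = ", "),
         ": ", path)
  if (any(df$concentration_pM < 0))
    stop("negative concentration in histogram: ", path)
  if (any(diff(df$bin_lo) <= 0))
    stop("bin edges must be strictly increasing: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  out <- data.frame(bin_lo = df$bin_lo, bin_hi = df$bin_hi,
                    mean_intensity = df$mean_intensity,
                    concentration = df$concentration_pM,
                    n_events = df$n_events, valid = as.logical(df$valid))
  structure(out, class = c("bas_histogram", "data.frame"),
            acq = if (!is.null(side$acquisition))
              acq_from_list(side$acquisition),
            dilution_factor = side$dilution_factor %||% 1)
}

#' Write / read a fission time course
#'
#' A directory of per-time histogram CSVs plus a `manifest.json` naming the
#' files, times and condition labels.
#'
#' @param tc A `bas_time_course`.
#' @param dir Directory path (created if needed).
#' @export
write_time_course <- function(tc, dir) {
  stopifnot(inherits(tc, "bas_time_course"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("histogram_%03d.csv", seq_along(tc$times))
  for (i in seq_along(tc$times))
    write_histogram(tc$histograms[[i]], file.path(dir, files[i]))
  jsonlite::write_json(list(times = tc$times, files = files,
                            temperature = tc$temperature,
                            protein_conc = tc$protein_conc),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  paths <- file.path(dir, man$files)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  fission_time_course(man$times, lapply(paths, read_histogram),
                      temperature = man$temperature,
                      protein_conc = man$protein_conc)
}

#' Write / read an FCS curve
#'
#' CSV with columns `lag_s`, `G` (and `sigma` when available).
#'
#' @param curve An `fcs_curve`.
#' @param path CSV file path.
#' @export
write_fcs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  utils::write.csv(data.frame(lag_s = curve$lag, G = curve$G,
                              sigma = curve$sigma), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fcs_curve
#' @export
read_fcs_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("lag_s", "G") %in% names(df)))
    stop("FCS CSV must have columns lag_s, G: ", path)
  if (any(diff(df$lag_s) <= 0) || any(df$lag_s <= 0))
    stop("lags must be positive and strictly increasing: ", path)
  structure(data.frame(lag = df$lag_s, G = df$G,
                       sigma = df$sigma %||% NA_real_,
                       n_pairs = NA_real_),
            class = c("fcs_curve", "data.frame"))
}
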