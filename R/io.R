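# On-disk format: <stem>.tsv (time_s, flow_ml_s, pco2_mmHg at full double
# precision) plus <stem>.meta.json holding the recording metadata. Plain
# text by design so recordings diff and archive cleanly.

meta_fields <- c("mode", "eep", "weight", "instr_dead_space",
                 "transport_delay", "pa_co2", "pa_o2", "barometric")

#' Write a recording to disk
#'
#' Writes `<stem>.tsv` with header `time_s flow_ml_s pco2_mmHg` (one row per
#' sample, `%.17g` so doubles round-trip exactly) and `<stem>.meta.json`
#' with the metadata fields. Output bytes are deterministic for identical
#' input.
#'
#' @param series A [gas_time_series()].
#' @param stem Path stem (no extension); directories must exist.
#' @return Invisibly, the two paths written.
#' @export
write_recording <- function(series, stem) {
  validate_gas_time_series(series)
  tsv <- paste0(stem, ".tsv")
  rows <- sprintf("%.17g\t%.17g\t%.17g", series$t, series$flow, series$pco2)
  con <- file(tsv, open = "wb")
  on.exit(close(con))
  writeLines(c("time_s\tflow_ml_s\tpco2_mmHg", rows), con, sep = "\n")
  close(con); on.exit()

  meta_path <- paste0(stem, ".meta.json")
  m <- unclass(series$meta)[meta_fields]
  jsonlite::write_json(m, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, meta = meta_path))
}

#' Read a recording from disk
#'
#' Loads `<stem>.tsv` + `<stem>.meta.json` written by [write_recording()]
#' and returns a fully validated [gas_time_series()]; any invariant
#' violation (missing column, non-uniform timestamps, bad metadata) aborts
#' the load.
#'
#' @param stem Path stem (no extension), or the path to the `.tsv` file.
#' @return A [gas_time_series()].
#' @export
read_recording <- function(stem) {
  stem <- sub("\\.tsv$", "", stem)
  tsv <- paste0(stem, ".tsv")
  meta_path <- paste0(stem, ".meta.json")
  if (!file.exists(tsv)) stop("read_recording: no such file: ", tsv)
  if (!file.exists(meta_path)) {
    stop("read_recording: missing metadata sidecar: ", meta_path)
  }
  d <- utils::read.delim(tsv, check.names = FALSE)
  need <- c("time_s", "flow_ml_s", "pco2_mmHg")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("read_recording: missing column '", miss[1], "' in ", tsv)
  }
  mj <- jsonlite::read_json(meta_path)
  miss_m <- setdiff(meta_fields, names(mj))
  if (length(miss_m) > 0L) {
    stop("read_recording: missing metadata field '", miss_m[1], "' in ",
         meta_path)
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  for (f in setdiff(meta_fields, "mode")) {
    if (!is.null(mj[[f]]) && !is.numeric(mj[[f]])) {
      stop("read_recording: metadata field '", f,
           "' must be numeric (check its unit tag) in ", meta_path)
    }
  }
  meta <- recording_meta(mode = as.character(mj$mode),
                         eep = num_or_na(mj$eep),
                         weight = num_or_na(mj$weight),
                         instr_dead_space = num_or_na(mj$instr_dead_space),
                         transport_delay = num_or_na(mj$transport_delay),
                         pa_co2 = num_or_na(mj$pa_co2),
                         pa_o2 = num_or_na(mj$pa_o2),
                         barometric = num_or_na(mj$barometric))
  dt <- diff(d$time_s)
  fs <- 1 / stats::median(dt)
  gas_time_series(d$time_s, d$flow_ml_s, d$pco2_mmHg, fs, meta)
}

#' Write simulation ground truth as JSON
#'
#' Stores the generator parameters, seed, simulated arterial PaCO2 and the
#' oracle-computed clean-profile indices beside a recording, as
#' `<stem>.truth.json`.
#'
#' @param truth The `truth` element returned by [synthesize_recording()].
#' @param stem Path stem shared with the recording files.
#' @return Invisibly, the path written.
#' @export
write_sim_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "sim_truth"))
  path <- paste0(stem, ".truth.json")
  payload <- list(
    params = unclass(truth$params),
    flow = unclass(truth$flow),
    sensor = unclass(truth$sensor),
    seed = truth$seed,
    n_breaths = truth$n_breaths,
    pa_co2 = truth$pa_co2,
    oracle = unclass(truth$oracle)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth written by [write_sim_truth()]
#'
#' @param stem Path stem (or the `.truth.json` path itself).
#' @return A `sim_truth` record.
#' @export
read_sim_truth <- function(stem) {
  path <- if (grepl("\\.truth\\.json$", stem)) stem else
    paste0(stem, ".truth.json")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  oracle <- x$oracle
  oracle$flags <- as.character(oracle$flags)
  structure(
    list(params = do.call(expirogram_params, x$params),
         flow = do.call(flow_pattern, x$flow),
         sensor = do.call(sensor_model, x$sensor),
         seed = as.integer(x$seed), n_breaths = as.integer(x$n_breaths),
         pa_co2 = x$pa_co2,
         oracle = do.call(new_capno_indices, oracle)),
    class = "sim_truth")
}
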