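#' Sweep sets: stacks of equal-length traces with acquisition metadata
#'
#' A `sweep_set` is the unit of detection: a sweeps-by-samples numeric matrix
#' (pA for voltage clamp, mV for field recordings) together with the
#' acquisition parameters and per-sweep metadata. Currents are stored as
#' recorded, inward negative. Sample 0 is the sweep start; `stim_time` is in
#' ms from sweep start; all analysis windows are half-open `[start, end)`.
#'
#' @param data numeric matrix, one row per sweep.
#' @param sampling_rate samples per second, > 0.
#' @param stim_time stimulus time, ms from sweep start, within the sweep.
#' @param holding_potential holding potential in mV (-60 or +40 for voltage
#'   clamp); `NA` for field recordings.
#' @param units `"pA"` or `"mV"`.
#' @param metadata data frame with one row per sweep; a `sweep_index` column
#'   is added when absent. Conventional columns: `sweep_index`, `acq_order`,
#'   `timestamp` (s).
#' @param info named list of experiment-level labels (experiment id, cell id,
#'   animal id, genotype, age).
#' @return an object of class `"sweep_set"`.
#' @export
sweep_set <- function(data, sampling_rate, stim_time,
                      holding_potential = NA, units = "pA",
                      metadata = NULL, info = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1)
    stop("a sweep_set needs a numeric matrix with at least one sweep")
  if (anyNA(data)) stop("sweep data must not contain missing samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  sweep_ms <- ncol(data) / sampling_rate * 1000
  if (!is.numeric(stim_time) || stim_time < 0 || stim_time >= sweep_ms)
    stop("stim_time must lie within the sweep")
  units <- match.arg(units, c("pA", "mV"))
  if (is.null(metadata)) metadata <- data.frame(sweep_index = seq_len(nrow(data)))
  if (!is.data.frame(metadata) || nrow(metadata) != nrow(data))
    stop("metadata must be a data frame with one row per sweep")
  if (is.null(metadata$sweep_index)) metadata$sweep_index <- seq_len(nrow(data))
  structure(list(data = unname(data),
                 sampling_rate = as.numeric(sampling_rate),
                 stim_time = as.numeric(stim_time),
                 holding_potential = as.numeric(holding_potential),
                 units = units,
                 metadata = metadata,
                 info = info),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  hp <- if (is.na(x$holding_potential)) "field" else
    sprintf("%+g mV", x$holding_potential)
  cat(sprintf("Sweep set: %d sweeps x %d samples (%s), %g kHz, stim at %g ms (%s)\n",
              nrow(x$data), ncol(x$data), x$units,
              x$sampling_rate / 1000, x$stim_time, hp))
  invisible(x)
}

#' Number of sweeps in a sweep set
#' @param x a [sweep_set()].
#' @return integer count.
#' @export
n_sweeps <- function(x) nrow(x$data)

#' Sample times of a sweep set
#' @param x a [sweep_set()].
#' @return numeric vector of sample times in ms from sweep start.
#' @export
sweep_times <- function(x) (seq_len(ncol(x$data)) - 1) / x$sampling_rate * 1000

# scalar header fields shared by the CSV writer/reader
sweepset_header_fields <- c("sampling_rate", "stim_time", "holding_potential", "units")

#' Write a sweep set to file
#'
#' Two dialects share one logical schema and are selected by extension:
#' `.csv` is a plain-text layout (a `# key: value` header block naming the
#' acquisition parameters and experiment labels, then one CSV row per sweep:
#' metadata columns followed by sample columns `s1..sN`, printed with 17
#' significant digits so the array payload round-trips bit-exactly), and
#' `.rds` is the native array container. Existing files are only replaced
#' with `overwrite = TRUE`.
#'
#' @param x a [sweep_set()].
#' @param path output file, ending in `.csv` or `.rds`.
#' @param overwrite replace an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(x, path, overwrite = FALSE) {
  stopifnot(inherits(x, "sweep_set"))
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(x, path)
    return(invisible(path))
  }
  if (ext != "csv") stop("unsupported sweep-set extension: .", ext)
  hdr <- c("# minstim-sweepset v1",
           sprintf("# sampling_rate: %.17g", x$sampling_rate),
           sprintf("# stim_time: %.17g", x$stim_time),
           sprintf("# holding_potential: %s",
                   if (is.na(x$holding_potential)) "NA"
                   else sprintf("%.17g", x$holding_potential)),
           sprintf("# units: %s", x$units))
  for (nm in names(x$info))
    hdr <- c(hdr, sprintf("# info.%s: %s", nm, as.character(x$info[[nm]])))
  samp <- matrix(formatC(x$data, digits = 17, format = "g"),
                 nrow = nrow(x$data))
  colnames(samp) <- paste0("s", seq_len(ncol(samp)))
  tab <- cbind(x$metadata, as.data.frame(samp, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_header_block <- function(path) {
  lines <- readLines(path)
  hdr_n <- which(!startsWith(lines, "#"))[1] - 1
  if (is.na(hdr_n) || hdr_n < 1)
    stop("format error: no header block in ", path)
  kv <- list()
  for (ln in lines[seq_len(hdr_n)][-1]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  list(kv = kv, body = lines[-seq_len(hdr_n)])
}

#' Read a sweep set from file
#'
#' Reads either dialect written by [write_sweepset()] (selected by
#' extension) and validates the layout: missing header fields and ragged or
#' non-numeric sample blocks are format errors naming the problem.
#'
#' @param path a `.csv` or `.rds` file written by [write_sweepset()].
#' @return a [sweep_set()].
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stop("cannot find sweep-set file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    x <- readRDS(path)
    if (!inherits(x, "sweep_set")) stop("format error: not a sweep_set: ", path)
    return(x)
  }
  if (ext != "csv") stop("unsupported sweep-set extension: .", ext)
  h <- read_header_block(path)
  for (fld in c("sampling_rate", "stim_time", "units"))
    if (is.null(h$kv[[fld]]))
      stop("format error: header of ", path, " is missing field '", fld, "'")
  tab <- read.csv(text = h$body, stringsAsFactors = FALSE)
  samp_cols <- grep("^s[0-9]+$", names(tab))
  if (length(samp_cols) < 1) stop("format error: no sample columns in ", path)
  data <- as.matrix(tab[, samp_cols, drop = FALSE])
  if (!is.numeric(data) || anyNA(data))
    stop("format error: ragged or non-numeric sample block in ", path)
  info_keys <- grep("^info\\.", names(h$kv), value = TRUE)
  info <- setNames(lapply(info_keys, function(k) h$kv[[k]]),
                   sub("^info\\.", "", info_keys))
  hp <- h$kv[["holding_potential"]]
  sweep_set(data,
            sampling_rate = as.numeric(h$kv[["sampling_rate"]]),
            stim_time = as.numeric(h$kv[["stim_time"]]),
            holding_potential = if (is.null(hp) || hp == "NA") NA else as.numeric(hp),
            units = h$kv[["units"]],
            metadata = tab[, -samp_cols, drop = FALSE],
            info = info)
}

# ---- event tables ----------------------------------------------------------

event_table_columns <- c("sweep_index", "holding_potential", "baseline",
                         "peak_amplitude", "peak_latency", "amplitude",
                         "charge", "failure", "excluded", "exclude_reason")

new_event_table <- function(df, noise_sd = NA_real_, params = NULL) {
  stopifnot(all(event_table_columns %in% names(df)))
  df <- df[, event_table_columns]
  structure(df, class = c("event_table", "data.frame"),
            noise_sd = noise_sd, params = params)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d sweeps, %d failures, %d excluded (noise SD %.3g)\n",
              nrow(x), sum(x$failure, na.rm = TRUE), sum(x$excluded),
              attr(x, "noise_sd")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write an event table to file
#'
#' Plain CSV, one row per sweep, with a short `# key: value` header carrying
#' the noise estimate. The column order is fixed and stable:
#' `sweep_index, holding_potential, baseline, peak_amplitude, peak_latency,
#' amplitude, charge, failure, excluded, exclude_reason`.
#'
#' @param events an event table from [classify_failures()].
#' @param path output `.csv` file.
#' @param overwrite replace an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path, overwrite = FALSE) {
  stopifnot(inherits(events, "event_table"))
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# minstim-events v1",
               sprintf("# noise_sd: %.17g", attr(events, "noise_sd"))), con)
  df <- as.data.frame(events)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path a `.csv` file.
#' @return an event table.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("cannot find event-table file: ", path)
  h <- read_header_block(path)
  tab <- read.csv(text = h$body, stringsAsFactors = FALSE)
  miss <- setdiff(event_table_columns, names(tab))
  if (length(miss))
    stop("format error: event table ", path, " is missing column(s) ",
         paste(miss, collapse = ", "))
  tab$failure <- as.logical(tab$failure)
  tab$excluded <- as.logical(tab$excluded)
  tab$exclude_reason <- as.character(tab$exclude_reason)
  tab$exclude_reason[is.na(tab$exclude_reason)] <- ""
  new_event_table(tab, noise_sd = as.numeric(h$kv[["noise_sd"]]))
}
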