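#' Trial-structured multi-channel time series
#'
#' Container for an ensemble of repetitions (trials) of a multi-channel
#' recording. Values are held as a dense array indexed
#' `[channel, repetition, sample]`; all repetitions of a channel must have
#' equal length and no missing values are allowed. Sample indices are
#' 0-based throughout the package and intervals are half-open; physical time
#' enters only through `sampling_rate`.
#'
#' @param values numeric array `[channel, repetition, sample]`, or a matrix
#'   `[repetition, sample]` for a single channel.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param time_origin sample index (0-based) of the stimulus/cycle onset.
#'
#' @return An object of class `ensemble_ts`.
#' @export
#' @examples
#' x <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
#' ens <- ensemble_ts(x, sampling_rate = 1000, channel_labels = c("X", "Y"))
#' ens
ensemble_ts <- function(values, sampling_rate, channel_labels = NULL,
                        time_origin = 0) {
  if (is.matrix(values)) values <- array(values, dim = c(1L, dim(values)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a [channel, repetition, sample] array")
  if (anyNA(values)) stop("ensemble contains missing values (NaN/NA)")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be > 0")
  if (dim(values)[2] < 1L) stop("need at least one repetition")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(values)[1]))
  if (length(channel_labels) != dim(values)[1])
    stop("`channel_labels` must match the number of channels")
  structure(
    list(values = values, sampling_rate = sampling_rate,
         channel_labels = channel_labels, time_origin = time_origin),
    class = "ensemble_ts")
}

#' @export
print.ensemble_ts <- function(x, ...) {
  d <- dim(x$values)
  cat("<ensemble_ts> ", d[1], " channel(s) x ", d[2], " repetition(s) x ",
      d[3], " sample(s) @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("  channels:", paste(x$channel_labels, collapse = ", "),
      " | time origin at sample", x$time_origin, "\n")
  invisible(x)
}

n_channels <- function(x) dim(x$values)[1]
n_repetitions <- function(x) dim(x$values)[2]
n_samples <- function(x) dim(x$values)[3]

#' Extract one channel as a repetition-by-sample matrix
#'
#' @param data an [ensemble_ts()].
#' @param channel channel label or index.
#' @return numeric matrix `[repetition, sample]`.
#' @export
channel_matrix <- function(data, channel) {
  stopifnot(inherits(data, "ensemble_ts"))
  i <- if (is.character(channel)) match(channel, data$channel_labels) else channel
  if (is.na(i) || i < 1 || i > n_channels(data))
    stop("unknown channel: ", channel)
  m <- data$values[i, , , drop = FALSE]
  dim(m) <- dim(data$values)[2:3]
  m
}

#' Analysis window
#'
#' Half-open interval `[t_start, t_end)` of 0-based sample indices within a
#' repetition. The window delimits the reference time points whose neighbour
#' statistics enter TE estimation (the temporal-resolution parameter of
#' mixed time/ensemble pooling); it is distinct from the embedding window,
#' which provides the history of each reference point.
#'
#' @param t_start,t_end 0-based sample indices, `t_end > t_start`.
#' @param label optional window label.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(t_start, t_end, label = NULL) {
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`")
  if (t_start < 0) stop("`t_start` must be >= 0")
  if (is.null(label)) label <- paste0("[", t_start, ",", t_end, ")")
  structure(list(t_start = as.integer(t_start), t_end = as.integer(t_end),
                 label = label),
            class = "analysis_window")
}

#' Restrict an ensemble to an analysis window
#'
#' Returns a view of the ensemble restricted to samples
#' `[t_start, t_end)` in every repetition, with the time origin shifted
#' accordingly. Slicing composes: two consecutive selections equal one
#' combined selection.
#'
#' @param data an [ensemble_ts()].
#' @param window an [analysis_window()].
#' @return An [ensemble_ts()] with `t_end - t_start` samples.
#' @export
select_window <- function(data, window) {
  stopifnot(inherits(data, "ensemble_ts"), inherits(window, "analysis_window"))
  L <- n_samples(data)
  if (window$t_end > L)
    stop("window [", window$t_start, ",", window$t_end,
         ") outside recorded range of ", L, " samples")
  idx <- (window$t_start + 1L):window$t_end   # 0-based -> R indexing
  ensemble_ts(data$values[, , idx, drop = FALSE], data$sampling_rate,
              data$channel_labels, data$time_origin - window$t_start)
}

#' Screen an ensemble for drifts across repetitions
#'
#' Ensemble pooling assumes stationarity *over repetitions*: the
#' distribution at a fixed within-trial time must not drift over the course
#' of the recording (e.g. through learning effects). A standard screen is to
#' compare means and variances between the first and second half of the
#' recorded repetitions. A channel is flagged when its split-half mean
#' difference exceeds three standard errors.
#'
#' @param data an [ensemble_ts()].
#' @return A list with the array shape, a per-channel data frame of
#'   split-half means/variances, drift flags, and notes.
#' @export
validate_ensemble <- function(data) {
  stopifnot(inherits(data, "ensemble_ts"))
  R <- n_repetitions(data)
  notes <- character(0)
  if (R < 2) {
    notes <- c(notes, paste("single repetition: ensemble pooling impossible",
                            "without pooling over time"))
  }
  half1 <- seq_len(R %/% 2)
  half2 <- setdiff(seq_len(R), half1)
  per_channel <- do.call(rbind, lapply(seq_len(n_channels(data)), function(i) {
    m <- channel_matrix(data, i)
    rep_means <- rowMeans(m)
    if (length(half2) >= 1 && length(half1) >= 1) {
      m1 <- mean(rep_means[half1]); m2 <- mean(rep_means[half2])
      se <- sqrt(var(rep_means[half1]) / length(half1) +
                   var(rep_means[half2]) / max(length(half2), 2))
      drift <- is.finite(se) && se > 0 && abs(m1 - m2) > 3 * se
    } else {
      m1 <- mean(rep_means); m2 <- NA_real_; se <- NA_real_; drift <- FALSE
    }
    data.frame(channel = data$channel_labels[i],
               mean_half1 = m1, mean_half2 = m2,
               var_half1 = if (length(half1) > 1) var(rep_means[half1]) else NA_real_,
               var_half2 = if (length(half2) > 1) var(rep_means[half2]) else NA_real_,
               split_se = se, drift_flag = drift)
  }))
  list(shape = dim(data$values), sampling_rate = data$sampling_rate,
       per_channel = per_channel, notes = notes)
}

# ---------------------------------------------------------------------------
# File I/O: delimited text (one file per channel, rows = repetitions) and an
# R-native binary container (serialized list keyed by channel label).

#' Write an ensemble to disk
#'
#' Two on-disk layouts are supported. `"csv"` writes one comma-delimited
#' file per channel (`<label>.csv` inside `path`, created as a directory)
#' with repetitions as rows and samples as columns, preceded by
#' `#`-prefixed header lines carrying the sampling rate and time origin.
#' `"rds"` writes a single R-native binary container keyed by channel label.
#'
#' @param data an [ensemble_ts()].
#' @param path output directory (`"csv"`) or file (`"rds"`).
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(data, path, format = c("csv", "rds")) {
  stopifnot(inherits(data, "ensemble_ts"))
  format <- match.arg(format)
  if (format == "rds") {
    channels <- lapply(seq_len(n_channels(data)), function(i) channel_matrix(data, i))
    names(channels) <- data$channel_labels
    saveRDS(list(channels = channels, sampling_rate = data$sampling_rate,
                 time_origin = data$time_origin), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_channels(data))) {
    f <- file.path(path, paste0(data$channel_labels[i], ".csv"))
    con <- file(f, "w")
    writeLines(c(paste0("# channel: ", data$channel_labels[i]),
                 paste0("# sampling_rate: ", data$sampling_rate),
                 paste0("# time_origin: ", data$time_origin)), con)
    write.table(format(channel_matrix(data, i), digits = 17, trim = TRUE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read an ensemble from disk
#'
#' Counterpart of [write_ensemble()]. For `"csv"`, `path` is the directory
#' holding one `<label>.csv` per channel; ragged repetition lengths raise a
#' structural error naming the offending file, and any NaN fails validation.
#'
#' @param path directory (`"csv"`) or file (`"rds"`).
#' @param format `"csv"` or `"rds"`.
#' @return An [ensemble_ts()].
#' @export
load_ensemble <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    obj <- readRDS(path)
    vals <- simplify2array(obj$channels)        # [rep, sample, channel]
    vals <- unname(aperm(vals, c(3, 1, 2)))
    return(ensemble_ts(vals, obj$sampling_rate, names(obj$channels),
                       obj$time_origin))
  }
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no channel files (*.csv) found in ", path)
  read_one <- function(f) {
    header <- grep("^#", readLines(f, n = 10), value = TRUE)
    get <- function(key) {
      ln <- grep(paste0("^# ", key, ":"), header, value = TRUE)
      if (length(ln) == 0) NA else sub(paste0("^# ", key, ":\\s*"), "", ln[1])
    }
    rows <- read.table(f, sep = ",", comment.char = "#", header = FALSE,
                       fill = TRUE, colClasses = "numeric")
    lens <- apply(rows, 1, function(r) sum(!is.na(r)))
    if (length(unique(lens)) > 1)
      stop("ragged repetitions in ", basename(f), ": lengths ",
           paste(unique(lens), collapse = ", "))
    list(label = get("channel"), fs = as.numeric(get("sampling_rate")),
         origin = as.numeric(get("time_origin")), m = as.matrix(rows))
  }
  parts <- lapply(files, read_one)
  dims <- unique(lapply(parts, function(p) dim(p$m)))
  if (length(dims) > 1) stop("channels disagree in repetitions x samples shape")
  vals <- unname(aperm(simplify2array(lapply(parts, function(p) p$m)),
                       c(3, 1, 2)))
  labels <- vapply(parts, function(p) p$label, character(1))
  fs <- unique(vapply(parts, function(p) p$fs, numeric(1)))
  if (length(fs) != 1 || is.na(fs)) stop("missing or inconsistent sampling_rate header")
  origin <- parts[[1]]$origin
  ensemble_ts(vals, fs, labels, if (is.na(origin)) 0 else origin)
}
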