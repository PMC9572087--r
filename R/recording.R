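#' Construct a labeled tri-axial recording
#'
#' A `har_recording` holds uniformly sampled tri-axial acceleration in
#' g-units together with a per-sample activity label and the sampling
#' frequency. All downstream stages (segmentation, feature extraction)
#' consume this type.
#'
#' @param time numeric vector of sample times in seconds, uniformly spaced
#'   at `1/fs` within tolerance. If `NULL`, a grid `(0:(n-1))/fs` is built.
#' @param x,y,z numeric vectors of equal length, acceleration in g-units.
#' @param label activity class per sample (character or factor).
#' @param fs sampling frequency in Hz, `> 0`.
#' @return An object of class `har_recording`: a list with elements
#'   `time`, `x`, `y`, `z`, `label` (factor) and `fs`.
#' @export
#' @examples
#' r <- har_recording(x = sin(1:100 / 5), y = rnorm(100, sd = 0.01),
#'                    z = rep(1, 100), label = "walk", fs = 20)
#' r
har_recording <- function(x, y, z, label, fs, time = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  if (length(time) != n) stop("time must match the channel length")
  label <- rep_len(as.character(label), n)
  structure(
    list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), label = factor(label), fs = fs),
    class = "har_recording"
  )
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$x), x$fs, length(x$x) / x$fs))
  tab <- table(x$label)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.har_recording <- function(x) length(x$x)

# Uniform-spacing check shared by segment_recording(); tolerance is a
# fraction of the sample interval.
check_uniform <- function(recording, tol_frac = 0.1) {
  dt <- diff(recording$time)
  if (length(dt) && max(abs(dt - 1 / recording$fs)) > tol_frac / recording$fs)
    stop("irregular sampling: timestamps deviate from 1/fs beyond tolerance")
  invisible(TRUE)
}

#' Read a recording from a text file in a known dialect
#'
#' Supports three layouts: `generic_csv` (header
#' `timestamp,x,y,z,label`), `wisdm` (comma-separated
#' `user,activity,timestamp,x,y,z` lines, optionally `;`-terminated) and
#' `pamap2` (space-separated IMU columns; the 16-g accelerometer of the
#' chosen sensor location is used, with activity-id as label).
#' Malformed lines are skipped and counted in a single warning. Because
#' raw device timestamps are often irregular, the returned recording is
#' placed on a uniform time grid at `fs`.
#'
#' @param path file path.
#' @param dialect one of `"generic_csv"`, `"wisdm"`, `"pamap2"`.
#' @param fs sampling frequency in Hz (required for `wisdm`; defaults to
#'   50 for `generic_csv` if no better information, 100 for `pamap2`).
#' @param pamap2_location IMU placement for `pamap2`: `"hand"`,
#'   `"chest"` or `"ankle"`.
#' @return A [har_recording].
#' @export
read_recording <- function(path, dialect = c("generic_csv", "wisdm", "pamap2"),
                           fs = NULL,
                           pamap2_location = c("hand", "chest", "ankle")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
    generic_csv = read_generic_csv(path, fs %||% 50),
    wisdm = read_wisdm(path, fs %||% 20),
    pamap2 = read_pamap2(path, fs %||% 100, match.arg(pamap2_location))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_generic_csv <- function(path, fs) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z", "label")
  if (!all(need %in% names(df)))
    stop("generic_csv requires columns: ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(df[, c("x", "y", "z")]) &
    is.finite(df$x) & is.finite(df$y) & is.finite(df$z)
  if (any(!ok)) warning(sum(!ok), " malformed line(s) skipped")
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) stop("empty recording after parsing")
  har_recording(df$x, df$y, df$z, df$label, fs)
}

read_wisdm <- function(path, fs) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(gsub(";", "", lines, fixed = TRUE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  bad <- vapply(parts, function(p) length(p) != 6L ||
                  anyNA(suppressWarnings(as.numeric(p[4:6]))), logical(1))
  if (any(bad)) warning(sum(bad), " malformed line(s) skipped")
  parts <- parts[!bad]
  if (!length(parts)) stop("empty recording after parsing")
  m <- do.call(rbind, parts)
  har_recording(as.numeric(m[, 4]), as.numeric(m[, 5]), as.numeric(m[, 6]),
                m[, 2], fs)
}

read_pamap2 <- function(path, fs, location) {
  # column layout: 1 time, 2 activity id, 3 heart rate, then 17 columns
  # per IMU (hand, chest, ankle); 16-g accel occupies IMU columns 2-4.
  base <- switch(location, hand = 3L, chest = 20L, ankle = 37L)
  cols <- base + 2:4
  df <- utils::read.table(path, header = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < max(cols)) stop("not a PAMAP2-style table: too few columns")
  acc <- df[, cols]
  ok <- stats::complete.cases(acc) &
    apply(acc, 1L, function(r) all(is.finite(as.numeric(r))))
  if (any(!ok)) warning(sum(!ok), " malformed line(s) skipped")
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) stop("empty recording after parsing")
  har_recording(df[[cols[1]]], df[[cols[2]]], df[[cols[3]]],
                paste0("activity_", df[[2]]), fs)
}

#' Write a recording as generic CSV
#'
#' Inverse of the `generic_csv` dialect of [read_recording()].
#'
#' @param recording a [har_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "har_recording"))
  df <- data.frame(timestamp = recording$time, x = recording$x,
                   y = recording$y, z = recording$z,
                   label = as.character(recording$label))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Down-sample a recording by an integer factor
#'
#' Applies an anti-alias low-pass before decimation (via
#' [signal::decimate()]) to each axis; labels are taken at the kept
#' sample positions. Intended for sampling-frequency sensitivity
#' experiments (e.g. reducing 100 Hz recordings to 20 Hz).
#'
#' @param recording a [har_recording].
#' @param factor integer decimation factor `>= 2`.
#' @return A [har_recording] at `fs / factor`.
#' @export
resample_recording <- function(recording, factor) {
  stopifnot(inherits(recording, "har_recording"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be an integer >= 2")
  keep <- seq(1L, length(recording$x), by = factor)
  dec <- function(v) signal::decimate(v, factor)[seq_along(keep)]
  har_recording(dec(recording$x), dec(recording$y), dec(recording$z),
                as.character(recording$label)[keep], recording$fs / factor)
}
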