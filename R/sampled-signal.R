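#' Uniformly sampled single-channel biosignal
#'
#' Lightweight container for a uniformly sampled EMG or ECG trace. All
#' processing functions in the package accept and return this class so that
#' the sampling rate travels with the samples.
#'
#' @param samples Numeric vector of sample values (mV, or normalized
#'   amplitude units for EMG).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param kind Signal kind, `"emg"` or `"ecg"`.
#' @param meta Optional named list of provenance fields (state label, seed,
#'   ...) carried along and written to file headers.
#'
#' @return An object of class `sampled_signal`: a numeric vector with
#'   attributes `fs`, `kind` and `meta`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250,
#'                     kind = "ecg")
#' duration(s)
#' @export
sampled_signal <- function(samples, fs, kind = c("emg", "ecg"), meta = list()) {
  kind <- match.arg(kind)
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)")
  structure(as.numeric(samples), fs = as.numeric(fs), kind = kind,
            meta = meta, class = "sampled_signal")
}

#' @rdname sampled_signal
#' @param x A `sampled_signal`.
#' @export
duration <- function(x) length(x) / attr(x, "fs")

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> kind=%s fs=%g Hz n=%d (%.3f s)\n",
              attr(x, "kind"), attr(x, "fs"), length(x), duration(x)))
  invisible(x)
}

# Replace the sample values, keeping fs/kind/meta.
with_samples <- function(x, samples) {
  sampled_signal(samples, fs = attr(x, "fs"), kind = attr(x, "kind"),
                 meta = attr(x, "meta"))
}

signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("not a sampled_signal: missing sampling rate")
  fs
}

# Accept either a sampled_signal or a bare numeric vector plus fs.
as_sampled <- function(x, fs = NULL, kind = "emg") {
  if (inherits(x, "sampled_signal")) return(x)
  if (is.null(fs)) stop("'fs' is required when 'x' is a plain numeric vector")
  sampled_signal(x, fs = fs, kind = kind)
}

#' Read and write sampled signals as delimited text
#'
#' Signals are stored as two-column delimited text (`time_s`, `value`) with a
#' leading `#`-comment header carrying the sampling rate, signal kind and any
#' provenance fields, so a file round-trips to an identical
#' [sampled_signal()].
#'
#' @param x A `sampled_signal`.
#' @param path File path.
#' @return `read_signal()` returns a `sampled_signal`; `write_signal()`
#'   returns `path` invisibly.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "sampled_signal"))
  meta <- attr(x, "meta")
  hdr <- c(sprintf("# fs=%.10g", signal_fs(x)),
           sprintf("# kind=%s", attr(x, "kind")))
  if (length(meta))
    hdr <- c(hdr, sprintf("# %s=%s", names(meta),
                          vapply(meta, format, character(1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s\tvalue"), con)
  t <- (seq_along(x) - 1) / signal_fs(x)
  utils::write.table(data.frame(t = sprintf("%.6f", t),
                                v = sprintf("%.8g", as.numeric(x))),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"fs" %in% keys) stop("signal file lacks an fs header line: ", path)
  fs <- as.numeric(vals[["fs"]])
  kind <- if ("kind" %in% keys) vals[["kind"]] else "emg"
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  meta <- as.list(vals[setdiff(keys, c("fs", "kind"))])
  sampled_signal(dat[[2]], fs = fs, kind = kind, meta = meta)
}
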