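# On-disk session format: a directory with header.txt (key=value),
# row-major float32 signal files, and a trials.csv event table. The
# format is deliberately language-neutral and trivially parseable.

readHeader <- function(path) {
  lines <- readLines(file.path(path, "header.txt"))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1L), 2L),
                  vapply(kv, `[`, character(1L), 1L))
}

#' Write a session to a directory
#'
#' Serializes a [LaminarSession-class] as `header.txt` (key=value pairs:
#' session_id, n_channels, spacing_mm, dtype, and per-signal sampling
#' rate, unit, sample count and file name), one little-endian float32
#' binary per signal (row-major: channel 1's samples first), and
#' `trials.csv`. An optional ground-truth table is written as
#' `ground_truth.csv`.
#'
#' @param session a [LaminarSession-class].
#' @param path target directory (created if needed).
#' @param truth optional ground-truth data.frame.
#' @return the path, invisibly.
#' @export
writeSession <- function(session, path, truth = NULL) {
  stopifnot(is(session, "LaminarSession"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(session_id = session@id,
           n_channels = as.character(session@nChannels),
           spacing_mm = as.character(session@spacingMm),
           dtype = "float32")
  for (nm in names(session@signals)) {
    sig <- session@signals[[nm]]
    fn <- paste0(nm, ".bin")
    con <- file(file.path(path, fn), "wb")
    writeBin(as.vector(t(sig@samples)), con, size = 4L, endian = "little")
    close(con)
    hdr[paste0(nm, "_fs_hz")] <- as.character(sig@fsHz)
    hdr[paste0(nm, "_unit")] <- sig@unit
    hdr[paste0(nm, "_n_samples")] <- as.character(ncol(sig@samples))
    hdr[paste0(nm, "_file")] <- fn
  }
  writeLines(paste0(names(hdr), "=", unname(hdr)),
             file.path(path, "header.txt"))
  utils::write.csv(session@trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(truth, file.path(path, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [writeSession()]. The stored sample count of every signal is
#' checked against the file size; a mismatch (e.g. a header edited to the
#' wrong rate/length) is an error.
#'
#' @param path session directory.
#' @return a [LaminarSession-class].
#' @export
readSession <- function(path) {
  hdr <- readHeader(path)
  nC <- as.integer(hdr[["n_channels"]])
  sp <- as.numeric(hdr[["spacing_mm"]])
  sigNames <- sub("_file$", "", grep("_file$", names(hdr), value = TRUE))
  signals <- list()
  for (nm in sigNames) {
    fn <- file.path(path, hdr[[paste0(nm, "_file")]])
    nS <- as.integer(hdr[[paste0(nm, "_n_samples")]])
    expect <- nC * nS
    sz <- file.info(fn)$size
    if (is.na(sz) || sz != 4 * expect)
      stop("signal file '", basename(fn), "' has ", sz %/% 4,
           " samples but the header declares ", expect)
    con <- file(fn, "rb")
    v <- readBin(con, "numeric", n = expect, size = 4L, endian = "little")
    close(con)
    signals[[nm]] <- ContinuousSignal(
      matrix(v, nC, nS, byrow = TRUE),
      fsHz = as.numeric(hdr[[paste0(nm, "_fs_hz")]]),
      spacingMm = sp, unit = hdr[[paste0(nm, "_unit")]])
  }
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  new("LaminarSession", id = hdr[["session_id"]], signals = signals,
      trials = trials, nChannels = nC, spacingMm = sp)
}
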