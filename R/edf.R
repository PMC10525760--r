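#' Read a multichannel recording from EDF/EDF+ files
#'
#' Minimal reader for the European Data Format: fixed-width ASCII header,
#' one 256-byte block plus 256 bytes per signal, followed by data records
#' of little-endian 16-bit integers that are mapped linearly from the
#' digital to the physical range. Covers continuous EDF recordings with a
#' common sampling rate across the selected channels; EDF+ annotation
#' channels are ignored.
#'
#' When several files are given (nights are often stored in multi-hour
#' blocks) they are concatenated in start-time order; a gap or overlap
#' between consecutive files larger than one sample period raises a
#' warning, and the data are concatenated as recorded.
#'
#' @param paths one or more EDF file paths.
#' @param channels optional character include-list of channel labels (the
#'   stand-in for clinical channel exclusion); default: all non-annotation
#'   channels.
#' @return a [raw_recording()].
#' @export
read_edf <- function(paths, channels = NULL) {
  parts <- lapply(paths, read_edf_one, channels = channels)
  if (length(parts) == 1) return(parts[[1]])
  starts <- vapply(parts, function(p)
    as.numeric(p$start_time %||% NA_real_), numeric(1))
  if (!anyNA(starts)) {
    ord <- order(starts)
    parts <- parts[ord]; starts <- starts[ord]
    for (i in seq_along(parts)[-1]) {
      expected <- starts[i - 1] +
        nrow(parts[[i - 1]]$samples) * parts[[i - 1]]$sample_period
      if (abs(starts[i] - expected) > parts[[i]]$sample_period)
        warning(sprintf(
          "gap of %.3f s between EDF blocks %d and %d; epochs spanning it are unreliable",
          starts[i] - expected, i - 1, i))
    }
  }
  ids <- parts[[1]]$contact_ids
  dt <- parts[[1]]$sample_period
  for (p in parts[-1]) {
    if (!identical(p$contact_ids, ids) || p$sample_period != dt)
      stop_invalid("EDF blocks differ in channels or sampling rate",
                   "invalid_parameter")
  }
  raw_recording(do.call(rbind, lapply(parts, `[[`, "samples")),
                dt, ids, parts[[1]]$start_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_edf_one <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  startdate <- trimws(rd(8)); starttime <- trimws(rd(8))
  num(8)                                  # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)),
                              character(1))
  labels <- field(16)
  field(80); dims <- field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))             # samples per record per signal
  field(32)

  keep <- !grepl("^EDF Annotations", labels)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stop_invalid(paste("channels not in file:",
                         paste(missing, collapse = ", ")),
                   "invalid_parameter")
    keep <- keep & labels %in% channels
  }
  if (!any(keep)) stop_invalid("no channels selected", "empty_data")
  if (length(unique(spr[keep])) != 1)
    stop_invalid("selected channels have different sampling rates",
                 "invalid_parameter")

  sig <- which(keep)
  out <- matrix(0, n_rec * spr[sig[1]], length(sig))
  scale <- (pmax - pmin) / (dmax - dmin)
  offs <- cumsum(c(0, spr))[seq_len(ns)]
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", per_rec, size = 2, signed = TRUE,
                     endian = "little")
    for (j in seq_along(sig)) {
      s <- sig[j]
      x <- block[(offs[s] + 1):(offs[s] + spr[s])]
      out[((r - 1) * spr[s] + 1):(r * spr[s]), j] <-
        (x - dmin[s]) * scale[s] + pmin[s]
    }
  }
  start <- tryCatch({
    dmy <- as.integer(strsplit(startdate, "\\.")[[1]])
    yy <- dmy[3]; yy <- if (yy >= 85) 1900 + yy else 2000 + yy
    as.POSIXct(sprintf("%04d-%02d-%02d %s", yy, dmy[2], dmy[1],
                       gsub("\\.", ":", starttime)), tz = "UTC")
  }, error = function(e) NULL)
  raw_recording(out, rec_dur / spr[sig[1]], labels[sig], start)
}

#' Write a recording to an EDF file
#'
#' Counterpart of [read_edf()]. Samples are quantised to 16-bit integers
#' over a symmetric physical range per channel, in 1 s data records; a
#' trailing part-second is dropped. Quantisation error is bounded by the
#' channel's peak amplitude divided by 2^15.
#'
#' @param raw a [raw_recording()]; the sampling rate must be a whole
#'   number of samples per second.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- 1 / raw$sample_period
  if (abs(fs - round(fs)) > 1e-9)
    stop_invalid("write_edf needs an integer sampling rate",
                 "invalid_parameter")
  fs <- round(fs)
  ns <- ncol(raw$samples)
  n_rec <- nrow(raw$samples) %/% fs
  if (n_rec < 1) stop_invalid("less than one second of data", "empty_data")
  peak <- apply(abs(raw$samples), 2, max)
  peak <- ifelse(peak > 0, peak * 1.0001, 1)
  # render each physical bound in at most 8 header characters, and use the
  # rendered (slightly rounded) value for quantisation so read == write
  fmt8 <- function(x) {
    for (dg in 7:1) {
      s <- trimws(formatC(x, format = "g", digits = dg))
      if (nchar(s) <= 7) return(s)  # leaves room for the minus sign
    }
    stop_invalid("physical range unrepresentable in EDF header",
                 "invalid_parameter")
  }
  pstr <- vapply(peak, fmt8, character(1))
  pr <- as.numeric(pstr)
  start <- raw$start_time %||% as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    writeChar(formatC(x, width = -w), con, eos = NULL)
  }
  pad("0", 8)
  pad("X X X X", 80)
  pad("Startdate X X X X", 80)
  pad(format(start, "%d.%m.%y"), 8)
  pad(format(start, "%H.%M.%S"), 8)
  pad(256 * (ns + 1), 8)
  pad("", 44)
  pad(n_rec, 8)
  pad("1", 8)
  pad(ns, 4)
  for (lab in raw$contact_ids) pad(lab, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(paste0("-", pstr[i]), 8)
  for (i in seq_len(ns)) pad(pstr[i], 8)
  for (i in seq_len(ns)) pad(-32768, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((raw$samples[idx, j] + pr[j]) / (2 * pr[j]) * 65535) - 32768
      dig <- base::pmin(base::pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
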