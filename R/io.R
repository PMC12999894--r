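#' @include AllClasses.R
NULL

# canonical case for 10-20 labels: first letters upper, trailing 'z' lower
canonicalCase <- function(x) {
  if (!length(x)) return(character())
  core <- sub("^\\s+|\\s+$", "", x)
  ifelse(grepl("^[A-Za-z]+[0-9]*z?$", core, ignore.case = TRUE),
         paste0(toupper(substr(core, 1, 1)),
                gsub("Z", "z", substr(core, 2, nchar(core)))),
         core)
}

#' Normalize channel labels
#'
#' Strips whitespace and normalizes case to canonical 10-20 form
#' (`fp1 -> Fp1`, `CZ -> Cz`). No regional aliasing (`T7` is *not* renamed
#' to `T3`); labels are otherwise kept verbatim.
#'
#' @param channels character vector.
#' @return normalized character vector.
#' @export
normalizeChannelLabels <- function(channels) {
  canonicalCase(as.character(channels))
}

#' Built-in montages and lobe map
#'
#' `montageChannels` returns the ordered channel list of a supported
#' montage: `"mhrc16"` (16 channels, as in the adolescent dataset) or
#' `"repod19"` (full 19-channel 10-20 set). `defaultMontage` returns the
#' channel-to-lobe map used for lobe-wise analysis: frontal
#' \{Fp1, Fp2, F3, F4, F7, F8, Fz\}, central \{C3, C4, Cz\}, parietal
#' \{P3, P4, Pz\}, temporal \{T3, T4, T5, T6\}, occipital \{O1, O2\}.
#' Midline electrodes are assigned to the lobe of their line (Fz frontal,
#' Cz central, Pz parietal), standard 10-20 anatomy.
#'
#' @param name montage name.
#' @return `montageChannels`: character vector; `defaultMontage`: named
#'   character vector mapping channel label to lobe.
#' @examples
#' defaultMontage()[montageChannels("mhrc16")]
#' @export
montageChannels <- function(name = c("mhrc16", "repod19")) {
  name <- match.arg(name)
  switch(name,
    mhrc16 = c("O1", "O2", "P3", "P4", "Pz", "T5", "T6", "C3", "C4", "Cz",
               "T3", "T4", "F3", "F4", "F7", "F8"),
    repod19 = c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1",
                "O2", "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz"))
}

LOBES <- c("frontal", "central", "parietal", "temporal", "occipital")

#' @rdname montageChannels
#' @export
defaultMontage <- function() {
  c(Fp1 = "frontal", Fp2 = "frontal", F3 = "frontal", F4 = "frontal",
    F7 = "frontal", F8 = "frontal", Fz = "frontal",
    C3 = "central", C4 = "central", Cz = "central",
    P3 = "parietal", P4 = "parietal", Pz = "parietal",
    T3 = "temporal", T4 = "temporal", T5 = "temporal", T6 = "temporal",
    O1 = "occipital", O2 = "occipital")
}

#' Read a channel-to-lobe montage map from YAML or JSON
#'
#' The file must contain a mapping `lobe: [channels]` for a subset of
#' \{frontal, central, parietal, temporal, occipital\}. The result overrides
#' the built-in default map.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return named character vector channel -> lobe.
#' @export
readMontageMap <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(obj), LOBES)
  if (length(bad))
    stop("unknown lobes in montage map: ", paste(bad, collapse = ", "))
  map <- unlist(lapply(names(obj), function(l)
    setNames(rep(l, length(obj[[l]])),
             normalizeChannelLabels(unlist(obj[[l]])))))
  if (anyDuplicated(names(map)))
    stop("montage map assigns a channel to more than one lobe")
  map
}

#' Channels of a lobe
#'
#' Subsets a channel list to the channels belonging to one cortical lobe,
#' preserving the input order. Channels absent from the montage map are an
#' error (never silently dropped).
#'
#' @param channels character vector of channel labels.
#' @param lobe one of `"frontal"`, `"central"`, `"parietal"`, `"temporal"`,
#'   `"occipital"`.
#' @param montage named channel -> lobe map; see [defaultMontage()].
#' @return character vector (possibly empty).
#' @examples
#' lobeChannels(montageChannels("mhrc16"), "frontal")
#' @export
lobeChannels <- function(channels, lobe, montage = defaultMontage()) {
  lobe <- match.arg(lobe, LOBES)
  channels <- normalizeChannelLabels(channels)
  unknown <- setdiff(channels, names(montage))
  if (length(unknown))
    stop("channels not in montage map: ", paste(unknown, collapse = ", "))
  channels[montage[channels] == lobe]
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit) reader/writer.
# Minimal but standard-conforming: ASCII header, one or more fixed-duration
# data records of interleaved little-endian int16 samples.

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x)
  formatC(x, width = -width, flag = " ")
}

#' Write a Recording to an EDF file
#'
#' Samples are quantized to 16 bits over the physical range `physRange`
#' (microvolts); the record duration is 1 s, so `fs` must be a positive
#' integer and any trailing partial second is dropped.
#'
#' @param rec a [Recording-class].
#' @param path output file.
#' @param physRange length-2 physical range in microvolts; all samples must
#'   lie inside it.
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(rec, path, physRange = c(-1000, 1000)) {
  stopifnot(is(rec, "Recording"))
  fs <- samplingRate(rec)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- signalData(rec)
  if (any(x < physRange[1] | x > physRange[2]))
    stop("samples outside the physical range ", physRange[1], "..",
         physRange[2], " uV")
  ns <- nrow(x)
  nrec <- floor(ncol(x) / fs)
  if (nrec < 1) stop("recording shorter than one 1-s EDF record")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(paste("subject", subjectId(rec)), 80),
    padField(paste("label", classLabel(rec)), 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (ns + 1), 8), padField("", 44),
    padField(nrec, 8), padField("1", 8), padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- function(vals, width) for (v in vals) writeChar(padField(v, width),
                                                         con, eos = NULL)
  sig(channelLabels(rec), 16)
  sig(rep("", ns), 80)
  sig(rep("uV", ns), 8)
  sig(rep(format(physRange[1]), ns), 8)
  sig(rep(format(physRange[2]), ns), 8)
  sig(rep("-32768", ns), 8)
  sig(rep("32767", ns), 8)
  sig(rep("", ns), 80)
  sig(rep(fs, ns), 8)
  sig(rep("", ns), 32)

  gain <- (physRange[2] - physRange[1]) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - physRange[1]) / gain) - 32768
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

readHeaderFields <- function(con, n, width) {
  vapply(seq_len(n), function(i)
    sub("\\s+$", "", readChar(con, width)), "")
}

#' Read an EDF file into a Recording
#'
#' All signals must share one sampling rate (mixed rates are rejected).
#' Channel labels are normalized to canonical 10-20 case; subject id and
#' class label default to the file name and `"CONTROL"` unless supplied.
#'
#' @param path EDF file.
#' @param subjectId,label optional metadata overrides.
#' @return a [Recording-class].
#' @export
readEDF <- function(path, subjectId = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readChar(con, 8)
  if (!grepl("^0", version)) stop("malformed EDF: bad version field")
  patient <- sub("\\s+$", "", readChar(con, 80))
  recInfo <- sub("\\s+$", "", readChar(con, 80))
  readChar(con, 16)                       # date + time
  hdrBytes <- suppressWarnings(as.integer(readChar(con, 8)))
  readChar(con, 44)
  nrec <- suppressWarnings(as.integer(readChar(con, 8)))
  dur <- suppressWarnings(as.numeric(readChar(con, 8)))
  ns <- suppressWarnings(as.integer(readChar(con, 4)))
  if (anyNA(c(hdrBytes, nrec, dur, ns)) || ns < 1)
    stop("malformed EDF: bad header counts")
  if (hdrBytes != 256 * (ns + 1)) stop("malformed EDF: header size mismatch")

  labels <- readHeaderFields(con, ns, 16)
  readChar(con, 80 * ns)
  readChar(con, 8 * ns)
  physMin <- as.numeric(readHeaderFields(con, ns, 8))
  physMax <- as.numeric(readHeaderFields(con, ns, 8))
  digMin <- as.numeric(readHeaderFields(con, ns, 8))
  digMax <- as.numeric(readHeaderFields(con, ns, 8))
  readChar(con, 80 * ns)
  spr <- as.integer(readHeaderFields(con, ns, 8))
  readChar(con, 32 * ns)
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("malformed EDF: bad signal headers")
  if (length(unique(spr / dur)) != 1L)
    stop("unsupported input: signals have mixed sampling rates")

  fs <- spr[1] / dur
  data <- matrix(0, ns, nrec * spr[1])
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little")
      if (length(dig) < spr[ch]) stop("malformed EDF: truncated data record")
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - digMin[ch]) * gain[ch] + physMin[ch]
    }
  }
  if (is.null(subjectId)) {
    subjectId <- if (grepl("^subject ", patient)) sub("^subject ", "", patient)
                 else sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  }
  if (is.null(label)) {
    label <- if (grepl("^label SCH$", recInfo)) "SCH" else "CONTROL"
  }
  Recording(data, fs = fs, channels = labels, subjectId = subjectId,
            label = label)
}

# ---------------------------------------------------------------------------
# Delimited-text matrices (one header row of channel labels)

#' Read a delimited-text EEG matrix
#'
#' Expects a numeric matrix with one header row of channel labels, one
#' column per channel (`orientation = "samples_rows"`, default) or one row
#' per channel (`"samples_cols"`, no header in that case unless the first
#' column holds labels).
#'
#' @param path delimited text file.
#' @param fs sampling rate in Hz (the text format carries none).
#' @param channels optional channel labels overriding the header.
#' @param orientation `"samples_rows"` or `"samples_cols"`.
#' @param sep field separator.
#' @param subjectId,label metadata.
#' @return a [Recording-class].
#' @export
readMatrixEEG <- function(path, fs, channels = NULL,
                          orientation = c("samples_rows", "samples_cols"),
                          sep = ",", subjectId = NULL,
                          label = c("CONTROL", "SCH")) {
  orientation <- match.arg(orientation)
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = sep, blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("format error: empty file ", path)
  if (length(unique(nf)) != 1L)
    stop("format error: ragged rows (line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields, expected ", nf[1], ")")
  raw <- read.csv(path, header = (orientation == "samples_rows"), sep = sep,
                  colClasses = "character", check.names = FALSE)
  m <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    line <- bad["row"] + (orientation == "samples_rows")
    stop("format error: non-numeric cell at line ", line,
         ", field ", bad["col"])
  }
  if (orientation == "samples_rows") {
    data <- t(num)
    if (is.null(channels)) channels <- colnames(raw)
  } else {
    data <- num
    if (is.null(channels))
      stop("samples_cols orientation requires explicit channel labels")
  }
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  Recording(data, fs = fs, channels = channels, subjectId = subjectId,
            label = label)
}

#' Write a Recording as delimited text
#'
#' One header row of channel labels, one row per sample (samples-in-rows).
#' Values are written with full precision so a re-read is bitwise equal.
#'
#' @param rec a [Recording-class].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeMatrixEEG <- function(rec, path, sep = ",") {
  x <- t(signalData(rec))
  lines <- c(paste(channelLabels(rec), collapse = sep),
             apply(x, 1, function(r)
               paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = sep)))
  writeLines(lines, path)
  invisible(path)
}
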