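#' Read an ASCII epoch file
#'
#' One epoch stored as samples rows x channels columns, plain numbers,
#' tab-, space- or comma-delimited (auto-detected). A non-numeric first
#' line is treated as a header and skipped. Columns follow montage order.
#'
#' @param path file path.
#' @param montage a [montage()]; the column count must equal the montage
#'   size.
#' @return Channels x samples numeric matrix with montage labels as
#'   rownames.
#' @export
read_ascii_epoch <- function(path, montage = default_montage()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty epoch file: ", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split_line <- function(l) {
    if (sep == ",") trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    else strsplit(trimws(l), "[ \t]+")[[1]]
  }
  first <- suppressWarnings(as.numeric(split_line(lines[[1]])))
  start <- 1L
  if (anyNA(first)) start <- 2L   # header line
  nrows <- length(lines) - start + 1L
  if (nrows < 1) stop("no numeric rows in ", path)
  cells <- lapply(lines[start:length(lines)], split_line)
  ncols <- length(cells[[1]])
  if (ncols != length(montage$labels))
    stop("file has ", ncols, " columns but montage has ",
         length(montage$labels), " channels: ", path)
  m <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    if (length(cells[[r]]) != ncols)
      stop("row ", r + start - 1L, " has ", length(cells[[r]]),
           " cells, expected ", ncols, ": ", path)
    v <- suppressWarnings(as.numeric(cells[[r]]))
    if (anyNA(v))
      stop("non-numeric cell at row ", r + start - 1L, ", column ",
           which(is.na(v))[1], ": ", path)
    m[r, ] <- v
  }
  out <- t(m)
  rownames(out) <- montage$labels
  out
}

#' Write an ASCII epoch file
#'
#' Inverse of [read_ascii_epoch()]: full-precision numbers, samples in
#' rows, channels in columns, so the round trip is bit-identical.
#'
#' @param epoch channels x samples numeric matrix.
#' @param path file path.
#' @param sep delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_ascii_epoch <- function(epoch, path, sep = "\t") {
  m <- t(as.matrix(epoch))
  txt <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Write a synthetic cohort as ASCII epoch files plus manifest
#'
#' Each subject's recording is epoched and every epoch written with
#' [write_ascii_epoch()]. A tab-delimited manifest (`manifest.tsv`) lists
#' subject id, group, seed and the epoch files.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param n_epochs,epoch_length epoching geometry.
#' @return Path of the manifest file, invisibly.
#' @export
write_ascii_cohort <- function(cohort, dir, n_epochs = 6, epoch_length = 4096) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    ep <- make_epochs(s$recording, n_epochs, epoch_length)
    files <- character(n_epochs)
    for (e in seq_len(n_epochs)) {
      f <- file.path(dir, sprintf("%s_epoch%d.txt", s$id, e))
      write_ascii_epoch(ep$epochs[[e]], f)
      files[e] <- basename(f)
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject = s$id, group = s$group, seed = s$seed,
      sampling_rate = s$recording$sampling_rate,
      files = paste(files, collapse = ";"))
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort from an ASCII manifest
#'
#' Reads the manifest written by [write_ascii_cohort()] (columns `subject`,
#' `group`, `sampling_rate`, `files`; paths relative to the manifest) and
#' concatenates each subject's contiguous epochs back into one recording.
#'
#' @param manifest_path path to the manifest TSV.
#' @param montage a [montage()] describing the channel layout.
#' @return An `eeg_cohort`-like list (without generator seeds).
#' @export
read_cohort_ascii <- function(manifest_path, montage = default_montage()) {
  mf <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(mf)), function(i) {
    files <- strsplit(mf$files[i], ";", fixed = TRUE)[[1]]
    eps <- lapply(file.path(base, files), read_ascii_epoch, montage = montage)
    fs <- if ("sampling_rate" %in% names(mf)) mf$sampling_rate[i]
          else montage$sampling_rate
    list(id = mf$subject[i], group = mf$group[i],
         seed = if ("seed" %in% names(mf)) mf$seed[i] else NA_integer_,
         recording = recording(do.call(cbind, eps), fs, montage$labels))
  })
  structure(list(subjects = subjects, groups = unique(mf$group)),
            class = "eeg_cohort")
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, a single data
#' record holding the whole signal, per-channel physical scaling from the
#' signal range.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- rec$signals
  ns <- nrow(sig)
  nsamp <- ncol(sig)
  dmin <- -32768; dmax <- 32767
  phys_min <- apply(sig, 1, min)
  phys_max <- apply(sig, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  dur <- nsamp / rec$sampling_rate
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(1, 8)
  wr(format(dur, digits = 7), 8); wr(ns, 4)
  for (l in rec$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)          # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)          # prefilter
  for (i in seq_len(ns)) wr(nsamp, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    # header fields are parsed back so scaling matches the reader exactly
    pmn <- as.numeric(format(phys_min[i], digits = 7))
    pmx <- as.numeric(format(phys_max[i], digits = 7))
    dig <- round((sig[i, ] - pmn) / (pmx - pmn) * (dmax - dmin) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the header, rejects mixed per-channel sampling rates, and returns
#' physically scaled signals. When a montage is given, its labels are
#' matched case-insensitively and channels reordered accordingly; missing
#' channels are an error listing the absent labels.
#'
#' @param path EDF file path.
#' @param montage optional [montage()] to match against.
#' @return An [recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 256) stop("not a valid EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.numeric(rd(8)); rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates across channels are not supported")
  seek(con, hdr_bytes)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    block <- matrix(NA_real_, ns, spr[1])
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[i]) stop("truncated EDF data: ", path)
      block[i, ] <- (raw - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax[i] - pmin[i]) + pmin[i]
    }
    chunks[[r]] <- block
  }
  sig <- do.call(cbind, chunks)
  fs <- spr[1] / rec_dur
  if (!is.null(montage)) {
    pos <- match(tolower(montage$labels), tolower(labels))
    if (anyNA(pos))
      stop("montage channel(s) absent from EDF: ",
           paste(montage$labels[is.na(pos)], collapse = ", "))
    sig <- sig[pos, , drop = FALSE]
    labels <- montage$labels
  }
  recording(sig, fs, labels)
}

#' Write pipeline results as delimited tables
#'
#' Writes `subject_metrics.tsv` (per-subject, per-band connectivity and
#' graph measures) and `group_stats.tsv` (band, measure, t, df, p, eta_p2)
#' at full precision. Empty inputs produce headers-only files.
#'
#' @param results a `pipeline_result` from [run_pipeline()], or a list with
#'   elements `subject_metrics` and `group_stats`.
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    df
  }
  p1 <- file.path(dir, "subject_metrics.tsv")
  p2 <- file.path(dir, "group_stats.tsv")
  utils::write.table(fmt(results$subject_metrics), p1, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(results$group_stats), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(results$correlations)) {
    p3 <- file.path(dir, "pli_power_correlations.tsv")
    utils::write.table(fmt(results$correlations), p3, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
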