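# Dataset plumbing: rhythm-pure windowing of long annotated records,
# 8:1:1 splitting, CinC-2017-style directory loading, and the two
# on-disk dataset dialects (per-segment CSV directory; single-file
# container) written by the simulator and read back here.
#
# Coordinate convention everywhere: 0-based, half-open [start, end)
# sample intervals.

#' Rhythm interval table
#'
#' Validates and normalizes a set of rhythm intervals for one record:
#' 0-based half-open `[start, end)` sample intervals, non-overlapping and
#' ordered, each carrying a rhythm label (e.g. `"AFIB"`, `"N"`, `"AFL"`).
#'
#' @param start,end Integer sample indices, `start < end`.
#' @param rhythm Character rhythm labels.
#' @return A `data.frame` with columns `start`, `end`, `rhythm`.
#' @export
rhythm_intervals <- function(start, end, rhythm) {
  stopifnot(length(start) == length(end),
            length(start) == length(rhythm))
  iv <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   rhythm = as.character(rhythm),
                   stringsAsFactors = FALSE)
  iv <- iv[order(iv$start), , drop = FALSE]
  if (any(iv$start >= iv$end))
    stop("every interval needs start < end", call. = FALSE)
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop("rhythm intervals overlap", call. = FALSE)
  rownames(iv) <- NULL
  iv
}

#' Window a long record into rhythm-pure fixed-length segments
#'
#' Cuts non-overlapping consecutive windows of `window_s` seconds. A
#' window is emitted only if it lies entirely inside a single rhythm
#' interval; windows restart at each interval boundary, so an interval of
#' `L` samples yields exactly `floor(L / (window_s * fs))` windows and no
#' window ever straddles a rhythm change. The binary label is `"af"` iff
#' the enclosing interval's rhythm is in `af_labels`, else `"non_af"`.
#'
#' @param signal Numeric vector (single lead) or matrix with leads in
#'   columns, in which case `lead` selects one.
#' @param fs Sampling rate, Hz (> 0).
#' @param intervals A [rhythm_intervals()] table.
#' @param window_s Window length in seconds (> 0).
#' @param af_labels Rhythm labels counted as AF (default `"AFIB"`:
#'   flutter and junctional rhythms are non-AF).
#' @param lead Lead column when `signal` is a matrix (default 1).
#' @return List of `ecg_segment` objects with labels `"af"` / `"non_af"`.
#' @export
window_record <- function(signal, fs, intervals, window_s = 10,
                          af_labels = "AFIB", lead = 1L) {
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  if (is.matrix(signal)) signal <- signal[, lead]
  wlen <- round(window_s * fs)
  out <- list()
  for (r in seq_len(nrow(intervals))) {
    iv <- intervals[r, ]
    L <- min(iv$end, length(signal)) - iv$start
    if (L < wlen) next
    nwin <- floor(L / wlen)
    lab <- if (iv$rhythm %in% af_labels) "af" else "non_af"
    for (w in seq_len(nwin)) {
      s0 <- iv$start + (w - 1L) * wlen       # 0-based
      out[[length(out) + 1L]] <-
        new_ecg_segment(signal[(s0 + 1L):(s0 + wlen)], fs, lab, window_s)
    }
  }
  structure(out, class = c("ecg_dataset", "list"))
}

largest_remainder <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Split indices 8:1:1 into train / validation / test
#'
#' Random permutation under `seed`; sizes follow the 8:1:1 ratio with
#' largest-remainder rounding. With `stratify_labels`, the ratio holds
#' within every class (to within one element).
#'
#' @param n Number of items (>= 10, so all three parts are nonempty).
#' @param seed Integer seed.
#' @param stratify_labels Optional length-`n` label vector.
#' @return List with integer index vectors `train`, `val`, `test` and the
#'   `seed`; the three sets partition `1:n`.
#' @export
split_811 <- function(n, seed = 1L, stratify_labels = NULL) {
  if (n < 10)
    stop("`n` must be >= 10 to realize three nonempty 8:1:1 parts",
         call. = FALSE)
  props <- c(0.8, 0.1, 0.1)
  assign_one <- function(idx) {
    sizes <- largest_remainder(length(idx), props)
    perm <- with_seed(derive_seed(seed, length(idx) + idx[1]),
                      sample(idx, length(idx)))
    list(train = perm[seq_len(sizes[1])],
         val = perm[sizes[1] + seq_len(sizes[2])],
         test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  if (is.null(stratify_labels)) {
    parts <- assign_one(seq_len(n))
  } else {
    stopifnot(length(stratify_labels) == n)
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in unique(stratify_labels)) {
      p <- assign_one(which(stratify_labels == cl))
      parts$train <- c(parts$train, p$train)
      parts$val <- c(parts$val, p$val)
      parts$test <- c(parts$test, p$test)
    }
  }
  list(train = sort(parts$train), val = sort(parts$val),
       test = sort(parts$test), seed = as.integer(seed))
}

#' Load a directory of CinC-2017-style records
#'
#' Expects single-lead records as per-segment CSV files (see
#' [write_dataset_csv()] for the dialect) plus a label table
#' `labels.csv` with columns `record_id,label` mapping file stem to one of
#' Normal / AF / Other / Noise (case-insensitive). Records without a label
#' row, and label rows without a record, are returned in `errors` rather
#' than silently dropped; durations outside \[9, 30\] s are kept with a
#' warning.
#'
#' @param path Directory containing record CSVs and `labels.csv`.
#' @param fs Expected sampling rate (default 300 Hz).
#' @return List with `segments` (an `ecg_dataset`) and `errors`
#'   (character vector of mismatch messages, empty if clean).
#' @export
load_cinc_style <- function(path, fs = 300) {
  lab_file <- file.path(path, "labels.csv")
  if (!file.exists(lab_file))
    stop("no labels.csv found in ", path, call. = FALSE)
  labs <- read.csv(lab_file, stringsAsFactors = FALSE)
  if (!all(c("record_id", "label") %in% names(labs)))
    stop("labels.csv must have columns record_id,label", call. = FALSE)
  files <- list.files(path, pattern = "\\.csv$", full.names = FALSE)
  files <- setdiff(files, "labels.csv")
  ids <- sub("\\.csv$", "", files)
  errors <- character(0)
  for (missing in setdiff(labs$record_id, ids))
    errors <- c(errors, sprintf("label row '%s' has no record file",
                                missing))
  segs <- list()
  for (i in seq_along(ids)) {
    row <- match(ids[i], labs$record_id)
    if (is.na(row)) {
      errors <- c(errors, sprintf("record '%s' has no label row", ids[i]))
      next
    }
    seg <- read_segment_csv(file.path(path, files[i]))
    seg$label <- tolower(labs$label[row])
    if (seg$duration < 9 || seg$duration > 30)
      warning(sprintf("record '%s' duration %.1f s outside [9, 30] s",
                      ids[i], seg$duration), call. = FALSE)
    segs[[length(segs) + 1L]] <- seg
  }
  list(segments = structure(segs, class = c("ecg_dataset", "list")),
       errors = errors)
}

# --- dataset serialization --------------------------------------------------

#' Write / read a dataset as a directory of per-segment CSV files
#'
#' One CSV per segment: comment header lines `# fs:`, `# label:`,
#' `# duration:` followed by a single `mv` column, one sample per row.
#'
#' @param dataset An `ecg_dataset` (list of `ecg_segment`).
#' @param path Directory (created if needed).
#' @param digits Significant digits written (default 6).
#' @return `read_dataset_csv()` returns an `ecg_dataset`.
#' @export
write_dataset_csv <- function(dataset, path, digits = 6) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset)) {
    seg <- dataset[[i]]
    f <- file.path(path, sprintf("seg%05d.csv", i))
    con <- file(f, "w")
    writeLines(c(sprintf("# fs: %g", seg$fs),
                 sprintf("# label: %s", seg$label),
                 sprintf("# duration: %g", seg$duration),
                 "mv"), con)
    writeLines(formatC(seg$samples, digits = digits, format = "g"), con)
    close(con)
  }
  invisible(path)
}

read_segment_csv <- function(file) {
  hdr <- readLines(file, n = 10)
  meta <- function(key, default = NA) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  fs <- as.numeric(meta("fs"))
  label <- meta("label", "unknown")
  x <- utils::read.csv(file, comment.char = "#")$mv
  dur <- as.numeric(meta("duration", length(x) / fs))
  new_ecg_segment(x, fs, label, dur)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  files <- sort(list.files(path, pattern = "^seg[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no segment CSVs in ", path, call. = FALSE)
  structure(lapply(files, read_segment_csv),
            class = c("ecg_dataset", "list"))
}

#' Write / read a dataset as a single container file
#'
#' Single-file dialect holding parallel `signals` / `labels` / `fs` /
#' `durations` components (serialized R container; a compact alternative
#' to the CSV directory for large runs).
#'
#' @param dataset An `ecg_dataset`.
#' @param file File path.
#' @return `read_dataset_container()` returns an `ecg_dataset`.
#' @export
write_dataset_container <- function(dataset, file) {
  saveRDS(list(signals = lapply(dataset, `[[`, "samples"),
               labels = vapply(dataset, `[[`, character(1), "label"),
               fs = vapply(dataset, `[[`, numeric(1), "fs"),
               durations = vapply(dataset, `[[`, numeric(1), "duration")),
          file)
  invisible(file)
}

#' @rdname write_dataset_container
#' @export
read_dataset_container <- function(file) {
  x <- readRDS(file)
  structure(Map(new_ecg_segment, x$signals, x$fs, x$labels, x$durations),
            class = c("ecg_dataset", "list"))
}

dataset_labels <- function(dataset)
  vapply(dataset, `[[`, character(1), "label")
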