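# Windowing arithmetic and purity, 8:1:1 splitting, dataset dialects,
# CinC-style loading, WFDB round-trips.

test_that("windowing yields floor(L/window) rhythm-pure segments", {
  fs <- 250
  sig <- rnorm(25 * fs)
  iv <- rhythm_intervals(0, 25 * fs, "AFIB")
  segs <- window_record(sig, fs, iv, window_s = 10)
  expect_length(segs, 2)                       # floor(25/10)
  expect_true(all(vapply(segs, `[[`, "", "label") == "af"))
  # 9-s interval is too short for a 10-s window
  expect_length(window_record(rnorm(9 * fs), fs,
                              rhythm_intervals(0, 9 * fs, "AFIB"), 10), 0)
})

test_that("windows restart at rhythm boundaries and never straddle them", {
  fs <- 250
  sig <- seq_len(8000) / 1000                  # recognizable values
  iv <- rhythm_intervals(c(0, 3000), c(3000, 8000), c("N", "AFIB"))
  segs <- window_record(sig, fs, iv, window_s = 10)
  expect_length(segs, 3)                       # floor(3000/2500) + floor(5000/2500)
  expect_identical(vapply(segs, `[[`, "", "label"),
                   c("non_af", "af", "af"))
  # purity by post-hoc scan: recover each window's sample range from the
  # recognizable values and check it sits inside one interval
  for (s in segs) {
    first <- round(s$samples[1] * 1000)        # 1-based index into sig
    rng0 <- c(first - 1, first - 1 + length(s$samples))  # 0-based [a, b)
    inside <- any(iv$start <= rng0[1] & rng0[2] <= iv$end)
    expect_true(inside)
  }
  # count conservation across random interval layouts
  set.seed(31)
  for (rep in 1:10) {
    cuts <- sort(sample(1000:19000, 3))
    iv2 <- rhythm_intervals(c(0, cuts), c(cuts, 20000),
                            sample(c("N", "AFIB", "AFL", "J"), 4,
                                   replace = TRUE))
    segs2 <- window_record(rnorm(20000), fs, iv2, window_s = 4)
    expected <- sum(floor((iv2$end - iv2$start) / (4 * fs)))
    expect_length(segs2, expected)
  }
})

test_that("flutter and junctional rhythms map to non-AF by default", {
  fs <- 250
  iv <- rhythm_intervals(c(0, 2500, 5000), c(2500, 5000, 7500),
                         c("AFL", "J", "AFIB"))
  segs <- window_record(rnorm(7500), fs, iv, window_s = 10)
  expect_identical(vapply(segs, `[[`, "", "label"),
                   c("non_af", "non_af", "af"))
})

test_that("8:1:1 split partitions exactly with largest-remainder sizes", {
  sp <- split_811(10, seed = 1)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 8L, val = 1L, test = 1L))
  sp2 <- split_811(100, seed = 2)
  expect_identical(lengths(sp2[c("train", "val", "test")]),
                   c(train = 80L, val = 10L, test = 10L))
  expect_identical(sort(c(sp2$train, sp2$val, sp2$test)), 1:100)
  expect_identical(split_811(57, seed = 5), split_811(57, seed = 5))
  expect_false(identical(split_811(57, seed = 5), split_811(57, seed = 6)))
  expect_error(split_811(9), ">= 10")
})

test_that("stratified splits hold the ratio within each class", {
  labels <- rep(c("a", "b"), c(60, 40))
  sp <- split_811(100, seed = 3, stratify_labels = labels)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:100)
  for (cl in c("a", "b")) {
    idx <- which(labels == cl)
    n_cl <- length(idx)
    expect_identical(length(intersect(sp$train, idx)),
                     as.integer(0.8 * n_cl))
    expect_identical(length(intersect(sp$val, idx)),
                     as.integer(0.1 * n_cl))
    expect_identical(length(intersect(sp$test, idx)),
                     as.integer(0.1 * n_cl))
  }
})

test_that("both dataset dialects round-trip", {
  ds <- tiny_segments(3, c("normal", "af"), seed = 8, duration = 2)
  d <- file.path(tempdir(), "csvds")
  write_dataset_csv(ds, d)
  back <- read_dataset_csv(d)
  expect_length(back, 6)
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(ds, `[[`, "", "label"))
  expect_equal(back[[1]]$samples, ds[[1]]$samples, tolerance = 1e-4)
  expect_identical(back[[1]]$fs, 250)
  f <- tempfile(fileext = ".rds")
  write_dataset_container(ds, f)
  back2 <- read_dataset_container(f)
  expect_identical(back2[[4]]$samples, ds[[4]]$samples)
  expect_identical(vapply(back2, `[[`, 0, "duration"),
                   vapply(ds, `[[`, 0, "duration"))
})

test_that("CinC-style loading preserves labels and reports mismatches", {
  dir <- file.path(tempdir(), "cinc")
  unlink(dir, recursive = TRUE)
  ds <- make_dataset(2, c("normal", "af", "other", "noise"), fs = 300,
                     duration_policy = c(9, 30), seed = 4)
  write_dataset_csv(ds, dir)
  ids <- sub("\\.csv$", "", list.files(dir, pattern = "^seg"))
  labs <- data.frame(record_id = ids,
                     label = vapply(ds, `[[`, "", "label"))
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  got <- load_cinc_style(dir)
  expect_length(got$segments, 8)
  expect_length(got$errors, 0)
  expect_setequal(unique(vapply(got$segments, `[[`, "", "label")),
                  c("normal", "af", "other", "noise"))
  # unlabeled record and orphan label row are both reported
  write.csv(labs[-1, ], file.path(dir, "labels.csv"), row.names = FALSE)
  got2 <- load_cinc_style(dir)
  expect_length(got2$segments, 7)
  expect_match(got2$errors, "no label row", all = FALSE)
  labs2 <- rbind(labs, data.frame(record_id = "ghost", label = "af"))
  write.csv(labs2, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_match(load_cinc_style(dir)$errors, "no record file", all = FALSE)
  # out-of-range duration: kept, with a warning
  short <- make_dataset(1, "normal", fs = 300, duration_policy = 5,
                        seed = 6)
  write_dataset_csv(short, dir)   # overwrites seg00001.csv
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_warning(got3 <- load_cinc_style(dir), "outside \\[9, 30\\]")
  expect_length(got3$segments, 8)
})

test_that("WFDB records round-trip through write and read", {
  rec <- file.path(tempdir(), "wf01")
  fs <- 250
  sig <- synthesize_segment(rhythm_params("normal"), fs, 20, 3)$samples
  rhy <- data.frame(sample = c(0, 1500, 3700),
                    rhythm = c("N", "AFIB", "N"))
  write_wfdb_record(rec, sig, fs, rhy)
  got <- read_wfdb_record(rec)
  expect_identical(got$fs, fs)
  expect_identical(nrow(got$signal), length(sig))
  expect_lt(max(abs(got$signal[, 1] - sig)), 1 / 200 + 1e-9)  # ADC quantization
  expect_identical(got$intervals$start, c(0, 1500, 3700))
  expect_identical(got$intervals$end, c(1500, 3700, length(sig)))
  expect_identical(got$intervals$rhythm, c("N", "AFIB", "N"))
})

test_that("annotation edge cases: single opening annotation, long gaps", {
  rec <- file.path(tempdir(), "wf02")
  write_wfdb_record(rec, rnorm(3000) / 10, 250,
                    data.frame(sample = 0, rhythm = "AFIB"))
  got <- read_wfdb_record(rec)
  expect_identical(nrow(got$intervals), 1L)
  expect_identical(got$intervals$start, 0)
  expect_identical(got$intervals$end, 3000)
  # two annotations with a gap beyond the 10-bit delta limit (SKIP path)
  rec2 <- file.path(tempdir(), "wf03")
  write_wfdb_record(rec2, rnorm(300000) / 10, 250,
                    data.frame(sample = c(0, 150000),
                               rhythm = c("N", "AFIB")))
  got2 <- read_wfdb_record(rec2)
  expect_identical(got2$intervals$start, c(0, 150000))
  expect_identical(got2$intervals$end, c(150000, 300000))
  expect_identical(got2$intervals$rhythm, c("N", "AFIB"))
})

test_that("missing files give distinct record / annotation errors", {
  expect_error(read_wfdb_record(file.path(tempdir(), "nothere")),
               "no record")
  rec <- file.path(tempdir(), "wf04")
  write_wfdb_record(rec, rnorm(500) / 10, 250,
                    data.frame(sample = 0, rhythm = "N"))
  file.remove(paste0(rec, ".atr"))
  expect_error(read_wfdb_record(rec), "no rhythm labels")
})

test_that("multi-lead records keep all leads and windowing can select one", {
  rec <- file.path(tempdir(), "wf05")
  sig <- cbind(rnorm(5000) / 10, rnorm(5000) / 10)
  write_wfdb_record(rec, sig, 250, data.frame(sample = 0, rhythm = "AFIB"))
  got <- read_wfdb_record(rec)
  expect_identical(ncol(got$signal), 2L)
  segs <- window_record(got$signal, got$fs, got$intervals, window_s = 10,
                        lead = 2L)
  expect_length(segs, 2)
})
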