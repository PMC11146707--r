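# Synthetic ECG generator: rhythm statistics, beat morphology, spectral
# content, determinism, and dataset bookkeeping.

test_that("rhythm parameter constraints encode the AF phenomenology", {
  expect_error(rhythm_params("normal", rr_cv = 0.2), "rr_cv")
  expect_error(rhythm_params("normal", p_wave_amplitude = 0), "P-wave")
  expect_error(rhythm_params("af", rr_cv = 0.1), "rr_cv")
  expect_error(rhythm_params("af", f_wave_amplitude = 0), "f-wave")
  expect_error(rhythm_params("af", f_wave_freq = 12), "4, 10")
  p <- rhythm_params("af")
  expect_identical(p$p_wave_amplitude, 0)
  expect_gt(p$f_wave_amplitude, 0)
})

test_that("simulated RR intervals have the class-defining statistics", {
  # sinus: ~13 intervals cover 10 s at mean 0.8 s, low dispersion
  counts <- integer(200); cvs <- numeric(200)
  pn <- rhythm_params("normal")
  for (i in 1:200) {
    rr <- simulate_rr(pn, 10, seed = i)
    counts[i] <- length(rr)
    cvs[i] <- sd(rr) / mean(rr)
  }
  expect_true(all(counts >= 12 & counts <= 14))
  expect_true(median(counts) == 13)
  expect_true(all(cvs <= 0.08 * 1.8))      # small-sample slack on CV
  # AF: high dispersion
  cva <- vapply(1:200, function(i) {
    rr <- simulate_rr(rhythm_params("af"), 10, seed = i)
    sd(rr) / mean(rr)
  }, numeric(1))
  expect_gt(mean(cva >= 0.15), 0.95)
  # long-run empirical CV within 20% of the requested value
  rr60 <- simulate_rr(rhythm_params("af"), 120, seed = 3)
  expect_lt(abs(sd(rr60) / mean(rr60) - 0.25) / 0.25, 0.2)
  rr60n <- simulate_rr(pn, 120, seed = 3)
  expect_lt(abs(sd(rr60n) / mean(rr60n) - 0.05) / 0.05, 0.2)
})

test_that("RR simulation covers the duration and validates inputs", {
  rr <- simulate_rr(rhythm_params("normal"), 0.8, seed = 1)
  expect_true(length(rr) %in% 1:2)
  expect_gte(sum(rr), 0.8)
  expect_error(simulate_rr(rhythm_params("normal", mean_rr = 0.1), 10),
               "nonphysiological")
  expect_error(simulate_rr(rhythm_params("normal"), 0), "duration")
})

test_that("beat template has the P-QRS-T morphology", {
  tpl <- beat_template(250)
  ext <- find_extrema(as.numeric(tpl), floor = 0.05)
  expect_length(ext$index, 5)
  expect_identical(sign(ext$value), c(1, -1, 1, -1, 1))  # P Q R S T
  expect_identical(which.max(tpl), which.max(abs(tpl)))  # R is global max
  # no P: nothing positive in the 120-200 ms pre-R window
  tp0 <- beat_template(250, include_p = FALSE)
  tt <- attr(tp0, "t")
  win <- tt >= -0.2 & tt <= -0.12
  expect_true(all(tp0[win] < 0.05))
  expect_error(beat_template(50), "100")
})

test_that("templates at 250 and 300 Hz agree after resampling", {
  t300 <- beat_template(300)
  t250 <- beat_template(250)
  interp <- spline(attr(t300, "t"), as.numeric(t300),
                   xout = attr(t250, "t"))$y
  expect_lt(sqrt(mean((interp - as.numeric(t250))^2)), 1e-3)
})

test_that("synthesized segments are deterministic, finite and bounded", {
  s1 <- synthesize_segment(rhythm_params("af"), 250, 10, seed = 42)
  s2 <- synthesize_segment(rhythm_params("af"), 250, 10, seed = 42)
  expect_identical(s1$samples, s2$samples)
  s3 <- synthesize_segment(rhythm_params("af"), 250, 10, seed = 43)
  expect_false(identical(s1$samples, s3$samples))
  expect_length(s1$samples, 2500)
  expect_true(all(is.finite(s1$samples)))
  expect_true(all(abs(s1$samples) <= 5))
  expect_error(synthesize_segment(rhythm_params("af"), 250, 0.5), "1, 120")
})

test_that("AF segments carry excess 4-10 Hz power once QRS energy is masked", {
  band_power <- function(seg) {
    x <- seg$samples
    for (p in detect_r_peaks(x, seg$fs)) {
      i <- max(1, p - 0.1 * seg$fs):min(length(x), p + 0.15 * seg$fs)
      x[i] <- 0
    }
    sp <- stats::spec.pgram(stats::ts(x, frequency = seg$fs), spans = 11,
                            plot = FALSE, taper = 0)
    sum(sp$spec[sp$freq >= 4 & sp$freq <= 10])
  }
  pa <- vapply(1:10, function(i) band_power(
    synthesize_segment(rhythm_params("af"), 250, 10, i)), numeric(1))
  pn <- vapply(1:10, function(i) band_power(
    synthesize_segment(rhythm_params("normal"), 250, 10, i)), numeric(1))
  expect_gt(min(pa), max(pn))
})

test_that("the noise class has no plausible beat structure", {
  peaks <- vapply(1:20, function(i) length(detect_r_peaks(
    synthesize_segment(rhythm_params("noise"), 250, 10, i)$samples, 250)),
    integer(1))
  expect_true(all(peaks < 2))
  # while rhythm classes yield a physiological beat count
  expect_gt(length(detect_r_peaks(
    synthesize_segment(rhythm_params("normal"), 250, 10, 1)$samples,
    250)), 8)
})

test_that("datasets are balanced, bounded and seed-deterministic", {
  ds <- make_dataset(5, c("af", "normal"), fs = 250,
                     duration_policy = 10, seed = 1)
  expect_length(ds, 10)
  expect_true(all(vapply(ds, function(s) length(s$samples), 0L) == 2500))
  labs <- table(vapply(ds, `[[`, "", "label"))
  expect_equal(unname(labs[c("af", "normal")]), c(5L, 5L),
               ignore_attr = TRUE)
  dsv <- make_dataset(4, c("normal", "af", "other", "noise"), fs = 300,
                      duration_policy = c(9, 30), seed = 2)
  durs <- vapply(dsv, `[[`, 0, "duration")
  expect_true(all(durs >= 9 & durs <= 30))
  expect_true(all(vapply(dsv, function(s)
    length(s$samples) == round(300 * s$duration), TRUE)))
  expect_identical(
    make_dataset(3, c("af"), 250, 10, seed = 9)[[2]]$samples,
    make_dataset(3, c("af"), 250, 10, seed = 9)[[2]]$samples)
  expect_false(identical(
    make_dataset(3, c("af"), 250, 10, seed = 9)[[2]]$samples,
    make_dataset(3, c("af"), 250, 10, seed = 10)[[2]]$samples))
  expect_error(make_dataset(2, c("af", "ventricular")), "unknown class")
})

test_that("an RR-CV threshold separates synthetic AF from sinus rhythm", {
  ds <- sanity_dataset()[1:300]
  cv <- vapply(ds, segment_rr_cv, numeric(1))
  lab <- vapply(ds, `[[`, "", "label")
  pred <- ifelse(!is.na(cv) & cv >= 0.12, "af", "normal")
  expect_gte(mean(pred == lab), 0.95)
})
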