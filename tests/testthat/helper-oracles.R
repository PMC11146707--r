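# Shared oracles and fixture builders. Everything is generated in code;
# nothing is read from disk except files the tests themselves write to
# tempdirs.

# Brute-force receptive field: build the block as a linear unit (no
# normalization or rectifier, causal padding, no shortcut), perturb each
# input cell in turn, and count how many cells influence the last output
# position. Independent of the analyzer's tap-union arithmetic.
rf_perturbation_oracle <- function(block, seed = 42) {
  span <- max(vapply(block$branches, function(b)
    (b$kernel_size - 1L) * max(b$dilation_factor, 1L), integer(1)))
  L <- span + 8L
  unit <- build_block(block, in_channels = 1L, seed = seed,
                      padding = "causal", norm = FALSE,
                      activation = "linear", skip = FALSE)
  base <- array(0, c(L, 1L, 1L))
  y0 <- unit_forward(unit, base)$y[L, , 1]
  influenced <- 0L
  for (i in seq_len(L)) {
    xp <- base
    xp[i, 1, 1] <- 1
    y1 <- unit_forward(unit, xp)$y[L, , 1]
    if (any(abs(y1 - y0) > 1e-12)) influenced <- influenced + 1L
  }
  influenced
}

random_block_spec <- function(seed) {
  afmsdc:::with_seed(seed, {
    n_br <- sample(1:3, 1)
    branches <- lapply(seq_len(n_br), function(j)
      conv_branch(kernel_size = sample(1:8, 1), stride = 1L,
                  dilation_factor = sample(0:7, 1),
                  filters = sample(c(2L, 4L, 8L), 1)))
    block_spec(sprintf("random_%d", seed), branches, skip = FALSE)
  })
}

# Strict local extrema of a sampled waveform, robust to flat-topped peaks
# (plateaus count once); values below `floor` are ignored.
find_extrema <- function(y, floor = 0.05) {
  r <- rle(sign(diff(y)))
  nz <- r$values != 0                      # flat runs merge into neighbors
  vals <- r$values[nz]
  ends <- cumsum(r$lengths)[nz]
  ext <- integer(0)
  for (i in seq_len(max(length(vals) - 1, 0)))
    if (vals[i] != vals[i + 1]) ext <- c(ext, ends[i] + 1L)
  ext <- ext[abs(y[ext]) > floor]
  list(index = ext, value = y[ext])
}

# Cached balanced AF/normal dataset shared by the heavier tests.
sanity_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dataset(450, c("normal", "af"), fs = 250,
                             duration_policy = 10, seed = 20240603)
    cache
  }
})

tiny_segments <- function(n, classes = c("normal", "af"), seed = 1,
                          duration = 2, fs = 250) {
  make_dataset(n, classes, fs = fs, duration_policy = duration,
               seed = seed)
}
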