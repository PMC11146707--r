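# Block and network construction on top of the layer primitives.
#
# A built unit keeps its trainable parameters in a flat named list so the
# optimizer and the parameter-count introspection can treat every model the
# same way. Naming scheme:
#   stem_W                          stem convolution (no bias, BN follows)
#   b<i>_bn_gamma / b<i>_bn_beta    pre-activation batchnorm of block i
#   b<i>_br<j>_W / b<i>_br<j>_b     branch j convolution of block i
#   b<i>_proj_W                     pointwise shortcut projection (no bias)
#   top_bn_gamma / top_bn_beta      final batchnorm before pooling
#   head_W / head_b                 linear classification head
# Batchnorm running statistics live in `state`, not `params`.

cat_channels <- function(ys) {
  d1 <- dim(ys[[1]])
  Cs <- vapply(ys, function(y) dim(y)[2], integer(1))
  out <- array(0, c(d1[1], sum(Cs), d1[3]))
  off <- 0L
  for (y in ys) {
    out[, off + seq_len(dim(y)[2]), ] <- y
    off <- off + dim(y)[2]
  }
  out
}

split_channels <- function(dy, Cs) {
  off <- 0L
  lapply(Cs, function(C) {
    s <- dy[, off + seq_len(C), , drop = FALSE]
    off <<- off + C
    s
  })
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims)) * sqrt(2 / fan_in), dim = dims)
}

block_config <- function(block, in_channels, stride = 1L, padding = "same",
                         norm = TRUE, activation = c("relu", "linear"),
                         skip = block$skip, prefix = "b1_") {
  activation <- match.arg(activation)
  out_channels <- block_out_channels(block)
  identity_skip <- skip && stride == 1L && in_channels == out_channels
  list(block = block, in_channels = as.integer(in_channels),
       out_channels = out_channels, stride = as.integer(stride),
       padding = padding, norm = norm, activation = activation,
       skip = skip, identity_skip = identity_skip, prefix = prefix)
}

block_init <- function(cfg) {
  p <- cfg$prefix
  params <- list(); state <- list()
  if (cfg$norm) {
    params[[paste0(p, "bn_gamma")]] <- rep(1, cfg$in_channels)
    params[[paste0(p, "bn_beta")]] <- rep(0, cfg$in_channels)
    state[[paste0(p, "bn_mean")]] <- rep(0, cfg$in_channels)
    state[[paste0(p, "bn_var")]] <- rep(1, cfg$in_channels)
  }
  for (j in seq_along(cfg$block$branches)) {
    br <- cfg$block$branches[[j]]
    params[[sprintf("%sbr%d_W", p, j)]] <-
      he_init(c(br$kernel_size, cfg$in_channels, br$filters),
              br$kernel_size * cfg$in_channels)
    params[[sprintf("%sbr%d_b", p, j)]] <- rep(0, br$filters)
  }
  if (cfg$skip && !cfg$identity_skip) {
    params[[paste0(p, "proj_W")]] <-
      he_init(c(1L, cfg$in_channels, cfg$out_channels), cfg$in_channels)
  }
  list(params = params, state = state)
}

block_forward <- function(cfg, params, state, x, training = FALSE) {
  p <- cfg$prefix
  cache <- list()
  h <- x
  if (cfg$norm) {
    bn <- bn_forward(h, params[[paste0(p, "bn_gamma")]],
                     params[[paste0(p, "bn_beta")]],
                     state[[paste0(p, "bn_mean")]],
                     state[[paste0(p, "bn_var")]], training)
    h <- bn$y
    cache$bn <- bn$cache
    state[[paste0(p, "bn_mean")]] <- bn$rmean
    state[[paste0(p, "bn_var")]] <- bn$rvar
  }
  if (cfg$activation == "relu") {
    r <- relu_forward(h)
    h <- r$y
    cache$relu <- r$cache
  }
  ys <- vector("list", length(cfg$block$branches))
  cache$branches <- vector("list", length(cfg$block$branches))
  for (j in seq_along(cfg$block$branches)) {
    br <- cfg$block$branches[[j]]
    cv <- conv1d_forward(h, params[[sprintf("%sbr%d_W", p, j)]],
                         params[[sprintf("%sbr%d_b", p, j)]],
                         stride = cfg$stride,
                         dilation = effective_dilation(br),
                         padding = cfg$padding)
    ys[[j]] <- cv$y
    cache$branches[[j]] <- cv$cache
  }
  y <- cat_channels(ys)
  if (cfg$skip) {
    if (cfg$identity_skip) {
      y <- y + x
    } else {
      pj <- conv1d_forward(x, params[[paste0(p, "proj_W")]], NULL,
                           stride = cfg$stride, dilation = 1L,
                           padding = cfg$padding)
      y <- y + pj$y
      cache$proj <- pj$cache
    }
  }
  list(y = y, cache = cache, state = state)
}

block_backward <- function(cfg, cache, dy) {
  p <- cfg$prefix
  grads <- list()
  Cs <- vapply(cfg$block$branches, function(b) b$filters, integer(1))
  dys <- split_channels(dy, Cs)
  dh <- NULL
  for (j in seq_along(cfg$block$branches)) {
    g <- conv1d_backward(cache$branches[[j]], dys[[j]])
    grads[[sprintf("%sbr%d_W", p, j)]] <- g$dw
    grads[[sprintf("%sbr%d_b", p, j)]] <- g$db
    dh <- if (is.null(dh)) g$dx else dh + g$dx
  }
  if (cfg$activation == "relu") dh <- relu_backward(cache$relu, dh)
  if (cfg$norm) {
    bg <- bn_backward(cache$bn, dh)
    grads[[paste0(p, "bn_gamma")]] <- bg$dgamma
    grads[[paste0(p, "bn_beta")]] <- bg$dbeta
    dx <- bg$dx
  } else dx <- dh
  if (cfg$skip) {
    if (cfg$identity_skip) {
      dx <- dx + dy
    } else {
      g <- conv1d_backward(cache$proj, dy)
      grads[[paste0(p, "proj_W")]] <- g$dw
      dx <- dx + g$dx
    }
  }
  list(dx = dx, grads = grads)
}

#' Build a single MSDC / residual computation block
#'
#' Instantiates one block as a runnable unit mapping an input array of shape
#' `(length, in_channels, batch)` to `(length', sum of branch filters,
#' batch)`. Branch outputs are concatenated on the channel axis; the
#' optional shortcut adds the input, through a pointwise projection when
#' channel counts or temporal lengths differ. The block is pre-activation:
#' a shared batch normalization and rectifier are applied to the block
#' input before the parallel branch convolutions.
#'
#' @param block A [block_spec()].
#' @param in_channels Input channel count.
#' @param seed Integer seed for weight initialization.
#' @param stride Temporal stride applied by every branch (and the
#'   projection), default 1.
#' @param padding `"same"` (default), `"causal"` (all padding on the left),
#'   or `"valid"` (no padding; errors if the input is shorter than the
#'   largest branch span).
#' @param norm,activation Set `norm = FALSE` / `activation = "linear"` to
#'   strip the nonlinearities, e.g. for linear-response analyses.
#' @param skip Keep the shortcut connection (default: the spec's setting).
#' @return An object of class `msdc_unit` with elements `params` (named
#'   list of trainable arrays), `state`, and the block configuration.
#' @examples
#' u <- build_block(msdc_block("msdc_a"), in_channels = 32, seed = 1)
#' y <- unit_forward(u, array(0, c(100, 32, 2)))$y
#' dim(y)  # 100 32 2
#' @export
build_block <- function(block, in_channels, seed = 1L, stride = 1L,
                        padding = "same", norm = TRUE,
                        activation = c("relu", "linear"),
                        skip = block$skip) {
  stopifnot(inherits(block, "block_spec"))
  if (in_channels < 1) stop("`in_channels` must be >= 1", call. = FALSE)
  cfg <- block_config(block, in_channels, stride = stride,
                      padding = padding, norm = norm,
                      activation = match.arg(activation), skip = skip,
                      prefix = "b1_")
  init <- with_seed(seed, block_init(cfg))
  structure(list(cfg = cfg, params = init$params, state = init$state),
            class = "msdc_unit")
}

#' Run a built block forward
#'
#' @param unit A unit from [build_block()].
#' @param x Numeric array `(length, in_channels, batch)`.
#' @param training Use batch statistics for normalization (default FALSE:
#'   running statistics).
#' @return List with `y` (output array) and internal caches.
#' @export
unit_forward <- function(unit, x, training = FALSE) {
  stopifnot(inherits(unit, "msdc_unit"))
  if (length(dim(x)) != 3 || dim(x)[2] != unit$cfg$in_channels)
    stop(sprintf("input must be (length, %d, batch)", unit$cfg$in_channels),
         call. = FALSE)
  block_forward(unit$cfg, unit$params, unit$state, x, training)
}

#' Count trainable parameters of a built unit or model
#'
#' Sums the element counts of the actual parameter arrays — the framework's
#' own introspection, independent of the static analyzer formulas.
#'
#' @param x A built unit ([build_block()]), model ([build_network()]), or a
#'   named list of parameter arrays.
#' @param pattern Optional regular expression restricting which parameter
#'   names are counted (e.g. `"_br[0-9]+_"` for branch convolutions only).
#' @return Integer total element count.
#' @export
count_params <- function(x, pattern = NULL) {
  params <- if (is.list(x) && !is.null(x$params)) x$params else x
  nm <- names(params)
  if (!is.null(pattern)) nm <- grep(pattern, nm, value = TRUE)
  sum(vapply(params[nm], length, integer(1)))
}

# ---------------------------------------------------------------------------

#' Network specification
#'
#' Describes a full detection network: a stem convolution, `n_blocks`
#' identical-type blocks (with temporal halving at the scheduled block
#' indices), a final normalization/rectifier, global average pooling over
#' time, and a linear head with `n_classes` outputs. Global pooling makes
#' the head length-agnostic, so `input_length = "variable"` is supported.
#'
#' @param block A [block_spec()] or canonical block name.
#' @param n_blocks Number of stacked blocks (the full-scale networks use
#'   15).
#' @param n_classes 2 (AF / non-AF) or 4 (Normal / AF / Other / Noise).
#' @param classes Character vector of class labels, length `n_classes`.
#' @param input_rate Sampling rate in Hz the network expects.
#' @param input_length Samples per record, or `"variable"`.
#' @param downsample_schedule Block indices at which all branches (and the
#'   shortcut projection) use stride 2, halving the temporal length.
#'   Default: every 4th block.
#' @param stem_kernel,stem_filters,stem_stride Stem convolution geometry.
#'   The stem filter count must equal the block output channel count so
#'   identity shortcuts apply (default: it does).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(block, n_blocks = 15L, n_classes = 2L,
                         classes = NULL, input_rate = 250,
                         input_length = "variable",
                         downsample_schedule = seq(4L, n_blocks, by = 4L),
                         stem_kernel = 16L, stem_filters = NULL,
                         stem_stride = 1L) {
  if (is.character(block)) block <- msdc_block(block)
  stopifnot(inherits(block, "block_spec"))
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  if (!n_classes %in% c(2L, 4L))
    stop("`n_classes` must be 2 or 4", call. = FALSE)
  if (is.null(classes))
    classes <- if (n_classes == 2) c("non_af", "af")
               else c("normal", "af", "other", "noise")
  if (length(classes) != n_classes)
    stop("`classes` must have length `n_classes`", call. = FALSE)
  downsample_schedule <- as.integer(downsample_schedule)
  if (length(downsample_schedule) &&
      (any(downsample_schedule < 1L) ||
       any(downsample_schedule > n_blocks)))
    stop("`downsample_schedule` indices must lie in 1..n_blocks",
         call. = FALSE)
  C <- block_out_channels(block)
  if (is.null(stem_filters)) stem_filters <- C
  structure(list(block = block, n_blocks = n_blocks,
                 n_classes = as.integer(n_classes),
                 classes = as.character(classes),
                 input_rate = as.numeric(input_rate),
                 input_length = input_length,
                 downsample_schedule = downsample_schedule,
                 stem_kernel = as.integer(stem_kernel),
                 stem_filters = as.integer(stem_filters),
                 stem_stride = as.integer(stem_stride)),
            class = "network_spec")
}

#' Preset detection networks
#'
#' `scale = "full"` gives the 15-block networks (AF-MSDC A/B/C and the
#' 1D-ResNet baseline). `scale = "reduced"` gives the 4-block desk-scale
#' variant used for synthetic-data experiments: a stride-10 stem and
#' temporal halving at blocks 2 and 4 keep activations small while the
#' receptive field still spans several heartbeats.
#'
#' @param type Block type: `"residual"`, `"msdc_a"`, `"msdc_b"`, `"msdc_c"`.
#' @param scale `"full"` or `"reduced"`.
#' @param n_classes,classes,input_rate,input_length Passed through to
#'   [network_spec()].
#' @return A [network_spec()].
#' @export
afmsdc_network <- function(type = c("msdc_a", "msdc_b", "msdc_c",
                                    "residual"),
                           scale = c("full", "reduced"), n_classes = 2L,
                           classes = NULL, input_rate = 250,
                           input_length = "variable") {
  type <- match.arg(type)
  scale <- match.arg(scale)
  if (scale == "full")
    network_spec(type, n_blocks = 15L, n_classes = n_classes,
                 classes = classes, input_rate = input_rate,
                 input_length = input_length)
  else
    network_spec(type, n_blocks = 4L, n_classes = n_classes,
                 classes = classes, input_rate = input_rate,
                 input_length = input_length,
                 downsample_schedule = c(2L, 4L), stem_stride = 10L)
}

block_stride_at <- function(spec, i)
  if (i %in% spec$downsample_schedule) 2L else 1L

#' Build a detection network
#'
#' Instantiates the network described by a [network_spec()] with seeded
#' random weights: stem convolution, `n_blocks` pre-activation blocks,
#' final batchnorm + rectifier, global average pooling, linear head.
#' Two builds with the same spec and seed produce bit-identical weights.
#'
#' @param spec A [network_spec()].
#' @param seed Integer initialization seed.
#' @return An object of class `msdc_model`.
#' @examples
#' m <- build_network(network_spec("msdc_b", n_blocks = 2), seed = 1)
#' scores <- model_forward(m, array(rnorm(500), c(500, 1, 1)))$scores
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  C <- spec$stem_filters
  with_seed(seed, {
    params <- list(
      stem_W = he_init(c(spec$stem_kernel, 1L, C), spec$stem_kernel))
    state <- list()
    cfgs <- vector("list", spec$n_blocks)
    for (i in seq_len(spec$n_blocks)) {
      cfgs[[i]] <- block_config(spec$block, C,
                                stride = block_stride_at(spec, i),
                                prefix = sprintf("b%d_", i))
      init <- block_init(cfgs[[i]])
      params <- c(params, init$params)
      state <- c(state, init$state)
    }
    params$top_bn_gamma <- rep(1, C)
    params$top_bn_beta <- rep(0, C)
    state$top_bn_mean <- rep(0, C)
    state$top_bn_var <- rep(1, C)
    params$head_W <- he_init(c(C, spec$n_classes), C)
    dim(params$head_W) <- c(C, spec$n_classes)
    params$head_b <- rep(0, spec$n_classes)
    structure(list(spec = spec, cfgs = cfgs, params = params,
                   state = state, seed = as.integer(seed)),
              class = "msdc_model")
  })
}

#' Network forward pass
#'
#' @param model An [build_network()] model.
#' @param x Numeric array `(length, 1, batch)`, or a matrix
#'   `(length, batch)` which is promoted.
#' @param training Logical; use batch statistics and record caches for the
#'   backward pass.
#' @return List with `scores` (matrix `batch x n_classes`), `caches`, and
#'   the (possibly updated) `state`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "msdc_model"))
  if (length(dim(x)) == 2) dim(x) <- c(dim(x)[1], 1L, dim(x)[2])
  params <- model$params; state <- model$state
  caches <- list()
  st <- conv1d_forward(x, params$stem_W, NULL, stride = model$spec$stem_stride,
                       dilation = 1L, padding = "same")
  h <- st$y
  caches$stem <- st$cache
  caches$blocks <- vector("list", model$spec$n_blocks)
  for (i in seq_len(model$spec$n_blocks)) {
    bf <- block_forward(model$cfgs[[i]], params, state, h, training)
    h <- bf$y
    caches$blocks[[i]] <- bf$cache
    state <- bf$state
  }
  bn <- bn_forward(h, params$top_bn_gamma, params$top_bn_beta,
                   state$top_bn_mean, state$top_bn_var, training)
  state$top_bn_mean <- bn$rmean; state$top_bn_var <- bn$rvar
  caches$top_bn <- bn$cache
  r <- relu_forward(bn$y); caches$top_relu <- r$cache
  g <- gap_forward(r$y); caches$gap <- g$cache
  d <- dense_forward(g$y, params$head_W, params$head_b)
  caches$dense <- d$cache
  list(scores = d$y, caches = caches, state = state)
}

model_backward <- function(model, caches, dscores) {
  grads <- list()
  db <- dense_backward(caches$dense, dscores)
  grads$head_W <- db$dW; grads$head_b <- db$db
  dh <- gap_backward(caches$gap, db$dh)
  dh <- relu_backward(caches$top_relu, dh)
  bb <- bn_backward(caches$top_bn, dh)
  grads$top_bn_gamma <- bb$dgamma; grads$top_bn_beta <- bb$dbeta
  dh <- bb$dx
  for (i in rev(seq_len(model$spec$n_blocks))) {
    bg <- block_backward(model$cfgs[[i]], caches$blocks[[i]], dh)
    grads <- c(grads, bg$grads)
    dh <- bg$dx
  }
  sg <- conv1d_backward(caches$stem, dh)
  grads$stem_W <- sg$dw
  grads
}

#' Static full-convention parameter count of a network
#'
#' Computes, from the specification alone, the number of trainable scalars
#' the built network will contain: stem weights, per-block batchnorm
#' scale/shift, branch convolution weights and biases, shortcut projection
#' weights where the schedule forces a stride, the final batchnorm, and the
#' linear head. Matches [count_params()] on the built model exactly. The
#' `"tabulated"` convention instead sums the design-stage `k*f` block
#' counts over the stack.
#'
#' @param spec A [network_spec()].
#' @param convention `"full"` (default) or `"tabulated"`.
#' @return Numeric parameter count.
#' @export
network_param_count <- function(spec, convention = c("full", "tabulated")) {
  stopifnot(inherits(spec, "network_spec"))
  convention <- match.arg(convention)
  if (convention == "tabulated")
    return(spec$n_blocks * block_param_count(spec$block))
  C <- spec$stem_filters
  total <- spec$stem_kernel * 1 * C                 # stem, no bias
  for (i in seq_len(spec$n_blocks)) {
    total <- total + 2 * C                          # bn gamma + beta
    total <- total + block_param_count(spec$block, "full", in_channels = C)
    stride <- block_stride_at(spec, i)
    identity_skip <- spec$block$skip && stride == 1L &&
      C == block_out_channels(spec$block)
    if (spec$block$skip && !identity_skip)
      total <- total + C * block_out_channels(spec$block)  # 1x1, no bias
  }
  total + 2 * C +                                   # top bn
    C * spec$n_classes + spec$n_classes             # head
}

# --- checkpointing ----------------------------------------------------------

spec_to_list <- function(spec) {
  list(block = list(name = spec$block$name,
                    branches = lapply(spec$block$branches, function(b)
                      c(b$kernel_size, b$stride, b$dilation_factor,
                        b$filters)),
                    skip = spec$block$skip),
       n_blocks = spec$n_blocks, n_classes = spec$n_classes,
       classes = spec$classes, input_rate = spec$input_rate,
       input_length = spec$input_length,
       downsample_schedule = spec$downsample_schedule,
       stem_kernel = spec$stem_kernel, stem_filters = spec$stem_filters,
       stem_stride = spec$stem_stride)
}

spec_from_list <- function(x) {
  blk <- block_spec(x$block$name,
                    lapply(x$block$branches, function(t) {
                      t <- as.numeric(unlist(t))
                      conv_branch(t[1], t[2], t[3], t[4])
                    }),
                    skip = isTRUE(x$block$skip))
  network_spec(blk, n_blocks = x$n_blocks, n_classes = x$n_classes,
               classes = as.character(unlist(x$classes)),
               input_rate = x$input_rate,
               input_length = if (identical(x$input_length, "variable"))
                 "variable" else as.numeric(x$input_length),
               downsample_schedule = as.integer(unlist(
                 x$downsample_schedule)),
               stem_kernel = x$stem_kernel, stem_filters = x$stem_filters,
               stem_stride = x$stem_stride)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights, the normalization
#' state, and the network specification embedded as JSON (the spec
#' round-trips losslessly).
#'
#' @param model An `msdc_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored `msdc_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "msdc_model"))
  saveRDS(list(spec_json = jsonlite::toJSON(spec_to_list(model$spec),
                                            auto_unbox = TRUE, digits = NA),
               params = model$params, state = model$state,
               seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  spec <- spec_from_list(jsonlite::fromJSON(x$spec_json,
                                            simplifyVector = FALSE))
  model <- build_network(spec, seed = x$seed)
  model$params <- x$params
  model$state <- x$state
  model
}

#' @export
print.msdc_model <- function(x, ...) {
  cat(sprintf("msdc model: %d x '%s' blocks, %d classes, %s params\n",
              x$spec$n_blocks, x$spec$block$name, x$spec$n_classes,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}
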