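#' Dilated-convolution branch specification
#'
#' One parallel branch of an MSDC (multi-scale dilated convolution) block,
#' described by the tuple `(k, s, d, f)`: kernel size (number of taps),
#' stride, dilation factor, and number of filters. The dilation factor
#' follows the convention in which `d = 0` denotes a plain (contiguous)
#' convolution; the spacing between consecutive kernel taps on the input is
#' `max(d, 1)`, so `d = 0` and `d = 1` are equivalent.
#'
#' @param kernel_size Positive integer, number of kernel taps.
#' @param stride Positive integer stride.
#' @param dilation_factor Non-negative integer dilation factor.
#' @param filters Positive integer, number of output filters.
#' @return An object of class `conv_branch`.
#' @examples
#' conv_branch(8, 1, 2, 16)
#' @export
conv_branch <- function(kernel_size, stride = 1L, dilation_factor = 0L,
                        filters = 1L) {
  check_count <- function(x, name, min) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < min)
      stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                   name, min, deparse(x)), call. = FALSE)
    as.integer(x)
  }
  structure(list(
    kernel_size     = check_count(kernel_size, "kernel_size", 1L),
    stride          = check_count(stride, "stride", 1L),
    dilation_factor = check_count(dilation_factor, "dilation_factor", 0L),
    filters         = check_count(filters, "filters", 1L)
  ), class = "conv_branch")
}

# Effective spacing between matched input elements: d = 0 and d = 1 both
# mean contiguous taps.
effective_dilation <- function(branch) max(branch$dilation_factor, 1L)

#' Input tap positions of a dilated branch
#'
#' The set of input positions (0-based, anchored at 0) touched by one
#' application of the branch kernel: `{ i * max(d, 1) : i = 0 .. k-1 }`.
#'
#' @param branch A [conv_branch()].
#' @return Integer vector of `k` distinct positions, increasing.
#' @examples
#' tap_positions(conv_branch(8, 1, 2, 8))  # 0 2 4 ... 14
#' @export
tap_positions <- function(branch) {
  stopifnot(inherits(branch, "conv_branch"))
  seq(0L, by = effective_dilation(branch),
      length.out = branch$kernel_size)
}

#' Branch parameter count under the analyzer's tabulation convention
#'
#' Counts `k * f` weights for a branch: the tabulation used when comparing
#' block designs, which deliberately excludes input-channel multiplicity and
#' bias terms. For real model sizing see [block_param_count()] with
#' `convention = "full"`.
#'
#' @param branch A [conv_branch()].
#' @return Integer, `kernel_size * filters`.
#' @export
branch_param_count <- function(branch) {
  stopifnot(inherits(branch, "conv_branch"))
  branch$kernel_size * branch$filters
}

#' @export
format.conv_branch <- function(x, ...) {
  sprintf("(%d, %d, %d, %d)", x$kernel_size, x$stride, x$dilation_factor,
          x$filters)
}

#' @export
print.conv_branch <- function(x, ...) {
  cat("conv branch (k, s, d, f) =", format(x), "\n")
  invisible(x)
}

#' MSDC / residual block specification
#'
#' An ordered list of parallel dilated-convolution branches plus the merge
#' and shortcut policy. Branch outputs are merged by channel concatenation,
#' so the block's output channel count is the sum of branch filter counts;
#' an optional shortcut adds the block input (projected by a pointwise
#' convolution when shapes differ).
#'
#' @param name Block name (free-form; the four canonical blocks are
#'   `"residual"`, `"msdc_a"`, `"msdc_b"`, `"msdc_c"`, see [msdc_block()]).
#' @param branches List of [conv_branch()] objects, at least one.
#' @param skip Logical, keep the residual shortcut (default `TRUE`).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(name, branches, skip = TRUE) {
  if (!is.list(branches) || length(branches) == 0L)
    stop("`branches` must be a non-empty list of conv_branch objects",
         call. = FALSE)
  ok <- vapply(branches, inherits, logical(1), what = "conv_branch")
  if (!all(ok))
    stop("`branches` element(s) ", paste(which(!ok), collapse = ", "),
         " are not conv_branch objects", call. = FALSE)
  structure(list(name = as.character(name)[1], branches = branches,
                 skip = isTRUE(skip), merge = "concat"),
            class = "block_spec")
}

#' Canonical block specifications
#'
#' The four canonical blocks, with their published branch tuples
#' `(k, s, d, f)`:
#' \describe{
#'   \item{residual}{(16, 1, 0, 32)}
#'   \item{msdc_a}{(8, 1, 2, 16), (6, 1, 3, 16)}
#'   \item{msdc_b}{(8, 1, 2, 8), (6, 1, 3, 8), (1, 1, 5, 8), (1, 1, 7, 8)}
#'   \item{msdc_c}{(8, 1, 2, 32)}
#' }
#' All four produce 32 output channels, which is what makes the MSDC blocks
#' drop-in replacements for the residual block.
#'
#' @param name One of `"residual"`, `"msdc_a"`, `"msdc_b"`, `"msdc_c"`.
#' @return A [block_spec()].
#' @examples
#' block_receptive_field(msdc_block("msdc_a"))  # 11
#' @export
msdc_block <- function(name = c("residual", "msdc_a", "msdc_b", "msdc_c")) {
  name <- match.arg(name)
  tuples <- switch(name,
    residual = list(c(16, 1, 0, 32)),
    msdc_a   = list(c(8, 1, 2, 16), c(6, 1, 3, 16)),
    msdc_b   = list(c(8, 1, 2, 8), c(6, 1, 3, 8), c(1, 1, 5, 8),
                    c(1, 1, 7, 8)),
    msdc_c   = list(c(8, 1, 2, 32)))
  block_spec(name, lapply(tuples, function(t)
    conv_branch(t[1], t[2], t[3], t[4])))
}

# Published reference values for the canonical blocks. `rf_printed` is the
# receptive field as printed in the source table; for msdc_b it disagrees
# with the tap-union rule (13 vs 11) and the analyzer flags this.
canonical_reference <- function() {
  data.frame(
    block = c("residual", "msdc_a", "msdc_b", "msdc_c"),
    rf_printed = c(16L, 11L, 13L, 8L),
    params_printed = c(512L, 224L, 128L, 256L),
    stringsAsFactors = FALSE
  )
}

#' Block receptive field under the tap-union rule
#'
#' Counts the distinct input positions that participate in producing one
#' output unit of the block: the union of [tap_positions()] over all
#' branches, every branch anchored at position 0.
#'
#' @param block A [block_spec()].
#' @return Positive integer.
#' @examples
#' block_receptive_field(msdc_block("residual"))  # 16
#' @export
block_receptive_field <- function(block) {
  stopifnot(inherits(block, "block_spec"))
  length(unique(unlist(lapply(block$branches, tap_positions))))
}

#' Block parameter count
#'
#' Two conventions are exposed. `"tabulated"` sums `k * f` over branches:
#' the convention used in design-stage block comparisons, which ignores
#' input-channel multiplicity and biases. `"full"` is the engineering count
#' of an actual convolution layer, `in_channels * k * f + f` per branch
#' (weights plus bias), and requires `in_channels`.
#'
#' @param block A [block_spec()].
#' @param convention `"tabulated"` (default) or `"full"`.
#' @param in_channels Input channel count, required for `"full"`.
#' @return Integer parameter count.
#' @examples
#' block_param_count(msdc_block("msdc_b"))                      # 128
#' block_param_count(msdc_block("msdc_c"), "full", in_channels = 32)
#' @export
block_param_count <- function(block,
                              convention = c("tabulated", "full"),
                              in_channels = NULL) {
  stopifnot(inherits(block, "block_spec"))
  convention <- match.arg(convention)
  if (convention == "tabulated")
    return(sum(vapply(block$branches, branch_param_count, integer(1))))
  if (is.null(in_channels) || in_channels < 1)
    stop("`in_channels` is required for the full convention", call. = FALSE)
  sum(vapply(block$branches, function(b)
    in_channels * b$kernel_size * b$filters + b$filters, numeric(1)))
}

block_out_channels <- function(block)
  sum(vapply(block$branches, function(b) b$filters, integer(1)))

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("block '%s': %d branch(es) %s, %d output channels\n",
              x$name, length(x$branches),
              paste(vapply(x$branches, format, character(1)), collapse = ""),
              block_out_channels(x)))
  cat(sprintf("  receptive field %d, tabulated params %d, skip %s\n",
              block_receptive_field(x), block_param_count(x),
              if (x$skip) "on" else "off"))
  invisible(x)
}

#' Architecture report for the canonical blocks
#'
#' Static analysis of one or all canonical blocks: branch tuples, tap-union
#' receptive field, tabulated (`k*f`) parameter count, plus the published
#' reference values and a discrepancy flag where the tap-union rule and the
#' printed receptive field disagree (block `msdc_b`: rule 11 vs printed 13 —
#' the printed value cannot be reconciled with the printed branch tuples and
#' parameter count).
#'
#' @param blocks Character vector of canonical block names, or a list of
#'   [block_spec()] objects. Default: all four canonical blocks.
#' @return A data.frame with columns `block`, `branches`,
#'   `receptive_field`, `params_tabulated`, and for canonical blocks
#'   `rf_printed`, `params_printed`, `rf_flag`.
#' @export
architecture_report <- function(blocks = c("residual", "msdc_a", "msdc_b",
                                           "msdc_c")) {
  if (is.character(blocks)) blocks <- lapply(blocks, msdc_block)
  if (inherits(blocks, "block_spec")) blocks <- list(blocks)
  rows <- lapply(blocks, function(b) {
    data.frame(
      block = b$name,
      branches = paste(vapply(b$branches, format, character(1)),
                       collapse = ""),
      receptive_field = block_receptive_field(b),
      params_tabulated = block_param_count(b),
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  ref <- canonical_reference()
  rep <- merge(rep, ref, by = "block", all.x = TRUE, sort = FALSE)
  rep$rf_flag <- !is.na(rep$rf_printed) &
    rep$rf_printed != rep$receptive_field
  rep[match(vapply(blocks, `[[`, character(1), "name"), rep$block), ,
      drop = FALSE]
}
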