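#' @importFrom rlang abort %||%
#' @importFrom stats quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Classed abort so callers/tests can distinguish failure modes.
cp_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "colonyprofiler_error"))
}

# Physical positions (um) of voxel centers along one axis: voxel i spans
# [(i-1)*step, i*step), its center sits at (i - 0.5)*step.
vox_centers <- function(n, step) (seq_len(n) - 0.5) * step

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    cp_abort(sprintf("`%s` must be a single positive number.", name),
             "cp_error_spec")
  }
  invisible(x)
}
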