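#' @importFrom stats cor fisher.test median p.adjust rbeta rbinom rnorm
#'   rpois runif var
#' @importFrom utils head read.table write.table
NULL

# Internal parameter checks ------------------------------------------------

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param("'%s' must be a single value in [0, 1]", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop_param("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# Draw a length-2 bp range (either a single value or c(min, max))
check_range <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || any(is.na(x)) ||
      any(x < 1)) {
    stop_param("'%s' must be a positive length or a c(min, max) range", name)
  }
  if (length(x) == 1L) x <- c(x, x)
  if (x[1] > x[2]) stop_param("'%s' has min > max", name)
  as.integer(round(x))
}

# Derive a stream-specific child seed from a master seed; double
# arithmetic avoids integer overflow, result kept < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep.int(range[1], n)
  else sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
}
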