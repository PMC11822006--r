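#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate cor cutree dist filter hclust ks.test median
#'   prcomp quantile rbinom rnorm runif sd setNames wilcox.test
#' @importFrom utils head read.csv tail write.csv
NULL

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-entity substream seed, so adding one entity never
# perturbs the stream of another (e.g. cells vs. the behavior track).
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483399)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

# Maximal run length of TRUE values in a logical vector.
longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

# Moving-average (boxcar) smoother with shrinking one-sided windows at the
# edges, so output length equals input length and no NA padding appears.
boxcar_smooth <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
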