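#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that every stochastic operation in the package draws from one seeded
#' generator per call without disturbing global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Shift a matrix by (di, dj) with edge replication; used by the box filter,
# the Sobel operator and the thinning pass.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Longest run of TRUE in a logical vector (0 if none).
longest_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# Clamp to [0, 255] and round to integer 8-bit values.
quantize8 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  round(m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
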