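#' @importFrom stats rexp rpois rnorm rlnorm runif coef lm sd smooth.spline
#'   predict
#' @importFrom utils write.table read.table head modifyList
NULL

# Internal error helper: classed conditions so callers can test on class
# rather than on message text.
pw_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "polwave_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pw_check <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) pw_stop(class, msg, ...)
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed and a stage label, so adding a
# stage never perturbs the draws of earlier stages.  Plain polynomial string
# hash folded into [0, 2^31 - 2].
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646 + 1)
}

#' Exact binned coverage of a set of segments
#'
#' Distributes linear segments `[s0, s1)` (base-pair coordinates) over the
#' bins defined by `edges`, returning per-bin total overlap length.  Exact,
#' and O((n + m) log n) via prefix sums, so it scales to whole-cohort
#' rendering without compiled code.
#'
#' @param s0,s1 numeric vectors of segment starts/ends (`s1 >= s0`).
#' @param edges increasing numeric vector of bin edges (length nbins + 1).
#' @return numeric vector of length `length(edges) - 1`.
#' @keywords internal
binned_segment_coverage <- function(s0, s1, edges) {
  stopifnot(length(s0) == length(s1))
  nb <- length(edges) - 1L
  if (length(s0) == 0L) return(numeric(nb))
  keep <- s1 > s0
  s0 <- s0[keep]; s1 <- s1[keep]
  if (length(s0) == 0L) return(numeric(nb))
  # F(x) = total covered length below x = sum_i clamp(x - s0_i, 0, len_i)
  o0 <- sort(s0); o1 <- sort(s1)
  c0 <- c(0, cumsum(o0)); c1 <- c(0, cumsum(o1))
  Fx <- function(x) {
    i0 <- findInterval(x, o0)  # segments with s0 < x (ties: s0 <= x, fine)
    i1 <- findInterval(x, o1)  # segments with s1 <= x
    # fully passed segments contribute (s1 - s0); partial contribute (x - s0)
    (c1[i1 + 1L] - c0[i1 + 1L]) + (i0 - i1) * x - (c0[i0 + 1L] - c0[i1 + 1L])
  }
  fe <- Fx(edges)
  diff(fe)
}

# Counts of point positions per bin (half-open bins [edge_i, edge_{i+1})).
binned_point_counts <- function(pos, edges) {
  nb <- length(edges) - 1L
  if (length(pos) == 0L) return(integer(nb))
  idx <- findInterval(pos, edges, rightmost.closed = FALSE)
  tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
}

# format a number for deterministic text output (no scientific notation)
fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
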