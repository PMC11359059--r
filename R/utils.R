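## Internal helpers: seeded evaluation, classed conditions, label agreement.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so package functions never perturb user randomness.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Condition constructors: a small taxonomy so callers can test errors by
## class rather than by message text.
stopWith <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "psafl_error")))
}
stopConfig  <- function(msg, ...) stopWith("psafl_config_error", msg, ...)
stopInput   <- function(msg, ...) stopWith("psafl_input_error", msg, ...)
stopData    <- function(msg, ...) stopWith("psafl_data_error", msg, ...)
stopNumeric <- function(msg, ...) stopWith("psafl_numeric_error", msg, ...)
stopEval    <- function(msg, ...) stopWith("psafl_eval_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

## All permutations of a vector (k! rows); k is small (<= 8) everywhere.
allPermutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- allPermutations(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Permutation-invariant label agreement
#'
#' Fraction of points on which two hard partitions agree under the best
#' one-to-one relabeling of the first partition onto the second. Equals 1
#' exactly when the partitions are identical up to label permutation. Used
#' throughout to compare recovered clusters with generating groups without
#' caring about arbitrary cluster indices.
#'
#' @param a,b integer (or factor) label vectors of equal length.
#' @return agreement in `[0, 1]`.
#' @examples
#' bestPermutationAgreement(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
bestPermutationAgreement <- function(a, b) {
  a <- as.integer(as.factor(a))
  b <- as.integer(as.factor(b))
  if (length(a) != length(b)) {
    stopInput("label vectors differ in length (%d vs %d)", length(a), length(b))
  }
  la <- sort(unique(a))
  lb <- sort(unique(b))
  ## pad the smaller label set so the mapping is one-to-one
  k <- max(length(la), length(lb))
  targets <- seq_len(k)
  perms <- allPermutations(targets)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    mapped <- perms[r, ][match(a, la)]
    agree <- mean(mapped == b)
    if (agree > best) best <- agree
  }
  best
}
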