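#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's random-number state, seeds the generator, evaluates
#' `expr`, and restores the previous state, so that library functions never
#' clobber user-level reproducibility.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-subject seed from a master seed
#'
#' Splitting rule: `(master * 48271 + subject_id * 1009) mod 2147483562 + 1`,
#' kept below 2^31 so it is a valid R integer seed. Subjects are therefore
#' mutually independent yet fully reproducible from the master seed.
#'
#' @param master_seed integer master seed.
#' @param subject_id integer subject index (1-based).
#' @param stream optional extra offset to split independent random streams
#'   within one subject (e.g. rest vs evoked vs behavior).
#' @return integer seed.
#' @export
subject_seed <- function(master_seed, subject_id, stream = 0L) {
  m <- 2147483562
  s <- (as.double(master_seed) * 48271 + as.double(subject_id) * 1009 +
          as.double(stream) * 97003) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

## all permutations of 1..n as a matrix (n! x n); used by the exact
## Spearman null and by exact-enumeration permutation schemes for tiny n
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}
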