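# Evaluate an expression under a local RNG state: the global .Random.seed is
# saved and restored, so library code never perturbs the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed: one master seed fans out to named substreams
# so individual operations are reproducible in isolation. Kept within the
# 32-bit integer range.
substream <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1048573
  as.integer((as.numeric(seed) %% 1048573) * 2039 + h) %% 2147483629L
}

#' Seeded cross-validation fold assignment
#'
#' Samples are assigned to `k` folds by a seeded permutation, giving fold
#' sizes that differ by at most one. With `groups` supplied, whole groups
#' (e.g. all time-points of one plant) are kept in a single fold.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param groups Optional length-`n` grouping vector.
#' @return Integer vector of fold labels in `1:k`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L, groups = NULL) {
  if (n < k) stop("need at least k samples for k folds", call. = FALSE)
  if (is.null(groups)) {
    perm <- with_seed(seed, sample.int(n))
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(k), n)
    folds
  } else {
    stopifnot(length(groups) == n)
    ug <- unique(groups)
    perm <- with_seed(seed, sample(seq_along(ug)))
    gf <- integer(length(ug))
    gf[perm] <- rep_len(seq_len(k), length(ug))
    gf[match(groups, ug)]
  }
}
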