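`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so generators never leak global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Area under the ROC curve by rank statistic
#'
#' Computes the probability that a randomly chosen positive case scores above
#' a randomly chosen negative case (the Mann-Whitney formulation of the
#' AUROC), used to quantify how well diffused intensities separate planted
#' module genes from background genes.
#'
#' @param scores numeric vector of scores (higher = more candidate-like).
#' @param positive logical vector, `TRUE` for positive (e.g. hidden module)
#'   cases.
#' @return a single number in \[0, 1\].
#' @examples
#' auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive))
    stop("'scores' and 'positive' must have the same length")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc needs at least one positive and one negative case")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
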