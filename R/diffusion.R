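# Markov signal diffusion: the signal vector is treated as a row vector and
# propagated through the row-stochastic transition matrix, S_t = S_{t-1} P.
# Plain matrix-power semantics, no restart term; row-stochasticity conserves
# total signal mass at every step.

.check_pair <- function(s0, P) {
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (length(s0) != nrow(P))
    stop("signal vector and transition matrix dimensions differ (",
         length(s0), " vs ", nrow(P), ")")
  if (!is.null(names(s0)) && !is.null(rownames(P)) &&
      !identical(names(s0), rownames(P)))
    stop("signal vector and transition matrix gene indices differ")
}

#' Diffuse a signal vector for a fixed number of steps
#'
#' @param s0 named non-negative numeric vector over the gene universe.
#' @param P row-stochastic transition matrix (base or `Matrix` sparse) over
#'   the same universe.
#' @param t non-negative integer number of steps.
#' @return named numeric vector, `s0` propagated `t` times through `P`.
#' @examples
#' P <- matrix(c(0, 1, 0, 0.5, 0, 0.5, 0, 1, 0), 3, byrow = TRUE)
#' diffuse(c(1, 0, 0), P, 2)  # 3-gene chain: (0.5, 0, 0.5)
#' @export
diffuse <- function(s0, P, t) {
  .check_pair(s0, P)
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  s <- as.numeric(s0)
  for (step in seq_len(t)) s <- as.numeric(s %*% P)
  names(s) <- names(s0) %||% rownames(P)
  s
}

#' Diffuse until the signal stabilizes
#'
#' Iterates single diffusion steps and stops at the first step t where the
#' relative L1 change `||S_t - S_{t-1}||_1 / ||S_{t-1}||_1` falls below
#' `tol`, or at `max_t` with a warning.
#'
#' @inheritParams diffuse
#' @param tol positive relative L1 change tolerance.
#' @param max_t maximum number of steps (>= 1).
#' @return list of class `diffusion_profile` with `signal` (final vector),
#'   `t` (steps taken), `trace` (relative change at each step) and
#'   `converged`.
#' @export
diffuse_until_converged <- function(s0, P, tol = 1e-3, max_t = 50L) {
  .check_pair(s0, P)
  if (tol <= 0) stop("tol must be > 0")
  if (max_t < 1) stop("max_t must be >= 1")
  mass <- sum(s0)
  if (mass <= 0) stop("zero initial signal mass: nothing to diffuse")
  s <- as.numeric(s0)
  trace <- numeric(0)
  converged <- FALSE
  t_used <- 0L
  for (step in seq_len(max_t)) {
    s_new <- as.numeric(s %*% P)
    change <- sum(abs(s_new - s)) / sum(abs(s))
    trace <- c(trace, change)
    if (abs(sum(s_new) - mass) > 1e-9 * max(1, mass))
      warning("signal mass drift at step ", step,
              ": is the matrix row-stochastic?")
    s <- s_new
    t_used <- step
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("diffusion did not converge within ", max_t, " steps ",
            "(last relative change ", signif(trace[length(trace)], 3), ")")
  names(s) <- names(s0) %||% rownames(P)
  structure(list(signal = s, t = t_used, trace = trace,
                 converged = converged),
            class = "diffusion_profile")
}

#' Diffuse one signal through many tissue matrices
#'
#' @param s0 named signal vector shared by all tissues.
#' @param matrices named list of row-stochastic matrices over the same gene
#'   index (see [build_all_tissues()]).
#' @inheritParams diffuse_until_converged
#' @return list with `intensity` (genes x tissues matrix of final diffused
#'   intensities) and `profiles` (per-tissue `diffusion_profile`).
#' @export
diffuse_all_tissues <- function(s0, matrices, tol = 1e-3, max_t = 50L) {
  if (length(matrices) == 0) stop("no tissue matrices supplied")
  if (is.null(names(matrices))) stop("tissue matrices must be named")
  profiles <- lapply(names(matrices), function(tis) {
    tryCatch(diffuse_until_converged(s0, matrices[[tis]], tol, max_t),
             error = function(e)
               stop("tissue '", tis, "': ", conditionMessage(e),
                    call. = FALSE))
  })
  names(profiles) <- names(matrices)
  intensity <- vapply(profiles, function(p) p$signal,
                      numeric(length(s0)))
  rownames(intensity) <- names(s0) %||% rownames(matrices[[1]])
  list(intensity = intensity, profiles = profiles)
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat("Diffusion profile: converged =", x$converged,
      "after t =", x$t, "steps\n")
  cat("Relative L1 change trace:",
      paste(signif(x$trace, 3), collapse = ", "), "\n")
  invisible(x)
}
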