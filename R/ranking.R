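with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Posterior rank probabilities of the treatments
#'
#' Ranks the treatments within every posterior draw by their basic
#' parameter (the reference sits at 0). These are survival hazard ratios,
#' so by default a smaller log HR is better and rank 1 is the treatment
#' with the lowest hazard. Exact ties (possible only with degenerate
#' draws) are broken by a seeded uniform jitter of magnitude 1e-12.
#'
#' @param post an `nma_posterior`, or a numeric draws matrix with one
#'   column per treatment (already including the reference).
#' @param direction `"lower"` (default: lower hazard ranks first) or
#'   `"higher"`.
#' @param jitter_seed seed for the tie-breaking jitter.
#' @return Matrix of class `rank_probabilities`: `P[t, r]` is the
#'   posterior probability that treatment `t` has rank `r`. Rows and
#'   columns each sum to 1 (doubly stochastic).
#' @export
rank_probabilities <- function(post, direction = c("lower", "higher"),
                               jitter_seed = 20201L) {
  direction <- match.arg(direction)
  d <- if (inherits(post, "nma_posterior")) full_draws(post) else as.matrix(post)
  if (is.null(colnames(d)))
    colnames(d) <- paste0("T", seq_len(ncol(d)))
  if (nrow(d) < 1000)
    warning("fewer than 1000 draws; rank probabilities will be noisy")
  k <- ncol(d)
  jit <- with_preserved_seed(jitter_seed,
                             matrix(runif(length(d), -5e-13, 5e-13), nrow(d), k))
  score <- d + jit
  if (direction == "higher") score <- -score
  P <- matrix(0, k, k, dimnames = list(colnames(d), paste0("rank", seq_len(k))))
  rk <- t(apply(score, 1, rank, ties.method = "first"))
  for (r in seq_len(k))
    P[, r] <- colMeans(rk == r)
  structure(P, class = c("rank_probabilities", "matrix"),
            direction = direction)
}

#' Surface under the cumulative ranking curve
#'
#' For treatment t with cumulative rank probabilities
#' \eqn{cum_t(r) = P(rank_t \le r)},
#' \eqn{SUCRA_t = \sum_{r=1}^{T-1} cum_t(r) / (T-1)}: 1 for a treatment
#' certainly ranked best, 0 for one certainly ranked last, and the values
#' average exactly 0.5 across treatments.
#'
#' @param rank_probs a `rank_probabilities` matrix (or any matrix whose
#'   rows are treatments and columns ranks, rows summing to 1).
#' @return data.frame of class `sucra_result` with columns `treatment`,
#'   `sucra`, sorted best first.
#' @export
sucra <- function(rank_probs) {
  P <- unclass(rank_probs)
  if (ncol(P) < 2) stop("need at least 2 treatments")
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("malformed rank-probability matrix: rows must sum to 1")
  k <- ncol(P)
  cum <- t(apply(P, 1, cumsum))
  s <- rowSums(cum[, seq_len(k - 1), drop = FALSE]) / (k - 1)
  out <- data.frame(treatment = rownames(P), sucra = unname(s),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sucra, out$treatment), ]
  rownames(out) <- NULL
  class(out) <- c("sucra_result", "data.frame")
  out
}
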