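new_pooled <- function(design, horizon, model, loghr, se, k, q, tau2) {
  structure(
    list(design = design, horizon = horizon, model = model,
         loghr = loghr, se = se,
         ci95 = exp(c(loghr - 1.96 * se, loghr + 1.96 * se)),
         k = k, q_stat = q, tau2 = tau2),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s [%s, OS-%s]: HR %.3f (95%% CI %.3f-%.3f), k=%d, Q=%.3f, tau2=%.4f\n",
              if (is.null(x$design)) "pooled" else x$design,
              x$model, if (is.null(x$horizon)) "?" else x$horizon,
              exp(x$loghr), x$ci95[1], x$ci95[2], x$k, x$q_stat, x$tau2))
  invisible(x)
}

#' Inverse-variance fixed-effect pooling of log hazard ratios
#'
#' Weights are the reciprocal sampling variances: the pooled estimate is
#' \eqn{\sum w_i y_i / \sum w_i} with standard error
#' \eqn{(\sum w_i)^{-1/2}}; the 95% confidence interval uses the normal
#' 1.96 quantile on the log scale.
#'
#' @param loghr numeric vector of log hazard ratios (all for the same
#'   design and horizon).
#' @param se their standard errors (> 0).
#' @param design,horizon optional labels carried into the result.
#' @return A `pooled_estimate` (`tau2 = 0` by definition; `q_stat` is the
#'   Cochran heterogeneity statistic).
#' @export
pool_fixed <- function(loghr, se, design = NULL, horizon = NULL) {
  if (!length(loghr)) stop("no estimates to pool")
  if (length(loghr) != length(se) || any(se <= 0))
    stop("loghr and se must have equal length with se > 0")
  w <- 1 / se^2
  mu <- sum(w * loghr) / sum(w)
  q <- sum(w * (loghr - mu)^2)
  new_pooled(design, horizon, "fixed", mu, 1 / sqrt(sum(w)),
             length(loghr), q, 0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' The method-of-moments heterogeneity variance is
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / C)} with
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i} from the fixed-effect weights,
#' after which the estimates are re-pooled with weights
#' \eqn{1/(se_i^2 + \tau^2)}.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_estimate` with `model = "random"`.
#' @export
pool_dl <- function(loghr, se, design = NULL, horizon = NULL) {
  if (length(loghr) < 2) stop("DerSimonian-Laird needs at least 2 estimates")
  if (length(loghr) != length(se) || any(se <= 0))
    stop("loghr and se must have equal length with se > 0")
  w <- 1 / se^2
  mu_f <- sum(w * loghr) / sum(w)
  q <- sum(w * (loghr - mu_f)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (length(loghr) - 1)) / C)
  wr <- 1 / (se^2 + tau2)
  new_pooled(design, horizon, "random", sum(wr * loghr) / sum(wr),
             1 / sqrt(sum(wr)), length(loghr), q, tau2)
}

#' Pairwise meta-analysis of every design with direct evidence
#'
#' The direct head-to-head stage of the pipeline: for each design (unordered
#' treatment pair) with at least one trial at the horizon, the trial-level
#' log HRs from [pairwise_contrasts()] are pooled. A single-trial design is
#' passed through unchanged (Q = 0, tau2 = 0) under either model.
#'
#' @param net an `evidence_network` with survivor columns.
#' @param horizon outcome year 1..4.
#' @param model `"random"` (DerSimonian-Laird, the reporting default) or
#'   `"fixed"`.
#' @return data.frame, one row per design in alphabetical order:
#'   `design`, `treat_a`, `treat_b`, `k`, `model`, `loghr` (of `treat_b`
#'   vs `treat_a`), `se`, `hr`, `ci_low`, `ci_high`, `q_stat`, `tau2`.
#' @export
pool_designs <- function(net, horizon = 1L, model = c("random", "fixed")) {
  model <- match.arg(model)
  pc <- pairwise_contrasts(net, horizon)
  pool_contrast_table(pc, model = model, horizon = horizon)
}

# pools a pairwise-contrast table (columns design/treat_a/treat_b/loghr/se)
pool_contrast_table <- function(pc, model = "random", horizon = NULL) {
  designs <- sort(unique(pc$design))
  rows <- lapply(designs, function(d) {
    sub <- pc[pc$design == d, , drop = FALSE]
    p <- if (nrow(sub) == 1 || model == "fixed")
      pool_fixed(sub$loghr, sub$se, d, horizon)
    else
      pool_dl(sub$loghr, sub$se, d, horizon)
    data.frame(
      design = d, treat_a = sub$treat_a[1], treat_b = sub$treat_b[1],
      k = p$k, model = model, loghr = p$loghr, se = p$se,
      hr = exp(p$loghr), ci_low = p$ci95[1], ci_high = p$ci95[2],
      q_stat = p$q_stat, tau2 = p$tau2, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
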