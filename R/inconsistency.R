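#' Design-level direct estimates
#'
#' Fixed-effect pooling of all trials sharing a design, the aggregation
#' behind the net-heat machinery: the design-by-treatment view works with
#' one direct estimate per design. Input is a pairwise-contrast table
#' ([pairwise_contrasts()]) or an `evidence_network` plus horizon.
#'
#' @param x pairwise-contrast data.frame (`design`, `treat_a`, `treat_b`,
#'   `loghr`, `se`) or an `evidence_network`.
#' @param horizon outcome year (used when `x` is a network).
#' @return data.frame, one row per design: `design`, `treat_a`, `treat_b`,
#'   `loghr` (of `treat_b` vs `treat_a`), `se`, `k`.
#' @export
design_estimates <- function(x, horizon = 1L) {
  pc <- if (inherits(x, "evidence_network")) pairwise_contrasts(x, horizon) else x
  if (!nrow(pc)) stop("no contrasts to aggregate")
  designs <- sort(unique(pc$design))
  rows <- lapply(designs, function(dd) {
    sub <- pc[pc$design == dd, , drop = FALSE]
    p <- pool_fixed(sub$loghr, sub$se)
    data.frame(design = dd, treat_a = sub$treat_a[1], treat_b = sub$treat_b[1],
               loghr = p$loghr, se = p$se, k = p$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

design_matrix <- function(designs, reference) {
  treatments <- sort(unique(c(designs$treat_a, designs$treat_b)))
  if (!reference %in% treatments)
    stop("reference ", reference, " not in the design network")
  params <- setdiff(treatments, reference)
  X <- matrix(0, nrow(designs), length(params),
              dimnames = list(designs$design, params))
  for (i in seq_len(nrow(designs))) {
    b <- designs$treat_b[i]; a <- designs$treat_a[i]
    if (b != reference) X[i, b] <- 1
    if (a != reference) X[i, a] <- X[i, a] - 1
  }
  X
}

#' Weighted least-squares consistency fit of design-level estimates
#'
#' Regresses the design-level direct log HRs on the consistency design
#' matrix (each design's contrast expressed through the basic parameters)
#' with inverse-variance weights. The residual
#' \eqn{Q = \sum_d w_d (y_d - \hat y_d)^2} measures design-by-treatment
#' inconsistency: it is exactly 0 when the design network has no
#' independent loops, and grows with direct-vs-indirect disagreement
#' around loops. The hat matrix \eqn{H = X (X'WX)^- X'W} (pseudo-inverse,
#' tolerance 1e-10) maps direct estimates to network estimates.
#'
#' @param designs data.frame from [design_estimates()].
#' @param reference reference treatment fixing the gauge.
#' @return List of class `consistency_fit`: `coef` (basic parameters),
#'   `fitted`, `resid`, `hat`, `Q`, `q_per_design`, `df`, `designs`.
#' @export
consistency_fit <- function(designs, reference = "TACE") {
  reference <- normalize_treatment(reference)
  g <- igraph::graph_from_edgelist(
    as.matrix(designs[c("treat_a", "treat_b")]), directed = FALSE)
  if (igraph::components(g)$no > 1)
    stop("design network is disconnected")
  X <- design_matrix(designs, reference)
  w <- 1 / designs$se^2
  M <- crossprod(X, X * w)
  G <- pinv(M, tol = 1e-10)
  coef <- drop(G %*% crossprod(X * w, designs$loghr))
  names(coef) <- colnames(X)
  H <- X %*% G %*% t(X * w)
  dimnames(H) <- list(designs$design, designs$design)
  fitted <- drop(H %*% designs$loghr)
  resid <- designs$loghr - fitted
  qpd <- w * resid^2
  names(qpd) <- designs$design
  sv <- svd(sqrt(w) * X)$d
  rank <- if (length(sv)) sum(sv > 1e-10 * max(sv)) else 0L
  structure(
    list(coef = coef, fitted = fitted, resid = resid, hat = H,
         Q = sum(qpd), q_per_design = qpd, df = nrow(designs) - rank,
         designs = designs, reference = reference),
    class = "consistency_fit"
  )
}

#' Net-heat contribution and inconsistency-detachment matrices
#'
#' The computed content of a net heat display. The contribution matrix is
#' built from the hat-matrix rows of the consistency fit: entry (r, c) is
#' the (normalized, non-negative) weight of design c's direct estimate in
#' design r's network estimate, so each row sums to 1 and a design's
#' self-contribution is at most 1. The change matrix holds, per column c,
#' the signed change in each remaining design's Q contribution when design
#' c's direct evidence is detached (removed and the consistency model
#' refitted): positive values (warm colours) mean detaching c reduces that
#' design's inconsistency, negative values (blue) mean it increases it.
#'
#' @param designs data.frame from [design_estimates()] (>= 2 designs).
#' @param reference reference treatment.
#' @return List of class `net_heat`: `contribution`, `change`, and `q`
#'   (class `q_decomposition`: `q_total`, `q_per_design`, `df`,
#'   `leave_one_out` = Q after detaching each design).
#' @export
net_heat <- function(designs, reference = "TACE") {
  if (nrow(designs) < 2) stop("need at least 2 designs")
  fit <- consistency_fit(designs, reference)
  n <- nrow(designs)
  labs <- designs$design

  contrib <- abs(fit$hat)
  rs <- rowSums(contrib)
  contrib <- contrib / ifelse(rs > 0, rs, 1)

  change <- matrix(0, n, n, dimnames = list(labs, labs))
  loo <- setNames(numeric(n), labs)
  for (c_i in seq_len(n)) {
    rest <- designs[-c_i, , drop = FALSE]
    # detaching may disconnect a treatment; keep the reference component
    gg <- igraph::graph_from_edgelist(
      as.matrix(rest[c("treat_a", "treat_b")]), directed = FALSE)
    comp <- igraph::components(gg)
    if (!fit$reference %in% names(comp$membership)) { loo[c_i] <- 0; next }
    keep_t <- names(comp$membership)[
      comp$membership == comp$membership[[fit$reference]]]
    rest <- rest[rest$treat_a %in% keep_t & rest$treat_b %in% keep_t, ,
                 drop = FALSE]
    if (!nrow(rest)) { loo[c_i] <- 0; next }
    refit <- consistency_fit(rest, fit$reference)
    loo[c_i] <- refit$Q
    change[match(rest$design, labs), c_i] <-
      fit$q_per_design[rest$design] - refit$q_per_design
  }

  structure(
    list(contribution = contrib, change = change,
         q = structure(list(q_total = fit$Q,
                            q_per_design = fit$q_per_design,
                            df = fit$df, leave_one_out = loo),
                       class = "q_decomposition"),
         fit = fit),
    class = "net_heat"
  )
}

#' @export
print.q_decomposition <- function(x, ...) {
  cat("Design inconsistency Q =", round(x$q_total, 4),
      "on", x$df, "df\n")
  cat("largest per-design contributions:\n")
  top <- sort(x$q_per_design, decreasing = TRUE)
  print(round(utils::head(top, 5), 4))
  invisible(x)
}
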