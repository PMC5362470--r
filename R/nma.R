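#' Model settings for the Bayesian network meta-analysis
#'
#' The consistency model expresses every contrast through basic parameters
#' \eqn{d_k}, the log hazard ratio of treatment k versus the reference
#' (TACE, the anchor of the evidence base); \eqn{d_{ref} \equiv 0}. Priors
#' are vague at the scale of plausible hazard ratios: \eqn{d_k \sim N(0,
#' prior\_sd^2)} and, under the random-effects model, a uniform prior on the
#' between-trial standard deviation \eqn{\tau} of the trial-specific
#' contrasts.
#'
#' @param reference reference treatment code.
#' @param prior_sd prior standard deviation of each basic parameter on the
#'   log-HR scale.
#' @param tau_upper upper bound of the uniform prior on tau.
#' @param method `"random"` (heterogeneity estimated) or `"fixed"`
#'   (tau fixed at 0, the common-effect model).
#' @param chains number of MCMC chains (>= 2).
#' @param iter posterior iterations per chain after burn-in (>= 1000).
#' @param burnin burn-in iterations per chain (adaptation happens here).
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @return A list of class `nma_spec`.
#' @export
nma_spec <- function(reference = "TACE", prior_sd = 10, tau_upper = 5,
                     method = c("random", "fixed"), chains = 4,
                     iter = 20000, burnin = 5000, seed = 1) {
  method <- match.arg(method)
  if (tau_upper <= 0) stop("tau_upper must be > 0")
  if (chains < 2) stop("need at least 2 chains")
  if (iter < 1000) stop("need at least 1000 posterior iterations")
  if (prior_sd <= 0) stop("prior_sd must be > 0")
  structure(
    list(reference = normalize_treatment(reference), prior_sd = prior_sd,
         tau_upper = tau_upper, method = method, chains = as.integer(chains),
         iter = as.integer(iter), burnin = as.integer(burnin),
         seed = as.integer(seed)),
    class = "nma_spec"
  )
}

#' Assemble the contrast-based NMA likelihood
#'
#' Builds the internal model object from a baseline-contrast table (as
#' produced by [network_contrasts()], or hand-made: one row per contrast
#' with columns `trial`, `treat_a`, `treat_b`, `loghr`, `se`, and
#' `var_base` for multi-arm trials). Each trial is one multivariate-normal
#' likelihood block: the observed contrast vector is centred on the
#' design-mapped basic parameters with covariance equal to the sampling
#' covariance (off-diagonals = shared baseline-arm variance) plus
#' \eqn{\tau^2} times a matrix with unit diagonal and 1/2 off-diagonals
#' (the exchangeable random-effects structure for contrasts sharing a
#' baseline).
#'
#' @param contrasts contrast table (see above).
#' @param spec an [nma_spec()].
#' @return A list of class `nma_model` with the design matrices and
#'   covariance blocks; `params` names the basic parameters (all treatments
#'   except the reference).
#' @export
build_nma_model <- function(contrasts, spec = nma_spec()) {
  need <- c("trial", "treat_a", "treat_b", "loghr", "se")
  miss <- setdiff(need, names(contrasts))
  if (length(miss))
    stop("contrast table is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(contrasts)) stop("empty contrast table")
  if (is.null(contrasts$var_base)) contrasts$var_base <- 0

  treatments <- sort(unique(c(contrasts$treat_a, contrasts$treat_b)))
  ref <- spec$reference
  if (!ref %in% treatments)
    stop("reference ", ref, " does not appear in the contrasts")

  g <- igraph::graph_from_edgelist(
    as.matrix(contrasts[c("treat_a", "treat_b")]), directed = FALSE)
  if (igraph::components(g)$no > 1)
    stop("evidence network is disconnected; restrict to the component ",
         "around the reference first (see connected_component())")

  params <- setdiff(treatments, ref)
  p <- length(params)
  xrow <- function(a, b) {
    r <- numeric(p)
    if (b != ref) r[match(b, params)] <- 1
    if (a != ref) r[match(a, params)] <- r[match(a, params)] - 1
    r
  }

  blocks <- split(seq_len(nrow(contrasts)), contrasts$trial)
  uni <- list(X = NULL, y = numeric(0), s2 = numeric(0))
  multi <- list()
  for (idx in blocks) {
    m <- length(idx)
    X <- t(vapply(idx, function(i)
      xrow(contrasts$treat_a[i], contrasts$treat_b[i]), numeric(p)))
    if (m == 1) {
      uni$X <- rbind(uni$X, X)
      uni$y <- c(uni$y, contrasts$loghr[idx])
      uni$s2 <- c(uni$s2, contrasts$se[idx]^2)
    } else {
      S <- matrix(contrasts$var_base[idx][1], m, m)
      diag(S) <- contrasts$se[idx]^2
      P <- matrix(0.5, m, m); diag(P) <- 1
      multi[[length(multi) + 1]] <-
        list(X = X, y = contrasts$loghr[idx], S = S, P = P)
    }
  }
  if (is.null(uni$X)) uni$X <- matrix(0, 0, p)

  structure(
    list(params = params, reference = ref, treatments = treatments,
         uni = uni, multi = multi, n_trials = length(blocks),
         n_contrasts = nrow(contrasts)),
    class = "nma_model"
  )
}

# log-likelihood of all blocks at (d, tau)
nma_loglik <- function(model, d, tau) {
  ll <- 0
  if (length(model$uni$y)) {
    v <- model$uni$s2 + tau^2
    r <- model$uni$y - drop(model$uni$X %*% d)
    ll <- ll - 0.5 * sum(log(2 * pi * v) + r^2 / v)
  }
  for (b in model$multi) {
    V <- b$S + tau^2 * b$P
    U <- chol(V)
    r <- b$y - drop(b$X %*% d)
    z <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(U))) +
                        sum(z^2))
  }
  ll
}

# conjugate joint draw of d | tau: precision = prior + sum X' V^-1 X
draw_d <- function(model, tau, prior_prec) {
  p <- length(model$params)
  A <- diag(prior_prec, p)
  bvec <- numeric(p)
  if (length(model$uni$y)) {
    w <- 1 / (model$uni$s2 + tau^2)
    Xw <- model$uni$X * w
    A <- A + crossprod(model$uni$X, Xw)
    bvec <- bvec + drop(crossprod(Xw, model$uni$y))
  }
  for (b in model$multi) {
    Vi <- chol2inv(chol(b$S + tau^2 * b$P))
    A <- A + t(b$X) %*% Vi %*% b$X
    bvec <- bvec + drop(t(b$X) %*% Vi %*% b$y)
  }
  U <- chol(A)
  mean_d <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
  mean_d + backsolve(U, rnorm(p))
}

run_chain <- function(model, spec, chain_seed) {
  set.seed(chain_seed)
  p <- length(model$params)
  prior_prec <- 1 / spec$prior_sd^2
  random <- spec$method == "random"
  tau <- if (random) min(0.1, spec$tau_upper / 2) else 0
  d <- numeric(p)
  scale <- 0.1
  n_keep <- spec$iter
  total <- spec$burnin + n_keep
  draws <- matrix(NA_real_, n_keep, p)
  tau_draws <- numeric(n_keep)
  acc <- 0; att <- 0

  for (i in seq_len(total)) {
    d <- draw_d(model, tau, prior_prec)
    if (random) {
      ll0 <- nma_loglik(model, d, tau)
      if (!is.finite(ll0)) stop("non-finite likelihood in MCMC")
      prop <- tau + rnorm(1, 0, scale)
      alpha <- 0
      if (prop >= 0 && prop <= spec$tau_upper) {
        ll1 <- nma_loglik(model, d, prop)
        alpha <- min(1, exp(ll1 - ll0))
        if (runif(1) < alpha) tau <- prop
      }
      if (i <= spec$burnin) {
        # Robbins-Monro adaptation toward 0.44 acceptance, burn-in only
        scale <- scale * exp((alpha - 0.44) * min(0.25, 5 / sqrt(i)))
        scale <- min(max(scale, 1e-4), spec$tau_upper)
      } else {
        att <- att + 1; acc <- acc + alpha
      }
    }
    if (i > spec$burnin) {
      draws[i - spec$burnin, ] <- d
      tau_draws[i - spec$burnin] <- tau
    }
  }
  if (random && att > 0 && acc / att < 1e-3)
    stop("tau sampler: acceptance collapsed to zero after adaptation")
  list(d = draws, tau = tau_draws,
       accept = if (att > 0) acc / att else NA_real_)
}

split_rhat <- function(mat_by_chain) {
  # mat_by_chain: list of vectors (one per chain); split each in half
  halves <- unlist(lapply(mat_by_chain, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian network meta-analysis by MCMC
#'
#' Metropolis-within-Gibbs sampling of the consistency model: the basic
#' parameters d are updated jointly from their exact multivariate-normal
#' full conditional (the model is linear-Gaussian given tau), and tau takes
#' a random-walk Metropolis step whose scale adapts toward 44% acceptance
#' during burn-in only, keeping the post-burn-in kernel fixed. Chains are
#' seeded deterministically from `spec$seed`, so a repeated call gives
#' bit-identical draws. Convergence is summarized by the split potential
#' scale reduction factor; values above 1.05 trigger a warning.
#'
#' @param model an `nma_model` from [build_nma_model()], or a contrast
#'   table, which is passed through [build_nma_model()] first.
#' @param spec an [nma_spec()].
#' @return An object of class `nma_posterior`: `draws` (matrix, one column
#'   per basic parameter), `tau` (vector), `chain` (chain index per draw),
#'   `rhat`, `accept_tau`, plus the model dimensions and the spec echo.
#' @export
run_nma <- function(model, spec = nma_spec()) {
  if (!inherits(model, "nma_model")) model <- build_nma_model(model, spec)
  chains <- lapply(seq_len(spec$chains), function(ch) {
    run_chain(model, spec,
              chain_seed = as.integer((as.numeric(spec$seed) * 1009 + ch) %%
                                        2147483629))
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "d"))
  colnames(draws) <- model$params
  tau <- unlist(lapply(chains, `[[`, "tau"))
  chain_id <- rep(seq_len(spec$chains), each = spec$iter)

  rhat <- vapply(seq_along(model$params), function(j)
    split_rhat(lapply(chains, function(c) c$d[, j])), 0)
  names(rhat) <- model$params
  if (spec$method == "random")
    rhat <- c(rhat, tau = split_rhat(lapply(chains, `[[`, "tau")))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("potential scale reduction above 1.05 for: ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "))

  structure(
    list(draws = draws, tau = tau, chain = chain_id, rhat = rhat,
         accept_tau = mean(vapply(chains, `[[`, 0, "accept")),
         params = model$params, reference = model$reference,
         treatments = model$treatments, spec = spec),
    class = "nma_posterior"
  )
}

#' One-call network meta-analysis of an evidence network
#'
#' Convenience wrapper: restricts the network to the connected component
#' around the reference at the horizon, extracts baseline contrasts, and
#' runs the sampler.
#'
#' @param net an `evidence_network` with survivor columns.
#' @param horizon outcome year 1..4.
#' @param spec an [nma_spec()].
#' @return An `nma_posterior`.
#' @export
nma <- function(net, horizon = 1L, spec = nma_spec()) {
  sub <- connected_component(net, horizon, spec$reference)
  run_nma(network_contrasts(sub, horizon), spec)
}

#' @export
print.nma_posterior <- function(x, ...) {
  cat("NMA posterior:", length(x$params), "basic parameters vs",
      x$reference, "|", nrow(x$draws), "draws in",
      x$spec$chains, "chains\n")
  cat("  max split R-hat:", round(max(x$rhat), 4), "\n")
  if (x$spec$method == "random")
    cat("  tau posterior median:", round(median(x$tau), 4), "\n")
  invisible(x)
}

#' @export
summary.nma_posterior <- function(object, ...) {
  qs <- function(x) c(mean = mean(x), median = median(x),
                      lo = unname(quantile(x, 0.025)),
                      hi = unname(quantile(x, 0.975)))
  tab <- t(apply(object$draws, 2, qs))
  if (object$spec$method == "random")
    tab <- rbind(tab, tau = qs(object$tau))
  cbind(as.data.frame(tab), rhat = object$rhat[rownames(tab)])
}

# posterior draws including the reference column (identically 0)
full_draws <- function(post) {
  d <- cbind(post$draws, 0)
  colnames(d) <- c(post$params, post$reference)
  d[, sort(colnames(d)), drop = FALSE]
}

#' League table of all pairwise hazard ratios
#'
#' Per-draw relative effects are formed from the basic parameters (so the
#' consistency identity holds exactly in every draw) and summarized by the
#' posterior median and 2.5/97.5 percentiles. Cell (row, column) is the
#' hazard ratio of the row treatment versus the column treatment; values
#' below 1 favour the row treatment. Medians satisfy reciprocal symmetry:
#' cell(a,b) * cell(b,a) = 1.
#'
#' @param post an `nma_posterior`.
#' @return A list of class `league_table` with matrices `hr`, `lo`, `hi`.
#' @export
league_table <- function(post) {
  d <- full_draws(post)
  tts <- colnames(d)
  k <- length(tts)
  hr <- lo <- hi <- matrix(1, k, k, dimnames = list(tts, tts))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    x <- d[, i] - d[, j]
    hr[i, j] <- exp(median(x))
    lo[i, j] <- exp(quantile(x, 0.025))
    hi[i, j] <- exp(quantile(x, 0.975))
  }
  structure(list(hr = hr, lo = lo, hi = hi, reference = post$reference),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  k <- ncol(x$hr)
  out <- matrix("", k, k, dimnames = dimnames(x$hr))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- if (i == j) "." else
      sprintf("%.*f (%.*f, %.*f)", digits, x$hr[i, j],
              digits, x$lo[i, j], digits, x$hi[i, j])
  cat("League table (row vs column hazard ratio; <1 favours row)\n")
  print(out, quote = FALSE)
  invisible(x)
}
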