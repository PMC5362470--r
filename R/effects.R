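#' Continuity correction for boundary survival counts
#'
#' A survivor count of 0 or of `at_risk` makes the log cumulative hazard
#' infinite; such arms receive the standard correction of adding 0.5 to the
#' survivor count and 1.0 to the number at risk. Interior counts are
#' returned unchanged.
#'
#' @param survivors survivor count at the horizon.
#' @param at_risk number of patients at risk (enrolled).
#' @return A list with `survivors`, `at_risk`, and logical `corrected`.
#' @export
continuity_correct <- function(survivors, at_risk) {
  if (at_risk < 1 || survivors < 0 || survivors > at_risk)
    stop("need 0 <= survivors <= at_risk and at_risk >= 1")
  if (survivors == 0 || survivors == at_risk)
    list(survivors = survivors + 0.5, at_risk = at_risk + 1, corrected = TRUE)
  else
    list(survivors = survivors, at_risk = at_risk, corrected = FALSE)
}

# per-arm pieces of the cloglog transform: log cumulative hazard and its
# delta-method variance. S = s/n, H = -log S,
# Var(log H) = (1 - S) / (n * S * log(S)^2).
arm_loghaz <- function(survivors, at_risk) {
  cc <- continuity_correct(survivors, at_risk)
  S <- cc$survivors / cc$at_risk
  if (S <= 0 || S >= 1)
    stop("degenerate arm: survival proportion ", signif(S, 3),
         " outside (0,1) after continuity correction")
  list(
    log_cumhaz = log(-log(S)),
    var = (1 - S) / (cc$at_risk * S * log(S)^2),
    corrected = cc$corrected
  )
}

#' Log hazard ratio from two arms' survival proportions
#'
#' Reconstructs an aggregate-data log hazard ratio at a yearly horizon via
#' the complementary log-log transform: with survival proportion
#' \eqn{S = s/n} and cumulative hazard \eqn{H = -\ln S}, the log HR of arm a
#' versus arm b is \eqn{\ln H_a - \ln H_b}, assuming proportional hazards up
#' to the horizon. The delta-method variance per arm is
#' \eqn{(1-S) / (n S (\ln S)^2)}; the two arms' variances add.
#'
#' HR < 1 means arm a has the lower hazard (better survival).
#'
#' @param surv_a,surv_b lists with `survivors` and `at_risk` (see
#'   [survival_record()]).
#' @param horizon outcome year, carried through to the estimate.
#' @return A list of class `loghr_estimate`: `loghr`, `se`, `var_a`, `var_b`,
#'   `horizon`, `corrected`.
#' @examples
#' a <- survival_record(25, 100)  # S = 0.25
#' b <- survival_record(50, 100)  # S = 0.50
#' cloglog_loghr(a, b, horizon = 1)$loghr  # log(2)
#' @export
cloglog_loghr <- function(surv_a, surv_b, horizon = 1L) {
  if (!is.null(surv_a$horizon) && !is.null(surv_b$horizon) &&
      !identical(surv_a$horizon, surv_b$horizon))
    stop("mismatched horizons between arms")
  la <- arm_loghaz(surv_a$survivors, surv_a$at_risk)
  lb <- arm_loghaz(surv_b$survivors, surv_b$at_risk)
  structure(
    list(
      loghr = la$log_cumhaz - lb$log_cumhaz,
      se = sqrt(la$var + lb$var),
      var_a = la$var,
      var_b = lb$var,
      horizon = as.integer(horizon),
      corrected = la$corrected || lb$corrected
    ),
    class = "loghr_estimate"
  )
}

#' A per-arm survival record
#'
#' @param survivors survivor count at the horizon.
#' @param at_risk patients at risk.
#' @param horizon optional outcome year 1..4.
#' @export
survival_record <- function(survivors, at_risk, horizon = NULL) {
  if (at_risk < 1 || survivors < 0 || survivors > at_risk)
    stop("need 0 <= survivors <= at_risk and at_risk >= 1")
  list(survivors = survivors, at_risk = at_risk, horizon = horizon)
}

#' Baseline contrasts with covariance for one trial
#'
#' Converts a trial's arms at one horizon into log-HR contrasts against a
#' baseline arm. For multi-arm trials the contrasts share the baseline arm,
#' so their sampling covariance has the baseline arm's log-cumulative-hazard
#' variance on the off-diagonal.
#'
#' @param net an `evidence_network` whose arms carry survivor columns
#'   `s1`..`s4`.
#' @param article_id,subtrial identify the trial.
#' @param horizon outcome year 1..4.
#' @param baseline baseline treatment code; default is the lexicographically
#'   smallest treatment in the trial.
#' @return A list of class `contrast_set`: `contrasts` (data.frame with
#'   `treat_a` = baseline, `treat_b`, `loghr` of b vs a, `se`), `cov`
#'   (covariance matrix), `baseline`, `horizon`.
#' @export
trial_contrasts <- function(net, article_id, subtrial = 1L, horizon = 1L,
                            baseline = NULL) {
  check_horizon(horizon)
  arms <- trial_arms(net, article_id, subtrial)
  if (!nrow(arms))
    stop("no arms for trial ", article_id, "/", subtrial)
  scol <- paste0("s", horizon)
  if (!scol %in% names(arms) || anyNA(arms[[scol]]))
    stop("trial ", article_id, "/", subtrial,
         " has no survivor counts at year ", horizon)
  tr_row <- network_trials(net)
  oc <- tr_row$outcomes[tr_row$article_id == article_id &
                        tr_row$subtrial == subtrial]
  if (!length(oc) || !trial_reports(oc, horizon))
    stop("trial ", article_id, "/", subtrial,
         " does not report outcome year ", horizon)

  arms <- arms[order(arms$treatment, arms$arm_id), , drop = FALSE]
  if (is.null(baseline)) baseline <- arms$treatment[1]
  if (!baseline %in% arms$treatment)
    stop("baseline ", baseline, " is not an arm of the trial")
  ib <- which(arms$treatment == baseline)[1]

  hb <- arm_loghaz(arms[[scol]][ib], arms$n_enrolled[ib])
  others <- setdiff(seq_len(nrow(arms)), ib)
  est <- lapply(others, function(i) {
    hi <- arm_loghaz(arms[[scol]][i], arms$n_enrolled[i])
    list(treat = arms$treatment[i],
         loghr = hi$log_cumhaz - hb$log_cumhaz,
         var = hi$var + hb$var)
  })
  k <- length(est)
  cov <- matrix(hb$var, k, k)
  diag(cov) <- vapply(est, `[[`, 0, "var")
  contrasts <- data.frame(
    treat_a = baseline,
    treat_b = vapply(est, `[[`, "", "treat"),
    loghr = vapply(est, `[[`, 0, "loghr"),
    se = sqrt(diag(cov)),
    stringsAsFactors = FALSE
  )
  structure(
    list(contrasts = contrasts, cov = cov, baseline = baseline,
         var_baseline = hb$var, horizon = as.integer(horizon),
         article_id = article_id, subtrial = subtrial),
    class = "contrast_set"
  )
}

#' All baseline contrasts of a network at one horizon
#'
#' One [trial_contrasts()] set per trial that reports the horizon and has
#' survivor counts, flattened into the contrast table consumed by the NMA
#' and the design-level machinery.
#'
#' @param net an `evidence_network` with survivor columns.
#' @param horizon outcome year 1..4.
#' @return data.frame with columns `trial` (article/subtrial key),
#'   `article_id`, `subtrial`, `treat_a` (trial baseline), `treat_b`,
#'   `loghr`, `se`, `var_base` (baseline-arm variance, the off-diagonal
#'   covariance of contrasts within a multi-arm trial), `horizon`.
#' @export
network_contrasts <- function(net, horizon = 1L) {
  check_horizon(horizon)
  tr <- network_trials(net)
  tr <- tr[trial_reports(tr$outcomes, horizon), , drop = FALSE]
  scol <- paste0("s", horizon)
  out <- list()
  for (i in seq_len(nrow(tr))) {
    arms <- trial_arms(net, tr$article_id[i], tr$subtrial[i])
    if (!scol %in% names(arms) || anyNA(arms[[scol]])) {
      message("network_contrasts: trial ", tr$article_id[i], "/",
              tr$subtrial[i], " has no survivor counts at year ", horizon,
              "; omitted")
      next
    }
    cs <- trial_contrasts(net, tr$article_id[i], tr$subtrial[i], horizon)
    df <- cs$contrasts
    df$trial <- paste0(tr$article_id[i], "/", tr$subtrial[i])
    df$article_id <- tr$article_id[i]
    df$subtrial <- tr$subtrial[i]
    df$var_base <- cs$var_baseline
    df$horizon <- as.integer(horizon)
    out[[i]] <- df
  }
  if (!length(out))
    return(data.frame(trial = character(0), article_id = character(0),
                      subtrial = integer(0), treat_a = character(0),
                      treat_b = character(0), loghr = numeric(0),
                      se = numeric(0), var_base = numeric(0),
                      horizon = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("trial", "article_id", "subtrial", "treat_a", "treat_b",
        "loghr", "se", "var_base", "horizon")]
}

#' Per-design head-to-head contrasts (one row per arm pair per trial)
#'
#' Unlike [network_contrasts()], which anchors every trial at one baseline
#' arm, this expands each trial into all of its arm pairs, giving the direct
#' evidence per design that the pairwise meta-analysis pools. Orientation is
#' alphabetical: `loghr` is the log HR of `treat_b` versus `treat_a` with
#' `treat_a < treat_b`.
#'
#' @inheritParams network_contrasts
#' @return data.frame with `trial`, `treat_a`, `treat_b`, `design`, `loghr`,
#'   `se`, `horizon`.
#' @export
pairwise_contrasts <- function(net, horizon = 1L) {
  check_horizon(horizon)
  tr <- network_trials(net)
  tr <- tr[trial_reports(tr$outcomes, horizon), , drop = FALSE]
  scol <- paste0("s", horizon)
  out <- list()
  for (i in seq_len(nrow(tr))) {
    arms <- trial_arms(net, tr$article_id[i], tr$subtrial[i])
    if (!scol %in% names(arms) || anyNA(arms[[scol]])) {
      message("pairwise_contrasts: trial ", tr$article_id[i], "/",
              tr$subtrial[i], " has no survivor counts at year ", horizon,
              "; omitted")
      next
    }
    arms <- arms[order(arms$treatment, arms$arm_id), , drop = FALSE]
    cmb <- utils::combn(nrow(arms), 2)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      if (arms$treatment[i1] == arms$treatment[i2]) next
      est <- cloglog_loghr(
        survival_record(arms[[scol]][i2], arms$n_enrolled[i2]),
        survival_record(arms[[scol]][i1], arms$n_enrolled[i1]),
        horizon
      )
      out[[length(out) + 1]] <- data.frame(
        trial = paste0(tr$article_id[i], "/", tr$subtrial[i]),
        treat_a = arms$treatment[i1],
        treat_b = arms$treatment[i2],
        design = design_key(arms$treatment[i1], arms$treatment[i2]),
        loghr = est$loghr,
        se = est$se,
        horizon = as.integer(horizon),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(trial = character(0), treat_a = character(0),
                      treat_b = character(0), design = character(0),
                      loghr = numeric(0), se = numeric(0),
                      horizon = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
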