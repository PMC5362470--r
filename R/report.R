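#' Published direct (head-to-head) hazard-ratio estimates
#'
#' The package bundles transcriptions of the published pairwise-pooled
#' direct hazard ratios that accompany the 42-article network, for the
#' 1- and 2-year horizons. Each row gives the pooled HR of `treat_col`
#' versus `treat_row` with its 95% interval; the log-scale standard error
#' is recovered from the interval width, `(log(hi) - log(lo)) / (2 * 1.96)`.
#' The result is a design-level contrast table directly consumable by
#' [build_nma_model()] or [consistency_fit()] (one pseudo-trial per design).
#'
#' One transcribed OS-2 interval (the PAI vs PEI design) does not bracket
#' its printed point estimate in the source; it is kept verbatim and only
#' its width is used.
#'
#' @param horizon 1 or 2.
#' @return data.frame with `trial`, `design`, `treat_a`, `treat_b`,
#'   `loghr` (of `treat_b` vs `treat_a`), `se`, `var_base`, `hr`, `lo`, `hi`.
#' @export
published_direct_estimates <- function(horizon = 1L) {
  if (!horizon %in% c(1L, 2L))
    stop("published direct estimates are packaged for horizons 1 and 2")
  f <- system.file("extdata", paste0("direct_pairwise_os", horizon, ".csv"),
                   package = "hccnma", mustWork = TRUE)
  raw <- read.csv(f, stringsAsFactors = FALSE)
  data.frame(
    trial = design_key(raw$treat_row, raw$treat_col),
    design = design_key(raw$treat_row, raw$treat_col),
    treat_a = raw$treat_row,
    treat_b = raw$treat_col,
    loghr = log(raw$hr),
    se = (log(raw$hi) - log(raw$lo)) / (2 * 1.96),
    var_base = 0,
    hr = raw$hr, lo = raw$lo, hi = raw$hi,
    stringsAsFactors = FALSE
  )
}

#' Descriptive report of an evidence network
#'
#' Computes and prints the baseline description of the evidence base:
#' patient totals per treatment, design count, two-/three-arm article
#' structure, and per-horizon outcome coverage.
#'
#' @param net an `evidence_network`.
#' @param file optional path; when given the report is also written there
#'   as plain text.
#' @return Invisibly, a list with `totals`, `designs`, `structure`,
#'   `coverage`, `n_articles`.
#' @export
describe_network <- function(net, file = NULL) {
  tot <- patient_totals(net)
  des <- count_designs(net)
  str_ <- arm_structure(net)
  cov <- outcome_coverage(net)
  n_art <- length(unique(net$studies$article_id))

  lines <- c(
    sprintf("Articles: %d (%d two-arm, %d three-arm)",
            n_art, str_$two_arm, str_$three_arm),
    sprintf("Patients: %d", tot$grand_total),
    sprintf("Designs with direct evidence: %d", des$n),
    "Patients per treatment:",
    sprintf("  %-10s %5d (%.2f%%)", names(tot$by_treatment),
            tot$by_treatment, tot$percent),
    sprintf("Articles reporting OS-%d: %d", 1:4, cov)
  )
  cat(lines, sep = "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(list(totals = tot, designs = des, structure = str_,
                 coverage = cov, n_articles = n_art))
}

write_league_csv <- function(lt, path) {
  k <- ncol(lt$hr)
  out <- matrix("", k, k, dimnames = dimnames(lt$hr))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- if (i == j) "1" else
      sprintf("%.4f (%.4f, %.4f)", lt$hr[i, j], lt$lo[i, j], lt$hi[i, j])
  df <- data.frame(treatment = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("# cell = HR of row treatment vs column treatment; HR < 1 favours the row", con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full analysis chain and write its artifacts
#'
#' For each requested horizon: restrict to the connected component around
#' the reference, extract contrasts, pool every design pairwise, fit the
#' Bayesian NMA, rank by SUCRA, and decompose design inconsistency. One
#' output set per horizon is written under `outdir`
#' (`pairwise_osH.csv`, `league_osH.csv`, `sucra_osH.csv`,
#' `netheat_contribution_osH.csv`, `netheat_change_osH.csv`,
#' `posterior_osH.json`) plus a `metadata.json` echoing seeds and settings,
#' sufficient to reproduce every file bit-for-bit.
#'
#' @param net an `evidence_network` with survivor columns.
#' @param horizons outcome years to analyze.
#' @param outdir output directory (created if needed).
#' @param spec an [nma_spec()].
#' @return Invisibly, a named list (per horizon) with the in-memory
#'   results: `pairwise`, `posterior`, `league`, `sucra`, `netheat`.
#' @export
full_run <- function(net, horizons = 1:4, outdir = tempdir(),
                     spec = nma_spec()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (h in horizons) {
    sub <- connected_component(net, h, spec$reference)
    pw <- pool_designs(sub, h, model = "random")
    write.csv(pw, file.path(outdir, sprintf("pairwise_os%d.csv", h)),
              row.names = FALSE)

    post <- run_nma(network_contrasts(sub, h), spec)
    lt <- league_table(post)
    write_league_csv(lt, file.path(outdir, sprintf("league_os%d.csv", h)))

    rp <- rank_probabilities(post)
    su <- sucra(rp)
    su_out <- cbind(su, as.data.frame(unclass(rp)[su$treatment, , drop = FALSE]))
    write.csv(su_out, file.path(outdir, sprintf("sucra_os%d.csv", h)),
              row.names = FALSE)

    de <- design_estimates(sub, h)
    nh <- net_heat(de, spec$reference)
    write.csv(as.data.frame(nh$contribution),
              file.path(outdir, sprintf("netheat_contribution_os%d.csv", h)))
    write.csv(as.data.frame(nh$change),
              file.path(outdir, sprintf("netheat_change_os%d.csv", h)))

    sm <- summary(post)
    jsonlite::write_json(
      list(horizon = h, reference = post$reference,
           parameters = cbind(parameter = rownames(sm), sm),
           q_total = nh$q$q_total, q_df = nh$q$df,
           seed = spec$seed, method = spec$method),
      file.path(outdir, sprintf("posterior_os%d.json", h)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    results[[paste0("os", h)]] <-
      list(pairwise = pw, posterior = post, league = lt, sucra = su,
           netheat = nh)
  }
  jsonlite::write_json(
    list(seed = spec$seed, chains = spec$chains, iter = spec$iter,
         burnin = spec$burnin, method = spec$method,
         prior_sd = spec$prior_sd, tau_upper = spec$tau_upper,
         reference = spec$reference, horizons = as.integer(horizons),
         package_version = as.character(utils::packageVersion("hccnma"))),
    file.path(outdir, "metadata.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(results)
}
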