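#' @importFrom stats median quantile rnorm runif rbinom setNames sd var
#' @importFrom utils read.csv write.csv
NULL

HCC_TREATMENTS <- c(
  "TACE", "TACE+EBRT", "TACE+HIFU", "TACE+PEI", "TACE+RFA", "TACE+RT",
  "TACE+SOR", "TARE-90Y", "DEB-TACE", "PAI", "PEI", "RFA", "RT"
)

normalize_treatment <- function(x) {
  x <- toupper(trimws(x))
  gsub("\\s*\\+\\s*", "+", x)
}

#' Build an evidence network from raw comparison rows and a canonical arms table
#'
#' An evidence network is the data structure underlying every stage of the
#' analysis: a set of treatments (nodes), a roster of randomized trials whose
#' arms connect those nodes, and per-article flags saying which of the yearly
#' overall-survival horizons (OS-1..OS-4) each article reports.
#'
#' Two tables define a network. `studies` holds one row per published
#' comparison (multi-arm articles print one sub-row per treatment pair), and
#' `arms` holds each physical patient group exactly once. Multi-arm articles
#' therefore contribute two or three arm rows even though they print three
#' comparison sub-rows, and every patient is counted once. Articles that
#' randomized the same treatment pair twice with disjoint patients carry a
#' `subtrial` index in the arms table; each subtrial is an independent trial
#' statistically while the article remains the counting unit descriptively.
#'
#' The constructor cross-validates the two tables: every comparison row must be
#' reconstructable from the arms of one subtrial of its article (same two
#' treatments with the same sizes), and any disagreement is an error.
#'
#' @param studies data.frame with columns `article_id`, `trial_label`,
#'   `region`, `year`, `treatment_1`, `treatment_2`, `size_1`, `size_2`,
#'   `outcomes` (a string over "1234", e.g. `"123"`).
#' @param arms data.frame with columns `article_id`, `arm_id`, `treatment`,
#'   `n_enrolled`, optionally `subtrial` (defaults to 1) and survivor-count
#'   columns `s1`..`s4`.
#' @return An object of class `evidence_network`.
#' @seealso [read_evidence_network()], [hcc_network()]
#' @export
evidence_network <- function(studies, arms) {
  req_s <- c("article_id", "trial_label", "treatment_1", "treatment_2",
             "size_1", "size_2", "outcomes")
  req_a <- c("article_id", "arm_id", "treatment", "n_enrolled")
  miss <- setdiff(req_s, names(studies))
  if (length(miss))
    stop("studies table is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(req_a, names(arms))
  if (length(miss))
    stop("arms table is missing columns: ", paste(miss, collapse = ", "))

  studies$treatment_1 <- normalize_treatment(studies$treatment_1)
  studies$treatment_2 <- normalize_treatment(studies$treatment_2)
  arms$treatment <- normalize_treatment(arms$treatment)
  studies$outcomes <- as.character(studies$outcomes)
  if (is.null(arms$subtrial)) arms$subtrial <- 1L

  if (anyDuplicated(arms$arm_id))
    stop("duplicated arm_id in arms table")
  if (any(arms$n_enrolled < 1 | arms$n_enrolled != round(arms$n_enrolled)))
    stop("n_enrolled must be a positive integer for every arm")
  bad <- !grepl("^[1234]+$", studies$outcomes)
  if (any(bad))
    stop("malformed outcomes string in rows: ",
         paste(studies$trial_label[bad], collapse = ", "))

  surv_cols <- intersect(paste0("s", 1:4), names(arms))
  if (length(surv_cols)) {
    sm <- as.matrix(arms[surv_cols])
    if (any(sm < 0 | sm > arms$n_enrolled, na.rm = TRUE))
      stop("survivor counts must lie in [0, n_enrolled]")
    if (ncol(sm) > 1) {
      d <- t(apply(sm, 1, diff))
      if (any(d > 1e-9, na.rm = TRUE))
        stop("survivor counts must be non-increasing across years")
    }
  }

  # reconstruct each printed comparison row from the canonical arms
  studies$subtrial <- NA_integer_
  for (i in seq_len(nrow(studies))) {
    a <- arms[arms$article_id == studies$article_id[i], , drop = FALSE]
    if (!nrow(a))
      stop("no arms found for article ", studies$article_id[i])
    found <- FALSE
    for (st in sort(unique(a$subtrial))) {
      ast <- a[a$subtrial == st, , drop = FALSE]
      i1 <- which(ast$treatment == studies$treatment_1[i] &
                  ast$n_enrolled == studies$size_1[i])
      i2 <- which(ast$treatment == studies$treatment_2[i] &
                  ast$n_enrolled == studies$size_2[i])
      ok <- any(outer(i1, i2, function(x, y) x != y))
      if (ok) { studies$subtrial[i] <- st; found <- TRUE; break }
    }
    if (!found)
      stop("comparison row '", studies$trial_label[i],
           "' cannot be reconstructed from the arms table ",
           "(treatment/size mismatch)")
  }

  key <- paste(arms$article_id, arms$subtrial, sep = "\r")
  for (k in unique(key)) {
    tr <- arms$treatment[key == k]
    if (length(unique(tr)) < 2)
      stop("trial ", sub("\r", "/", k),
           " has fewer than 2 distinct treatments")
  }

  net <- structure(
    list(
      studies = studies,
      arms = arms,
      treatments = sort(unique(arms$treatment)),
      horizon = NULL
    ),
    class = "evidence_network"
  )
  net
}

#' Read an evidence network from the two-file CSV schema
#'
#' @param studies_file path to the raw comparison rows CSV.
#' @param arms_file path to the canonical arms CSV.
#' @return An `evidence_network`.
#' @export
read_evidence_network <- function(studies_file, arms_file) {
  for (f in c(studies_file, arms_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  studies <- read.csv(studies_file, colClasses = c(outcomes = "character"),
                      check.names = FALSE)
  arms <- read.csv(arms_file, check.names = FALSE)
  evidence_network(studies, arms)
}

#' The packaged 42-article HCC evidence network
#'
#' Loads the hand-transcribed network of 42 randomized trials comparing 13
#' minimally invasive therapies for unresectable hepatocellular carcinoma:
#' 38 two-arm and 4 three-arm articles, 5,666 patients, 16 head-to-head
#' designs, with per-article flags for the four yearly overall-survival
#' horizons. Survivor counts are not part of the fixture (the source trials'
#' per-horizon survival proportions are not republished here), so this network
#' supports the descriptive and structural operations; effect extraction
#' requires survivor columns, as produced by [simulate_network()] or supplied
#' in user data.
#'
#' @return An `evidence_network` with 13 treatments and 42 articles.
#' @export
hcc_network <- function() {
  net <- read_evidence_network(
    system.file("extdata", "studies_raw.csv", package = "hccnma",
                mustWork = TRUE),
    system.file("extdata", "arms.csv", package = "hccnma", mustWork = TRUE)
  )
  if (!identical(sort(net$treatments), sort(HCC_TREATMENTS)))
    stop("packaged fixture is corrupt: unexpected treatment set")
  net
}

#' @export
print.evidence_network <- function(x, ...) {
  tot <- patient_totals(x)
  cat("Evidence network:",
      length(x$treatments), "treatments,",
      length(unique(x$studies$article_id)), "articles,",
      tot$grand_total, "patients\n")
  if (!is.null(x$horizon))
    cat("  restricted to outcome horizon OS-", x$horizon, "\n", sep = "")
  cat("  designs with direct evidence:", count_designs(x)$n, "\n")
  invisible(x)
}

# one row per statistical trial (article x subtrial); outcomes are the union
# over the trial's printed rows
network_trials <- function(net) {
  s <- net$studies
  key <- paste(s$article_id, s$subtrial, sep = "\r")
  idx <- !duplicated(key)
  out <- data.frame(
    article_id = s$article_id[idx],
    subtrial = s$subtrial[idx],
    stringsAsFactors = FALSE
  )
  out$outcomes <- vapply(which(idx), function(i) {
    rows <- s$outcomes[key == key[i]]
    paste(sort(unique(unlist(strsplit(rows, "")))), collapse = "")
  }, character(1))
  out
}

trial_arms <- function(net, article_id, subtrial = 1L) {
  a <- net$arms
  a[a$article_id == article_id & a$subtrial == subtrial, , drop = FALSE]
}

trial_reports <- function(outcomes, horizon) {
  grepl(as.character(horizon), outcomes, fixed = TRUE)
}

check_horizon <- function(horizon) {
  if (!is.null(horizon) &&
      (length(horizon) != 1 || !horizon %in% 1:4))
    stop("horizon must be a single year in 1..4")
  horizon
}

#' Patients enrolled per treatment
#'
#' Each canonical arm is counted exactly once, so the shared arms of
#' multi-arm articles are not double-counted even though they appear in
#' several printed comparison rows.
#'
#' @param net an `evidence_network`.
#' @return A list with `by_treatment` (named integer vector), `percent`
#'   (share of the grand total, in percent) and `grand_total`.
#' @export
patient_totals <- function(net) {
  by_tr <- tapply(net$arms$n_enrolled, net$arms$treatment, sum)
  by_tr <- by_tr[order(-by_tr, names(by_tr))]
  grand <- sum(net$arms$n_enrolled)
  list(
    by_treatment = by_tr,
    percent = 100 * by_tr / grand,
    grand_total = grand
  )
}

design_key <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = " vs ")
}

#' Designs (unordered treatment pairs) with direct evidence
#'
#' A design is a distinct unordered pair of treatments compared head-to-head
#' within at least one trial; a three-arm trial contributes all three of its
#' pairs. Trial duplication cannot change the count (set semantics).
#'
#' @param net an `evidence_network`.
#' @param horizon optional outcome year 1..4; only trials reporting that
#'   horizon contribute.
#' @return A list with `n` (the count) and `designs` (a sorted data.frame
#'   with columns `treat_a`, `treat_b`).
#' @export
count_designs <- function(net, horizon = NULL) {
  check_horizon(horizon)
  tr <- network_trials(net)
  if (!is.null(horizon))
    tr <- tr[trial_reports(tr$outcomes, horizon), , drop = FALSE]
  pairs <- character(0)
  for (i in seq_len(nrow(tr))) {
    arms <- trial_arms(net, tr$article_id[i], tr$subtrial[i])
    tts <- sort(unique(arms$treatment))
    if (length(tts) >= 2) {
      cmb <- utils::combn(tts, 2)
      pairs <- c(pairs, design_key(cmb[1, ], cmb[2, ]))
    }
  }
  pairs <- sort(unique(pairs))
  parts <- strsplit(pairs, " vs ", fixed = TRUE)
  list(
    n = length(pairs),
    designs = data.frame(
      treat_a = vapply(parts, `[`, "", 1),
      treat_b = vapply(parts, `[`, "", 2),
      stringsAsFactors = FALSE
    )
  )
}

#' Number of articles reporting each yearly survival outcome
#'
#' An article counts once per horizon regardless of how many comparison
#' sub-rows it prints.
#'
#' @param net an `evidence_network`.
#' @return Named integer vector over years "1".."4".
#' @export
outcome_coverage <- function(net) {
  s <- net$studies
  art <- tapply(s$outcomes, s$article_id, function(o)
    paste(sort(unique(unlist(strsplit(o, "")))), collapse = ""))
  vapply(as.character(1:4), function(y)
    sum(grepl(y, art, fixed = TRUE)), integer(1))
}

#' Two-arm and three-arm article counts
#'
#' Article arity is the number of distinct treatments across its canonical
#' arms; an article whose sub-rows repeat the same treatment pair with
#' disjoint patients is a two-arm article.
#'
#' @param net an `evidence_network`.
#' @return A list with `two_arm`, `three_arm`, and `arity` (named vector of
#'   distinct-treatment counts per article).
#' @export
arm_structure <- function(net) {
  arity <- tapply(net$arms$treatment, net$arms$article_id,
                  function(t) length(unique(t)))
  list(
    two_arm = sum(arity == 2),
    three_arm = sum(arity == 3),
    arity = arity
  )
}

#' Maximal connected subnetwork around a reference treatment
#'
#' Restricts the network to trials reporting the given horizon, then keeps
#' only the treatments connected (through direct comparisons) to the
#' reference. In the packaged network PAI's single article does not report
#' OS-4, so the 4-year network drops PAI and retains 12 treatments.
#'
#' @param net an `evidence_network`.
#' @param horizon outcome year 1..4.
#' @param reference treatment that must remain in the network.
#' @return An `evidence_network` restricted to the connected component; the
#'   `horizon` field is set and dropped treatments are reported via `message()`.
#' @export
connected_component <- function(net, horizon, reference = "TACE") {
  check_horizon(horizon)
  reference <- normalize_treatment(reference)
  tr <- network_trials(net)
  tr <- tr[trial_reports(tr$outcomes, horizon), , drop = FALSE]
  if (!nrow(tr))
    stop("no trials report outcome year ", horizon)

  edges <- character(0)
  trial_nodes <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    arms <- trial_arms(net, tr$article_id[i], tr$subtrial[i])
    tts <- sort(unique(arms$treatment))
    trial_nodes[[i]] <- tts
    cmb <- utils::combn(tts, 2)
    edges <- c(edges, rbind(cmb[1, ], cmb[2, ]))
  }
  nodes <- sort(unique(unlist(trial_nodes)))
  if (!reference %in% nodes)
    stop("reference treatment ", reference,
         " is not in any trial reporting year ", horizon)
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  keep <- names(comp$membership)[
    comp$membership == comp$membership[[reference]]]

  dropped <- setdiff(net$treatments, keep)
  if (length(dropped))
    message("connected_component: dropping ",
            paste(dropped, collapse = ", "),
            " (no path to ", reference, " at OS-", horizon, ")")

  in_comp <- vapply(trial_nodes, function(tt) all(tt %in% keep), logical(1))
  tr <- tr[in_comp, , drop = FALSE]
  skey <- paste(net$studies$article_id, net$studies$subtrial, sep = "\r")
  tkey <- paste(tr$article_id, tr$subtrial, sep = "\r")
  akey <- paste(net$arms$article_id, net$arms$subtrial, sep = "\r")

  sub <- net
  sub$studies <- net$studies[skey %in% tkey, , drop = FALSE]
  sub$arms <- net$arms[akey %in% tkey, , drop = FALSE]
  sub$treatments <- sort(unique(sub$arms$treatment))
  sub$horizon <- as.integer(horizon)
  sub
}
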