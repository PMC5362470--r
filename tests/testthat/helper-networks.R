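# toy-network builders shared across the suite

# a two-arm trial table: one study row + two arms, optional survivors
toy_two_arm <- function(article = "t1", ta = "A", tb = "B",
                        na = 10, nb = 20, sa = NULL, sb = NULL,
                        outcomes = "1") {
  studies <- data.frame(
    article_id = article, trial_label = article, region = "x", year = 2020,
    treatment_1 = ta, treatment_2 = tb, size_1 = na, size_2 = nb,
    outcomes = outcomes, stringsAsFactors = FALSE
  )
  arms <- data.frame(
    article_id = article,
    arm_id = paste0(article, ".", c(ta, tb)),
    subtrial = 1L, treatment = c(ta, tb), n_enrolled = c(na, nb),
    stringsAsFactors = FALSE
  )
  if (!is.null(sa)) { arms$s1 <- c(sa, sb) }
  list(studies = studies, arms = arms)
}

bind_toys <- function(...) {
  parts <- list(...)
  evidence_network(
    do.call(rbind, lapply(parts, `[[`, "studies")),
    do.call(rbind, lapply(parts, `[[`, "arms"))
  )
}

# the fixture, loaded once per test run
fixture_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- hcc_network()
    net
  }
})

# short sampler settings for unit tests (conjugate d-update mixes fast)
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(chains = 2, iter = 1500, burnin = 500, seed = 42)
  do.call(nma_spec, utils::modifyList(defaults, args))
}

# random connected design set over `k` treatments for property tests
random_design_set <- function(k = 5, extra = 3) {
  tts <- LETTERS[seq_len(k)]
  # spanning tree first, then extra random edges -> connected, maybe loops
  el <- cbind(tts[1], tts[-1])
  if (extra > 0) {
    more <- t(replicate(extra, sort(sample(tts, 2))))
    el <- rbind(el, more)
  }
  el <- unique(el)
  data.frame(
    design = hccnma:::design_key(el[, 1], el[, 2]),
    treat_a = pmin(el[, 1], el[, 2]),
    treat_b = pmax(el[, 1], el[, 2]),
    loghr = rnorm(nrow(el)),
    se = runif(nrow(el), 0.1, 0.5),
    k = 1L, stringsAsFactors = FALSE
  )
}
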