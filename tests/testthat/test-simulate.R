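small_config <- function(tau = 0.1, n = 100, seed = 1) {
  roster <- data.frame(
    article_id = c("s1", "s2", "s3", "s4"),
    treatments = c("A,B", "B,C", "A,C", "A,B,C"),
    n = paste(n, n, sep = ",")[1],
    outcomes = "1234", stringsAsFactors = FALSE
  )
  roster$n <- c(rep(paste(n, n, sep = ","), 3), paste(n, n, n, sep = ","))
  simulation_config(
    treatments = c("A", "B", "C"), d = c(B = -0.5, C = 0.3), tau = tau,
    baseline_survival = c(0.7, 0.5, 0.35, 0.25), roster = roster,
    reference = "A", seed = seed
  )
}

test_that("config validation enforces survival shape and connectivity", {
  expect_error(small_config(tau = -1), "tau")
  cfg <- small_config()
  expect_equal(unname(cfg$d["A"]), 0)

  bad <- data.frame(article_id = "s1", treatments = "A,B", n = "10,10",
                    outcomes = "1")
  expect_error(
    simulation_config(c("A", "B", "C"), c(B = 1, C = 1), 0.1,
                      c(0.6, 0.4), bad, reference = "A"),
    "connected")
  expect_error(
    simulation_config(c("A", "B"), c(B = 1), 0.1, c(0.4, 0.6), bad[0, ],
                      reference = "A"),
    "non-increasing")
})

test_that("simulation is deterministic and respects count invariants", {
  cfg <- small_config(seed = 33)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$network$arms, s2$network$arms)

  cfg2 <- small_config(seed = 34)
  expect_false(identical(simulate_network(cfg2)$network$arms,
                         s1$network$arms))

  a <- s1$network$arms
  sm <- as.matrix(a[paste0("s", 1:4)])
  expect_true(all(sm >= 0 & sm <= a$n_enrolled))
  expect_true(all(t(apply(sm, 1, diff)) <= 0))
})

test_that("huge arms recover the true effects (law of large numbers)", {
  cfg <- small_config(tau = 0, n = 1e6, seed = 5)
  sim <- simulate_network(cfg)
  ct <- network_contrasts(sim$network, 1)
  for (i in seq_len(nrow(ct))) {
    truth <- cfg$d[ct$treat_b[i]] - cfg$d[ct$treat_a[i]]
    expect_lt(abs(ct$loghr[i] - truth), 0.01)
  }
})

test_that("null effects give pooled estimates centred on zero", {
  roster <- do.call(rbind, replicate(12, data.frame(
    article_id = NA, treatments = "A,B", n = "400,400", outcomes = "1"),
    simplify = FALSE))
  roster$article_id <- paste0("n", 1:12)
  cfg <- simulation_config(c("A", "B"), c(B = 0), 0, c(0.6, 0.45, 0.3, 0.2),
                           roster, reference = "A", seed = 8)
  sim <- simulate_network(cfg)
  pw <- pool_designs(sim$network, 1, "fixed")
  expect_lt(abs(pw$loghr), 3 * pw$se)
  expect_lt(abs(pw$loghr), 0.15)
})

test_that("heterogeneity inflates between-trial spread monotonically", {
  spread <- vapply(c(0, 0.5), function(tau) {
    cfg <- small_config(tau = tau, n = 2000, seed = 13)
    # widen: many replicates of the same design
    roster <- do.call(rbind, replicate(15, data.frame(
      article_id = NA, treatments = "A,B", n = "2000,2000",
      outcomes = "1"), simplify = FALSE))
    roster$article_id <- paste0("h", 1:15)
    cfg <- simulation_config(c("A", "B"), c(B = -0.4), tau,
                             c(0.6, 0.4, 0.3, 0.2), roster,
                             reference = "A", seed = 13)
    ct <- simulate_network(cfg)
    sd(network_contrasts(ct$network, 1)$loghr)
  }, 0)
  expect_gt(spread[2], spread[1])
})

test_that("three-arm contrast draws share the baseline random effect", {
  # with tau large and n huge, the empirical covariance of the two
  # extracted contrasts across replicates approaches tau^2 / 2
  tau <- 0.6
  roster <- data.frame(article_id = "m1", treatments = "A,B,C",
                       n = "200000,200000,200000", outcomes = "1")
  draws <- t(vapply(1:500, function(r) {
    cfg <- simulation_config(c("A", "B", "C"), c(B = 0, C = 0), tau,
                             c(0.5, 0.4), roster, reference = "A",
                             seed = 5000 + r)
    ct <- network_contrasts(simulate_network(cfg)$network, 1)
    ct$loghr
  }, numeric(2)))
  expect_equal(cov(draws[, 1], draws[, 2]), tau^2 / 2, tolerance = 0.25)
  expect_equal(var(draws[, 1]), tau^2, tolerance = 0.25)
})

test_that("simulated networks round-trip through the CSV schema", {
  cfg <- small_config(seed = 55)
  sim <- simulate_network(cfg)
  sdir <- tempfile(); dir.create(sdir)
  write.csv(sim$network$studies, file.path(sdir, "studies_raw.csv"),
            row.names = FALSE)
  write.csv(sim$network$arms, file.path(sdir, "arms.csv"), row.names = FALSE)
  back <- read_evidence_network(file.path(sdir, "studies_raw.csv"),
                                file.path(sdir, "arms.csv"))
  expect_equal(patient_totals(back), patient_totals(sim$network))
  expect_equal(count_designs(back)$n, count_designs(sim$network)$n)
  expect_equal(network_contrasts(back, 2), network_contrasts(sim$network, 2))
})

test_that("the fixture scenario mirrors the packaged network topology", {
  cfg <- fixture_scenario(seed = 3)
  sim <- simulate_network(cfg)
  expect_equal(count_designs(sim$network)$n, 16)
  expect_length(sim$network$treatments, 13)
  # PAI still disconnects at OS-4
  expect_message(sub4 <- connected_component(sim$network, 4), "PAI")
  expect_length(sub4$treatments, 12)
  # arm sizes default to 100
  expect_true(all(sim$network$arms$n_enrolled == 100))
})
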