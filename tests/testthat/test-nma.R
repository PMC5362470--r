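one_design_table <- function(y, se) {
  data.frame(trial = paste0("t", seq_along(y)), treat_a = "TACE",
             treat_b = "RFA", loghr = y, se = se, var_base = 0,
             stringsAsFactors = FALSE)
}

test_that("model building maps contrasts to basic parameters", {
  ct <- one_design_table(0.5, 0.1)
  m <- build_nma_model(ct, quick_spec())
  expect_equal(m$params, "RFA")
  expect_equal(unname(m$uni$X), matrix(1, 1, 1))

  tri <- data.frame(
    trial = c("t1", "t2", "t3"), treat_a = c("A", "A", "B"),
    treat_b = c("B", "C", "C"), loghr = c(0.2, 0.5, 0.3), se = 0.1,
    var_base = 0, stringsAsFactors = FALSE
  )
  m2 <- build_nma_model(tri, quick_spec(reference = "A"))
  expect_equal(m2$params, c("B", "C"))
  expect_equal(unname(m2$uni$X),
               rbind(c(1, 0), c(0, 1), c(-1, 1)))
  expect_error(
    build_nma_model(tri, quick_spec(reference = "Z")), "reference")

  disc <- rbind(tri[1, ],
                data.frame(trial = "t9", treat_a = "X", treat_b = "Y",
                           loghr = 0, se = 0.1, var_base = 0))
  expect_error(build_nma_model(disc, quick_spec(reference = "A")),
               "disconnected")
})

test_that("fixture-shaped horizon-1 model has 12 basic parameters", {
  cfg <- fixture_scenario(seed = 2)
  sim <- simulate_network(cfg)
  ct <- suppressMessages(network_contrasts(sim$network, 1))
  m <- build_nma_model(ct, quick_spec())
  expect_length(m$params, 12)
  expect_false("TACE" %in% m$params)
})

test_that("single-contrast posterior matches the conjugate closed form", {
  post <- run_nma(one_design_table(0.5, 0.1),
                  quick_spec(method = "fixed", iter = 4000))
  expect_lt(abs(mean(post$draws) - 0.5), 0.02)
  expect_lt(abs(sd(post$draws) - 0.1) / 0.1, 0.10)
})

test_that("identical seeds give bit-identical draws", {
  ct <- one_design_table(c(0.4, 0.6), c(0.2, 0.2))
  sp <- quick_spec(seed = 99)
  p1 <- run_nma(ct, sp)
  p2 <- run_nma(ct, sp)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$tau, p2$tau)
  p3 <- run_nma(ct, quick_spec(seed = 100))
  expect_false(identical(p1$draws, p3$draws))
})

test_that("a consistent triangle with tiny errors is recovered to 3 decimals", {
  tri <- data.frame(
    trial = c("t1", "t2", "t3"), treat_a = c("A", "A", "B"),
    treat_b = c("B", "C", "C"), loghr = c(0.2, 0.5, 0.3), se = 0.002,
    var_base = 0, stringsAsFactors = FALSE
  )
  post <- run_nma(tri, quick_spec(reference = "A", method = "fixed",
                                  iter = 3000))
  med <- apply(post$draws, 2, median)
  expect_equal(unname(med[c("B", "C")]), c(0.2, 0.5), tolerance = 5e-4)
})

test_that("indirect-only estimation adds means and variances along a chain", {
  chain <- data.frame(
    trial = c("t1", "t2"), treat_a = c("A", "B"), treat_b = c("B", "C"),
    loghr = c(0.5, 0.3), se = c(0.1, 0.15), var_base = 0,
    stringsAsFactors = FALSE
  )
  post <- run_nma(chain, quick_spec(reference = "A", method = "fixed",
                                    iter = 6000))
  dC <- post$draws[, "C"]
  expect_lt(abs(mean(dC) - 0.8), 0.02)
  expect_lt(abs(var(dC) - (0.1^2 + 0.15^2)) / (0.1^2 + 0.15^2), 0.15)
})

test_that("consistency identity holds exactly in every draw", {
  tri <- data.frame(
    trial = c("t1", "t2", "t3"), treat_a = c("A", "A", "B"),
    treat_b = c("B", "C", "C"), loghr = c(0.1, 0.9, 0.4), se = 0.2,
    var_base = 0, stringsAsFactors = FALSE
  )
  post <- run_nma(tri, quick_spec(reference = "A"))
  d <- hccnma:::full_draws(post)
  # exact by construction; tolerance covers floating-point reassociation only
  expect_equal((d[, "C"] - d[, "A"]),
               (d[, "B"] - d[, "A"]) + (d[, "C"] - d[, "B"]),
               tolerance = 1e-13)
})

test_that("shrinking the effect prior drives estimates toward zero", {
  ct <- one_design_table(1.0, 0.2)
  wide <- run_nma(ct, quick_spec(method = "fixed"))
  narrow <- run_nma(ct, quick_spec(method = "fixed", prior_sd = 0.05))
  expect_lt(abs(mean(narrow$draws)), abs(mean(wide$draws)))
  expect_lt(abs(mean(narrow$draws)), 0.15)
})

test_that("league table has unit diagonal and reciprocal symmetry", {
  tri <- data.frame(
    trial = c("t1", "t2", "t3"), treat_a = c("A", "A", "B"),
    treat_b = c("B", "C", "C"), loghr = c(0.2, 0.7, 0.4), se = 0.25,
    var_base = 0, stringsAsFactors = FALSE
  )
  post <- run_nma(tri, quick_spec(reference = "A"))
  lt <- league_table(post)
  expect_equal(unname(diag(lt$hr)), rep(1, 3))
  for (i in 1:3) for (j in 1:3)
    expect_equal(lt$hr[i, j] * lt$hr[j, i], 1, tolerance = 1e-9)
  # interval endpoints bracket the median
  expect_true(all(lt$lo <= lt$hr & lt$hr <= lt$hi))
})

test_that("random-effects fit recovers heterogeneity on a big design", {
  # 12 trials of one design, true tau = 0.3: posterior tau should move
  # well away from 0 and the DL estimate should be in the same range
  set.seed(31)
  tau <- 0.3
  y <- rnorm(12, 0.4, sqrt(0.05^2 + tau^2))
  ct <- one_design_table(y, rep(0.05, 12))
  post <- run_nma(ct, quick_spec(iter = 4000))
  expect_gt(median(post$tau), 0.1)
  dl <- pool_dl(y, rep(0.05, 12))
  expect_equal(median(post$tau), sqrt(dl$tau2), tolerance = 0.5)
  expect_true(all(post$rhat < 1.1))
})

test_that("model spec validates its inputs", {
  expect_error(nma_spec(chains = 1), "chains")
  expect_error(nma_spec(iter = 10), "1000")
  expect_error(nma_spec(tau_upper = -1), "tau_upper")
  expect_error(nma_spec(prior_sd = 0), "prior_sd")
})
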