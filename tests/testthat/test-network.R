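test_that("fixture loads, validates, and reports the published structure", {
  net <- fixture_net()
  expect_s3_class(net, "evidence_network")
  expect_length(net$treatments, 13)
  expect_length(unique(net$studies$article_id), 42)

  tot <- patient_totals(net)
  expect_equal(tot$grand_total, 5666)
  expect_equal(unname(tot$by_treatment[["TACE"]]), 2392)
  expect_equal(unname(tot$by_treatment[["RFA"]]), 891)
  expect_equal(round(unname(tot$percent[["TACE"]]), 2), 42.22)
  # conservation: grand total equals sum of per-treatment totals
  expect_equal(sum(tot$by_treatment), tot$grand_total)
})

test_that("tampered fixture is rejected by cross-validation", {
  studies <- read.csv(system.file("extdata", "studies_raw.csv",
                                  package = "hccnma"),
                      colClasses = c(outcomes = "character"))
  arms <- read.csv(system.file("extdata", "arms.csv", package = "hccnma"))
  arms$n_enrolled[arms$arm_id == "peng2013.RFA"] <- 96  # disagree with row
  expect_error(evidence_network(studies, arms), "reconstruct")
})

test_that("degenerate inputs are rejected", {
  t1 <- toy_two_arm()
  bad <- t1
  bad$studies$outcomes <- "5"
  expect_error(bind_toys(bad), "outcomes")
  bad <- t1  # both tables agree but the trial compares A with itself
  bad$arms$treatment <- c("A", "A")
  bad$studies$treatment_2 <- "A"
  expect_error(bind_toys(bad), "distinct treatments")
})

test_that("design counting uses set semantics over treatment pairs", {
  net <- fixture_net()
  expect_equal(count_designs(net)$n, 16)
  expect_equal(count_designs(net, 1)$n, 16)
  expect_error(count_designs(net, 7), "horizon")

  # single two-arm trial
  toy <- bind_toys(toy_two_arm())
  expect_equal(count_designs(toy)$n, 1)
  tot <- patient_totals(toy)
  expect_equal(as.vector(tot$by_treatment[c("A", "B")]), c(10, 20))
  expect_equal(tot$grand_total, 30)

  # duplicating a trial row cannot change the design count
  dup <- bind_toys(toy_two_arm("t1"), toy_two_arm("t2"))
  expect_equal(count_designs(dup)$n, 1)
})

test_that("outcome coverage counts articles once per horizon", {
  net <- fixture_net()
  expect_equal(unname(outcome_coverage(net)), c(40, 41, 36, 23))

  # removing two articles that lack OS-1 leaves the OS-1 count unchanged
  keep <- !net$studies$article_id %in% c("shibata2009", "koda2001")
  keepa <- !net$arms$article_id %in% c("shibata2009", "koda2001")
  reduced <- evidence_network(net$studies[keep, ], net$arms[keepa, ])
  expect_equal(unname(outcome_coverage(reduced)[1]),
               unname(outcome_coverage(net)[1]))
  # but the OS-2/OS-3/OS-4 counts each drop by two
  expect_equal(unname(outcome_coverage(reduced)[2:4]),
               unname(outcome_coverage(net)[2:4]) - 2L)
})

test_that("article arity distinguishes true three-arm trials", {
  net <- fixture_net()
  st <- arm_structure(net)
  expect_equal(st$two_arm, 38)
  expect_equal(st$three_arm, 4)
  expect_setequal(names(st$arity)[st$arity == 3],
                  c("yang2009", "cheng2008", "cheng2001", "allgaier1998"))
  # lin2004 repeats one pair with disjoint patients: a two-arm article
  expect_equal(unname(st$arity[["lin2004"]]), 2)

  toy <- bind_toys(toy_two_arm())
  expect_equal(arm_structure(toy)$two_arm, 1)
  expect_equal(arm_structure(toy)$three_arm, 0)
})

test_that("connected component drops PAI at OS-4 and nothing at OS-1", {
  net <- fixture_net()
  expect_message(sub4 <- connected_component(net, 4), "PAI")
  expect_length(sub4$treatments, 12)
  expect_false("PAI" %in% sub4$treatments)
  expect_equal(sub4$horizon, 4L)

  sub1 <- connected_component(net, 1)
  expect_length(sub1$treatments, 13)

  # horizon-filtered designs are a subset of the full network's designs
  full <- count_designs(net)$designs
  for (h in 1:4) {
    dh <- count_designs(net, h)$designs
    expect_true(all(paste(dh$treat_a, dh$treat_b) %in%
                      paste(full$treat_a, full$treat_b)))
  }

  # a fully connected triangle passes through unchanged
  tri <- bind_toys(toy_two_arm("x1", "A", "B"), toy_two_arm("x2", "B", "C"),
                   toy_two_arm("x3", "A", "C"))
  sub <- connected_component(tri, 1, "A")
  expect_setequal(sub$treatments, c("A", "B", "C"))
  expect_error(connected_component(tri, 1, "Z"), "reference")
})

test_that("removing any article never increases a count", {
  net <- fixture_net()
  base_tot <- patient_totals(net)$grand_total
  base_des <- count_designs(net)$n
  base_cov <- outcome_coverage(net)
  set.seed(1)
  for (art in sample(unique(net$studies$article_id), 6)) {
    red <- evidence_network(net$studies[net$studies$article_id != art, ],
                            net$arms[net$arms$article_id != art, ])
    expect_lt(patient_totals(red)$grand_total, base_tot)
    expect_lte(count_designs(red)$n, base_des)
    expect_true(all(outcome_coverage(red) <= base_cov))
  }
})
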