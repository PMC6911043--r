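mkEvents <- function(incWt, excWt, incMut, excMut, type = "SE",
                     siteId = NULL) {
  n <- length(incWt)
  id <- sprintf("e%03d", seq_len(n))
  if (is.null(siteId)) siteId <- sprintf("s%03d", seq_len(n))
  rbind(data.frame(event_id = id, condition = "wt", inclusion = incWt,
                   exclusion = excWt, type = type, site_id = siteId),
        data.frame(event_id = id, condition = "mut", inclusion = incMut,
                   exclusion = excMut, type = type, site_id = siteId))
}

test_that("psi from counts is the inclusion ratio with NA at zero depth", {
  expect_equal(psiFromCounts(8, 2), 0.8)
  expect_equal(psiFromCounts(0, 5), 0)
  expect_true(is.na(psiFromCounts(0, 0)))
  expect_equal(psiFromCounts(c(8, 0), c(2, 0)), c(0.8, NA))
})

test_that("Bayes factor matches the numerical-integration oracle to 1e-6", {
  set.seed(14)
  cases <- rbind(
    expand.grid(i1 = c(0, 1, 20, 50), e1 = c(0, 1, 20, 50),
                i2 = c(0, 5, 50), e2 = c(0, 5, 50)),
    data.frame(i1 = sample(0:50, 60, TRUE), e1 = sample(0:50, 60, TRUE),
               i2 = sample(0:50, 60, TRUE), e2 = sample(0:50, 60, TRUE)))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    bf <- bayesFactor(cs$i1, cs$e1, cs$i2, cs$e2)
    expect_equal(bf, oracleBF(cs$i1, cs$e1, cs$i2, cs$e2),
                 tolerance = 1e-6)
  }
})

test_that("Bayes factor behaves as evidence against shared inclusion", {
  expect_lt(bayesFactor(40, 40, 40, 40), 1)     # identical counts
  expect_gt(bayesFactor(20, 0, 0, 20), 1e6)     # opposite extremes
  expect_equal(bayesFactor(0, 0, 15, 5), 1)     # one empty condition
})

test_that("differential calls require all three gates", {
  ## dpsi=0.25, BF and reads comfortably over threshold
  ev <- mkEvents(incWt = c(40, 20, 39), excWt = c(40, 20, 1),
                 incMut = c(60, 21, 40), excMut = c(20, 19, 0))
  calls <- callDifferentialEvents(ev)
  expect_equal(calls$dpsi[1], 0.25)
  expect_gt(calls$bayes_factor[1], 5)
  expect_identical(calls$call[1], "mut_preferred")
  ## small dpsi fails the dpsi gate
  expect_identical(calls$call[2], "none")
  ## dpsi below 0.10 in the other direction also fails
  expect_lt(abs(calls$dpsi[3]), 0.10)
  expect_identical(calls$call[3], "none")

  ## read gate: min(total_wt, total_mut) < 10 -> none even when extreme
  ev2 <- mkEvents(incWt = 8, excWt = 0, incMut = 0, excMut = 8)
  expect_identical(callDifferentialEvents(ev2)$call, "none")
  expect_identical(callDifferentialEvents(ev2, readsMin = 8L)$call,
                   "wt_preferred")

  ## BF gate at the threshold
  ev3 <- mkEvents(incWt = 12, excWt = 8, incMut = 17, excMut = 3)
  c3 <- callDifferentialEvents(ev3)
  expect_identical(c3$call, ifelse(c3$bayes_factor >= 5 &
                                     abs(c3$dpsi) >= 0.1,
                                   "mut_preferred", "none"))
})

test_that("swapping conditions negates dpsi and mirrors calls exactly", {
  set.seed(15)
  n <- 60
  ev <- mkEvents(incWt = rbinom(n, 40, 0.5), excWt = rbinom(n, 40, 0.5),
                 incMut = rbinom(n, 40, 0.5), excMut = rbinom(n, 40, 0.5))
  fwd <- callDifferentialEvents(ev)
  swapped <- ev
  swapped$condition <- ifelse(ev$condition == "wt", "mut", "wt")
  rev <- callDifferentialEvents(swapped)
  rev <- rev[match(fwd$event_id, rev$event_id), ]
  expect_equal(rev$dpsi, -fwd$dpsi)
  expect_equal(rev$bayes_factor, fwd$bayes_factor)
  map <- c(mut_preferred = "wt_preferred", wt_preferred = "mut_preferred",
           none = "none")
  expect_identical(unname(map[fwd$call]), rev$call)
})

test_that("event-type frequency test matches hand-computed chi-squared", {
  ann <- c(SE = 30, RI = 30)
  res <- eventTypeFrequencyTest(
    data.frame(type = rep(c("SE", "RI"), c(50, 10))), ann)
  expect_equal(res$chisq, 400 / 30 + 400 / 30)
  expect_equal(res$p, pchisq(800 / 30, df = 1, lower.tail = FALSE))

  resEq <- eventTypeFrequencyTest(
    data.frame(type = rep(c("SE", "RI"), c(30, 30))), ann)
  expect_equal(resEq$chisq, 0)
  expect_equal(resEq$p, 1)

  expect_warning(
    eventTypeFrequencyTest(
      data.frame(type = rep(c("SE", "RI"), c(5, 5))),
      c(SE = 10, RI = 0)),
    "merged")
})

test_that("SE acceptor trinucleotides stratify by inclusion direction", {
  sites <- spliceSites("c1", c(100L, 200L, 300L), "+",
                       c("s1", "s2", "s3"), "g1",
                       acceptor = c("CAG", "CAG", "TAG"))
  calls <- data.frame(event_id = c("e1", "e2", "e3"), type = "SE",
                      site_id = c("s1", "s2", "s3"),
                      dpsi = c(0.3, 0.2, -0.4),
                      call = c("mut_preferred", "mut_preferred",
                               "wt_preferred"))
  tri <- seAcceptorTrinucleotides(calls, sites)
  expect_equal(unname(tri["CAG", "increased"]), 1)
  expect_equal(unname(tri["TAG", "decreased"]), 1)
  expect_warning(seAcceptorTrinucleotides(calls[0, ], sites), "no called")
})

test_that("generator coupling enriches CAG among mutant-included skipped exons", {
  cfg <- simConfig(nGenes = 300L, sitesPerGene = 5L, intronLength = 200L,
                   cohort = list(nMut = 20L, nWt = 20L, psiBetaA = 2,
                                 psiBetaB = 2, deltaPsi = 0.3,
                                 affectedFraction = 0.4, depth = 150L,
                                 coupling = 1, nEvents = 800L))
  ref <- simulateReference(cfg, 71, genome = FALSE)
  sim <- simulatePsiCohort(ref, cfg, 71)
  calls <- callDifferentialEvents(sim$counts)
  tri <- seAcceptorTrinucleotides(calls, ref$sites)
  expect_gt(tri["CAG", "increased"], tri["CAG", "decreased"])
  expect_gt(tri["TAG", "decreased"], tri["TAG", "increased"])
})

test_that("cohort caller applies the t-test and median-difference gates", {
  set.seed(16)
  jitter <- rnorm(10, 0, 0.002)
  psi <- rbind(
    flat = rep(0.6, 10) + jitter,
    shifted = c(rep(0.8, 5), rep(0.6, 5)) + jitter,
    tiny = c(rep(0.612, 5), rep(0.6, 5)) + jitter
  )
  colnames(psi) <- sprintf("s%d", 1:10)
  se <- psiExperiment(psi, rep(c("mut", "wt"), each = 5))
  cc <- cohortCall(se)
  expect_false(cc$called[cc$event_id == "flat"])
  expect_true(cc$called[cc$event_id == "shifted"])
  expect_equal(cc$direction[cc$event_id == "shifted"], 1)
  ## significant but below the 2.5% median-difference gate
  expect_false(cc$called[cc$event_id == "tiny"])

  ## an event with <2 values in a group is skipped, not called
  psi2 <- psi
  psi2["flat", 1:4] <- NA
  se2 <- psiExperiment(psi2, rep(c("mut", "wt"), each = 5))
  cc2 <- suppressMessages(cohortCall(se2))
  expect_true(cc2$skipped[cc2$event_id == "flat"])
  expect_false(cc2$called[cc2$event_id == "flat"])
})

test_that("CAG/TAG cohort co-association handles exact and degenerate tables", {
  calls <- data.frame(
    event_id = sprintf("e%d", 1:20), called = TRUE,
    dmedian = c(rep(0.2, 10), rep(-0.2, 10)))
  acc <- setNames(c(rep("CAG", 10), rep("TAG", 10)), calls$event_id)
  res <- cohortCagTagTest(calls, acc)
  expect_equal(unname(res$table), rbind(c(10, 0), c(0, 10)))
  expect_equal(res$p, oracleFisherP(res$table), tolerance = 1e-9)

  accBal <- setNames(rep(c("CAG", "TAG"), 10), calls$event_id)
  resBal <- cohortCagTagTest(calls, accBal)
  expect_equal(resBal$p, 1)
  expect_equal(resBal$odds_ratio, 1, tolerance = 1e-6)

  ## all events in one direction: degenerate margin
  callsUp <- calls; callsUp$dmedian <- 0.2
  expect_warning(resDeg <- cohortCagTagTest(callsUp, acc), "degenerate")
  expect_equal(resDeg$p, 1)
})

test_that("event Z-scores standardise against the wild-type group", {
  psi <- rbind(ev1 = c(0.7, c(0.4, 0.5, 0.6)),
               ev2 = c(0.5, c(0.5, 0.5, 0.5)),
               ev3 = c(0.9, c(0.2, NA, NA)))
  colnames(psi) <- c("m1", "w1", "w2", "w3")
  se <- psiExperiment(psi, c("mut", "wt", "wt", "wt"))
  z <- eventZscores(se)
  expect_equal(z["ev1", "m1"], (0.7 - 0.5) / 0.1)
  expect_true(is.na(z["ev2", "m1"]))   # wt sd = 0
  expect_true(is.na(z["ev3", "m1"]))   # <2 wt values

  ## leave-one-out: wild-type samples against their own group center on 0
  set.seed(17)
  mat <- matrix(rbeta(20 * 12, 2, 2), nrow = 20,
                dimnames = list(sprintf("e%d", 1:20),
                                sprintf("w%d", 1:12)))
  zs <- unlist(lapply(1:12, function(j) {
    se <- psiExperiment(mat, replace(rep("wt", 12), j, "mut"))
    eventZscores(se)
  }))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.1)
})

test_that("overlap association matches the hypergeometric oracle and calibrates", {
  refCalls <- data.frame(event_id = sprintf("e%d", 1:20),
                         dpsi = c(rep(0.3, 10), rep(-0.3, 10)),
                         call = "mut_preferred")
  z <- matrix(c(rep(2.5, 10), rep(-2.5, 10)), ncol = 1,
              dimnames = list(sprintf("e%d", 1:20), "m1"))
  res <- overlapAssociation(refCalls, z)
  expect_equal(unname(res$table), rbind(c(10, 0), c(0, 10)))
  expect_equal(res$p, oracleFisherP(res$table), tolerance = 1e-9)

  ## shuffled direction labels: association vanishes
  set.seed(18)
  ps <- vapply(1:30, function(i) {
    shuffled <- refCalls
    shuffled$dpsi <- sample(refCalls$dpsi)
    suppressWarnings(overlapAssociation(shuffled, z)$p)
  }, 0)
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.2)

  expect_error(overlapAssociation(refCalls, z, zThresh = 5), "empty")
  expect_error(overlapAssociation(refCalls[0, ], z), "empty")
})
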