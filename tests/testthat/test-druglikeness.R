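# Flat parameter rows make the ADS return an exact constant, which lets the
# geometric-mean composition be checked exactly.
const_params <- function(value) {
  p <- qed_params()
  p$a <- value; p$b <- 0; p$c <- 0; p$d <- 0; p$e <- 1; p$f <- 1; p$dmax <- 1
  p
}

fixture_desc <- c(MW = 300, ALOGP = 2.5, HBA = 5, HBD = 2, PSA = 80,
                  ROTB = 4, AROM = 2, ALERTS = 0)

test_that("desirabilities agree with an independent formula evaluation", {
  p <- qed_params()
  for (k in QED_DESCRIPTORS) {
    grid <- switch(k, MW = seq(50, 900, by = 50),
                   ALOGP = seq(-4, 8, by = 0.5),
                   PSA = seq(0, 250, by = 10), 0:12)
    for (x in grid) {
      expect_equal(ads_desirability(x, p[k, ]),
                   oracle_ads(x, p[k, "a"], p[k, "b"], p[k, "c"],
                              p[k, "d"], p[k, "e"], p[k, "f"],
                              p[k, "dmax"]),
                   tolerance = 1e-9, info = paste(k, x))
    }
  }
  # frozen spot value for d_MW(300), computed with the oracle
  expect_equal(ads_desirability(300, p["MW", ]), 0.9971726, tolerance = 1e-6)
  expect_error(ads_desirability(1, list(a = 1, b = 1, c = 1, d = 1, e = -1,
                                        f = 1, dmax = 1)), "positive")
})

test_that("desirability tails flatten to a/dmax above the clamp floor", {
  p <- qed_params()
  # both tails of the double sigmoid decay to the offset term a (scaled)
  expect_equal(ads_desirability(1e6, p["MW", ]), p["MW", "a"] / p["MW", "dmax"])
  expect_equal(ads_desirability(-1e6, p["ALOGP", ]),
               p["ALOGP", "a"] / p["ALOGP", "dmax"])
  for (k in QED_DESCRIPTORS) {
    expect_gte(ads_desirability(1e9, p[k, ]), 1e-6)
    expect_gte(ads_desirability(-1e9, p[k, ]), 1e-6)
  }
  expect_gt(ads_desirability(p["MW", "c"], p["MW", ]), 0.97)
})

test_that("qed is the exact geometric mean of the eight desirabilities", {
  r <- qed(fixture_desc)
  expect_equal(r$qed, exp(mean(log(r$desirabilities))), tolerance = 1e-12)
  # frozen via two-step oracle composition (oracle_ads then exp-mean-log)
  expect_equal(r$qed, 0.886509563496233, tolerance = 1e-9)
  expect_gte(r$qed, min(r$desirabilities))
  expect_lte(r$qed, max(r$desirabilities))

  # constant-desirability parameterisations give exact identities
  expect_equal(qed(fixture_desc, params = const_params(1))$qed, 1)
  expect_equal(qed(fixture_desc, params = const_params(0.5))$qed, 0.5)

  expect_error(qed(fixture_desc[-1]), "MW")
})

test_that("the 7-descriptor variant drops ALERTS only", {
  r8 <- qed(fixture_desc)
  r7 <- qed(fixture_desc, use_alerts = FALSE)
  expect_length(r7$desirabilities, 7)
  expect_false("ALERTS" %in% names(r7$desirabilities))
  expect_equal(r7$qed, exp(mean(log(r8$desirabilities[1:7]))),
               tolerance = 1e-12)
})

test_that("qed increases when any one descriptor moves toward its mode", {
  p <- qed_params()
  withr::with_seed(21, {
    for (i in 1:200) {
      desc <- c(MW = runif(1, 100, 700), ALOGP = runif(1, -2, 6),
                HBA = sample(0:10, 1), HBD = sample(0:6, 1),
                PSA = runif(1, 5, 200), ROTB = sample(0:10, 1),
                AROM = sample(0:5, 1), ALERTS = sample(0:3, 1))
      base <- qed(desc)
      k <- sample(QED_DESCRIPTORS, 1)
      nudged <- desc
      nudged[k] <- desc[k] + 0.1 * (p[k, "c"] - desc[k])
      moved <- qed(nudged)
      if (moved$desirabilities[k] >= base$desirabilities[k]) {
        expect_gte(moved$qed, base$qed)
      } else {
        expect_lte(moved$qed, base$qed)
      }
    }
  })
})

test_that("the drug-likeness gate is strict and conserves counts", {
  tab <- compound_fixture(30, seed = 5)
  scored <- score_qed(tab)
  expect_equal(scored$qed, vapply(seq_len(30), function(i) {
    qed(scored[i, QED_DESCRIPTORS])$qed
  }, numeric(1)), tolerance = 1e-12)

  scored$qed[1] <- 0.5  # exactly at threshold
  g <- qed_gate(scored)
  expect_true(scored$compound_id[1] %in% g$failed$compound_id)
  expect_equal(nrow(g$passed) + nrow(g$failed), 30)

  empty <- qed_gate(scored[0, ])
  expect_equal(nrow(empty$passed), 0)
  expect_equal(nrow(empty$failed), 0)

  withr::with_seed(31, {
    for (i in 1:5) {
      thr <- runif(1)
      g <- qed_gate(scored, thr)
      expect_equal(nrow(g$passed) + nrow(g$failed), nrow(scored))
      expect_true(all(g$passed$qed > thr))
      expect_true(all(g$failed$qed <= thr))
    }
  })
})
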