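mk_summary <- function(...) {
  vals <- list(...)
  tibble::tibble(sample = paste0("s", seq_along(vals[[1]])), !!!vals)
}

test_that("expert thresholds flag in the metric's bad direction only", {
  s <- mk_summary(periodicity = c(0.9, 0.4), pct_CDS = c(80, 30),
                  pct_rRNA = c(5, 40), pct_tRNA = c(2, 12))
  fl <- expert_threshold_flags(s)
  get <- function(sm, m) fl$flagged[fl$sample == sm & fl$metric == m]
  expect_false(get("s1", "periodicity"))  # 0.9 >= 0.5
  expect_true(get("s2", "periodicity"))
  expect_true(get("s2", "pct_rRNA"))      # 40 > 20
  expect_false(get("s1", "pct_rRNA"))
  expect_true(get("s2", "pct_CDS"))
  expect_true(get("s2", "pct_tRNA"))

  # configured metric absent from the summary emits nothing
  fl2 <- expert_threshold_flags(s[, c("sample", "periodicity")])
  expect_setequal(unique(fl2$metric), "periodicity")

  # custom thresholds override the defaults
  fl3 <- expert_threshold_flags(s, list(pct_rRNA = c(max = 50)))
  expect_false(any(fl3$flagged))
})

test_that("Tukey's fence flags match the brute-force oracle", {
  s <- mk_summary(metric = c(1, 2, 3, 4, 100))
  fl <- tukey_flags(s, metrics = "metric")
  expect_equal(fl$flagged, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  const <- mk_summary(metric = rep(7, 6))
  expect_false(any(tukey_flags(const, metrics = "metric")$flagged))

  expect_warning(few <- tukey_flags(mk_summary(metric = c(1, 2, 3))),
                 "at least 4")
  expect_equal(nrow(few), 0L)

  withr::with_seed(21, {
    for (i in 1:300) {
      n <- sample(4:30, 1)
      x <- round(stats::rnorm(n, sd = sample(c(0.5, 5, 50), 1)), 2)
      got <- tukey_flags(mk_summary(metric = x), metrics = "metric")$flagged
      expect_identical(got, bf_tukey_outliers(x), info = paste("case", i))
    }
  })
})

test_that("control percent error uses the 25% threshold strictly", {
  s <- mk_summary(periodicity = c(0.80, 0.55, 0.70))
  fl <- control_flags(s, controls = "s1")
  expect_equal(nrow(fl), 2L)
  expect_true(fl$flagged[fl$sample == "s2"])    # |0.55-0.8|/0.8 = 31.25%
  expect_false(fl$flagged[fl$sample == "s3"])   # 12.5%
  expect_equal(unique(fl$reference), 0.80)

  eq <- control_flags(mk_summary(m = c(0.6, 0.6)), controls = "s1",
                      metrics = "m")
  expect_false(eq$flagged)  # observed = control -> 0%

  # symmetric in which equal-valued sample is the control
  a <- control_flags(mk_summary(m = c(0.5, 0.8)), controls = "s1",
                     metrics = "m")$flagged
  b <- control_flags(mk_summary(m = c(0.8, 0.5)), controls = "s2",
                     metrics = "m")$flagged
  expect_identical(a, b)

  expect_warning(z <- control_flags(mk_summary(m = c(0, 1)), controls = "s1",
                                    metrics = "m"), "zero")
  expect_equal(nrow(z), 0L)
  expect_error(control_flags(s, controls = "nope"), "not in summary")

  # multiple controls -> mean reference
  s4 <- mk_summary(m = c(0.6, 1.0, 0.81))
  fl4 <- control_flags(s4, controls = c("s1", "s2"), metrics = "m")
  expect_equal(fl4$reference, 0.8)
  expect_false(fl4$flagged)  # 1.25% error
})

test_that("flags are monotone: pushing a value further out never unflags it", {
  base <- c(1, 2, 3, 4, 100)
  for (bump in c(10, 1e3, 1e6)) {
    x <- base
    x[5] <- x[5] + bump
    fl <- tukey_flags(mk_summary(metric = x), metrics = "metric")
    expect_true(fl$flagged[5], info = paste("bump", bump))
  }
  for (bump in c(0.1, 1, 10)) {
    s <- mk_summary(m = c(0.8, 1.2 + bump))
    expect_true(control_flags(s, controls = "s1", metrics = "m")$flagged)
  }
})

test_that("reference fences flag degraded samples against good references", {
  ref <- tibble::tibble(sample = paste0("r", 1:6),
                        periodicity = c(0.68, 0.70, 0.71, 0.69, 0.72, 0.70),
                        pct_rRNA = c(4, 5, 6, 5, 4, 5))
  good <- mk_summary(periodicity = 0.695, pct_rRNA = 5.5)
  expect_false(any(reference_flags(good, ref)$flagged))

  bad <- mk_summary(periodicity = 0.34, pct_rRNA = 30)
  fl <- reference_flags(bad, ref)
  expect_true(all(fl$flagged))
  expect_equal(unique(fl$method), "reference")

  expect_error(reference_flags(good, ref[0, ]), "empty")

  # reference table supplied as a TSV path
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(ref, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_true(all(reference_flags(bad, p)$flagged))
})

test_that("detect_anomalies combines the applicable strategies", {
  s <- mk_summary(periodicity = c(0.7, 0.71, 0.69, 0.2),
                  pct_rRNA = c(5, 6, 5, 45))
  fl <- detect_anomalies(s, controls = "s1")
  expect_setequal(unique(fl$method), c("expert", "tukey", "control"))
  expect_true(any(fl$flagged[fl$sample == "s4"]))
  expect_false(any(fl$flagged[fl$sample %in% c("s1", "s2", "s3")]))
})
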