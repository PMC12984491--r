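test_that("ecg_record enforces the 12-lead invariants", {
  leads <- stats::setNames(replicate(8, numeric(100), simplify = FALSE),
                           vcg_independent_leads())
  rec <- ecg_record(leads, fs = 500)
  expect_setequal(names(rec$leads), vcg_lead_names())
  expect_true(all(lengths(rec$leads) == 100))

  expect_error(ecg_record(leads[-3L], fs = 500), "V1 absent")
  bad <- leads; bad$II <- numeric(50)
  expect_error(ecg_record(bad, fs = 500), "unequal")
  bad <- leads; bad$V3[1] <- NaN
  expect_error(ecg_record(bad, fs = 500), "finite")
  expect_error(ecg_record(leads, fs = -1), "positive")
})

test_that("augmented limb leads satisfy the Goldberger identities", {
  expect_equal(derive_augmented_leads(numeric(5), numeric(5)),
               list(III = numeric(5), aVR = numeric(5), aVL = numeric(5),
                    aVF = numeric(5)))
  one <- rep(1, 5)
  aug <- derive_augmented_leads(one, one)
  expect_equal(aug$III, rep(0, 5))
  expect_equal(aug$aVR, rep(-1, 5))
  expect_equal(aug$aVL, rep(0.5, 5))
  expect_equal(aug$aVF, rep(0.5, 5))
  expect_error(derive_augmented_leads(1:3, 1:4), "length")

  set.seed(1)
  for (i in 1:20) {
    I <- rnorm(50); II <- rnorm(50)
    aug <- derive_augmented_leads(I, II)
    expect_equal(I + aug$III, II)
    expect_equal(aug$aVR, -(I + II) / 2)
    expect_equal(aug$aVL, I - II / 2)
    expect_equal(aug$aVF, II - I / 2)
  }
})

test_that("CSV dialect reads 12-lead records and flags missing leads", {
  n <- 1000L
  tab <- data.frame(time_s = (seq_len(n) - 1) / 500)
  for (ld in vcg_lead_names()) tab[[ld]] <- numeric(n)
  path <- file.path(tempdir(), "zeros.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  rec <- read_record(path, dialect = "csv")
  expect_s3_class(rec, "ecg_record")
  expect_equal(length(rec$leads$I) / rec$sampling_rate, n / 500)
  expect_true(all(vapply(rec$leads, function(x) all(x == 0), logical(1))))

  tab$V6 <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_record(path, dialect = "csv"), "lead V6 absent")
  expect_error(read_record(file.path(tempdir(), "nope.csv"),
                           dialect = "csv"), "unreadable")
})

test_that("non-500 Hz input is resampled (or rejected on request)", {
  n <- 500L
  tab <- data.frame(time_s = (seq_len(n) - 1) / 250)
  for (ld in vcg_lead_names()) {
    tab[[ld]] <- sin(2 * pi * 5 * tab$time_s)
  }
  path <- file.path(tempdir(), "slow.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  rec <- read_record(path, dialect = "csv")
  expect_equal(rec$sampling_rate, 500)
  expect_equal(length(rec$leads$I), 1000L)
  # resampled sine still a 5 Hz sine (interior samples)
  t2 <- (seq_len(1000L) - 1) / 500
  expect_lt(max(abs(rec$leads$I[100:900] -
                      sin(2 * pi * 5 * t2[100:900]))), 0.02)
  expect_error(read_record(path, dialect = "csv", on_rate = "reject"),
               "sampling rate")
})

test_that("WFDB write-then-read round-trips within one quantization step", {
  out <- synthesize_record(cohort_presets()$NORMAL, 3L)
  dir <- file.path(tempdir(), "wfdbtest")
  base <- write_wfdb(out$record, dir, gain = 200)
  back <- read_record(paste0(base, ".hea"), dialect = "wfdb")
  for (ld in vcg_independent_leads()) {
    expect_lt(max(abs(back$leads[[ld]] - out$record$leads[[ld]])),
              1 / 200 + 1e-12, label = paste("lead", ld))
  }
  # idempotent to within quantization: write the read-back, read again
  back$record_id <- "again"
  base2 <- write_wfdb(back, dir, gain = 200)
  back2 <- read_record(paste0(base2, ".hea"))
  expect_equal(back2$leads$V5, back$leads$V5, tolerance = 1e-12)
})

test_that("exclusion_filter matches rules with a negation guard", {
  res <- exclusion_filter("ventricular paced rhythm")
  expect_equal(res$decision, "exclude")
  expect_true("paced" %in% res$matched)

  expect_equal(exclusion_filter("sinus rhythm, otherwise normal ecg")$decision,
               "keep")

  res <- exclusion_filter("atrial fibrillation with rapid ventricular response")
  expect_equal(res$decision, "exclude")
  expect_true("afib" %in% res$matched)

  # negated mention within the guard window does not match
  expect_equal(exclusion_filter("sinus rhythm, no atrial fibrillation")$decision,
               "keep")
  expect_equal(exclusion_filter("without evidence of bundle branch block")$decision,
               "keep")

  # empty report: strict excludes, lenient keeps with warning
  expect_equal(exclusion_filter("")$matched, "no report")
  expect_warning(res <- exclusion_filter("", strict = FALSE), "lenient")
  expect_equal(res$decision, "keep")
})

test_that("exclusion decision is invariant to rule order", {
  txt <- "atrial flutter and left bundle branch block"
  rules <- default_exclusion_rules()
  a <- exclusion_filter(txt, rules)
  b <- exclusion_filter(txt, rev(rules))
  expect_equal(a$decision, b$decision)
  expect_setequal(a$matched, b$matched)
})

test_that("select_primary_ecg follows the lexicographic priority", {
  one <- data.frame(record_id = "A", is_clean = FALSE,
                    label_definitive = FALSE, timestamp = 1)
  expect_equal(select_primary_ecg(one), "A")

  two <- data.frame(record_id = c("A", "B"), is_clean = c(TRUE, TRUE),
                    label_definitive = c(TRUE, FALSE), timestamp = c(2, 1))
  expect_equal(select_primary_ecg(two), "A")

  tie <- data.frame(record_id = c("B", "A"), is_clean = TRUE,
                    label_definitive = TRUE, timestamp = c(2, 1))
  expect_equal(select_primary_ecg(tie), "A")
  tie$timestamp <- c(1, 1)
  expect_equal(select_primary_ecg(tie), "A")  # record_id tie-break

  expect_error(select_primary_ecg(one[0, ]), "no candidate")
})
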