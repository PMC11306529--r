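test_that("IQR prefilter uses linear-interpolation quantiles and strict cutoffs", {
  m <- rbind(flat = rep(0.5, 4), spread = c(0, 0.3, 0.6, 0.9))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(IQR(c(0, 0.3, 0.6, 0.9), type = 7), 0.45)  # oracle for the fixture
  expect_equal(iqr_prefilter(m, 0.1), "spread")
  expect_equal(iqr_prefilter(m, 0), "spread")  # strict: IQR 0 is not > 0
  expect_error(iqr_prefilter(m[0, , drop = FALSE]), "non-empty")
})

test_that("bh_adjust matches the step-up oracle and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(0)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(20); perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_paired_cohort <- function(patients) {
  as_cohort_annotation(data.frame(
    sample_id = c(paste0(patients, "_a"), paste0(patients, "_b")),
    patient_id = rep(patients, 2),
    timepoint = rep(c("week0", "week12"), each = length(patients)),
    arm = "combination"))
}

test_that("paired testing recovers planted shifts and controls nulls", {
  set.seed(0)
  n_pairs <- 30; n_planted <- 100; n_null <- 900
  patients <- sprintf("P%02d", seq_len(n_pairs))
  annot <- make_paired_cohort(patients)
  mu <- runif(n_planted + n_null, 0.2, 0.6)
  probes <- sprintf("cg%04d", seq_len(n_planted + n_null))
  before <- matrix(pmin(1, pmax(0, mu + rnorm(length(mu) * n_pairs, sd = 0.05))),
                   ncol = n_pairs, dimnames = list(probes, paste0(patients, "_a")))
  shift <- c(rep(0.3, n_planted), rep(0, n_null))
  after <- matrix(pmin(1, pmax(0, mu + shift + rnorm(length(mu) * n_pairs, sd = 0.05))),
                  ncol = n_pairs, dimnames = list(probes, paste0(patients, "_b")))
  res <- paired_differential(before, after, annot)
  planted <- res$probe %in% probes[seq_len(n_planted)]
  expect_gte(sum(res$significant[planted]), 95)
  expect_lte(sum(res$significant[!planted]), 0.05 * n_null)
})

test_that("degenerate paired inputs are handled explicitly", {
  patients <- sprintf("P%02d", 1:6)
  annot <- make_paired_cohort(patients)
  m <- matrix(runif(30, 0.2, 0.8), nrow = 5,
              dimnames = list(sprintf("cg%02d", 1:5), paste0(patients, "_a")))
  after <- m; colnames(after) <- paste0(patients, "_b")

  # after == before: all deltas zero, zero-variance branch, nothing significant
  res <- paired_differential(m, after, annot, min_iqr = NULL)
  expect_true(all(res$mean_delta == 0))
  expect_true(all(res$note == "zero_variance"))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))

  # constant nonzero delta: flagged zero variance, p forced to 1
  after2 <- m + 0.2; colnames(after2) <- paste0(patients, "_b")
  res2 <- paired_differential(m, after2, annot, min_iqr = NULL)
  expect_true(all(res2$note == "zero_variance"))
  expect_equal(res2$mean_delta, rep(0.2, 5))

  # patients lacking a timepoint are dropped with a message
  expect_message(
    res3 <- paired_differential(m, after[, 1:4] + 0, annot, min_iqr = NULL),
    "lacking one timepoint")
  expect_equal(attr(res3, "n_pairs_used"), 4L)
})

test_that("significance rule holds its level on pure-null paired data", {
  set.seed(1)
  n_probes <- 2000; n_pairs <- 20
  patients <- sprintf("P%02d", seq_len(n_pairs))
  annot <- make_paired_cohort(patients)
  probes <- sprintf("cg%04d", seq_len(n_probes))
  mk <- function(suffix) {
    matrix(pmin(1, pmax(0, 0.5 + rnorm(n_probes * n_pairs, sd = 0.1))),
           ncol = n_pairs, dimnames = list(probes, paste0(patients, suffix)))
  }
  res <- paired_differential(mk("_a"), mk("_b"), annot)
  n_tested <- sum(!is.na(res$p))
  expect_gt(n_tested, 1000)  # the IQR filter keeps most of these probes
  rate <- sum(res$significant) / n_tested
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_tested))
})

test_that("results are invariant to patient ordering", {
  set.seed(2)
  patients <- sprintf("P%02d", 1:10)
  annot <- make_paired_cohort(patients)
  m0 <- matrix(runif(50, 0.1, 0.9), nrow = 5,
               dimnames = list(sprintf("cg%02d", 1:5), paste0(patients, "_a")))
  m1 <- matrix(runif(50, 0.1, 0.9), nrow = 5,
               dimnames = list(sprintf("cg%02d", 1:5), paste0(patients, "_b")))
  r1 <- paired_differential(m0, m1, annot, min_iqr = NULL)
  perm <- sample(10)
  r2 <- paired_differential(m0[, perm], m1[, rev(perm)], annot, min_iqr = NULL)
  expect_equal(r1, r2, ignore_attr = TRUE)
})
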