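# A hand-built leave-one-out fit for aggregation tests.
fake_fit <- function(models, intercepts) {
  structure(list(models = models, intercepts = intercepts,
                 lambdas = rep(0.1, length(intercepts)),
                 loo = tibble::tibble(sample_id = names(intercepts),
                                      y = rep(c(TRUE, FALSE), length.out = length(intercepts)),
                                      probability = 0.5),
                 n_models = length(intercepts), seed = 0),
            class = "loo_signature_fit")
}

test_that("aggregation keeps majority probes and averages coefficients", {
  models <- tibble::tibble(
    held_out = c("s1", "s2", "s3", "s1"),
    probe = c("A", "A", "A", "B"),
    coef = c(1, 2, 3, 9))
  fit <- fake_fit(models, intercepts = c(s1 = 1, s2 = 2, s3 = 3))
  sig <- aggregate_signature(fit)
  expect_equal(sig$coef[sig$probe == "A"], 2)       # mean of 1, 2, 3
  expect_false("B" %in% sig$probe)                  # 1/3 < 0.5
  expect_equal(sig_intercept(sig), 2)               # intercept over all models

  # exactly half the models is inclusive
  m4 <- tibble::tibble(held_out = c("s1", "s2"), probe = "C", coef = c(2, 4))
  fit4 <- fake_fit(m4, intercepts = c(s1 = 0, s2 = 0, s3 = 0, s4 = 0))
  sig4 <- aggregate_signature(fit4)
  expect_true("C" %in% sig4$probe)
  expect_equal(sig4$coef, 3)                        # present-only average
  sig4_all <- aggregate_signature(fit4, coef_average = "all")
  expect_equal(sig4_all$coef, 6 / 4)                # absent models count as 0

  # order of models is irrelevant
  fit_rev <- fake_fit(models[4:1, ], intercepts = c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(aggregate_signature(fit_rev)$coef, sig$coef)

  expect_warning(agg <- aggregate_signature(fake_fit(m4[0, ], c(s1 = 0, s2 = 0))),
                 "empty")
  expect_equal(nrow(agg), 0)
})

test_that("scoring is the linear model plus logistic transform", {
  sig <- meth_signature("cg1", coef = 2, intercept = 0)
  m <- beta_mat(0.5, nrow = 1, probes = "cg1", samples = "s1")
  sc <- score_samples(sig, m)
  expect_equal(sc$score, 1)
  expect_equal(sc$probability, 1 / (1 + exp(-1)))

  # all-zero coefficients give probability one half everywhere
  sig0 <- meth_signature(c("cg1", "cg2"), coef = c(0, 0), intercept = 0)
  m2 <- beta_mat(runif(8), nrow = 2, probes = c("cg1", "cg2"))
  expect_equal(score_samples(sig0, m2)$probability, rep(0.5, 4))

  # linear in the coefficients
  siga <- meth_signature(c("cg1", "cg2"), coef = c(1, 2))
  sigb <- meth_signature(c("cg1", "cg2"), coef = c(3, -1))
  sigab <- meth_signature(c("cg1", "cg2"), coef = c(4, 1))
  expect_equal(score_samples(siga, m2)$score + score_samples(sigb, m2)$score,
               score_samples(sigab, m2)$score)

  expect_error(score_samples(sig, m2[2, , drop = FALSE]), "cg1")
  m3 <- m2; m3[1, 2] <- NA
  expect_error(score_samples(siga, m3), "missing value")
})

test_that("translation picks the strongest expression correlate with its sign", {
  # one gene is the exact negative of the probe profile
  meth <- beta_mat(seq(0.1, 0.8, length.out = 8), nrow = 1, probes = "cg1")
  expr <- rbind(gNEG = 1 - meth[1, ], gNOISE = c(0.4, 0.4, 0.41, 0.4, 0.4, 0.42, 0.4, 0.4))
  colnames(expr) <- colnames(meth)
  sig <- meth_signature("cg1", coef = 0.5)
  tr <- translate_signature(sig, meth, expr)
  expect_equal(tr$gene, "gNEG")
  expect_equal(tr$rho, -1)
  expect_equal(tr$coef, -0.5)

  # zero-variance probe skipped with a warning
  meth2 <- rbind(meth, cgFLAT = rep(0.5, 8))
  sig2 <- meth_signature(c("cg1", "cgFLAT"), coef = c(0.5, 1))
  expect_warning(tr2 <- translate_signature(sig2, meth2, expr), "cgFLAT")
  expect_equal(nrow(tr2), 1)

  expect_error(translate_signature(sig, meth, expr[, 0]), "shared sample")
})

test_that("translated coefficients equal probe coefficient times exact rho", {
  sig <- read_signature(published_signature_path())
  design <- exact_corr_design(sig$probe, sig$rho)
  tr <- translate_signature(sig, design$meth, design$expr)
  expect_equal(tr$probe, sig$probe)
  expect_equal(tr$rho, sig$rho, tolerance = 1e-12)
  expect_equal(tr$coef, sig$coef * sig$rho, tolerance = 1e-12)
})

test_that("hybrid score standardizes and averages", {
  a <- setNames(c(1, 2, 3, 10), paste0("s", 1:4))
  expect_equal(hybrid_score(a, a)$hybrid, as.numeric(zscore <- (a - mean(a)) / sd(a)),
               ignore_attr = TRUE)
  b <- setNames(rnorm(4), paste0("s", 1:4))
  expect_lt(abs(mean(hybrid_score(a, b)$hybrid)), 1e-12)
  neg <- -a + 5  # z(neg) == -z(a)
  expect_equal(hybrid_score(a, neg)$hybrid, rep(0, 4), tolerance = 1e-12)
  expect_error(hybrid_score(a, setNames(rep(1, 4), names(a))), "zero-variance")
  expect_error(hybrid_score(a, b[c(1, 2)]), "same samples")
})

test_that("ROC agrees with the brute-force concordance oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 200
    labels <- runif(n) < 0.4
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_identical(roc_with_cutoff(scores, labels)$auc, oracle_auc(scores, labels))
  }
  # cross-check against an independent ROC implementation
  set.seed(7)
  sc <- rnorm(80); lb <- runif(80) < 0.5
  expect_equal(roc_with_cutoff(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(as.numeric(lb), sc,
                                              quiet = TRUE, direction = "<"))))
})

test_that("ROC endpoints: perfect separation, all ties, single class", {
  r <- roc_with_cutoff(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))
  expect_equal(c(r$auc, r$sensitivity, r$specificity), c(1, 1, 1))
  expect_equal(roc_with_cutoff(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_with_cutoff(1:4, rep(TRUE, 4)), "both classes")
})

test_that("constant features yield empty models and class-rate probabilities", {
  x <- beta_mat(rep(0.5, 8 * 12), nrow = 8)
  y <- setNames(rep(c(TRUE, FALSE), 6), colnames(x))
  fit <- loo_lasso(x, y, seed = 1)
  expect_equal(nrow(fit$models), 0)
  # intercept-only: probability equals the training-set class rate, which
  # takes one of two values depending on the held-out label
  expect_equal(sort(unique(round(fit$loo$probability, 10))),
               sort(round(c(6 / 11, 5 / 11), 10)))
})

test_that("label permutation destroys leave-one-out signal", {
  co <- generate_cohort(small_cfg(seed = 5))
  x <- co$beta$week0[co$truth$predictive_probes, ]
  y <- setNames(co$annotation$pcr[match(colnames(x), co$annotation$sample_id)],
                colnames(x))
  real_auc <- {
    fit <- loo_lasso(x, y, seed = 0)
    roc_with_cutoff(fit$loo$probability, fit$loo$y)$auc
  }
  expect_gt(real_auc, 0.85)
  set.seed(0)
  aucs <- vapply(1:10, function(i) {
    yp <- setNames(sample(y), colnames(x))
    fit <- loo_lasso(x, yp, seed = i)
    roc_with_cutoff(fit$loo$probability, fit$loo$y)$auc
  }, numeric(1))
  # under permuted labels the held-out probabilities carry no signal; the
  # mean LOO AUC sits at or below chance (leave-one-out is pessimistic when
  # models reduce to the intercept: the training class rate moves against
  # the held-out label), and no permutation approaches the real-label AUC
  expect_lt(mean(aucs), 0.6)
  expect_lt(max(aucs), real_auc)
})

test_that("loo_lasso rejects unusable designs", {
  x <- beta_mat(runif(40), nrow = 4)
  expect_error(loo_lasso(x, setNames(rep(TRUE, 10), colnames(x))), "single class")
  y <- setNames(rep(c(TRUE, FALSE), 5), colnames(x))
  expect_error(loo_lasso(x[, 1:4], y[1:4]), "inner_folds")
})
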