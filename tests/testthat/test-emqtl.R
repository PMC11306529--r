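delta_annot <- function(patients) {
  as_cohort_annotation(data.frame(
    sample_id = c(paste0(patients, "_a"), paste0(patients, "_b")),
    patient_id = rep(patients, 2),
    timepoint = rep(c("week0", "week12"), each = length(patients)),
    arm = "combination"))
}

test_that("paired_delta forms per-patient differences independent of column order", {
  patients <- sprintf("P%02d", 1:5)
  annot <- delta_annot(patients)
  t0 <- matrix(runif(15, 0.1, 0.5), nrow = 3,
               dimnames = list(c("f1", "f2", "f3"), paste0(patients, "_a")))
  t1 <- t0 + 0.2; colnames(t1) <- paste0(patients, "_b")
  d <- paired_delta(t0, t1, annot)
  expect_equal(unname(d), matrix(0.2, 3, 5), tolerance = 1e-12)
  expect_equal(colnames(d), patients)
  # shuffled columns give the same result
  d2 <- paired_delta(t0[, c(3, 1, 4, 2, 5)], t1[, 5:1], annot)
  expect_identical(d, d2)
  # identical timepoints give all-zero deltas
  t1b <- t0; colnames(t1b) <- paste0(patients, "_b")
  expect_true(all(paired_delta(t0, t1b, annot) == 0))
})

test_that("emqtl_scan matches the per-pair correlation-test oracle exactly", {
  set.seed(3)
  n_pat <- 12
  dm <- matrix(rnorm(5 * n_pat), nrow = 5,
               dimnames = list(paste0("cg", 1:5), paste0("P", 1:n_pat)))
  de <- matrix(rnorm(5 * n_pat), nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("P", 1:n_pat)))
  res <- emqtl_scan(dm, de)
  m <- attr(res, "n_tested_pairs")
  expect_equal(m, 25L)
  for (i in seq_len(nrow(res))) {
    ct <- cor.test(dm[res$probe[i], ], de[res$gene[i], ])
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(res$p_bonf[i], min(1, ct$p.value * m), tolerance = 1e-12)
  }
})

test_that("perfect anticorrelation is significant; independence is controlled", {
  patients <- paste0("P", 1:10)
  dm <- matrix(seq(-0.5, 0.4, 0.1), nrow = 1, dimnames = list("cg1", patients))
  de <- -dm; rownames(de) <- "g1"
  res <- emqtl_scan(dm, de)
  expect_equal(res$r, -1)
  expect_true(res$significant)

  # family-wise control under a global null, 100 replicates
  set.seed(0)
  any_sig <- vapply(1:100, function(i) {
    x <- matrix(rnorm(30 * 20), nrow = 30, dimnames = list(paste0("cg", 1:30), paste0("P", 1:20)))
    y <- matrix(rnorm(30 * 20), nrow = 30, dimnames = list(paste0("g", 1:30), paste0("P", 1:20)))
    any(emqtl_scan(x, y)$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

# Directly constructed association table with planted anti-correlated blocks.
planted_assoc <- function(n_blocks, probes_per = 10, genes_per = 10, r_in = -0.9) {
  probes <- sprintf("cg%03d", seq_len(n_blocks * probes_per))
  genes <- sprintf("g%03d", seq_len(n_blocks * genes_per))
  grid <- expand.grid(probe = probes, gene = genes, stringsAsFactors = FALSE)
  pb <- (match(grid$probe, probes) - 1) %/% probes_per
  gb <- (match(grid$gene, genes) - 1) %/% genes_per
  grid$r <- ifelse(pb == gb, r_in, 0.05)
  grid$p <- ifelse(pb == gb, 1e-10, 0.5)
  grid$p_bonf <- pmin(1, grid$p * nrow(grid))
  grid$significant <- grid$p_bonf < 0.05
  tibble::as_tibble(grid)
}

test_that("co-clustering recovers planted blocks and respects edge cases", {
  assoc <- planted_assoc(2)
  bc <- cocluster(assoc, k = 2)
  truth_block <- (match(bc$assignments$feature,
                        c(sprintf("cg%03d", 1:20), sprintf("g%03d", 1:20))) - 1) %/% 10 %% 2
  expect_equal(mclust::adjustedRandIndex(bc$assignments$bicluster, truth_block), 1)

  # k = 1 puts everything in one bicluster
  bc1 <- cocluster(assoc, k = 1)
  expect_true(all(bc1$assignments$bicluster == 1))

  # permutation of the association rows relabels but does not repartition
  set.seed(9)
  bc_perm <- cocluster(assoc[sample(nrow(assoc)), ], k = 2)
  merged <- merge(bc$assignments, bc_perm$assignments, by = c("feature", "type"))
  expect_equal(mclust::adjustedRandIndex(merged$bicluster.x, merged$bicluster.y), 1)

  expect_error(cocluster(assoc, k = 50), "exceeds")
  # every feature is assigned to exactly one bicluster
  expect_equal(anyDuplicated(bc$assignments$feature), 0L)
})

test_that("silhouette-based selection finds the planted number of blocks", {
  sel2 <- select_k(planted_assoc(2), k_range = 2:5)
  expect_equal(sel2$k, 2L)
  sel3 <- select_k(planted_assoc(3), k_range = 2:6)
  expect_equal(sel3$k, 3L)
  expect_equal(sel3$scores$k, 2:6)  # a score is reported for every candidate
  expect_true(all(is.finite(sel3$scores$silhouette)))
})

test_that("bicluster delta scores are feature means per patient", {
  assoc <- planted_assoc(2)
  bc <- cocluster(assoc, k = 2)
  set.seed(4)
  dm <- matrix(rnorm(40 * 6), nrow = 40,
               dimnames = list(sprintf("cg%03d", 1:40), paste0("P", 1:6)))
  feats <- bc$assignments$feature[bc$assignments$bicluster == 1 &
                                    bc$assignments$type == "probe"]
  sc <- bicluster_delta_score(dm, bc, bicluster = 1)
  expect_equal(sc$score, unname(colMeans(dm[feats, ])), tolerance = 1e-14)
  # trivial cases
  dm0 <- dm * 0
  expect_true(all(bicluster_delta_score(dm0, bc, 1)$score == 0))
  expect_error(bicluster_delta_score(dm[1:5, ], bc, 1), "absent")
})

test_that("response association distinguishes planted signal from none", {
  patients <- sprintf("P%02d", 1:20)
  annot <- as_cohort_annotation(data.frame(
    sample_id = paste0(patients, "_a"), patient_id = patients,
    timepoint = "week0", arm = rep(c("combination", "chemo"), 10),
    pcr = rep(c(TRUE, FALSE), each = 10),
    tumor_fraction_left = seq(0, 0.95, length.out = 20)))
  # identical distributions: t about 0
  sc_null <- tibble::tibble(patient_id = patients, score = rep(c(0.1, 0.2), 10))
  res_null <- associate_response(sc_null, annot, "pcr")
  expect_gt(res_null$p, 0.5)
  # score exactly linear in tumor fraction left
  sc_lin <- tibble::tibble(patient_id = patients,
                           score = 2 * annot$tumor_fraction_left + 1)
  res_lin <- associate_response(sc_lin, annot, "fraction")
  expect_equal(res_lin$estimate, 1, tolerance = 1e-12)
  # arm filtering restricts n
  res_arm <- associate_response(sc_lin, annot, "fraction", arm = "chemo")
  expect_equal(res_arm$n, 10L)
  expect_error(associate_response(sc_null[1:4, ], annot, "pcr"), "group")
})

test_that("planted cohort biclusters associate with simulated response", {
  co <- generate_cohort(sim_config(seed = 0))
  dm <- paired_delta(co$beta$week0, co$beta$week12, co$annotation)
  de <- paired_delta(co$expr$week0, co$expr$week12, co$annotation)
  assoc <- emqtl_scan(dm, de)
  bc <- cocluster(assoc, k = 2)
  expect_gte(planted_ari(bc, co$truth, "probe"), 0.9)
  expect_gte(planted_ari(bc, co$truth, "gene"), 0.9)
  # the bicluster matching planted block 1 carries a response effect
  asn <- bc$assignments
  b1 <- asn$bicluster[asn$type == "probe" &
                        asn$feature %in% co$truth$bicluster_probes[[1]]][1]
  sc <- bicluster_delta_score(dm, bc, bicluster = b1)
  expect_lt(associate_response(sc, co$annotation, "pcr")$p, 0.05)
})
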