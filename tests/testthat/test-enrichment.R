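test_that("gene set enrichment p-values equal exact tail enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(S = universe[1:5])
  res <- hypergeom_gene_sets(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-15)  # 1/252
  expect_equal(res$fold, 2)                                  # (5/5)/(5/10)

  # disjoint query: overlap 0, p = 1
  res0 <- hypergeom_gene_sets(universe[6:10], sets, universe)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  # random instances against the enumeration oracle
  set.seed(5)
  for (i in 1:50) {
    N <- sample(10:60, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    sets_i <- list(S = sample(uni, K))
    query <- sample(uni, n)
    r <- hypergeom_gene_sets(query, sets_i, uni)
    expect_equal(r$p, oracle_hyper_tail(r$overlap, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeom_gene_sets(c("zz"), sets, universe), "outside")
})

test_that("fold enrichment of a background-uniform query is centered at 1", {
  set.seed(6)
  uni <- paste0("g", 1:500)
  sets <- list(S = uni[1:100])
  folds <- vapply(1:100, function(i) {
    hypergeom_gene_sets(sample(uni, 50), sets, uni)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("chromatin-state consensus keeps concordant regions only", {
  t1 <- interval_track("chr1", 0, 100, "PrAct")
  t2 <- interval_track("chr1", 0, 100, "PrAct")
  cons <- collapse_chromhmm(list(a = t1, b = t2), c(a = "lum", b = "lum"))$lum
  expect_equal(cons, t1)

  # discordant tail is omitted
  t3 <- interval_track(c("chr1", "chr1"), c(0, 60), c(60, 100), c("PrAct", "EhAct"))
  cons2 <- collapse_chromhmm(list(a = t1, b = t3), c(a = "lum", b = "lum"))$lum
  expect_equal(cons2$start, 0L)
  expect_equal(cons2$end, 60L)
  expect_equal(cons2$label, "PrAct")

  # adjacent same-state pieces merge into maximal intervals
  t4 <- interval_track(c("chr1", "chr1"), c(0, 60), c(60, 100), c("PrAct", "PrAct"))
  cons3 <- collapse_chromhmm(list(a = t1, b = t4), c(a = "lum", b = "lum"))$lum
  expect_equal(nrow(cons3), 1)
  expect_equal(cons3$end, 100L)

  # consensus never exceeds the thinnest line's coverage
  t5 <- interval_track("chr1", 10, 50, "PrAct")
  cons4 <- collapse_chromhmm(list(a = t1, b = t5), c(a = "lum", b = "lum"))$lum
  expect_lte(sum(cons4$end - cons4$start), 40)

  over <- interval_track(c("chr1", "chr1"), c(0, 50), c(100, 150), c("A", "B"))
  expect_error(collapse_chromhmm(list(a = over, b = t1), c(a = "lum", b = "lum")),
               "overlapping")
  expect_error(collapse_chromhmm(list(a = t1), c(a = "lum")), "fewer than 2")
})

test_that("region enrichment counts probes inside labeled intervals", {
  bg <- tibble::tibble(probe = paste0("cg", 1:20), chrom = "chr1",
                       pos = seq(0L, 1900L, 100L))
  track <- interval_track(c("chr1", "chr1"), c(0, 1000), c(1000, 2000),
                          c("EhAct", "QsLow"))
  # query frequencies equal to background give fold 1 for every state
  q_bal <- bg[c(1:5, 11:15), ]
  r_bal <- region_enrichment(q_bal, track, bg)
  expect_equal(r_bal$fold, c(1, 1))
  # all query probes in one state: fold = 1 / background rate
  q_all <- bg[1:10, ]
  r_all <- region_enrichment(q_all, track, bg)
  expect_equal(r_all$fold[r_all$query_label == "EhAct"], 2)
  expect_equal(r_all$p[r_all$query_label == "EhAct"],
               oracle_hyper_tail(10, 10, 20, 10), tolerance = 1e-12)
})

test_that("TFBS windows extend 150 bp and merge duplicate sites", {
  x <- 1000L
  probes <- tibble::tibble(probe = "cgX", chrom = "chr1", pos = x)
  bg <- tibble::tibble(probe = c("cgX", paste0("bg", 1:9)), chrom = "chr1",
                       pos = c(x, seq(10000L, 90000L, 10000L)))
  near <- list(TF = interval_track("chr1", x + 100, x + 120, "site"))
  far <- list(TF = interval_track("chr1", x + 200, x + 220, "site"))
  expect_equal(tfbs_enrichment(probes, near, bg)$overlap, 1L)
  expect_equal(tfbs_enrichment(probes, far, bg)$overlap, 0L)

  # duplicated overlapping sites count once after merging
  dup <- list(TF = interval_track(c("chr1", "chr1"), c(x + 100, x + 110),
                                  c(x + 120, x + 130), "site"))
  expect_identical(tfbs_enrichment(probes, dup, bg), tfbs_enrichment(probes, near, bg))
})

test_that("loop membership needs the two opposite anchors", {
  loops <- loop_set("chr1", startA = 0, endA = 100, startB = 1000, endB = 1100)
  probe_pos <- tibble::tibble(probe = c("cgA", "cgB"), chrom = "chr1",
                              pos = c(50L, 1050L))
  tss <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1", pos = c(1050L, 60L))
  # probe in anchor A, TSS in anchor B (and the mirrored orientation)
  r1 <- loop_enrichment(tibble::tibble(probe = "cgA", gene = "gA"),
                        loops, probe_pos, tss)
  expect_equal(r1$overlap, 1L)
  r2 <- loop_enrichment(tibble::tibble(probe = "cgB", gene = "gB"),
                        loops, probe_pos, tss)
  expect_equal(r2$overlap, 1L)
  # both members inside the same anchor does not count
  r3 <- loop_enrichment(tibble::tibble(probe = "cgA", gene = "gB"),
                        loops, probe_pos, tss)
  expect_equal(r3$overlap, 0L)
})

test_that("loop enrichment equals brute-force enumeration on a toy genome", {
  set.seed(8)
  probe_pos <- tibble::tibble(probe = paste0("cg", 1:10), chrom = "chr1",
                              pos = as.integer(sample(0:5000, 10)))
  tss <- tibble::tibble(gene = paste0("g", 1:10), chrom = "chr1",
                        pos = as.integer(sample(0:5000, 10)))
  anchors <- as.integer(sample(0:4500, 6))
  loops <- loop_set("chr1", startA = anchors[1:3], endA = anchors[1:3] + 400L,
                    startB = anchors[4:6], endB = anchors[4:6] + 400L)
  query <- tidyr::expand_grid(probe = probe_pos$probe[1:5], gene = tss$gene[1:5])
  res <- loop_enrichment(query, loops, probe_pos, tss)

  inside <- function(pos, s, e) pos >= s & pos < e
  in_loop <- function(p, g) {
    pp <- probe_pos$pos[probe_pos$probe == p]
    gp <- tss$pos[tss$gene == g]
    any(inside(pp, loops$startA, loops$endA) & inside(gp, loops$startB, loops$endB) |
          inside(pp, loops$startB, loops$endB) & inside(gp, loops$startA, loops$endA))
  }
  all_pairs <- tidyr::expand_grid(probe = probe_pos$probe, gene = tss$gene)
  K <- sum(mapply(in_loop, all_pairs$probe, all_pairs$gene))
  k <- sum(mapply(in_loop, query$probe, query$gene))
  expect_equal(res$overlap, k)
  expect_equal(res$background_hits, K)
  expect_equal(res$fold, (k / nrow(query)) / (K / nrow(all_pairs)))
  expect_equal(res$p, oracle_hyper_tail(k, K, nrow(all_pairs), nrow(query)),
               tolerance = 1e-12)
})
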