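# Hypergeometric enrichment of gene lists against gene set collections, of
# CpGs against chromatin-state and TF-binding-site tracks, and of CpG-gene
# pairs against chromatin loop anchors. All p-values are upper hypergeometric
# tails P(X >= overlap); fold enrichment is the query annotation frequency
# over the background annotation frequency. Interval arithmetic is delegated
# to GenomicRanges behind the 0-based half-open track surface.

hyper_p <- function(k, K, N, n) {
  # P(X >= k) drawing n from N with K annotated
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

enrich_row <- function(label, k, n, K, N) {
  tibble::tibble(query_label = label, overlap = as.integer(k),
                 query_size = as.integer(n), background_hits = as.integer(K),
                 background_size = as.integer(N),
                 fold = if (K > 0) (k / n) / (K / N) else NA_real_,
                 p = hyper_p(k, K, N, n))
}

#' Hypergeometric gene set enrichment
#'
#' One test per gene set: the overlap between the query genes and the set
#' (both intersected with the universe) against the hypergeometric null of
#' drawing `length(query)` genes from the universe. P-values are
#' BH-corrected across sets.
#'
#' @param query Character vector of query gene ids (must lie within
#'   `universe`).
#' @param sets A named list of gene id vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @return A tibble with one row per set: `query_label`, `overlap`,
#'   `query_size`, `background_hits`, `background_size`, `fold`, `p`, `q`.
#' @export
hypergeom_gene_sets <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0 || length(query) == 0) {
    stop_methrx("query and universe must be non-empty")
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop_methrx(paste0("query gene(s) outside the universe: ",
                       paste(head(outside, 5), collapse = ", ")))
  }
  n <- length(query); N <- length(universe)
  out <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    enrich_row(nm, length(intersect(query, set)), n, length(set), N)
  }))
  out$q <- bh_adjust(out$p)
  out
}

#' Collapse chromatin-state tracks into a subtype consensus
#'
#' For every subtype with at least two cell lines, keeps the genomic
#' positions where all lines of the subtype carry the same chromatin state
#' (positions uncovered by any line, or with discordant states, are
#' omitted), and merges adjacent same-state pieces into maximal intervals.
#'
#' @param tracks Named list of [interval_track()] tibbles, one per cell
#'   line; intervals within a track must not overlap.
#' @param subtype_map Named character vector mapping cell line name to
#'   subtype.
#' @return A named list of consensus [interval_track()] tibbles, one per
#'   subtype.
#' @export
collapse_chromhmm <- function(tracks, subtype_map) {
  unknown <- setdiff(names(subtype_map), names(tracks))
  if (length(unknown)) {
    stop_methrx(paste0("subtype_map names missing from tracks: ",
                       paste(unknown, collapse = ", ")))
  }
  for (nm in names(tracks)) {
    gr <- track_to_granges(tracks[[nm]])
    if (length(gr) > 1 && any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
      stop_methrx(sprintf("track '%s' has overlapping intervals", nm))
    }
  }
  subtypes <- unique(subtype_map)
  out <- lapply(subtypes, function(st) {
    lines <- names(subtype_map)[subtype_map == st]
    if (length(lines) < 2) {
      stop_methrx(sprintf("subtype '%s' has fewer than 2 cell lines", st))
    }
    grs <- lapply(tracks[lines], track_to_granges)
    pieces <- GenomicRanges::disjoin(unlist(methods::as(grs, "GRangesList")))
    labels <- vapply(seq_along(pieces), function(i) {
      lab <- vapply(grs, function(g) {
        hit <- IRanges::findOverlapPairs(pieces[i], g, type = "within")
        if (length(hit) == 0) NA_character_ else S4Vectors::second(hit)$label[1]
      }, character(1))
      if (anyNA(lab) || length(unique(lab)) != 1) NA_character_ else lab[1]
    }, character(1))
    keep <- !is.na(labels)
    if (!any(keep)) {
      return(interval_track(character(), integer(), integer(), character()))
    }
    pieces <- pieces[keep]
    labels <- labels[keep]
    # merge adjacent pieces with equal state into maximal intervals
    merged <- lapply(unique(labels), function(lab) {
      red <- GenomicRanges::reduce(pieces[labels == lab])
      tibble::tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                     start = GenomicRanges::start(red) - 1L,
                     end = GenomicRanges::end(red), label = lab)
    })
    tbl <- dplyr::arrange(dplyr::bind_rows(merged), .data$chrom, .data$start)
    interval_track(tbl$chrom, tbl$start, tbl$end, tbl$label)
  })
  names(out) <- subtypes
  out
}

# Count probes (1-bp positions) falling inside intervals of each label.
probe_state_hits <- function(probes, track) {
  gr_p <- probes_to_granges(probes)
  gr_t <- track_to_granges(track)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_t)
  tibble::tibble(probe = gr_p$probe[S4Vectors::queryHits(hits)],
                 label = gr_t$label[S4Vectors::subjectHits(hits)]) |>
    dplyr::distinct()
}

#' CpG enrichment in chromatin states
#'
#' For every state label in the track, tests whether the query probes fall
#' inside intervals of that state more often than the background probes do,
#' by an upper hypergeometric tail with the background as the urn. P-values
#' are BH-corrected across states.
#'
#' @param query Probe position tibble (`probe`, `chrom`, `pos`; 0-based
#'   1-bp positions); probe ids must be a subset of `background`'s.
#' @param track An [interval_track()] of labeled states.
#' @param background Probe position tibble for the background universe
#'   (e.g. all array probes).
#' @return An enrichment tibble, one row per state (see
#'   [hypergeom_gene_sets()] for columns).
#' @export
region_enrichment <- function(query, track, background) {
  outside <- setdiff(query$probe, background$probe)
  if (length(outside)) {
    stop_methrx(paste0("query probe(s) outside the background: ",
                       paste(head(outside, 5), collapse = ", ")))
  }
  bg_hits <- probe_state_hits(background, track)
  n <- length(unique(query$probe)); N <- length(unique(background$probe))
  out <- dplyr::bind_rows(lapply(sort(unique(track$label)), function(st) {
    in_state <- bg_hits$probe[bg_hits$label == st]
    enrich_row(st, length(intersect(query$probe, in_state)), n, length(in_state), N)
  }))
  out$q <- bh_adjust(out$p)
  out
}

#' CpG enrichment in transcription factor binding sites
#'
#' Each probe's 1-bp position is extended by `window` bp on both sides
#' (default 150, giving a 301-bp half-open window); a probe hits a TF when
#' its window intersects any of the TF's sites after union-merging the
#' sites across experiments. One hypergeometric test per TF, BH-corrected
#' across TFs.
#'
#' @param query,background Probe position tibbles (`probe`, `chrom`, `pos`).
#' @param tf_tracks Named list of [interval_track()] tibbles, one per TF.
#' @param window Extension in bp on each side of the probe position.
#' @return An enrichment tibble, one row per TF.
#' @export
tfbs_enrichment <- function(query, tf_tracks, background, window = 150) {
  outside <- setdiff(query$probe, background$probe)
  if (length(outside)) {
    stop_methrx(paste0("query probe(s) outside the background: ",
                       paste(head(outside, 5), collapse = ", ")))
  }
  win <- function(probes) {
    GenomicRanges::GRanges(probes$chrom,
                           IRanges::IRanges(start = probes$pos - window + 1L,
                                            end = probes$pos + window + 1L),
                           probe = probes$probe)
  }
  bg_gr <- win(background)
  n <- length(unique(query$probe)); N <- length(unique(background$probe))
  out <- dplyr::bind_rows(lapply(names(tf_tracks), function(tf) {
    sites <- GenomicRanges::reduce(track_to_granges(tf_tracks[[tf]]))
    hit_probes <- unique(bg_gr$probe[S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bg_gr, sites))])
    enrich_row(tf, length(intersect(query$probe, hit_probes)), n,
               length(hit_probes), N)
  }))
  out$q <- bh_adjust(out$p)
  out
}

#' CpG-gene pair enrichment in chromatin loops
#'
#' A pair is "in a loop" when the CpG lies inside one anchor and the gene's
#' transcription start site inside the opposite anchor of the same loop.
#' The query pairs are tested against the background of all possible cis
#' (same-chromosome) probe-gene pairs formed from the supplied positions.
#'
#' @param pairs Tibble with `probe` and `gene` columns: the CpG-gene pairs
#'   to test (e.g. a bicluster's pairs). Pairs whose members lie on
#'   different chromosomes, or whose gene has no TSS, are dropped with a
#'   message.
#' @param loops A `loop_set` of cis loops.
#' @param probe_pos Probe position tibble (`probe`, `chrom`, `pos`).
#' @param gene_tss Gene TSS tibble (`gene`, `chrom`, `pos`).
#' @return A one-row enrichment tibble (no multiplicity correction: single
#'   test).
#' @export
loop_enrichment <- function(pairs, loops, probe_pos, gene_tss) {
  no_tss <- setdiff(pairs$gene, gene_tss$gene)
  if (length(no_tss)) {
    rlang::inform(paste0("loop_enrichment: dropping pair(s) for gene(s) without TSS: ",
                         paste(head(no_tss, 5), collapse = ", ")))
  }
  no_pos <- setdiff(pairs$probe, probe_pos$probe)
  if (length(no_pos)) {
    stop_methrx(paste0("probe(s) without position: ", paste(head(no_pos, 5), collapse = ", ")))
  }
  pp <- setNames(seq_len(nrow(probe_pos)), probe_pos$probe)
  gg <- setNames(seq_len(nrow(gene_tss)), gene_tss$gene)
  pairs <- pairs[pairs$gene %in% gene_tss$gene, c("probe", "gene")]
  pairs <- dplyr::distinct(pairs)
  cis <- probe_pos$chrom[pp[pairs$probe]] == gene_tss$chrom[gg[pairs$gene]]
  if (any(!cis)) {
    rlang::inform(sprintf("loop_enrichment: dropping %d trans pair(s)", sum(!cis)))
    pairs <- pairs[cis, ]
  }
  if (nrow(pairs) == 0) stop_methrx("no usable cis query pairs")

  gr_probe <- probes_to_granges(probe_pos)
  gr_tss <- GenomicRanges::GRanges(gene_tss$chrom,
                                   IRanges::IRanges(start = gene_tss$pos + 1L, width = 1L),
                                   gene = gene_tss$gene)
  anchorA <- GenomicRanges::GRanges(loops$chrom,
                                    IRanges::IRanges(start = loops$startA + 1L, end = loops$endA))
  anchorB <- GenomicRanges::GRanges(loops$chrom,
                                    IRanges::IRanges(start = loops$startB + 1L, end = loops$endB))

  pair_key <- function(p, g) paste(p, g, sep = "\r")
  in_loop_keys <- function(probe_anchor, tss_anchor) {
    hp <- GenomicRanges::findOverlaps(gr_probe, probe_anchor)
    ht <- GenomicRanges::findOverlaps(gr_tss, tss_anchor)
    pt <- tibble::tibble(loop = S4Vectors::subjectHits(hp),
                         probe = gr_probe$probe[S4Vectors::queryHits(hp)])
    tt <- tibble::tibble(loop = S4Vectors::subjectHits(ht),
                         gene = gr_tss$gene[S4Vectors::queryHits(ht)])
    joined <- dplyr::inner_join(pt, tt, by = "loop", relationship = "many-to-many")
    unique(pair_key(joined$probe, joined$gene))
  }
  # opposite ends required: probe in A with TSS in B, or probe in B with TSS in A
  loop_keys <- union(in_loop_keys(anchorA, anchorB), in_loop_keys(anchorB, anchorA))

  # background: all possible cis probe x gene pairs
  bg <- tidyr::expand_grid(pi = seq_len(nrow(probe_pos)), gi = seq_len(nrow(gene_tss)))
  bg <- bg[probe_pos$chrom[bg$pi] == gene_tss$chrom[bg$gi], ]
  bg_keys <- pair_key(probe_pos$probe[bg$pi], gene_tss$gene[bg$gi])
  K <- sum(bg_keys %in% loop_keys)
  N <- length(bg_keys)
  k <- sum(pair_key(pairs$probe, pairs$gene) %in% loop_keys)
  out <- enrich_row("in_loop", k, nrow(pairs), K, N)
  out$q <- out$p
  out
}
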