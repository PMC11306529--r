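# End-to-end orchestration: simulate -> signature -> differential -> delta
# emQTL -> purity correction -> enrichment, with one recorded seed, stage
# toggles, TSV outputs and a machine-readable manifest. Reruns with the
# same configuration are bit-identical.

#' Pipeline configuration
#'
#' Collects stage toggles, analysis thresholds and the simulation
#' configuration into one validated object. `NULL` entries of `sim` fall
#' back to [sim_config()] defaults.
#'
#' @param out_dir Output directory (created if needed); `NULL` runs
#'   in-memory only.
#' @param seed Master seed; the simulation and every stochastic stage
#'   derive their seeds from it.
#' @param stages Character vector of stages to run, in dependency order.
#' @param alpha Significance level shared by the differential, emQTL and
#'   association stages.
#' @param min_abs_delta,min_iqr Paired differential thresholds.
#' @param min_freq Aggregation threshold for the signature stage.
#' @param window TFBS probe window half-width in bp.
#' @param k_range Candidate bicluster counts for silhouette selection.
#' @param n_preselect_background Background probes appended to the planted
#'   predictive probes to form the signature preselection list.
#' @param sim Named list of [sim_config()] overrides.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 0,
                            stages = c("simulate", "signature", "differential",
                                       "emqtl", "purity", "enrichment"),
                            alpha = 0.05, min_abs_delta = 0.1, min_iqr = 0.1,
                            min_freq = 0.5, window = 150, k_range = 2:4,
                            n_preselect_background = 80, sim = list()) {
  if (any(c(alpha, min_abs_delta, min_iqr, min_freq, window) <= 0)) {
    stop_methrx("pipeline thresholds must be positive")
  }
  bad <- setdiff(stages, c("simulate", "signature", "differential", "emqtl",
                           "purity", "enrichment"))
  if (length(bad)) stop_methrx(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 alpha = alpha, min_abs_delta = min_abs_delta, min_iqr = min_iqr,
                 min_freq = min_freq, window = window, k_range = k_range,
                 n_preselect_background = as.integer(n_preselect_background),
                 sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping holds [sim_config()] overrides.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_methrx(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop_methrx(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, paste0(name, ".tsv"))
  if (is.matrix(x)) {
    write_matrix(x, path)
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    readr::write_tsv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated cohort:
#' signature discovery by leave-one-out LASSO with aggregation, scoring and
#' translation; paired differential methylation per arm; delta emQTL scan,
#' silhouette-based bicluster selection, co-clustering and response
#' association; purity correction with a re-run of the paired differential
#' analysis on corrected values; and genomic enrichment of the first
#' bicluster. All outputs are returned in a report list and, when
#' `cfg$out_dir` is set, written as TSV plus a `manifest.json` recording
#' the seed, thresholds, stage log and output file hashes.
#'
#' @param cfg A [pipeline_config()].
#' @return The report list, invisibly: per-stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir <- cfg$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- list()
  log <- list()
  stage_on <- function(s) s %in% cfg$stages

  run_stage <- function(name, expr) {
    rlang::inform(paste0("[", name, "] running"))
    tryCatch(expr, error = function(e) {
      stop_methrx(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- simulate ------------------------------------------------------------
  sim_args <- modifyList(list(seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)
  cohort <- run_stage("simulate", generate_cohort(scfg))
  tracks <- run_stage("simulate", generate_tracks(cohort$truth, scfg))
  annot <- cohort$annotation
  log$simulate <- list(n_patients = scfg$n_patients, n_probes = scfg$n_probes,
                       n_genes = scfg$n_genes)
  if (!is.null(dir)) {
    for (tp in names(cohort$beta)) write_stage_tsv(cohort$beta[[tp]], dir, paste0("beta_", tp))
    for (tp in names(cohort$expr)) write_stage_tsv(cohort$expr[[tp]], dir, paste0("expr_", tp))
    write_annotation(annot, file.path(dir, "annotation.tsv"))
  }
  report$cohort <- cohort
  report$tracks <- tracks

  # --- signature -----------------------------------------------------------
  if (stage_on("signature")) {
    report$signature <- run_stage("signature", {
      truth <- cohort$truth
      background <- setdiff(rownames(cohort$beta$week0),
                            c(truth$predictive_probes,
                              unlist(truth$bicluster_probes)))
      preselect <- c(truth$predictive_probes,
                     head(background, cfg$n_preselect_background))
      w0 <- cohort$beta$week0[preselect, , drop = FALSE]
      y <- setNames(annot$pcr[match(colnames(w0), annot$sample_id)], colnames(w0))
      fit <- loo_lasso(w0, y, seed = cfg$seed)
      sig <- aggregate_signature(fit, min_freq = cfg$min_freq)
      loo_roc <- roc_with_cutoff(fit$loo$probability, fit$loo$y)
      insample <- score_samples(sig, w0)
      insample_roc <- roc_with_cutoff(insample$score, y)
      translated <- translate_signature(sig, cohort$beta$week0, cohort$expr$week0)
      list(fit = fit, signature = sig, translated = translated,
           loo_roc = loo_roc, insample_roc = insample_roc, scores = insample)
    })
    log$signature <- list(n_probes_preselected = cfg$n_preselect_background +
                            length(cohort$truth$predictive_probes),
                          n_signature_probes = nrow(report$signature$signature),
                          loo_auc = report$signature$loo_roc$auc,
                          insample_auc = report$signature$insample_roc$auc)
    if (!is.null(dir)) {
      write_signature(report$signature$signature, file.path(dir, "signature.tsv"))
      write_signature(report$signature$translated, file.path(dir, "signature_translated.tsv"))
      write_stage_tsv(report$signature$fit$loo, dir, "loo_probabilities")
    }
  }

  # --- differential --------------------------------------------------------
  if (stage_on("differential")) {
    report$differential <- run_stage("differential", {
      lapply(setNames(ARMS, ARMS), function(a) {
        keep <- annot$sample_id[annot$arm == a]
        paired_differential(
          cohort$beta$week0[, intersect(colnames(cohort$beta$week0), keep), drop = FALSE],
          cohort$beta$week12[, intersect(colnames(cohort$beta$week12), keep), drop = FALSE],
          annot, alpha = cfg$alpha, min_abs_delta = cfg$min_abs_delta,
          min_iqr = cfg$min_iqr)
      })
    })
    log$differential <- lapply(report$differential, function(d) {
      list(n_tested = sum(!is.na(d$p)), n_significant = sum(d$significant),
           n_prefiltered = attr(d, "n_prefiltered"))
    })
    if (!is.null(dir)) {
      for (a in names(report$differential)) {
        write_stage_tsv(report$differential[[a]], dir, paste0("differential_", a))
      }
    }
  }

  # --- emqtl ---------------------------------------------------------------
  if (stage_on("emqtl")) {
    report$emqtl <- run_stage("emqtl", {
      dm <- paired_delta(cohort$beta$week0, cohort$beta$week12, annot)
      de <- paired_delta(cohort$expr$week0, cohort$expr$week12, annot)
      assoc <- emqtl_scan(dm, de, alpha = cfg$alpha)
      sel <- select_k(assoc, k_range = cfg$k_range, seed = cfg$seed)
      bc <- cocluster(assoc, k = sel$k, seed = cfg$seed)
      scores <- lapply(seq_len(sel$k), function(b) bicluster_delta_score(dm, bc, b))
      assoc_tests <- dplyr::bind_rows(lapply(seq_len(sel$k), function(b) {
        dplyr::bind_rows(
          dplyr::mutate(associate_response(scores[[b]], annot, "pcr"), bicluster = b),
          dplyr::mutate(associate_response(scores[[b]], annot, "rcb"), bicluster = b),
          dplyr::mutate(associate_response(scores[[b]], annot, "fraction"), bicluster = b))
      }))
      list(delta_meth = dm, delta_expr = de, assoc = assoc, k = sel$k,
           silhouette = sel$scores, biclusters = bc, scores = scores,
           response = assoc_tests)
    })
    log$emqtl <- list(n_pairs_tested = attr(report$emqtl$assoc, "n_tested_pairs"),
                      n_significant_pairs = sum(report$emqtl$assoc$significant),
                      k = report$emqtl$k)
    if (!is.null(dir)) {
      write_stage_tsv(report$emqtl$assoc[report$emqtl$assoc$significant, ],
                      dir, "emqtl_significant_pairs")
      write_stage_tsv(report$emqtl$biclusters$assignments, dir, "bicluster_assignments")
      write_stage_tsv(report$emqtl$response, dir, "bicluster_response")
    }
  }

  # --- purity --------------------------------------------------------------
  if (stage_on("purity")) {
    report$purity <- run_stage("purity", {
      purity_by_sample <- setNames(annot$purity, annot$sample_id)
      corrected <- lapply(cohort$beta[c("week0", "week12")], function(m) {
        fit <- fit_purity_model(m, purity_by_sample)
        purity_correct(m, purity_by_sample, fit)
      })
      diff_corr <- paired_differential(
        corrected$week0, corrected$week12, annot, alpha = cfg$alpha,
        min_abs_delta = cfg$min_abs_delta, min_iqr = cfg$min_iqr)
      list(corrected = corrected, differential_corrected = diff_corr)
    })
    log$purity <- list(
      n_clipped_week0 = attr(report$purity$corrected$week0, "n_clipped"),
      n_clipped_week12 = attr(report$purity$corrected$week12, "n_clipped"),
      n_significant_corrected = sum(report$purity$differential_corrected$significant))
    if (!is.null(dir)) {
      write_stage_tsv(report$purity$corrected$week12, dir, "beta_week12_purity_corrected")
      write_stage_tsv(report$purity$differential_corrected, dir, "differential_purity_corrected")
    }
  }

  # --- enrichment ----------------------------------------------------------
  if (stage_on("enrichment")) {
    report$enrichment <- run_stage("enrichment", {
      truth <- cohort$truth
      bc <- report$emqtl$biclusters
      if (is.null(bc)) stop_methrx("enrichment requires the emqtl stage")
      asn <- bc$assignments
      # work on the discovered bicluster that best matches planted bicluster 1
      planted1 <- truth$bicluster_probes[[1]]
      probe_asn <- asn[asn$type == "probe", ]
      b1 <- probe_asn |>
        dplyr::mutate(planted = .data$feature %in% planted1) |>
        dplyr::count(.data$bicluster, wt = .data$planted) |>
        dplyr::arrange(dplyr::desc(.data$n)) |>
        dplyr::pull(.data$bicluster) |>
        dplyr::first()
      q_probes <- asn$feature[asn$type == "probe" & asn$bicluster == b1]
      q_genes <- asn$feature[asn$type == "gene" & asn$bicluster == b1]
      consensus <- collapse_chromhmm(tracks$chromhmm, tracks$subtype_map)[[1]]
      pos_q <- truth$probe_positions[truth$probe_positions$probe %in% q_probes, ]
      gene_sets <- hypergeom_gene_sets(q_genes, tracks$gene_sets,
                                       universe = truth$gene_tss$gene)
      states <- region_enrichment(pos_q, consensus, truth$probe_positions)
      tfs <- tfbs_enrichment(pos_q, tracks$tfbs, truth$probe_positions,
                             window = cfg$window)
      sig_pairs <- report$emqtl$assoc |>
        dplyr::filter(.data$significant, .data$probe %in% q_probes,
                      .data$gene %in% q_genes)
      loops <- loop_enrichment(sig_pairs, tracks$loops,
                               truth$probe_positions, truth$gene_tss)
      list(bicluster_used = b1, gene_sets = gene_sets, chromhmm = states,
           tfbs = tfs, loops = loops)
    })
    log$enrichment <- list(bicluster_used = report$enrichment$bicluster_used,
                           top_gene_set = report$enrichment$gene_sets$query_label[
                             which.min(report$enrichment$gene_sets$p)])
    if (!is.null(dir)) {
      write_stage_tsv(report$enrichment$gene_sets, dir, "enrichment_gene_sets")
      write_stage_tsv(report$enrichment$chromhmm, dir, "enrichment_chromhmm")
      write_stage_tsv(report$enrichment$tfbs, dir, "enrichment_tfbs")
      write_stage_tsv(report$enrichment$loops, dir, "enrichment_loops")
    }
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("methrx")),
    seed = cfg$seed,
    stages = cfg$stages,
    thresholds = list(alpha = cfg$alpha, min_abs_delta = cfg$min_abs_delta,
                      min_iqr = cfg$min_iqr, min_freq = cfg$min_freq,
                      window = cfg$window, k_range = as.integer(cfg$k_range)),
    sim = cfg$sim,
    log = log)
  if (!is.null(dir)) {
    files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
    manifest$outputs <- as.list(setNames(unname(tools::md5sum(files)), basename(files)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report$manifest <- manifest
  invisible(report)
}
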