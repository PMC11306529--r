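# Seeded synthetic-cohort generator. The cohorts carry the statistical
# structure the downstream analyses assume: a bimodal beta-value landscape,
# probes whose pre-treatment methylation separates responders from
# non-responders, paired-timepoint deltas organized into anti-correlated
# CpG-gene bicluster blocks driven by a per-patient latent response factor,
# and tumor-purity mixing with a fixed per-probe non-tumor methylation level
# (the exact identifiability assumption of the purity correction).

#' Simulation configuration
#'
#' Defaults define the reference cohort used throughout the package's tests:
#' 60 patients, 300 probes of which 20 carry a planted mean beta difference
#' of 0.4 between responders and non-responders at week 0, two planted
#' CpG-gene bicluster blocks (30 probes and 20 genes each) whose paired
#' week 0 to week 12 changes are driven by a latent per-patient response
#' factor with opposite signs on methylation and expression, and tumor
#' purity drawn uniformly from (0.3, 0.9).
#'
#' @param n_patients Number of patients (each sampled at all timepoints).
#' @param pcr_prevalence Probability of pathological complete response.
#' @param n_probes,n_genes Total probes and genes.
#' @param n_predictive_probes Probes with a planted week-0 response effect.
#' @param predictive_effect Mean beta difference between response groups at
#'   the planted probes.
#' @param n_biclusters Number of planted delta biclusters.
#' @param n_bicluster_probes,n_bicluster_genes Features per planted bicluster.
#' @param bicluster_effect Scale (beta units) of the latent-factor-driven
#'   methylation deltas inside each bicluster.
#' @param bicluster_meth_sign Sign of the methylation delta per bicluster for
#'   a patient with positive latent factor; expression deltas take the
#'   opposite sign, so CpG-gene delta correlations are negative.
#' @param latent_response_shift Mean shift of the latent factor in responders
#'   (links bicluster deltas to response).
#' @param purity_range Tumor purity is drawn uniformly from this interval.
#' @param noise_sd Measurement noise (beta units) added to observed values
#'   and to planted deltas.
#' @param sample_sd Per-sample biological variation around each probe's
#'   baseline tumor methylation.
#' @param expr_noise_sd Noise on expression deltas (log-intensity units).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 60, pcr_prevalence = 0.3,
                       n_probes = 300, n_genes = 120,
                       n_predictive_probes = 20, predictive_effect = 0.4,
                       n_biclusters = 2, n_bicluster_probes = 30,
                       n_bicluster_genes = 20, bicluster_effect = 0.15,
                       bicluster_meth_sign = c(1, -1),
                       latent_response_shift = 1.5,
                       purity_range = c(0.3, 0.9),
                       noise_sd = 0.03, sample_sd = 0.05,
                       expr_noise_sd = 0.3, seed = 0) {
  cfg <- list(n_patients = as.integer(n_patients), pcr_prevalence = pcr_prevalence,
              n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_predictive_probes = as.integer(n_predictive_probes),
              predictive_effect = predictive_effect,
              n_biclusters = as.integer(n_biclusters),
              n_bicluster_probes = as.integer(n_bicluster_probes),
              n_bicluster_genes = as.integer(n_bicluster_genes),
              bicluster_effect = bicluster_effect,
              bicluster_meth_sign = rep_len(bicluster_meth_sign, n_biclusters),
              latent_response_shift = latent_response_shift,
              purity_range = purity_range, noise_sd = noise_sd,
              sample_sd = sample_sd, expr_noise_sd = expr_noise_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_patients, cfg$n_probes, cfg$n_genes, cfg$n_predictive_probes,
              cfg$n_biclusters, cfg$n_bicluster_probes, cfg$n_bicluster_genes)
  if (any(counts <= 0)) stop_methrx("sim_config counts must be positive")
  if (cfg$n_predictive_probes > cfg$n_probes) {
    stop_methrx("n_predictive_probes cannot exceed n_probes")
  }
  if (cfg$n_predictive_probes + cfg$n_biclusters * cfg$n_bicluster_probes > cfg$n_probes) {
    stop_methrx("planted probes (predictive + bicluster) exceed n_probes")
  }
  if (cfg$n_biclusters * cfg$n_bicluster_genes > cfg$n_genes) {
    stop_methrx("planted bicluster genes exceed n_genes")
  }
  if (!(length(cfg$purity_range) == 2 && cfg$purity_range[1] <= cfg$purity_range[2] &&
        cfg$purity_range[1] > 0 && cfg$purity_range[2] <= 1)) {
    stop_methrx("purity_range must be (lo, hi) within (0, 1] with lo <= hi")
  }
  if (!all(is.finite(c(cfg$predictive_effect, cfg$bicluster_effect, cfg$noise_sd)))) {
    stop_methrx("effects and noise must be finite")
  }
  structure(cfg, class = "sim_config")
}

clip01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

#' Generate a synthetic longitudinal cohort with planted signal
#'
#' Produces observed beta and expression matrices for weeks 0, 12 and 25,
#' per-sample annotation, and the ground truth behind them. Observed beta
#' values mix true tumor methylation with a fixed per-probe non-tumor level:
#' `observed = purity * tumor + (1 - purity) * normal + noise`, clipped to
#' \[0, 1\].
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `beta` and `expr` (named lists of matrices
#'   per timepoint), `annotation` (tibble) and `truth` (list with planted
#'   probe/gene memberships, true tumor betas, purity, the latent response
#'   factor and the toy genome layout).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  probes <- sprintf("cg%06d", seq_len(cfg$n_probes))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # Planted feature memberships: predictive probes first, then bicluster
  # blocks, disjoint by construction.
  predictive <- probes[seq_len(cfg$n_predictive_probes)]
  bc_probes <- lapply(seq_len(cfg$n_biclusters), function(k) {
    offset <- cfg$n_predictive_probes + (k - 1) * cfg$n_bicluster_probes
    probes[offset + seq_len(cfg$n_bicluster_probes)]
  })
  bc_genes <- lapply(seq_len(cfg$n_biclusters), function(k) {
    genes[(k - 1) * cfg$n_bicluster_genes + seq_len(cfg$n_bicluster_genes)]
  })

  # Clinical design.
  pcr <- rbinom(n, 1, cfg$pcr_prevalence) == 1
  if (sum(pcr) < 2) pcr[1:2] <- TRUE
  if (sum(!pcr) < 2) pcr[(n - 1):n] <- FALSE
  arm <- rep(c("combination", "chemo"), length.out = n)
  er <- ifelse(runif(n) < 0.75, "pos", "neg")
  f <- rnorm(n) + cfg$latent_response_shift * as.numeric(pcr)
  fraction_left <- plogis(-1.2 * f + rnorm(n, sd = 0.4))
  fraction_left[pcr] <- pmin(fraction_left[pcr], 0.05)
  rcb_class <- ifelse(pcr | fraction_left < 0.25, "low", "high")

  # Baseline tumor methylation: bimodal probe means; planted predictive
  # probes sit mid-range and separate response groups by predictive_effect.
  low_mode <- runif(cfg$n_probes) < 0.5
  base <- ifelse(low_mode, rbeta(cfg$n_probes, 2, 8), rbeta(cfg$n_probes, 8, 2))
  names(base) <- probes
  base[predictive] <- 0.5
  dir_pred <- rep(c(-1, 1), length.out = cfg$n_predictive_probes)

  tumor_w0 <- matrix(rep(base, n), nrow = cfg$n_probes, ncol = n,
                     dimnames = list(probes, patients))
  shift <- outer(dir_pred * cfg$predictive_effect, as.numeric(pcr) - 0.5)
  tumor_w0[predictive, ] <- tumor_w0[predictive, ] + shift
  tumor_w0 <- clip01(tumor_w0 + matrix(rnorm(length(tumor_w0), sd = cfg$sample_sd),
                                       nrow = cfg$n_probes))

  # Paired deltas: inside bicluster k the methylation delta is
  # sign_k * effect * f_i + noise; the expression delta takes the opposite
  # sign, giving negative CpG-gene delta correlations.
  delta_meth <- matrix(0, cfg$n_probes, n, dimnames = list(probes, patients))
  for (k in seq_len(cfg$n_biclusters)) {
    s <- cfg$bicluster_meth_sign[k] * cfg$bicluster_effect
    block <- outer(rep(s, length(bc_probes[[k]])), f) +
      matrix(rnorm(length(bc_probes[[k]]) * n, sd = cfg$noise_sd),
             nrow = length(bc_probes[[k]]))
    delta_meth[bc_probes[[k]], ] <- block
  }
  tumor_w12 <- clip01(tumor_w0 + delta_meth)
  tumor_w25 <- clip01(tumor_w12 + matrix(rnorm(length(tumor_w12), sd = cfg$noise_sd),
                                         nrow = cfg$n_probes))
  tumor <- list(week0 = tumor_w0, week12 = tumor_w12, week25 = tumor_w25)

  # Non-tumor methylation is a fixed per-probe constant, so the purity
  # correction's identifiability assumption holds exactly here.
  normal <- rbeta(cfg$n_probes, 2, 2)
  names(normal) <- probes

  purity <- lapply(TIMEPOINTS, function(tp) {
    p <- runif(n, cfg$purity_range[1], cfg$purity_range[2])
    names(p) <- patients
    p
  })
  names(purity) <- TIMEPOINTS

  beta <- lapply(TIMEPOINTS, function(tp) {
    p <- purity[[tp]]
    obs <- sweep(tumor[[tp]], 2, p, `*`) + outer(normal, 1 - p) +
      matrix(rnorm(cfg$n_probes * n, sd = cfg$noise_sd), nrow = cfg$n_probes)
    colnames(obs) <- paste0(patients, "_", tp)
    clip01(obs)
  })
  names(beta) <- TIMEPOINTS

  # Expression: gene baselines on a log-intensity scale; week-12 deltas are
  # the anti-correlated mirror of the methylation deltas.
  gene_base <- rnorm(cfg$n_genes, mean = 7, sd = 1)
  expr_w0 <- matrix(gene_base, cfg$n_genes, n, dimnames = list(genes, patients)) +
    matrix(rnorm(cfg$n_genes * n, sd = 0.5), nrow = cfg$n_genes)
  delta_expr <- matrix(rnorm(cfg$n_genes * n, sd = cfg$expr_noise_sd),
                       nrow = cfg$n_genes, dimnames = list(genes, patients))
  for (k in seq_len(cfg$n_biclusters)) {
    s <- -cfg$bicluster_meth_sign[k]  # opposite sign to methylation
    delta_expr[bc_genes[[k]], ] <- delta_expr[bc_genes[[k]], ] +
      outer(rep(s, length(bc_genes[[k]])), f)
  }
  expr_w12 <- expr_w0 + delta_expr
  expr_w25 <- expr_w12 + matrix(rnorm(cfg$n_genes * n, sd = cfg$expr_noise_sd),
                                nrow = cfg$n_genes)
  expr <- list(week0 = expr_w0, week12 = expr_w12, week25 = expr_w25)
  for (tp in TIMEPOINTS) colnames(expr[[tp]]) <- paste0(patients, "_", tp)

  annotation <- dplyr::bind_rows(lapply(TIMEPOINTS, function(tp) {
    tibble::tibble(sample_id = paste0(patients, "_", tp), patient_id = patients,
                   timepoint = tp, arm = arm, er_status = er, pcr = pcr,
                   rcb_class = rcb_class, tumor_fraction_left = fraction_left,
                   purity = purity[[tp]])
  }))
  annotation <- as_cohort_annotation(annotation)

  # Toy genome layout used by generate_tracks(): probes and TSSs spaced
  # 1 kb apart on one chromosome, so all pairs are cis.
  probe_positions <- tibble::tibble(probe = probes, chrom = "chr1",
                                    pos = 1000L * seq_len(cfg$n_probes) - 500L)
  gene_tss <- tibble::tibble(gene = genes, chrom = "chr1",
                             pos = 1000L * cfg$n_probes + 1000L * seq_len(cfg$n_genes))

  membership <- tibble::tibble(
    feature = c(unlist(bc_probes), unlist(bc_genes)),
    type = c(rep("probe", cfg$n_biclusters * cfg$n_bicluster_probes),
             rep("gene", cfg$n_biclusters * cfg$n_bicluster_genes)),
    bicluster = c(rep(seq_len(cfg$n_biclusters), each = cfg$n_bicluster_probes),
                  rep(seq_len(cfg$n_biclusters), each = cfg$n_bicluster_genes)))

  truth <- list(predictive_probes = predictive, bicluster_membership = membership,
                bicluster_probes = bc_probes, bicluster_genes = bc_genes,
                tumor_beta = tumor, normal_beta = normal, purity = purity,
                latent_factor = setNames(f, patients),
                probe_positions = probe_positions, gene_tss = gene_tss)

  list(beta = beta, expr = expr, annotation = annotation, truth = truth, config = cfg)
}

#' Generate annotation tracks consistent with a simulated cohort
#'
#' Builds toy genomic context matched to the planted biclusters: bicluster-1
#' probes fall inside active-enhancer (`EhAct`) chromatin segments and inside
#' the planted transcription factor's binding sites, bicluster-1 CpG-gene
#' pairs are connected by loop anchors, and the gene set collection contains
#' one set per planted bicluster plus random background sets. Background
#' probes receive enhancer/TF annotation at a fixed background rate.
#'
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param cfg The [sim_config()] used to generate the cohort.
#' @param cell_lines Names of the simulated chromatin-state tracks.
#' @param background_rate Annotation rate for background probes.
#' @return A list with `gene_sets`, `chromhmm` (named list of
#'   [interval_track()] per cell line), `subtype_map`, `tfbs` (named list per
#'   TF) and `loops` (a `loop_set`).
#' @export
generate_tracks <- function(truth, cfg, cell_lines = c("lineA", "lineB"),
                            background_rate = 0.1) {
  set.seed(cfg$seed + 1L)
  pos <- truth$probe_positions
  tss <- truth$gene_tss
  bc1_probes <- truth$bicluster_probes[[1]]
  bc1_genes <- truth$bicluster_genes[[1]]
  is_bc1 <- pos$probe %in% bc1_probes
  planted <- unlist(truth$bicluster_probes)

  # Chromatin states: each probe owns a 1 kb segment; bicluster-1 segments
  # are enhancers, background segments are enhancers at background_rate and
  # quiescent otherwise. The second cell line disagrees on a small fraction
  # of background segments, exercising the consensus step.
  seg_start <- pos$pos - 500L
  seg_end <- pos$pos + 500L
  base_state <- ifelse(is_bc1, "EhAct",
                       ifelse(runif(nrow(pos)) < background_rate, "EhAct", "QsLow"))
  chromhmm <- lapply(seq_along(cell_lines), function(i) {
    state <- base_state
    if (i > 1) {
      flip <- !is_bc1 & runif(length(state)) < 0.05
      state[flip] <- ifelse(state[flip] == "EhAct", "QsLow", "EhAct")
    }
    interval_track(pos$chrom, seg_start, seg_end, state)
  })
  names(chromhmm) <- cell_lines
  subtype_map <- setNames(rep("simulated", length(cell_lines)), cell_lines)

  # TF binding sites: the planted TF covers every bicluster-1 probe (sites
  # within the 150 bp window) and background probes at background_rate; a
  # second TF binds uniformly at random.
  tf_site <- function(keep) {
    interval_track(pos$chrom[keep], pos$pos[keep] - 50L, pos$pos[keep] + 50L, "site")
  }
  planted_tf_hits <- is_bc1 | (!pos$probe %in% planted & runif(nrow(pos)) < background_rate)
  other_tf_hits <- runif(nrow(pos)) < background_rate
  tfbs <- list(TF_planted = tf_site(planted_tf_hits),
               TF_background = tf_site(other_tf_hits))

  # Loops: each bicluster-1 probe loops to a bicluster-1 gene TSS, plus
  # random background loops between non-planted probes and genes.
  gene_for_probe <- rep_len(bc1_genes, length(bc1_probes))
  tss_pos <- setNames(tss$pos, tss$gene)
  probe_pos <- setNames(pos$pos, pos$probe)
  avail_p <- pos$probe[!pos$probe %in% planted]
  avail_g <- setdiff(tss$gene, unlist(truth$bicluster_genes))
  bg_probes <- sample(avail_p, min(10, length(avail_p)))
  bg_genes <- sample(avail_g, min(10, length(avail_g)))
  bg_genes <- rep_len(bg_genes, length(bg_probes))
  loops <- loop_set(
    chrom = "chr1",
    startA = c(probe_pos[bc1_probes] - 250L, probe_pos[bg_probes] - 250L),
    endA = c(probe_pos[bc1_probes] + 250L, probe_pos[bg_probes] + 250L),
    startB = c(tss_pos[gene_for_probe] - 250L, tss_pos[bg_genes] - 250L),
    endB = c(tss_pos[gene_for_probe] + 250L, tss_pos[bg_genes] + 250L))

  # Gene sets: one set per planted bicluster plus random background sets.
  sets <- c(lapply(truth$bicluster_genes, identity),
            lapply(1:3, function(i) sample(tss$gene, min(15, length(tss$gene)))))
  names(sets) <- c(sprintf("PLANTED_BICLUSTER_%d", seq_along(truth$bicluster_genes)),
                   sprintf("RANDOM_SET_%d", 1:3))
  gene_sets <- structure(sets, class = "gene_set_collection")

  list(gene_sets = gene_sets, chromhmm = chromhmm, subtype_map = subtype_map,
       tfbs = tfbs, loops = loops)
}
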