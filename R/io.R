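# Readers and writers for every on-disk format the pipeline touches:
# probe/gene x sample TSV matrices, cohort annotation TSV, signature TSV,
# GMT gene sets, BED4 interval tracks and BEDPE loops. All coordinates are
# 0-based half-open (BED convention); CpG probes are 1-bp intervals
# [pos, pos + 1). Numeric values are written with full (17 significant
# digit) precision so that write -> read is an exact round trip.

TIMEPOINTS <- c("week0", "week12", "week25")
ARMS <- c("combination", "chemo")
ER_LEVELS <- c("pos", "neg", "unknown")
RCB_LEVELS <- c("low", "high")

fmt_num <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

#' Read a probe or gene by sample matrix from TSV
#'
#' The first column holds feature ids (probes or genes), the header row holds
#' sample ids. Empty cells become missing values. Beta matrices are validated
#' against the \[0, 1\] range; expression matrices only need finite entries.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"beta"` for methylation beta values, `"expr"` for (log-scale)
#'   expression intensities.
#' @return A numeric matrix with feature row names and sample column names.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' write_matrix(m, p)
#' all.equal(read_matrix(p, "beta"), m)
read_matrix <- function(path, kind = c("beta", "expr")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE)
  ids <- df[[1]]
  cols <- lapply(df[, -1, drop = FALSE], function(x) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is.na(x)
    if (any(bad)) {
      stop_methrx(sprintf("non-numeric cell '%s' in %s", x[which(bad)[1]], basename(path)))
    }
    v
  })
  m <- do.call(cbind, cols)
  if (is.null(m)) stop_methrx(sprintf("%s has no sample columns", basename(path)))
  rownames(m) <- ids
  validate_matrix(m, kind = kind, what = basename(path))
}

#' Write a feature by sample matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (feature id) column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature") {
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a per-sample cohort annotation table
#'
#' Required columns: `sample_id`, `patient_id`, `timepoint`
#' (`week0`/`week12`/`week25`) and `arm` (`combination`/`chemo`). Optional
#' columns `er_status` (`pos`/`neg`/`unknown`), `pcr` (logical), `rcb_class`
#' (`low` = RCB 0/I, `high` = RCB II/III), `tumor_fraction_left` (>= 0) and
#' `purity` (in (0, 1\]) are filled with missing values when absent. Each
#' patient may contribute at most one sample per timepoint.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A validated tibble, one row per sample.
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE)
  as_cohort_annotation(df)
}

#' Validate a data frame of cohort annotation
#'
#' @param df Data frame with at least `sample_id`, `patient_id`, `timepoint`
#'   and `arm`; see [read_annotation()] for the full column contract.
#' @return A validated tibble with the canonical column set and types.
#' @export
as_cohort_annotation <- function(df) {
  need <- c("sample_id", "patient_id", "timepoint", "arm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_methrx(paste0("annotation is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    patient_id = as.character(df$patient_id),
    timepoint = as.character(df$timepoint),
    arm = as.character(df$arm),
    er_status = if ("er_status" %in% names(df)) as.character(df$er_status) else NA_character_,
    pcr = if ("pcr" %in% names(df)) as.logical(df$pcr) else NA,
    rcb_class = if ("rcb_class" %in% names(df)) as.character(df$rcb_class) else NA_character_,
    tumor_fraction_left = if ("tumor_fraction_left" %in% names(df))
      as.numeric(df$tumor_fraction_left) else NA_real_,
    purity = if ("purity" %in% names(df)) as.numeric(df$purity) else NA_real_
  )
  bad_tp <- setdiff(unique(out$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    stop_methrx(paste0("unknown timepoint value(s): ", paste(bad_tp, collapse = ", "),
                       " (expected ", paste(TIMEPOINTS, collapse = "/"), ")"))
  }
  bad_arm <- setdiff(unique(out$arm), ARMS)
  if (length(bad_arm)) {
    stop_methrx(paste0("unknown arm value(s): ", paste(bad_arm, collapse = ", ")))
  }
  out$er_status[is.na(out$er_status)] <- "unknown"
  bad_er <- setdiff(unique(out$er_status), ER_LEVELS)
  if (length(bad_er)) stop_methrx(paste0("unknown er_status value(s): ", paste(bad_er, collapse = ", ")))
  bad_rcb <- setdiff(unique(out$rcb_class[!is.na(out$rcb_class)]), RCB_LEVELS)
  if (length(bad_rcb)) stop_methrx(paste0("unknown rcb_class value(s): ", paste(bad_rcb, collapse = ", ")))
  if (anyDuplicated(out$sample_id)) stop_methrx("duplicate sample_id in annotation")
  key <- paste(out$patient_id, out$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), c("patient_id", "timepoint")]
    stop_methrx(sprintf("duplicated (patient_id, timepoint): %s at %s",
                        dup$patient_id[1], dup$timepoint[1]))
  }
  if (any(!is.na(out$tumor_fraction_left) & out$tumor_fraction_left < 0)) {
    stop_methrx("tumor_fraction_left must be >= 0")
  }
  if (any(!is.na(out$purity) & (out$purity <= 0 | out$purity > 1))) {
    stop_methrx("purity must lie in (0, 1]")
  }
  out
}

#' Write a cohort annotation table to TSV
#' @param annot Annotation tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  out <- annot
  out$tumor_fraction_left <- fmt_num(out$tumor_fraction_left)
  out$purity <- fmt_num(out$purity)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# ---- signatures -----------------------------------------------------------

new_signature <- function(tbl, intercept, feature_col) {
  stopifnot(feature_col %in% names(tbl))
  # A translated signature may map two CpGs to the same gene (scores sum
  # over entries), so uniqueness is enforced on the provenance probe there.
  key <- if (feature_col == "gene" && "probe" %in% names(tbl) && !anyNA(tbl$probe)) {
    tbl$probe
  } else {
    tbl[[feature_col]]
  }
  if (anyDuplicated(key)) {
    stop_methrx(sprintf("duplicate %s ids in signature",
                        if (identical(key, tbl[[feature_col]])) feature_col else "probe"))
  }
  if ("rho" %in% names(tbl) && any(abs(tbl$rho) > 1 + 1e-12, na.rm = TRUE)) {
    stop_methrx("signature rho values must lie in [-1, 1]")
  }
  structure(tbl,
            intercept = as.numeric(intercept),
            class = c(if (feature_col == "probe") "meth_signature" else "expr_signature",
                      class(tbl)))
}

#' Construct a CpG methylation signature
#'
#' A sparse linear model over probes: per-probe coefficients plus an
#' intercept, with optional per-probe metadata (annotated gene, the Pearson
#' correlation `rho` between the probe's methylation and that gene's
#' expression, and a functional cluster label).
#'
#' @param probe Character vector of unique probe ids.
#' @param coef Numeric coefficients, one per probe.
#' @param intercept Model intercept (default 0).
#' @param gene,rho,cluster Optional per-probe metadata.
#' @return A tibble of class `meth_signature` with an `intercept` attribute.
#' @export
meth_signature <- function(probe, coef, intercept = 0, gene = NA_character_,
                           rho = NA_real_, cluster = NA_character_) {
  new_signature(tibble::tibble(probe = as.character(probe), coef = as.numeric(coef),
                               gene = gene, rho = rho, cluster = cluster),
                intercept, "probe")
}

#' Construct a translated gene expression signature
#'
#' @param gene Character vector of unique gene ids.
#' @param coef Numeric coefficients (probe coefficient times `rho`).
#' @param intercept Model intercept.
#' @param probe,rho Provenance: the source probe and the signed correlation
#'   used to translate its coefficient.
#' @return A tibble of class `expr_signature` with an `intercept` attribute.
#' @export
expr_signature <- function(gene, coef, intercept = 0, probe = NA_character_,
                           rho = NA_real_) {
  new_signature(tibble::tibble(gene = as.character(gene), coef = as.numeric(coef),
                               probe = probe, rho = rho),
                intercept, "gene")
}

#' Read or write a signature TSV
#'
#' The on-disk format is a TSV whose first column is `probe` (methylation
#' signature) or `gene` (expression signature), a `coef` column, optional
#' metadata columns (`gene`/`probe`, `rho`, `cluster`, ...), and the model
#' intercept stored in a `# intercept: <value>` comment line.
#'
#' @param path Path to the signature file.
#' @return For `read_signature()`, a `meth_signature` or `expr_signature`
#'   tibble depending on the leading column.
#' @export
read_signature <- function(path) {
  lines <- readr::read_lines(path)
  ic_line <- grep("^#\\s*intercept:", lines, value = TRUE)
  intercept <- if (length(ic_line)) as.numeric(sub("^#\\s*intercept:\\s*", "", ic_line[1])) else 0
  df <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                        col_types = readr::cols(.default = readr::col_guess()),
                        na = c("", "NA"), progress = FALSE)
  if (!"coef" %in% names(df)) stop_methrx("signature file must have a 'coef' column")
  first <- names(df)[1]
  if (!first %in% c("probe", "gene")) {
    stop_methrx("signature file must start with a 'probe' or 'gene' column")
  }
  df[[1]] <- as.character(df[[1]])
  new_signature(tibble::as_tibble(df), intercept, first)
}

#' @rdname read_signature
#' @param sig A `meth_signature` or `expr_signature`.
#' @export
write_signature <- function(sig, path) {
  df <- tibble::as_tibble(sig)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  header <- sprintf("# intercept: %s", fmt_num(attr(sig, "intercept") %||% 0))
  body <- c(paste(names(df), collapse = "\t"),
            do.call(paste, c(lapply(df, function(x) ifelse(is.na(x), "", x)),
                             sep = "\t")))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Intercept of a signature
#' @param sig A `meth_signature` or `expr_signature`.
#' @return The scalar model intercept.
#' @export
sig_intercept <- function(sig) attr(sig, "intercept") %||% 0

# ---- gene sets ------------------------------------------------------------

#' Read a GMT gene set collection
#'
#' Standard GMT dialect: one set per line, tab-separated, the first field the
#' set name, the second a description (ignored), remaining fields gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_methrx(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop_methrx("duplicate gene set names in GMT")
  if (any(lengths(sets) == 0)) stop_methrx("empty gene set in GMT")
  structure(sets, class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- interval tracks and loops --------------------------------------------

#' Construct a labeled genomic interval track
#'
#' Intervals use the BED convention: 0-based half-open `[start, end)`.
#'
#' @param chrom,start,end,label Vectors describing the intervals.
#' @return A tibble of class `interval_track`.
#' @export
interval_track <- function(chrom, start, end, label = ".") {
  tbl <- tibble::tibble(chrom = as.character(chrom), start = as.integer(start),
                        end = as.integer(end), label = as.character(label))
  if (any(tbl$start < 0)) stop_methrx("negative interval coordinates")
  if (any(tbl$start >= tbl$end)) {
    i <- which(tbl$start >= tbl$end)[1]
    stop_methrx(sprintf("interval start >= end at %s:%d-%d", tbl$chrom[i], tbl$start[i], tbl$end[i]))
  }
  class(tbl) <- c("interval_track", class(tbl))
  tbl
}

#' Read a BED4 interval track
#'
#' @param path Path to a BED file with columns chrom, start, end and
#'   (optionally) a label; extra columns are ignored.
#' @return An [interval_track()] tibble.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 3)) {
    stop_methrx(sprintf("malformed BED line %d: fewer than 3 fields", which(nfield < 3)[1]))
  }
  chrom <- vapply(f, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop_methrx(sprintf("malformed BED line %d: non-integer coordinates",
                        which(is.na(start) | is.na(end))[1]))
  }
  label <- ifelse(nfield >= 4, vapply(f, function(x) x[4] %||% ".", character(1)), ".")
  if (any(start >= end)) {
    stop_methrx(sprintf("BED line %d: start >= end", which(start >= end)[1]))
  }
  interval_track(chrom, start, end, label)
}

#' Write an interval track as BED4
#' @param track An [interval_track()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  readr::write_lines(paste(track$chrom, track$start, track$end, track$label, sep = "\t"), path)
  invisible(path)
}

#' Read a BEDPE loop file, keeping cis loops only
#'
#' Pairs whose two anchors lie on different chromosomes (trans loops) are
#' dropped; the dropped count is reported via a message and stored in the
#' `n_trans_dropped` attribute.
#'
#' @param path Path to a BEDPE file (6+ tab-separated columns).
#' @return A tibble of class `loop_set` with columns `chrom`, `startA`,
#'   `endA`, `startB`, `endB`.
#' @export
read_bedpe <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6)) {
    stop_methrx(sprintf("malformed BEDPE line %d: fewer than 6 fields", which(lengths(f) < 6)[1]))
  }
  col <- function(i) vapply(f, `[`, character(1), i)
  ints <- function(i) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) stop_methrx(sprintf("malformed BEDPE line %d: non-integer coordinate", which(is.na(v))[1]))
    v
  }
  tbl <- tibble::tibble(chromA = col(1), startA = ints(2), endA = ints(3),
                        chromB = col(4), startB = ints(5), endB = ints(6))
  if (any(tbl$startA >= tbl$endA | tbl$startB >= tbl$endB)) {
    stop_methrx("BEDPE anchor with start >= end")
  }
  cis <- tbl$chromA == tbl$chromB
  n_trans <- sum(!cis)
  if (n_trans > 0) {
    rlang::inform(sprintf("read_bedpe: dropped %d trans loop(s); %d cis loops kept",
                          n_trans, sum(cis)))
  }
  out <- tibble::tibble(chrom = tbl$chromA[cis], startA = tbl$startA[cis], endA = tbl$endA[cis],
                        startB = tbl$startB[cis], endB = tbl$endB[cis])
  structure(out, n_trans_dropped = n_trans, class = c("loop_set", class(out)))
}

#' Construct a cis loop set from anchor coordinates
#' @param chrom,startA,endA,startB,endB Anchor coordinates (0-based half-open),
#'   both anchors on `chrom`.
#' @return A `loop_set` tibble.
#' @export
loop_set <- function(chrom, startA, endA, startB, endB) {
  out <- tibble::tibble(chrom = as.character(chrom),
                        startA = as.integer(startA), endA = as.integer(endA),
                        startB = as.integer(startB), endB = as.integer(endB))
  if (any(out$startA >= out$endA | out$startB >= out$endB)) {
    stop_methrx("loop anchor with start >= end")
  }
  structure(out, n_trans_dropped = 0L, class = c("loop_set", class(out)))
}

#' Write a loop set as BEDPE
#' @param loops A `loop_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  readr::write_lines(paste(loops$chrom, loops$startA, loops$endA,
                           loops$chrom, loops$startB, loops$endB, sep = "\t"), path)
  invisible(path)
}

# Convert an interval track (0-based half-open) to GRanges (1-based closed).
track_to_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1L, end = track$end),
                         label = track$label)
}

# Convert probe positions (tibble: probe, chrom, pos; 0-based 1-bp) to GRanges.
probes_to_granges <- function(probes) {
  need <- c("probe", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    stop_methrx("probe position table needs columns probe, chrom, pos")
  }
  if (anyNA(probes$pos) || anyNA(probes$chrom)) {
    stop_methrx("probe without a genomic position")
  }
  GenomicRanges::GRanges(probes$chrom,
                         IRanges::IRanges(start = probes$pos + 1L, width = 1L),
                         probe = probes$probe)
}
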