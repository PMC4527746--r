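# Readers and writers for the interchange formats. All coordinates are
# 1-based inclusive except BED exports, which convert to 0-based half-open.

.write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path, mode = "character") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "probe_id")
    .err("lohscan_io_error", "%s: first column must be 'probe_id'", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$probe_id
  if (mode == "numeric") storage.mode(m) <- "double"
  m
}

#' Write / read a genotype matrix (TSV, probes x samples)
#' @param mat Character matrix of `AA`/`AB`/`BB`/`NC` calls.
#' @param path File path.
#' @return The path (writer) or the matrix (reader), invisibly for writers.
#' @export
write_genotype_tsv <- function(mat, path) .write_matrix_tsv(mat, path)

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  m <- .read_matrix_tsv(path)
  bad <- !(m %in% .GENO_CODES)
  if (any(bad))
    .err("lohscan_io_error", "%s: %d cells hold unknown genotype codes",
         path, sum(bad))
  m
}

#' Write / read a copy-number signal matrix (TSV, probes x samples)
#' @param mat Numeric matrix on the CN scale.
#' @param path File path.
#' @return The path (writer) or the numeric matrix (reader).
#' @export
write_signal_tsv <- function(mat, path) .write_matrix_tsv(mat, path)

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) .read_matrix_tsv(path, mode = "numeric")

#' Write / read the probe annotation table (TSV)
#' @param annotation Data frame with `probe_id`, `chrom`, `arm`, `position`,
#'   `cytoband`, `gene`.
#' @param path File path.
#' @return The path (writer) or the annotation data frame (reader).
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "arm", "position")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    .err("lohscan_annotation_error", "%s: missing columns %s", path,
         paste(miss, collapse = ","))
  if (anyNA(ann$arm) || any(!nzchar(ann$arm)))
    .err("lohscan_annotation_error", "%s: probes with missing arm label: %s",
         path, paste(utils::head(ann$probe_id[is.na(ann$arm) | !nzchar(ann$arm)], 5),
                     collapse = ","))
  ann
}

#' Write / read the clinical table (CSV)
#' @param clinical Clinical data frame (see [generate_clinical()] for the
#'   documented header).
#' @param path File path.
#' @return The path (writer) or the clinical data frame (reader).
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age", "smoking", "time_months",
            "vital_status")
  miss <- setdiff(need, names(clin))
  if (length(miss))
    .err("lohscan_io_error", "%s: missing clinical columns %s", path,
         paste(miss, collapse = ","))
  bad <- which(is.na(clin$time_months) | clin$time_months <= 0 |
                 !clin$vital_status %in% c("OSCC_death", "other_death",
                                           "censored"))
  if (length(bad))
    .err("lohscan_io_error",
         "%s: malformed clinical rows (line %s): need positive time and a valid vital_status",
         path, paste(utils::head(bad + 1L, 5), collapse = ","))
  clin
}

#' Write per-sample segments in IGV SEG format
#'
#' Columns: sample, chromosome, start, end (1-based inclusive probe-anchored
#' nucleotide positions from the annotation), number of probes, segment
#' mean.
#'
#' @param segments Per-sample list of segment tables from
#'   [segment_cohort()].
#' @param annotation Annotation table supplying nucleotide positions.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_seg <- function(segments, annotation, path) {
  rows <- lapply(names(segments), function(s) {
    seg <- segments[[s]]
    data.frame(sample = s, chrom = seg$chrom,
               loc_start = annotation$position[seg$start],
               loc_end = annotation$position[seg$end],
               num_probes = seg$n_probes, seg_mean = seg$seg_mean,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a consensus frequency track as BED
#'
#' Probe intervals with the fraction as score; converts the package's
#' 1-based inclusive coordinates to BED's 0-based half-open convention.
#'
#' @param consensus A [consensus_frequencies()] result.
#' @param annotation Annotation table.
#' @param path File path.
#' @param column Which fraction column to export (default `"loh_frac"`).
#' @return The path, invisibly.
#' @export
write_consensus_bed <- function(consensus, annotation, path,
                                column = "loh_frac") {
  hit <- match(consensus$probe_id, annotation$probe_id)
  bed <- data.frame(chrom = annotation$chrom[hit],
                    start = annotation$position[hit] - 1L,
                    end = annotation$position[hit],
                    name = consensus$probe_id,
                    score = consensus[[column]])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the six standard input files for a cohort
#'
#' Writes paired genotype TSVs, paired signal TSVs, the annotation TSV and
#' the clinical CSV, plus a ground-truth segment table (TSV) when the
#' cohort carries one.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lohscan_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    blood_genotype = file.path(dir, "blood_genotype.tsv"),
    tumor_genotype = file.path(dir, "tumor_genotype.tsv"),
    blood_signal = file.path(dir, "blood_signal.tsv"),
    tumor_signal = file.path(dir, "tumor_signal.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "ground_truth.tsv"))
  write_genotype_tsv(cohort$blood_genotype, paths[["blood_genotype"]])
  write_genotype_tsv(cohort$tumor_genotype, paths[["tumor_genotype"]])
  write_signal_tsv(cohort$blood_signal, paths[["blood_signal"]])
  write_signal_tsv(cohort$tumor_signal, paths[["tumor_signal"]])
  write_annotation_tsv(cohort$annotation, paths[["annotation"]])
  write_clinical_csv(cohort$clinical, paths[["clinical"]])
  truth_tab <- do.call(rbind, lapply(cohort$truth$segments, function(s)
    data.frame(chrom = s$chrom, type = s$type,
               start = min(s$probes), end = max(s$probes),
               carriers = paste(s$carriers, collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(truth_tab, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read and align the standard input files
#'
#' Loads the paired genotype and signal matrices, annotation and clinical
#' table; checks that both tissues carry the same samples, that every probe
#' is annotated, and sorts probes into annotation (genome) order and
#' samples by identifier.
#'
#' @param paths Named list/vector with entries `blood_genotype`,
#'   `tumor_genotype`, `blood_signal`, `tumor_signal`, `annotation`,
#'   `clinical`.
#' @return List with the six aligned structures plus `validation`, a small
#'   summary (probe/sample counts, no-call rates).
#' @export
read_inputs <- function(paths) {
  need <- c("blood_genotype", "tumor_genotype", "blood_signal",
            "tumor_signal", "annotation", "clinical")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    .err("lohscan_io_error", "missing input paths: %s",
         paste(miss, collapse = ","))
  bg <- read_genotype_tsv(paths[["blood_genotype"]])
  tg <- read_genotype_tsv(paths[["tumor_genotype"]])
  bs <- read_signal_tsv(paths[["blood_signal"]])
  ts <- read_signal_tsv(paths[["tumor_signal"]])
  ann <- read_annotation_tsv(paths[["annotation"]])
  clin <- read_clinical_csv(paths[["clinical"]])

  mats <- list(blood_genotype = bg, tumor_genotype = tg,
               blood_signal = bs, tumor_signal = ts)
  samples <- sort(colnames(bg))
  for (nm in names(mats)) {
    missing <- setdiff(samples, colnames(mats[[nm]]))
    extra <- setdiff(colnames(mats[[nm]]), samples)
    if (length(missing) || length(extra))
      .err("lohscan_pairing_error",
           "%s is not paired with blood_genotype (missing: %s; extra: %s)",
           nm, paste(missing, collapse = ","), paste(extra, collapse = ","))
  }
  probes <- ann$probe_id
  for (nm in names(mats)) {
    unknown <- setdiff(rownames(mats[[nm]]), probes)
    if (length(unknown))
      .err("lohscan_annotation_error",
           "%s holds probes absent from the annotation: %s", nm,
           paste(utils::head(unknown, 5), collapse = ","))
    if (!setequal(rownames(mats[[nm]]), probes))
      .err("lohscan_annotation_error",
           "%s is missing annotated probes", nm)
    mats[[nm]] <- mats[[nm]][probes, samples, drop = FALSE]
  }
  missing_clin <- setdiff(samples, clin$sample_id)
  if (length(missing_clin))
    .err("lohscan_pairing_error", "samples missing from clinical table: %s",
         paste(missing_clin, collapse = ","))

  validation <- list(
    n_probes = length(probes), n_samples = length(samples),
    nc_rate_blood = mean(mats$blood_genotype == "NC"),
    nc_rate_tumor = mean(mats$tumor_genotype == "NC"))
  c(mats, list(annotation = ann,
               clinical = clin[match(samples, clin$sample_id), ],
               validation = validation))
}
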