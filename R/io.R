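## Readers perform strict validation (unique ids, numeric/integer cells,
## required columns) and name the offending row/column in errors; every
## writer's output is readable by its paired reader with full fidelity.

.checkCols <- function(df, cols, what, path) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stopf("%s '%s': missing column(s) %s", what, path,
          paste(missing, collapse = ", "))
}

#' Read a probe-by-sample count table
#'
#' Tab-separated with probe ids in the first column and one column per
#' sample, or MatrixMarket (`.mtx`) with sidecar `<path>.rows` /
#' `<path>.cols` id files.
#'
#' @param path counts file.
#' @return integer matrix, probes x samples.
#' @export
readCounts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stopf("reading MatrixMarket counts requires the Matrix package")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".rows"))
    colnames(m) <- readLines(paste0(path, ".cols"))
    if (any(m != round(m)) || any(m < 0))
      stopf("counts file '%s': non-integer or negative entries", path)
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- df[[1]]
  if (anyDuplicated(probes))
    stopf("counts file '%s': duplicate probe id '%s'", path,
          probes[duplicated(probes)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stopf("counts file '%s': duplicate sample id", path)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num != round(num) | num < 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stopf("counts file '%s': non-integer cell at probe '%s', sample '%s'",
          path, probes[i], colnames(m)[j])
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(probes, colnames(m))
  num
}

#' @rdname readCounts
#' @param counts integer matrix to write.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(probe = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a sample design table
#'
#' CSV with columns `sample`, `plate`, `timepoint`, `chemical`,
#' `concentration_uM`, `vehicle_pct`, `replicate`. Concentration 0 rows
#' are vehicle controls; concentrations are uM totals.
#'
#' @param path design CSV.
#' @return data.frame.
#' @export
readDesign <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, .designCols, "design file", path)
  if (anyDuplicated(df$sample))
    stopf("design file '%s': duplicate sample id '%s'", path,
          df$sample[duplicated(df$sample)][1])
  if (any(!is.finite(df$concentration_uM)) || any(df$concentration_uM < 0))
    stopf("design file '%s': concentrations must be nonnegative numbers",
          path)
  df
}

#' @rdname readDesign
#' @param design data.frame to write.
#' @export
writeDesign <- function(design, path) {
  utils::write.csv(design[, .designCols], path, row.names = FALSE,
                   quote = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' One tab-separated line per set: set id, description, then member gene
#' ids.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `"PathwayDb"`), with a
#'   `"descriptions"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("GMT file '%s', line %d: expected id, description and >= 1 gene",
            path, i)
    id <- parts[1]
    if (id %in% names(sets))
      stopf("GMT file '%s', line %d: duplicate set id '%s'", path, i, id)
    sets[[id]] <- parts[-(1:2)]
    desc[id] <- parts[2]
  }
  structure(sets, descriptions = desc, class = c("PathwayDb", "list"))
}

#' @rdname readGmt
#' @param pathways named list of gene-id vectors.
#' @param descriptions optional named descriptions (defaults to the ids).
#' @export
writeGmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(pathways, "descriptions")
  if (is.null(descriptions))
    descriptions <- setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(id)
    paste(c(id, descriptions[[id]], pathways[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read / write mixture compositions
#'
#' CSV with one row per mixture component: `mixture`, `component`,
#' `molarity_uM` (per-component molarity at a reference exposure level).
#'
#' @param path mixtures CSV.
#' @return named list of [MixtureDefinition-class] objects.
#' @export
readMixtures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("mixture", "component", "molarity_uM"), "mixtures file",
             path)
  out <- lapply(split(df, df$mixture), function(sub)
    mixtureDefinition(sub$mixture[1], sub$component, sub$molarity_uM))
  out[unique(df$mixture)]
}

#' @rdname readMixtures
#' @param mixtures list of [MixtureDefinition-class] objects.
#' @export
writeMixtures <- function(mixtures, path) {
  df <- do.call(rbind, lapply(mixtures, function(m)
    data.frame(mixture = m@mixtureId, component = m@components,
               molarity_uM = m@molarities, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read / write the per-sample LDH table
#' @param path CSV with columns `sample`, `rlu`, `is_blank`.
#' @return data.frame.
#' @export
readLdh <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("sample", "rlu", "is_blank"), "LDH file", path)
  df$is_blank <- as.logical(df$is_blank)
  df
}

#' @rdname readLdh
#' @param ldh data.frame to write.
#' @export
writeLdh <- function(ldh, path)
  utils::write.csv(ldh, path, row.names = FALSE, quote = FALSE)

#' Read / write the per-sample QC-metric table
#' @param path CSV with columns `sample`, `mapped_reads`,
#'   `fraction_mapped`, `n_probes_min5`, `n_probes_80pct`, `gini`.
#' @return data.frame.
#' @export
readQcMetrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("sample", "mapped_reads", "fraction_mapped",
                   "n_probes_min5", "n_probes_80pct", "gini"),
             "QC-metrics file", path)
  df
}

#' @rdname readQcMetrics
#' @param metrics data.frame to write.
#' @export
writeQcMetrics <- function(metrics, path)
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)

#' Write / read an exclusion report's per-sample table
#' @param report an [ExclusionReport-class].
#' @param path CSV path (`sample`, `status`, semicolon-joined `reasons`).
#' @export
writeExclusionReport <- function(report, path)
  utils::write.csv(sampleStatus(report), path, row.names = FALSE,
                   quote = FALSE)

#' @rdname writeExclusionReport
#' @return data.frame with `sample`, `status`, `reasons`.
#' @export
readExclusionReport <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("sample", "status", "reasons"), "exclusion report", path)
  df$reasons[is.na(df$reasons)] <- ""
  df
}

#' Write / read a normalized log2 expression matrix
#' @param norm numeric matrix, probes x samples.
#' @param path TSV path (probe ids in the first column).
#' @export
writeNormalized <- function(norm, path) {
  df <- data.frame(probe = rownames(norm), norm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeNormalized
#' @return numeric matrix.
#' @export
readNormalized <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a simulated study's tables to a directory
#'
#' Emits the counts TSV, design CSV, LDH CSV, QC-metrics CSV and (when
#' present) ground-truth CSV of a [PodExperiment-class], in the formats
#' the pipeline readers consume.
#'
#' @param study a [PodExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.csv"),
             ldh = file.path(dir, "ldh.csv"),
             qcMetrics = file.path(dir, "qc_metrics.csv"))
  writeCounts(counts(study), paths["counts"])
  writeDesign(designTable(study), paths["design"])
  writeLdh(ldhTable(study), paths["ldh"])
  writeQcMetrics(qcMetrics(study), paths["qcMetrics"])
  if (nrow(groundTruth(study))) {
    paths["groundTruth"] <- file.path(dir, "ground_truth.csv")
    utils::write.csv(groundTruth(study), paths["groundTruth"],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Assemble a PodExperiment from its component tables
#' @param counts probe x sample integer matrix.
#' @param design design table (see [readDesign()]).
#' @param ldh LDH table (see [readLdh()]).
#' @param metrics QC-metric table (see [readQcMetrics()]).
#' @param gt optional ground-truth table.
#' @return a [PodExperiment-class].
#' @export
podExperiment <- function(counts, design, ldh, metrics,
                          gt = data.frame()) {
  counts <- counts[, design$sample, drop = FALSE]
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(design,
                                                 row.names = design$sample))
  out <- new("PodExperiment", se, ldh = ldh, qcMetrics = metrics,
             groundTruth = gt)
  validObject(out)
  out
}
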