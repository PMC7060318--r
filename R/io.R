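## Readers and writers for the on-disk formats (tolerant readers, strict
## deterministic writers), pipeline configuration and the end-to-end driver.
##
## Coordinate conventions: on-disk probe annotation is BED-style 0-based
## half-open; all in-memory positions are 1-based (array-manifest
## convention). Conversion happens only in this file.

#' Read a beta-value matrix TSV
#'
#' Expects probes as rows (first column = probe id), samples as columns with
#' a header of sample ids, "NA" for missing. Gzipped files are handled
#' transparently. Values outside [0,1] raise an error naming the offending
#' probe/sample cells.
#'
#' @param path file path (.tsv or .tsv.gz).
#' @return A [MethylationSet-class] (beta assay only).
#' @export
readBetaMatrix <- function(path) {
  dt <- if (grepl("\\.gz$", path)) {
    ## base connections decompress transparently
    data.table::fread(text = readLines(path), sep = "\t", header = TRUE,
                      data.table = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  }
  if (ncol(dt) < 2) stop("beta matrix needs a probe-id column plus samples")
  probes <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric beta values in ", path)
  rownames(mat) <- probes
  MethylationSet(mat)
}

#' Write a beta-value matrix TSV
#'
#' Strict writer: probes as rows, 6 significant digits, NA as "NA",
#' deterministic row/column order (as stored).
#'
#' @param M a [MethylationSet-class] or probes x samples matrix.
#' @param path output path (gzipped when it ends in .gz).
#' @export
writeBetaMatrix <- function(M, path) {
  beta <- if (is(M, "MethylationSet")) betaValues(M) else as.matrix(M)
  out <- data.frame(probe = rownames(beta), .fmtNum(beta),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe", colnames(beta))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read COJO-style .ma summary statistics
#'
#' Whitespace-delimited columns SNP A1 A2 freq b se p N with a header.
#' Alleles are upper-cased; rows with se <= 0 raise an error naming the row;
#' extra columns are kept with a warning (tolerant-reader policy).
#'
#' @param path file path.
#' @return data.frame of summary associations.
#' @export
readSummaryMa <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  missing <- setdiff(need, colnames(dt))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(dt), need)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  for (cc in c("freq", "b", "se", "p", "N"))
    if (!is.numeric(dt[[cc]]))
      stop("non-numeric values in column '", cc, "' of ", path)
  bad <- which(dt$se <= 0)
  if (length(bad))
    stop("non-positive se at row(s) ", paste(head(bad, 5L), collapse = ", "),
         " of ", path)
  dt$A1 <- toupper(dt$A1); dt$A2 <- toupper(dt$A2)
  dt
}

#' Write COJO-style .ma summary statistics
#' @param x summary data.frame (SNP A1 A2 freq b se p N; extra columns
#'   dropped).
#' @param path output path.
#' @export
writeSummaryMa <- function(x, path) {
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  out <- x[need]
  for (cc in c("freq", "b", "se", "p")) out[[cc]] <- .fmtNum(out[[cc]])
  data.table::fwrite(out, path, sep = " ", quote = FALSE, na = "NA")
  invisible(path)
}

.normChrom <- function(x) sub("^chr", "", as.character(x))

#' Read BED-like probe annotation
#'
#' Tab-separated columns: chrom, start (0-based), end, probe, gene,
#' crossReactive (0/1), sexChromosome (0/1); the last three are optional.
#' Positions are converted to 1-based in memory (bp = start + 1), chromosome
#' labels "chr4" and "4" are normalized identically.
#'
#' @param path file path.
#' @return data.frame probe, chrom, bp, gene, crossReactive, sexChromosome.
#' @export
readProbeAnnotation <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 4) stop("annotation needs at least chrom/start/end/probe")
  colnames(dt)[1:4] <- c("chrom", "start", "end", "probe")
  if (ncol(dt) >= 5) colnames(dt)[5] <- "gene"
  if (ncol(dt) >= 6) colnames(dt)[6] <- "crossReactive"
  if (ncol(dt) >= 7) colnames(dt)[7] <- "sexChromosome"
  if (any(dt$start >= dt$end))
    stop("invalid interval(s): start must be < end (0-based half-open)")
  if (anyDuplicated(dt$probe))
    stop("duplicate probe id(s): ",
         paste(head(unique(dt$probe[duplicated(dt$probe)]), 5L), collapse = ", "))
  data.frame(probe = as.character(dt$probe), chrom = .normChrom(dt$chrom),
             bp = dt$start + 1L,
             gene = if ("gene" %in% colnames(dt)) as.character(dt$gene) else NA,
             crossReactive = if ("crossReactive" %in% colnames(dt))
               as.logical(dt$crossReactive) else FALSE,
             sexChromosome = if ("sexChromosome" %in% colnames(dt))
               as.logical(dt$sexChromosome) else FALSE,
             stringsAsFactors = FALSE)
}

#' Write BED-like probe annotation
#' @param ann data.frame with probe, chrom, bp (1-based) and optional gene
#'   and flag columns.
#' @param path output path.
#' @export
writeProbeAnnotation <- function(ann, path) {
  out <- data.frame(chrom = ann$chrom, start = ann$bp - 1L, end = ann$bp,
                    probe = ann$probe,
                    gene = if ("gene" %in% colnames(ann)) ann$gene else ".",
                    crossReactive = as.integer(isTRUE(ann$crossReactive) |
                                                 ann$crossReactive %in% TRUE),
                    sexChromosome = as.integer(isTRUE(ann$sexChromosome) |
                                                 ann$sexChromosome %in% TRUE))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an association table TSV
#'
#' Fixed column order Chr, Probe, bp, Gene, b, se, p, method.
#' @param records association data.frame from a scan.
#' @param path output path.
#' @export
writeAssociationTable <- function(records, path) {
  out <- data.frame(Chr = records$chrom, Probe = records$probe,
                    bp = records$bp, Gene = records$gene,
                    b = .fmtNum(records$b), se = .fmtNum(records$se),
                    p = .fmtNum(records$p), method = records$method)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.configDefaults <- function() {
  list(seed = 1L, outDir = "pipeline_out",
       nSamples = 300L, nProbes = 1000L, nCohorts = 2L,
       caseFraction = 0.5, liabilityVarianceExplained = 0.3,
       nCausalProbes = 50L,
       sdMin = 0.02, detectRateMin = 0.95, detectP = 0.01,
       momentWindowBp = 50000, partitionThresholdP = 0.01,
       smrNSnps = 30L, logLevel = "info")
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration; unknown keys are rejected with a message
#' listing them, missing keys fall back to defaults. The configuration
#' round-trips losslessly through [yaml::write_yaml].
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           "; known keys: ", paste(names(cfg), collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates the configured cohorts, applies probe QC, estimates cell-type
#' proportions, fits the all-probe variance-component model, runs the MOA
#' and MOMENT scans per cohort, meta-analyses the cohorts, runs an SMR/HEIDI
#' analysis on a simulated summary trio, and evaluates the cross-cohort
#' methylation classifier. Every stage writes its output under
#' \code{config$outDir} together with a JSON log of parameters and the seed;
#' rerunning with the same configuration reproduces the outputs.
#'
#' @param config list from [readPipelineConfig()] (or compatible).
#' @return (invisibly) a list of stage results.
#' @export
runPipeline <- function(config = readPipelineConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list(parameters = config, started = "run",
              package = as.character(utils::packageVersion("methMWAS")))
  simCfg <- simulationConfig(
    nSamples = config$nSamples, nProbes = config$nProbes,
    nCausalProbes = config$nCausalProbes,
    liabilityVarianceExplained = config$liabilityVarianceExplained,
    caseFraction = config$caseFraction, seed = config$seed)
  cohorts <- lapply(seq_len(config$nCohorts), function(i) {
    ## cohorts share the causal architecture (discovery/replication design)
    sim <- simulateMethylationCohort(simCfg, cohortSeed = config$seed + i)
    qc <- qcProbes(sim$mset, detectRateMin = config$detectRateMin,
                   detectP = config$detectP, sdMin = config$sdMin)
    ctp <- estimateCellProportions(qc$mset, sim$reference)
    W <- standardizeProbes(qc$mset)
    cd <- as.data.frame(SummarizedExperiment::colData(qc$mset))
    covs <- data.frame(sex = cd$sex, age = scale(cd$age)[, 1],
                       smoking = cd$smoking,
                       ctp[, setdiff(colnames(ctp), c("eos", "granulocyte")),
                           drop = FALSE])
    design <- cohortDesign(cd$status, covs, sampleIds = rownames(cd))
    ann <- probeAnnotation(qc$mset)
    ve <- remlFit(design, computeORM(W))
    moa <- moaScan(design, W, ann, varianceEstimate = ve)
    mom <- momentScan(design, W, ann, windowBp = config$momentWindowBp,
                      thresholdP = config$partitionThresholdP)
    writeBetaMatrix(qc$mset, file.path(config$outDir,
                                       sprintf("cohort%d_beta.tsv.gz", i)))
    writeAssociationTable(moa, file.path(config$outDir,
                                         sprintf("cohort%d_moa.tsv", i)))
    writeAssociationTable(mom, file.path(config$outDir,
                                         sprintf("cohort%d_moment.tsv", i)))
    list(sim = sim, qc = qc, ctp = ctp, W = W, design = design, ann = ann,
         varianceEstimate = ve, moa = moa, moment = mom)
  })
  log$qcReports <- lapply(cohorts, function(co) co$qc$report)
  log$rho2 <- vapply(cohorts, function(co) rho2(co$varianceEstimate), 1)
  log$lambdaMOA <- vapply(cohorts, function(co) genomicInflation(co$moa), 1)

  meta <- NULL
  if (length(cohorts) >= 2) {
    meta <- metaAnalyze(lapply(cohorts, `[[`, "moa"))
    writeAssociationTable(cbind(meta, method = "MOA-meta"),
                          file.path(config$outDir, "meta_moa.tsv"))
    log$bonferroni <- bonferroniThreshold(attr(meta, "nCommon"))
  }

  trio <- simulateSummaryTrio(nSnps = config$smrNSnps,
                              seed = config$seed + 100L)
  h <- harmonizeSummary(trio$mqtl, trio$eqtl)
  inst <- selectInstrument(h$exposure)
  smr <- if (inst$status == "ok") {
    i <- match(inst$snp, h$exposure$SNP)
    smrTest(h$exposure$b[i], h$exposure$se[i],
            h$outcome$b[i], h$outcome$se[i])
  } else NULL
  heidi <- heidiTest(trio$mqtl, trio$eqtl, trio$panel)
  log$smr <- smr; log$heidi <- heidi[c("status", "p", "nSnps")]

  classifier <- NULL
  if (length(cohorts) >= 2) {
    classifier <- evaluateClassifier(
      cohorts[[1]]$design, cohorts[[1]]$W,
      cohorts[[2]]$design, cohorts[[2]]$W,
      targetCovariates = as.data.frame(covariateMatrix(cohorts[[2]]$design))[, -1])
    log$classifierAUC <- unname(classifier$auc["auc"])
    log$classifierR2 <- classifier$nagelkerke$R2
  }
  jsonlite::write_json(log, file.path(config$outDir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(cohorts = cohorts, meta = meta, smr = smr, heidi = heidi,
                 classifier = classifier, log = log))
}

#' Write / read an omics relationship matrix as an ids + lower-triangle pair
#'
#' Plain-text storage: `<prefix>.orm.id` holds one sample id per line;
#' `<prefix>.orm.tsv` holds rows `i j value` (1-based indices, j <= i,
#' including the diagonal) plus a header line recording the probe count m.
#'
#' @param orm an [OmicsRelationshipMatrix-class].
#' @param prefix output path prefix.
#' @return (invisibly) the prefix.
#' @export
writeORM <- function(orm, prefix) {
  A <- ormMatrix(orm)
  writeLines(rownames(A), paste0(prefix, ".orm.id"))
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    value = .fmtNum(A[idx]))
  con <- file(paste0(prefix, ".orm.tsv"), "w")
  writeLines(sprintf("# m=%d", orm@m), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  invisible(prefix)
}

#' @rdname writeORM
#' @export
readORM <- function(prefix) {
  ids <- readLines(paste0(prefix, ".orm.id"))
  lines <- readLines(paste0(prefix, ".orm.tsv"))
  m <- as.integer(sub("# m=", "", lines[1]))
  tri <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tri$i, tri$j)] <- tri$value
  A[cbind(tri$j, tri$i)] <- tri$value
  new("OmicsRelationshipMatrix", A = A, m = m)
}

#' Write / read a covariate table TSV
#'
#' First column `sample`, remaining columns covariates; strict 6-significant
#' digit writer, tolerant reader.
#'
#' @param covariates data.frame with sample ids as rownames.
#' @param path file path.
#' @return the covariate data.frame (reader) or the path (writer,
#'   invisibly).
#' @export
writeCovariateTable <- function(covariates, path) {
  df <- as.data.frame(covariates)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmtNum)
  out <- cbind(sample = rownames(covariates), df)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeCovariateTable
#' @export
readCovariateTable <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (colnames(dt)[1] != "sample")
    stop("covariate table must start with a 'sample' column")
  rownames(dt) <- dt$sample
  dt[, -1, drop = FALSE]
}
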