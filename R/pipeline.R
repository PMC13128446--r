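#' Read and write the delimited-text interchange formats
#'
#' All tables are plain CSV. `readApexCsv()` expects an intensity matrix
#' (rows = proteins, first column `protein`, blank cells = missing) and a
#' sample sheet with the [ApexExperiment-class] columns; `readPlateCsv()`
#' expects long-format plate data (`compound`, `concentration`,
#' `replicate`, `response`, optional `timepoint_min`, `well`);
#' `readPhotometryCsv()` expects `time_s`, `f465`, `f405` plus a YAML
#' metadata sidecar (`fs_hz`, `baseline_start_s`, `baseline_end_s`,
#' `injection_s`, `animal_id`).
#'
#' @param matrixPath,sheetPath,path,metaPath file paths.
#' @return the corresponding object.
#' @name interchange
NULL

#' @rdname interchange
#' @export
readApexCsv <- function(matrixPath, sheetPath) {
  raw <- utils::read.csv(matrixPath, check.names = FALSE)
  if (names(raw)[1] != "protein")
    stop("intensity matrix must have a leading 'protein' column ",
         "(found '", names(raw)[1], "')")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw$protein
  sheet <- utils::read.csv(sheetPath)
  need <- c("sample", "role", "ligand", "time_min", "time_rank",
            "replicate", "batch")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(sheet$sample %in% colnames(mat)))
    stop("sample sheet rows without matrix columns: ",
         paste(setdiff(sheet$sample, colnames(mat)), collapse = ", "))
  mat <- mat[, sheet$sample, drop = FALSE]
  ApexExperiment(mat, sheet[, setdiff(names(sheet), "sample")])
}

#' @rdname interchange
#' @export
readPlateCsv <- function(path) {
  plate <- utils::read.csv(path)
  need <- c("compound", "concentration", "replicate", "response")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate CSV is missing column(s): ", paste(miss, collapse = ", "))
  plate
}

#' @rdname interchange
#' @export
readPhotometryCsv <- function(path, metaPath) {
  tr <- utils::read.csv(path)
  need <- c("time_s", "f465", "f405")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("photometry CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  meta <- yaml::read_yaml(metaPath)
  PhotometryRecording(tr$f465, tr$f405, fs = meta$fs_hz, time = tr$time_s,
                      baselineWindow = c(meta$baseline_start_s,
                                         meta$baseline_end_s),
                      injectionTime = meta$injection_s,
                      animalId = meta$animal_id %||% "animal1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeApexCsv <- function(apex, matrixPath, sheetPath) {
  mat <- SummarizedExperiment::assay(apex, "log2intensity")
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, matrixPath, row.names = FALSE, na = "")
  cd <- as.data.frame(SummarizedExperiment::colData(apex))
  utils::write.csv(data.frame(sample = colnames(mat), cd,
                              check.names = FALSE),
                   sheetPath, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a seeded simulated run: `"simulate"` writes
#' every input family to `outDir`; `"doseresponse"`, `"bias"`, `"apex"`,
#' `"photometry"` and `"endpoints"` run the corresponding analysis stage on
#' the simulated inputs; `"all"` chains simulation and every analysis
#' stage. Each run writes a resolved configuration (YAML) and the stage
#' outputs as CSV into `outDir`, so the run can be reconstructed exactly.
#' Unknown configuration keys are rejected.
#'
#' @param subcommand one of `"simulate"`, `"doseresponse"`, `"bias"`,
#'   `"apex"`, `"photometry"`, `"endpoints"`, `"all"`.
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving all generators.
#' @param config named list of stage parameter overrides; supported keys:
#'   `kinetic_timepoints` (integer count of timepoints for the bias stage),
#'   `kinetic_experiments`, `apex_repeats` (NNLS repeats), `apex_proteins`,
#'   `family` (for `"simulate"`).
#' @return invisibly, a named list of written file paths.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "doseresponse",
                                       "bias", "apex", "photometry",
                                       "endpoints"),
                        outDir, seed = 1L, config = list()) {
  subcommand <- match.arg(subcommand)
  allowed <- c("kinetic_timepoints", "kinetic_experiments", "apex_repeats",
               "apex_proteins", "family")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  resolved <- list(subcommand = subcommand, seed = seed,
                   config = config,
                   package_version =
                     as.character(utils::packageVersion("MORpharm")))
  yaml::write_yaml(resolved, file.path(outDir, "run_config.yaml"))
  written <- c(run_config = file.path(outDir, "run_config.yaml"))
  wcsv <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written[[sub("\\.csv$", "", name)]] <<- p
    p
  }

  nTp <- config$kinetic_timepoints %||% 23L
  nEx <- config$kinetic_experiments %||% 3L
  tps <- seq(2, by = 2, length.out = nTp)

  doSimulate <- function() {
    plate <- simulateBretPlate(seed)
    wcsv(plate$data, "bret_plate.csv")
    yaml::write_yaml(plate$truth, file.path(outDir,
                                            "bret_plate_truth.yaml"))
    kin <- simulateKineticBret(seed, timepoints = tps,
                               nExperiments = nEx)
    wcsv(kin$data, "bret_kinetic.csv")
    bind <- simulateBindingKinetic(seed)
    wcsv(bind$data$association, "binding_association.csv")
    wcsv(bind$data$dissociation, "binding_dissociation.csv")
    ap <- simulateApex(seed, nProteins = config$apex_proteins %||% 160L)
    writeApexCsv(ap$apex, file.path(outDir, "apex_matrix.csv"),
                 file.path(outDir, "apex_samples.csv"))
    written[["apex_matrix"]] <<- file.path(outDir, "apex_matrix.csv")
    written[["apex_samples"]] <<- file.path(outDir, "apex_samples.csv")
    ph <- simulatePhotometry(seed)
    wcsv(data.frame(time_s = ph$rec@time, f465 = ph$rec@f465,
                    f405 = ph$rec@f405), "photometry.csv")
    yaml::write_yaml(list(fs_hz = ph$rec@fs,
                          baseline_start_s = ph$rec@baselineWindow[1],
                          baseline_end_s = ph$rec@baselineWindow[2],
                          injection_s = ph$rec@injectionTime,
                          animal_id = ph$rec@animalId,
                          transient_times = ph$truth$transientTimes),
                     file.path(outDir, "photometry_meta.yaml"))
    ep <- simulateEndpoints(seed)
    wcsv(ep$data$hotplate, "endpoints_hotplate.csv")
    wcsv(ep$data$pk, "endpoints_pk.csv")
    wcsv(ep$data$withdrawal, "endpoints_withdrawal.csv")
  }

  doDoseResponse <- function() {
    plate <- readPlateCsv(file.path(outDir, "bret_plate.csv"))
    net <- subtractLigandFree(plate)
    ref <- fitLogistic3(net[net$compound == "DAMGO", ],
                        compound = "DAMGO")
    fits <- do.call(rbind, lapply(sort(unique(net$compound)),
                                  function(cmp) {
      f <- fitLogistic3(net[net$compound == cmp, ], compound = cmp)
      nm <- normalizeToDamgo(f, ref)
      data.frame(compound = cmp, pEC50 = pec50(f),
                 EC50_nM = ec50(f) * 1e9, Emax_pct = nm[["top"]],
                 convergence = isConverged(f))
    }))
    wcsv(fits, "dose_response_fits.csv")
  }

  doBias <- function() {
    kin <- readPlateCsv(file.path(outDir, "bret_kinetic.csv"))
    # simulated kinetic plate is reused for both pathways with a
    # pathway-specific seed so the two arms are independent
    kin2 <- simulateKineticBret(seed + 1L, timepoints = tps,
                                nExperiments = nEx)$data
    bt <- biasTable(kin, kin2)
    wcsv(bt, "bias_table.csv")
    tc <- summarizeTimecourse(timecoursePharmacology(kin))
    wcsv(tc, "timecourse_pharmacology.csv")
  }

  doApex <- function() {
    apex <- readApexCsv(file.path(outDir, "apex_matrix.csv"),
                        file.path(outDir, "apex_samples.csv"))
    scores <- do.call(rbind, lapply(c("DAMGO", "FNZ", "DFNZ"),
                                    function(lg) {
      s <- scoreTimecourse(apex, lg)
      s$ligand <- lg
      s$interactor <- s$protein %in% callInteractors(s)
      s
    }))
    wcsv(scores, "apex_scores.csv")
    panel <- selectMarkers(apex)
    wcsv(panel, "apex_markers.csv")
    tp <- traffickingProfile(apex, panel,
                             nRepeats = config$apex_repeats %||% 200L,
                             seed = seed)
    wcsv(tp$samples, "apex_coefficients.csv")
    wcsv(tp$profile, "apex_trafficking.csv")
  }

  doPhotometry <- function() {
    rec <- readPhotometryCsv(file.path(outDir, "photometry.csv"),
                             file.path(outDir, "photometry_meta.yaml"))
    rec <- preprocessRecording(rec)
    f0 <- fitBaseline(rec)
    dff <- computeDff(rec@f465, f0)
    wcsv(data.frame(time_s = rec@time, dff = dff), "photometry_dff.csv")
    inBase <- rec@time >= rec@baselineWindow[1] &
      rec@time <= rec@baselineWindow[2]
    thr <- setTransientThreshold(dff[inBase], rec@fs)
    ts <- detectTransients(dff, thr, time = rec@time,
                           window = c(rec@injectionTime,
                                      max(rec@time)))
    wcsv(transients(ts), "photometry_events.csv")
    wcsv(slowAuc(dff, rec@fs, time = rec@time,
                 injectionTime = rec@injectionTime),
         "photometry_auc.csv")
  }

  doEndpoints <- function() {
    hp <- utils::read.csv(file.path(outDir, "endpoints_hotplate.csv"))
    hp$mpe <- percentMPE(hp$latency_s, hp$baseline_s, hp$max_s)
    doseMeans <- tapply(hp$mpe, hp$dose_mgkg, mean)
    ed <- ed50(as.numeric(names(doseMeans)), as.numeric(doseMeans))
    pk <- utils::read.csv(file.path(outDir, "endpoints_pk.csv"))
    pk$unbound_nM <- unboundConcentration(pk$total_nM, pk$fraction_bound)
    ratio <- brainPlasmaRatio(
      mean(pk$unbound_nM[pk$matrix_type == "brain"]),
      mean(pk$unbound_nM[pk$matrix_type == "plasma"]))
    wd <- utils::read.csv(file.path(outDir, "endpoints_withdrawal.csv"))
    scores <- withdrawalScoreTable(wd)
    wcsv(data.frame(quantity = c("ed50_mgkg", "brain_plasma_ratio"),
                    value = c(ed$ed50, ratio)), "endpoints_summary.csv")
    wcsv(scores, "withdrawal_scores.csv")
  }

  stages <- switch(subcommand,
    all = c("simulate", "doseresponse", "bias", "apex", "photometry",
            "endpoints"),
    simulate = "simulate", doseresponse = "doseresponse", bias = "bias",
    apex = "apex", photometry = "photometry", endpoints = "endpoints")
  for (st in stages) {
    switch(st,
      simulate = doSimulate(), doseresponse = doDoseResponse(),
      bias = doBias(), apex = doApex(), photometry = doPhotometry(),
      endpoints = doEndpoints())
  }
  invisible(written)
}
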