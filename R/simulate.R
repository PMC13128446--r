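#' Seeded synthetic data generators
#'
#' Each `simulate*()` generator produces one input family with a known
#' ground truth, so every downstream analysis stage can be tested without
#' external data. All generators are deterministic under a fixed seed: the
#' single global integer seed drives a splittable per-generator stream
#' (each family derives its own sub-seed), so adding a generator never
#' perturbs the output of the others. With all noise scales at zero the
#' output satisfies the generating equations exactly at every sampled
#' point, and the returned `truth` echoes the generating parameters
#' verbatim.
#'
#' @name simulators
NULL

logistic3 <- function(x, bottom, top, ec50) {
  bottom + (top - bottom) / (1 + ec50 / x)
}

defaultBretCompounds <- function() {
  # raw-scale curves; efficacies echo the G_oA potencies/efficacies of the
  # reference full agonist and the two nitazenes (% DAMGO)
  data.frame(
    compound = c("DAMGO", "FNZ", "DFNZ"),
    ec50 = c(5e-9, 0.51e-9, 1.66e-9),
    emax_pct = c(100, 118.5, 116.5),
    stringsAsFactors = FALSE)
}

#' Simulate a BRET agonist concentration-response plate
#'
#' Responses follow a three-parameter logistic on the raw BRET-ratio scale
#' with additive Gaussian noise; a DAMGO reference compound and ligand-free
#' wells are always included.
#'
#' @param seed integer seed.
#' @param compounds data.frame with `compound`, `ec50` (molar), `emax_pct`
#'   (% of the reference span); defaults to DAMGO plus the two nitazene
#'   agonists with their measured G-protein potencies.
#' @param concentrations molar dilution series (default 8 half-log steps
#'   from 1e-11).
#' @param nReplicates replicates per concentration (default 3).
#' @param bottom,refSpan raw-scale lower asymptote and reference span.
#' @param noiseSd additive Gaussian noise s.d. on the raw scale (>= 0).
#' @param nLigandFree ligand-free wells per compound (default 3).
#' @return list with `data` (long-format plate: `compound`, `concentration`,
#'   `replicate`, `response`, `well`) and `truth` (the generating
#'   parameters).
#' @export
simulateBretPlate <- function(seed = 1L,
                              compounds = defaultBretCompounds(),
                              concentrations = 10^seq(-11, -7.5, by = 0.5),
                              nReplicates = 3L, bottom = 0.30,
                              refSpan = 0.10, noiseSd = 0.003,
                              nLigandFree = 3L) {
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  if (any(compounds$ec50 <= 0)) stop("EC50 values must be > 0")
  if (noiseSd < 0) stop("noise sd must be >= 0")
  if (nReplicates < 1) stop("at least one replicate is required")
  if (length(concentrations) < 4)
    stop("at least 4 concentrations are required")
  rows <- list()
  localSeed(familySeed(seed, "bret_plate"), {
    for (i in seq_len(nrow(compounds))) {
      top <- bottom + refSpan * compounds$emax_pct[i] / 100
      for (r in seq_len(nReplicates)) {
        mu <- logistic3(concentrations, bottom, top, compounds$ec50[i])
        rows[[length(rows) + 1L]] <- data.frame(
          compound = compounds$compound[i],
          concentration = concentrations, replicate = r,
          response = mu + rnorm(length(mu), 0, noiseSd),
          well = "ligand")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compound = compounds$compound[i], concentration = 0,
        replicate = seq_len(nLigandFree),
        response = bottom + rnorm(nLigandFree, 0, noiseSd),
        well = "ligand_free")
    }
  })
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- list(seed = seed, family = "bret_plate",
                compounds = compounds, bottom = bottom, refSpan = refSpan,
                concentrations = concentrations, noiseSd = noiseSd,
                nReplicates = nReplicates)
  list(data = data, truth = truth)
}

defaultKineticTrajectories <- function(timepoints) {
  # %Emax trajectories emulating the measured functional kinetics: both
  # nitazenes start supramaximal at 2 min and relax exponentially to their
  # plateaus (G-protein pathway values); pEC50 drifts slowly upward
  relax <- function(e0, eInf, tau) eInf + (e0 - eInf) * exp(-(timepoints -
                                                              timepoints[1]) / tau)
  list(
    DAMGO = list(emax_pct = rep(100, length(timepoints)),
                 pec50 = rep(8.3, length(timepoints))),
    FNZ = list(emax_pct = relax(120.8, 111.2, 8),
               pec50 = rep(9.3, length(timepoints))),
    DFNZ = list(emax_pct = relax(123.2, 98.4, 8),
                pec50 = rep(8.8, length(timepoints))))
}

#' Simulate a kinetic BRET time-course plate
#'
#' One concentration-response plate per timepoint on the default
#' 2-46 min grid in 2-min cycles (23 timepoints), with each compound's
#' %Emax and pEC50 following a supplied per-timepoint trajectory relative
#' to the reference span.
#'
#' @param seed integer seed.
#' @param timepoints strictly increasing minutes grid (default
#'   `seq(2, 46, by = 2)`).
#' @param trajectories named list (one per compound) of lists with
#'   `emax_pct` and `pec50` vectors of `length(timepoints)`; default
#'   trajectories emulate the measured G-protein kinetics of the reference
#'   agonist and the two nitazenes.
#' @param nExperiments independent experiments (default 9).
#' @param concentrations molar dilution series.
#' @param bottom,refSpan,noiseSd raw-scale parameters as in
#'   [simulateBretPlate()].
#' @return list with `data` (long format with `timepoint_min`) and `truth`.
#' @export
simulateKineticBret <- function(seed = 1L,
                                timepoints = seq(2, 46, by = 2),
                                trajectories = NULL,
                                nExperiments = 9L,
                                concentrations = 10^seq(-11, -7.5,
                                                        by = 0.5),
                                bottom = 0.30, refSpan = 0.10,
                                noiseSd = 0.002) {
  if (any(diff(timepoints) <= 0))
    stop("timepoint grid must be strictly increasing")
  if (is.null(trajectories))
    trajectories <- defaultKineticTrajectories(timepoints)
  for (cmp in names(trajectories)) {
    tr <- trajectories[[cmp]]
    if (length(tr$emax_pct) != length(timepoints) ||
        length(tr$pec50) != length(timepoints))
      stop("trajectory length for '", cmp,
           "' does not match the timepoint count")
  }
  if (noiseSd < 0) stop("noise sd must be >= 0")
  rows <- list()
  localSeed(familySeed(seed, "bret_kinetic"), {
    for (ti in seq_along(timepoints)) {
      for (cmp in names(trajectories)) {
        tr <- trajectories[[cmp]]
        top <- bottom + refSpan * tr$emax_pct[ti] / 100
        ec <- 10^(-tr$pec50[ti])
        for (ex in seq_len(nExperiments)) {
          mu <- logistic3(concentrations, bottom, top, ec)
          rows[[length(rows) + 1L]] <- data.frame(
            compound = cmp, concentration = concentrations,
            timepoint_min = timepoints[ti], replicate = ex,
            response = mu + rnorm(length(mu), 0, noiseSd))
        }
      }
    }
  })
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- list(seed = seed, family = "bret_kinetic",
                timepoints = timepoints, trajectories = trajectories,
                bottom = bottom, refSpan = refSpan, noiseSd = noiseSd,
                nExperiments = nExperiments,
                concentrations = concentrations)
  list(data = data, truth = truth)
}

#' Simulate association and dissociation binding time courses
#'
#' Dissociation: `B(t) = B0 * exp(-k_off * t)`. Association:
#' `B(t) = Beq * (1 - exp(-k_obs * t))` with `k_obs = k_on * L + k_off`.
#' Time grids default to fixed intervals over 0-120 min.
#'
#' @param seed integer seed.
#' @param kOn association rate constant, /M/min.
#' @param kOff dissociation rate constant, /min.
#' @param L radioligand concentration, molar.
#' @param b0,beq signal scales of the two curves.
#' @param times minutes (both curves).
#' @param nReplicates replicates per timepoint.
#' @param noiseSd additive Gaussian noise s.d. (>= 0).
#' @return list with `data` (list of `association` and `dissociation`
#'   data.frames with `time_min`, `replicate`, `bound`) and `truth`
#'   (including the implied `kObs` and `tHalf`).
#' @export
simulateBindingKinetic <- function(seed = 1L, kOn = 7e8, kOff = 0.075,
                                   L = 0.3e-9, b0 = 100, beq = 100,
                                   times = seq(0, 120, by = 5),
                                   nReplicates = 2L, noiseSd = 1) {
  if (kOn < 0 || kOff < 0) stop("rate constants must be nonnegative")
  if (L <= 0) stop("ligand concentration must be > 0")
  if (noiseSd < 0) stop("noise sd must be >= 0")
  kObs <- kOn * L + kOff
  rows <- function(mu) do.call(rbind, lapply(seq_len(nReplicates),
    function(r) data.frame(time_min = times, replicate = r,
                           bound = mu + rnorm(length(mu), 0, noiseSd))))
  localSeed(familySeed(seed, "binding_kinetic"), {
    dis <- rows(b0 * exp(-kOff * times))
    asc <- rows(beq * (1 - exp(-kObs * times)))
  })
  truth <- list(seed = seed, family = "binding_kinetic", kOn = kOn,
                kOff = kOff, kObs = kObs, tHalf = log(2) / kOff, L = L,
                b0 = b0, beq = beq, noiseSd = noiseSd)
  list(data = list(association = asc, dissociation = dis), truth = truth)
}

defaultTrajectory <- function() {
  # PM -> early endosome shift over ranks 1..5 (agonist-driven
  # internalization); weights per compartment row, ranks in columns
  rbind(plasma_membrane = c(1.0, 0.8, 0.55, 0.35, 0.2),
        early_endosome = c(0.0, 0.2, 0.40, 0.50, 0.55),
        late_endosome_lysosome = c(0.0, 0.0, 0.05, 0.15, 0.25),
        cytoplasm = c(0.0, 0.0, 0.0, 0.0, 0.0))
}

#' Simulate an APEX proximity-labelling dataset
#'
#' Spatial-reference samples are drawn around per-compartment log2
#' profiles (marker proteins elevated in their own compartment); MOR-APEX
#' samples at time ranks 1..5 (0, 1, 5, 10, 30 min) are mixtures of the
#' compartment profiles on the linear intensity scale with per-timepoint
#' nonnegative weights, then logged, plus an additive batch offset and
#' Gaussian noise on the log2 scale. Missing entries are recorded as `NA`
#' (missing-at-random), never as zero.
#'
#' @param seed integer seed.
#' @param nProteins total proteins (default 160).
#' @param nMarkersPerCompartment markers elevated per compartment
#'   (default 15).
#' @param markerEffect log2 elevation of a marker in its own compartment
#'   (default 3).
#' @param ligands MOR-APEX ligand arms (default DAMGO, FNZ, DFNZ).
#' @param trajectory compartments x 5 matrix of nonnegative mixing weights,
#'   or a named list (one matrix per ligand); default encodes a
#'   PM-to-endosome shift.
#' @param nRefReplicates replicates per spatial reference (default 3).
#' @param nMorReplicates replicates per ligand x timepoint (default 4).
#' @param batchOffsets additive log2 offsets, one per batch (default
#'   `c(0, 0.3)`); samples are assigned to batches in rotation.
#' @param noiseSd log2-scale Gaussian noise s.d. (default 0.25).
#' @param missingRate missing-at-random rate in `[0, 1)`.
#' @return list with `apex` (an [ApexExperiment-class]) and `truth`.
#' @export
simulateApex <- function(seed = 1L, nProteins = 160L,
                         nMarkersPerCompartment = 15L, markerEffect = 3,
                         ligands = c("DAMGO", "FNZ", "DFNZ"),
                         trajectory = defaultTrajectory(),
                         nRefReplicates = 3L, nMorReplicates = 4L,
                         batchOffsets = c(0, 0.3), noiseSd = 0.25,
                         missingRate = 0.05) {
  comps <- apexCompartments()
  if (nRefReplicates < 1 || nMorReplicates < 1)
    stop("replicate counts must be >= 1")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (is.matrix(trajectory))
    trajectory <- setNames(rep(list(trajectory), length(ligands)), ligands)
  for (lg in ligands) {
    tr <- trajectory[[lg]]
    if (is.null(tr) || nrow(tr) != length(comps) || ncol(tr) != 5)
      stop("trajectory for '", lg, "' must be ", length(comps),
           " compartments x 5 time ranks")
    if (any(tr < 0)) stop("mixing weights must be nonnegative")
  }
  timesMin <- c(0, 1, 5, 10, 30)
  nMark <- nMarkersPerCompartment * length(comps)
  if (nProteins < nMark)
    stop("nProteins must be at least ", nMark)
  out <- NULL
  localSeed(familySeed(seed, "apex"), {
    base <- rnorm(nProteins, mean = 20, sd = 1.2)
    profiles <- matrix(rep(base, length(comps)), ncol = length(comps),
                       dimnames = list(paste0("P",
                                              sprintf("%04d",
                                                      seq_len(nProteins))),
                                       comps))
    markerOf <- rep(NA_character_, nProteins)
    for (k in seq_along(comps)) {
      ix <- ((k - 1) * nMarkersPerCompartment + 1):(k *
                                                    nMarkersPerCompartment)
      profiles[ix, k] <- profiles[ix, k] + markerEffect
      markerOf[ix] <- comps[k]
    }
    linProf <- 2^profiles

    cols <- list(); sheet <- list()
    addSample <- function(name, values, role, ligand, timeMin, timeRank,
                          replicate, batch, compartment) {
      cols[[name]] <<- values
      sheet[[name]] <<- data.frame(
        sample = name, role = role, ligand = ligand, time_min = timeMin,
        time_rank = timeRank, replicate = replicate, batch = batch,
        compartment = compartment)
    }
    batchIdx <- 0L
    nextBatch <- function() {
      batchIdx <<- batchIdx + 1L
      paste0("b", (batchIdx - 1L) %% length(batchOffsets) + 1L)
    }
    for (k in seq_along(comps)) {
      for (r in seq_len(nRefReplicates)) {
        b <- nextBatch()
        off <- batchOffsets[as.integer(sub("b", "", b))]
        y <- profiles[, k] + off + rnorm(nProteins, 0, noiseSd)
        addSample(paste0("ref_", comps[k], "_", r), y,
                  "spatial_reference", "none", NA_real_, NA_integer_, r,
                  b, comps[k])
      }
    }
    for (lg in ligands) {
      tr <- trajectory[[lg]]
      for (ti in 1:5) {
        w <- tr[, ti]
        mixLin <- as.numeric(linProf %*% w)
        mixLog <- log2(pmax(mixLin, .Machine$double.xmin))
        for (r in seq_len(nMorReplicates)) {
          b <- nextBatch()
          off <- batchOffsets[as.integer(sub("b", "", b))]
          y <- mixLog + off + rnorm(nProteins, 0, noiseSd)
          addSample(paste0("mor_", lg, "_t", ti, "_", r), y, "mor_apex",
                    lg, timesMin[ti], ti, r, b, NA_character_)
        }
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- rownames(profiles)
    ss <- do.call(rbind, sheet)
    if (missingRate > 0) {
      mask <- matrix(runif(length(mat)) < missingRate, nrow(mat))
      mat[mask] <- NA_real_
    }
    out <- list(mat = mat, sheet = ss, profiles = profiles,
                markerOf = markerOf)
  })
  apex <- ApexExperiment(out$mat, out$sheet[, -1])
  truth <- list(seed = seed, family = "apex", trajectory = trajectory,
                markerOf = out$markerOf, profiles = out$profiles,
                batchOffsets = batchOffsets, noiseSd = noiseSd,
                missingRate = missingRate, markerEffect = markerEffect,
                timesMin = timesMin)
  list(apex = apex, truth = truth)
}

#' Simulate a two-channel photometry recording
#'
#' The biosensor (465 nm) channel is a shared slow drift plus bleaching
#' decay plus a sensor-specific slow physiological fluctuation (smooth
#' oscillation in the tens-of-seconds range, emulating spontaneous
#' neuromodulator tone that the isosbestic channel does not report) plus
#' Gaussian-bump transients plus instrument noise; the isosbestic (405 nm)
#' channel carries only the shared drift and bleach, affinely scaled.
#' With zero noise, zero physiological fluctuation and zero transients,
#' isosbestic rescaling recovers the biosensor baseline exactly and dF/F is
#' identically zero. The baseline MAD of dF/F is set by the physiological
#' component, so the per-animal prominence threshold (2.5 x MAD) sits above
#' the background's own peak prominences while transients of amplitude
#' >= 5 x MAD clear it.
#'
#' @param seed integer seed.
#' @param fs sampling rate, Hz (default 400; at least 20x the 10 Hz
#'   anti-alias cutoff used downstream).
#' @param durationSec recording length (default 2400 s: a 10-min baseline
#'   followed by 30 min post-injection).
#' @param baselineSec baseline window length from t = 0 (default 600 s; the
#'   injection happens at its end).
#' @param transientTimes peak times, seconds (must lie within the record);
#'   default 14 post-injection events.
#' @param transientAmp amplitude(s) of the Gaussian bumps (a.u.).
#' @param transientSd bump width s.d., seconds.
#' @param bleachTau bleaching time constant, seconds.
#' @param driftAmp shared slow sinusoidal drift amplitude (a.u.; removed by
#'   isosbestic rescaling).
#' @param physAmp sensor-specific physiological oscillation amplitude on
#'   the dF/F scale (default 0.015; a 10x smaller faster component is
#'   added). Zero disables the component.
#' @param physPeriods periods of the two physiological sinusoids, seconds.
#' @param noiseSd per-channel Gaussian instrument noise s.d. (>= 0).
#' @param isoScale,isoOffset affine map from the shared component to the
#'   isosbestic channel.
#' @return list with `rec` (a [PhotometryRecording-class]) and `truth`.
#' @export
simulatePhotometry <- function(seed = 1L, fs = 400, durationSec = 2400,
                               baselineSec = 600,
                               transientTimes = seq(660, 2300, by = 120),
                               transientAmp = 0.08, transientSd = 1.5,
                               bleachTau = 8000, driftAmp = 0.01,
                               physAmp = 0.015, physPeriods = c(37, 11.3),
                               noiseSd = 0.002, isoScale = 0.6,
                               isoOffset = 0.2) {
  if (fs <= 0) stop("sampling rate must be > 0")
  if (any(transientTimes < 0 | transientTimes > durationSec))
    stop("transient times must lie within the record")
  if (!all(is.finite(c(bleachTau, driftAmp))))
    stop("bleaching/drift parameters must be finite")
  if (noiseSd < 0) stop("noise sd must be >= 0")
  tt <- seq(0, durationSec - 1 / fs, by = 1 / fs)
  amp <- rep(transientAmp, length.out = length(transientTimes))
  shared <- exp(-tt / bleachTau) + driftAmp * sin(2 * pi * tt / 120)
  bumps <- rep(0, length(tt))
  for (i in seq_along(transientTimes))
    bumps <- bumps + amp[i] * exp(-(tt - transientTimes[i])^2 /
                                    (2 * transientSd^2))
  rec <- NULL
  localSeed(familySeed(seed, "photometry"), {
    phases <- runif(2, 0, 2 * pi)
    phys <- physAmp * sin(2 * pi * tt / physPeriods[1] + phases[1]) +
      0.1 * physAmp * sin(2 * pi * tt / physPeriods[2] + phases[2])
    # physiological fluctuation and transients are fractional changes of
    # the fluorescence (they scale with F), instrument noise is additive
    f465 <- shared * (1 + phys + bumps) + rnorm(length(tt), 0, noiseSd)
    f405 <- isoScale * shared + isoOffset + rnorm(length(tt), 0, noiseSd)
    rec <- PhotometryRecording(f465, f405, fs = fs, time = tt,
                                baselineWindow = c(0, baselineSec),
                                injectionTime = baselineSec)
  })
  truth <- list(seed = seed, family = "photometry", fs = fs,
                transientTimes = transientTimes, transientAmp = amp,
                transientSd = transientSd, bleachTau = bleachTau,
                driftAmp = driftAmp, physAmp = physAmp,
                physPeriods = physPeriods, noiseSd = noiseSd,
                isoScale = isoScale, isoOffset = isoOffset)
  list(rec = rec, truth = truth)
}

#' Simulate scalar pharmacology endpoint tables
#'
#' Generates a hot-plate latency table (logistic dose effect on %MPE with
#' Gaussian noise, 45 s cut-off), a pharmacokinetic table (brain/plasma
#' total concentrations with stated protein binding) and a withdrawal
#' observation table (Poisson counts, Bernoulli checked signs, two raters).
#'
#' @param seed integer seed.
#' @param doses mg/kg (hot-plate arm).
#' @param ed50True true ED50, mg/kg.
#' @param nSubjects subjects per dose.
#' @param baselineSec,maxSec hot-plate baseline latency and cut-off.
#' @param mpeNoiseSd noise s.d. on the %MPE scale.
#' @return list with `data` (list of `hotplate`, `pk`, `withdrawal`) and
#'   `truth`.
#' @export
simulateEndpoints <- function(seed = 1L,
                              doses = c(0.001, 0.003, 0.01, 0.03),
                              ed50True = 0.005, nSubjects = 6L,
                              baselineSec = 10, maxSec = 45,
                              mpeNoiseSd = 5) {
  out <- NULL
  localSeed(familySeed(seed, "endpoints"), {
    hp <- do.call(rbind, lapply(doses, function(d) {
      mpe <- 100 / (1 + ed50True / d)
      mpeObs <- pmin(pmax(mpe + rnorm(nSubjects, 0, mpeNoiseSd), 0), 100)
      data.frame(subject = seq_len(nSubjects), dose_mgkg = d,
                 baseline_s = baselineSec,
                 latency_s = baselineSec +
                   mpeObs / 100 * (maxSec - baselineSec),
                 max_s = maxSec)
    }))
    pk <- data.frame(
      subject = rep(seq_len(nSubjects), 2),
      matrix_type = rep(c("brain", "plasma"), each = nSubjects),
      total_nM = c(rnorm(nSubjects, 17, 1), rnorm(nSubjects, 9.4, 0.8)),
      fraction_bound = 0.946)
    signs <- names(withdrawalCheckedWeights())
    wd <- do.call(rbind, lapply(seq_len(nSubjects), function(a) {
      do.call(rbind, lapply(1:2, function(rater) {
        row <- data.frame(animal = paste0("rat", a), rater = rater,
                          jump_attempts = rpois(1, 3),
                          paw_tremors = rpois(1, 1),
                          wet_dog_shakes = rpois(1, 1),
                          fecal_deposits = rpois(1, 2),
                          weight_loss_g = rpois(1, 2))
        for (s in signs) row[[s]] <- rbinom(1, 1, 0.2) == 1
        row
      }))
    }))
    out <- list(hotplate = hp, pk = pk, withdrawal = wd)
  })
  truth <- list(seed = seed, family = "endpoints", ed50 = ed50True,
                doses = doses, baselineSec = baselineSec, maxSec = maxSec,
                mpeNoiseSd = mpeNoiseSd, ppb = 0.946)
  list(data = out, truth = truth)
}
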