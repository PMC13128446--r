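#' @import methods
#' @importFrom stats anova coef cor lm mad median poly predict
#'   quantile rbinom rnorm rpois runif sd setNames vcov approx pt
NULL

#' Three-parameter logistic concentration-response fit
#'
#' Holds the least-squares estimates of a three-parameter logistic model
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{(\log_{10} EC_{50} -
#' \log_{10} x)})}{y = bottom + (top - bottom)/(1 + EC50/x)}
#' fitted on the log10-concentration scale with the pEC50 as the free
#' location parameter. For competition ("decreasing") orientation the sign of
#' the slope term is reversed and the inflection is reported as an IC50.
#'
#' @slot compound character label of the fitted compound.
#' @slot bottom,top lower and upper asymptotes (signal units); `bottom <= top`
#'   is enforced by the fitting parameterization.
#' @slot ec50 half-maximal effective (or inhibitory) concentration, molar.
#' @slot direction `"increasing"` (agonist) or `"decreasing"` (competition).
#' @slot converged logical convergence flag; non-convergence and degenerate
#'   inputs are flagged, never silent.
#' @slot flags character vector of quality flags (e.g. `"nonidentifiable"`).
#' @slot vcov variance-covariance matrix of the internal parameters
#'   (bottom, log-span, pEC50), or a 0x0 matrix when unavailable.
#' @slot n number of observations used in the fit.
#'
#' @seealso [fitLogistic3()], [pec50()], [ec50()], [emax()]
#' @export
setClass("LogisticFit",
  representation(
    compound = "character",
    bottom = "numeric",
    top = "numeric",
    ec50 = "numeric",
    direction = "character",
    converged = "logical",
    flags = "character",
    vcov = "matrix",
    n = "integer"
  ),
  prototype(
    compound = NA_character_, bottom = NA_real_, top = NA_real_,
    ec50 = NA_real_, direction = "increasing", converged = FALSE,
    flags = character(), vcov = matrix(numeric(), 0, 0), n = 0L
  )
)

setValidity("LogisticFit", function(object) {
  msg <- character()
  if (!object@direction %in% c("increasing", "decreasing"))
    msg <- c(msg, "direction must be 'increasing' or 'decreasing'")
  if (isTRUE(object@converged)) {
    if (!is.na(object@ec50) && object@ec50 <= 0)
      msg <- c(msg, "ec50 must be > 0")
    if (!is.na(object@bottom) && !is.na(object@top) &&
        object@bottom > object@top + 1e-12)
      msg <- c(msg, "bottom must be <= top")
  }
  if (length(msg)) msg else TRUE
})

#' Radioligand binding kinetic fit
#'
#' Result container for exponential association / dissociation fits.
#' The dissociation half-life is definitional, `tHalf = ln(2)/kOff`, and is
#' always derived from the stored rate constant so the identity holds exactly.
#'
#' @slot kOff dissociation rate constant, per minute.
#' @slot kObs observed association rate constant, per minute (association
#'   fits only, otherwise `NA`).
#' @slot kOn association rate constant, per molar per minute
#'   (`(kObs - kOff)/L`), `NA` for dissociation-only fits.
#' @slot b0 initial bound signal (dissociation) or `NA`.
#' @slot beq equilibrium bound signal (association) or `NA`.
#' @slot ligandConc radioligand concentration L, molar (`NA` if not used).
#' @slot converged logical convergence flag.
#' @slot flags character quality flags (e.g. `"nonphysical_kon"`,
#'   `"nondecaying"`).
#'
#' @seealso [fitDissociation()], [fitAssociation()], [tHalf()]
#' @export
setClass("KineticFit",
  representation(
    kOff = "numeric", kObs = "numeric", kOn = "numeric",
    b0 = "numeric", beq = "numeric", ligandConc = "numeric",
    converged = "logical", flags = "character"
  ),
  prototype(
    kOff = NA_real_, kObs = NA_real_, kOn = NA_real_,
    b0 = NA_real_, beq = NA_real_, ligandConc = NA_real_,
    converged = FALSE, flags = character()
  )
)

setValidity("KineticFit", function(object) {
  if (isTRUE(object@converged) && !is.na(object@kOff) && object@kOff <= 0)
    "kOff must be > 0 for a converged fit" else TRUE
})

#' Competition binding affinity estimate
#'
#' IC50 from a one-site competition curve together with the equilibrium
#' inhibition constant Ki obtained via the Cheng-Prusoff correction
#' `Ki = IC50 / (1 + L/Kd)`.
#'
#' @slot ic50 half-maximal inhibitory concentration, molar.
#' @slot ki Cheng-Prusoff corrected inhibition constant, molar.
#' @slot ligandConc radioligand concentration L, molar.
#' @slot kd radioligand equilibrium dissociation constant, molar.
#' @slot fit the underlying [LogisticFit-class] (decreasing orientation).
#'
#' @seealso [oneSiteCompetition()], [chengPrusoff()]
#' @export
setClass("AffinityEstimate",
  representation(
    ic50 = "numeric", ki = "numeric", ligandConc = "numeric",
    kd = "numeric", fit = "LogisticFit"
  )
)

setValidity("AffinityEstimate", function(object) {
  msg <- character()
  if (!is.na(object@ki) && !is.na(object@ic50) &&
      object@ki > object@ic50 + 1e-12)
    msg <- c(msg, "ki must be <= ic50 when L >= 0")
  if (length(msg)) msg else TRUE
})

#' APEX proximity-labelling experiment container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] holding protein
#' log2 intensities (assay `"log2intensity"`, proteins x samples, `NA` =
#' missing; missingness is explicit, never silently zero) with the sample
#' sheet in `colData`. Required `colData` columns:
#' `role` (`"mor_apex"` or `"spatial_reference"`), `ligand`, `time_min`,
#' `time_rank` (rank encoding 1..5 of times 0, 1, 5, 10, 30 min),
#' `replicate`, `batch`, and `compartment` (spatial references only; one of
#' `"plasma_membrane"`, `"early_endosome"`, `"late_endosome_lysosome"`,
#' `"cytoplasm"`).
#'
#' @seealso [ApexExperiment()], [scoreTimecourse()], [selectMarkers()],
#'   [deconvolveSample()]
#' @export
#' @import SummarizedExperiment
setClass("ApexExperiment", contains = "SummarizedExperiment")

apexCompartments <- function() {
  c("plasma_membrane", "early_endosome", "late_endosome_lysosome", "cytoplasm")
}

setValidity("ApexExperiment", function(object) {
  msg <- character()
  need <- c("role", "ligand", "time_min", "time_rank", "replicate", "batch",
            "compartment")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(miss, collapse = ", ")))
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2intensity' is required")
  if (!length(msg)) {
    bad <- setdiff(unique(cd$role), c("mor_apex", "spatial_reference"))
    if (length(bad))
      msg <- c(msg, paste0("unknown role(s): ", paste(bad, collapse = ", ")))
    isref <- cd$role == "spatial_reference"
    if (any(isref)) {
      badc <- setdiff(unique(cd$compartment[isref]), apexCompartments())
      if (length(badc))
        msg <- c(msg, paste0("unknown compartment(s): ",
                             paste(badc, collapse = ", ")))
    }
    mor <- cd[!isref, , drop = FALSE]
    if (nrow(mor)) {
      # time_rank must be the rank of time_min within the MOR-APEX samples
      tm <- sort(unique(mor$time_min))
      expected <- match(mor$time_min, tm)
      if (!all(mor$time_rank == expected))
        msg <- c(msg, "time_rank must equal the rank of time_min")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Two-channel fibre-photometry recording
#'
#' Paired biosensor (465 nm) and isosbestic (405 nm) traces on a uniform
#' time grid, with the baseline window and injection time needed by the
#' downstream correction and transient analysis.
#'
#' @slot time numeric, seconds, uniform grid.
#' @slot f465 biosensor channel, arbitrary units.
#' @slot f405 isosbestic channel, arbitrary units.
#' @slot fs sampling rate, Hz.
#' @slot baselineWindow numeric length-2, `[t0, t1]` seconds; must precede
#'   the injection time.
#' @slot injectionTime seconds.
#' @slot animalId character label.
#'
#' @seealso [PhotometryRecording()], [preprocessRecording()],
#'   [fitBaseline()], [computeDff()]
#' @export
setClass("PhotometryRecording",
  representation(
    time = "numeric", f465 = "numeric", f405 = "numeric",
    fs = "numeric", baselineWindow = "numeric",
    injectionTime = "numeric", animalId = "character"
  )
)

setValidity("PhotometryRecording", function(object) {
  msg <- character()
  if (length(object@f465) != length(object@time) ||
      length(object@f405) != length(object@time))
    msg <- c(msg, "channels and time grid must have equal length")
  if (object@fs <= 0) msg <- c(msg, "sampling rate must be > 0")
  if (length(object@baselineWindow) != 2 ||
      diff(object@baselineWindow) <= 0)
    msg <- c(msg, "baselineWindow must be an increasing [t0, t1]")
  if (length(msg) == 0 && object@baselineWindow[2] > object@injectionTime)
    msg <- c(msg, "baseline window must precede the injection time")
  if (length(msg)) msg else TRUE
})

#' Detected fluorescence transients
#'
#' Events isolated from a dF/F trace by a fixed prominence threshold:
#' local maxima whose topographic prominence is at least the threshold.
#' Amplitude is the prominence, duration the full width at half prominence,
#' and frequency the event count per minute of the analysis window.
#'
#' @slot events data.frame with columns `peak_time_s`, `amplitude`,
#'   `duration_s`.
#' @slot threshold the prominence threshold used (fixed per animal).
#' @slot frequencyPerMin events per minute over the analysis window.
#' @slot window numeric length-2 analysis window, seconds.
#'
#' @seealso [detectTransients()], [setTransientThreshold()]
#' @export
setClass("TransientSet",
  representation(
    events = "data.frame", threshold = "numeric",
    frequencyPerMin = "numeric", window = "numeric"
  )
)

setValidity("TransientSet", function(object) {
  msg <- character()
  if (nrow(object@events)) {
    if (any(object@events$amplitude < object@threshold - 1e-12))
      msg <- c(msg, "every event's prominence must be >= threshold")
    if (any(object@events$duration_s <= 0))
      msg <- c(msg, "durations must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Spatial-reference deconvolution coefficients for one sample
#'
#' Median nonnegative least-squares coefficients of the true compartments
#' over randomized repeats (dummy columns resampled each repeat, their
#' coefficients dropped).
#'
#' @slot coefficients named numeric, one median coefficient per compartment;
#'   all `>= 0`.
#' @slot nRepeats number of randomization repeats.
#' @slot nDummy number of random dummy columns appended per repeat.
#' @slot seed integer seed recorded for reproducibility.
#'
#' @seealso [deconvolveSample()]
#' @export
setClass("SpatialCoefficients",
  representation(
    coefficients = "numeric", nRepeats = "integer",
    nDummy = "integer", seed = "integer"
  )
)

setValidity("SpatialCoefficients", function(object) {
  if (any(object@coefficients < 0))
    "all coefficients must be nonnegative" else TRUE
})
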