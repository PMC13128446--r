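#' Percent maximum possible effect
#'
#' `%MPE = 100 * (measure - baseline) / (maxResponse - baseline)`. Values
#' above 100% are possible only when the measure exceeds the stated maximum
#' (cut-offs normally cap measures) and are flagged with a warning.
#'
#' @param measure experimental measure (e.g. hot-plate latency, seconds).
#' @param baseline pre-treatment baseline, same units.
#' @param maxResponse maximum possible response (e.g. the 45 s hot-plate
#'   cut-off), must exceed the baseline.
#' @return percent maximum possible effect.
#' @examples
#' percentMPE(27.5, 10, 45)  # 50
#' @export
percentMPE <- function(measure, baseline, maxResponse) {
  if (any(maxResponse <= baseline))
    stop("maxResponse must be greater than baseline")
  mpe <- 100 * (measure - baseline) / (maxResponse - baseline)
  if (any(mpe > 100, na.rm = TRUE))
    warning("measure exceeds the stated maximum response (",
            "%MPE > 100)")
  mpe
}

#' Standardized uptake value
#'
#' `SUV = C / (dose / BW)` where `C` is the tissue concentration (kBq/ml),
#' `dose` the administered dose (MBq) and `BW` the body weight (kg). With
#' these units the SUV carries a factor kBq.kg / (ml.MBq); identical
#' concentration and dose-per-weight give SUV = 1 in matched units.
#'
#' @param tissueConc tissue concentration, kBq/ml.
#' @param dose administered dose, MBq.
#' @param bodyWeight kg.
#' @return SUV.
#' @examples
#' suv(2, 4, 0.5)  # 0.25
#' @export
suv <- function(tissueConc, dose, bodyWeight) {
  if (any(dose <= 0)) stop("dose must be > 0")
  if (any(bodyWeight <= 0)) stop("body weight must be > 0")
  tissueConc / (dose / bodyWeight)
}

#' Unbound concentration from plasma protein binding
#'
#' `unbound = total * (1 - ppb)` with `ppb` the bound fraction (e.g. 0.946
#' for 94.6% plasma protein binding).
#'
#' @param totalConc total concentration (any unit).
#' @param ppb bound fraction, in `[0, 1)`.
#' @return unbound concentration, same unit as `totalConc`.
#' @examples
#' unboundConcentration(100, 0.946)  # 5.4
#' @export
unboundConcentration <- function(totalConc, ppb) {
  if (any(ppb < 0 | ppb >= 1)) stop("ppb must be in [0, 1)")
  totalConc * (1 - ppb)
}

#' Brain-to-plasma concentration ratio
#'
#' Ratios above 1 indicate net brain accumulation relative to plasma;
#' ratios below 1 indicate active clearance/impaired penetrance.
#'
#' @param brainUnbound unbound brain concentration.
#' @param plasmaUnbound unbound plasma concentration, > 0.
#' @return brain/plasma quotient.
#' @examples
#' brainPlasmaRatio(0.91, 0.51)  # ~1.8
#' @export
brainPlasmaRatio <- function(brainUnbound, plasmaUnbound) {
  if (any(plasmaUnbound <= 0)) stop("plasma concentration must be > 0")
  brainUnbound / plasmaUnbound
}

#' Percent of compound remaining (microsomal stability)
#'
#' @param concT concentration at time t.
#' @param conc0 concentration at t = 0, > 0.
#' @return `100 * concT / conc0`.
#' @examples
#' percentRemaining(25, 50)  # 50
#' @export
percentRemaining <- function(concT, conc0) {
  if (any(conc0 <= 0)) stop("baseline concentration must be > 0")
  100 * concT / conc0
}

#' Fold difference between two quantities
#'
#' @param a numerator.
#' @param b denominator, > 0.
#' @return `a / b`.
#' @examples
#' foldDifference(0.3, 0.005)  # 60
#' @export
foldDifference <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be > 0")
  a / b
}

withdrawalCheckedWeights <- function() {
  c(abdominal_spasms = 2, abnormal_posture = 3, diarrhea = 2,
    irritability_vocalization = 3, genital_grooming = 3,
    profuse_salivation = 7, ptosis = 2, swallowing_movements = 2,
    teeth_chattering = 2)
}

gradeJumps <- function(n) {
  # 1 point for 1-4 attempts, 2 for 5-9, 3 for >10; exactly 10 is
  # unassigned by the scheme and scored in the 2-point bracket (literal
  # reading of ">10")
  ifelse(n <= 0, 0, ifelse(n <= 4, 1, ifelse(n <= 10, 2, 3)))
}
gradeTremors <- function(n) {
  # 2 points for 1-2, 4 for >3; exactly 3 takes the higher bracket
  ifelse(n <= 0, 0, ifelse(n <= 2, 2, 4))
}
gradeShakes <- function(n) {
  # 1 point for 1-2, 2 for >3; exactly 3 takes the higher bracket
  ifelse(n <= 0, 0, ifelse(n <= 2, 1, 2))
}

#' Naloxone-precipitated withdrawal score for one rater's observation
#'
#' Weighted sum of graded somatic signs (jump attempts 1/2/3 points for
#' 1-4 / 5-9 / >10 attempts; paw tremor 2 or 4 points for 1-2 / 3 or more;
#' wet dog shakes 1 or 2 points for 1-2 / 3 or more; 1 point per fecal
#' deposit), checked signs (abdominal spasms 2, abnormal posture 3,
#' diarrhea 2, irritability/vocalization 3, genital grooming 3, profuse
#' salivation 7, ptosis 2, swallowing movements 2, teeth chattering 2) and
#' 1 point per gram of weight loss (fractional grams rounded to nearest).
#' The score is monotone nondecreasing in every count, flag and gram, and
#' the empty observation scores 0.
#'
#' @param jumpAttempts,pawTremors,wetDogShakes,fecalDeposits nonnegative
#'   counts.
#' @param checkedSigns character vector of observed checked signs (any of
#'   `names(withdrawalCheckedWeights())`), or a named logical vector.
#' @param weightLossG grams lost (>= 0 contributes; negative treated as 0).
#' @return total score for this observation.
#' @examples
#' withdrawalScore(jumpAttempts = 7)  # 2
#' withdrawalScore(checkedSigns = c("profuse_salivation", "ptosis"))  # 9
#' @export
withdrawalScore <- function(jumpAttempts = 0, pawTremors = 0,
                            wetDogShakes = 0, fecalDeposits = 0,
                            checkedSigns = character(),
                            weightLossG = 0) {
  counts <- c(jumpAttempts, pawTremors, wetDogShakes, fecalDeposits)
  if (any(counts < 0)) stop("counts must be nonnegative")
  w <- withdrawalCheckedWeights()
  if (is.logical(checkedSigns)) {
    checkedSigns <- names(checkedSigns)[checkedSigns]
  }
  unknown <- setdiff(checkedSigns, names(w))
  if (length(unknown))
    stop("unknown checked sign(s): ", paste(unknown, collapse = ", "))
  gradeJumps(jumpAttempts) + gradeTremors(pawTremors) +
    gradeShakes(wetDogShakes) + fecalDeposits +
    sum(w[unique(checkedSigns)]) + max(0, round(weightLossG))
}

#' Withdrawal score averaged across raters
#'
#' Scores each rater's observation row with [withdrawalScore()], averages
#' across the raters of each animal, and returns per-animal scores
#' (matching the two-experimenter averaging of the scoring protocol).
#'
#' @param obs data.frame with one row per rater per animal: columns
#'   `animal`, `rater`, `jump_attempts`, `paw_tremors`, `wet_dog_shakes`,
#'   `fecal_deposits`, `weight_loss_g`, plus one logical column per checked
#'   sign (names from `names(withdrawalCheckedWeights())`).
#' @return data.frame with `animal` and `score`.
#' @export
withdrawalScoreTable <- function(obs) {
  need <- c("animal", "rater", "jump_attempts", "paw_tremors",
            "wet_dog_shakes", "fecal_deposits", "weight_loss_g")
  if (!all(need %in% names(obs)))
    stop("obs must have columns: ", paste(need, collapse = ", "))
  signCols <- intersect(names(withdrawalCheckedWeights()), names(obs))
  perRow <- vapply(seq_len(nrow(obs)), function(i) {
    flags <- if (length(signCols))
      vapply(signCols, function(s) isTRUE(obs[i, s]), logical(1))
    else logical(0)
    withdrawalScore(obs$jump_attempts[i], obs$paw_tremors[i],
                    obs$wet_dog_shakes[i], obs$fecal_deposits[i],
                    names(flags)[flags], obs$weight_loss_g[i])
  }, numeric(1))
  out <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$animal),
                               function(ix) data.frame(
                                 animal = obs$animal[ix[1]],
                                 score = mean(perRow[ix]))))
  rownames(out) <- NULL
  out
}

#' ED50 from a normalized dose-response relationship
#'
#' Fits %MPE means against dose with a logistic whose asymptotes are fixed
#' at 0 and 100 (normalized response), leaving the log ED50 as the free
#' location parameter: `y = 100 / (1 + 10^(log10(ED50) - log10(dose)))`.
#' Dose units are preserved in the output.
#'
#' @param dose doses (> 0, e.g. mg/kg).
#' @param mpe mean %MPE per dose.
#' @param hillSlope fix the slope at 1 (default) or estimate it
#'   (`hillSlope = NA`).
#' @return list with `ed50` (dose units), `converged`, `flags`.
#' @examples
#' d <- c(0.001, 0.003, 0.01, 0.03)
#' ed50(d, 100 / (1 + 0.005 / d))$ed50  # 0.005
#' @export
ed50 <- function(dose, mpe, hillSlope = 1) {
  if (length(dose) < 3) stop("at least 3 doses are required")
  if (any(dose <= 0)) stop("doses must be > 0")
  ld <- log10(dose)
  flags <- character()
  if (max(mpe) - min(mpe) < 1e-8 ||
      cor(ld, mpe) <= 0)
    flags <- c(flags, "nonmonotone_or_flat")
  start <- list(led50 = ld[which.min(abs(mpe - 50))])
  form <- if (is.na(hillSlope))
    mpe ~ 100 / (1 + 10^(h * (led50 - ld)))
  else mpe ~ 100 / (1 + 10^(hillSlope * (led50 - ld)))
  if (is.na(hillSlope)) start$h <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(form,
                      data = data.frame(mpe = mpe, ld = ld,
                                        hillSlope = hillSlope),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(ed50 = NA_real_, converged = FALSE,
                flags = c(flags, paste0("fit_error: ",
                                        conditionMessage(fit)))))
  list(ed50 = 10^unname(coef(fit)["led50"]),
       converged = isTRUE(fit$convInfo$isConv), flags = flags)
}
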