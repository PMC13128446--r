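#' Fit a three-parameter logistic concentration-response model
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + 10^(s *
#' (log10(EC50) - log10(x))))` with `s = +1` for agonist (increasing) data
#' and `s = -1` for competition (decreasing) data. The fit is performed on
#' the log10-concentration scale with the pEC50 as the free location
#' parameter, and the span is parameterized as `exp(logspan)` so `bottom <=
#' top` holds by construction rather than by clipping.
#'
#' Starting values follow standard robust practice: bottom/top from the
#' min/max of the per-concentration mean responses, pEC50 from the
#' concentration whose mean response is closest to the half-span.
#' Replicates are fitted jointly with equal weights (pooled-curve practice);
#' fit per experiment by subsetting beforehand when per-experiment estimates
#' are needed.
#'
#' @param data data.frame with columns `concentration` (molar, > 0) and
#'   `response`; additional columns (`compound`, `replicate`, ...) are
#'   ignored. Alternatively supply `concentration` and `response` vectors.
#' @param response optional numeric vector when `data` is a concentration
#'   vector.
#' @param compound label stored in the result.
#' @param direction `"increasing"` or `"decreasing"` (competition
#'   orientation).
#' @return a [LogisticFit-class]. Non-convergence or degenerate
#'   (non-identifiable) inputs yield `isConverged(fit) == FALSE` with a flag,
#'   never a silent failure.
#' @examples
#' x <- 10^seq(-11, -7.5, by = 0.5)
#' y <- 100 / (1 + 1e-9 / x)
#' fit <- fitLogistic3(data.frame(concentration = x, response = y))
#' ec50(fit)
#' @export
fitLogistic3 <- function(data, response = NULL, compound = NA_character_,
                         direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.data.frame(data)) {
    data <- data.frame(concentration = data, response = response)
  }
  if (!all(c("concentration", "response") %in% names(data)))
    stop("data must have 'concentration' and 'response' columns")
  x <- data$concentration
  y <- data$response
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(x)) < 4)
    stop("at least 4 distinct concentrations are required for a ",
         "3-parameter fit")
  lx <- log10(x)
  sgn <- if (direction == "increasing") 1 else -1

  doseMeans <- tapply(y, lx, mean)
  lv <- as.numeric(names(doseMeans))
  span0 <- max(doseMeans) - min(doseMeans)
  if (span0 <= max(1e-12, 1e-8 * max(abs(doseMeans)))) {
    # constant responses: ec50 is non-identifiable
    return(new("LogisticFit", compound = compound,
               bottom = min(doseMeans), top = max(doseMeans),
               ec50 = NA_real_, direction = direction, converged = FALSE,
               flags = "nonidentifiable", n = length(y)))
  }
  half <- min(doseMeans) + span0 / 2
  pec0 <- -lv[which.min(abs(doseMeans - half))]
  start <- c(bottom = unname(min(doseMeans)),
             logspan = log(span0),
             pec50 = unname(pec0))

  model <- function(p, lx) {
    p[["bottom"]] + exp(p[["logspan"]]) /
      (1 + 10^(sgn * (-p[["pec50"]] - lx)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + exp(logspan) / (1 + 10^(sgn * (-pec50 - lx))),
      data = data.frame(y = y, lx = lx, sgn = sgn),
      start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("LogisticFit", compound = compound,
               bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
               direction = direction, converged = FALSE,
               flags = paste0("fit_error: ", conditionMessage(fit)),
               n = length(y)))
  }
  p <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(numeric(), 0, 0))
  bottomHat <- unname(p["bottom"])
  topHat <- bottomHat + exp(unname(p["logspan"]))
  ec <- 10^(-unname(p["pec50"]))
  flags <- character()
  conv <- isTRUE(fit$convInfo$isConv)
  if (!conv) flags <- c(flags, "nonconverged")
  # inflection far outside the tested range is effectively non-identifiable
  if (-log10(ec) > -min(lx) + 2 || -log10(ec) < -max(lx) - 2)
    flags <- c(flags, "ec50_outside_range")
  new("LogisticFit", compound = compound, bottom = bottomHat, top = topHat,
      ec50 = ec, direction = direction, converged = conv, flags = flags,
      vcov = vc, n = length(y))
}

#' Predict from a logistic fit
#'
#' @param fit a [LogisticFit-class].
#' @param concentration molar concentrations (> 0).
#' @return fitted responses.
#' @export
predictLogistic <- function(fit, concentration) {
  stopifnot(is(fit, "LogisticFit"))
  sgn <- if (fit@direction == "increasing") 1 else -1
  fit@bottom + (fit@top - fit@bottom) /
    (1 + 10^(sgn * (log10(fit@ec50) - log10(concentration))))
}

#' Normalize responses to the DAMGO positive control
#'
#' Expresses responses as percent of the reference (DAMGO) span: the
#' reference fit's minimum asymptote is subtracted and the result divided by
#' the reference span (top - bottom), times 100. The map is affine, so it
#' preserves ordering and ratios of spans; values above 100% (supramaximal
#' efficacy) are legitimate.
#'
#' @param y numeric responses, or a [LogisticFit-class] whose asymptotes are
#'   normalized (returning a named vector with `bottom` and `top` in % of the
#'   reference span).
#' @param damgoFit the reference [LogisticFit-class].
#' @return normalized values, % of the reference span.
#' @examples
#' ref <- new("LogisticFit", bottom = 0.1, top = 0.6, ec50 = 1e-9,
#'            direction = "increasing", converged = TRUE)
#' normalizeToDamgo(0.7, ref)  # 120
#' @export
normalizeToDamgo <- function(y, damgoFit) {
  stopifnot(is(damgoFit, "LogisticFit"))
  span <- damgoFit@top - damgoFit@bottom
  if (!is.finite(span) || span <= 0)
    stop("reference span (top - bottom) must be > 0")
  if (is(y, "LogisticFit")) {
    return(c(bottom = 100 * (y@bottom - damgoFit@bottom) / span,
             top = 100 * (y@top - damgoFit@bottom) / span))
  }
  100 * (y - damgoFit@bottom) / span
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L/Kd)` where `L` is the radioligand concentration and
#' `Kd` its equilibrium dissociation constant. With `L = 0` there is no
#' competition correction and `Ki = IC50`.
#'
#' @param ic50 molar, > 0.
#' @param L radioligand concentration, molar, >= 0.
#' @param kd radioligand Kd, molar, > 0.
#' @return Ki, molar.
#' @examples
#' chengPrusoff(10e-9, 5e-9, 5e-9)  # 5 nM
#' @export
chengPrusoff <- function(ic50, L, kd) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(L < 0)) stop("L must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  ic50 / (1 + L / kd)
}

#' Fit a dissociation (exponential decay) time course
#'
#' Fits specific binding `B(t) = B0 * exp(-k_off * t)` by nonlinear least
#' squares (inputs are assumed background-subtracted specific binding).
#' The dissociation half-life is `t_1/2 = ln(2)/k_off` exactly.
#'
#' @param time minutes.
#' @param bound specific binding signal.
#' @return a [KineticFit-class] with `kOff`, `b0` and (via [tHalf()]) the
#'   half-life. A non-decaying series is flagged `"nondecaying"`.
#' @examples
#' t <- seq(0, 60, by = 5)
#' fit <- fitDissociation(t, 100 * exp(-0.075 * t))
#' tHalf(fit)
#' @export
fitDissociation <- function(time, bound) {
  stopifnot(length(time) == length(bound))
  keep <- is.finite(time) & is.finite(bound)
  time <- time[keep]; bound <- bound[keep]
  if (length(unique(time)) < 5)
    stop("at least 5 timepoints are required")
  # log-linear start (guard against non-positive signals)
  pos <- bound > 0
  slope <- if (sum(pos) >= 2)
    unname(coef(lm(log(bound[pos]) ~ time[pos]))[2]) else 0
  if (!is.finite(slope) || slope >= 0) {
    return(new("KineticFit", converged = FALSE, flags = "nondecaying"))
  }
  start <- list(b0 = max(bound), koff = -slope)
  fit <- tryCatch(
    minpack.lm::nlsLM(bound ~ b0 * exp(-koff * time),
                      data = data.frame(bound = bound, time = time),
                      start = start, lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new("KineticFit", converged = FALSE,
               flags = paste0("fit_error: ", conditionMessage(fit))))
  p <- coef(fit)
  new("KineticFit", kOff = unname(p["koff"]), b0 = unname(p["b0"]),
      converged = isTRUE(fit$convInfo$isConv))
}

#' Fit an association time course with known k_off
#'
#' Fits `B(t) = Beq * (1 - exp(-k_obs * t))`, then derives the association
#' rate constant `k_on = (k_obs - k_off) / L`, with `k_off` taken from the
#' dissociation fit as an input parameter (mirroring standard kinetic binding
#' practice). A fitted `k_obs < k_off` makes `k_on` non-physical and is
#' flagged.
#'
#' @param time minutes.
#' @param bound specific binding signal.
#' @param koff dissociation rate constant, per minute, > 0 (or a
#'   [KineticFit-class] from [fitDissociation()]).
#' @param L radioligand concentration, molar, > 0.
#' @return a [KineticFit-class] with `kObs`, `kOn`, `beq`.
#' @examples
#' t <- seq(0, 120, by = 5)
#' fit <- fitAssociation(t, 50 * (1 - exp(-0.285 * t)), koff = 0.075,
#'                       L = 0.3e-9)
#' kOn(fit)  # 7e8
#' @export
fitAssociation <- function(time, bound, koff, L) {
  if (is(koff, "KineticFit")) koff <- kOff(koff)
  if (!is.finite(koff) || koff <= 0) stop("koff must be supplied and > 0")
  if (!is.finite(L) || L <= 0) stop("L must be > 0")
  stopifnot(length(time) == length(bound))
  keep <- is.finite(time) & is.finite(bound)
  time <- time[keep]; bound <- bound[keep]
  if (length(unique(time)) < 4)
    stop("at least 4 timepoints are required")
  start <- list(beq = max(bound), kobs = max(koff * 2, 1 /
                                               max(median(time), 1e-9)))
  fit <- tryCatch(
    minpack.lm::nlsLM(bound ~ beq * (1 - exp(-kobs * time)),
                      data = data.frame(bound = bound, time = time),
                      start = start, lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new("KineticFit", kOff = koff, ligandConc = L, converged = FALSE,
               flags = paste0("fit_error: ", conditionMessage(fit))))
  p <- coef(fit)
  kobs <- unname(p["kobs"])
  kon <- (kobs - koff) / L
  flags <- character()
  if (kon < 0) flags <- "nonphysical_kon"
  new("KineticFit", kOff = koff, kObs = kobs, kOn = kon,
      beq = unname(p["beq"]), ligandConc = L,
      converged = isTRUE(fit$convInfo$isConv), flags = flags)
}

#' One-site competition binding fit with Cheng-Prusoff conversion
#'
#' Fits the decreasing three-parameter logistic to competition binding data
#' (response falling with competitor concentration), takes the inflection as
#' the IC50 and converts to Ki via [chengPrusoff()]. Increasing
#' (wrong-orientation) data are flagged.
#'
#' @param data data.frame with `concentration` (molar) and `response`.
#' @param L radioligand concentration, molar.
#' @param kd radioligand Kd, molar.
#' @param compound label.
#' @return an [AffinityEstimate-class].
#' @export
oneSiteCompetition <- function(data, L, kd, compound = NA_character_) {
  fit <- fitLogistic3(data, compound = compound, direction = "decreasing")
  if (!isConverged(fit)) {
    est <- new("AffinityEstimate", ic50 = NA_real_, ki = NA_real_,
               ligandConc = L, kd = kd, fit = fit)
    return(est)
  }
  # orientation check: fitted responses must fall with concentration
  lo <- predictLogistic(fit, min(data$concentration))
  hi <- predictLogistic(fit, max(data$concentration))
  if (hi > lo) fit@flags <- c(fit@flags, "orientation_increasing")
  ic <- ec50(fit)
  new("AffinityEstimate", ic50 = ic, ki = chengPrusoff(ic, L, kd),
      ligandConc = L, kd = kd, fit = fit)
}

#' Subtract ligand-free (background) wells from plate responses
#'
#' Documented pre-step for raw plate data: the mean of the ligand-free well
#' readings is subtracted from every ligand-treated reading, per compound
#' grouping column if present.
#'
#' @param plate long-format data.frame with columns `response` and `well`
#'   (values `"ligand"` / `"ligand_free"`), optionally grouped by `compound`.
#' @return the plate with background-subtracted responses and ligand-free
#'   rows removed.
#' @export
subtractLigandFree <- function(plate) {
  stopifnot(all(c("response", "well") %in% names(plate)))
  groups <- if ("compound" %in% names(plate)) plate$compound else
    rep("all", nrow(plate))
  out <- lapply(split(plate, groups), function(g) {
    bg <- mean(g$response[g$well == "ligand_free"])
    if (!is.finite(bg)) bg <- 0
    g <- g[g$well == "ligand", , drop = FALSE]
    g$response <- g$response - bg
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
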