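#' Net BRET responses from a raw-scale fit
#'
#' The net BRET ratio is the raw response minus the minimum response derived
#' from the fitted raw BRET curve (the fitted lower asymptote, not the data
#' minimum). Adding a constant to all raw values therefore leaves net BRET
#' unchanged.
#'
#' @param fit a converged raw-scale [LogisticFit-class].
#' @param raw raw BRET responses.
#' @return net responses (same length as `raw`).
#' @examples
#' f <- new("LogisticFit", bottom = 0.30, top = 0.45, ec50 = 1e-9,
#'          direction = "increasing", converged = TRUE)
#' netBret(f, 0.42)  # 0.12
#' @export
netBret <- function(fit, raw) {
  stopifnot(is(fit, "LogisticFit"))
  if (!isConverged(fit))
    stop("raw-scale fit did not converge; net BRET is undefined ",
         "(flags: ", paste(fit@flags, collapse = ", "), ")")
  raw - fit@bottom
}

#' Per-timepoint pharmacology of a kinetic BRET plate
#'
#' For every timepoint (and, when `perExperiment = TRUE`, every independent
#' experiment) a three-parameter dose-response regression is fitted on the
#' raw BRET scale, the net BRET span is taken from the fitted curve
#' (fitted maximum minus fitted minimum), and each compound's maximum net
#' BRET is normalized to the reference span at the same timepoint, reported
#' as %Emax. Timepoints where the reference curve is missing or does not
#' converge are skipped with a warning and reported as gaps, never
#' interpolated.
#'
#' @param plate long-format data.frame with columns `compound`,
#'   `concentration` (molar), `timepoint_min`, `replicate` (independent
#'   experiment id) and `response` (raw BRET ratio).
#' @param reference reference compound label (default `"DAMGO"`).
#' @param perExperiment fit each independent experiment separately (the
#'   default), enabling across-experiment dispersion downstream; `FALSE`
#'   pools replicates into one fit per compound x timepoint.
#' @return data.frame with columns `compound`, `timepoint_min`, `replicate`
#'   (`NA` when pooled), `emax_pct` (% of the reference span), `pec50`,
#'   `ec50_M`, `converged`.
#' @export
timecoursePharmacology <- function(plate, reference = "DAMGO",
                                   perExperiment = TRUE) {
  need <- c("compound", "concentration", "timepoint_min", "replicate",
            "response")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if (!reference %in% plate$compound)
    stop("reference compound '", reference, "' not found in plate")
  out <- list()
  for (tp in sort(unique(plate$timepoint_min))) {
    sub <- plate[plate$timepoint_min == tp, , drop = FALSE]
    expts <- if (perExperiment) sort(unique(sub$replicate)) else NA
    for (ex in expts) {
      se <- if (perExperiment) sub[sub$replicate == ex, , drop = FALSE]
            else sub
      refFit <- tryCatch(
        fitLogistic3(se[se$compound == reference, , drop = FALSE],
                     compound = reference),
        error = function(e) NULL)
      if (is.null(refFit) || !isConverged(refFit)) {
        warning("reference fit unavailable at timepoint ", tp,
                if (perExperiment) paste0(" (experiment ", ex, ")"),
                "; timepoint skipped", call. = FALSE)
        next
      }
      refSpan <- refFit@top - refFit@bottom
      for (cmp in sort(unique(se$compound))) {
        fit <- tryCatch(
          fitLogistic3(se[se$compound == cmp, , drop = FALSE],
                       compound = cmp),
          error = function(e) NULL)
        ok <- !is.null(fit) && isConverged(fit)
        # maximum net BRET of the fitted curve = fitted span
        span <- if (ok) fit@top - fit@bottom else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          compound = cmp, timepoint_min = tp,
          replicate = if (perExperiment) ex else NA,
          emax_pct = 100 * span / refSpan,
          pec50 = if (ok) pec50(fit) else NA_real_,
          ec50_M = if (ok) ec50(fit) else NA_real_,
          converged = ok)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize per-experiment pharmacology across experiments
#'
#' @param tp output of [timecoursePharmacology()] with `perExperiment = TRUE`.
#' @return data.frame per compound x timepoint with mean/sd of `emax_pct`
#'   and `pec50` and `n_experiments`.
#' @export
summarizeTimecourse <- function(tp) {
  key <- interaction(tp$compound, tp$timepoint_min, drop = TRUE)
  out <- lapply(split(tp, key), function(g) {
    g <- g[g$converged, , drop = FALSE]
    data.frame(compound = g$compound[1],
               timepoint_min = g$timepoint_min[1],
               emax_pct = mean(g$emax_pct), emax_sd = sd(g$emax_pct),
               pec50 = mean(g$pec50), pec50_sd = sd(g$pec50),
               n_experiments = nrow(g))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound, res$timepoint_min), ]
  rownames(res) <- NULL
  res
}

#' Transduction index
#'
#' The proxy transduction index `TI = log10(%Emax / EC50)` (distinct from
#' the operational-model transduction coefficient). EC50 is in molar; the
#' choice of concentration unit cancels in all DAMGO-referenced differences,
#' and the logarithm base is 10 (configurable).
#'
#' @param emaxPct efficacy as % of the reference maximal effect, > 0.
#' @param ec50 molar, > 0.
#' @param base logarithm base (default 10).
#' @return TI value(s).
#' @examples
#' transductionIndex(100, 1e-9)  # 11
#' @export
transductionIndex <- function(emaxPct, ec50, base = 10) {
  if (any(emaxPct <= 0, na.rm = TRUE)) stop("emaxPct must be > 0")
  if (any(ec50 <= 0, na.rm = TRUE)) stop("ec50 must be > 0")
  log(emaxPct / ec50, base = base)
}

#' DAMGO-referenced bias factor
#'
#' `deltaTI = TI_compound - TI_reference` per pathway, and
#' `bias = deltaTI(Go) - deltaTI(beta-arrestin 2)` at a given timepoint.
#' The reference compound's bias is identically zero, and swapping the
#' pathways negates the bias.
#'
#' @param tiCompoundGo,tiRefGo TI of compound and reference for the
#'   G-protein pathway.
#' @param tiCompoundBarr,tiRefBarr TI of compound and reference for the
#'   beta-arrestin 2 pathway.
#' @return list with `dTI_Go`, `dTI_barr2`, `bias`.
#' @examples
#' biasFactor(11.5, 11.0, 10.8, 10.6)$bias  # 0.3
#' @export
biasFactor <- function(tiCompoundGo, tiRefGo, tiCompoundBarr, tiRefBarr) {
  dGo <- tiCompoundGo - tiRefGo
  dBarr <- tiCompoundBarr - tiRefBarr
  list(dTI_Go = dGo, dTI_barr2 = dBarr, bias = dGo - dBarr)
}

#' Standard-error propagation for the bias calculus
#'
#' `sem = sd / sqrt(n)` per compound and pathway (sd is the
#' across-experiment s.d. of TI); per pathway
#' `SE_assay = sqrt(sem_compound^2 + sem_reference^2)`; and across pathways
#' `SE_final = sqrt(SE_Go^2 + SE_barr2^2)`. Root-sum-square composition is
#' monotone: `SE_final >= SE_assay >= sem` componentwise.
#'
#' @param sdCompoundGo,nCompoundGo,sdRefGo,nRefGo s.d. of TI across
#'   experiments and number of experiments, G-protein pathway.
#' @param sdCompoundBarr,nCompoundBarr,sdRefBarr,nRefBarr same for the
#'   beta-arrestin 2 pathway.
#' @return list with `sem` (named vector), `SE_Go`, `SE_barr2`, `SE_final`.
#' @examples
#' propagateSE(3, 1, 4, 1, 1, 2, 1, 2)
#' @export
propagateSE <- function(sdCompoundGo, nCompoundGo, sdRefGo, nRefGo,
                        sdCompoundBarr, nCompoundBarr, sdRefBarr, nRefBarr) {
  ns <- c(nCompoundGo, nRefGo, nCompoundBarr, nRefBarr)
  sds <- c(sdCompoundGo, sdRefGo, sdCompoundBarr, sdRefBarr)
  if (any(ns < 1)) stop("number of experiments must be >= 1")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  sem <- sds / sqrt(ns)
  names(sem) <- c("compound_Go", "ref_Go", "compound_barr2", "ref_barr2")
  seGo <- sqrt(sem["compound_Go"]^2 + sem["ref_Go"]^2)
  seBarr <- sqrt(sem["compound_barr2"]^2 + sem["ref_barr2"]^2)
  list(sem = sem, SE_Go = unname(seGo), SE_barr2 = unname(seBarr),
       SE_final = unname(sqrt(seGo^2 + seBarr^2)))
}

#' Efficacy decline between the initial response and the plateau
#'
#' @param eInitialPct,ePlateauPct efficacies on the % reference scale.
#' @return decline in percentage points (negative = rise).
#' @examples
#' efficacyDecline(123.2, 98.4)  # 24.8
#' @export
efficacyDecline <- function(eInitialPct, ePlateauPct) {
  eInitialPct - ePlateauPct
}

#' Full bias table for a two-pathway kinetic BRET dataset
#'
#' Computes, per compound and timepoint, the transduction indices for both
#' pathways (per independent experiment, then averaged), the
#' DAMGO-referenced delta-TI values, the bias factor and the propagated
#' standard errors. Unconverged compound/timepoint cells are reported as
#' gaps (`NA`), never interpolated.
#'
#' @param plateGo,plateBarr kinetic plates (see [timecoursePharmacology()])
#'   for the G-protein and beta-arrestin 2 pathways.
#' @param reference reference compound (default `"DAMGO"`).
#' @return data.frame (a bias table) with columns `compound`,
#'   `timepoint_min`, `TI_Go`, `TI_barr2`, `dTI_Go`, `dTI_barr2`, `bias`,
#'   `sem_TI_Go`, `sem_TI_barr2`, `SE_Go`, `SE_barr2`, `SE_final`, `n_Go`,
#'   `n_barr2`.
#' @export
biasTable <- function(plateGo, plateBarr, reference = "DAMGO") {
  tiOf <- function(plate) {
    tp <- timecoursePharmacology(plate, reference = reference,
                                 perExperiment = TRUE)
    tp <- tp[tp$converged & tp$emax_pct > 0, , drop = FALSE]
    tp$TI <- transductionIndex(tp$emax_pct, tp$ec50_M)
    key <- interaction(tp$compound, tp$timepoint_min, drop = TRUE)
    res <- lapply(split(tp, key), function(g) data.frame(
      compound = g$compound[1], timepoint_min = g$timepoint_min[1],
      TI = mean(g$TI), sd = sd(g$TI), n = nrow(g)))
    do.call(rbind, res)
  }
  go <- tiOf(plateGo)
  ba <- tiOf(plateBarr)
  m <- merge(go, ba, by = c("compound", "timepoint_min"),
             suffixes = c("_Go", "_barr2"))
  ref <- m[m$compound == reference,
           c("timepoint_min", "TI_Go", "TI_barr2", "sd_Go", "sd_barr2",
             "n_Go", "n_barr2")]
  names(ref)[-1] <- paste0("ref_", names(ref)[-1])
  m <- merge(m, ref, by = "timepoint_min")
  m$dTI_Go <- m$TI_Go - m$ref_TI_Go
  m$dTI_barr2 <- m$TI_barr2 - m$ref_TI_barr2
  m$bias <- m$dTI_Go - m$dTI_barr2
  m$sem_TI_Go <- m$sd_Go / sqrt(m$n_Go)
  m$sem_TI_barr2 <- m$sd_barr2 / sqrt(m$n_barr2)
  m$SE_Go <- sqrt(m$sem_TI_Go^2 + (m$ref_sd_Go / sqrt(m$ref_n_Go))^2)
  m$SE_barr2 <- sqrt(m$sem_TI_barr2^2 +
                     (m$ref_sd_barr2 / sqrt(m$ref_n_barr2))^2)
  m$SE_final <- sqrt(m$SE_Go^2 + m$SE_barr2^2)
  cols <- c("compound", "timepoint_min", "TI_Go", "TI_barr2", "dTI_Go",
            "dTI_barr2", "bias", "sem_TI_Go", "sem_TI_barr2", "SE_Go",
            "SE_barr2", "SE_final", "n_Go", "n_barr2")
  res <- m[order(m$compound, m$timepoint_min), cols]
  rownames(res) <- NULL
  res
}
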