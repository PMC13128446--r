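#' Construct an ApexExperiment
#'
#' @param log2intensity numeric matrix, proteins x samples, `NA` = missing.
#' @param sampleSheet data.frame with one row per sample and the columns
#'   documented in [ApexExperiment-class].
#' @return an [ApexExperiment-class].
#' @export
ApexExperiment <- function(log2intensity, sampleSheet) {
  if (is.null(rownames(log2intensity)))
    rownames(log2intensity) <- paste0("P", seq_len(nrow(log2intensity)))
  if (!"compartment" %in% names(sampleSheet))
    sampleSheet$compartment <- NA_character_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = log2intensity),
    colData = S4Vectors::DataFrame(sampleSheet,
                                   row.names = colnames(log2intensity)))
  new("ApexExperiment", se)
}

#' Score a protein's time course after ligand treatment
#'
#' Fits each protein's log2 intensities over the treatment time course with
#' a continuous cubic polynomial in the time rank (ranks 1..5 encode 0, 1,
#' 5, 10, 30 min; rank encoding resolves the rapid early changes) plus an
#' additive batch term, and compares it with a batch-only null model by an
#' F test. The maximum log2 fold change is the signed mean change of largest
#' magnitude between rank 1 and any single later rank, computed after
#' imputing missing cells from the fitted model.
#'
#' The polynomial basis is orthogonalized over the observed rank grid
#' (`stats::poly`); fitted values are basis-independent. With fewer distinct
#' ranks than 4 the degree is reduced to ranks - 1.
#'
#' @param apex an [ApexExperiment-class].
#' @param ligand which ligand's MOR-APEX samples to score.
#' @param proteins optional subset of protein ids.
#' @return data.frame with columns `protein`, `F`, `p`, `max_log2fc`,
#'   `df1`, `df2`, `flag` (`""`, `"all_missing"`, `"insufficient_df"`).
#' @seealso [callInteractors()]
#' @export
scoreTimecourse <- function(apex, ligand, proteins = NULL) {
  stopifnot(is(apex, "ApexExperiment"))
  cd <- SummarizedExperiment::colData(apex)
  sel <- cd$role == "mor_apex" & cd$ligand == ligand
  if (!any(sel)) stop("no MOR-APEX samples for ligand '", ligand, "'")
  mat <- SummarizedExperiment::assay(apex, "log2intensity")[, sel,
                                                            drop = FALSE]
  rank <- as.numeric(cd$time_rank[sel])
  batch <- factor(cd$batch[sel])
  if (length(unique(rank)) < 2)
    stop("at least 2 distinct time ranks are required")
  ids <- if (is.null(proteins)) rownames(mat) else proteins
  res <- lapply(ids, function(p) {
    y <- mat[p, ]
    obs <- is.finite(y)
    flag <- ""
    if (sum(obs) == 0 || length(unique(rank[obs])) < 2) {
      return(data.frame(protein = p, F = NA_real_, p = NA_real_,
                        max_log2fc = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, flag = "all_missing"))
    }
    d <- data.frame(y = y[obs], rank = rank[obs],
                    batch = droplevels(batch[obs]))
    if (sd(d$y) < 1e-12) {
      # a perfectly constant series carries no time information; both
      # models fit exactly and the F ratio would be rounding noise
      return(data.frame(protein = p, F = 0, p = 1, max_log2fc = 0,
                        df1 = NA_real_, df2 = NA_real_,
                        flag = "constant"))
    }
    deg <- min(3, length(unique(d$rank)) - 1)
    full <- if (nlevels(d$batch) > 1)
      lm(y ~ poly(rank, deg) + batch, data = d)
    else lm(y ~ poly(rank, deg), data = d)
    null <- if (nlevels(d$batch) > 1) lm(y ~ batch, data = d)
            else lm(y ~ 1, data = d)
    if (full$df.residual <= 0) {
      return(data.frame(protein = p, F = NA_real_, p = NA_real_,
                        max_log2fc = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, flag = "insufficient_df"))
    }
    a <- anova(null, full)
    Fstat <- a$F[2]
    pval <- a$`Pr(>F)`[2]
    # impute missing cells from the fitted model at (rank, batch), then take
    # per-rank observed-or-imputed means
    yImp <- y
    if (any(!obs)) {
      newd <- data.frame(rank = rank[!obs], batch = batch[!obs])
      # predictions for batches unseen by the fit fall back to fitted means
      yImp[!obs] <- tryCatch(predict(full, newdata = newd),
                             error = function(e) mean(d$y))
    }
    rankMeans <- tapply(yImp, rank, mean)
    r1 <- rankMeans[as.character(min(rank))]
    later <- rankMeans[names(rankMeans) != as.character(min(rank))]
    deltas <- later - r1
    maxfc <- if (length(deltas)) deltas[which.max(abs(deltas))] else 0
    data.frame(protein = p, F = Fstat, p = pval,
               max_log2fc = unname(maxfc), df1 = a$Df[2],
               df2 = a$Res.Df[2], flag = flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call significant MOR-proximal interactors
#'
#' Proteins with a maximum log2 fold change above `log2(1.5)` over the time
#' series and an F-test P value at or below 0.05. Thresholds are applied
#' raw; no multiple-testing correction is performed anywhere in this
#' pipeline (the analysis uses raw thresholds by design) -- interpret
#' accordingly.
#'
#' @param scores output of [scoreTimecourse()].
#' @param fcThreshold log2 fold-change threshold (default `log2(1.5)`);
#'   applied to `abs(max_log2fc)`.
#' @param pThreshold P-value threshold (default 0.05, inclusive).
#' @return character vector of protein ids.
#' @export
callInteractors <- function(scores, fcThreshold = log2(1.5),
                            pThreshold = 0.05) {
  ok <- !is.na(scores$p) & !is.na(scores$max_log2fc) &
    abs(scores$max_log2fc) > fcThreshold & scores$p <= pThreshold
  scores$protein[ok]
}

#' Select location-specific marker proteins from the spatial references
#'
#' For each non-redundant pair of compartments a pairwise mean-difference
#' log2FC and a two-sample t statistic are computed, with the variance
#' pooled across all spatial references (residual variance of a one-way
#' compartment model over every reference sample). A protein enters the
#' panel if (i) for some pair `p < 0.005` and `|log2FC| > 1.0`, and (ii) its
#' observed intensity exceeds the 50th percentile of all observed protein
#' intensities (over reference and MOR-APEX samples jointly) in every
#' replicate of at least one reference.
#'
#' @param apex an [ApexExperiment-class] containing the spatial-reference
#'   samples (MOR-APEX samples, if present, contribute only to the global
#'   intensity percentile).
#' @param pThreshold pairwise P-value threshold (default 0.005, strict).
#' @param fcThreshold pairwise log2FC threshold (default 1.0, strict).
#' @return data.frame with columns `protein` and `compartment` (the winning
#'   compartment, i.e. the highest-mean compartment among the passing
#'   pairs), ordered by protein id.
#' @export
selectMarkers <- function(apex, pThreshold = 0.005, fcThreshold = 1.0) {
  stopifnot(is(apex, "ApexExperiment"))
  cd <- SummarizedExperiment::colData(apex)
  mat <- SummarizedExperiment::assay(apex, "log2intensity")
  isref <- cd$role == "spatial_reference"
  if (sum(isref) == 0) stop("no spatial_reference samples")
  refMat <- mat[, isref, drop = FALSE]
  comp <- factor(cd$compartment[isref])
  if (nlevels(comp) < 2) stop("at least 2 compartments are required")
  ncomp <- table(comp)
  if (any(ncomp < 2))
    stop("every compartment needs >= 2 replicates for a variance estimate")
  # global 50th percentile over all observed intensities
  med <- median(mat[is.finite(mat)])
  pairs <- utils::combn(levels(comp), 2, simplify = FALSE)
  out <- lapply(rownames(refMat), function(p) {
    y <- refMat[p, ]
    obs <- is.finite(y)
    if (!all(obs)) {
      # pooled-variance t test requires complete reference replicates here;
      # proteins not quantified across all references cannot be markers
      return(NULL)
    }
    means <- tapply(y, comp, mean)
    # pooled residual variance across all references (equal-variance model)
    ss <- sum(tapply(y, comp, function(v) sum((v - mean(v))^2)))
    dfres <- length(y) - nlevels(comp)
    s2 <- ss / dfres
    passComp <- character()
    for (pr in pairs) {
      fc <- means[pr[1]] - means[pr[2]]
      seDiff <- sqrt(s2 * (1 / ncomp[pr[1]] + 1 / ncomp[pr[2]]))
      tstat <- fc / seDiff
      pval <- 2 * pt(-abs(tstat), df = dfres)
      if (is.finite(pval) && pval < pThreshold && abs(fc) > fcThreshold) {
        passComp <- c(passComp, if (fc > 0) pr[1] else pr[2])
      }
    }
    if (!length(passComp)) return(NULL)
    # intensity filter: above the global median in all replicates of at
    # least one reference
    highIn <- tapply(y, comp, function(v) all(v > med))
    if (!any(highIn)) return(NULL)
    win <- names(which.max(means[unique(passComp)]))
    data.frame(protein = p, compartment = win)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(protein = character(), compartment = character()))
  res <- res[order(res$protein), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scale intensities linearly to [0, 1] per protein
#'
#' On the linear intensity scale, each protein's maximum observed intensity
#' across all spatial-reference and MOR-APEX samples is set to 1.0 and every
#' other observation to observed/maximum; missing values are set to zero.
#' Scaling is idempotent. Proteins whose row maximum is zero are dropped
#' with a record (attribute `"dropped"`).
#'
#' @param apex an [ApexExperiment-class] (log2 assay) or a linear-scale
#'   numeric matrix.
#' @return numeric matrix in `[0, 1]`, proteins x samples, with attribute
#'   `"dropped"` listing removed rows.
#' @export
scaleIntensities <- function(apex) {
  lin <- if (is(apex, "ApexExperiment"))
    2^SummarizedExperiment::assay(apex, "log2intensity")
  else as.matrix(apex)
  lin[!is.finite(lin)] <- NA
  rowmax <- apply(lin, 1, function(v)
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  dropped <- rownames(lin)[rowmax <= 0]
  keep <- rowmax > 0
  scaled <- lin[keep, , drop = FALSE] / rowmax[keep]
  scaled[is.na(scaled)] <- 0
  attr(scaled, "dropped") <- dropped
  scaled
}

#' Build the spatial-reference system (F and S matrices)
#'
#' `F` has one column per compartment holding the mean (per spatial
#' reference) scaled intensity over all observed proteins; the
#' location-specific subset matrix `S` is the rows of `F` restricted to the
#' marker panel. Column order follows the declared compartment order.
#'
#' @param scaled scaled intensity matrix from [scaleIntensities()].
#' @param sampleSheet data.frame describing the columns of `scaled` (needs
#'   `role` and `compartment`).
#' @param panel marker panel from [selectMarkers()] (or a character vector
#'   of protein ids).
#' @param compartments compartment column order (default the four canonical
#'   compartments present in the data).
#' @return list with matrices `F` (all proteins x compartments) and `S`
#'   (panel proteins x compartments).
#' @export
buildReferenceSystem <- function(scaled, sampleSheet, panel,
                                 compartments = NULL) {
  stopifnot(ncol(scaled) == nrow(sampleSheet))
  ids <- if (is.data.frame(panel)) panel$protein else as.character(panel)
  if (!length(ids)) stop("marker panel is empty")
  missing <- setdiff(ids, rownames(scaled))
  if (length(missing))
    stop("panel protein(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  isref <- sampleSheet$role == "spatial_reference"
  if (is.null(compartments))
    compartments <- intersect(apexCompartments(),
                              unique(sampleSheet$compartment[isref]))
  Fmat <- sapply(compartments, function(k) {
    cols <- which(isref & sampleSheet$compartment == k)
    rowMeans(scaled[, cols, drop = FALSE])
  })
  rownames(Fmat) <- rownames(scaled)
  list(F = Fmat, S = Fmat[ids, , drop = FALSE])
}

#' Deconvolve one MOR-APEX sample into compartment coefficients
#'
#' Per randomization repeat, the location-specific matrix `S` is appended
#' with `nDummy` additional columns whose entries are sampled i.i.d. with
#' replacement from the entries of `S` (damping spurious low-but-nonzero
#' coefficients), the nonnegative least-squares problem
#' `min || [S, D] b - y ||` s.t. `b >= 0` is solved (Lawson-Hanson), and the
#' coefficients of the true compartments are kept. The reported value is
#' the per-compartment median over all repeats; the seed is recorded.
#'
#' @param y scaled intensity vector of the sample over the panel proteins
#'   (aligned to the rows of `S`).
#' @param S panel-restricted reference matrix from
#'   [buildReferenceSystem()].
#' @param nRepeats number of randomization repeats (default 1000).
#' @param nDummy number of dummy columns per repeat (default 3).
#' @param seed integer seed for the dummy-column stream.
#' @return a [SpatialCoefficients-class].
#' @export
deconvolveSample <- function(y, S, nRepeats = 1000L, nDummy = 3L,
                             seed = 1L) {
  if (length(y) != nrow(S))
    stop("sample vector must align with the rows of S (",
         length(y), " vs ", nrow(S), ")")
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  pool <- as.numeric(S)
  ncomp <- ncol(S)
  draws <- matrix(NA_real_, ncomp, nRepeats)
  localSeed(seed, {
    for (r in seq_len(nRepeats)) {
      D <- matrix(sample(pool, nrow(S) * nDummy, replace = TRUE),
                  nrow(S), nDummy)
      beta <- pracma::lsqnonneg(cbind(S, D), y)$x
      draws[, r] <- beta[seq_len(ncomp)]
    }
  })
  med <- apply(draws, 1, median)
  names(med) <- colnames(S)
  new("SpatialCoefficients", coefficients = med,
      nRepeats = as.integer(nRepeats), nDummy = as.integer(nDummy),
      seed = as.integer(seed))
}

#' Receptor trafficking profile across all MOR-APEX samples
#'
#' Runs [deconvolveSample()] for every MOR-APEX sample and groups the
#' coefficients by ligand and time rank (replicate mean and s.d.), yielding
#' per-ligand location-coefficient trajectories that model receptor
#' trafficking over the activation time course.
#'
#' @param apex an [ApexExperiment-class].
#' @param panel marker panel from [selectMarkers()].
#' @param nRepeats,nDummy,seed passed to [deconvolveSample()] (each sample
#'   gets its own derived seed stream).
#' @return list with `samples` (per-sample coefficients, long format) and
#'   `profile` (ligand x time_rank x compartment means and s.d.).
#' @export
traffickingProfile <- function(apex, panel, nRepeats = 1000L, nDummy = 3L,
                               seed = 1L) {
  stopifnot(is(apex, "ApexExperiment"))
  cd <- SummarizedExperiment::colData(apex)
  scaled <- scaleIntensities(apex)
  sys <- buildReferenceSystem(scaled, as.data.frame(cd), panel)
  morIdx <- which(cd$role == "mor_apex")
  ids <- if (is.data.frame(panel)) panel$protein else as.character(panel)
  rows <- lapply(seq_along(morIdx), function(i) {
    j <- morIdx[i]
    y <- scaled[ids, j]
    sc <- deconvolveSample(y, sys$S, nRepeats = nRepeats, nDummy = nDummy,
                           seed = as.integer(seed) + i)
    data.frame(sample = colnames(scaled)[j], ligand = cd$ligand[j],
               time_rank = cd$time_rank[j], time_min = cd$time_min[j],
               replicate = cd$replicate[j],
               compartment = names(spatialCoef(sc)),
               coefficient = unname(spatialCoef(sc)))
  })
  samples <- do.call(rbind, rows)
  key <- interaction(samples$ligand, samples$time_rank,
                     samples$compartment, drop = TRUE)
  prof <- do.call(rbind, lapply(split(samples, key), function(g)
    data.frame(ligand = g$ligand[1], time_rank = g$time_rank[1],
               time_min = g$time_min[1], compartment = g$compartment[1],
               mean = mean(g$coefficient), sd = sd(g$coefficient),
               n = nrow(g))))
  prof <- prof[order(prof$ligand, prof$time_rank, prof$compartment), ]
  rownames(prof) <- NULL
  rownames(samples) <- NULL
  list(samples = samples, profile = prof)
}
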