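# Shared helpers and independent oracles used across the suite.

# Match detected event times to ground-truth times (one-to-one, within
# `tol` seconds); returns the number of true positives.
matchEvents <- function(detected, truth, tol = 4) {
  tp <- 0L
  used <- rep(FALSE, length(truth))
  for (pt in detected) {
    d <- abs(truth - pt)
    i <- which.min(d)
    if (length(i) && d[i] <= tol && !used[i]) {
      tp <- tp + 1L
      used[i] <- TRUE
    }
  }
  tp
}

# Independent nested-model F-test oracle: explicit design matrices (raw
# polynomial columns + batch dummy columns), least squares via qr.solve,
# residual sums of squares, and the classical F ratio. Stays independent of
# the lm/poly/anova path used by the implementation.
oracleTimecourseF <- function(y, rank, batch, degree = 3) {
  obs <- is.finite(y)
  y <- y[obs]; rank <- rank[obs]; batch <- factor(batch[obs])
  Xnull <- model.matrix(~batch)
  Xfull <- cbind(Xnull, outer(rank, seq_len(degree), `^`))
  rss <- function(X) {
    beta <- qr.solve(X, y)
    sum((y - X %*% beta)^2)
  }
  rss0 <- rss(Xnull)
  rss1 <- rss(Xfull)
  df1 <- ncol(Xfull) - ncol(Xnull)
  df2 <- length(y) - ncol(Xfull)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       rss0 = rss0, rss1 = rss1, df1 = df1, df2 = df2)
}

# Build a small ApexExperiment directly from a matrix and minimal
# annotations (bypasses the generator; used for constructed toys).
toyApex <- function(mat, role, compartment = NA, ligand = "none",
                    time_rank = NA, time_min = NA, replicate = 1,
                    batch = "b1") {
  n <- ncol(mat)
  ApexExperiment(mat, data.frame(
    role = rep(role, length.out = n),
    ligand = rep(ligand, length.out = n),
    time_min = rep(time_min, length.out = n),
    time_rank = rep(time_rank, length.out = n),
    replicate = rep(replicate, length.out = n),
    batch = rep(batch, length.out = n),
    compartment = rep(compartment, length.out = n)))
}
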