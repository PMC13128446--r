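test_that("time-course F statistic matches an explicit nested-model oracle", {
  # 20-point toy: 5 ranks x 2 replicates x 2 batches
  set.seed(7)
  rank <- rep(1:5, each = 4)
  batch <- rep(c("b1", "b2"), 10)
  y <- 0.4 * rank - 0.05 * rank^3 + ifelse(batch == "b2", 0.8, 0) +
    rnorm(20, 0, 0.3)
  mat <- matrix(y, nrow = 1, dimnames = list("P1", paste0("s", 1:20)))
  apex <- toyApex(mat, role = "mor_apex", ligand = "DFNZ",
                  time_rank = rank, time_min = c(0, 1, 5, 10, 30)[rank],
                  replicate = rep(1:4, 5), batch = batch)
  got <- scoreTimecourse(apex, "DFNZ")
  want <- oracleTimecourseF(y, rank, batch)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
})

test_that("constant and noiseless-trend series score as expected", {
  rank <- rep(1:5, each = 3)
  flat <- matrix(rep(5, 15), nrow = 1, dimnames = list("P1", NULL))
  apex <- toyApex(flat, role = "mor_apex", ligand = "DAMGO",
                  time_rank = rank, time_min = c(0, 1, 5, 10, 30)[rank],
                  replicate = rep(1:3, 5), batch = "b1")
  s <- scoreTimecourse(apex, "DAMGO")
  expect_equal(s$max_log2fc, 0)
  expect_true(is.na(s$F) || s$F < 1e-10)  # zero residual and zero effect
  # noiseless rise of 2 log2 units by rank 5, one batch
  y <- 10 + 0.5 * (rank - 1)
  rise <- matrix(y, nrow = 1, dimnames = list("P1", NULL))
  apex2 <- toyApex(rise, role = "mor_apex", ligand = "DAMGO",
                   time_rank = rank, time_min = c(0, 1, 5, 10, 30)[rank],
                   replicate = rep(1:3, 5), batch = "b1")
  s2 <- scoreTimecourse(apex2, "DAMGO")
  expect_equal(s2$max_log2fc, 2.0, tolerance = 1e-8)
  expect_gt(s2$F, 1e10)  # bounded only by machine precision
})

test_that("missing cells are imputed from the fitted model for max log2FC", {
  rank <- rep(1:5, each = 3)
  y <- 10 + 0.5 * (rank - 1)
  y[rank == 5][1] <- NA  # one missing cell at the top rank
  mat <- matrix(y, nrow = 1, dimnames = list("P1", NULL))
  apex <- toyApex(mat, role = "mor_apex", ligand = "DAMGO",
                  time_rank = rank, time_min = c(0, 1, 5, 10, 30)[rank],
                  replicate = rep(1:3, 5), batch = "b1")
  s <- scoreTimecourse(apex, "DAMGO")
  # imputation from a perfect cubic fit restores the noiseless value
  expect_equal(s$max_log2fc, 2.0, tolerance = 1e-6)
  # an all-missing protein is skipped with a record, not dropped silently
  mat2 <- rbind(P1 = y, P2 = NA_real_)
  apex2 <- toyApex(mat2, role = "mor_apex", ligand = "DAMGO",
                   time_rank = rank, time_min = c(0, 1, 5, 10, 30)[rank],
                   replicate = rep(1:3, 5), batch = "b1")
  s2 <- scoreTimecourse(apex2, "DAMGO")
  expect_equal(s2$flag[s2$protein == "P2"], "all_missing")
})

test_that("interactor calling applies both thresholds", {
  scores <- data.frame(
    protein = paste0("P", 1:4),
    F = c(10, 10, 10, 10),
    p = c(0.001, 0.04, 0.2, 0.04),
    max_log2fc = c(log2(1.4), 1.0, 2.0, -1.0))
  got <- callInteractors(scores)
  # P1 fails the FC filter despite p = 0.001; P3 fails the p filter;
  # P4 passes on magnitude (signed change of largest magnitude)
  expect_setequal(got, c("P2", "P4"))
  # constructed set of 10 with exactly 3 passing
  sc10 <- data.frame(protein = paste0("Q", 1:10),
                     F = 5,
                     p = c(rep(0.01, 5), rep(0.5, 5)),
                     max_log2fc = c(rep(1, 3), rep(0.2, 2), rep(1, 5)))
  expect_length(callInteractors(sc10), 3)
})

test_that("marker selection applies pairwise t, fold-change and intensity filters", {
  # 4 compartments x 3 replicates; constructed so exactly 2 proteins pass
  comps <- c("plasma_membrane", "early_endosome",
             "late_endosome_lysosome", "cytoplasm")
  nrep <- 3
  mkRow <- function(means, sd = 0.05, seed) {
    set.seed(seed)
    as.numeric(vapply(means, function(m) m + rnorm(nrep, 0, sd),
                      numeric(nrep)))
  }
  mat <- rbind(
    A = mkRow(c(24, 20, 20, 20), seed = 1),   # strong PM marker, high
    B = mkRow(c(20, 24, 20, 20), seed = 2),   # strong EE marker, high
    C = mkRow(c(20.3, 20, 20, 20), seed = 3), # FC too small
    D = mkRow(c(12, 8, 8, 8), seed = 4),      # elevated but dim (below med)
    E = mkRow(c(20, 20, 20, 20), seed = 5),   # no difference
    G = mkRow(c(21, 20.5, 20.2, 20.6), seed = 6))  # modest, fails t/FC
  colnames(mat) <- paste0("r", seq_len(ncol(mat)))
  apex <- toyApex(mat, role = "spatial_reference",
                  compartment = rep(comps, each = nrep),
                  replicate = rep(1:nrep, 4))
  panel <- selectMarkers(apex)
  expect_setequal(panel$protein, c("A", "B"))
  expect_equal(panel$compartment[panel$protein == "A"],
               "plasma_membrane")
  expect_equal(panel$compartment[panel$protein == "B"], "early_endosome")
  # all-identical compartments give an empty panel
  same <- matrix(20, nrow = 3, ncol = 12,
                 dimnames = list(paste0("P", 1:3), paste0("r", 1:12)))
  same <- same + matrix(rnorm(36, 0, 0.01), 3)
  apexSame <- toyApex(same, role = "spatial_reference",
                      compartment = rep(comps, each = 3),
                      replicate = rep(1:3, 4))
  expect_equal(nrow(selectMarkers(apexSame)), 0)
  # a compartment with a single replicate is refused
  apexBad <- toyApex(mat[, -(1:2)], role = "spatial_reference",
                     compartment = rep(comps, each = nrep)[-(1:2)],
                     replicate = rep(1:nrep, 4)[-(1:2)])
  expect_error(selectMarkers(apexBad), "replicates")
})

test_that("intensity scaling follows the observed/rowmax rule with missing as zero", {
  lin <- rbind(P1 = c(100, 200, NA), P2 = c(5, 5, 5))
  scaled <- scaleIntensities(lin)
  expect_equal(unname(scaled["P1", ]), c(0.5, 1.0, 0.0))
  expect_equal(unname(scaled["P2", ]), c(1, 1, 1))  # all-equal row
  expect_true(all(scaled >= 0 & scaled <= 1))
  # idempotent
  expect_equal(unname(scaleIntensities(scaled)), unname(scaled))
  # zero rows dropped with a record
  z <- rbind(P1 = c(1, 2), P2 = c(0, 0))
  s2 <- scaleIntensities(z)
  expect_equal(rownames(s2), "P1")
  expect_equal(attr(s2, "dropped"), "P2")
})

test_that("reference system means replicates and restricts rows to the panel", {
  scaled <- rbind(P1 = c(0.2, 0.4, 0.6, 1, 1, 1),
                  P2 = c(1, 1, 1, 0.1, 0.2, 0.3))
  sheet <- data.frame(
    role = "spatial_reference",
    compartment = rep(c("plasma_membrane", "early_endosome"), each = 3))
  sys <- buildReferenceSystem(scaled, sheet, panel = "P1",
                              compartments = c("plasma_membrane",
                                               "early_endosome"))
  expect_equal(unname(sys$F["P1", "plasma_membrane"]), 0.4)
  expect_equal(unname(sys$F["P2", "early_endosome"]), 0.2)
  expect_equal(rownames(sys$S), "P1")
  expect_equal(colnames(sys$S), c("plasma_membrane", "early_endosome"))
  expect_error(buildReferenceSystem(scaled, sheet, panel = "P9"),
               "absent")
  expect_error(buildReferenceSystem(scaled, sheet, panel = character()),
               "empty")
})

test_that("deconvolution recovers pure and mixed samples and is seed-deterministic", {
  set.seed(10)
  S <- matrix(runif(40 * 4), 40, 4,
              dimnames = list(NULL, c("plasma_membrane", "early_endosome",
                                      "late_endosome_lysosome",
                                      "cytoplasm")))
  # a sample equal to the PM column recovers the 0/1 indicator exactly
  pure <- deconvolveSample(S[, 1], S, nRepeats = 200, seed = 3)
  expect_equal(unname(spatialCoef(pure)), c(1, 0, 0, 0),
               tolerance = 1e-8)
  mix <- deconvolveSample(0.6 * S[, 1] + 0.4 * S[, 2], S,
                          nRepeats = 200, seed = 3)
  expect_equal(unname(spatialCoef(mix)), c(0.6, 0.4, 0, 0),
               tolerance = 1e-6)
  expect_true(all(spatialCoef(mix) >= 0))
  # same seed twice gives identical medians
  again <- deconvolveSample(0.6 * S[, 1] + 0.4 * S[, 2], S,
                            nRepeats = 200, seed = 3)
  expect_identical(spatialCoef(mix), spatialCoef(again))
  expect_error(deconvolveSample(S[1:10, 1], S, nRepeats = 10), "align")
  expect_error(deconvolveSample(S[, 1], S, nRepeats = 0), "nRepeats")
})

test_that("trafficking profile recovers a PM-to-endosome shift monotonically", {
  sim <- simulateApex(6, nProteins = 100, nMarkersPerCompartment = 12,
                      ligands = "DAMGO", batchOffsets = c(0, 0),
                      noiseSd = 0.1, missingRate = 0)
  panel <- selectMarkers(sim$apex)
  expect_gt(nrow(panel), 20)
  tp <- traffickingProfile(sim$apex, panel, nRepeats = 50, seed = 2)
  pm <- tp$profile[tp$profile$compartment == "plasma_membrane", ]
  pm <- pm[order(pm$time_rank), ]
  ee <- tp$profile[tp$profile$compartment == "early_endosome", ]
  ee <- ee[order(ee$time_rank), ]
  # ground-truth weights fall (PM) and rise (EE) across ranks
  expect_true(all(diff(pm$mean) < 0.05))
  expect_lt(pm$mean[5], pm$mean[1])
  expect_gt(ee$mean[5], ee$mean[1])
  # a pure-PM simulation yields a flat PM ~ 1 profile
  pure <- rbind(plasma_membrane = rep(1, 5), early_endosome = rep(0, 5),
                late_endosome_lysosome = rep(0, 5),
                cytoplasm = rep(0, 5))
  simP <- simulateApex(7, nProteins = 100, nMarkersPerCompartment = 12,
                       ligands = "DAMGO", trajectory = pure,
                       batchOffsets = c(0, 0), noiseSd = 0.05,
                       missingRate = 0)
  panelP <- selectMarkers(simP$apex)
  tpP <- traffickingProfile(simP$apex, panelP, nRepeats = 50, seed = 2)
  pmP <- tpP$profile[tpP$profile$compartment == "plasma_membrane", ]
  expect_true(all(abs(pmP$mean - 1) < 0.1))
})

test_that("ApexExperiment validity enforces the sample-sheet contract", {
  mat <- matrix(rnorm(20), 4, 5,
                dimnames = list(paste0("P", 1:4), paste0("s", 1:5)))
  sheet <- data.frame(role = "mor_apex", ligand = "DAMGO",
                      time_min = c(0, 1, 5, 10, 30), time_rank = 1:5,
                      replicate = 1, batch = "b1",
                      compartment = NA_character_)
  expect_s4_class(ApexExperiment(mat, sheet), "ApexExperiment")
  badRank <- sheet; badRank$time_rank <- c(2, 1, 3, 4, 5)
  expect_error(ApexExperiment(mat, badRank), "rank")
  badRole <- sheet; badRole$role <- "mystery"
  expect_error(ApexExperiment(mat, badRole), "role")
})
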