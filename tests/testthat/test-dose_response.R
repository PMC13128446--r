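test_that("three-parameter logistic recovers generator truth on noiseless data", {
  x <- 10^seq(-11, -7.5, by = 0.5)  # 8 half-log concentrations
  y <- 0 + (100 - 0) / (1 + 1e-9 / x)
  fit <- fitLogistic3(data.frame(concentration = x, response = y))
  expect_true(isConverged(fit))
  expect_equal(bottom(fit), 0, tolerance = 1e-3)
  expect_equal(emax(fit), 100, tolerance = 1e-3)
  expect_equal(ec50(fit), 1e-9, tolerance = 1e-3)  # within 0.1%
  # midpoint identity: fitted response at x = ec50 is (top + bottom)/2
  expect_equal(predictLogistic(fit, ec50(fit)),
               (emax(fit) + bottom(fit)) / 2)
})

test_that("degenerate and invalid concentration-response inputs are refused or flagged", {
  x <- 10^seq(-10, -8, length.out = 6)
  expect_error(fitLogistic3(data.frame(concentration = c(1e-9, 2e-9, 3e-9),
                                       response = c(1, 2, 3))),
               "4 distinct concentrations")
  expect_error(fitLogistic3(data.frame(concentration = c(-1e-9, x[-1]),
                                       response = rep(1, 6))),
               "positive")
  flat <- fitLogistic3(data.frame(concentration = x,
                                  response = rep(5, 6)))
  expect_false(isConverged(flat))
  expect_true("nonidentifiable" %in% flat@flags)
  expect_true(is.na(ec50(flat)))
})

test_that("DAMGO normalization maps the reference span to [0, 100] and is affine", {
  ref <- new("LogisticFit", compound = "DAMGO", bottom = 0.1, top = 0.6,
             ec50 = 1e-9, direction = "increasing", converged = TRUE)
  expect_equal(normalizeToDamgo(0.6, ref), 100)
  expect_equal(normalizeToDamgo(0.1, ref), 0)
  expect_equal(normalizeToDamgo(0.7, ref), 120)  # supramaximal efficacy
  # affine: preserves ordering and ratios of spans
  y <- c(0.15, 0.3, 0.55)
  ny <- normalizeToDamgo(y, ref)
  expect_equal(order(ny), order(y))
  expect_equal(diff(ny)[1] / diff(ny)[2], diff(y)[1] / diff(y)[2])
  zero <- new("LogisticFit", bottom = 0.2, top = 0.2, ec50 = 1e-9,
              direction = "increasing", converged = FALSE)
  expect_error(normalizeToDamgo(0.5, zero), "span")
})

test_that("Cheng-Prusoff conversion matches hand arithmetic and is monotone", {
  expect_equal(chengPrusoff(10e-9, 0, 5e-9), 10e-9)     # L = 0: Ki = IC50
  expect_equal(chengPrusoff(10e-9, 5e-9, 5e-9), 5e-9)   # 10/(1 + 1)
  expect_equal(chengPrusoff(3e-9, 5e-9, 2.5e-9), 1e-9)  # 3/(1 + 2)
  expect_error(chengPrusoff(1e-9, 1e-9, 0), "kd")
  # monotone decreasing in L, increasing in kd
  Ls <- seq(0, 2e-8, length.out = 10)
  expect_true(all(diff(chengPrusoff(1e-8, Ls, 5e-9)) < 0))
  kds <- seq(1e-9, 1e-8, length.out = 10)
  expect_true(all(diff(chengPrusoff(1e-8, 5e-9, kds)) > 0))
})

test_that("dissociation fits give t_half = ln2/k_off exactly and flag non-decay", {
  t <- seq(0, 60, by = 4)
  fit <- fitDissociation(t, 100 * exp(-0.075 * t))
  expect_true(isConverged(fit))
  expect_equal(kOff(fit), 0.075, tolerance = 1e-6)
  expect_equal(tHalf(fit), log(2) / 0.075, tolerance = 1e-6)  # 9.242 min
  fit2 <- fitDissociation(t, 80 * exp(-0.062 * t))
  expect_equal(tHalf(fit2), log(2) / 0.062, tolerance = 1e-6)  # 11.18 min
  # the identity holds exactly for every emitted fit, including noisy ones
  set.seed(4)
  fit3 <- fitDissociation(t, 100 * exp(-0.05 * t) + rnorm(length(t), 0, 2))
  expect_identical(tHalf(fit3) * kOff(fit3), log(2))
  # scaling law: halving k_off doubles t_half
  half <- fitDissociation(t, 100 * exp(-0.0375 * t))
  expect_equal(tHalf(half), 2 * tHalf(fit), tolerance = 1e-5)
  rising <- fitDissociation(t, 100 * exp(0.02 * t))
  expect_false(isConverged(rising))
  expect_true("nondecaying" %in% rising@flags)
})

test_that("association fits recover k_on with k_off supplied as input", {
  t <- seq(0, 120, by = 5)
  kobs <- 0.285  # k_on*L + k_off = 7e8 * 3e-10 + 0.075, by hand
  fit <- fitAssociation(t, 50 * (1 - exp(-kobs * t)), koff = 0.075,
                        L = 0.3e-9)
  expect_true(isConverged(fit))
  expect_equal(kObs(fit), 0.285, tolerance = 1e-6)
  expect_equal(kOn(fit), 7e8, tolerance = 1e-4)
  # Beq recovered within 0.1% on noiseless input
  expect_lt(abs(fit@beq - 50) / 50, 1e-3)
  # k_obs = k_off gives k_on = 0
  f0 <- fitAssociation(t, 50 * (1 - exp(-0.075 * t)), koff = 0.075,
                       L = 0.3e-9)
  expect_equal(kOn(f0), 0, tolerance = 1e3)  # /M/min scale: 1e3 ~ 1e-6 rel
  # fitted k_obs below the supplied k_off is non-physical
  slow <- fitAssociation(t, 50 * (1 - exp(-0.02 * t)), koff = 0.075,
                         L = 0.3e-9)
  expect_true("nonphysical_kon" %in% slow@flags)
  # a KineticFit can be passed straight through as the k_off source
  dis <- fitDissociation(seq(0, 60, 4), 100 * exp(-0.075 * seq(0, 60, 4)))
  fit2 <- fitAssociation(t, 50 * (1 - exp(-kobs * t)), koff = dis,
                         L = 0.3e-9)
  expect_equal(kOn(fit2), 7e8, tolerance = 1e-4)
})

test_that("one-site competition yields Ki via Cheng-Prusoff round trip", {
  x <- 10^seq(-11, -6, length.out = 10)
  y <- 100 / (1 + x / 2e-9)  # decreasing, IC50 = 2 nM
  est <- oneSiteCompetition(data.frame(concentration = x, response = y),
                            L = 5e-9, kd = 5e-9)
  expect_equal(ic50(est), 2e-9, tolerance = 1e-4)
  expect_equal(ki(est), 1e-9, tolerance = 1e-4)  # 2/(1 + 1) by hand
  expect_lte(ki(est), ic50(est))
  # flat competition data flagged, not silently fitted
  flat <- oneSiteCompetition(data.frame(concentration = x,
                                        response = rep(50, 10)),
                             L = 5e-9, kd = 5e-9)
  expect_true(is.na(ki(flat)))
  # replicate-averaged equals pooled on noiseless data
  rep2 <- data.frame(concentration = rep(x, 2), response = rep(y, 2))
  est2 <- oneSiteCompetition(rep2, L = 5e-9, kd = 5e-9)
  expect_equal(ic50(est2), ic50(est), tolerance = 1e-8)
})

test_that("pEC50 recovery stays accurate under replicate noise", {
  # 8 concentrations x 3 replicates, 5% CV noise; median absolute pEC50
  # error < 0.1 over repeated simulations
  x <- 10^seq(-11, -7.5, by = 0.5)
  errs <- vapply(1:60, function(s) {
    set.seed(s)
    mu <- 100 / (1 + 1e-9 / x)
    d <- data.frame(concentration = rep(x, 3),
                    response = rep(mu, 3) * (1 + rnorm(3 * length(x),
                                                       0, 0.05)))
    fit <- fitLogistic3(d)
    abs(pec50(fit) - 9)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("ligand-free wells are subtracted per compound", {
  plate <- data.frame(
    compound = rep(c("A", "B"), each = 4),
    response = c(1.2, 1.4, 0.2, 0.2, 2.4, 2.6, 0.5, 0.5),
    well = rep(c("ligand", "ligand", "ligand_free", "ligand_free"), 2))
  out <- subtractLigandFree(plate)
  expect_equal(out$response[out$compound == "A"], c(1.0, 1.2))
  expect_equal(out$response[out$compound == "B"], c(1.9, 2.1))
  expect_false("ligand_free" %in% out$well)
})
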