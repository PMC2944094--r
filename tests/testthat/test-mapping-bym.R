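test_that("the same seed gives bitwise-identical chains", {
  lat <- makeLattice(4)
  set.seed(1); O <- rpois(16, 30); E <- rep(30, 16)
  f1 <- bymFit(O, E, lat$adjacency, n_iter = 800, n_burn = 200, thin = 2,
               seed = 123)
  f2 <- bymFit(O, E, lat$adjacency, n_iter = 800, n_burn = 200, thin = 2,
               seed = 123)
  expect_identical(f1$samples, f2$samples)
  f3 <- bymFit(O, E, lat$adjacency, n_iter = 800, n_burn = 200, thin = 2,
               seed = 124)
  expect_false(identical(f1$samples$rr, f3$samples$rr))
})

test_that("a flat field at high counts yields posterior means near 1 and equivocal exceedance", {
  lat <- makeLattice(6)
  fit <- bymFit(rep(200, 36), rep(200, 36), lat$adjacency,
                n_iter = 4000, n_burn = 1000, thin = 3, seed = 5)
  expect_true(all(fit$posterior_mean_rr > 0.93 &
                    fit$posterior_mean_rr < 1.07))
  ex <- exceedanceProb(fit)
  expect_true(all(ex > 0.2 & ex < 0.8))
})

test_that("a high-risk block is flagged with near-certain exceedance while the far field stays equivocal", {
  lat <- makeLattice(10, 1000)
  ids <- lat$geography$area_id
  block <- ids[as.vector(outer(4:6, 4:6, function(r, c) (r - 1) * 10 + c))]
  truth <- ifelse(ids %in% block, 3, 1)
  set.seed(2024)
  E <- rep(50, 100)
  O <- rpois(100, E * truth)
  fit <- bymFit(O, E, lat$adjacency, n_iter = 4000, n_burn = 500,
                thin = 4, seed = 99)
  ex <- exceedanceProb(fit)
  expect_gt(min(ex[block]), 0.95)
  cls <- classifyRisk(fit$posterior_mean_rr, ex)
  expect_true(all(cls[match(block, ids)] == "elevated"))
  # far field: typical areas equivocal (individual null areas can still
  # fluctuate high at E = 50, which is what the classification rule absorbs)
  expect_lt(median(ex[setdiff(ids, block)]), 0.6)
})

test_that("the sampler reproduces closed-form posterior moments under a conjugate normal likelihood", {
  lat3 <- makeLattice(3)
  n <- 9
  set.seed(42)
  y <- rnorm(n, 1, 0.5)
  prec <- rep(4, n)
  tau_u <- 2; tau_v <- 3
  fit <- bymFit(y, rep(1, n), lat3$adjacency, n_iter = 26000,
                n_burn = 1000, thin = 5, seed = 7, family = "normal",
                obs_prec = prec, fix_tau = c(tau_u, tau_v))
  eta_s <- log(fit$samples$rr)

  # closed form: Gaussian posterior of (mu, u, v) with u confined to the
  # sum-to-zero subspace, computed by linear algebra
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, lat3$adjacency$neighbours[[i]]] <- 1
  L <- diag(rowSums(W)) - W
  B <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  A <- cbind(1, B, diag(n))
  P <- diag(prec)
  Q <- t(A) %*% P %*% A
  Q[2:n, 2:n] <- Q[2:n, 2:n] + tau_u * t(B) %*% L %*% B
  Q[(n + 1):(2 * n), (n + 1):(2 * n)] <-
    Q[(n + 1):(2 * n), (n + 1):(2 * n)] + tau_v * diag(n)
  m_post <- solve(Q, t(A) %*% P %*% y)
  eta_mean <- as.vector(A %*% m_post)
  eta_sd <- sqrt(diag(A %*% solve(Q) %*% t(A)))

  expect_lt(max(abs(colMeans(eta_s) - eta_mean)), 0.03)
  expect_true(all(abs(apply(eta_s, 2, sd) / eta_sd - 1) < 0.05))
})

test_that("exceedance probabilities count the retained samples above the threshold", {
  hand <- c(0.2, 0.5, 1.01, 1.1, 1.3, 1.6, 2.0, 1.05, 1.2, 0.7)  # 7 above 1
  s <- matrix(rep(hand, 10), ncol = 1)
  expect_equal(unname(exceedanceProb(s)), 0.7)
  expect_equal(unname(exceedanceProb(matrix(2, 100, 3))), rep(1, 3))
  sym <- matrix(1 + rep(c(-0.3, 0.3), 50), 100, 2)
  expect_equal(unname(exceedanceProb(sym)), c(0.5, 0.5))
  expect_error(exceedanceProb(matrix(1, 10, 2)), "100")
})

test_that("the 0.8/0.2 rule classifies elevated, lowered and uncertain areas", {
  expect_equal(as.character(classifyRisk(1.4, 0.92)), "elevated")
  expect_equal(as.character(classifyRisk(0.7, 0.10)), "lowered")
  expect_equal(as.character(classifyRisk(1.4, 0.50)), "uncertain")
  # both conditions must fire
  expect_equal(as.character(classifyRisk(0.98, 0.85)), "uncertain")
  expect_equal(as.character(classifyRisk(1.2, 0.75)), "uncertain")
  expect_true(is.na(classifyRisk(NA_real_, 0.5)))
  expect_error(classifyRisk(1, 1.2), "\\[0, 1\\]")
})

test_that("full-Bayes smoothing tracks a spatially correlated truth better than global-mean EB", {
  lat10 <- makeLattice(10)
  W <- matrix(0, 100, 100)
  for (i in 1:100) W[i, lat10$adjacency$neighbours[[i]]] <- 1
  sim <- simulateCounts(lat10$geography, rrIcarField(10),
                        adjacency = lat10$adjacency, n_age_bands = 18,
                        mean_py = 10000, seed = 303)
  ids <- lat10$geography$area_id
  Ei <- expectedCount(sim$population, sim$reference_rates)[ids]
  Oi <- as.numeric(tapply(sim$counts$events, sim$counts$area_id, sum)[ids])
  sm_truth <- (as.vector(W %*% sim$truth) + sim$truth) / (rowSums(W) + 1)
  eb <- ebPoissonGamma(Oi, Ei)
  fb <- bymFit(Oi, Ei, lat10$adjacency, n_iter = 5500, n_burn = 500,
               thin = 5, seed = 304)
  expect_gt(cor(fb$posterior_mean_rr, sm_truth, method = "spearman"),
            cor(eb$eb_rr, sm_truth, method = "spearman"))
})

test_that("the risk-field wrapper assembles raw, EB, FB, exceedance and class, with zero-E areas missing", {
  lat <- makeLattice(4)
  set.seed(8)
  E <- c(runif(15, 20, 50), 0)
  O <- c(rpois(15, E[-16]), 0L)
  expect_warning(
    fld <- smoothedRiskField(O, E, lat$adjacency, seed = 31,
                             n_iter = 1200, n_burn = 200, thin = 2),
    "excluded")
  expect_s3_class(fld, "smoothed_risk_field")
  expect_true(all(c("raw_rr", "eb_rr", "fb_rr", "exceedance",
                    "classification") %in% names(fld)))
  expect_true(is.na(fld$fb_rr[16]) && is.na(fld$eb_rr[16]) &&
                is.na(fld$classification[16]))
  expect_true(all(fld$exceedance[-16] >= 0 & fld$exceedance[-16] <= 1))
})

test_that("invalid sampler configurations are rejected", {
  lat <- makeLattice(3)
  O <- rep(5, 9); E <- rep(5, 9)
  expect_error(bymFit(O, E, lat$adjacency), "seed")
  expect_error(bymFit(O, E, lat$adjacency, n_iter = 100, n_burn = 100,
                      seed = 1), "exceed")
  expect_error(bymFit(O, E, lat$adjacency, seed = 1,
                      priors = list(tau_u = c(0.5, -1),
                                    tau_v = c(0.5, 0.0005))),
               "prior")
})

test_that("islands are handled: unstructured smoothing only, with a warning", {
  geo <- areaGeography(c("p", "q", "r", "s"), list(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)),
    rbind(c(0, 1), c(1, 1), c(1, 2), c(0, 2)),
    rbind(c(9, 9), c(10, 9), c(10, 10), c(9, 10))))
  suppressWarnings(adj <- buildAdjacency(geo, "queen"))
  expect_warning(
    fit <- bymFit(c(10, 12, 9, 11), rep(10, 4), adj, n_iter = 600,
                  n_burn = 100, thin = 1, seed = 2),
    "no neighbours")
  expect_true(all(is.finite(fit$posterior_mean_rr)))
})
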