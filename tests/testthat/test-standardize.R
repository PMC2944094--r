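mk_pop <- function(area, py, sex = "male", band = "0-4", year = 2000L,
                   age_bands = defaultAgeBands()) {
  stratPopulation(data.frame(area_id = area, sex = sex, age_band = band,
                             year = year, person_years = py),
                  age_bands = age_bands)
}

mk_rates <- function(sex, band, rate) {
  referenceRates(data.frame(sex = sex, age_band = band, rate = rate),
                 strata = c("sex", "age_band"))
}

test_that("expected counts project reference rates onto the study person-years", {
  # single stratum: 1000 PY at rate 0.005 -> E = 5
  E <- expectedCount(mk_pop("a", 1000), mk_rates("male", "0-4", 0.005))
  expect_equal(unname(E), 5)

  # hand sum over two strata: 100 x 0.01 + 200 x 0.02 = 5
  pop <- mk_pop("a", c(100, 200), band = c("0-4", "5-9"))
  rates <- mk_rates(c("male", "male"), c("0-4", "5-9"), c(0.01, 0.02))
  expect_equal(unname(expectedCount(pop, rates)), 5)

  # missing reference stratum is a named error
  pop2 <- mk_pop("a", c(100, 100), band = c("0-4", "10-14"))
  expect_error(expectedCount(pop2, rates), "10-14")
})

test_that("when the study population is the reference population, E equals the reference observed total", {
  lat <- makeLattice(4)
  sim <- simulateCounts(lat$geography, rrConstant(1.3), seed = 11,
                        n_age_bands = 4, mean_py = 5000)
  rates <- referenceRates(sim$counts, sim$population)
  E <- expectedCount(sim$population, rates, by_area = FALSE)
  expect_equal(E, tableTotal(sim$counts))
})

test_that("expected counts are additive over disjoint area sets", {
  lat <- makeLattice(5)
  sim <- simulateCounts(lat$geography, rrConstant(1), seed = 3,
                        n_age_bands = 6)
  E <- expectedCount(sim$population, sim$reference_rates)
  ids <- lat$geography$area_id
  split1 <- ids[1:10]; split2 <- ids[11:25]
  e1 <- expectedCount(sim$population[sim$population$area_id %in% split1, ],
                      sim$reference_rates, by_area = FALSE)
  e2 <- expectedCount(sim$population[sim$population$area_id %in% split2, ],
                      sim$reference_rates, by_area = FALSE)
  expect_equal(e1 + e2, sum(E))
})

test_that("indirect ratios reproduce routine report values at 2 dp", {
  # printed two-band refinery table and county/city tables, all at 2 dp
  cases <- list(
    list(103, 101.88, 1.01), list(148, 118.23, 1.25),
    list(266, 226.53, 1.17), list(87, 120.92, 0.72),
    list(1917, 2031.76, 0.94), list(246, 298.99, 0.82),
    list(27, 21.29, 1.27))
  for (cs in cases) {
    r <- indirectRatio(cs[[1]], cs[[2]])
    expect_equal(round(r$ratio, 2), cs[[3]])
  }
  # Byar 95% limits on verified rows
  r87 <- indirectRatio(87, 120.92)
  expect_equal(round(r87$ci, 2), c(0.58, 0.89))
  r27 <- indirectRatio(27, 21.29)
  expect_equal(round(r27$ci, 2), c(0.84, 1.85))
  r1917 <- indirectRatio(1917, 2031.76)
  expect_equal(round(r1917$ci[1], 2), 0.90)
})

test_that("zero observed counts give ratio 0, lower 0, and the zero-count upper bound", {
  r <- indirectRatio(0, 3)
  expect_equal(r$ratio, 0)
  expect_equal(r$ci[1], 0)
  z <- qnorm(0.975)
  expect_equal(r$ci[2], (1 - 1 / 9 + z / 3)^3 / 3)
  expect_error(indirectRatio(3, 0), "positive")
  expect_error(indirectRatio(-1, 3), "non-negative")
})

test_that("Byar and exact Poisson limits agree within 0.01 on the ratio scale for O >= 20", {
  for (O in c(20, 35, 60, 100, 250, 500, 1000, 2000)) {
    for (ratio in c(0.5, 1, 1.5)) {
      E <- O / ratio
      b <- indirectRatio(O, E, method = "byar")$ci
      x <- indirectRatio(O, E, method = "exact_poisson")$ci
      expect_lt(max(abs(b - x)), 0.01)
    }
  }
})

test_that("CI width strictly decreases in O at fixed ratio", {
  Os <- c(5, 10, 20, 50, 100, 400, 1000)
  widths <- sapply(Os, function(O) {
    ci <- indirectRatio(O, O / 1.2)$ci
    ci[2] - ci[1]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("counts generated exactly at the reference rates give ratio 1 exactly", {
  pop <- mk_pop("a", c(1000, 2000), band = c("0-4", "5-9"))
  rates <- mk_rates(c("male", "male"), c("0-4", "5-9"), c(0.004, 0.003))
  E <- expectedCount(pop, rates, by_area = FALSE)
  O <- 1000 * 0.004 + 2000 * 0.003  # O_s = n_s r_s
  expect_identical(indirectRatio(O, E)$ratio, 1)
})

test_that("adjusting for a covariate that is constant across areas is a no-op", {
  lat <- makeLattice(4)
  sim <- simulateCounts(lat$geography, rrConstant(1), seed = 5,
                        n_age_bands = 5)
  # constant quintile everywhere: rates by (sex, age, quintile) equal the
  # age-sex rates, so adjusted E must match unadjusted E
  cts <- as.data.frame(sim$counts); cts$quintile <- 3L
  pop <- as.data.frame(sim$population); pop$quintile <- 3L
  bands <- attr(sim$counts, "age_bands")
  cts <- stratCounts(cts, age_bands = bands)
  pop <- stratPopulation(pop, age_bands = bands)
  r_adj <- referenceRates(cts, pop,
                          strata = c("sex", "age_band", "quintile"))
  r_unadj <- referenceRates(cts, pop, strata = c("sex", "age_band"))
  expect_equal(expectedCount(pop, r_adj), expectedCount(pop, r_unadj))
})

test_that("direct standardization: identities and a hand-computed rate", {
  bands2 <- c("0-4", "5-9")
  cts <- stratCounts(data.frame(area_id = "a", sex = "male",
                                age_band = bands2, year = 2000L,
                                events = c(10L, 20L)))
  pop <- mk_pop("a", c(1000, 1000), band = bands2)

  # weights 0.5/0.5 on rates 10/1000 and 20/1000 -> 1500 per 100000
  std <- data.frame(sex = "male", age_band = bands2, weight = c(0.5, 0.5))
  r <- directRate(cts, pop, std)
  expect_equal(r$rate, 1500)

  # equal stratum rates r -> rate = per * r regardless of weights
  cts2 <- stratCounts(data.frame(area_id = "a", sex = "male",
                                 age_band = bands2, year = 2000L,
                                 events = c(10L, 40L)))
  pop2 <- mk_pop("a", c(1000, 4000), band = bands2)
  std_skew <- data.frame(sex = "male", age_band = bands2,
                         weight = c(0.9, 0.1))
  expect_equal(directRate(cts2, pop2, std_skew)$rate, 1e5 * 0.01)

  # standard population = study population -> crude rate
  r_self <- directRate(cts, pop, pop)
  expect_equal(r_self$rate, 1e5 * 30 / 2000)
  expect_true(r_self$ci[1] <= r_self$rate && r_self$rate <= r_self$ci[2])

  # events in a stratum without person-years is an error
  pop0 <- mk_pop("a", c(1000, 0), band = bands2)
  expect_error(directRate(cts, pop0, std), "zero person-years")
})

test_that("the deprivation index is the z-score sum of its four components", {
  set.seed(9)
  inputs <- data.frame(area_id = paste0("w", 1:5),
                       male_unemployment = c(.05, .10, .02, .08, .12),
                       no_car_access = c(.30, .45, .15, .40, .50),
                       low_social_class = c(.20, .35, .10, .25, .40),
                       overcrowding = c(.02, .06, .01, .04, .08))
  idx <- carstairsIndex(inputs)
  # oracle: direct z-sum recomputation
  zsum <- rowSums(scale(as.matrix(inputs[, -1])))
  expect_equal(unname(idx), unname(zsum))
  # symmetry: mirrored areas sum to zero
  two <- data.frame(area_id = c("p", "q"),
                    male_unemployment = c(.04, .08),
                    no_car_access = c(.2, .4),
                    low_social_class = c(.1, .3),
                    overcrowding = c(.02, .06))
  expect_equal(sum(carstairsIndex(two)), 0)
  # an area sitting at the mean of every component scores zero
  three <- data.frame(area_id = c("p", "m", "q"),
                      male_unemployment = c(.04, .06, .08),
                      no_car_access = c(.2, .3, .4),
                      low_social_class = c(.1, .2, .3),
                      overcrowding = c(.02, .04, .06))
  expect_equal(unname(carstairsIndex(three)["m"]), 0)
  # zero-variance components are dropped with a warning
  flat <- inputs; flat$overcrowding <- 0.05
  expect_warning(idx2 <- carstairsIndex(flat), "zero variance")
  expect_equal(unname(idx2),
               unname(rowSums(scale(as.matrix(flat[, 2:4])))))
  expect_error(carstairsIndex(inputs[1, , drop = FALSE]), "at least 2")
  bad <- inputs; bad$overcrowding[1] <- 1.2
  expect_error(carstairsIndex(bad), "proportion")
})
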