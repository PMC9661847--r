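test_that("predicted occurrence matches numerical beta integration", {
  # quadrature oracle for 1 - BetaCDF(d; N_T m p, N_T m (1-p))
  p <- 0.01; m <- 0.05; N_T <- 1000; d <- 0.001
  a <- N_T * m * p; b <- N_T * m * (1 - p)
  oracle <- integrate(function(x) dbeta(x, a, b), d, 1,
                      rel.tol = 1e-12)$value
  expect_equal(predict_occurrence(p, m, N_T, d), oracle, tolerance = 1e-8)
})

test_that("predicted occurrence is monotone and respects beta limits", {
  grid <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5)
  f <- predict_occurrence(grid, m = 0.05, N_T = 1000, d = 0.001)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  # concentration limit: abundant taxa certain, sub-threshold taxa absent
  expect_gt(predict_occurrence(0.01, m = 1e5, N_T = 1000, d = 0.001), 1 - 1e-6)
  expect_lt(predict_occurrence(1e-4, m = 1e5, N_T = 1000, d = 0.001), 1e-6)
  expect_error(predict_occurrence(0, 0.1, 1000), "strictly")
})

test_that("Wilson interval matches its closed form and shrinks with n", {
  ci <- wilson_interval(0.5, 100)
  expect_equal(round(unname(ci[1, "lo"]), 3), 0.404)
  expect_equal(round(unname(ci[1, "hi"]), 3), 0.596)
  expect_equal(unname(wilson_interval(0, 10)[1, "lo"]), 0)
  widths <- sapply(c(10, 50, 200, 1000), function(n) {
    ci <- wilson_interval(0.3, n); ci[1, "hi"] - ci[1, "lo"]
  })
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_interval(0.5, 0), "n")
})

test_that("migration rate is recovered from self-generated sinks", {
  sim <- simulate_neutral_sinks(300, m = 0.05, N_T = 1000, n_sinks = 200, seed = 7)
  fit <- fit_neutral(sim$profile, sim$sinks)
  expect_lt(abs(fit$m / 0.05 - 1), 0.25)
  expect_gte(fit$R2, 0.7)
  # R2 equals the independent one-line oracle on (F, Fhat)
  r2_oracle <- 1 - sum((fit$taxa$F_obs - fit$taxa$F_hat)^2) /
    sum((fit$taxa$F_obs - mean(fit$taxa$F_obs))^2)
  expect_equal(fit$R2, r2_oracle, tolerance = 1e-12)
})

test_that("shuffling occurrences against abundances destroys the fit", {
  sim <- simulate_neutral_sinks(150, m = 0.05, N_T = 1000, n_sinks = 100, seed = 3)
  shuffled <- sim$sinks$counts
  set.seed(1)
  colnames(shuffled) <- sample(colnames(shuffled))
  fit <- fit_neutral(sim$profile, count_table(shuffled))
  expect_lte(fit$R2, 1)
  expect_lt(fit$R2, 0.3)
})

test_that("partition labels respect the Wilson band by construction", {
  for (s in 1:3) {
    sim <- simulate_neutral_sinks(100, m = 0.03 * s, N_T = 800,
                                  n_sinks = 60, seed = s)
    fit <- fit_neutral(sim$profile, sim$sinks)
    with(fit$taxa, {
      expect_true(all((partition == "neutral") == (F_obs >= ci_lo & F_obs <= ci_hi)))
      expect_true(all(ci_lo <= F_hat & F_hat <= ci_hi))
      expect_true(all(F_hat >= 0 & F_hat <= 1))
    })
  }
})

test_that("fit preconditions are enforced", {
  sim <- simulate_neutral_sinks(100, m = 0.05, seed = 1)
  few <- subset_count_table(sim$sinks, samples = 1:5)
  expect_error(fit_neutral(sim$profile, few), ">= 10 sink")
  tiny <- sim$profile[1:5]
  expect_error(fit_neutral(tiny / sum(tiny), sim$sinks), ">= 20 shared taxa")
})

test_that("single-source multi-fit reduces to the plain neutral fit", {
  sim <- simulate_neutral_sinks(120, m = 0.05, N_T = 1000, n_sinks = 80, seed = 2)
  mfit <- fit_multi_source(list(saliva = sim$source), sim$sinks)
  plain <- fit_neutral(sim$source, sim$sinks)
  expect_equal(mfit$fit$m, plain$m, tolerance = 1e-8)
  expect_equal(mfit$fit$R2, plain$R2, tolerance = 1e-8)
  expect_true(all(mfit$attribution$site == "saliva"))
})

test_that("disjoint sources are attributed perfectly with matching quartiles", {
  set.seed(21)
  n <- 60
  profA <- c({x <- rlnorm(30, 0, 1); x / sum(x)}, rep(0, 30))
  profB <- c(rep(0, 30), {x <- rlnorm(30, 0, 1); x / sum(x)})
  taxa <- sprintf("t%02d", 1:60)
  srcA <- count_table(t(rmultinom(20, 5000, profA)) |>
                        (\(m) {dimnames(m) <- list(sprintf("a%02d", 1:20), taxa); m})())
  srcB <- count_table(t(rmultinom(20, 5000, profB)) |>
                        (\(m) {dimnames(m) <- list(sprintf("b%02d", 1:20), taxa); m})())
  sink_mix <- 0.7 * profA + 0.3 * profB
  sinks <- count_table(t(rmultinom(n, 2000, sink_mix)) |>
                         (\(m) {dimnames(m) <- list(sprintf("s%02d", 1:n), taxa); m})())
  mfit <- fit_multi_source(list(A = srcA, B = srcB), sinks)
  attr_ <- mfit$attribution
  expect_true(all(attr_$site[substr(attr_$taxon, 2, 2) != ""] ==
                    ifelse(as.integer(substr(attr_$taxon, 2, 3)) <= 30, "A", "B")))
  # contribution table equals direct enumeration of the attribution frame
  q <- quantile(attr_$F_lung, c(0.25, 0.75))
  grp <- ifelse(attr_$F_lung <= q[1], "lower-quartile",
                ifelse(attr_$F_lung >= q[2], "upper-quartile", "interquartile"))
  expect_equal(as.vector(mfit$contribution),
               as.vector(table(factor(attr_$site, c("A", "B")),
                               factor(grp, c("lower-quartile", "interquartile",
                                             "upper-quartile")))))
  expect_equal(sum(mfit$contribution), nrow(attr_))
})

test_that("abundance ties in attribution break deterministically", {
  taxa <- sprintf("t%02d", 1:25)
  base <- matrix(40, 12, 25, dimnames = list(sprintf("s%02d", 1:12), taxa))
  srcX <- count_table(base); srcY <- count_table(base)  # identical profiles
  set.seed(2)
  sinks <- count_table(t(rmultinom(15, 1000, rep(1 / 25, 25))) |>
                         (\(m) {dimnames(m) <- list(sprintf("k%02d", 1:15), taxa); m})())
  a <- fit_multi_source(list(Y = srcY, X = srcX), sinks)
  b <- fit_multi_source(list(X = srcX, Y = srcY), sinks)
  expect_equal(a$attribution$site, b$attribution$site)
  expect_true(all(a$attribution$site == "X"))  # lexicographic tie-break
})
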