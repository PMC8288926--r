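# Frozen expected values below were computed with independent scalar
# fixed-point iteration (u <- 1 - exp(-a u) style loops run to 1e-14) and
# are asserted against the package's root-finding path.

test_that("er_F solves the ER self-consistency", {
  expect_equal(er_F(0.9, 1), 0)
  expect_equal(er_F(4, 0.25), 0)        # z x = 1: threshold, value 0
  expect_equal(er_F(4, 1), 0.9801725987, tolerance = 1e-8)
  expect_equal(er_F(4, 0.5), 0.7968121300, tolerance = 1e-7)
  # continuity at the threshold: just above z x = 1 the root is tiny
  expect_lt(er_F(1.001, 1), 0.01)
  # non-decreasing in z and in x
  for (z in c(1.5, 2, 4)) expect_true(all(diff(er_F(z, seq(0, 1, 0.05))) >= 0))
  x <- 0.8
  expect_true(all(diff(sapply(c(1, 2, 3, 5), er_F, x = x)) >= 0))
})

test_that("occupation control rescales the usable fraction", {
  Fb <- function(x) er_F(4, x)
  expect_equal(occupation_F(Fb, 1)(0.7), Fb(0.7))
  expect_equal(occupation_F(Fb, 0)(0.7), 0)
  expect_equal(occupation_F(Fb, 0.5)(1), er_F(4, 0.5))
  expect_equal(occupation_F(Fb, 0.5)(1), er_F(2, 1), tolerance = 1e-9)
})

test_that("configmodel_F reduces to er_F for Poisson degrees", {
  k <- 0:50
  d <- degree_dist(k, dpois(k, 4))
  expect_equal(configmodel_F(d, 0), 0)
  expect_equal(configmodel_F(d, 1), er_F(4, 1), tolerance = 1e-3)
  expect_equal(configmodel_F(d, 0.5), er_F(4, 0.5), tolerance = 1e-3)
  expect_equal(configmodel_F(d, 0.2), 0)  # subcritical
})

test_that("power-law threshold in x decreases as the cutoff K grows", {
  xc <- sapply(c(32, 64, 128, 256), function(K)
    configmodel_threshold(power_law_degrees(2.5, 2, K)))
  expect_true(all(diff(xc) < 0))
  # and configmodel_F turns on at that threshold
  d <- power_law_degrees(2.5, 2, 64)
  expect_equal(configmodel_F(d, configmodel_threshold(d) * 0.9), 0)
  expect_gt(configmodel_F(d, configmodel_threshold(d) * 1.5), 0)
})

test_that("the generation recursion reproduces known ER values", {
  mkF <- function(z) function(x) er_F(z, x)
  # subcritical: psi identically zero
  tr <- recursion_trace(mkF(0.5), mkF(0.5), n_max = 20)
  expect_true(all(tr$psi_seq == 0))
  # psi^1 at z = 2.455 is the classical giant component
  tr <- recursion_trace(mkF(2.455), mkF(2.455), n_max = 5, tol = 0)
  expect_equal(tr$psi_seq[1], 0.8865637079, tolerance = 1e-8)
  # sequences stay in [0,1] and are non-increasing
  expect_true(all(tr$psi_seq >= 0 & tr$psi_seq <= 1))
  expect_true(all(diff(tr$psi_seq) <= 1e-12))
  expect_true(all(diff(tr$S_seq) <= 1e-12))
  # slightly above the infinite-generation threshold psi decreases to >= jump
  tr <- recursion_trace(mkF(2.47), mkF(2.47), n_max = 5000, tol = 1e-12)
  expect_true(tr$converged)
  expect_gte(min(tr$psi_seq), 0.5117 - 1e-3)
  # the recursion limit satisfies the fixed-point equation
  S <- tr$S_seq[tr$n]
  expect_equal(S, er_F(2.47, S), tolerance = 1e-6)
  # and agrees with the bisection-based fixed-point finder
  fp <- infinite_fixed_point(function(x) er_F(2.47, x))
  expect_equal(fp[["S"]], S, tolerance = 1e-6)
})

test_that("finite-generation thresholds: z_c^1 = 1 and z_c^2 from z S(z) = 1", {
  mk <- function(z) function(x) er_F(z, x)
  z1 <- finite_generation_threshold(1, mk, bracket = c(0.5, 2))
  expect_equal(z1, 1, tolerance = 1e-3)
  z2 <- finite_generation_threshold(2, mk, bracket = c(1.2, 2))
  expect_equal(z2, 1 / (1 - exp(-1)), tolerance = 1e-3)  # 1.581977
  # thresholds increase with generation toward the infinite-generation value
  z3 <- finite_generation_threshold(3, mk, bracket = c(1.2, 2.5))
  z6 <- finite_generation_threshold(6, mk, bracket = c(1.2, 2.5))
  expect_true(z1 < z2 && z2 < z3 && z3 < z6)
  expect_lt(z6, 2.4554)
  expect_error(finite_generation_threshold(1, mk, bracket = c(1.5, 2)), "bracket")
})

test_that("infinite-generation fixed point: subcritical null, supercritical root", {
  expect_equal(infinite_fixed_point(function(x) er_F(2, x)),
               c(S = 0, psi = 0))
  fp <- infinite_fixed_point(function(x) er_F(4, x))
  expect_equal(fp[["S"]], 0.9782434650, tolerance = 1e-7)  # root of S=1-e^{-4S^2}
  expect_equal(fp[["psi"]], fp[["S"]]^2, tolerance = 1e-9)
})

test_that("ER discontinuous critical point matches the tangency closed form", {
  cp <- er_critical_point()
  # tangency system: S = 1 - exp(-z S^2) with unit-slope touching
  expect_equal(cp$critical, 2.4554, tolerance = 1e-4)
  expect_equal(cp$S_c, 0.7153, tolerance = 1e-4)
  expect_equal(cp$psi_c, cp$S_c^2)
  expect_equal(cp$S_c, (1 + sqrt(1 - 2 / cp$critical)) / 2, tolerance = 1e-10)
  # the generic bisection on the control value agrees
  gen <- discontinuous_critical_point(function(z) function(x) er_F(z, x),
                                      bracket = c(2, 3))
  expect_equal(gen$critical, cp$critical, tolerance = 1e-3)
  expect_equal(gen$S_c, cp$S_c, tolerance = 5e-3)
  expect_equal(gen$psi_c, cp$psi_c, tolerance = 1e-2)
})

test_that("SF layers with m = 2 keep a discontinuous transition under dilution", {
  d <- power_law_degrees(2.5, 2, 64)
  res <- discontinuous_critical_point(
    function(p) function(x) configmodel_F(d, p * x),
    bracket = c(0.01, 0.9))
  expect_gt(res$critical, 0.01)   # non-trivial critical occupation
  expect_gt(res$psi_c, 0.1)       # with a macroscopic jump
})

test_that("degenerate identity map cannot be bracketed", {
  expect_error(
    discontinuous_critical_point(function(ctrl) function(x) x * ctrl / ctrl,
                                 bracket = c(0.1, 0.9)),
    "fixed point")
})

test_that("node-removal control S0 = p shifts the fixed point", {
  # implemented for completeness: S = p F(S)
  fp_full <- infinite_fixed_point(function(x) er_F(6, x), S0 = 1)
  fp_rm <- infinite_fixed_point(function(x) er_F(6, x), S0 = 0.7)
  expect_lt(fp_rm[["S"]], fp_full[["S"]])
  expect_gt(fp_rm[["S"]], 0)
})
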