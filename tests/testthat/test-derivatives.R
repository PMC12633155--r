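ref <- build_reference_network()
zero_state <- setNames(rep(0, nrow(ref$species)), ref$species$name)

test_that("input species follow first-order input processing", {
  # at zero state with full stimulus: dX = k_input * 1 = 1
  d <- cell_derivatives(zero_state, c(TGFB = 1), numeric(), ref)
  expect_equal(d[["TGFB"]], 1.0)
  # at X = 1 production balances degradation: steady state X* = 1
  x <- zero_state; x[["TGFB"]] <- 1
  expect_equal(cell_derivatives(x, c(TGFB = 1), numeric(), ref)[["TGFB"]], 0)
  # feedback contribution enters at k_feedback
  d <- cell_derivatives(zero_state, numeric(), c(TGFBfb = 0.4), ref)
  expect_equal(d[["TGFB"]], 0.5 * 0.4)
})

test_that("receptor activation matches the competitive-inhibition form", {
  # dR = k_receptor*L*R_total - k_inhib*R*I - k_deg*R with R_total = 1
  x <- zero_state
  x[["TGFB"]] <- 0.5; x[["TGFBR"]] <- 0.5
  expect_equal(cell_derivatives(x, numeric(), numeric(), ref)[["TGFBR"]],
               2 * 0.5 * 1 - 1 * 0.5)
  # adding the endogenous inhibitor BAMBI subtracts k_inhib * R * I
  x[["BAMBI"]] <- 0.8
  expect_equal(cell_derivatives(x, numeric(), numeric(), ref)[["TGFBR"]],
               2 * 0.5 - 0.5 * 0.5 * 0.8 - 1 * 0.5)
})

test_that("products with an inactive activator vanish along a chain", {
  toy <- toy_chain_network()
  x <- setNames(rep(0, 4), toy$species$name)
  d <- cell_derivatives(x, c(I = 1), numeric(), toy)
  expect_gt(d[["I"]], 0)
  expect_equal(unname(d[c("A", "B", "C")]), c(0, 0, 0))
  # once A is active, B is produced but C still is not
  x[["A"]] <- 0.5
  d <- cell_derivatives(x, c(I = 1), numeric(), toy)
  expect_gt(d[["B"]], 0)
  expect_equal(d[["C"]], 0)
})

test_that("at the zero state no species is spontaneously consumed", {
  d <- cell_derivatives(zero_state, numeric(), numeric(), ref)
  expect_true(all(d >= 0))
  expect_true(all(d == 0))  # no production without an active activator
  d <- cell_derivatives(zero_state,
                        setNames(rep(1, 10), ref$inputs), numeric(), ref)
  expect_true(all(d >= 0))
  expect_true(all(d[ref$inputs] == 1))
})

test_that("an isolated input species converges to its analytic fixed point", {
  # X* = clip((k_input * I + k_feedback * C) / k_degradation, 0, 1)
  toy <- network_spec(
    species = data.frame(name = c("I", "A"), module = c("input", "other")),
    edges = list(list(target = "A", activators = "I", sign = "production")),
    inputs = "I",
    feedback_fields = data.frame(name = "G", precursor = "A",
                                 target_input = "I"))
  for (io in list(c(I = 0.7, C = 0), c(I = 0.4, C = 0.6), c(I = 1, C = 1))) {
    target <- min(1, 1 * io[["I"]] + 0.5 * io[["C"]])
    x <- setNames(rep(0, 2), toy$species$name)
    for (step in 1:400) {
      d <- cell_derivatives(x, c(I = io[["I"]]), c(G = io[["C"]]), toy)
      x <- pmin(pmax(x + 0.1 * d, 0), 1)
    }
    expect_equal(x[["I"]], target, tolerance = 1e-6)
  }
})

test_that("single-cell dynamics agree with an independent ODE solver", {
  # deSolve integrates the same right-hand side; forward Euler at dt = 0.01
  # must land on the same state at t = 5 to within the Euler error
  toy <- toy_chain_network()
  rhs <- function(t, y, parms) {
    list(unname(cell_derivatives(y, c(I = 1), numeric(), toy)))
  }
  y0 <- setNames(rep(0, 4), toy$species$name)
  sol <- deSolve::lsoda(y0, times = c(0, 5), func = rhs)
  x <- y0
  for (k in 1:500) {
    x <- pmin(pmax(x + 0.01 * cell_derivatives(x, c(I = 1), numeric(), toy),
                   0), 1)
  }
  expect_equal(unname(x), unname(sol[2, -1]), tolerance = 1e-2)
})

test_that("vectorized derivatives equal naive term-by-term summation", {
  set.seed(101)
  for (k in 1:100) {
    x <- setNames(runif(132), ref$species$name)
    iext <- setNames(runif(10), ref$inputs)
    fb <- setNames(runif(4), ref$feedback_fields$name)
    fast <- cell_derivatives(x, iext, fb, ref)
    slow <- naive_cell_derivs(x, iext, fb, ref)
    expect_lt(max(abs(fast - slow[names(fast)])), 1e-12)
  }
})

test_that("a state vector of the wrong length is rejected", {
  expect_error(cell_derivatives(rep(0, 5), numeric(), numeric(), ref),
               "length 5 .* 132 species")
  expect_error(cell_derivatives(zero_state, c(Smad3 = 1), numeric(), ref),
               "non-input species")
})
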