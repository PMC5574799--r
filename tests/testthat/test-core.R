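tab1 <- scen("table1_default", p = .1, q = .9, d = .6, R = 6)

test_that("branch classification follows the two thresholds", {
  # L1 = 4, L2 = 6, Ps = 3
  expect_equal(as.character(classify_branch(c(0, 0.9), tab1)), c("RA", "RA"))
  expect_equal(as.character(classify_branch(1, tab1)), "AR")   # pool == L1
  expect_equal(as.character(classify_branch(2, tab1)), "AR")
  expect_equal(as.character(classify_branch(3, tab1)), "SAR")  # pool == L2
  expect_equal(as.character(classify_branch(4, tab1)), "SAR")
  expect_error(classify_branch(NaN, tab1), "finite")
  expect_error(classify_branch(Inf, tab1), "finite")
})

test_that("one-year step reproduces hand-computed cost accounting", {
  # accumulation year: no costs
  r <- rrbm_step(0, tab1)
  expect_identical(as.character(r$branch), "RA")
  expect_identical(c(r$C_f, r$C_a, r$C_v), c(0, 0, 0))
  expect_equal(r$y_next, 3)
  # asexual year: C_v = 0.6 * (5 - 4)
  r <- rrbm_step(2, tab1)
  expect_identical(as.character(r$branch), "AR")
  expect_equal(r$C_v, 0.6)
  expect_identical(c(r$C_f, r$C_a), c(0, 0))
  expect_equal(r$y_next, 4.4)
  # flowering year: pool 4, above-threshold excess 2
  r <- rrbm_step(1, scen("fig1c"))
  expect_identical(as.character(r$branch), "SAR")
  expect_equal(r$C_f, 0.2)
  expect_equal(r$C_v, 1.8)
  expect_equal(r$C_a, 1.2)
  expect_equal(r$y_next, 4 - 3.2)
})

test_that("trajectories settle on the branch equilibria of the worked examples", {
  tr <- rrbm_simulate(scen("fig1a"), years = 200)
  expect_true(all(tail(tr$branch, 100) == "AR"))
  expect_equal(tail(tr$y_next, 1), 4.0, tolerance = 1e-10)
  tr <- rrbm_simulate(scen("fig1c"), years = 200)
  expect_true(all(tail(tr$branch, 100) == "SAR"))
  expect_equal(tail(tr$y_next, 1), 0.875, tolerance = 1e-10)
})

test_that("a one-year simulation equals a single step", {
  for (nm in c("fig1a", "fig1c", "fig1d")) {
    tr <- rrbm_simulate(scen(nm), y0 = 1.3, years = 1)
    df <- as.data.frame(tr)
    attr(df, "params") <- NULL
    attr(df, "y0") <- NULL
    class(df) <- "data.frame"
    expect_equal(df, rrbm_step(1.3, scen(nm)))
  }
})

test_that("simulated years satisfy conservation and proportional seed set", {
  set.seed(101)
  draws <- draw_params(50)
  for (i in seq_len(nrow(draws))) {
    m <- row_rrbm(draws, i)
    tr <- rrbm_simulate(m, years = 300)
    # exact resource conservation every year
    expect_lt(max(abs(tr$y_next - tr$y_start - m$Ps +
                        (tr$C_f + tr$C_a + tr$C_v))), 1e-12)
    # records chain: next year's start is this year's end
    expect_identical(tr$y_start[-1], tr$y_next[-nrow(tr)])
    # branch recorded is the branch the classifier assigns
    expect_identical(tr$branch, classify_branch(tr$y_start, m))
    # costs match their branch
    ra <- tr$branch == "RA"; ar <- tr$branch == "AR"; sar <- tr$branch == "SAR"
    expect_true(all(tr$C_f[!sar] == 0) && all(tr$C_a[!sar] == 0))
    expect_true(all(tr$C_v[ra] == 0))
    expect_equal(tr$C_v[ar], m$d * (tr$pool[ar] - m$L1), tolerance = 1e-14)
    # seed set proportional to flowering: C_a = R * C_f
    if (any(sar)) {
      expect_lt(max(abs(tr$C_a[sar] / tr$C_f[sar] - m$R)), 1e-12)
      expect_equal(tr$C_f[sar], m$p * (tr$pool[sar] - m$L1), tolerance = 1e-14)
    }
    expect_true(all(tr$C_f >= 0 & tr$C_a >= 0 & tr$C_v >= 0))
  }
})

test_that("pure accumulation escapes the sub-threshold region on schedule", {
  set.seed(202)
  draws <- draw_params(40)
  for (i in seq_len(nrow(draws))) {
    m <- row_rrbm(draws, i)
    y0 <- m$L1 - m$Ps - runif(1, 0, 3)  # start strictly below the RA exit
    n <- ceiling((m$L1 - y0) / m$Ps)
    tr <- rrbm_simulate(m, y0 = y0, years = n)
    expect_true(tr$branch[n] != "RA")
    if (n > 1) expect_true(all(tr$branch[seq_len(n - 1)] == "RA"))
  }
})

test_that("the compiled iterator agrees with the pure-R step", {
  set.seed(303)
  draws <- draw_params(20)
  for (i in seq_len(nrow(draws))) {
    m <- row_rrbm(draws, i)
    tr <- rrbm_simulate(m, y0 = 0.5, years = 60)
    y <- 0.5
    manual <- vapply(seq_len(60), function(t) {
      r <- rrbm_step(y, m)
      y <<- r$y_next
      r$y_next
    }, numeric(1))
    expect_equal(tr$y_next, manual, tolerance = 1e-12)
  }
})

test_that("the single-threshold limit recovers the classic budget-model update", {
  # classic map: accumulate below L, flower above with total cost (1+R) times
  # the excess over L
  rbm_oracle <- function(y, L, Ps, R) {
    ifelse(y + Ps > L, y + Ps - (1 + R) * (y + Ps - L), y + Ps)
  }
  set.seed(404)
  for (case in list(c(L = 4, Ps = 3, R = 1.5), c(L = 2, Ps = 1, R = 4))) {
    m <- suppressWarnings(rrbm(case[["L"]], case[["L"]], case[["Ps"]], p = 1,
                               q = 0, d = .5, R = case[["R"]],
                               reduction = TRUE))
    ys <- runif(500, -5, 15)
    got <- vapply(ys, function(y) rrbm_step(y, m)$y_next, numeric(1))
    expect_equal(got, rbm_oracle(ys, case[["L"]], case[["Ps"]], case[["R"]]),
                 tolerance = 1e-13)
  }
})

test_that("divergent trajectories abort with the offending year", {
  m <- quiet_rrbm(2, 3, 3, p = .5, q = .5, d = .6, R = 1e13)
  err <- tryCatch(rrbm_simulate(m, years = 10), error = identity)
  expect_s3_class(err, "rrbm_divergence_error")
  expect_identical(err$year, 1L)
  expect_match(conditionMessage(err), "year 1")
})

test_that("simulation is deterministic and the CSV round-trips bit-exactly", {
  m <- scen("fig1b")
  t1 <- rrbm_simulate(m, years = 500)
  t2 <- rrbm_simulate(m, years = 500)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(t1, f1)
  write_trajectory(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_trajectory(f1)
  for (col in c("y_start", "pool", "C_f", "C_a", "C_v", "y_next")) {
    expect_identical(back[[col]], t1[[col]])
  }
  expect_identical(back$branch, t1$branch)
  expect_identical(back$t, t1$t)
})
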