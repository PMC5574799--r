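# Scenario shortcut that silences the (expected) overdraft warning of the
# bundled flowering-heavy examples.
scen <- function(name, ...) suppressWarnings(rrbm_scenario(name, ...))

quiet_rrbm <- function(...) suppressWarnings(rrbm(...))

# Random parameter draws used by the property suites. Thresholds and surplus
# span the bundled worked examples (L1 in {2, 4}, L2 in {3, 6, 8}, Ps = 3);
# the allocation coefficients span their full open ranges and R the sweep
# range. Draws are a data frame, one parameter set per row.
draw_params <- function(n) {
  L1 <- runif(n, 0.5, 4)
  data.frame(
    L1 = L1,
    L2 = L1 + runif(n, 0.2, 4),
    Ps = runif(n, 0.3, 5),
    p = runif(n, 0.02, 0.98),
    q = runif(n, 0.02, 0.98),
    d = runif(n, 0.02, 0.98),
    R = runif(n, 0.2, 10))
}

row_rrbm <- function(draws, i) {
  quiet_rrbm(draws$L1[i], draws$L2[i], draws$Ps[i], draws$p[i], draws$q[i],
             draws$d[i], draws$R[i])
}

# terminal reserve of the orbit from y0 after `years` years
terminal_y <- function(params, y0 = 0, years = 2000) {
  tail(rrbm_simulate(params, y0 = y0, years = years)$y_next, 1)
}
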