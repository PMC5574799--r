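#' Refined resource budget model parameters
#'
#' Construct the parameter set of the refined resource budget model (RRBM):
#' a piecewise-linear annual map of the stored resource `y` of a single
#' perennial plant that can reproduce both sexually and asexually. Each year
#' the plant adds the annual surplus `Ps` to its reserve; the pool `y + Ps`
#' is then compared with the asexual threshold `L1` and the sexual threshold
#' `L2`:
#'
#' * pool below `L1`: pure resource accumulation (RA), no reproduction;
#' * pool between `L1` and `L2`: asexual reproduction (AR) with cost
#'   `d * (pool - L1)`;
#' * pool at or above `L2`: simultaneous sexual and asexual reproduction
#'   (SAR) with flowering cost `Cf = p * (pool - L1)`, asexual cost
#'   `Cv = q * (pool - L1)` and seed-set cost `Ca = R * Cf`.
#'
#' A pool exactly at `L2` flowers. At `L1` the asexual cost is zero, so the
#' boundary between RA and AR is seamless.
#'
#' @param L1 asexual-reproduction threshold (resource units); must satisfy
#'   `L1 < L2` (or `L1 == L2` when `reduction = TRUE`).
#' @param L2 sexual-reproduction threshold (resource units).
#' @param Ps annual surplus remaining after growth and maintenance
#'   (resource units per year); must be positive.
#' @param p flowering coefficient, the fraction of the above-threshold pool
#'   spent on flowers; in `(0, 1)` (`p = 1` allowed in reduction mode).
#' @param q asexual reproductive coefficient at the SAR stage; in `(0, 1)`
#'   (`q = 0` allowed in reduction mode).
#' @param d depletion fraction of the AR branch; in `(0, 1)`.
#' @param R depletion coefficient, the ratio of seed-set cost to flowering
#'   cost; positive.
#' @param reduction logical; when `TRUE` the classic single-threshold
#'   resource budget model limit is permitted: `L1 == L2` (which empties the
#'   AR band), `p == 1` and `q == 0`.
#'
#' @details
#' `p` and `q` are not constrained to sum below one: the total SAR
#' allocation fraction is `p + q + R*p`, and values above one overdraw the
#' above-threshold pool, driving the reserve negative after a heavy
#' flowering year. That overdraft is a real feature of the dynamics (it is
#' what produces masting cycles), so it is permitted, but a warning of class
#' `rrbm_overdraft` is signalled when `p + q + R*p > 1` so that the user
#' knows the reserve can go negative.
#'
#' @return An object of class `"rrbm"`: a list with the seven parameters and
#'   the `reduction` flag. Use [coef()] to extract the parameters as a named
#'   numeric vector and [summary()] for the fixed-point/stability report.
#' @seealso [rrbm_simulate()], [rrbm_analyze()], [period_code()],
#'   [rrbm_scenario()]
#' @examples
#' m <- rrbm(L1 = 2, L2 = 8, Ps = 3, p = 0.1, q = 0.9, d = 0.6, R = 6)
#' coef(m)
#' @export
rrbm <- function(L1, L2, Ps, p, q, d, R, reduction = FALSE) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("parameter %s must be a single finite number", name),
           call. = FALSE)
    }
    as.double(x)
  }
  L1 <- num1(L1, "L1"); L2 <- num1(L2, "L2"); Ps <- num1(Ps, "Ps")
  p <- num1(p, "p"); q <- num1(q, "q"); d <- num1(d, "d"); R <- num1(R, "R")

  if (reduction) {
    if (L1 > L2) stop("invalid thresholds: L1 <= L2 is required", call. = FALSE)
    if (p <= 0 || p > 1) stop("flowering coefficient p must lie in (0, 1]",
                              call. = FALSE)
    if (q < 0 || q >= 1) stop("asexual coefficient q must lie in [0, 1)",
                              call. = FALSE)
  } else {
    if (L1 >= L2) {
      stop("invalid thresholds: L1 < L2 is required (use reduction = TRUE ",
           "for the single-threshold limit L1 == L2)", call. = FALSE)
    }
    if (p <= 0 || p >= 1) stop("flowering coefficient p must lie in (0, 1)",
                               call. = FALSE)
    if (q <= 0 || q >= 1) stop("asexual coefficient q must lie in (0, 1)",
                               call. = FALSE)
  }
  if (Ps <= 0) stop("annual surplus Ps must be positive", call. = FALSE)
  if (d <= 0 || d >= 1) stop("depletion fraction d must lie in (0, 1)",
                             call. = FALSE)
  if (R <= 0) stop("depletion coefficient R must be positive", call. = FALSE)

  obj <- structure(
    list(L1 = L1, L2 = L2, Ps = Ps, p = p, q = q, d = d, R = R,
         reduction = reduction),
    class = "rrbm")
  s <- p + q + R * p
  if (s > 1) {
    warning(warningCondition(
      sprintf(paste0("total SAR allocation fraction p + q + R*p = %.6g ",
                     "exceeds 1: reproduction can overdraw the reserve ",
                     "(negative y is permitted)"), s),
      class = "rrbm_overdraft"))
  }
  obj
}

# internal: trusted constructor, no validation, no overdraft warning.
# Used by sweeps, where the base parameters were validated once and each
# grid cell only swaps p, q and R within their already-checked ranges.
new_rrbm <- function(L1, L2, Ps, p, q, d, R, reduction = FALSE) {
  structure(list(L1 = L1, L2 = L2, Ps = Ps, p = p, q = q, d = d, R = R,
                 reduction = reduction),
            class = "rrbm")
}

as_rrbm <- function(x) {
  if (inherits(x, "rrbm")) return(x)
  stop("expected an 'rrbm' parameter object; see ?rrbm", call. = FALSE)
}

#' @export
coef.rrbm <- function(object, ...) {
  unlist(object[c("L1", "L2", "Ps", "p", "q", "d", "R")])
}

#' @export
print.rrbm <- function(x, ...) {
  cat("Refined resource budget model parameters\n")
  cat(sprintf("  thresholds   L1 = %g, L2 = %g\n", x$L1, x$L2))
  cat(sprintf("  surplus      Ps = %g per year\n", x$Ps))
  cat(sprintf("  allocation   p = %g (flowering), q = %g (asexual), d = %g (AR)\n",
              x$p, x$q, x$d))
  s <- x$p + x$q + x$R * x$p
  cat(sprintf("  seed set     R = %g  (SAR allocation p + q + R*p = %g)\n",
              x$R, s))
  if (isTRUE(x$reduction)) cat("  reduction mode (classic single-threshold limit)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scenario registry: named worked-example parameter sets bundled with the
# package. fig1a-fig1d are the four single-run illustrations (asexual-only
# equilibrium, three-year masting cycle, constant annual flowering, and the
# unstable/overdraft case); fig2_base fixes the thresholds and d used by the
# (p, q, R) phase-diagram sweeps; table1_default carries the reference
# threshold/surplus values with the allocation coefficients left free.

.scenario_registry <- list(
  table1_default = list(
    params = list(L1 = 4, L2 = 6, Ps = 3),
    source = "reference thresholds and surplus; p, q, d, R free in (0,1) / R > 0"),
  fig1a = list(
    params = list(L1 = 2, Ps = 3, L2 = 8, d = 0.6, p = 0.1, q = 0.9, R = 6),
    source = "asexual-only equilibrium (wide AR band)"),
  fig1b = list(
    params = list(L1 = 2, Ps = 3, L2 = 6, d = 0.6, p = 0.1, q = 0.9, R = 6),
    source = "periodic sexual + asexual reproduction (three-year cycle)"),
  fig1c = list(
    params = list(L1 = 2, Ps = 3, L2 = 3, d = 0.6, p = 0.1, q = 0.9, R = 6),
    source = "constant annual sexual + asexual reproduction"),
  fig1d = list(
    params = list(L1 = 2, Ps = 3, L2 = 3, d = 0.6, p = 0.1, q = 0.9, R = 12),
    source = "unstable flowering equilibrium (heavy seed-set overdraft)"),
  fig2_base = list(
    params = list(L1 = 2, Ps = 3, L2 = 3, d = 0.6),
    source = "base thresholds for the (p, q, R) phase-diagram sweeps"))

#' Bundled worked-example scenarios
#'
#' `rrbm_scenarios()` lists the bundled named parameter sets;
#' `rrbm_scenario()` instantiates one as an [rrbm] object. Scenarios
#' `table1_default` and `fig2_base` leave some coefficients unset; supply
#' them through `...`.
#'
#' @param name scenario name, one of the rows of `rrbm_scenarios()`.
#' @param ... named parameter overrides (e.g. `p`, `q`, `R`) merged over the
#'   scenario values before validation.
#' @return `rrbm_scenario()` returns an [rrbm] object; `rrbm_scenarios()`
#'   returns a data frame with one row per scenario.
#' @examples
#' rrbm_scenarios()
#' rrbm_scenario("fig1a")
#' rrbm_scenario("fig2_base", p = 0.1, q = 0.9, R = 6)
#' @export
rrbm_scenario <- function(name, ...) {
  if (!name %in% names(.scenario_registry)) {
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(.scenario_registry), collapse = ", ")),
         call. = FALSE)
  }
  base <- .scenario_registry[[name]]$params
  over <- list(...)
  bad <- setdiff(names(over), c("L1", "L2", "Ps", "p", "q", "d", "R"))
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(base, over)
  missing <- setdiff(c("L1", "L2", "Ps", "p", "q", "d", "R"), names(merged))
  if (length(missing)) {
    stop(sprintf("scenario '%s' leaves %s unset; supply via ...", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  do.call(rrbm, merged)
}

#' @rdname rrbm_scenario
#' @export
rrbm_scenarios <- function() {
  rows <- lapply(names(.scenario_registry), function(nm) {
    p <- .scenario_registry[[nm]]$params
    g <- function(k) if (is.null(p[[k]])) NA_real_ else p[[k]]
    data.frame(scenario = nm, L1 = g("L1"), L2 = g("L2"), Ps = g("Ps"),
               p = g("p"), q = g("q"), d = g("d"), R = g("R"),
               description = .scenario_registry[[nm]]$source,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
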