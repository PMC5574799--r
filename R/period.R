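#' Long-run reproductive period code
#'
#' Classifies the long-run reproductive behaviour of a parameter set into
#' the integer colour-bar code used by the phase diagrams:
#'
#' * `-1` - no flowering year in the analysis window: the plant reproduces
#'   asexually (or merely accumulates) every year;
#' * `0`  - the plant flowers every year on a constant orbit (the stable
#'   flowering equilibrium);
#' * `1`  - the plant flowers every year but the orbit is not constant;
#' * `2`-`18` - flowering recurs at a constant interval of that many years
#'   (masting with that period);
#' * `19` - the flowering interval exceeds 18 years or is irregular
#'   (long-period or chaotic reproduction).
#'
#' The orbit is simulated for `burn_in + window` years from `y0`; only the
#' window is analysed. Flowering years are the SAR-branch years. Constancy
#' for the 0-vs-1 call is judged on the final 100 window years (the
#' attractor, free of any slowly decaying transient): the reserve range
#' there must not exceed `tol`.
#'
#' @inheritParams lyapunov_numeric
#' @param window analysis window in years; at least 72 (four times the
#'   maximum recognized period).
#' @param tol absolute tolerance on reserves for the constant-orbit call
#'   (default `1e-9`).
#' @return An object of class `rrbm_period`: a list with fields `code`
#'   (integer in `{-1, 0, ..., 19}`), `intervals` (the distinct inter-
#'   flowering intervals observed), `n_sexual` (flowering years in the
#'   window), `cycle_constant` (logical: terminal reserve range within
#'   `tol`), and `flags` (any of `no_sexual_events`, `aperiodic`,
#'   `exceeded_max_period`). Divergent orbits raise an
#'   `rrbm_divergence_error`.
#' @examples
#' period_code(rrbm_scenario("fig1a"))$code  # -1, asexual every year
#' period_code(rrbm_scenario("fig1b"))$code  #  3, flowers every third year
#' period_code(rrbm_scenario("fig1c"))$code  #  0, constant annual flowering
#' @export
period_code <- function(params, y0 = 0, burn_in = 1000, window = 2000,
                        tol = 1e-9, guard = 1e12) {
  params <- as_rrbm(params)
  window <- as.integer(window)
  if (is.na(window) || window < 72L) {
    stop("window must be at least 72 years (four maximal cycles)",
         call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)
  orb <- .orbit(params, y0, as.integer(burn_in), window, guard)
  .period_from_orbit(orb, window, tol)
}

.period_from_orbit <- function(orb, window, tol) {
  max_period <- 18L
  sar <- which(orb$branch == 2L)
  flags <- character(0)
  tail_y <- orb$y[seq.int(max(1L, window - 99L), window)]
  constant <- (max(tail_y) - min(tail_y)) <= tol

  if (length(sar) == 0L) {
    code <- -1L
    flags <- "no_sexual_events"
    intervals <- integer(0)
  } else if (length(sar) == 1L) {
    code <- 19L
    flags <- "exceeded_max_period"
    intervals <- integer(0)
  } else {
    iv <- diff(sar)
    intervals <- sort(unique(iv))
    if (all(iv == 1L)) {
      code <- if (constant) 0L else 1L
    } else if (length(intervals) == 1L) {
      m <- intervals[1L]
      if (m <= max_period) {
        code <- as.integer(m)
      } else {
        code <- 19L
        flags <- "exceeded_max_period"
      }
    } else {
      code <- 19L
      flags <- "aperiodic"
    }
  }
  structure(list(code = code, intervals = intervals,
                 n_sexual = length(sar), cycle_constant = constant,
                 flags = flags),
            class = "rrbm_period")
}

#' @export
print.rrbm_period <- function(x, ...) {
  meaning <- if (x$code == -1L) "asexual every year (no flowering)"
  else if (x$code == 0L) "flowers every year, constant orbit"
  else if (x$code == 1L) "flowers every year, non-constant orbit"
  else if (x$code <= 18L) sprintf("flowers every %d years", x$code)
  else "long or irregular reproductive period"
  cat(sprintf("Reproductive period code: %d  (%s)\n", x$code, meaning))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Phase-diagram sweep over the allocation coefficients
#'
#' Tiles the open unit square of `(p, q)` at each requested depletion
#' coefficient `R` and records the reproductive period code of every cell,
#' producing the phase diagrams that show how the flowering/asexual
#' allocation trade-off and the seed-set cost shape masting. Cells are
#' independent, so the result does not depend on evaluation order.
#'
#' An `n_grid`-point axis over (0, 1) samples the midpoints
#' `i / (n_grid + 1)`, `i = 1, ..., n_grid`, so the excluded endpoints 0
#' and 1 are never touched. With `simplex = TRUE` only cells with
#' `p + q <= 1` (total allocation within the pool) are evaluated; the rest
#' are `NA`. A cell whose orbit trips the divergence guard is recorded as
#' the sentinel code `-9` rather than aborting the sweep.
#'
#' @param base an [rrbm] object (or a scenario name such as `"fig2_base"`)
#'   supplying `L1`, `L2`, `Ps` and `d`; its `p`, `q`, `R` are ignored.
#' @param R_values numeric vector of depletion coefficients, one phase
#'   diagram per value.
#' @param n_grid grid points per axis (default 51).
#' @param p_grid,q_grid optional explicit grids in (0, 1); override
#'   `n_grid`.
#' @param simplex restrict to `p + q <= 1`?
#' @inheritParams period_code
#' @return An object of class `rrbm_sweep`: a list of
#'   `rrbm_phase_diagram` objects (fields `R`, `p_grid`, `q_grid`, `codes`
#'   - a `length(q_grid)` x `length(p_grid)` integer matrix indexed
#'   `[q, p]` - and `base`), plus the simulation settings. Use
#'   [as.data.frame()] for the long format and [write_phase_diagram()] for
#'   CSV export.
#' @examples
#' sw <- rrbm_sweep(rrbm_scenario("fig2_base", p = .5, q = .5, R = 1),
#'                  R_values = 1, n_grid = 5)
#' sw[[1]]$codes
#' @export
rrbm_sweep <- function(base, R_values, n_grid = 51L, p_grid = NULL,
                       q_grid = NULL, simplex = FALSE, y0 = 0,
                       burn_in = 1000, window = 2000, tol = 1e-9,
                       guard = 1e12) {
  if (is.character(base)) {
    sc <- .scenario_registry[[base]]
    if (is.null(sc)) stop("unknown scenario '", base, "'", call. = FALSE)
    pr <- sc$params
    if (is.null(pr$L1) || is.null(pr$L2) || is.null(pr$Ps) || is.null(pr$d)) {
      stop("scenario '", base, "' does not fix L1, L2, Ps and d",
           call. = FALSE)
    }
    base <- new_rrbm(pr$L1, pr$L2, pr$Ps, p = 0.5, q = 0.5, d = pr$d, R = 1)
  }
  base <- as_rrbm(base)
  if (!is.numeric(R_values) || !length(R_values) || any(R_values <= 0)) {
    stop("R_values must be positive", call. = FALSE)
  }
  mid <- function(n) seq_len(n) / (n + 1)
  if (is.null(p_grid)) p_grid <- mid(as.integer(n_grid))
  if (is.null(q_grid)) q_grid <- mid(as.integer(n_grid))
  chk <- function(g, nm) {
    if (any(g <= 0) || any(g >= 1) || is.unsorted(g, strictly = TRUE)) {
      stop(nm, " must be strictly increasing inside (0, 1)", call. = FALSE)
    }
  }
  chk(p_grid, "p_grid"); chk(q_grid, "q_grid")

  diagrams <- lapply(R_values, function(R) {
    codes <- matrix(NA_integer_, nrow = length(q_grid),
                    ncol = length(p_grid),
                    dimnames = list(q = signif(q_grid, 6),
                                    p = signif(p_grid, 6)))
    for (j in seq_along(q_grid)) {
      for (i in seq_along(p_grid)) {
        if (simplex && p_grid[i] + q_grid[j] > 1) next
        cell <- new_rrbm(base$L1, base$L2, base$Ps, p = p_grid[i],
                         q = q_grid[j], d = base$d, R = R)
        codes[j, i] <- tryCatch(
          period_code(cell, y0 = y0, burn_in = burn_in, window = window,
                      tol = tol, guard = guard)$code,
          rrbm_divergence_error = function(e) -9L)
      }
    }
    structure(list(R = R, p_grid = p_grid, q_grid = q_grid, codes = codes,
                   base = base),
              class = "rrbm_phase_diagram")
  })
  structure(diagrams,
            settings = list(y0 = y0, burn_in = burn_in, window = window,
                            tol = tol, guard = guard, simplex = simplex),
            class = "rrbm_sweep")
}

#' @export
print.rrbm_phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram at R = %g (%d x %d cells)\n", x$R,
              length(x$q_grid), length(x$p_grid)))
  tab <- table(x$codes, useNA = "no")
  cat("  code counts:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.rrbm_sweep <- function(x, ...) {
  cat(sprintf("RRBM phase-diagram sweep over %d value(s) of R\n", length(x)))
  for (d in x) print(d)
  invisible(x)
}

#' @export
as.data.frame.rrbm_sweep <- function(x, ...) {
  do.call(rbind, lapply(x, function(d) {
    data.frame(R = d$R,
               p = rep(d$p_grid, each = length(d$q_grid)),
               q = rep(d$q_grid, times = length(d$p_grid)),
               code = as.vector(d$codes))
  }))
}

#' Write a sweep as long-format CSV
#'
#' One row per evaluated cell with columns `R`, `p`, `q`, `code`.
#'
#' @param x an `rrbm_sweep` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(x, path) {
  stopifnot(inherits(x, "rrbm_sweep"))
  d <- as.data.frame(x)
  d <- d[!is.na(d$code), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.rrbm_phase_diagram <- function(x, ...) {
  # colour scheme: divergent grey, -1 green, 0 blue, 1-18 graded yellow->red,
  # 19 dark red
  breaks <- c(-9.5, -1.5, -0.5, 0.5, seq(1.5, 18.5, by = 1), 19.5)
  cols <- c("grey60", "forestgreen", "steelblue",
            hcl.colors(18, "YlOrRd", rev = TRUE), "darkred")
  graphics::image(x$p_grid, x$q_grid, t(x$codes), breaks = breaks,
                  col = cols, xlab = "flowering coefficient p",
                  ylab = "asexual coefficient q",
                  main = sprintf("R = %g", x$R), useRaster = TRUE, ...)
  invisible(x)
}
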