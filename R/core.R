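#' Classify the annual branch taken from a given reserve
#'
#' Given the reserve `y` at the start of a year, the season's pool is
#' `y + Ps` and the branch is `RA` when the pool is below `L1`, `AR` when it
#' lies in `[L1, L2)`, and `SAR` when it reaches `L2`. A pool exactly at
#' `L2` flowers; a pool exactly at `L1` takes the AR branch with zero cost,
#' which coincides with RA.
#'
#' @param y starting reserve(s); numeric vector, finite.
#' @param params an [rrbm] parameter object.
#' @return A factor with levels `RA`, `AR`, `SAR`, one element per `y`.
#' @examples
#' p <- rrbm_scenario("table1_default", p = 0.1, q = 0.9, d = 0.6, R = 6)
#' classify_branch(c(0, 2, 4), p)
#' @export
classify_branch <- function(y, params) {
  params <- as_rrbm(params)
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("corrupt state: reserve y must be finite", call. = FALSE)
  }
  pool <- y + params$Ps
  code <- ifelse(pool < params$L1, 0L, ifelse(pool < params$L2, 1L, 2L))
  .branch_factor(code)
}

#' Advance the reserve one year
#'
#' Applies the annual map once and returns the full cost accounting of that
#' year: the branch taken, the flowering cost `C_f`, the seed-set cost
#' `C_a = R * C_f`, the asexual cost `C_v`, and the next reserve
#' `y_next = y + Ps - (C_f + C_a + C_v)`. The reserve is never floored at
#' zero: a SAR allocation fraction `p + q + R*p > 1` overdraws the pool and
#' drives `y_next` negative.
#'
#' @inheritParams classify_branch
#' @param y starting reserve; a single finite number.
#' @param t year index stored in the record (default 0).
#' @return A one-row data frame with columns `t`, `y_start`, `pool`,
#'   `branch`, `C_f`, `C_a`, `C_v`, `y_next`.
#' @examples
#' p <- rrbm_scenario("fig1c")
#' rrbm_step(1, p)  # flowering year: C_f = 0.2, C_a = 1.2, C_v = 1.8
#' @export
rrbm_step <- function(y, params, t = 0L) {
  params <- as_rrbm(params)
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y)) {
    stop("corrupt state: reserve y must be a single finite number",
         call. = FALSE)
  }
  pool <- y + params$Ps
  C_f <- 0; C_a <- 0; C_v <- 0
  if (pool < params$L1) {
    code <- 0L
  } else if (pool < params$L2) {
    code <- 1L
    C_v <- params$d * (pool - params$L1)
  } else {
    code <- 2L
    C_f <- params$p * (pool - params$L1)
    C_v <- params$q * (pool - params$L1)
    C_a <- params$R * C_f
  }
  y_next <- y + params$Ps - (C_f + C_a + C_v)
  data.frame(t = as.integer(t), y_start = y, pool = pool,
             branch = .branch_factor(code),
             C_f = C_f, C_a = C_a, C_v = C_v, y_next = y_next)
}

#' Simulate a reserve trajectory
#'
#' Iterates the annual map for `years` years from the initial reserve `y0`
#' and returns the full per-year record. The iteration is deterministic:
#' identical inputs give bit-identical output. If the reserve magnitude
#' exceeds `guard` the simulation aborts with an error of class
#' `rrbm_divergence_error` naming the year at which the guard tripped.
#'
#' @inheritParams classify_branch
#' @param y0 initial reserve (default 0, an empty store).
#' @param years number of years to simulate (at least 1).
#' @param guard divergence guard on `|y|` (default `1e12`).
#' @return An object of class `rrbm_trajectory`: a data frame with columns
#'   `t` (0-based year), `y_start`, `pool`, `branch`, `C_f`, `C_a`, `C_v`,
#'   `y_next`, with the parameters attached as attribute `params`.
#' @examples
#' tr <- rrbm_simulate(rrbm_scenario("fig1a"), years = 50)
#' tail(tr$y_start)  # settles on the asexual equilibrium y = 4
#' @export
rrbm_simulate <- function(params, y0 = 0, years = 2000, guard = 1e12) {
  params <- as_rrbm(params)
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0)) {
    stop("initial reserve y0 must be a single finite number", call. = FALSE)
  }
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("years must be at least 1", call. = FALSE)
  res <- .traj_core(params$L1, params$L2, params$Ps, params$p, params$q,
                    params$d, params$R, y0, years, guard)
  if (res$diverged_at > 0) {
    stop(errorCondition(
      sprintf("trajectory diverged (|y| > %g) at year %d", guard,
              res$diverged_at),
      class = "rrbm_divergence_error", year = res$diverged_at))
  }
  out <- data.frame(t = 0:(years - 1L), y_start = res$y_start,
                    pool = res$pool, branch = .branch_factor(res$branch),
                    C_f = res$C_f, C_a = res$C_a, C_v = res$C_v,
                    y_next = res$y_next)
  structure(out, params = params, y0 = y0,
            class = c("rrbm_trajectory", "data.frame"))
}

#' @rdname rrbm_simulate
#' @param object an [rrbm] parameter object.
#' @param nsim number of years to simulate.
#' @param seed ignored (the map has no stochastic component); accepted for
#'   compatibility with the [stats::simulate()] generic.
#' @param ... unused.
#' @export
simulate.rrbm <- function(object, nsim = 2000, seed = NULL, y0 = 0, ...) {
  rrbm_simulate(object, y0 = y0, years = nsim)
}

#' @export
print.rrbm_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("RRBM trajectory: %d years from y0 = %g\n", n,
              attr(x, "y0")))
  tab <- table(x$branch)
  cat("  branch counts:",
      paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (n > 6) cat("  ...", n - 6, "more years\n")
  invisible(x)
}

#' @export
plot.rrbm_trajectory <- function(x, last = 100L, ...) {
  n <- nrow(x)
  idx <- if (n > last) seq(n - last + 1L, n) else seq_len(n)
  d <- as.data.frame(x)[idx, ]
  graphics::matplot(d$t, cbind(d$y_start, d$C_f, d$C_a, d$C_v),
                    type = "l", lty = 1, lwd = c(2, 1, 1, 1),
                    col = c("black", "orange", "red", "forestgreen"),
                    xlab = "year", ylab = "resource units", ...)
  graphics::legend("topright", bty = "n", lty = 1,
                   lwd = c(2, 1, 1, 1),
                   col = c("black", "orange", "red", "forestgreen"),
                   legend = c("reserve y", "C_f (flowering)",
                              "C_a (seed set)", "C_v (asexual)"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Trajectory CSV serialization. Floats are written with 17 significant
# digits so a written file reads back bit-exactly.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a trajectory CSV
#'
#' The CSV has a header row and columns `t`, `y_start`, `pool`, `branch`,
#' `C_f`, `C_a`, `C_v`, `y_next`. Floating-point columns are serialized
#' with 17 significant digits, enough for IEEE doubles to round-trip
#' bit-exactly through `read_trajectory()`.
#'
#' @param x an `rrbm_trajectory` (or compatible data frame).
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `rrbm_trajectory` data frame (without
#'   the originating parameters attached).
#' @export
write_trajectory <- function(x, path) {
  cols <- c("t", "y_start", "pool", "branch", "C_f", "C_a", "C_v", "y_next")
  stopifnot(all(cols %in% names(x)))
  lines <- paste(x$t, .fmt17(x$y_start), .fmt17(x$pool),
                 as.character(x$branch), .fmt17(x$C_f), .fmt17(x$C_a),
                 .fmt17(x$C_v), .fmt17(x$y_next), sep = ",")
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(t = "integer", y_start = "numeric",
                                      pool = "numeric", branch = "character",
                                      C_f = "numeric", C_a = "numeric",
                                      C_v = "numeric", y_next = "numeric"))
  d$branch <- factor(d$branch, levels = .branch_levels)
  structure(d, class = c("rrbm_trajectory", "data.frame"))
}
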