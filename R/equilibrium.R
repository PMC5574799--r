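#' Closed-form fixed points of the annual map
#'
#' The map has two candidate equilibria, one per reproductive branch.
#'
#' `asexual_fixed_point()` reports the AR-branch equilibrium
#' `y2* = L1 + Ps/d - Ps`, which exists when `Ps < (L2 - L1) * d` (the
#' annual surplus is below the minimum AR spend needed to reach the sexual
#' threshold). Its Lyapunov exponent is `log(abs(1 - d))`, always negative
#' for `d` in (0, 1), so it is stable whenever it exists: the plant settles
#' into reproducing asexually every year.
#'
#' `sexual_fixed_point()` reports the SAR-branch equilibrium
#' `y1* = L1 - Ps + Ps / (p + q + R*p)`, which exists when
#' `Ps > (p + q + R*p) * (L2 - L1)` and has Lyapunov exponent
#' `log(abs(1 - p - q - R*p))`; it is stable iff `R*p < 2 - p - q`. A
#' stable `y1*` means the plant flowers every year with constant effort; an
#' unstable one means seed set overdraws the reserve and flowering becomes
#' intermittent.
#'
#' Existence is judged with strict inequalities; a condition holding only
#' within `tol` of equality is a measure-zero boundary case and is reported
#' as non-existent (see [classify_regime()], which flags such parameter
#' sets as scene 0). `value` and `lyapunov` are `NA` when the equilibrium
#' does not exist.
#'
#' @param params an [rrbm] parameter object.
#' @param tol equality tolerance for the existence condition and for the
#'   marginal-stability call (default `1e-12`).
#' @return An object of class `rrbm_fixed_point`: a list with fields
#'   `which` (`"asexual_branch"` or `"sexual_branch"`), `value`, `exists`,
#'   `stable` (`"stable"`, `"unstable"` or `"marginal"`), and `lyapunov`
#'   (natural log units).
#' @examples
#' asexual_fixed_point(rrbm_scenario("fig1a"))  # y2* = 4, stable
#' sexual_fixed_point(rrbm_scenario("fig1c"))   # y1* = 0.875, stable
#' @export
asexual_fixed_point <- function(params, tol = 1e-12) {
  params <- as_rrbm(params)
  margin <- (params$L2 - params$L1) * params$d - params$Ps
  exists <- margin > tol
  lyap <- log(abs(1 - params$d))
  structure(list(
    which = "asexual_branch",
    value = if (exists) params$L1 + params$Ps / params$d - params$Ps else NA_real_,
    exists = exists,
    stable = if (exists) .stability_state(lyap, tol) else NA_character_,
    lyapunov = if (exists) lyap else NA_real_),
    class = "rrbm_fixed_point")
}

#' @rdname asexual_fixed_point
#' @export
sexual_fixed_point <- function(params, tol = 1e-12) {
  params <- as_rrbm(params)
  s <- params$p + params$q + params$R * params$p
  margin <- params$Ps - s * (params$L2 - params$L1)
  exists <- margin > tol
  lyap <- log(abs(1 - s))
  structure(list(
    which = "sexual_branch",
    value = if (exists) params$L1 - params$Ps + params$Ps / s else NA_real_,
    exists = exists,
    stable = if (exists) .stability_state(lyap, tol) else NA_character_,
    lyapunov = if (exists) lyap else NA_real_),
    class = "rrbm_fixed_point")
}

.stability_state <- function(lyap, tol) {
  if (is.infinite(lyap) && lyap < 0) return("stable")
  if (abs(lyap) <= tol) "marginal" else if (lyap < 0) "stable" else "unstable"
}

#' @export
print.rrbm_fixed_point <- function(x, ...) {
  lab <- if (x$which == "sexual_branch") "y1* (SAR branch)" else "y2* (AR branch)"
  if (!x$exists) {
    cat(sprintf("%s: does not exist\n", lab))
  } else {
    cat(sprintf("%s = %.10g  [%s, lambda = %.6g]\n", lab, x$value, x$stable,
                x$lyapunov))
  }
  invisible(x)
}

#' Classify the reproductive regime
#'
#' Assigns the parameter set to one of four regimes ("scenes") according to
#' which equilibrium exists and whether the flowering equilibrium is
#' stable:
#'
#' 1. `Ps < (L2 - L1) * d`: the asexual equilibrium `y2*` exists and is
#'    stable; the plant reproduces asexually every year and never flowers.
#' 2. `(L2 - L1) * d < Ps < (p + q + R*p) * (L2 - L1)`: neither equilibrium
#'    exists; the plant alternates accumulation/asexual years with
#'    intermittent flowering years (masting cycles).
#' 3. `Ps > (p + q + R*p) * (L2 - L1)` and `R*p < 2 - p - q`: the flowering
#'    equilibrium `y1*` exists and is stable; annual flowering with
#'    constant effort.
#' 4. as 3 but `R*p > 2 - p - q`: `y1*` exists but is unstable; seed set
#'    overdraws the reserve and reproduction is variable.
#'
#' Comparisons are strict; when any governing quantity is within `tol` of
#' equality the scene is reported as `0` (boundary/degenerate) rather than
#' silently assigned. When both existence conditions hold simultaneously
#' (possible when `d > p + q + R*p`) the scenes are applied in the order
#' above, so the parameter set is reported as scene 1; that matches the
#' dynamics from an empty store, which cannot climb past the asexual
#' equilibrium into the flowering region.
#'
#' @inheritParams asexual_fixed_point
#' @return An object of class `rrbm_regime`: a list with fields `scene`
#'   (integer 0-4), `criteria` (data frame with the evaluated inequalities
#'   and their numeric sides), and `fixed_points` (list with components
#'   `sexual` and `asexual`, each an `rrbm_fixed_point`).
#' @examples
#' classify_regime(rrbm_scenario("fig1b"))$scene  # 2: masting cycles
#' @export
classify_regime <- function(params, tol = 1e-12) {
  params <- as_rrbm(params)
  s <- params$p + params$q + params$R * params$p
  dl <- params$L2 - params$L1
  a <- dl * params$d - params$Ps        # > 0: y2* exists
  b <- params$Ps - s * dl               # > 0: y1* exists
  cc <- (2 - params$p - params$q) - params$R * params$p  # > 0: y1* stable

  criteria <- data.frame(
    criterion = c("Ps < (L2 - L1) * d",
                  "Ps > (p + q + R*p) * (L2 - L1)",
                  "R*p < 2 - p - q"),
    lhs = c(params$Ps, params$Ps, params$R * params$p),
    rhs = c(dl * params$d, s * dl, 2 - params$p - params$q),
    satisfied = c(a > tol, b > tol, cc > tol),
    stringsAsFactors = FALSE)

  scene <- if (abs(a) <= tol || abs(b) <= tol || (b > tol && abs(cc) <= tol)) {
    0L
  } else if (a > tol) {
    1L
  } else if (b < -tol) {
    2L
  } else if (cc > tol) {
    3L
  } else {
    4L
  }

  structure(list(scene = scene, criteria = criteria,
                 fixed_points = list(sexual = sexual_fixed_point(params, tol),
                                     asexual = asexual_fixed_point(params, tol)),
                 params = params),
            class = "rrbm_regime")
}

#' @export
print.rrbm_regime <- function(x, ...) {
  lab <- c("0 (boundary/degenerate)",
           "1: asexual equilibrium, no flowering",
           "2: no equilibrium, masting cycles",
           "3: stable annual flowering",
           "4: unstable flowering equilibrium")[x$scene + 1L]
  cat("Reproductive regime: scene", lab, "\n")
  print(x$criteria, row.names = FALSE)
  print(x$fixed_points$sexual)
  print(x$fixed_points$asexual)
  invisible(x)
}

#' Numeric Lyapunov exponent from a simulated orbit
#'
#' The map is piecewise linear, so the local slope each year depends only
#' on the branch taken: 1 on RA, `1 - d` on AR, and `1 - (p + q + R*p)` on
#' SAR. The numeric exponent is the mean of `log(abs(slope))` over the
#' post-burn-in window. When the orbit settles on a single branch this
#' equals the analytic exponent of that branch's equilibrium; a value of
#' `-Inf` is returned when a visited branch has slope exactly zero (the
#' orbit is annihilated onto the threshold in one step).
#'
#' @inheritParams asexual_fixed_point
#' @param y0 initial reserve.
#' @param burn_in transient years discarded before averaging.
#' @param window years averaged (at least 100).
#' @param guard divergence guard passed to the simulator.
#' @return The mean log absolute slope (nats per year).
#' @examples
#' lyapunov_numeric(rrbm_scenario("fig1a"))  # log(0.4), the AR-branch value
#' @export
lyapunov_numeric <- function(params, y0 = 0, burn_in = 1000, window = 2000,
                             guard = 1e12) {
  params <- as_rrbm(params)
  window <- as.integer(window)
  if (is.na(window) || window < 100L) {
    stop("window must be at least 100 years", call. = FALSE)
  }
  orb <- .orbit(params, y0, as.integer(burn_in), window, guard)
  slopes <- c(1, 1 - params$d,
              1 - (params$p + params$q + params$R * params$p))[orb$branch + 1L]
  if (any(slopes == 0)) return(-Inf)
  mean(log(abs(slopes)))
}

# internal: post-burn-in orbit (y at the start of each window year plus the
# branch taken); throws rrbm_divergence_error on guard trip.
.orbit <- function(params, y0, burn_in, window, guard = 1e12) {
  res <- .orbit_core(params$L1, params$L2, params$Ps, params$p, params$q,
                     params$d, params$R, y0, burn_in, window, guard)
  if (res$diverged_at > 0) {
    stop(errorCondition(
      sprintf("trajectory diverged (|y| > %g) at year %d", guard,
              res$diverged_at),
      class = "rrbm_divergence_error", year = res$diverged_at))
  }
  res
}

#' Full equilibrium and stability report
#'
#' Convenience wrapper combining both fixed points, the regime
#' classification and the numeric Lyapunov exponent of the orbit started at
#' `y0`. `summary()` on an [rrbm] object calls this.
#'
#' @inheritParams lyapunov_numeric
#' @return An object of class `rrbm_analysis`: a list with fields `params`,
#'   `fixed_points`, `scene`, `criteria`, `lyapunov_numeric`, and the
#'   simulation `settings`.
#' @examples
#' rrbm_analyze(rrbm_scenario("fig1d"))
#' @export
rrbm_analyze <- function(params, y0 = 0, burn_in = 1000, window = 2000,
                         guard = 1e12) {
  params <- as_rrbm(params)
  reg <- classify_regime(params)
  lyap_num <- tryCatch(
    lyapunov_numeric(params, y0, burn_in, window, guard),
    rrbm_divergence_error = function(e) NA_real_)
  structure(list(params = params,
                 fixed_points = reg$fixed_points,
                 scene = reg$scene,
                 criteria = reg$criteria,
                 lyapunov_numeric = lyap_num,
                 settings = list(y0 = y0, burn_in = burn_in,
                                 window = window, guard = guard)),
            class = "rrbm_analysis")
}

#' @export
summary.rrbm <- function(object, ...) rrbm_analyze(object, ...)

#' @export
print.rrbm_analysis <- function(x, ...) {
  print(x$params)
  cat(sprintf("Scene: %d\n", x$scene))
  print(x$criteria, row.names = FALSE)
  print(x$fixed_points$sexual)
  print(x$fixed_points$asexual)
  cat(sprintf("Numeric Lyapunov exponent (orbit from y0 = %g): %.6g\n",
              x$settings$y0, x$lyapunov_numeric))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param x an `rrbm_analysis` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_analysis <- function(x, path = NULL) {
  stopifnot(inherits(x, "rrbm_analysis"))
  fp <- function(f) {
    list(which = f$which, value = f$value, exists = f$exists,
         stable = f$stable, lyapunov = f$lyapunov)
  }
  doc <- list(
    params = as.list(coef(x$params)),
    scene = x$scene,
    criteria = x$criteria,
    fixed_points = list(sexual = fp(x$fixed_points$sexual),
                        asexual = fp(x$fixed_points$asexual)),
    lyapunov_numeric = x$lyapunov_numeric,
    settings = x$settings)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
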