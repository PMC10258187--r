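# Non-inferiority and equivalence decisions built from pointwise bands via
# the intersection-union principle: the same (1 - alpha) one-sided bands
# serve both tests, so no multiplicity adjustment is needed, and the
# interval-wise test rejects iff every pointwise test on the grid rejects.
# Boundary comparisons are inclusive (<=, >=).

.new_eqtest <- function(type, contrast, reject, margin, alpha, lower, upper,
                        scope, t0 = NA_real_, interval = c(NA_real_, NA_real_),
                        first_rejection = NA_real_) {
  structure(list(type = type, contrast = contrast, reject = reject,
                 margin = margin, alpha = alpha, lower = lower, upper = upper,
                 scope = scope, t0 = t0, interval = interval,
                 first_rejection = first_rejection),
            class = "nph_eqtest")
}

#' Pointwise non-inferiority / equivalence test at a single time
#'
#' Non-inferiority (H0: contrast >= margin) is rejected iff the upper band
#' at `t0` satisfies `U(t0) <= margin`; equivalence (H0: |contrast| >=
#' margin) additionally requires `L(t0) >= -margin`. Both decisions use the
#' band's own one-sided `(1 - alpha)` bounds.
#'
#' @param band An `nph_band` from [pointwise_bands()] or [np_diff_bands()].
#' @param t0 A time on the band's grid (no interpolation is performed).
#' @param margin Positive margin (`delta` for the survival difference,
#'   `epsilon` for the log hazard ratio).
#' @param type `"equivalence"` or `"noninferiority"`.
#' @return An `nph_eqtest` with the decision and the evaluated bounds.
#' @export
pointwise_test <- function(band, t0, margin,
                           type = c("equivalence", "noninferiority")) {
  type <- match.arg(type)
  if (!inherits(band, "nph_band")) stop("band must be an nph_band",
                                        call. = FALSE)
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0) {
    stop("margin must be a positive number", call. = FALSE)
  }
  i <- which(abs(band$band$t - t0) < 1e-9)
  if (length(i) != 1L) {
    stop("t0 = ", t0, " is not on the band's grid; supply a grid containing ",
         "the test time (no silent interpolation)", call. = FALSE)
  }
  L <- band$band$lower[i]
  U <- band$band$upper[i]
  reject <- if (type == "noninferiority") U <= margin else
    (U <= margin && L >= -margin)
  .new_eqtest(type, band$contrast, reject, margin, band$alpha, L, U,
              scope = "point", t0 = t0)
}

#' Interval-wise non-inferiority / equivalence test
#'
#' Tests the interval hypotheses over `[t1, t2]`: equivalence rejects iff
#' `max U <= margin` and `min L >= -margin` over the band's grid points in
#' the interval (equivalently, iff every pointwise test rejects);
#' non-inferiority uses only the `max U` condition. Also reports the
#' earliest grid time from which the pointwise condition holds through
#' `t2`. The continuum is approximated by the band's grid; grid density is
#' the caller's responsibility.
#'
#' @inheritParams pointwise_test
#' @param interval `c(t1, t2)`; defaults to the band's full grid range.
#' @return An `nph_eqtest`; `$first_rejection` is `NA` if the condition
#'   never holds through `t2`.
#' @export
interval_test <- function(band, margin,
                          type = c("equivalence", "noninferiority"),
                          interval = NULL) {
  type <- match.arg(type)
  if (!inherits(band, "nph_band")) stop("band must be an nph_band",
                                        call. = FALSE)
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0) {
    stop("margin must be a positive number", call. = FALSE)
  }
  interval <- interval %||% range(band$band$t)
  keep <- band$band$t >= interval[1L] - 1e-9 & band$band$t <= interval[2L] + 1e-9
  if (!any(keep)) stop("no grid points inside the test interval",
                       call. = FALSE)
  L <- band$band$lower[keep]
  U <- band$band$upper[keep]
  tt <- band$band$t[keep]
  ok <- if (type == "noninferiority") U <= margin else
    (U <= margin & L >= -margin)
  reject <- all(ok)
  # earliest grid time from which the pointwise condition holds through t2
  holds_through <- rev(cumprod(rev(ok))) == 1
  first <- if (any(holds_through)) tt[which(holds_through)[1L]] else NA_real_
  .new_eqtest(type, band$contrast, reject, margin, band$alpha,
              lower = min(L), upper = max(U), scope = "interval",
              interval = interval, first_rejection = first)
}

#' @export
print.nph_eqtest <- function(x, ...) {
  lab <- if (x$contrast == "surv_diff") "S1 - S2" else "log(h1/h2)"
  if (x$scope == "point") {
    cat(sprintf("%s test for %s at t0 = %g\n", x$type, lab, x$t0))
  } else {
    cat(sprintf("%s test for %s on [%g, %g]\n", x$type, lab,
                x$interval[1L], x$interval[2L]))
  }
  cat(sprintf("  margin = %g, alpha = %g (one-sided bands)\n",
              x$margin, x$alpha))
  if (x$scope == "point") {
    cat(sprintf("  bounds at t0: [%.4f, %.4f]\n", x$lower, x$upper))
  } else {
    cat(sprintf("  min lower = %.4f, max upper = %.4f\n", x$lower, x$upper))
    if (!is.na(x$first_rejection)) {
      cat(sprintf("  pointwise condition holds from t = %g onward\n",
                  x$first_rejection))
    }
  }
  cat(if (x$reject) "  H0 REJECTED" else "  H0 not rejected",
      if (x$reject) sprintf("-> %s claimed\n", x$type) else "\n")
  invisible(x)
}

#' One-line machine-readable record of a test decision
#'
#' @param x An `nph_eqtest`.
#' @return A single tab-separated character line
#'   `type contrast scope t0/interval margin alpha lower upper reject`.
#' @export
format_test_record <- function(x) {
  stopifnot(inherits(x, "nph_eqtest"))
  where <- if (x$scope == "point") format(x$t0) else
    paste0(format(x$interval[1L]), ":", format(x$interval[2L]))
  paste(x$type, x$contrast, x$scope, where, x$margin, x$alpha,
        format(x$lower, digits = 8), format(x$upper, digits = 8),
        as.integer(x$reject), sep = "\t")
}
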