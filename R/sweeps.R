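# Discrete monotonicity of a numeric sequence, with a tolerance that
# absorbs floating-point noise on flat stretches.
monotone_direction <- function(x, tol = 1e-9) {
  d <- diff(x)
  if (all(d >= -tol) && any(d > tol)) return("increasing")
  if (all(d <= tol) && any(d < -tol)) return("decreasing")
  if (all(abs(d) <= tol)) return("constant")
  "non-monotone"
}

#' Sweep a confusion-matrix family over a parameter grid
#'
#' Evaluates the full metric and diagnostic report at every grid point and
#' annotates the result with discrete monotonicity flags for MCC and Kappa
#' (consecutive differences, tolerance `1e-9`) and with the grid location
#' of Kappa's minimum when it is interior.  Grid points whose matrix is
#' degenerate for the metrics are flagged in the `degenerate` column and
#' carry `NA` metrics; they are never silently dropped.
#'
#' @param spec a [family_spec()] object.
#' @param grid strictly increasing numeric vector (length at least 3) of
#'   sweep-parameter values; defaults to [default_grid()].
#' @return an object of class `"sweep_result"`: a list with `family`,
#'   `results` (data.frame with columns `param`, `acc`, `pe`, `kappa`,
#'   `mcc`, `alpha`, `beta`, `asy`, `ent`, `degenerate`), `mcc_monotone`,
#'   `kappa_monotone` and `kappa_argmin` (`NA` if the minimum sits on the
#'   grid boundary).
#' @examples
#' sr <- sweep_family(family_spec("ZA", N = 2), seq(0.5, 20, by = 0.5))
#' sr$kappa_monotone   # "non-monotone": Kappa dips and climbs back
#' sr$mcc_monotone     # "decreasing"
#' @export
sweep_family <- function(spec, grid = default_grid(spec)) {
  stopifnot(inherits(spec, "family_spec"))
  if (length(grid) < 3) stop("grid must have at least 3 points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(grid < spec$domain[1] | grid > spec$domain[2]))
    stop("grid leaves the domain of family ", spec$name)
  na_metrics <- data.frame(acc = NA_real_, pe = NA_real_,
                           kappa = NA_real_, mcc = NA_real_,
                           alpha = NA_real_, beta = NA_real_)
  one <- function(p) {
    cm <- tryCatch(spec$make(p), error = function(e) NULL)
    if (is.null(cm))  # construction itself degenerate at this point
      return(cbind(data.frame(param = p), na_metrics,
                   data.frame(asy = NA_real_, ent = NA_real_),
                   degenerate = TRUE))
    mr <- tryCatch(metric_report(cm), error = function(e) na_metrics)
    dg <- diagnostic_report(cm)
    cbind(data.frame(param = p), mr, dg,
          degenerate = is.na(mr$kappa[1]))
  }
  res <- do.call(rbind, lapply(grid, one))
  ok <- !res$degenerate
  kmin <- NA_real_
  if (any(ok)) {
    i <- which.min(res$kappa[ok])
    if (i > 1 && i < sum(ok)) kmin <- res$param[ok][i]
  }
  structure(list(family = spec,
                 results = res,
                 mcc_monotone = monotone_direction(res$mcc[ok]),
                 kappa_monotone = monotone_direction(res$kappa[ok]),
                 kappa_argmin = kmin),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> family ", x$family$name, ", ",
      nrow(x$results), " points in [",
      format(min(x$results$param)), ", ", format(max(x$results$param)),
      "]\n  MCC ", x$mcc_monotone, "; Kappa ", x$kappa_monotone,
      if (!is.na(x$kappa_argmin))
        paste0(" (interior minimum near ", signif(x$kappa_argmin, 6), ")"),
      "\n", sep = "")
  invisible(x)
}

# Golden-section minimization of f on [lo, hi]; deterministic, assumes f
# unimodal on the bracket.
golden_section <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

#' Locate Kappa's interior minimum along a family
#'
#' A coarse scan (200 points, geometrically spaced when the bracket is
#' positive) followed by golden-section refinement to `1e-8`.  Assumes
#' Kappa is unimodal on the bracket, which holds for the one-false-positive
#' binary families and for the Z_A family, whose Kappa is convex in the
#' sweep parameter.
#'
#' @param spec a [family_spec()] object.
#' @param bracket length-2 numeric `(lo, hi)` bracketing the minimum.
#' @return the minimizing parameter value.
#' @seealso [kappa_min_closed_form()] for the analytic prediction.
#' @export
find_kappa_minimum <- function(spec, bracket) {
  stopifnot(inherits(spec, "family_spec"), length(bracket) == 2,
            bracket[1] < bracket[2])
  f <- function(p) cohen_kappa(spec$make(p))
  grid <- if (bracket[1] > 0)
    exp(seq(log(bracket[1]), log(bracket[2]), length.out = 200))
  else seq(bracket[1], bracket[2], length.out = 200)
  ks <- vapply(grid, f, 0)
  i <- which.min(ks)
  if (i == 1L || i == length(grid))
    stop("no interior minimum of Kappa in the bracket [",
         bracket[1], ", ", bracket[2], "]")
  golden_section(f, grid[i - 1], grid[i + 1])
}

#' Closed-form location of Kappa's minimum for the analyzed families
#'
#' The stationary point of Kappa along the one-false-positive binary
#' sub-families and the Z_A family, obtained by solving `dK/db = 0`
#' symbolically:
#'
#' * `C1_equal_diag` (`[[a, b], [1, a]]`): `b0 = a^2 + (a+1) sqrt(a^2+1)`.
#' * `C1_zero_d` (`[[a, b], [1, 0]]`): `b0 = sqrt(a+1)`.
#' * `C1_unit_d` (`[[a, b], [1, 1]]`): `b0 = a + sqrt(2) (a+1)`
#'   (root of `b^2 - 2ab - a^2 - 4a - 2 = 0`).
#' * `ZA`: `A* = 1 + N sqrt(N (N-1))` (stationarity of the closed-form
#'   Kappa is `(1-A)^2 = N^3 (N-1)`).
#'
#' Beyond this point Kappa increases while the classification keeps
#' worsening — the incoherence this package quantifies.
#'
#' @param spec a [family_spec()] with name `"C1_equal_diag"`,
#'   `"C1_zero_d"`, `"C1_unit_d"` or `"ZA"`.
#' @return the predicted minimizing parameter value.
#' @export
kappa_min_closed_form <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  switch(spec$name,
    C1_equal_diag = {
      a <- spec$fixed$a
      a^2 + (a + 1) * sqrt(a^2 + 1)
    },
    C1_zero_d = sqrt(spec$fixed$a + 1),
    C1_unit_d = {
      a <- spec$fixed$a
      a + sqrt(2) * (a + 1)
    },
    ZA = {
      N <- spec$fixed$N
      1 + N * sqrt(N * (N - 1))
    },
    stop("no closed-form Kappa minimum implemented for family ",
         spec$name))
}

#' Closed-form MCC and Kappa along the Z_A family
#'
#' For the `N x N` all-ones matrix with top-right entry `A`:
#' `MCC(A) = (1-A) / ((N-1) (N^2 - 2 (1-A)))` and
#' `K(A) = N (1-A) / ((1-A)^2 - 2 N (N-1) (1-A) + N^3 (N-1))`.
#' Both vanish at `A = 1` (the symmetric all-ones matrix) and for `A != 1`
#' they satisfy the reciprocal relation `1/MCC - 1/K = (A-1)/N`.  As
#' `A -> Inf`, MCC tends to `-1/(2(N-1))` while Kappa creeps back to `0`
#' from below.
#'
#' @param n_classes integer `N >= 2`.
#' @param A non-negative real.
#' @return named numeric vector `c(mcc = , kappa = )`.
#' @export
zA_closed_forms <- function(n_classes, A) {
  if (n_classes < 2) stop("Z_A family needs at least 2 classes")
  if (A < 0) stop("Z_A family requires A >= 0")
  N <- n_classes
  u <- 1 - A
  c(mcc = u / ((N - 1) * (N^2 - 2 * u)),
    kappa = N * u / (u^2 - 2 * N * (N - 1) * u + N^3 * (N - 1)))
}

#' Kappa as a function of MCC on the C0 family
#'
#' On the binary family with no false positives (`c = 0`) the two
#' statistics are functionally linked: `K = 2 m^2 / (1 + m^2)` where
#' `m = MCC` ranges in `(0, 1)`.  The link is monotonically increasing, so
#' on this family the two measures always agree in direction.
#'
#' @param m MCC value in `(0, 1]`.
#' @return the corresponding Kappa value.
#' @export
c0_kappa_from_mcc <- function(m) {
  if (any(m <= 0 | m > 1))
    stop("the C0 functional relation is defined for MCC in (0, 1]")
  2 * m^2 / (1 + m^2)
}

#' Largest gap between MCC and Kappa on the C0 family
#'
#' Maximizes `g(m) = m - 2 m^2 / (1 + m^2)` over `m` in `(0, 1)` by
#' golden-section search (the stationary point solves
#' `(1 + m^2)^2 = 4 m`).  The gap peaks at about 0.13, attained near
#' MCC = 0.3.
#'
#' @param tol bracket tolerance of the search.
#' @return named numeric vector `c(argmax_mcc = , gap = )`.
#' @export
c0_max_gap <- function(tol = 1e-10) {
  g <- function(m) m - c0_kappa_from_mcc(m)
  m_star <- golden_section(function(m) -g(m), 1e-12, 1 - 1e-12, tol = tol)
  c(argmax_mcc = m_star, gap = g(m_star))
}

#' Check the binary ordering chains between Kappa, MCC and their bounds
#'
#' For a binary matrix `[[a, b], [c, d]]` with `c = 0` or `c = 1`,
#' evaluates Kappa, MCC and the two bounding fractions
#' `(ad - b c*) / ((a+b)(d+b))` and `(ad - b c*) / ((a+1)(d+1))` (for the
#' `c = 1` case; for `c = 0` the bounds are `ad/((a+b)(b+d))` and `1`) and
#' verifies the strict ordering chain dictated by the sign of `ad - b` and
#' the position of `b` relative to 1.  Boundary cases (`b = 1`, `ad = b`)
#' are reported as equality branches, not failures.
#'
#' @param a,b,d cells of the binary matrix; the false-positive cell is
#'   fixed by `case`.
#' @param case `"c0"` (no false positives) or `"c1"` (one false positive).
#' @param tol slack used for the strict inequalities.
#' @return a list with `case`, `branch` (human-readable label), `kappa`,
#'   `mcc`, `bounds` (numeric, the applicable bounding fractions) and
#'   `holds` (logical: did the whole chain hold).
#' @export
binary_ordering_check <- function(a, b, d, case = c("c1", "c0"),
                                  tol = 1e-12) {
  case <- match.arg(case)
  cc <- if (case == "c0") 0 else 1
  cm <- make_binary(a, b, cc, d)
  k <- cohen_kappa(cm)
  m <- mcc_multiclass(cm)
  chain_ok <- function(v) all(diff(v) > -tol)
  if (case == "c0") {
    lower <- a * d / ((a + b) * (b + d))
    return(list(case = case, branch = "0 < ad/((a+b)(b+d)) < K < MCC < 1",
                kappa = k, mcc = m, bounds = c(lower = lower, upper = 1),
                holds = chain_ok(c(0, lower, k, m, 1))))
  }
  det <- a * d - b
  f_marg <- det / ((a + b) * (d + b))   # marginal-product bound
  f_unit <- det / ((a + 1) * (d + 1))   # unit-cell bound
  if (a == 0 && d == 0) {
    if (b == 1)
      return(list(case = case, branch = "a=d=0, b=1: K = MCC = -1",
                  kappa = k, mcc = m, bounds = c(),
                  holds = abs(k + 1) < tol && abs(m + 1) < tol))
    return(list(case = case,
                branch = "a=d=0, b!=1: MCC = -1 < K = -2b/(1+b^2) < 0",
                kappa = k, mcc = m, bounds = c(),
                holds = abs(m + 1) < tol &&
                  abs(k + 2 * b / (1 + b^2)) < 1e-9 && k < 0))
  }
  if (abs(det) < tol)
    return(list(case = case, branch = "ad = b: K = MCC = 0",
                kappa = k, mcc = m, bounds = c(),
                holds = abs(k) < 1e-9 && abs(m) < 1e-9))
  if (abs(b - 1) < tol)
    return(list(case = case,
                branch = "b = 1 (symmetric): K = MCC = (ad-1)/((a+1)(d+1))",
                kappa = k, mcc = m, bounds = c(value = f_unit),
                holds = abs(k - m) < 1e-9 && abs(k - f_unit) < 1e-9))
  chain <- if (det > 0) {
    if (b > 1) c(0, f_marg, k, m, f_unit, 1)
    else       c(0, f_unit, k, m, f_marg, 1)
  } else {
    if (b > 1) c(max(-1, f_unit), m, k, f_marg, 0)
    else       c(max(-1, f_marg), m, k, f_unit, 0)
  }
  branch <- paste0(if (det > 0) "ad > b" else "ad < b", ", b ",
                   if (b > 1) "> 1" else "< 1")
  list(case = case, branch = branch, kappa = k, mcc = m,
       bounds = c(marginal = f_marg, unit = f_unit),
       holds = chain_ok(chain))
}

#' Roots where the C1_equal_diag lower bound touches -1
#'
#' For `[[a, b], [1, a]]` with `0 < a < (sqrt(2)-1)/2`, the bound
#' `(a^2 - b)/(a + b)^2` reaches `-1` at the two roots of
#' `b^2 - (1 - 2a) b + 2 a^2 = 0`, i.e.
#' `b_{1,2} = ((1-2a) -+ sqrt((1-2a)^2 - 8 a^2)) / 2`.  Returns `NA`s when
#' the discriminant is negative.
#'
#' @param a the common diagonal value.
#' @return numeric vector `c(b1 = , b2 = )`.
#' @export
c1_equal_diag_boundary_roots <- function(a) {
  disc <- (1 - 2 * a)^2 - 8 * a^2
  if (disc < 0) return(c(b1 = NA_real_, b2 = NA_real_))
  c(b1 = ((1 - 2 * a) - sqrt(disc)) / 2,
    b2 = ((1 - 2 * a) + sqrt(disc)) / 2)
}

#' Classify a family sweep into the agreement or disagreement regime
#'
#' Implements the summary rule of the study: along a one-parameter family,
#' Kappa and MCC move in opposite directions (a worse classifier scoring a
#' higher Kappa) exactly when the off-diagonal entropy decreases to zero,
#' which in turn forces the asymmetry to grow without bound.
#'
#' The entropy trend over the grid is classified as `"constant"` (total
#' variation below `1e-9`), `"decreasing_to_zero"` (decreasing on the tail
#' of the grid and ending below `zero_frac` of the attainable maximum
#' `log2(N^2 - N)`), or `"decreasing_to_positive_limit"`.  The asymmetry
#' trend is `"constant"` or `"increasing_unbounded"` by the same tail
#' logic.  The label is `"disagreement"` iff the entropy trend is
#' `"decreasing_to_zero"`; as a cross-check, the sign concordance of the
#' per-step changes of Kappa and MCC on the tail is computed and a warning
#' is raised if it contradicts the label.  A trend that changes direction
#' within the final 20% of the grid raises an error: the sweep is
#' inconclusive and the grid should be extended.
#'
#' @param sr a [sweep_family()] result whose grid reaches large parameter
#'   values (see [default_grid()]).
#' @param zero_frac fraction of the maximum entropy below which the tail
#'   counts as "reaching zero".
#' @return an object of class `"regime_label"`: list with `label`
#'   (`"agreement"`/`"disagreement"`), `entropy_trend`, `asymmetry_trend`,
#'   `tail_concordance` (fraction of tail steps where Kappa and MCC move
#'   the same way).
#' @export
classify_regime <- function(sr, zero_frac = 0.10) {
  stopifnot(inherits(sr, "sweep_result"))
  res <- sr$results[!sr$results$degenerate, ]
  n <- nrow(res)
  if (n < 10) stop("sweep too short to classify")
  tail_idx <- seq.int(max(1L, ceiling(0.8 * n)), n)
  if (length(tail_idx) < 3) tail_idx <- seq.int(n - 2L, n)
  N <- nrow(sr$family$make(res$param[1]))
  ent_max_possible <- log2(N^2 - N)
  ent <- res$ent
  asy <- res$asy
  tol <- 1e-9

  ent_trend <- if (max(ent) - min(ent) < tol) {
    "constant"
  } else {
    tail_dir <- monotone_direction(ent[tail_idx], tol)
    if (!tail_dir %in% c("decreasing", "constant"))
      stop("inconclusive sweep, extend grid: entropy trend changes ",
           "within the last 20% of the grid (", tail_dir, ")")
    if (ent[n] < zero_frac * ent_max_possible) "decreasing_to_zero"
    else "decreasing_to_positive_limit"
  }

  asy_scale <- max(abs(asy), 1)
  asy_trend <- if ((max(asy) - min(asy)) < tol * asy_scale) {
    "constant"
  } else {
    tail_dir <- monotone_direction(asy[tail_idx], tol * asy_scale)
    if (tail_dir != "increasing")
      stop("inconclusive sweep, extend grid: asymmetry trend on the ",
           "tail is ", tail_dir)
    "increasing_unbounded"
  }

  label <- if (ent_trend == "decreasing_to_zero") "disagreement"
           else "agreement"

  # A tail step enters the concordance count only when BOTH metrics move
  # appreciably (> 1e-5 of their full-grid variation): at the far end of a
  # long grid both statistics converge to their limits and sub-noise creep
  # in opposite directions carries no information about the regime.
  dk <- diff(res$kappa[tail_idx])
  dm <- diff(res$mcc[tail_idx])
  k_act <- max(tol, 1e-5 * diff(range(res$kappa)))
  m_act <- max(tol, 1e-5 * diff(range(res$mcc)))
  active <- abs(dk) > k_act & abs(dm) > m_act
  conc <- if (any(active)) mean(sign(dk[active]) == sign(dm[active]))
          else 1
  expected_conc <- if (label == "agreement") conc >= 0.5 else conc <= 0.5
  if (!expected_conc)
    warning("regime label '", label, "' disagrees with the empirical ",
            "Kappa/MCC concordance (", signif(conc, 3), ") on the tail")
  structure(list(label = label, entropy_trend = ent_trend,
                 asymmetry_trend = asy_trend, tail_concordance = conc),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("<regime_label> ", x$label, "\n  entropy: ", x$entropy_trend,
      "; asymmetry: ", x$asymmetry_trend,
      "; tail Kappa/MCC concordance: ", signif(x$tail_concordance, 3),
      "\n", sep = "")
  invisible(x)
}
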