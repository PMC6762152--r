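#' Construct a binary confusion matrix from its four cells
#'
#' Builds `[[a, b], [c, d]]` with the convention a = true positive,
#' b = false negative, c = false positive, d = true negative (rows = actual
#' positive/negative).  Marginal positivity (`a+b`, `c+d`, `a+c`, `b+d`
#' all `> 0`) is required so that Kappa and MCC are defined.
#'
#' @param a,b,c,d non-negative reals.
#' @return a 2x2 numeric matrix.
#' @examples
#' make_binary(1, 5, 0, 1)     # a C0-type matrix (no false positives)
#' make_binary(0.2, 5, 1, 0.2) # representative of [[1,25],[5,1]] / 5
#' @export
make_binary <- function(a, b, c, d) {
  cm <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  validate_confusion(cm)
  cm
}

#' The Z_A family: all ones except the top-right corner
#'
#' An `N x N` matrix of ones with entry `(1, N)` set to `A`: one dominant
#' actual class (row 1) whose excess mass is entirely misclassified into
#' class `N`.  A canonical pathological unbalanced scenario: as `A` grows
#' the classification only gets worse, MCC decreases monotonically, yet
#' Kappa turns around and climbs back towards zero after an interior
#' minimum at `A = 1 + N * sqrt(N * (N - 1))`.  For `N = 2` this is the
#' binary matrix `[[1, A], [1, 1]]`.
#'
#' @param n_classes integer `N >= 2`.
#' @param A non-negative real.
#' @return an `N x N` numeric matrix.
#' @seealso [zA_closed_forms()] for the closed-form Kappa and MCC.
#' @export
make_zA <- function(n_classes, A) {
  if (n_classes < 2) stop("Z_A family needs at least 2 classes")
  if (A < 0) stop("Z_A family requires A >= 0")
  cm <- matrix(1, n_classes, n_classes)
  cm[1, n_classes] <- A
  cm
}

# Domains of the five 3x3 example families, sweep parameter A.
.example_domains <- list(
  M1 = c(1, Inf), M2 = c(1, Inf), M3 = c(0, 999),
  M4 = c(50, 100), M5 = c(1, Inf))

#' The five 3x3 example families M1-M5
#'
#' Parametric 3x3 confusion matrices, each with a unit diagonal and
#' off-diagonal cells driven by a single parameter `A`, chosen to decouple
#' the two structural diagnostics (Frobenius asymmetry, off-diagonal
#' entropy):
#'
#' * `M1(A)`: rows `(1, 2A, A / A, 1, 2A / A, A, 1)`, `A >= 1`.  Asymmetry
#'   `2A` grows without bound but the off-diagonal distribution keeps the
#'   same shape, so entropy is constant at 2.5 bits.
#' * `M2(A)`: rows `(1, A, 1 / 1, 1, A^2 / 1, 1, 1)`, `A > 1`.  One cell
#'   dominates: entropy decreases to zero and asymmetry diverges.
#' * `M3(A)`: with `B = 1000 - A`, cyclic rows
#'   `(1, B, B+100 / B+100, 1, B / B, B+100, 1)`, `A` in `[0, 999]`.  The
#'   off-diagonal multiset is three `B`'s and three `B+100`'s, so asymmetry
#'   is constant at `100 * sqrt(6)` while entropy decreases to the positive
#'   limit `log2(3)`.
#' * `M4(A)`: with `B = 100 - A`, rows `(1, A, 1 / A^2, 1, B / 1, B^2, 1)`,
#'   `A` in `[50, 100]`.  Entropy decreases towards zero as `A` moves away
#'   from 50, asymmetry grows.
#' * `M5(A)`: rows `(1, 2A, A / A, 1, A+100 / A, A, 1)`, `A >= 1`.
#'   Asymmetry `sqrt(2 * (A^2 + 100^2))` diverges but entropy tends to the
#'   positive limit `log2(7) - 2/7`.
#'
#' @param name one of `"M1" ... "M5"`.
#' @param A sweep parameter, within the family's domain above.
#' @return a 3x3 numeric matrix.
#' @examples
#' make_example_family("M2", 10)
#' @export
make_example_family <- function(name, A) {
  name <- match.arg(name, names(.example_domains))
  dom <- .example_domains[[name]]
  lo_ok <- if (name == "M2") A > dom[1] else A >= dom[1]
  if (!lo_ok || A > dom[2])
    stop(name, " requires A in ",
         if (name == "M2") "(" else "[", dom[1], ", ", dom[2], "]",
         ", got ", A)
  B <- switch(name, M3 = 1000 - A, M4 = 100 - A, NA_real_)
  rows <- switch(name,
    M1 = c(1, 2 * A, A,       A, 1, 2 * A,       A, A, 1),
    M2 = c(1, A, 1,           1, 1, A^2,         1, 1, 1),
    M3 = c(1, B, B + 100,     B + 100, 1, B,     B, B + 100, 1),
    M4 = c(1, A, 1,           A^2, 1, B,         1, B^2, 1),
    M5 = c(1, 2 * A, A,       A, 1, A + 100,     A, A, 1))
  matrix(rows, 3, 3, byrow = TRUE)
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random integer confusion matrix for property tests
#'
#' Draws a reproducible `N x N` integer matrix with every cell at least 1
#' (so all row and column sums are positive) by spreading `total - N^2`
#' extra counts multinomially over the cells.  With `symmetric = TRUE` the
#' diagonal and the upper triangle are drawn the same way and the upper
#' triangle is mirrored, so the result equals its transpose; the realized
#' grand total then exceeds `total` because mirrored cells count twice.
#'
#' @param n_classes integer `N >= 2`.
#' @param total target number of cases; must be at least `N^2`
#'   (`N(N+1)/2` when `symmetric`).
#' @param seed optional integer seed; the global RNG stream is not
#'   disturbed.
#' @param symmetric if `TRUE`, return a symmetric matrix.
#' @return an integer-valued numeric matrix.
#' @export
random_confusion <- function(n_classes, total, seed = NULL,
                             symmetric = FALSE) {
  if (n_classes < 2) stop("need at least 2 classes")
  n_cells <- if (symmetric) n_classes * (n_classes + 1) / 2
             else n_classes^2
  if (total < n_cells)
    stop("infeasible constraints: total must be at least ", n_cells,
         " so that every cell can be positive")
  local_seed(seed, {
    extra <- as.vector(stats::rmultinom(1, total - n_cells,
                                        rep(1, n_cells))) + 1
    cm <- matrix(0, n_classes, n_classes)
    if (symmetric) {
      cm[upper.tri(cm, diag = TRUE)] <- extra
      cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
    } else {
      cm[] <- extra
    }
    cm
  })
}

#' Specification of a one-parameter confusion-matrix family
#'
#' Bundles a family name, its fixed parameters and the name of the swept
#' parameter with a generator function, for use by [sweep_family()],
#' [find_kappa_minimum()] and [classify_regime()].  Available families and
#' their fixed parameters:
#'
#' * `"C0"` (`a`, `d`): `[[a, b], [0, d]]`, sweep `b` — the
#'   perfectly-classified-negatives binary case, where Kappa and MCC agree.
#' * `"C1"` (`a`, `d`): `[[a, b], [1, d]]`, sweep `b` — one false positive;
#'   the binary disagreement case.
#' * `"C1_equal_diag"` (`a`): `[[a, b], [1, a]]`.
#' * `"C1_zero_d"` (`a`): `[[a, b], [1, 0]]`.
#' * `"C1_unit_d"` (`a`): `[[a, b], [1, 1]]`.
#' * `"ZA"` (`N`): [make_zA()] matrices, sweep `A`.
#' * `"M1" ... "M5"`: [make_example_family()] matrices, sweep `A`.
#'
#' @param name family name, see above.
#' @param ... fixed parameters (`a`, `d`, `N`) where the family needs them.
#' @return an object of class `"family_spec"`: a list with elements `name`,
#'   `fixed` (named list), `sweep_param`, `make` (function of the sweep
#'   parameter) and `domain` (length-2 numeric, possibly infinite).
#' @examples
#' sp <- family_spec("ZA", N = 3)
#' sp$make(10)
#' @export
family_spec <- function(name, ...) {
  name <- match.arg(name, c("C0", "C1", "C1_equal_diag", "C1_zero_d",
                            "C1_unit_d", "ZA", "M1", "M2", "M3", "M4",
                            "M5"))
  fixed <- list(...)
  need <- function(p, default = NULL) {
    if (!is.null(fixed[[p]])) return(fixed[[p]])
    if (is.null(default)) stop("family ", name, " needs parameter '", p, "'")
    default
  }
  spec <- switch(name,
    C0 = {
      a <- need("a", 1); d <- need("d", 1)
      list(fixed = list(a = a, d = d), sweep_param = "b",
           make = function(b) make_binary(a, b, 0, d),
           domain = c(0, Inf))
    },
    C1 = {
      a <- need("a", 1); d <- need("d", 1)
      list(fixed = list(a = a, d = d), sweep_param = "b",
           make = function(b) make_binary(a, b, 1, d),
           domain = c(0, Inf))
    },
    C1_equal_diag = {
      a <- need("a")
      list(fixed = list(a = a), sweep_param = "b",
           make = function(b) make_binary(a, b, 1, a),
           domain = c(0, Inf))
    },
    C1_zero_d = {
      a <- need("a")
      list(fixed = list(a = a), sweep_param = "b",
           make = function(b) make_binary(a, b, 1, 0),
           domain = c(0, Inf))
    },
    C1_unit_d = {
      a <- need("a")
      list(fixed = list(a = a), sweep_param = "b",
           make = function(b) make_binary(a, b, 1, 1),
           domain = c(0, Inf))
    },
    ZA = {
      N <- need("N", 2)
      list(fixed = list(N = N), sweep_param = "A",
           make = function(A) make_zA(N, A),
           domain = c(0, Inf))
    },
    {
      list(fixed = list(), sweep_param = "A",
           make = function(A) make_example_family(name, A),
           domain = .example_domains[[name]])
    })
  structure(c(list(name = name), spec), class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  fx <- if (length(x$fixed))
    paste(names(x$fixed), unlist(x$fixed), sep = " = ", collapse = ", ")
  else "none"
  cat("<family_spec> ", x$name, "  fixed: ", fx,
      "  sweep: ", x$sweep_param,
      " in [", x$domain[1], ", ", x$domain[2], "]\n", sep = "")
  invisible(x)
}

#' Default sweep grid for a family
#'
#' Geometric spacing when the sweep parameter is unbounded above (the
#' interesting behaviour spans orders of magnitude), linear otherwise.
#' Lower endpoints avoid degenerate boundary matrices (e.g. `b = 0` in the
#' binary families).  `M5`'s grid extends to `1e6` because its off-diagonal
#' entropy passes through an interior maximum (near `A = 400`) before
#' settling towards its positive limit, and regime classification inspects
#' the tail of the grid, which should sit well past that turning point.
#'
#' @param spec a [family_spec()] object.
#' @param n number of grid points.
#' @return strictly increasing numeric vector of length `n`.
#' @export
default_grid <- function(spec, n = 200) {
  stopifnot(inherits(spec, "family_spec"))
  geom <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = n))
  switch(spec$name,
    C0 = ,
    C1 = ,
    C1_equal_diag = ,
    C1_zero_d = ,
    C1_unit_d = geom(0.01, 1e4),
    ZA = geom(0.01, 1e4),
    M1 = geom(1, 1e4),
    M2 = geom(1.01, 1e4),
    M3 = seq(0, 999, length.out = n),
    M4 = seq(50, 100, length.out = n),
    M5 = geom(1, 1e6))
}
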