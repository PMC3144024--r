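#' @useDynLib ffca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Module-level state: LP call counters and the last feasibility witness.
the <- new.env(parent = emptyenv())
the$lp_calls <- integer()
the$last_witness <- NULL

#' LP call counters
#'
#' Every public feasibility or optimality query counts as one LP, grouped by a
#' caller-supplied label (e.g. the dispatch case that issued it). Internal
#' simplex phases are not counted separately.
#'
#' @return `lp_calls()` returns a named integer vector of counts per label;
#'   `lp_calls_reset()` zeroes it.
#' @export
lp_calls <- function() the$lp_calls

#' @rdname lp_calls
#' @export
lp_calls_reset <- function() {
  the$lp_calls <- integer()
  invisible(NULL)
}

count_lp <- function(label) {
  cur <- the$lp_calls
  cur[label] <- (if (label %in% names(cur)) cur[[label]] else 0L) + 1L
  the$lp_calls <- cur
}

#' Numerical tolerances
#'
#' `eps_feas` is the constraint tolerance below which a point is accepted as
#' satisfying its system; `zero_tol` is the magnitude below which a witness
#' entry is treated as zero when supports are inspected; `eps_ratio` is the
#' agreement tolerance between the max- and min-ratio LPs used to decide full
#' coupling.
#' @keywords internal
ffca_tol <- function(eps_feas = 1e-9, zero_tol = 1e-8, eps_ratio = 1e-6) {
  list(eps_feas = eps_feas, zero_tol = zero_tol, eps_ratio = eps_ratio)
}

#' Construct a linear feasibility system
#'
#' Declarative encoding of one system such as (P1): equality constraints
#' `A v = b` (typically the metabolite balances `S v = 0`), a set of variables
#' constrained non-negative, and pinned variables fixed to constants (the
#' cone's scale invariance lets every "v != 0" condition be realized as a pin
#' to +1 or -1).
#'
#' @param A numeric matrix of equality-constraint coefficients.
#' @param b right-hand side (default all zeros).
#' @param nonneg integer indices of variables constrained `>= 0`.
#' @param pinned named list or numeric vector: names/indices of pinned
#'   variables mapped to their fixed values.
#' @return an object of class `feasibility_system`.
#' @examples
#' sys <- feasibility_system(matrix(c(1, -1), 1), nonneg = 1:2,
#'                           pinned = c("1" = 1))
#' is_feasible(sys)
#' @export
feasibility_system <- function(A, b = NULL, nonneg = integer(),
                               pinned = numeric()) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  if (is.null(b)) b <- rep(0, nrow(A))
  stopifnot(length(b) == nrow(A))
  nonneg <- as.integer(nonneg)
  pin_idx <- as.integer(names(pinned))
  pin_val <- as.numeric(pinned)
  if (length(pin_idx) != length(pin_val) || anyNA(pin_idx))
    stop("`pinned` must be a named vector: index -> fixed value", call. = FALSE)
  if (anyDuplicated(pin_idx))
    stop("a variable cannot be pinned twice", call. = FALSE)
  idx_all <- c(nonneg, pin_idx)
  if (length(idx_all) > 0L && (min(idx_all) < 1L || max(idx_all) > n))
    stop("variable index out of range", call. = FALSE)
  clash <- pin_idx %in% nonneg & pin_val < 0
  if (any(clash))
    stop("pinned value conflicts with a non-negativity constraint on variable ",
         paste(pin_idx[clash], collapse = ", "), call. = FALSE)
  structure(list(A = A, b = as.numeric(b), nonneg = nonneg,
                 pin_idx = pin_idx, pin_val = pin_val, n = n),
            class = "feasibility_system")
}

#' @export
print.feasibility_system <- function(x, ...) {
  cat(sprintf(
    "<feasibility_system> %d equalities, %d variables (%d nonneg, %d pinned)\n",
    nrow(x$A), x$n, length(x$nonneg), length(x$pin_idx)))
  invisible(x)
}

# Translate a feasibility system plus objective into standard form
#   min c'z, A z = b, z >= 0
# by substituting pins into the rhs and splitting free variables into
# positive and negative parts. Returns the pieces needed to solve and to map
# a standard-form point back to the original coordinates.
standardize_system <- function(sys, objective = NULL) {
  keep <- setdiff(seq_len(sys$n), sys$pin_idx)
  b <- sys$b
  if (length(sys$pin_idx) > 0L)
    b <- b - as.vector(sys$A[, sys$pin_idx, drop = FALSE] %*% sys$pin_val)
  is_nn <- keep %in% sys$nonneg
  ncols <- length(keep) + sum(!is_nn)
  A_std <- matrix(0, nrow(sys$A), ncols)
  c_std <- numeric(ncols)
  map_pos <- integer(length(keep))   # standard-form column of v_k (positive part)
  map_neg <- integer(length(keep))   # column of negative part, 0 if none
  col <- 0L
  for (kk in seq_along(keep)) {
    k <- keep[[kk]]
    col <- col + 1L
    A_std[, col] <- sys$A[, k]
    map_pos[[kk]] <- col
    if (!is_nn[[kk]]) {
      col <- col + 1L
      A_std[, col] <- -sys$A[, k]
      map_neg[[kk]] <- col
    }
  }
  if (!is.null(objective)) {
    for (kk in seq_along(keep)) {
      c_std[map_pos[[kk]]] <- objective[[keep[[kk]]]]
      if (map_neg[[kk]] > 0L)
        c_std[map_neg[[kk]]] <- -objective[[keep[[kk]]]]
    }
  }
  list(A = A_std, b = b, c = c_std, keep = keep,
       map_pos = map_pos, map_neg = map_neg)
}

# Reconstruct a full-length point from a standard-form solution.
destandardize_point <- function(sys, std, z) {
  v <- numeric(sys$n)
  if (length(sys$pin_idx) > 0L) v[sys$pin_idx] <- sys$pin_val
  for (kk in seq_along(std$keep)) {
    val <- z[[std$map_pos[[kk]]]]
    if (std$map_neg[[kk]] > 0L) val <- val - z[[std$map_neg[[kk]]]]
    v[[std$keep[[kk]]]] <- val
  }
  v
}

solve_standard <- function(sys, objective = NULL) {
  std <- standardize_system(sys, objective)
  if (ncol(std$A) == 0L) {
    # every variable pinned: the system is a plain consistency check
    ok <- all(abs(std$b) <= 1e-9)
    z <- numeric(0)
    status <- if (ok) 0L else 1L
    return(list(status = status, std = std, z = z))
  }
  res <- .simplex_cpp(std$A, std$b, std$c)
  if (res$status == 3L)
    stop("LP solver hit its iteration limit; refusing to guess feasibility",
         call. = FALSE)
  list(status = res$status, std = std, z = as.numeric(res$x))
}

#' Test feasibility of a linear system
#'
#' Decides whether any point satisfies all constraints, by solving an LP with
#' a constant objective so the solver stops at the first feasible basis. The
#' witness point of the last feasible call is kept for inspection via
#' [last_witness()].
#'
#' @param sys a [feasibility_system].
#' @param count_as label under which to count this LP (see [lp_calls()]).
#' @return `TRUE` or `FALSE`. Solver breakdowns raise an error; they are never
#'   silently mapped to infeasibility.
#' @export
is_feasible <- function(sys, count_as = "feasibility") {
  stopifnot(inherits(sys, "feasibility_system"))
  count_lp(count_as)
  sol <- solve_standard(sys, objective = NULL)
  if (sol$status == 0L) {
    the$last_witness <- destandardize_point(sys, sol$std, sol$z)
    TRUE
  } else if (sol$status == 1L) {
    FALSE
  } else {
    stop("unexpected solver status for a constant-objective LP", call. = FALSE)
  }
}

#' @rdname is_feasible
#' @export
last_witness <- function() the$last_witness

#' Optimize one coordinate over a linear system
#'
#' Maximizes or minimizes `v[index]` subject to the system's constraints.
#' The backend reports unboundedness explicitly (an improving column with no
#' blocking ratio), so "no finite ratio" outcomes are first-class rather than
#' numerical accidents.
#'
#' @param sys a [feasibility_system].
#' @param index variable (reaction) index to optimize.
#' @param sense `"max"` or `"min"`.
#' @param count_as label for the LP counter.
#' @return a list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `point` (flux vector, when available) and `objective`.
#' @export
lp_optimize <- function(sys, index, sense = c("max", "min"),
                        count_as = "optimize") {
  stopifnot(inherits(sys, "feasibility_system"))
  sense <- match.arg(sense)
  count_lp(count_as)
  obj <- numeric(sys$n)
  obj[[index]] <- if (sense == "max") -1 else 1   # standard form minimizes
  if (index %in% sys$pin_idx) {
    # objective is constant; status reduces to plain feasibility
    sol <- solve_standard(sys, objective = NULL)
    if (sol$status == 1L) return(list(status = "infeasible", point = NULL,
                                      objective = NA_real_))
    v <- destandardize_point(sys, sol$std, sol$z)
    return(list(status = "optimal", point = v, objective = v[[index]]))
  }
  sol <- solve_standard(sys, obj)
  if (sol$status == 1L)
    return(list(status = "infeasible", point = NULL, objective = NA_real_))
  if (sol$status == 2L)
    return(list(status = "unbounded", point = NULL, objective = NA_real_))
  v <- destandardize_point(sys, sol$std, sol$z)
  list(status = "optimal", point = v, objective = v[[index]])
}
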