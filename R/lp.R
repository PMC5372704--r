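# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u
# with a dense revised simplex that always terminates on a vertex, so the
# reduced costs of the returned basis are well defined (needed for the
# sensitivity analysis).  Dimensions here are small (tens of metabolites and
# reactions), so the basis is refactorised with solve() at every iteration
# rather than updated incrementally.

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) \code{obj'x} subject to \code{A x = b} and
#' \code{lower <= x <= upper}, using a two-phase primal simplex on bounded
#' variables. All bounds must be finite; constraint-based models use a large
#' finite proxy (conventionally 1000) for unbounded fluxes.
#'
#' @param A constraint matrix (dense or sparse), one row per equality.
#' @param b right-hand side vector (length \code{nrow(A)}).
#' @param obj objective coefficients (length \code{ncol(A)}).
#' @param lower,upper finite variable bounds.
#' @param sense \code{"max"} or \code{"min"}.
#' @param tol feasibility/optimality tolerance (default \code{1e-9}).
#' @param max_iter iteration cap per phase.
#'
#' @return A list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"iteration_limit"}),
#'   \code{x} (primal solution), \code{objective}, \code{duals} (one per
#'   constraint row), \code{reduced_costs} (dObjective/dx at the optimal
#'   basis; zero for basic variables), \code{basis} (indices of basic
#'   variables) and \code{iterations}.
#'
#' @examples
#' # max x1 + x2 with x1 = x2 (one mass balance), x1 in [0, 4], x2 in [0, 7]
#' lp_solve(matrix(c(1, -1), 1, 2), 0, c(1, 1), c(0, 0), c(4, 7))$objective
#' @export
lp_solve <- function(A, b, obj, lower, upper, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  b <- as.numeric(b)
  obj <- as.numeric(obj)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  stopifnot(length(b) == m, length(obj) == n,
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("lp_solve requires finite variable bounds")
  if (any(lower > upper + tol))
    stop("lp_solve: lower bound exceeds upper bound")

  flip <- sense == "min"
  cvec <- if (flip) -obj else obj

  if (n == 0L) {
    feas <- all(abs(b) <= tol)
    return(list(status = if (feas) "optimal" else "infeasible",
                x = numeric(0), objective = 0,
                duals = rep(0, m), reduced_costs = numeric(0),
                basis = integer(0), iterations = 0L))
  }

  if (m == 0L) {
    x <- ifelse(cvec > 0, upper, lower)
    objective <- sum(cvec * x)
    return(list(status = "optimal", x = x,
                objective = if (flip) -objective else objective,
                duals = numeric(0),
                reduced_costs = if (flip) -cvec else cvec,
                basis = integer(0), iterations = 0L))
  }

  # start each structural variable at the bound nearer zero
  x0 <- ifelse(abs(lower) <= abs(upper), lower, upper)
  r <- b - as.numeric(A %*% x0)

  # artificial columns: signed unit vectors so artificial values start >= 0
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  ntot <- n + m
  lfull <- c(lower, rep(0, m))
  ufull <- c(upper, rep(Inf, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)

  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- .simplex_phase(Afull, c1, lfull, ufull, x, basis, tol, max_iter)
  if (ph1$status == "iteration_limit")
    return(.lp_fail("iteration_limit", m, n, ph1$iterations))
  if (-ph1$objective > 1e-7)
    return(list(status = "infeasible", x = numeric(0), objective = NA_real_,
                duals = rep(NA_real_, m), reduced_costs = rep(NA_real_, n),
                basis = integer(0), iterations = ph1$iterations))

  # phase 2: pin artificials at zero; basic artificials may remain at zero
  x <- ph1$x
  x[(n + 1L):ntot] <- 0
  ufull[(n + 1L):ntot] <- 0
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplex_phase(Afull, c2, lfull, ufull, x, ph1$basis, tol, max_iter)
  if (ph2$status != "optimal")
    return(.lp_fail(ph2$status, m, n, ph1$iterations + ph2$iterations))

  xs <- ph2$x[seq_len(n)]
  # snap to bounds within tolerance
  xs <- pmin(pmax(xs, lower), upper)
  snap <- abs(xs - lower) < 1e-9
  xs[snap] <- lower[snap]
  snap <- abs(xs - upper) < 1e-9
  xs[snap] <- upper[snap]

  z <- ph2$reduced_costs[seq_len(n)]
  y <- ph2$duals
  if (flip) {
    z <- -z
    y <- -y
  }
  list(status = "optimal", x = xs,
       objective = sum(obj * xs),
       duals = y, reduced_costs = z,
       basis = ph2$basis[ph2$basis <= n],
       iterations = ph1$iterations + ph2$iterations)
}

.lp_fail <- function(status, m, n, it) {
  list(status = status, x = numeric(0), objective = NA_real_,
       duals = rep(NA_real_, m), reduced_costs = rep(NA_real_, n),
       basis = integer(0), iterations = it)
}

# One simplex phase (maximization). Dantzig pricing with a switch to Bland's
# rule after a run of degenerate steps, which guarantees termination.
.simplex_phase <- function(A, cvec, lower, upper, x, basis, tol, max_iter) {
  m <- nrow(A)
  ntot <- ncol(A)
  in_basis <- rep(FALSE, ntot)
  in_basis[basis] <- TRUE
  degen <- 0L
  bland <- FALSE
  ptol <- 1e-9   # pivot tolerance
  etol <- 1e-9   # entering (dual feasibility) tolerance

  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cvec[basis]),
                  error = function(e) NULL)
    if (is.null(y))
      return(list(status = "numerical_error", iterations = it))
    z <- cvec - as.numeric(crossprod(A, y))

    movable <- !in_basis & (upper - lower) > ptol
    up_ok <- movable & (x <= lower + ptol) & (z > etol)
    dn_ok <- movable & (x >= upper - ptol) & (z < -etol)
    cand <- which(up_ok | dn_ok)
    if (length(cand) == 0L) {
      return(list(status = "optimal", x = x, basis = basis,
                  objective = sum(cvec * x),
                  duals = y, reduced_costs = z, iterations = it))
    }
    j <- if (bland) cand[1L] else cand[which.max(abs(z[cand]))]
    increase <- up_ok[j]

    w <- solve(B, A[, j])
    rate <- if (increase) -w else w

    # ratio test over basic variables
    tmax <- upper[j] - lower[j]           # bound-flip distance
    leave_pos <- 0L
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (rate[i] > ptol) {
        ti <- (upper[bi] - x[bi]) / rate[i]
      } else if (rate[i] < -ptol) {
        ti <- (lower[bi] - x[bi]) / rate[i]
      } else next
      if (ti < tmax - 1e-12) {
        tmax <- ti
        leave_pos <- i
      } else if (bland && leave_pos > 0L && abs(ti - tmax) <= 1e-12 &&
                 basis[i] < basis[leave_pos]) {
        leave_pos <- i
      }
    }

    if (!is.finite(tmax))
      return(list(status = "unbounded", iterations = it))
    tmax <- max(tmax, 0)

    step <- if (increase) tmax else -tmax
    x[basis] <- x[basis] + tmax * rate
    x[j] <- x[j] + step

    if (leave_pos == 0L) {
      # bound flip: variable crossed to its other bound, basis unchanged
      x[j] <- if (increase) upper[j] else lower[j]
    } else {
      bl <- basis[leave_pos]
      # snap the leaving variable onto the bound it hit
      x[bl] <- if (rate[leave_pos] > 0) upper[bl] else lower[bl]
      in_basis[bl] <- FALSE
      in_basis[j] <- TRUE
      basis[leave_pos] <- j
    }

    if (tmax < 1e-11) {
      degen <- degen + 1L
      if (degen > 60L) bland <- TRUE
    } else {
      degen <- 0L
      bland <- FALSE
    }
  }
  list(status = "iteration_limit", iterations = max_iter)
}
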