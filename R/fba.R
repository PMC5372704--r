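# Flux balance analysis: maximize (or minimize) the flux of an objective
# reaction subject to steady-state mass balance S v = 0 and flux bounds.

#' Flux balance analysis
#'
#' Solves \eqn{\max c'v} (or min) subject to \eqn{S v = 0} and
#' \eqn{v_l \le v \le v_u}, where the objective selects a single reaction,
#' conventionally the biomass reaction so that the optimum is the specific
#' growth rate \eqn{\mu} (1/h).
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id to optimize (default: the model objective).
#' @param sense \code{"max"} (default) or \code{"min"}.
#' @return A \code{flux_solution}: list with \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{mu} (objective value;
#'   \code{NA} unless optimal), \code{fluxes} and \code{reduced_costs} (named
#'   by reaction id; reduced costs are dObjective/dflux at the returned
#'   optimal basis and zero for basic reactions), \code{duals} (metabolite
#'   shadow prices) and \code{solver_log}.
#' @export
solve_fba <- function(model, objective = model$objective_id,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.na(objective) || !(objective %in% model$reactions$id))
    stop("objective reaction not found: ", objective)
  S <- build_stoichiometric_matrix(model)
  rids <- colnames(S)
  obj <- as.numeric(rids == objective)
  res <- lp_solve(S, rep(0, nrow(S)), obj,
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  sense = sense)
  log <- sprintf("bounded simplex: status=%s iterations=%d", res$status,
                 res$iterations)
  if (res$status != "optimal") {
    status <- if (res$status %in% c("infeasible", "unbounded"))
      res$status else "infeasible"
    return(structure(list(status = status, mu = NA_real_,
                          fluxes = stats::setNames(numeric(0), character(0)),
                          reduced_costs = stats::setNames(numeric(0), character(0)),
                          duals = stats::setNames(numeric(0), character(0)),
                          objective_id = objective, sense = sense,
                          solver_log = log),
                     class = "flux_solution"))
  }
  structure(list(status = "optimal",
                 mu = res$objective,
                 fluxes = stats::setNames(res$x, rids),
                 reduced_costs = stats::setNames(res$reduced_costs, rids),
                 duals = stats::setNames(res$duals, rownames(S)),
                 objective_id = objective, sense = sense,
                 solver_log = log),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal")
    cat(sprintf(", %s(%s) = %.6g", x$sense, x$objective_id, x$mu))
  cat("\n")
  invisible(x)
}

#' Growth predicate
#'
#' Growth is called when the optimal specific growth rate exceeds the zero
#' tolerance (default 1e-6 1/h); below that, growth is treated as zero in
#' all screens.
#'
#' @param mu growth rate, 1/h (NA counts as no growth).
#' @param epsilon zero-growth tolerance.
#' @return Logical.
#' @export
grows <- function(mu, epsilon = 1e-6) {
  !is.na(mu) && mu > epsilon
}
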