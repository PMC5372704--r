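# Scaled reduced costs of exchange reactions (growth elasticities).

#' Scaled reduced costs of exchange fluxes
#'
#' For every requested exchange reaction with a binding bound, computes the
#' scaled reduced cost W = w * q / mu, the fractional change in biomass per
#' fractional change of the exchanged compound's rate: w is the reduced cost
#' expressed as d(mu)/d(rate magnitude) so that a positive W always means
#' that allowing more of the current activity (more uptake for a consumed
#' nutrient, more secretion for a produced one) increases growth; q is the
#' flux magnitude. Reactions with zero reduced cost or zero scaled reduced
#' cost are omitted, as only those constrain the optimum.
#'
#' @param model the \code{metabolic_model} the solution came from.
#' @param solution an optimal \code{flux_solution} with \code{mu > 0}.
#' @param reactions exchange reaction ids to report (default: all exchanges).
#' @param tol zero tolerance on w and W.
#' @param check_uniqueness when \code{TRUE}, runs a per-reaction FVA at the
#'   fixed optimum and flags records whose exchange flux is not unique there
#'   (degenerate duals: reduced costs are then basis-dependent).
#' @return Data frame with \code{reaction_id}, \code{direction}
#'   (\code{"consumed"}/\code{"produced"}), \code{reduced_cost} (w),
#'   \code{flux_magnitude} (q), \code{scaled_reduced_cost} (W) and, if
#'   requested, \code{degenerate}.
#' @export
scaled_reduced_costs <- function(model, solution,
                                 reactions = exchange_ids(model),
                                 tol = 1e-9, check_uniqueness = FALSE) {
  if (solution$status != "optimal")
    stop("solution is not optimal")
  if (is.na(solution$mu) || solution$mu <= 0)
    stop("scaled reduced costs undefined at zero growth")
  mu <- solution$mu
  flux <- solution$fluxes[reactions]
  z <- solution$reduced_costs[reactions]
  # d(mu)/d(rate magnitude): uptake rates grow as flux becomes more negative
  w <- ifelse(flux < 0, -z, z)
  q <- abs(flux)
  W <- w * q / mu
  keep <- abs(w) > tol & abs(W) > tol
  out <- data.frame(
    reaction_id = reactions[keep],
    direction = ifelse(flux[keep] < 0, "consumed", "produced"),
    reduced_cost = unname(w[keep]),
    flux_magnitude = unname(q[keep]),
    scaled_reduced_cost = unname(W[keep]),
    stringsAsFactors = FALSE)
  if (check_uniqueness && nrow(out)) {
    i <- match(model$objective_id, model$reactions$id)
    fixed <- model
    fixed$reactions$lower_bound[i] <- mu
    fixed$reactions$upper_bound[i] <- mu
    rng <- fva(fixed, reactions = out$reaction_id)
    out$degenerate <- rng$span > 1e-6
    if (any(out$degenerate))
      warning("alternative optima detected for ",
              sum(out$degenerate), " exchange(s); their reduced costs are ",
              "basis-dependent")
  }
  out
}

#' Aggregate scaled reduced costs over several conditions
#'
#' Reports, per exchange reaction, the mean and sample standard deviation of
#' the reduced cost and the scaled reduced cost across condition-specific
#' solves (the "value +/- spread" presentation).
#'
#' @param records_list list of data frames from
#'   \code{\link{scaled_reduced_costs}}, one per condition.
#' @return Data frame with per-reaction means and standard deviations.
#' @export
summarize_reduced_costs <- function(records_list) {
  all <- do.call(rbind, records_list)
  ids <- unique(all$reaction_id)
  out <- lapply(ids, function(rid) {
    sub <- all[all$reaction_id == rid, ]
    data.frame(reaction_id = rid,
               direction = sub$direction[1],
               n_conditions = nrow(sub),
               reduced_cost_mean = mean(sub$reduced_cost),
               reduced_cost_sd = stats::sd(sub$reduced_cost),
               scaled_reduced_cost_mean = mean(sub$scaled_reduced_cost),
               scaled_reduced_cost_sd = stats::sd(sub$scaled_reduced_cost),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
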