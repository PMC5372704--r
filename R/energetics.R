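# Maintenance-energy (NGAM) estimation and ATP-production accounting.

#' Add the ATP maintenance (NGAM) reaction
#'
#' Adds "ATP + H2O -> ADP + Pi + H+" with id \code{ATPM}, kind \code{ngam}
#' and bounds (0, 0) until a maintenance value is set. Idempotent: calling it
#' on a model that already has \code{ATPM} returns the model unchanged.
#'
#' @param model a \code{metabolic_model} containing the four metabolites
#'   (ids \code{atp_c}, \code{h2o_c}, \code{adp_c}, \code{pi_c}, \code{h_c}
#'   by default).
#' @param metabolite_ids named character vector mapping roles
#'   \code{atp}, \code{h2o}, \code{adp}, \code{pi}, \code{h} to metabolite
#'   ids.
#' @return The model with the maintenance reaction present.
#' @export
add_ngam_reaction <- function(model,
                              metabolite_ids = c(atp = "atp_c", h2o = "h2o_c",
                                                 adp = "adp_c", pi = "pi_c",
                                                 h = "h_c")) {
  if ("ATPM" %in% model$reactions$id) return(model)
  need <- unname(metabolite_ids[c("atp", "h2o", "adp", "pi", "h")])
  missing <- setdiff(need, model$metabolites$id)
  if (length(missing))
    stop("model lacks metabolite(s) required for the maintenance reaction: ",
         paste(missing, collapse = ", "))
  add_reaction(model, "ATPM",
               stats::setNames(c(-1, -1, 1, 1, 1), need),
               lower_bound = 0, upper_bound = 0,
               name = "ATP maintenance requirement",
               subsystem = "Maintenance", kind = "ngam")
}

#' Measured exchange-rate constraint set
#'
#' @param records data frame with columns \code{reaction_id},
#'   \code{rate} (nonnegative magnitude, mmol gDW^-1 h^-1) and
#'   \code{direction} (\code{"consumption"} or \code{"production"}).
#' @param observed_mu observed specific growth rate, 1/h.
#' @return An object of class \code{rate_constraint_set}.
#' @export
rate_constraint_set <- function(records, observed_mu) {
  stopifnot(all(c("reaction_id", "rate", "direction") %in% names(records)),
            all(records$direction %in% c("consumption", "production")),
            all(records$rate >= 0), observed_mu > 0)
  structure(list(records = as.data.frame(records, stringsAsFactors = FALSE),
                 observed_mu = observed_mu),
            class = "rate_constraint_set")
}

#' Read / write a rates TSV (reaction_id, rate, direction; observed growth
#' rate in a '# observed_mu' header line)
#' @param path TSV path.
#' @return A \code{rate_constraint_set}.
#' @export
read_rates <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# observed_mu", first))
    stop("rates file lacks the '# observed_mu <value>' header line")
  mu <- as.numeric(sub("^# observed_mu[ \t]+", "", first))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  rate_constraint_set(df, mu)
}

#' @rdname read_rates
#' @param rates a \code{rate_constraint_set}.
#' @export
write_rates <- function(rates, path) {
  df <- rates$records
  lines <- c(sprintf("# observed_mu\t%s", .num_fmt(rates$observed_mu)),
             paste(names(df), collapse = "\t"),
             sprintf("%s\t%s\t%s", df$reaction_id, .num_fmt(df$rate),
                     df$direction))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.apply_rates <- function(model, rates) {
  ex <- exchange_ids(model)
  for (i in seq_len(nrow(rates$records))) {
    rid <- rates$records$reaction_id[i]
    if (!rid %in% ex)
      stop("measured rate refers to a non-exchange reaction: ", rid)
    v <- rates$records$rate[i]
    if (rates$records$direction[i] == "consumption") v <- -v
    model <- fix_flux(model, rid, v)
  }
  model
}

#' Fit the non-growth-associated maintenance (NGAM) flux
#'
#' Fixes the measured exchange rates as equality bounds, then sweeps the
#' maintenance flux over [0, ngam_max]: at each grid value the growth rate is
#' maximized and the relative error against the observed growth rate
#' recorded. A coarse sweep (step \code{grid_step}) is refined at
#' \code{refine_step} around the coarse argmin. Grid points where the
#' constrained model is infeasible are recorded and excluded from the argmin.
#'
#' @param model a \code{metabolic_model} containing \code{ATPM}.
#' @param rates a \code{\link{rate_constraint_set}}.
#' @param grid_step coarse sweep step (default 0.1 mmol ATP gDW^-1 h^-1).
#' @param refine_step refinement step (default 0.01).
#' @param ngam_max top of the sweep (default 5).
#' @return An \code{ngam_fit}: data frame \code{curve} (ngam, mu_pred,
#'   error, feasible), \code{best_ngam}, \code{predicted_mu_at_best},
#'   \code{observed_mu}.
#' @export
fit_ngam <- function(model, rates, grid_step = 0.1, refine_step = 0.01,
                     ngam_max = 5) {
  stopifnot(inherits(rates, "rate_constraint_set"))
  if (!"ATPM" %in% model$reactions$id)
    stop("model lacks the ATPM maintenance reaction; call add_ngam_reaction()")
  constrained <- .apply_rates(model, rates)
  mu_obs <- rates$observed_mu

  sweep <- function(grid) {
    mu <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      s <- solve_fba(fix_flux(constrained, "ATPM", grid[i]))
      if (s$status == "optimal") mu[i] <- s$mu
    }
    data.frame(ngam = grid, mu_pred = mu,
               error = abs(mu - mu_obs) / mu_obs,
               feasible = !is.na(mu))
  }

  coarse <- sweep(seq(0, ngam_max, by = grid_step))
  if (!any(coarse$feasible))
    stop("model infeasible at every NGAM grid point")
  g0 <- coarse$ngam[coarse$feasible][which.min(coarse$error[coarse$feasible])]
  fine <- sweep(seq(max(0, g0 - grid_step), min(ngam_max, g0 + grid_step),
                    by = refine_step))
  curve <- rbind(coarse, fine)
  curve <- curve[!duplicated(round(curve$ngam, 10)), ]
  curve <- curve[order(curve$ngam), ]
  rownames(curve) <- NULL
  feas <- curve[curve$feasible, ]
  best <- feas[which.min(feas$error), ]
  structure(list(curve = curve, best_ngam = best$ngam,
                 predicted_mu_at_best = best$mu_pred,
                 observed_mu = mu_obs),
            class = "ngam_fit")
}

#' @export
print.ngam_fit <- function(x, ...) {
  cat(sprintf(paste0("ngam_fit: best NGAM = %.3g mmol ATP gDW-1 h-1 ",
                     "(predicted mu %.5g vs observed %.5g, error %.3g%%)\n"),
              x$best_ngam, x$predicted_mu_at_best, x$observed_mu,
              100 * abs(x$predicted_mu_at_best - x$observed_mu) /
                x$observed_mu))
  invisible(x)
}

#' ATP production accounting by two methods
#'
#' The network method sums the fluxes of acetate kinase, pyruvate kinase and
#' phosphoglycerate kinase and subtracts hexokinase and fructokinase; the
#' fermentation method sums the D-lactate and acetate export fluxes (the
#' classic heterolactic estimate of 1 ATP per lactate + acetate). The ATP
#' synthase fraction relates synthase flux to total ATP production
#' (substrate-level + synthase).
#'
#' @param solution an optimal \code{flux_solution}.
#' @param reaction_roles named list mapping roles \code{acetate_kinase},
#'   \code{pyruvate_kinase}, \code{phosphoglycerate_kinase},
#'   \code{hexokinase}, \code{fructokinase}, \code{atp_synthase},
#'   \code{d_lactate_exchange}, \code{acetate_exchange} to reaction ids.
#' @return List with \code{network_rate}, \code{fermentation_rate} and
#'   \code{synthase_fraction}.
#' @export
atp_accounting <- function(solution, reaction_roles) {
  need <- c("acetate_kinase", "pyruvate_kinase", "phosphoglycerate_kinase",
            "hexokinase", "fructokinase", "atp_synthase",
            "d_lactate_exchange", "acetate_exchange")
  missing <- setdiff(need, names(reaction_roles))
  if (length(missing))
    stop("missing reaction role(s): ", paste(missing, collapse = ", "))
  fl <- function(role) {
    rid <- reaction_roles[[role]]
    if (!rid %in% names(solution$fluxes))
      stop("role ", role, " maps to unknown reaction ", rid)
    unname(solution$fluxes[rid])
  }
  network <- fl("acetate_kinase") + fl("pyruvate_kinase") +
    fl("phosphoglycerate_kinase") - fl("hexokinase") - fl("fructokinase")
  ferment <- fl("d_lactate_exchange") + fl("acetate_exchange")
  synthase <- fl("atp_synthase")
  slp <- fl("acetate_kinase") + fl("pyruvate_kinase") +
    fl("phosphoglycerate_kinase")
  total <- slp + synthase
  list(network_rate = network, fermentation_rate = ferment,
       synthase_fraction = if (total > 0) synthase / total else 0)
}

#' Mean relative discrepancy between the two ATP accounting methods
#'
#' For pairs of (network, fermentation) rates, computes the per-pair relative
#' shortfall \code{(1 - network/fermentation) * 100} and its mean. Pairs with
#' a zero fermentation rate are excluded with a warning.
#'
#' @param pairs two-column matrix or data frame: network rate, fermentation
#'   rate.
#' @return List with \code{mean_percent} and \code{per_pair_percent}.
#' @export
atp_method_discrepancy <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  keep <- pairs[, 2] != 0
  if (!all(keep))
    warning(sum(!keep), " pair(s) with zero fermentation rate excluded")
  pairs <- pairs[keep, , drop = FALSE]
  pp <- (1 - pairs[, 1] / pairs[, 2]) * 100
  list(mean_percent = mean(pp), per_pair_percent = pp)
}
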