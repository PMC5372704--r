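# Flux variability analysis, blocked reactions, dead-end metabolites.

#' Open all exchange bounds
#'
#' Sets every exchange reaction's bounds to (-open_bound, +open_bound): the
#' "unconstrained" network used for blocked-reaction detection, where no
#' medium limits uptake or secretion.
#'
#' @param model a \code{metabolic_model}.
#' @param open_bound magnitude of the opened bounds (default 1000).
#' @return The modified model.
#' @export
open_exchanges <- function(model, open_bound = 1000) {
  i <- which(model$reactions$kind == "exchange")
  model$reactions$lower_bound[i] <- -open_bound
  model$reactions$upper_bound[i] <- open_bound
  model
}

#' Flux variability analysis
#'
#' Minimizes and maximizes the flux through each reaction (two LPs per
#' reaction). With \code{fraction_of_optimum = f}, the objective reaction is
#' first bounded below by \code{f} times its optimum, restricting the scan to
#' the (near-)optimal subspace.
#'
#' @param model a \code{metabolic_model} (already constrained as desired).
#' @param reactions reaction ids to scan (default: all).
#' @param fraction_of_optimum optional value in [0, 1]; requires a model
#'   objective.
#' @return Data frame with \code{reaction_id}, \code{min_flux},
#'   \code{max_flux} and \code{span}.
#' @export
fva <- function(model, reactions = model$reactions$id,
                fraction_of_optimum = NULL) {
  if (!is.null(fraction_of_optimum)) {
    stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
    base <- solve_fba(model)
    if (base$status != "optimal")
      stop("base problem is ", base$status, "; FVA undefined")
    i <- match(model$objective_id, model$reactions$id)
    model$reactions$lower_bound[i] <- fraction_of_optimum * base$mu
  } else {
    # fail before any per-reaction solve if the base problem is infeasible
    S <- build_stoichiometric_matrix(model)
    chk <- lp_solve(S, rep(0, nrow(S)), rep(0, ncol(S)),
                    model$reactions$lower_bound, model$reactions$upper_bound)
    if (chk$status != "optimal")
      stop("base problem is infeasible; FVA undefined")
  }
  S <- build_stoichiometric_matrix(model)
  rids <- colnames(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  out <- data.frame(reaction_id = reactions,
                    min_flux = NA_real_, max_flux = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], rids)
    if (is.na(j)) stop("unknown reaction id: ", reactions[k])
    obj <- as.numeric(seq_along(rids) == j)
    lo <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, sense = "min")
    hi <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    out$min_flux[k] <- lo$objective
    out$max_flux[k] <- hi$objective
  }
  out$span <- out$max_flux - out$min_flux
  out
}

#' Blocked reactions
#'
#' A reaction is blocked when it cannot carry flux in the unconstrained
#' network (all exchanges opened): both its FVA extrema fall below the
#' tolerance in magnitude. Solutions of each subproblem are reused as flux
#' witnesses for the remaining reactions, so far fewer than 2n LPs are
#' typically needed.
#'
#' @param model a \code{metabolic_model}.
#' @param tol blocked tolerance on |flux| (default 1e-9, solver scale).
#' @param open open all exchange bounds first (default \code{TRUE}).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked <- function(model, tol = 1e-9, open = TRUE) {
  if (open) model <- open_exchanges(model)
  S <- build_stoichiometric_matrix(model)
  rids <- colnames(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  witnessed <- stats::setNames(rep(FALSE, length(rids)), rids)
  blocked <- character(0)
  for (j in seq_along(rids)) {
    if (witnessed[j]) next
    obj <- as.numeric(seq_along(rids) == j)
    hi <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, sense = "max")
    if (hi$status != "optimal") stop("unconstrained model infeasible")
    witnessed <- witnessed | abs(hi$x) > tol
    if (witnessed[j]) next
    lo <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, sense = "min")
    witnessed <- witnessed | abs(lo$x) > tol
    if (!witnessed[j]) blocked <- c(blocked, rids[j])
  }
  blocked
}

#' Structural dead-end metabolites
#'
#' After expanding every reversible reaction into both directions, a
#' metabolite is a structural dead-end iff it appears only as a product or
#' only as a substrate across all reactions.
#'
#' @param S stoichiometric matrix (from
#'   \code{\link{build_stoichiometric_matrix}}).
#' @param reversible logical vector per reaction (column), \code{TRUE} when
#'   the lower bound is negative.
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_ends_structural <- function(S, reversible) {
  S <- as(S, "CsparseMatrix")
  stopifnot(length(reversible) == ncol(S))
  produced <- consumed <- rep(FALSE, nrow(S))
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    pos <- col > 0; neg <- col < 0
    produced <- produced | pos
    consumed <- consumed | neg
    if (reversible[j]) {
      produced <- produced | neg
      consumed <- consumed | pos
    }
  }
  touched <- produced | consumed
  rownames(S)[touched & (produced != consumed)]
}

#' Functional dead-end metabolites
#'
#' For each metabolite, a temporary drain ("M ->") is added and maximized
#' (producibility) and a temporary source ("-> M") is added and maximized
#' (consumability); the metabolite is a dead-end iff either optimum falls
#' below the tolerance, i.e. the network cannot produce it or cannot consume
#' it, which is what forces its neighbouring reactions to zero flux.
#' Temporary reactions never persist in the returned state.
#'
#' @param model a \code{metabolic_model}.
#' @param tol flux tolerance (default 1e-9).
#' @param open open all exchange bounds first (default \code{TRUE}).
#' @param metabolites metabolite ids to probe (default: all).
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_ends_functional <- function(model, tol = 1e-9, open = TRUE,
                                      metabolites = model$metabolites$id) {
  if (open) model <- open_exchanges(model)
  S0 <- build_stoichiometric_matrix(model)
  m <- nrow(S0)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  dead <- character(0)
  idx <- match(metabolites, rownames(S0))
  if (anyNA(idx)) stop("unknown metabolite id(s)")
  for (i in idx) {
    probe <- numeric(m); probe[i] <- -1     # drain: consumes the metabolite
    S <- cbind(as.matrix(S0), probe)
    obj <- c(numeric(ncol(S0)), 1)
    hi <- lp_solve(S, rep(0, m), obj, c(lb, 0), c(ub, 1000), sense = "max")
    producible <- hi$status == "optimal" && hi$objective > tol
    consumable <- TRUE
    if (producible) {
      S[, ncol(S)] <- -probe                # source: produces the metabolite
      hi <- lp_solve(S, rep(0, m), obj, c(lb, 0), c(ub, 1000), sense = "max")
      consumable <- hi$status == "optimal" && hi$objective > tol
    }
    if (!producible || !consumable) dead <- c(dead, rownames(S0)[i])
  }
  dead
}

#' Blocked/dead-end report
#'
#' Combines blocked reactions with functional dead-end metabolites and
#' reports which blocked reactions touch at least one dead-end.
#'
#' @param model a \code{metabolic_model}.
#' @param tol flux tolerance.
#' @return List with \code{blocked}, \code{dead_end_metabolites} and
#'   \code{blocked_with_dead_end}.
#' @export
blocked_report <- function(model, tol = 1e-9) {
  blocked <- find_blocked(model, tol = tol)
  dead <- find_dead_ends_functional(model, tol = tol)
  with_dead <- blocked[vapply(blocked, function(rid) {
    any(names(model$stoichiometry[[rid]]) %in% dead)
  }, TRUE)]
  list(blocked = blocked, dead_end_metabolites = dead,
       blocked_with_dead_end = with_dead)
}

#' Histogram of FVA spans on a log10 scale
#'
#' Zero-span reactions are excluded from the bins and counted separately
#' (they are the blocked set under the scanned constraints). Bins sit at
#' integer log10 boundaries: bin b collects spans in [10^b, 10^(b+1)).
#'
#' @param ranges data frame from \code{\link{fva}}.
#' @param zero_tol spans below this count as zero (default 1e-9).
#' @return List with \code{bins} (data frame: log10_bin, count) and
#'   \code{n_zero_span}.
#' @export
span_histogram <- function(ranges, zero_tol = 1e-9) {
  spans <- ranges$span
  zero <- spans < zero_tol
  lg <- floor(log10(spans[!zero]) + 1e-12)
  tab <- table(lg)
  list(bins = data.frame(log10_bin = as.integer(names(tab)),
                         count = as.integer(tab)),
       n_zero_span = sum(zero))
}
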