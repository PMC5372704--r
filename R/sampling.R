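# Hit-and-run Monte Carlo sampling of the steady-state flux polytope
# {v : S v = 0, l <= v <= u}.
#
# Directions are drawn uniformly on the unit sphere of the null space of S
# (restricted to non-fixed reactions), chord endpoints come from exact
# line-box intersection, and the next point is uniform on the chord, so the
# chain never leaves the polytope and needs no rejection step.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

#' Sampler configuration
#'
#' @param n_points number of samples to keep (reference default 100000; use
#'   a few thousand for desk-scale work).
#' @param thinning_steps hit-and-run steps between kept samples (reference
#'   default 500).
#' @param seed RNG seed; identical configurations and seeds give bitwise
#'   identical sample sets.
#' @param warmup_points steps discarded before the first kept sample.
#' @return A list of class \code{sampler_config}.
#' @export
sampler_config <- function(n_points = 100000L, thinning_steps = 500L,
                           seed = 1L, warmup_points = 100L) {
  stopifnot(n_points >= 1, thinning_steps >= 1, warmup_points >= 0)
  structure(list(n_points = as.integer(n_points),
                 thinning_steps = as.integer(thinning_steps),
                 seed = as.integer(seed),
                 warmup_points = as.integer(warmup_points)),
            class = "sampler_config")
}

#' Bound the objective to its (near-)optimal value
#'
#' Solves the model once and sets the objective reaction's bounds to
#' \code{(fraction * mu_opt, mu_opt)}, restricting all later analyses
#' (FVA, sampling) to the near-optimal subspace.
#'
#' @param model a \code{metabolic_model}.
#' @param objective objective reaction id (default: model objective).
#' @param fraction value in (0, 1]; 0.9 reproduces the usual 90\%-of-optimum
#'   subspace.
#' @return The constrained model.
#' @export
constrain_near_optimal <- function(model, objective = model$objective_id,
                                   fraction = 0.9) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  s <- solve_fba(model, objective = objective)
  if (s$status != "optimal")
    stop("objective not solvable: status ", s$status)
  fix_flux(model, objective, c(fraction * s$mu, s$mu))
}

#' Hit-and-run sampling of the flux polytope
#'
#' @param model a \code{metabolic_model}, constrained as desired (medium,
#'   measured rates, near-optimal growth bounds).
#' @param config a \code{\link{sampler_config}}.
#' @return A \code{sample_set}: list with \code{samples} (matrix n_points x
#'   n_reactions, columns named by reaction id), \code{config} and
#'   \code{feasibility_report} (max |S v| and max bound violation over all
#'   samples).
#' @export
hit_and_run_sample <- function(model, config = sampler_config()) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  rids <- colnames(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  # non-empty polytope check + a feasible starting point
  chk <- lp_solve(S, rep(0, nrow(S)), rep(0, ncol(S)), lb, ub)
  if (chk$status != "optimal")
    stop("flux polytope is empty (status ", chk$status, ")")

  free <- which(ub - lb > 1e-9)
  n <- ncol(S)
  samples <- matrix(NA_real_, config$n_points, n,
                    dimnames = list(NULL, rids))

  if (length(free) == 0L) {
    samples[] <- rep(lb, each = config$n_points)  # all fixed: lb == ub
  } else {
    Sf <- S[, free, drop = FALSE]
    N <- MASS::Null(t(Sf))
    d <- ncol(N)
    if (d == 0L) {
      samples[] <- rep(chk$x, each = config$n_points)
    } else {
      # warm-up centre: average of FVA extreme-point solutions
      k <- min(5L, length(free))
      pts <- list(chk$x)
      for (j in free[seq_len(k)]) {
        obj <- as.numeric(seq_len(n) == j)
        for (sense in c("max", "min")) {
          r <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, sense = sense)
          if (r$status == "optimal") pts[[length(pts) + 1L]] <- r$x
        }
      }
      x <- Reduce(`+`, pts) / length(pts)
      x <- pmin(pmax(x, lb), ub)

      lbf <- lb[free]; ubf <- ub[free]
      xf <- x[free]
      total <- config$warmup_points +
        config$n_points * config$thinning_steps
      kept <- 0L
      samples_f <- matrix(NA_real_, config$n_points, length(free))
      .with_seed(config$seed, {
        for (step in seq_len(total)) {
          dir <- as.numeric(N %*% stats::rnorm(d))
          nrm <- sqrt(sum(dir^2))
          if (nrm > 1e-12) {
            dir <- dir / nrm
            pos <- dir > 1e-12
            neg <- dir < -1e-12
            tmax <- min((ubf[pos] - xf[pos]) / dir[pos],
                        (lbf[neg] - xf[neg]) / dir[neg], Inf)
            tmin <- max((lbf[pos] - xf[pos]) / dir[pos],
                        (ubf[neg] - xf[neg]) / dir[neg], -Inf)
            if (is.finite(tmin) && is.finite(tmax) && tmax > tmin) {
              xf <- xf + stats::runif(1, tmin, tmax) * dir
              xf <- pmin(pmax(xf, lbf), ubf)
            }
          }
          rem <- step - config$warmup_points
          if (rem > 0L && rem %% config$thinning_steps == 0L) {
            kept <- kept + 1L
            samples_f[kept, ] <- xf
          }
        }
      })
      base <- matrix(rep(x, each = config$n_points), config$n_points, n)
      base[, free] <- samples_f
      samples <- base
      colnames(samples) <- rids
    }
  }

  resid <- max(abs(S %*% t(samples)))
  bviol <- max(0, max(sweep(samples, 2, lb, `-`) * -1),
               max(sweep(samples, 2, ub, `-`)))
  structure(list(samples = samples, config = config,
                 feasibility_report = list(max_mass_balance_residual = resid,
                                           max_bound_violation = bviol)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d points x %d reactions (thinning %d, seed %d)\n",
              nrow(x$samples), ncol(x$samples), x$config$thinning_steps,
              x$config$seed))
  cat(sprintf("  max |S v| = %.3g, max bound violation = %.3g\n",
              x$feasibility_report$max_mass_balance_residual,
              x$feasibility_report$max_bound_violation))
  invisible(x)
}

#' Most variable reactions across a sample set
#'
#' Ranks reactions by their flux range (max - min) over the samples and
#' tallies the subsystems of the top k. Ties are broken by reaction id so
#' reports are reproducible.
#'
#' @param samples a \code{sample_set}.
#' @param model the sampled \code{metabolic_model} (for subsystems).
#' @param k how many reactions to keep (the classic report uses 50).
#' @return List with \code{ranking} (reaction_id, subsystem, flux_range) and
#'   \code{pathway_frequency} (subsystem counts over the top k, decreasing).
#' @export
top_variable_reactions <- function(samples, model, k = 50L) {
  M <- samples$samples
  if (k > ncol(M)) stop("k exceeds the number of reactions")
  rng <- apply(M, 2, max) - apply(M, 2, min)
  ord <- order(-rng, colnames(M))
  top <- ord[seq_len(k)]
  ranking <- data.frame(
    reaction_id = colnames(M)[top],
    subsystem = model$reactions$subsystem[match(colnames(M)[top],
                                                model$reactions$id)],
    flux_range = unname(rng[top]),
    stringsAsFactors = FALSE)
  tab <- sort(table(ranking$subsystem), decreasing = TRUE)
  list(ranking = ranking,
       pathway_frequency = data.frame(subsystem = names(tab),
                                      count = as.integer(tab),
                                      stringsAsFactors = FALSE))
}
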