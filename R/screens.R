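# In silico media and essentiality screens.
#
# A medium lists the nutrients whose uptake is permitted, each mapped to its
# exchange reaction with a maximal uptake rate. Applying a medium closes the
# uptake (lower) bound of every other exchange; secretion (upper) bounds are
# never touched. Components flagged always_open stand for species such as
# water that the medium never limits.

#' Construct a medium
#'
#' @param components data frame with columns \code{nutrient},
#'   \code{exchange_id}, \code{max_uptake} (nonnegative, mmol gDW^-1 h^-1)
#'   and optionally \code{always_open} (logical, default \code{FALSE}).
#' @return The validated medium data frame (class \code{medium}).
#' @export
medium <- function(components) {
  if (!"always_open" %in% names(components))
    components$always_open <- FALSE
  stopifnot(all(c("nutrient", "exchange_id", "max_uptake") %in%
                  names(components)))
  if (any(components$max_uptake < 0))
    stop("medium max_uptake must be nonnegative")
  if (anyDuplicated(components$exchange_id))
    stop("duplicate exchange ids in medium")
  structure(as.data.frame(components, stringsAsFactors = FALSE),
            class = c("medium", "data.frame"))
}

#' Read / write a medium TSV
#'
#' Columns: nutrient, exchange_id, max_uptake, always_open.
#' @param path TSV file path.
#' @return A \code{medium}.
#' @export
read_medium <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$always_open <- as.logical(df$always_open)
  df$max_uptake <- as.numeric(df$max_uptake)
  medium(df)
}

#' @rdname read_medium
#' @param med a \code{medium}.
#' @export
write_medium <- function(med, path) {
  df <- data.frame(nutrient = med$nutrient, exchange_id = med$exchange_id,
                   max_uptake = .num_fmt(med$max_uptake),
                   always_open = ifelse(med$always_open, "TRUE", "FALSE"),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Apply a medium to a model
#'
#' Every exchange reaction not listed in the medium gets lower bound 0 (no
#' uptake); every listed exchange gets lower bound \code{-max_uptake}.
#' Secretion bounds are untouched. Returns a modified copy.
#'
#' @param model a \code{metabolic_model}.
#' @param med a \code{\link{medium}}.
#' @return The constrained model.
#' @export
apply_medium <- function(model, med) {
  ex <- exchange_ids(model)
  missing <- setdiff(med$exchange_id, model$reactions$id)
  if (length(missing))
    stop("medium lists exchange reactions absent from the model: ",
         paste(missing, collapse = ", "))
  nonex <- setdiff(med$exchange_id, ex)
  if (length(nonex))
    stop("medium lists non-exchange reactions: ",
         paste(nonex, collapse = ", "))
  i <- match(ex, model$reactions$id)
  model$reactions$lower_bound[i] <- 0
  j <- match(med$exchange_id, model$reactions$id)
  model$reactions$lower_bound[j] <- -med$max_uptake
  model
}

#' Screen configuration
#'
#' @param growth_fraction_threshold relative growth threshold for omission
#'   and deletion calls: a perturbation abolishes growth when the mutant grows
#'   at less than this fraction of the wild type (default 0.20).
#' @param zero_growth_epsilon absolute zero-growth tolerance, 1/h.
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(growth_fraction_threshold = 0.20,
                          zero_growth_epsilon = 1e-6) {
  stopifnot(growth_fraction_threshold > 0, growth_fraction_threshold < 1,
            zero_growth_epsilon > 0)
  structure(list(growth_fraction_threshold = growth_fraction_threshold,
                 zero_growth_epsilon = zero_growth_epsilon),
            class = "screen_config")
}

#' Deletion screen configuration
#'
#' @param essentiality_reduction_threshold a knockout is essential when it
#'   reduces growth by at least this fraction (default 0.80).
#' @param zero_growth_epsilon absolute zero-growth tolerance, 1/h.
#' @return A list of class \code{deletion_config}.
#' @export
deletion_config <- function(essentiality_reduction_threshold = 0.80,
                            zero_growth_epsilon = 1e-6) {
  stopifnot(essentiality_reduction_threshold > 0,
            essentiality_reduction_threshold < 1)
  structure(list(essentiality_reduction_threshold =
                   essentiality_reduction_threshold,
                 zero_growth_epsilon = zero_growth_epsilon),
            class = "deletion_config")
}

.growth_call_df <- function(item, wt, mu, call) {
  data.frame(item = item, wild_type_mu = wt, perturbed_mu = mu, call = call,
             stringsAsFactors = FALSE)
}

#' Single-nutrient omission screen
#'
#' Removes each medium component in turn (uptake bound set to zero), re-runs
#' FBA, and calls no-growth when the mutant grows at less than the configured
#' fraction of the wild type. The wild type is solved once on the full
#' medium.
#'
#' @param model a \code{metabolic_model}.
#' @param med the full \code{\link{medium}}.
#' @param config a \code{\link{screen_config}}.
#' @return Data frame with one row per component: \code{item},
#'   \code{wild_type_mu}, \code{perturbed_mu}, \code{call}
#'   (\code{"growth"}/\code{"no_growth"}); no-growth means essential.
#' @export
single_omission_screen <- function(model, med, config = screen_config()) {
  base <- apply_medium(model, med)
  wt <- solve_fba(base)
  if (wt$status != "optimal" || !grows(wt$mu, config$zero_growth_epsilon))
    stop("wild type does not grow on the full medium; omission screen ",
         "undefined")
  out <- vector("list", nrow(med))
  for (i in seq_len(nrow(med))) {
    m2 <- apply_medium(model, med[-i, , drop = FALSE])
    s <- solve_fba(m2)
    mu <- if (s$status == "optimal") s$mu else 0
    call <- if (mu < config$growth_fraction_threshold * wt$mu)
      "no_growth" else "growth"
    out[[i]] <- .growth_call_df(med$nutrient[i], wt$mu, mu, call)
  }
  do.call(rbind, out)
}

#' Sole-carbon-source screen
#'
#' Each candidate source is added alone to a carbon-free base medium; the
#' call is growth iff the optimum exceeds the absolute zero-growth tolerance
#' (there is no wild type in this screen, so the relative threshold does not
#' apply).
#'
#' @param model a \code{metabolic_model}.
#' @param base_medium carbon-free \code{\link{medium}}; it must not support
#'   growth by itself.
#' @param sources character vector of exchange reaction ids to test.
#' @param uptake uptake bound given to each tested source.
#' @param config a \code{\link{screen_config}}.
#' @return Data frame of growth calls (one per source).
#' @export
carbon_source_screen <- function(model, base_medium, sources, uptake = 10,
                                 config = screen_config()) {
  s0 <- solve_fba(apply_medium(model, base_medium))
  if (s0$status == "optimal" && grows(s0$mu, config$zero_growth_epsilon))
    stop("base medium supports growth on its own; carbon screen confounded")
  out <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    med2 <- medium(rbind(
      as.data.frame(base_medium),
      data.frame(nutrient = sources[i], exchange_id = sources[i],
                 max_uptake = uptake, always_open = FALSE,
                 stringsAsFactors = FALSE)))
    s <- solve_fba(apply_medium(model, med2))
    mu <- if (s$status == "optimal") s$mu else 0
    call <- if (grows(mu, config$zero_growth_epsilon)) "growth" else
      "no_growth"
    out[[i]] <- .growth_call_df(sources[i], 0, mu, call)
  }
  if (length(out)) do.call(rbind, out) else
    .growth_call_df(character(0), numeric(0), numeric(0), character(0))
}

#' Single-gene deletion screen
#'
#' For each gene, reactions whose GPR evaluates to FALSE under the knockout
#' have both bounds set to zero, and growth is re-optimized. Essential means
#' growth is reduced by at least the configured fraction.
#'
#' @param model a \code{metabolic_model} (medium already applied, or pass
#'   \code{med}).
#' @param med optional \code{\link{medium}} applied before screening.
#' @param config a \code{\link{deletion_config}}.
#' @return Data frame with \code{item} (gene id), \code{wild_type_mu},
#'   \code{perturbed_mu}, \code{call} and \code{essential}.
#' @export
single_gene_deletion <- function(model, med = NULL,
                                 config = deletion_config()) {
  if (!is.null(med)) model <- apply_medium(model, med)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || !grows(wt$mu, config$zero_growth_epsilon))
    stop("wild type does not grow; deletion screen undefined")
  thr <- (1 - config$essentiality_reduction_threshold) * wt$mu
  gpr <- model$reactions$gpr
  has_gpr <- which(nzchar(gpr))
  out <- vector("list", nrow(model$genes))
  for (gi in seq_len(nrow(model$genes))) {
    g <- model$genes$id[gi]
    dead <- has_gpr[!vapply(gpr[has_gpr], evaluate_gpr, TRUE,
                            knocked_out = g)]
    if (!length(dead)) {
      mu <- wt$mu
    } else {
      m2 <- model
      m2$reactions$lower_bound[dead] <- 0
      m2$reactions$upper_bound[dead] <- 0
      s <- solve_fba(m2)
      mu <- if (s$status == "optimal") s$mu else 0
    }
    call <- if (mu < thr) "no_growth" else "growth"
    out[[gi]] <- .growth_call_df(g, wt$mu, mu, call)
  }
  res <- do.call(rbind, out)
  res$essential <- res$call == "no_growth"
  res
}

#' Single-reaction deletion screen
#'
#' Each reaction's flux is fixed to zero in turn (the knockout mechanism is
#' bound closure, not removal) and growth re-optimized; the result includes a
#' per-subsystem tally of essential reactions.
#'
#' @inheritParams single_gene_deletion
#' @return List with \code{calls} (per-reaction data frame including an
#'   \code{essential} flag and \code{subsystem}) and \code{pathway_summary}
#'   (essential-reaction counts by subsystem, decreasing).
#' @export
single_reaction_deletion <- function(model, med = NULL,
                                     config = deletion_config()) {
  if (!is.null(med)) model <- apply_medium(model, med)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || !grows(wt$mu, config$zero_growth_epsilon))
    stop("wild type does not grow; deletion screen undefined")
  thr <- (1 - config$essentiality_reduction_threshold) * wt$mu
  ids <- model$reactions$id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- solve_fba(fix_flux(model, ids[i], 0))
    mu <- if (s$status == "optimal") s$mu else 0
    call <- if (mu < thr) "no_growth" else "growth"
    out[[i]] <- .growth_call_df(ids[i], wt$mu, mu, call)
  }
  calls <- do.call(rbind, out)
  calls$essential <- calls$call == "no_growth"
  calls$subsystem <- model$reactions$subsystem
  ess <- calls[calls$essential, ]
  tab <- sort(table(ess$subsystem), decreasing = TRUE)
  summary <- data.frame(subsystem = names(tab),
                        essential_reactions = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(calls = calls, pathway_summary = summary)
}
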