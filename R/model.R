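# Model containers and integrity checks.
#
# A metabolic_model is a plain list of data frames plus a stoichiometry list,
# in the style of small constraint-based modeling toolkits: everything is
# inspectable with str() and editable with ordinary data-frame operations,
# and the validator enforces the structural invariants the analysis code
# relies on.

REACTION_KINDS <- c("intracellular", "extracellular", "transport", "exchange",
                    "demand", "sink", "biomass", "ngam")

#' Construct a metabolic model
#'
#' @param metabolites data frame with columns \code{id}, \code{name},
#'   \code{compartment} (\code{"intracellular"} or \code{"extracellular"});
#'   an optional numeric \code{carbon} column records skeleton carbon counts
#'   used by mass-plausibility checks.
#' @param reactions data frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound} (fluxes in mmol gDW^-1 h^-1),
#'   \code{gpr} (boolean gene association, possibly \code{""}),
#'   \code{subsystem} and \code{kind} (one of intracellular, extracellular,
#'   transport, exchange, demand, sink, biomass, ngam).
#' @param stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param genes data frame with columns \code{id}, \code{name}.
#' @param objective_id id of the objective (biomass) reaction, or \code{NA}.
#' @param validate run \code{\link{validate_model}} (default \code{TRUE}).
#'
#' @return An object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective_id = NA_character_,
                            validate = TRUE) {
  if (is.null(genes))
    genes <- data.frame(id = character(0), name = character(0),
                        stringsAsFactors = FALSE)
  if (!"carbon" %in% names(metabolites))
    metabolites$carbon <- rep(NA_real_, nrow(metabolites))
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  reactions$gpr[is.na(reactions$gpr)] <- ""
  model <- structure(list(
    metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
    reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
    stoichiometry = stoichiometry,
    genes = as.data.frame(genes, stringsAsFactors = FALSE),
    objective_id = objective_id
  ), class = "metabolic_model")
  if (validate) validate_model(model)
  model
}

#' Validate model integrity
#'
#' Checks the structural invariants: unique ids per namespace, known
#' compartments and reaction kinds, ordered finite bounds, non-empty
#' stoichiometries with finite nonzero coefficients over declared
#' metabolites, exchange reactions touching exactly one extracellular
#' metabolite, GPR genes declared, and a resolvable objective.
#'
#' @param model a \code{metabolic_model}.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id))
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id))
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (anyDuplicated(model$genes$id))
    stop("duplicate gene ids")
  bad <- setdiff(unique(met$compartment),
                 c("intracellular", "extracellular"))
  if (length(bad))
    stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(rxn$kind), REACTION_KINDS)
  if (length(bad))
    stop("unknown reaction kind(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(rxn$lower_bound)) || any(!is.finite(rxn$upper_bound)))
    stop("non-finite flux bounds")
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    i <- which(rxn$lower_bound > rxn$upper_bound)[1]
    stop("lower bound exceeds upper bound for reaction ", rxn$id[i])
  }
  if (!setequal(names(model$stoichiometry), rxn$id))
    stop("stoichiometry list does not match reaction ids")
  comp <- stats::setNames(met$compartment, met$id)
  for (rid in rxn$id) {
    s <- model$stoichiometry[[rid]]
    if (length(s) == 0)
      stop("empty stoichiometry for reaction ", rid)
    if (any(!is.finite(s)) || any(s == 0))
      stop("stoichiometry of reaction ", rid,
           " has non-finite or zero coefficients")
    unknown <- setdiff(names(s), met$id)
    if (length(unknown))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  ex <- rxn$id[rxn$kind == "exchange"]
  for (rid in ex) {
    s <- model$stoichiometry[[rid]]
    if (length(s) != 1)
      stop("exchange reaction ", rid, " must touch exactly one metabolite")
    if (comp[names(s)] != "extracellular")
      stop("exchange reaction ", rid, " touches a non-extracellular metabolite")
  }
  used_genes <- unique(unlist(lapply(rxn$gpr[nzchar(rxn$gpr)], gpr_genes)))
  missing <- setdiff(used_genes, model$genes$id)
  if (length(missing))
    stop("GPR references undeclared gene(s): ",
         paste(missing, collapse = ", "))
  if (!is.na(model$objective_id) &&
      !(model$objective_id %in% rxn$id))
    stop("objective reaction ", model$objective_id, " not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:",
      nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,",
      nrow(x$genes), "genes\n")
  cat("  objective:", x$objective_id, "\n")
  tab <- table(x$reactions$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Reaction ids of a given kind
#'
#' @param model a \code{metabolic_model}.
#' @param kind reaction kind, e.g. \code{"exchange"}.
#' @return Character vector of reaction ids.
#' @export
reactions_of_kind <- function(model, kind) {
  model$reactions$id[model$reactions$kind %in% kind]
}

#' Exchange reaction ids
#' @param model a \code{metabolic_model}.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_ids <- function(model) reactions_of_kind(model, "exchange")

#' Update flux bounds of a reaction
#'
#' Returns a modified copy; the input model is never touched. \code{fix_flux}
#' is the form used throughout the screens: fixing a measured rate sets both
#' bounds, passing a length-2 value sets an interval.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_id a reaction id present in the model.
#' @param value a single rate (applied as an equality, lower = upper) or a
#'   numeric length-2 vector \code{c(lo, hi)}.
#' @return The modified model.
#' @export
fix_flux <- function(model, reaction_id, value) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i))
    stop("unknown reaction id: ", reaction_id)
  if (length(value) == 1) value <- c(value, value)
  if (value[1] > value[2])
    stop("fix_flux: lo > hi for reaction ", reaction_id)
  model$reactions$lower_bound[i] <- value[1]
  model$reactions$upper_bound[i] <- value[2]
  model
}

#' Add a reaction to a model
#'
#' @param model a \code{metabolic_model}.
#' @param id,name reaction id and display name.
#' @param stoichiometry named numeric vector of metabolite coefficients.
#' @param lower_bound,upper_bound flux bounds.
#' @param gpr gene association string (default none).
#' @param subsystem pathway tag.
#' @param kind reaction kind (see \code{\link{metabolic_model}}).
#' @param validate re-validate the model afterwards.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound, upper_bound,
                         name = id, gpr = "", subsystem = "", kind = "intracellular",
                         validate = TRUE) {
  if (id %in% model$reactions$id)
    stop("reaction id already present: ", id)
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lower_bound,
    upper_bound = upper_bound, gpr = gpr, subsystem = subsystem,
    kind = kind, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  if (validate) validate_model(model)
  model
}

#' Remove a reaction from a model
#' @param model a \code{metabolic_model}.
#' @param id reaction id to drop.
#' @return The reduced model.
#' @export
remove_reaction <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  model$reactions <- model$reactions[-i, , drop = FALSE]
  model$stoichiometry[[id]] <- NULL
  model
}

#' Build the stoichiometric matrix
#'
#' Rows are metabolites and columns are reactions (the conventional
#' orientation), so the steady-state mass balance is \eqn{S v = 0}.
#'
#' @param model a \code{metabolic_model}.
#' @return A sparse \code{dgCMatrix} with dimnames
#'   \code{(metabolite ids, reaction ids)}.
#' @export
build_stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(rids)) {
    s <- model$stoichiometry[[rids[k]]]
    rows <- match(names(s), mids)
    if (anyNA(rows))
      stop("reaction ", rids[k], " references undeclared metabolite(s): ",
           paste(names(s)[is.na(rows)], collapse = ", "))
    ii <- c(ii, rows); jj <- c(jj, rep(k, length(s))); xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Metabolite connectivity
#'
#' Connectivity is the number of reactions in which a metabolite
#' participates (appears with a nonzero coefficient).
#'
#' @param model a \code{metabolic_model}.
#' @return Named integer vector over all metabolite ids.
#' @export
metabolite_connectivity <- function(model) {
  counts <- stats::setNames(integer(nrow(model$metabolites)),
                            model$metabolites$id)
  for (s in model$stoichiometry) {
    counts[names(s)] <- counts[names(s)] + 1L
  }
  counts
}
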