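# Plain-text model exchange format: a triplet of TSV files sharing a path
# prefix ("<prefix>.metabolites.tsv", "<prefix>.reactions.tsv",
# "<prefix>.genes.tsv"). Stoichiometry is serialized as "met:coeff;met:coeff"
# with a fixed significant-digit format so that write -> read -> write is
# byte-identical.

.num_fmt <- function(x) sprintf("%.15g", x)

.serialize_stoich <- function(s) {
  paste(sprintf("%s:%s", names(s), .num_fmt(unname(s))), collapse = ";")
}

.parse_stoich <- function(txt, rid) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed stoichiometry for reaction ", rid, ": ", txt)
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  vapply(kv, `[`, "", 1))
}

.write_tsv <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, quote = "")
}

#' Write a model
#'
#' @param model a \code{metabolic_model}.
#' @param path output path: the prefix of the TSV triplet, or the \code{.xml}
#'   file for SBML.
#' @param format \code{"tsv"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(write_model_sbml(model, path))
  met <- model$metabolites
  mdf <- data.frame(id = met$id, name = met$name,
                    compartment = met$compartment,
                    carbon = ifelse(is.na(met$carbon), "",
                                    .num_fmt(met$carbon)),
                    stringsAsFactors = FALSE)
  rxn <- model$reactions
  rdf <- data.frame(
    id = rxn$id, name = rxn$name,
    stoichiometry = vapply(model$stoichiometry[rxn$id], .serialize_stoich, ""),
    lower_bound = .num_fmt(rxn$lower_bound),
    upper_bound = .num_fmt(rxn$upper_bound),
    gpr = rxn$gpr, subsystem = rxn$subsystem, kind = rxn$kind,
    objective = ifelse(rxn$id == model$objective_id &
                         !is.na(model$objective_id), "1", "0"),
    stringsAsFactors = FALSE)
  gdf <- data.frame(id = model$genes$id, name = model$genes$name,
                    stringsAsFactors = FALSE)
  .write_tsv(mdf, paste0(path, ".metabolites.tsv"))
  .write_tsv(rdf, paste0(path, ".reactions.tsv"))
  .write_tsv(gdf, paste0(path, ".genes.tsv"))
  invisible(path)
}

#' Read a model
#'
#' @param path path prefix of the TSV triplet, or an SBML file.
#' @param format \code{"tsv"} or \code{"sbml"}.
#' @return A validated \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(read_model_sbml(path))
  mdf <- .read_tsv(paste0(path, ".metabolites.tsv"))
  rdf <- .read_tsv(paste0(path, ".reactions.tsv"))
  gdf <- .read_tsv(paste0(path, ".genes.tsv"))
  need <- c("id", "name", "stoichiometry", "lower_bound", "upper_bound",
            "gpr", "subsystem", "kind", "objective")
  missing <- setdiff(need, names(rdf))
  if (length(missing))
    stop("reactions file lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!nzchar(rdf$lower_bound)) || any(!nzchar(rdf$upper_bound))) {
    i <- which(!nzchar(rdf$lower_bound) | !nzchar(rdf$upper_bound))[1]
    stop("reaction ", rdf$id[i], " lacks flux bounds")
  }
  metabolites <- data.frame(
    id = mdf$id, name = mdf$name, compartment = mdf$compartment,
    carbon = ifelse(nzchar(mdf$carbon), suppressWarnings(as.numeric(mdf$carbon)),
                    NA_real_),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = rdf$id, name = rdf$name,
    lower_bound = as.numeric(rdf$lower_bound),
    upper_bound = as.numeric(rdf$upper_bound),
    gpr = rdf$gpr, subsystem = rdf$subsystem, kind = rdf$kind,
    stringsAsFactors = FALSE)
  stoich <- stats::setNames(
    Map(.parse_stoich, rdf$stoichiometry, rdf$id), rdf$id)
  obj <- rdf$id[rdf$objective == "1"]
  metabolic_model(metabolites, reactions, stoich,
                  genes = data.frame(id = gdf$id, name = gdf$name,
                                     stringsAsFactors = FALSE),
                  objective_id = if (length(obj)) obj[1] else NA_character_)
}
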