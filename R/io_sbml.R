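# SBML import/export.
#
# The writer emits SBML Level 3 Version 1 with the fbc (version 2) extension:
# flux bounds as global parameters referenced per reaction, gene associations
# as fbc:geneProductAssociation trees, and the objective in
# fbc:listOfObjectives. Reaction kind, subsystem and skeleton carbon counts
# travel in notes so a write -> read round trip is lossless.
#
# The reader tolerates both dialects found in distributed models: Level 3
# fbc bounds and Level 2 kinetic-law LOWER_BOUND/UPPER_BOUND parameters with
# notes-based GENE_ASSOCIATION strings. Unknown annotations are ignored with
# a warning. Reactions without any bound declaration get the conventional
# defaults (reversible: -1000..1000, irreversible: 0..1000), with a warning.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.gpr_to_fbc <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (node$op == "gene")
    return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                   pad, node$id))
  tag <- if (node$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(node$args, .gpr_to_fbc, "", indent = indent + 2)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

#' Write a model as SBML (Level 3 + fbc)
#'
#' @param model a \code{metabolic_model}.
#' @param path output \code{.xml} path.
#' @return \code{path}, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  met <- model$metabolites
  rxn <- model$reactions
  comp_of <- ifelse(met$compartment == "extracellular", "e", "c")

  # unique bound parameters
  bounds <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)),
                         .num_fmt(bounds))
  par_xml <- sprintf(
    "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
    pid, names(pid))

  sp_xml <- sprintf(paste0(
    "      <species id=\"%s\" name=\"%s\" compartment=\"%s\"",
    " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
    " constant=\"false\">\n",
    "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
    "<p>CARBON: %s</p></body></notes>\n",
    "      </species>"),
    met$id, .xml_escape(met$name), comp_of,
    ifelse(is.na(met$carbon), "NA", .num_fmt(met$carbon)))

  rxn_xml <- vapply(seq_len(nrow(rxn)), function(i) {
    s <- model$stoichiometry[[rxn$id[i]]]
    reac <- s[s < 0]; prod <- s[s > 0]
    ref <- function(sp, coef)
      sprintf(paste0("          <speciesReference species=\"%s\"",
                     " stoichiometry=\"%s\" constant=\"true\"/>"),
              sp, .num_fmt(abs(coef)))
    parts <- character(0)
    parts <- c(parts, sprintf(paste0(
      "      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\"",
      " fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
      rxn$id[i], .xml_escape(rxn$name[i]),
      if (rxn$lower_bound[i] < 0) "true" else "false",
      pid[.num_fmt(rxn$lower_bound[i])], pid[.num_fmt(rxn$upper_bound[i])]))
    parts <- c(parts, sprintf(paste0(
      "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
      "<p>KIND: %s</p><p>SUBSYSTEM: %s</p></body></notes>"),
      rxn$kind[i], .xml_escape(rxn$subsystem[i])))
    if (nzchar(rxn$gpr[i])) {
      ast <- .gpr_parse(rxn$gpr[i])
      parts <- c(parts, "        <fbc:geneProductAssociation>",
                 .gpr_to_fbc(ast, 10),
                 "        </fbc:geneProductAssociation>")
    }
    if (length(reac))
      parts <- c(parts, "        <listOfReactants>",
                 ref(names(reac), reac), "        </listOfReactants>")
    if (length(prod))
      parts <- c(parts, "        <listOfProducts>",
                 ref(names(prod), prod), "        </listOfProducts>")
    parts <- c(parts, "      </reaction>")
    paste(parts, collapse = "\n")
  }, "")

  gp_xml <- if (nrow(model$genes)) sprintf(paste0(
    "      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>"),
    model$genes$id, .xml_escape(model$genes$name)) else character(0)

  obj_xml <- if (!is.na(model$objective_id)) c(
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\"",
                   " fbc:coefficient=\"1\"/>"), model$objective_id),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>") else character(0)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    "  <model id=\"model\" fbc:strict=\"true\">",
    "    <listOfCompartments>",
    "      <compartment id=\"c\" name=\"cytosol\" constant=\"true\"/>",
    "      <compartment id=\"e\" name=\"extracellular\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>", sp_xml, "    </listOfSpecies>",
    "    <listOfParameters>", par_xml, "    </listOfParameters>",
    "    <listOfReactions>", rxn_xml, "    </listOfReactions>",
    obj_xml,
    "    <fbc:listOfGeneProducts>", gp_xml, "    </fbc:listOfGeneProducts>",
    "  </model>",
    "</sbml>")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(xml2::xml_attr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
  inner <- vapply(kids, .fbc_to_gpr, "")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(inner, collapse = op), ")")
}

.sbml_note <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  hit <- grep(paste0("^", key, ":"), txt, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(paste0("^", key, ":"), "", hit[1]))
}

#' Read a model from SBML
#'
#' Accepts Level 3 models with fbc flux bounds and gene products, and Level 2
#' models with kinetic-law LOWER_BOUND/UPPER_BOUND parameters and
#' notes-encoded GENE_ASSOCIATION strings. Species flagged as boundary
#' conditions are dropped from stoichiometries (the usual Level 2 exchange
#' encoding).
#'
#' @param path SBML file.
#' @return A validated \code{metabolic_model}.
#' @export
read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)

  comp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  comp_names <- tolower(paste(xml2::xml_attr(comp_nodes, "name"), comp_ids))
  extra <- comp_ids[grepl("extra|external|^e$|_e$|boundary", comp_names)]

  sp <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  scomp <- xml2::xml_attr(sp, "compartment")
  sbound <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  scarbon <- vapply(sp, function(n) {
    v <- .sbml_note(n, "CARBON")
    if (is.na(v) || v == "NA") NA_real_ else suppressWarnings(as.numeric(v))
  }, 0)
  keep <- !sbound
  metabolites <- data.frame(
    id = sid[keep],
    name = ifelse(is.na(sname[keep]), sid[keep], sname[keep]),
    compartment = ifelse(scomp[keep] %in% extra, "extracellular",
                         "intracellular"),
    carbon = scarbon[keep], stringsAsFactors = FALSE)
  boundary_ids <- sid[sbound]

  # fbc bound parameters
  pars <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  n <- length(rx)
  rid <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rid))
    stop("duplicate reaction ids in SBML: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  rname <- xml2::xml_attr(rx, "name")
  rname <- ifelse(is.na(rname), rid, rname)
  rev <- xml2::xml_attr(rx, "reversible") %in% c("true", NA)

  lb <- ub <- rep(NA_real_, n)
  gpr <- character(n)
  kind <- subsystem <- rep(NA_character_, n)
  stoich <- vector("list", n)
  warned_default <- FALSE

  for (i in seq_len(n)) {
    node <- rx[[i]]
    # stoichiometry
    sref <- function(which) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", which))
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    re <- sref("listOfReactants"); pr <- sref("listOfProducts")
    re[is.na(re)] <- 1; pr[is.na(pr)] <- 1
    s <- c(-re, pr)
    s <- s[!(names(s) %in% boundary_ids)]
    s <- tapply(s, names(s), sum)   # merge duplicated species refs
    s <- s[s != 0]
    stoich[[i]] <- stats::setNames(as.numeric(s), names(s))

    # bounds: fbc attributes, else kinetic-law parameters, else defaults
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(parval)) lb[i] <- parval[[lbp]]
    if (!is.na(ubp) && ubp %in% names(parval)) ub[i] <- parval[[ubp]]
    if (is.na(lb[i]) || is.na(ub[i])) {
      kl <- xml2::xml_find_all(node, paste0(
        ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb[i]) && "LOWER_BOUND" %in% kid)
        lb[i] <- kval[match("LOWER_BOUND", kid)]
      if (is.na(ub[i]) && "UPPER_BOUND" %in% kid)
        ub[i] <- kval[match("UPPER_BOUND", kid)]
    }
    if (is.na(lb[i]) || is.na(ub[i])) {
      if (is.na(lb[i])) lb[i] <- if (rev[i]) -1000 else 0
      if (is.na(ub[i])) ub[i] <- 1000
      if (!warned_default) {
        warning("reaction ", rid[i],
                " (and possibly others) lacks flux bounds; using ",
                "reversibility defaults", call. = FALSE)
        warned_default <- TRUE
      }
    }

    # gene association
    ga <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kid <- xml2::xml_children(ga)
      kid <- kid[xml2::xml_name(kid) %in% c("and", "or", "geneProductRef")]
      gpr[i] <- if (length(kid)) .fbc_to_gpr(kid[[1]]) else ""
    } else {
      ganote <- .sbml_note(node, "GENE_ASSOCIATION")
      gpr[i] <- if (!is.na(ganote)) ganote else ""
    }

    kind[i] <- .sbml_note(node, "KIND")
    subsystem[i] <- .sbml_note(node, "SUBSYSTEM")
  }

  # infer kinds when the file carries none
  compart <- stats::setNames(metabolites$compartment, metabolites$id)
  for (i in seq_len(n)) {
    if (!is.na(kind[i])) next
    s <- stoich[[i]]
    cc <- unique(compart[names(s)])
    kind[i] <- if (length(s) <= 1 &&
                   (grepl("^(EX|R_EX)_", rid[i]) ||
                    identical(unname(cc), "extracellular"))) "exchange"
      else if (grepl("biomass", rid[i], ignore.case = TRUE)) "biomass"
      else if (length(cc) > 1) "transport"
      else if (identical(unname(cc), "extracellular")) "extracellular"
      else "intracellular"
  }
  subsystem[is.na(subsystem)] <- ""

  gp <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- data.frame(
    id = xml2::xml_attr(gp, "id"),
    name = xml2::xml_attr(gp, "label"),
    stringsAsFactors = FALSE)
  if (!nrow(genes)) {
    gids <- unique(unlist(lapply(gpr[nzchar(gpr)], gpr_genes)))
    genes <- data.frame(id = gids, name = gids, stringsAsFactors = FALSE)
  }
  genes$name[is.na(genes$name)] <- genes$id[is.na(genes$name)]

  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  objective <- if (!inherits(fo, "xml_missing"))
    xml2::xml_attr(fo, "reaction") else NA_character_
  if (is.na(objective)) {
    bio <- rid[kind == "biomass"]
    if (length(bio)) objective <- bio[1]
  }

  reactions <- data.frame(id = rid, name = rname, lower_bound = lb,
                          upper_bound = ub, gpr = gpr, subsystem = subsystem,
                          kind = kind, stringsAsFactors = FALSE)
  metabolic_model(metabolites, reactions,
                  stats::setNames(stoich, rid), genes, objective)
}
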