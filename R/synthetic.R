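# Miniature heterofermentative lactic-acid-bacterium network generator.
#
# The toy network carries the metabolic features that drive the analyses:
# hexose catabolism through the 6-phosphogluconate/phosphoketolase route to
# D-lactate, acetate, ethanol and CO2; NAD+-regenerating mannitol and
# erythritol branches fed by fructose; proton-consuming malolactic
# decarboxylation with lactic-acid efflux that exports protons; a lumped
# citrate lyase; a proton-gradient-driven ATP synthase (protons re-enter the
# cell only through it, and leave it only with lactate or CO2 efflux); a
# biomass reaction over amino acids, sugar phosphate, pyruvate and ATP; an
# ATP-hydrolysis maintenance (NGAM) reaction; and exchanges for all boundary
# species, with a mix of essential and synthesizable amino acids.
#
# The carbon table assigns every metabolite a skeleton carbon count
# (cofactor pairs carry equal counts, inorganic species zero), so every
# non-exchange, non-biomass reaction is carbon balanced and checkable.

#' Configuration for the toy LAB network generator
#'
#' @param seed integer recorded with the model (generation itself is
#'   deterministic).
#' @param include_malolactic add the malolactic pathway (malate uptake,
#'   proton-consuming decarboxylation, lactic-acid efflux, malate
#'   dehydrogenase shunt to oxaloacetate).
#' @param include_citrate add the lumped citrate lyase route.
#' @param n_essential_amino_acids number of amino acids with no biosynthetic
#'   route (uptake-only).
#' @param n_synthesizable_amino_acids number of amino acids with a reversible
#'   transamination shunt (1 = alanine from pyruvate; 2 adds aspartate from
#'   oxaloacetate, which requires citrate or malolactic routes).
#' @param protons_per_atp ATP synthase stoichiometry (external protons
#'   translocated per ATP).
#' @param mannitol_branch,erythritol_branch NAD+-regenerating polyol branches.
#' @param oxygen_branch NADH oxidase sink with an oxygen exchange.
#' @param planted_orphan_metabolites number of dead-end metabolites planted
#'   as products with no consumer.
#' @param ethanol_cap upper flux bound of the lumped acetaldehyde/alcohol
#'   dehydrogenase (mmol gDW^-1 h^-1); a finite cap reflects the limited
#'   ethanol-forming capacity that makes the polyol branches valuable.
#' @param phosphoketolase_cap upper flux bound of phosphoketolase
#'   (mmol gDW^-1 h^-1); a capacity below the total hexose supply routes
#'   surplus sugar phosphate into the exopolysaccharide drain, which keeps
#'   growth energy-limited rather than carbon-limited.
#' @param gam growth-associated ATP requirement embedded in the biomass
#'   reaction (mmol ATP per gDW biomass).
#' @return A list of class \code{toy_network_config}.
#' @export
toy_network_config <- function(seed = 1L,
                               include_malolactic = TRUE,
                               include_citrate = TRUE,
                               n_essential_amino_acids = 3L,
                               n_synthesizable_amino_acids = 1L,
                               protons_per_atp = 3L,
                               mannitol_branch = TRUE,
                               erythritol_branch = TRUE,
                               oxygen_branch = TRUE,
                               planted_orphan_metabolites = 2L,
                               ethanol_cap = 4,
                               phosphoketolase_cap = 12,
                               gam = 40) {
  stopifnot(n_essential_amino_acids >= 0,
            n_synthesizable_amino_acids >= 0,
            planted_orphan_metabolites >= 0,
            protons_per_atp >= 1, ethanol_cap >= 0,
            phosphoketolase_cap > 0, gam > 0)
  if (n_synthesizable_amino_acids >= 2 &&
      !include_citrate && !include_malolactic)
    stop("aspartate synthesis needs an oxaloacetate source: enable ",
         "include_citrate or include_malolactic")
  structure(list(seed = as.integer(seed),
                 include_malolactic = include_malolactic,
                 include_citrate = include_citrate,
                 n_essential_amino_acids = as.integer(n_essential_amino_acids),
                 n_synthesizable_amino_acids = as.integer(n_synthesizable_amino_acids),
                 protons_per_atp = as.integer(protons_per_atp),
                 mannitol_branch = mannitol_branch,
                 erythritol_branch = erythritol_branch,
                 oxygen_branch = oxygen_branch,
                 planted_orphan_metabolites = as.integer(planted_orphan_metabolites),
                 ethanol_cap = ethanol_cap,
                 phosphoketolase_cap = phosphoketolase_cap,
                 gam = gam),
            class = "toy_network_config")
}

#' Generate the toy heterofermentative LAB model
#'
#' Builds the miniature network described in the package vignette, applies
#' the default complete medium to its exchange bounds, and (optionally)
#' records ground truth: the reference optimum, the essential nutrients and
#' reactions found by brute-force re-solves, the planted orphan metabolites,
#' the measured-exchange roles used by the synthetic-rate generator, and the
#' reaction roles used by ATP accounting.
#'
#' @param config a \code{\link{toy_network_config}}.
#' @param ground_truth compute the reference FBA and brute-force essentiality
#'   sets (costs ~2 LPs per reaction; disable for bulk property testing).
#' @return List with elements \code{model} (a \code{metabolic_model} with the
#'   default medium applied), \code{medium} (the default complete medium) and
#'   \code{ground_truth}.
#' @export
make_toy_lab_model <- function(config = toy_network_config(),
                               ground_truth = TRUE) {
  stopifnot(inherits(config, "toy_network_config"))
  cfg <- config

  mets <- list()   # id -> c(name, compartment, carbon)
  met <- function(id, name, comp, carbon) {
    mets[[id]] <<- list(name = name, compartment = comp, carbon = carbon)
  }
  rxns <- list()
  rxn <- function(id, s, lb, ub, name = id, gpr = "", subsystem = "",
                  kind = "intracellular") {
    rxns[[id]] <<- list(s = s, lb = lb, ub = ub, name = name, gpr = gpr,
                        subsystem = subsystem, kind = kind)
  }

  # --- core metabolites ------------------------------------------------
  met("glc_e", "alpha-D-glucose", "extracellular", 6)
  met("fru_e", "beta-D-fructose", "extracellular", 6)
  met("fru_c", "beta-D-fructose", "intracellular", 6)
  met("g6p_c", "glucose 6-phosphate", "intracellular", 6)
  met("f6p_c", "fructose 6-phosphate", "intracellular", 6)
  met("x5p_c", "xylulose 5-phosphate", "intracellular", 5)
  met("g3p_c", "glyceraldehyde 3-phosphate", "intracellular", 3)
  met("dpg13_c", "1,3-bisphosphoglycerate", "intracellular", 3)
  met("pep_c", "phosphoenolpyruvate", "intracellular", 3)
  met("pyr_c", "pyruvate", "intracellular", 3)
  met("pyr_e", "pyruvate", "extracellular", 3)
  met("actp_c", "acetyl phosphate", "intracellular", 2)
  met("ac_e", "acetate", "extracellular", 2)
  met("etoh_e", "ethanol", "extracellular", 2)
  met("lacD_c", "D-lactate", "intracellular", 3)
  met("lacD_e", "D-lactate", "extracellular", 3)
  met("co2_c", "carbon dioxide", "intracellular", 1)
  met("co2_e", "carbon dioxide", "extracellular", 1)
  met("glyc_e", "glycerol", "extracellular", 3)
  met("nh4_e", "ammonium", "extracellular", 0)
  met("pi_e", "orthophosphate", "extracellular", 0)
  met("h2o_c", "water", "intracellular", 0)
  met("h2o_e", "water", "extracellular", 0)
  met("h_c", "proton", "intracellular", 0)
  met("h_e", "proton", "extracellular", 0)
  met("ade_e", "adenine", "extracellular", 5)
  met("nac_e", "nicotinate", "extracellular", 6)
  met("atp_c", "ATP", "intracellular", 10)
  met("adp_c", "ADP", "intracellular", 10)
  met("pi_c", "orthophosphate", "intracellular", 0)
  met("nad_c", "NAD+", "intracellular", 11)
  met("nadh_c", "NADH", "intracellular", 11)

  FX <- 1000  # conventional proxy for an unbounded flux

  # --- phosphoketolase backbone ---------------------------------------
  rxn("HEXT", c(glc_e = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
      0, FX, "glucose permease + hexokinase (lumped)", "g_hex",
      "Phosphoketolase pathway", "transport")
  rxn("FRUt", c(fru_e = -1, fru_c = 1), 0, FX,
      "fructose permease", "g_fruT", "Transport", "transport")
  rxn("FRUK", c(fru_c = -1, atp_c = -1, f6p_c = 1, adp_c = 1, h_c = 1),
      0, FX, "fructokinase", "g_frk", "Phosphoketolase pathway")
  rxn("F6PI", c(g6p_c = -1, f6p_c = 1), -FX, FX,
      "glucose-6-phosphate isomerase", "g_pgi", "Phosphoketolase pathway")
  rxn("GND", c(g6p_c = -1, nad_c = -2, x5p_c = 1, co2_c = 1,
               nadh_c = 2, h_c = 2),
      0, FX, "oxidative 6-phosphogluconate branch (lumped)",
      "g_gnd1 and g_gnd2", "Phosphoketolase pathway")
  rxn("PKETX", c(x5p_c = -1, pi_c = -1, g3p_c = 1, actp_c = 1, h2o_c = 1),
      0, cfg$phosphoketolase_cap, "phosphoketolase", "g_xpk",
      "Phosphoketolase pathway")
  rxn("GAPD", c(g3p_c = -1, pi_c = -1, nad_c = -1, dpg13_c = 1,
                nadh_c = 1, h_c = 1),
      0, FX, "glyceraldehyde-3-phosphate dehydrogenase", "g_gap",
      "Glycolysis (lower)")
  rxn("PGK", c(dpg13_c = -1, adp_c = -1, pep_c = 1, atp_c = 1, h2o_c = 1),
      0, FX, "phosphoglycerate kinase + mutase + enolase (lumped)", "g_pgk",
      "Glycolysis (lower)")
  rxn("PYK", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
      0, FX, "pyruvate kinase", "g_pyk", "Glycolysis (lower)")

  # --- fermentation products ------------------------------------------
  rxn("LDHD", c(pyr_c = -1, nadh_c = -1, h_c = -1, lacD_c = 1, nad_c = 1),
      0, FX, "D-lactate dehydrogenase", "g_ldh1 or g_ldh2", "Fermentation")
  rxn("LACDt", c(lacD_c = -1, lacD_e = 1), 0, FX,
      "D-lactate efflux", "", "Transport", "transport")
  rxn("ACK", c(actp_c = -1, adp_c = -1, ac_e = 1, atp_c = 1), 0, FX,
      "acetate kinase + efflux (lumped)", "g_ack", "Fermentation")
  rxn("ETOHDH", c(actp_c = -1, nadh_c = -2, h_c = -2, etoh_e = 1,
                  nad_c = 2, pi_c = 1),
      0, cfg$ethanol_cap,
      "phosphotransacetylase + acetaldehyde/alcohol dehydrogenase (lumped)",
      "g_adh", "Fermentation")
  rxn("PYRt", c(pyr_c = -1, pyr_e = 1), 0, FX,
      "pyruvate efflux", "", "Transport", "transport")
  rxn("CO2t", c(co2_c = -1, h_c = -1, co2_e = 1, h_e = 1), 0, FX,
      "carbonic acid efflux (proton-exporting)", "", "Transport", "transport")
  rxn("CO2D", c(co2_c = -1, co2_e = 1), 0, FX,
      "carbon dioxide diffusion (proton-neutral)", "", "Transport",
      "transport")
  rxn("H2Ot", c(h2o_e = -1, h2o_c = 1), -FX, FX,
      "water diffusion", "", "Transport", "transport")
  rxn("PIt", c(pi_e = -1, pi_c = 1), -FX, FX,
      "phosphate transport", "g_pit", "Transport", "transport")
  rxn("ADPSYN", c(ade_e = -1, x5p_c = -1, pi_c = -1, adp_c = 1, h2o_c = 1),
      -FX, FX, "adenylate salvage (lumped, reversible)", "g_apt",
      "Cofactor metabolism", "transport")
  rxn("NADSYN", c(nac_e = -1, x5p_c = -1, atp_c = -1, nad_c = 1, adp_c = 1,
                  pi_c = 1),
      -FX, FX, "NAD salvage (lumped, reversible)", "g_nadS",
      "Cofactor metabolism", "transport")

  # --- exopolysaccharide drain ------------------------------------------
  # EPS biosynthesis from sugar phosphate gives the hexose-phosphate pool a
  # secretion valve, so growth can fall below the carbon-permitted maximum
  # (e.g. under a high maintenance burden) without violating mass balance.
  met("eps_e", "exopolysaccharide repeat unit", "extracellular", 6)
  rxn("EPSS", c(g6p_c = -1, eps_e = 1, pi_c = 1), 0, FX,
      "exopolysaccharide synthase + export (lumped)", "g_eps",
      "Exopolysaccharide biosynthesis", "transport")

  # --- acetoin / 2,3-butanediol branch ---------------------------------
  met("actn_c", "acetoin", "intracellular", 4)
  met("btd_e", "2,3-butanediol", "extracellular", 4)
  rxn("ALS", c(pyr_c = -2, h_c = -1, actn_c = 1, co2_c = 2), 0, FX,
      "acetolactate synthase + decarboxylase (lumped)", "g_als",
      "Acetoin metabolism")
  rxn("BTDD", c(actn_c = -1, nadh_c = -1, h_c = -1, btd_e = 1, nad_c = 1),
      0, FX, "2,3-butanediol dehydrogenase + efflux (lumped)", "g_btd",
      "Acetoin metabolism")

  # --- polyol redox branches ------------------------------------------
  if (cfg$mannitol_branch) {
    met("mnl_e", "D-mannitol", "extracellular", 6)
    rxn("MTLD", c(fru_c = -1, nadh_c = -1, h_c = -1, mnl_e = 1, nad_c = 1),
        0, FX, "mannitol dehydrogenase + efflux (lumped)", "g_mtl",
        "Mannitol branch")
  }
  if (cfg$erythritol_branch) {
    met("e4p_c", "erythrose 4-phosphate", "intracellular", 4)
    met("eryth_e", "erythritol", "extracellular", 4)
    rxn("TKT", c(f6p_c = -1, g3p_c = -1, e4p_c = 1, x5p_c = 1), -FX, FX,
        "transketolase", "g_tkt", "Erythritol branch")
    rxn("ERYD", c(e4p_c = -1, nadh_c = -1, h_c = -1, eryth_e = 1,
                  nad_c = 1, pi_c = 1),
        0, FX, "erythrose-4-phosphate reductase + phosphatase + efflux (lumped)",
        "g_ery", "Erythritol branch")
  }

  # --- malolactic fermentation ----------------------------------------
  if (cfg$include_malolactic) {
    met("mal_e", "(S)-malate", "extracellular", 4)
    met("mal_c", "(S)-malate", "intracellular", 4)
    met("lacL_c", "L-lactate", "intracellular", 3)
    met("lacL_e", "L-lactate", "extracellular", 3)
    rxn("MALt", c(mal_e = -1, mal_c = 1), 0, FX,
        "malate uniport", "g_malT", "Malolactic fermentation", "transport")
    rxn("MLE", c(mal_c = -1, h_c = -1, lacL_c = 1, co2_c = 1), 0, FX,
        "malolactic enzyme (proton-consuming decarboxylation)", "g_mle",
        "Malolactic fermentation")
    rxn("LDHL", c(pyr_c = -1, nadh_c = -1, h_c = -1, lacL_c = 1, nad_c = 1),
        0, FX, "L-lactate dehydrogenase", "g_ldhL", "Fermentation")
    rxn("LACLt", c(lacL_c = -1, h_c = -1, lacL_e = 1, h_e = 1), 0, FX,
        "L-lactic acid efflux (proton-exporting)", "", "Transport",
        "transport")
  }
  if (cfg$include_malolactic || cfg$include_citrate)
    met("oaa_c", "oxaloacetate", "intracellular", 4)
  if (cfg$include_malolactic) {
    rxn("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1, h_c = 1),
        0, FX, "malate dehydrogenase", "g_mdhB", "Malolactic fermentation")
  }

  # --- citrate ---------------------------------------------------------
  if (cfg$include_citrate) {
    met("cit_e", "citrate", "extracellular", 6)
    rxn("CITL", c(cit_e = -1, oaa_c = 1, ac_e = 1), 0, FX,
        "citrate diffusion + citrate lyase complex (lumped)", "g_cit",
        "Citrate metabolism", "transport")
  }
  if (cfg$include_malolactic || cfg$include_citrate) {
    rxn("OAADC", c(oaa_c = -1, h_c = -1, pyr_c = 1, co2_c = 1), 0, FX,
        "oxaloacetate decarboxylase", "g_oad", "Citrate metabolism")
  }

  # --- oxygen sink ------------------------------------------------------
  if (cfg$oxygen_branch) {
    met("o2_e", "oxygen", "extracellular", 0)
    rxn("NOX", c(nadh_c = -1, h_c = -1, o2_e = -0.5, nad_c = 1, h2o_c = 1),
        0, FX, "NADH oxidase (water-forming)", "g_nox", "Oxidative stress")
    rxn("POX", c(pyr_c = -1, pi_c = -1, o2_e = -0.5, actp_c = 1, co2_c = 1,
                 h2o_c = 1),
        0, 3, "pyruvate oxidase", "g_pox", "Oxidative stress")
  }

  # --- amino acids ------------------------------------------------------
  ess_ids <- character(0)
  if (cfg$n_essential_amino_acids > 0) {
    ess_names <- c("L-histidine", "L-leucine", "L-methionine",
                   "L-tryptophan", "L-valine", "L-isoleucine")
    for (i in seq_len(cfg$n_essential_amino_acids)) {
      id <- sprintf("aaE%d_e", i)
      nm <- if (i <= length(ess_names)) ess_names[i]
            else sprintf("essential amino acid %d", i)
      met(id, nm, "extracellular", 5)
      ess_ids <- c(ess_ids, id)
    }
  }
  syn_ids <- character(0)
  if (cfg$n_synthesizable_amino_acids >= 1) {
    met("ala_e", "L-alanine", "extracellular", 3)
    met("ala_c", "L-alanine", "intracellular", 3)
    rxn("ALAt", c(ala_e = -1, ala_c = 1), 0, FX,
        "alanine uptake", "", "Transport", "transport")
    rxn("ALAS", c(pyr_c = -1, nh4_e = -1, nadh_c = -1, ala_c = 1,
                  nad_c = 1, h2o_c = 1),
        -FX, FX, "alanine dehydrogenase (reversible transamination shunt)",
        "g_alaD", "Amino acid metabolism")
    syn_ids <- c(syn_ids, "ala_e")
  }
  if (cfg$n_synthesizable_amino_acids >= 2) {
    met("asp_e", "L-aspartate", "extracellular", 4)
    met("asp_c", "L-aspartate", "intracellular", 4)
    rxn("ASPt", c(asp_e = -1, asp_c = 1), 0, FX,
        "aspartate uptake", "", "Transport", "transport")
    rxn("ASPS", c(oaa_c = -1, nh4_e = -1, nadh_c = -1, asp_c = 1,
                  nad_c = 1, h2o_c = 1),
        -FX, FX, "aspartate dehydrogenase (reversible transamination shunt)",
        "g_aspC", "Amino acid metabolism")
    syn_ids <- c(syn_ids, "asp_e")
  }
  if (cfg$n_synthesizable_amino_acids > 2) {
    for (i in seq_len(cfg$n_synthesizable_amino_acids - 2L)) {
      ide <- sprintf("aaS%d_e", i); idc <- sprintf("aaS%d_c", i)
      met(ide, sprintf("synthesizable amino acid %d", i), "extracellular", 3)
      met(idc, sprintf("synthesizable amino acid %d", i), "intracellular", 3)
      rxn(sprintf("AASt%d", i), stats::setNames(c(-1, 1), c(ide, idc)),
          0, FX, "amino acid uptake", "", "Transport", "transport")
      rxn(sprintf("AASS%d", i),
          stats::setNames(c(-1, -1, -1, 1, 1, 1),
                          c("pyr_c", "nh4_e", "nadh_c", idc, "nad_c", "h2o_c")),
          -FX, FX, "transamination shunt", sprintf("g_aas%d", i),
          "Amino acid metabolism")
    }
  }

  # --- energy: ATP synthase and maintenance ----------------------------
  k <- cfg$protons_per_atp
  rxn("ATPS",
      c(adp_c = -1, pi_c = -1, h_e = -k, atp_c = 1, h2o_c = 1, h_c = k),
      0, FX, sprintf("F0F1 ATP synthase (%d H+ per ATP)", k),
      "g_atp1 and g_atp2", "Energy", "transport")

  # --- biomass ----------------------------------------------------------
  bm <- c(pyr_c = -0.4,
          atp_c = -cfg$gam, h2o_c = -cfg$gam,
          adp_c = cfg$gam, pi_c = cfg$gam, h_c = cfg$gam)
  for (id in ess_ids) bm[id] <- -0.3
  if (cfg$n_synthesizable_amino_acids >= 1) bm["ala_c"] <- -0.5
  if (cfg$n_synthesizable_amino_acids >= 2) bm["asp_c"] <- -0.4
  if (cfg$n_synthesizable_amino_acids > 2)
    for (i in seq_len(cfg$n_synthesizable_amino_acids - 2L))
      bm[sprintf("aaS%d_c", i)] <- -0.2
  rxn("BIOMASS", bm, 0, FX, "biomass assembly", "", "Biomass", "biomass")
  rxn("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      0, 0, "ATP maintenance requirement", "", "Maintenance", "ngam")

  # --- planted orphan metabolites --------------------------------------
  orphans <- character(0)
  if (cfg$planted_orphan_metabolites > 0) {
    for (i in seq_len(cfg$planted_orphan_metabolites)) {
      id <- sprintf("orph%d_c", i)
      met(id, sprintf("orphan by-product %d", i), "intracellular", 3)
      rxn(sprintf("ORPHS%d", i), stats::setNames(c(-1, 1), c("pyr_c", id)),
          0, FX, sprintf("orphan by-product synthesis %d", i), "",
          "Orphan", "intracellular")
      orphans <- c(orphans, id)
    }
  }

  # --- exchanges --------------------------------------------------------
  ext <- names(mets)[vapply(mets, function(m) m$compartment, "") ==
                       "extracellular"]
  for (id in ext) {
    exid <- paste0("EX_", id)
    lb <- if (id == "h_e") 0 else -FX   # protons enter only via ATP synthase
    rxn(exid, stats::setNames(-1, id), lb, FX,
        paste(mets[[id]]$name, "exchange"), "", "Exchange", "exchange")
  }

  # --- assemble ---------------------------------------------------------
  metabolites <- data.frame(
    id = names(mets),
    name = vapply(mets, function(m) m$name, ""),
    compartment = vapply(mets, function(m) m$compartment, ""),
    carbon = vapply(mets, function(m) m$carbon, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  reactions <- data.frame(
    id = names(rxns),
    name = vapply(rxns, function(r) r$name, ""),
    lower_bound = vapply(rxns, function(r) r$lb, 0),
    upper_bound = vapply(rxns, function(r) r$ub, 0),
    gpr = vapply(rxns, function(r) r$gpr, ""),
    subsystem = vapply(rxns, function(r) r$subsystem, ""),
    kind = vapply(rxns, function(r) r$kind, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  stoich <- lapply(rxns, function(r) r$s)
  gids <- sort(unique(unlist(lapply(reactions$gpr[nzchar(reactions$gpr)],
                                    gpr_genes))))
  genes <- data.frame(id = gids, name = gids, stringsAsFactors = FALSE)
  model <- metabolic_model(metabolites, reactions, stoich, genes,
                           objective_id = "BIOMASS")

  medium <- default_toy_medium(config)
  model <- apply_medium(model, medium)

  roles <- list(
    acetate_kinase = "ACK", pyruvate_kinase = "PYK",
    phosphoglycerate_kinase = "PGK", hexokinase = "HEXT",
    fructokinase = "FRUK", atp_synthase = "ATPS",
    d_lactate_exchange = "EX_lacD_e", acetate_exchange = "EX_ac_e")
  measured <- list(
    consumption = intersect(c("EX_glc_e", "EX_fru_e", "EX_mal_e",
                              "EX_cit_e"), reactions$id),
    production = intersect(c("EX_mnl_e", "EX_lacL_e", "EX_lacD_e", "EX_ac_e",
                             "EX_eryth_e", "EX_etoh_e"), reactions$id))

  gt <- list(seed = cfg$seed, orphan_metabolites = orphans,
             reaction_roles = roles, measured_exchanges = measured,
             essential_amino_acid_exchanges = paste0("EX_", ess_ids),
             synthesizable_amino_acid_exchanges = paste0("EX_", syn_ids),
             true_ngam = 0, optimal_mu = NA_real_,
             essential_nutrients = NULL, essential_reactions = NULL)

  if (ground_truth) {
    wt <- solve_fba(model)
    if (wt$status != "optimal" || !grows(wt$mu))
      stop("generated toy model fails to grow on its default medium")
    gt$optimal_mu <- wt$mu
    # brute-force omission: close each medium uptake in turn
    ess_nut <- character(0)
    for (i in seq_len(nrow(medium))) {
      m2 <- fix_flux(model, medium$exchange_id[i],
                     c(0, model$reactions$upper_bound[
                         match(medium$exchange_id[i], model$reactions$id)]))
      s <- solve_fba(m2)
      mu <- if (s$status == "optimal") s$mu else 0
      if (is.na(mu) || mu < 0.2 * wt$mu)
        ess_nut <- c(ess_nut, medium$nutrient[i])
    }
    gt$essential_nutrients <- ess_nut
    # brute-force reaction knockouts
    ess_rxn <- character(0)
    for (rid in reactions$id) {
      s <- solve_fba(fix_flux(model, rid, 0))
      mu <- if (s$status == "optimal") s$mu else 0
      if (is.na(mu) || mu < 0.2 * wt$mu) ess_rxn <- c(ess_rxn, rid)
    }
    gt$essential_reactions <- ess_rxn
  }

  list(model = model, medium = medium, ground_truth = gt)
}

#' Default complete medium for the toy network
#'
#' @param config the \code{\link{toy_network_config}} used to build the model.
#' @return A \code{medium} data frame (nutrient, exchange_id, max_uptake,
#'   always_open).
#' @export
default_toy_medium <- function(config = toy_network_config()) {
  comp <- list(
    list("D-glucose", "EX_glc_e", 10, FALSE),
    list("D-fructose", "EX_fru_e", 10, FALSE))
  if (config$include_malolactic)
    comp <- c(comp, list(list("L-malate", "EX_mal_e", 8, FALSE)))
  if (config$include_citrate)
    comp <- c(comp, list(list("citrate", "EX_cit_e", 2, FALSE)))
  if (config$n_synthesizable_amino_acids >= 1)
    comp <- c(comp, list(list("L-alanine", "EX_ala_e", 10, FALSE)))
  if (config$n_synthesizable_amino_acids >= 2)
    comp <- c(comp, list(list("L-aspartate", "EX_asp_e", 10, FALSE)))
  if (config$n_synthesizable_amino_acids > 2)
    for (i in seq_len(config$n_synthesizable_amino_acids - 2L))
      comp <- c(comp, list(list(sprintf("synthesizable amino acid %d", i),
                                sprintf("EX_aaS%d_e", i), 2, FALSE)))
  if (config$n_essential_amino_acids > 0)
    for (i in seq_len(config$n_essential_amino_acids))
      comp <- c(comp, list(list(sprintf("essential amino acid %d", i),
                                sprintf("EX_aaE%d_e", i), 5, FALSE)))
  comp <- c(comp, list(list("ammonium", "EX_nh4_e", 10, FALSE),
                       list("phosphate", "EX_pi_e", 5, FALSE),
                       list("adenine", "EX_ade_e", 1, FALSE),
                       list("nicotinate", "EX_nac_e", 1, FALSE)))
  if (config$oxygen_branch)
    comp <- c(comp, list(list("oxygen", "EX_o2_e", 20, FALSE)))
  comp <- c(comp, list(list("water", "EX_h2o_e", 1000, TRUE)))
  medium(data.frame(
    nutrient = vapply(comp, `[[`, "", 1),
    exchange_id = vapply(comp, `[[`, "", 2),
    max_uptake = vapply(comp, function(x) as.numeric(x[[3]]), 0),
    always_open = vapply(comp, `[[`, TRUE, 4),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic measured-exchange-rate dataset at known NGAM
#'
#' Fixes the maintenance reaction at \code{true_ngam}, solves FBA on the
#' model as constrained by its medium, reads off the fluxes of the measured
#' species (sugars, organic acids, alanine, fermentation products), and
#' optionally perturbs them with multiplicative Gaussian noise. The observed
#' growth rate is the noiseless optimum.
#'
#' @param toy the list returned by \code{\link{make_toy_lab_model}}, or a
#'   \code{metabolic_model} that contains an \code{ATPM} maintenance reaction
#'   and carries measured-exchange roles via the \code{measured} argument.
#' @param true_ngam maintenance flux, mmol ATP gDW^-1 h^-1, in [0, 5].
#' @param noise_sd_rel relative standard deviation of multiplicative noise.
#'   Noise is applied to the generating condition (the uptake capacities of
#'   the medium), not independently to each extracted rate: rates measured on
#'   a real, mass-conserving culture always satisfy the network's
#'   conservation laws, and independent per-rate noise would violate them in
#'   a network this small, making every equality-constrained fit infeasible.
#'   The noisy rate table therefore deviates from the nominal rates by about
#'   \code{noise_sd_rel} while remaining stoichiometrically consistent.
#' @param seed RNG seed for the noise draws.
#' @param measured optional list with \code{consumption} and
#'   \code{production} exchange-id vectors (defaults to the generator's).
#' @return List with \code{rates} (a \code{rate_constraint_set}) and
#'   \code{ground_truth} (\code{true_ngam}, \code{optimal_mu}).
#' @export
make_synthetic_rates <- function(toy, true_ngam, noise_sd_rel = 0, seed = 1L,
                                 measured = NULL) {
  if (inherits(toy, "metabolic_model")) {
    model <- toy
    if (is.null(measured)) stop("measured exchange roles required")
  } else {
    model <- toy$model
    if (is.null(measured)) measured <- toy$ground_truth$measured_exchanges
  }
  stopifnot(true_ngam >= 0, true_ngam <= 5, noise_sd_rel >= 0)
  if (!"ATPM" %in% model$reactions$id)
    stop("model lacks the ATPM maintenance reaction; call add_ngam_reaction()")
  m <- fix_flux(model, "ATPM", true_ngam)
  sol <- solve_fba(m)
  if (sol$status != "optimal" || !grows(sol$mu))
    stop("model infeasible (or zero growth) at NGAM = ", true_ngam)
  mu_obs <- sol$mu

  if (noise_sd_rel > 0) {
    if (inherits(toy, "metabolic_model") || is.null(toy$medium))
      stop("noisy rate generation needs the generator's medium ",
           "(pass the full make_toy_lab_model() result)")
    med <- toy$medium
    vary <- !med$always_open
    noisy <- .with_seed(seed, {
      f <- pmax(0, 1 + stats::rnorm(sum(vary), 0, noise_sd_rel))
      med$max_uptake[vary] <- med$max_uptake[vary] * f
      med
    })
    m <- fix_flux(apply_medium(model, noisy), "ATPM", true_ngam)
    sol <- solve_fba(m)
    if (sol$status != "optimal")
      stop("perturbed condition infeasible at NGAM = ", true_ngam)
  }

  ids <- c(measured$consumption, measured$production)
  dirs <- c(rep("consumption", length(measured$consumption)),
            rep("production", length(measured$production)))
  rate <- abs(sol$fluxes[ids])
  rates <- rate_constraint_set(
    data.frame(reaction_id = ids, rate = as.numeric(rate), direction = dirs,
               stringsAsFactors = FALSE),
    observed_mu = mu_obs)
  list(rates = rates,
       ground_truth = list(true_ngam = true_ngam, optimal_mu = mu_obs))
}

#' Load the packaged in-vivo/in-silico validation table
#'
#' The fixture transcribes the published validation table for the 454-gene
#' O. oeni reconstruction: nutrient rows grouped into carbon sources, amino
#' acids, nucleotides, minerals and vitamins, each with the in-vivo growth
#' call, the in-silico call, and the printed TP/TN/FP/FN label.
#'
#' @return A data frame with columns \code{item}, \code{category},
#'   \code{in_vivo}, \code{in_silico_paper} (both \code{"growth"} or
#'   \code{"no_growth"}) and \code{result_label}.
#' @export
load_validation_fixture <- function() {
  path <- system.file("extdata", "validation_table.tsv", package = "oenoflux",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$in_vivo <- ifelse(df$in_vivo == "+", "growth", "no_growth")
  df$in_silico_paper <- ifelse(df$in_silico_paper == "+", "growth",
                               "no_growth")
  df
}
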