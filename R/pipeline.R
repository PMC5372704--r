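# End-to-end analysis pipeline with a reproducible report bundle.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline run configuration
#'
#' @param model path to the model (TSV triplet prefix or SBML file).
#' @param model_format \code{"tsv"} or \code{"sbml"}.
#' @param medium optional medium TSV path.
#' @param rates optional measured-rates TSV path (enables the NGAM fit, ATP
#'   accounting inputs and sensitivity stages).
#' @param out_dir output directory for the report bundle.
#' @param seed RNG seed for the sampling stage.
#' @param growth_fraction_threshold,essentiality_reduction_threshold screen
#'   thresholds (see \code{\link{screen_config}},
#'   \code{\link{deletion_config}}).
#' @param fraction_of_optimum near-optimal floor for FVA/sampling, in (0, 1].
#' @param sample_points,sample_thinning sampler settings; set
#'   \code{sample_points = 0} to skip sampling.
#' @return A \code{run_config} list.
#' @export
run_config <- function(model, model_format = c("tsv", "sbml"),
                       medium = NULL, rates = NULL, out_dir = "results",
                       seed = 1L,
                       growth_fraction_threshold = 0.20,
                       essentiality_reduction_threshold = 0.80,
                       fraction_of_optimum = 0.9,
                       sample_points = 0L, sample_thinning = 100L) {
  structure(list(model = model, model_format = match.arg(model_format),
                 medium = medium, rates = rates, out_dir = out_dir,
                 seed = as.integer(seed),
                 growth_fraction_threshold = growth_fraction_threshold,
                 essentiality_reduction_threshold =
                   essentiality_reduction_threshold,
                 fraction_of_optimum = fraction_of_optimum,
                 sample_points = as.integer(sample_points),
                 sample_thinning = as.integer(sample_thinning)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the \code{\link{run_config}}
#'   arguments.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load and validate the model; FBA; FVA with blocked
#' reactions and dead-end metabolites; nutrient-omission and reaction/gene
#' deletion screens (when a medium is given); NGAM fit, ATP accounting and
#' scaled-reduced-cost sensitivity (when measured rates are given);
#' hit-and-run sampling of the near-optimal subspace (when requested). Every
#' artifact lands in \code{out_dir} next to a manifest recording inputs,
#' seed, package version and per-stage wall-clock. A stage failure aborts
#' with the stage name; artifacts of completed stages are kept.
#'
#' @param config a \code{\link{run_config}}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("oenoflux")),
    seed = config$seed,
    inputs = list(model = config$model, medium = config$medium,
                  rates = config$rates),
    settings = config[c("growth_fraction_threshold",
                        "essentiality_reduction_threshold",
                        "fraction_of_optimum", "sample_points",
                        "sample_thinning")],
    stages = list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  outfile <- function(x) file.path(config$out_dir, x)

  model <- stage("load_model", {
    m <- read_model(config$model, config$model_format)
    validate_model(m)
    m
  })
  med <- NULL
  if (!is.null(config$medium)) {
    med <- stage("load_medium", read_medium(config$medium))
    model <- apply_medium(model, med)
  }

  sol <- stage("fba", {
    s <- solve_fba(model)
    if (s$status != "optimal")
      stop("FBA not optimal: ", s$status)
    .write_tsv(data.frame(reaction_id = names(s$fluxes),
                          flux = .num_fmt(s$fluxes),
                          reduced_cost = .num_fmt(s$reduced_costs),
                          stringsAsFactors = FALSE),
               outfile("fba_fluxes.tsv"))
    s
  })

  stage("fva_blocked", {
    rng <- fva(model)
    blk <- find_blocked(model)
    rng$blocked <- rng$reaction_id %in% blk
    .write_tsv(data.frame(reaction_id = rng$reaction_id,
                          min_flux = .num_fmt(rng$min_flux),
                          max_flux = .num_fmt(rng$max_flux),
                          span = .num_fmt(rng$span),
                          blocked = ifelse(rng$blocked, "TRUE", "FALSE"),
                          stringsAsFactors = FALSE),
               outfile("fva.tsv"))
    dead <- find_dead_ends_functional(model)
    .write_tsv(data.frame(metabolite_id = dead, stringsAsFactors = FALSE),
               outfile("dead_end_metabolites.tsv"))
    NULL
  })

  if (!is.null(med)) {
    stage("screens", {
      sc <- screen_config(config$growth_fraction_threshold)
      dc <- deletion_config(config$essentiality_reduction_threshold)
      om <- single_omission_screen(model, med, sc)
      .write_tsv(data.frame(item = om$item,
                            wild_type_mu = .num_fmt(om$wild_type_mu),
                            perturbed_mu = .num_fmt(om$perturbed_mu),
                            call = om$call, stringsAsFactors = FALSE),
                 outfile("omission_screen.tsv"))
      del <- single_reaction_deletion(model, config = dc)
      .write_tsv(data.frame(item = del$calls$item,
                            perturbed_mu = .num_fmt(del$calls$perturbed_mu),
                            essential = ifelse(del$calls$essential, "TRUE",
                                               "FALSE"),
                            subsystem = del$calls$subsystem,
                            stringsAsFactors = FALSE),
                 outfile("reaction_deletion.tsv"))
      .write_tsv(del$pathway_summary, outfile("essential_pathways.tsv"))
      NULL
    })
  }

  if (!is.null(config$rates)) {
    rates <- stage("load_rates", read_rates(config$rates))
    stage("ngam_sensitivity", {
      m2 <- add_ngam_reaction(model)
      fit <- fit_ngam(m2, rates)
      .write_json(list(best_ngam = fit$best_ngam,
                       predicted_mu_at_best = fit$predicted_mu_at_best,
                       observed_mu = fit$observed_mu,
                       curve = fit$curve),
                  outfile("ngam_fit.json"))
      con <- .apply_rates(m2, rates)
      con <- fix_flux(con, "ATPM", fit$best_ngam)
      s <- solve_fba(con)
      if (s$status == "optimal") {
        sens <- scaled_reduced_costs(con, s)
        .write_tsv(data.frame(
          reaction_id = sens$reaction_id, direction = sens$direction,
          reduced_cost = .num_fmt(sens$reduced_cost),
          scaled_reduced_cost = .num_fmt(sens$scaled_reduced_cost),
          stringsAsFactors = FALSE), outfile("sensitivity.tsv"))
      }
      NULL
    })
  }

  if (config$sample_points > 0) {
    stage("sampling", {
      near <- constrain_near_optimal(model,
                                     fraction = config$fraction_of_optimum)
      ss <- hit_and_run_sample(near, sampler_config(
        n_points = config$sample_points,
        thinning_steps = config$sample_thinning,
        seed = config$seed))
      top <- top_variable_reactions(ss, model,
                                    k = min(50L, ncol(ss$samples)))
      .write_tsv(data.frame(
        reaction_id = top$ranking$reaction_id,
        subsystem = top$ranking$subsystem,
        flux_range = .num_fmt(top$ranking$flux_range),
        stringsAsFactors = FALSE), outfile("variable_reactions.tsv"))
      .write_json(ss$feasibility_report, outfile("sampling_feasibility.json"))
      NULL
    })
  }

  .write_json(manifest, outfile("manifest.json"))
  invisible(manifest)
}
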