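test_that("apply_medium closes unlisted uptakes and opens listed ones", {
  m <- TOY$model
  med <- TOY$medium
  con <- apply_medium(m, med)
  ex <- exchange_ids(con)
  listed <- med$exchange_id
  for (rid in ex) {
    i <- match(rid, con$reactions$id)
    if (rid %in% listed) {
      expect_equal(con$reactions$lower_bound[i],
                   -med$max_uptake[med$exchange_id == rid])
    } else {
      expect_equal(con$reactions$lower_bound[i], 0)
    }
    # secretion bounds untouched
    j <- match(rid, m$reactions$id)
    expect_equal(con$reactions$upper_bound[i], m$reactions$upper_bound[j])
  }

  empty <- medium(data.frame(nutrient = character(0),
                             exchange_id = character(0),
                             max_uptake = numeric(0),
                             always_open = logical(0)))
  expect_equal(solve_fba(apply_medium(m, empty))$mu, 0)

  expect_error(apply_medium(m, medium(data.frame(
    nutrient = "x", exchange_id = "PYK", max_uptake = 1))),
    "non-exchange")
  expect_error(apply_medium(m, medium(data.frame(
    nutrient = "x", exchange_id = "EX_nope", max_uptake = 1))),
    "absent")
})

test_that("medium files round trip", {
  f <- file.path(tempdir(), "medium.tsv")
  write_medium(TOY$medium, f)
  back <- read_medium(f)
  expect_equal(back$exchange_id, TOY$medium$exchange_id)
  expect_equal(back$max_uptake, TOY$medium$max_uptake)
  expect_equal(back$always_open, TOY$medium$always_open)
})

test_that("omission screen finds exactly the ground-truth essentials", {
  calls <- single_omission_screen(TOY$model, TOY$medium)
  expect_equal(nrow(calls), nrow(TOY$medium))
  essential <- calls$item[calls$call == "no_growth"]
  expect_setequal(essential, TOY$ground_truth$essential_nutrients)
  # the synthesizable amino acid has a biosynthetic shunt: never essential
  expect_true("L-alanine" %in% calls$item[calls$call == "growth"])
  # screen consistency: every call is confirmed by an independent re-solve
  wt <- calls$wild_type_mu[1]
  for (i in seq_len(nrow(calls))) {
    m2 <- apply_medium(TOY$model, TOY$medium[-i, , drop = FALSE])
    mu <- solve_fba(m2)$mu
    if (is.na(mu)) mu <- 0
    expect_equal(calls$call[i] == "no_growth", mu < 0.2 * wt)
  }
})

test_that("omitting a nutrient with zero optimal uptake keeps growth", {
  # glycerol has no catabolic route; add it to the medium and omit it
  med <- medium(rbind(as.data.frame(TOY$medium), data.frame(
    nutrient = "glycerol", exchange_id = "EX_glyc_e", max_uptake = 5,
    always_open = FALSE)))
  calls <- single_omission_screen(TOY$model, med)
  expect_equal(calls$call[calls$item == "glycerol"], "growth")
})

test_that("omission screen requires a growing wild type", {
  empty <- medium(data.frame(nutrient = "water", exchange_id = "EX_h2o_e",
                             max_uptake = 1000, always_open = TRUE))
  expect_error(single_omission_screen(TOY$model, empty), "does not grow")
})

test_that("carbon-source screen distinguishes usable sources", {
  med <- TOY$medium
  # alanine is itself catabolizable, so the carbon-free base excludes it;
  # growth on a sugar then relies on the alanine biosynthesis shunt
  base <- medium(med[!med$exchange_id %in%
                       c("EX_glc_e", "EX_fru_e", "EX_mal_e", "EX_cit_e",
                         "EX_ala_e"), ])
  calls <- carbon_source_screen(TOY$model, base,
                                c("EX_glc_e", "EX_fru_e", "EX_glyc_e"))
  expect_equal(calls$call[calls$item == "EX_glc_e"], "growth")
  expect_equal(calls$call[calls$item == "EX_fru_e"], "growth")
  expect_equal(calls$call[calls$item == "EX_glyc_e"], "no_growth")
  # alanine alone also sustains growth (pyruvate oxidase route)
  ala <- carbon_source_screen(TOY$model, base, "EX_ala_e")
  expect_equal(ala$call, "growth")

  expect_equal(nrow(carbon_source_screen(TOY$model, base, character(0))), 0)
  expect_error(carbon_source_screen(TOY$model, TOY$medium, "EX_glc_e"),
               "confounded")
})

test_that("gene deletions respect GPR logic", {
  calls <- single_gene_deletion(TOY$model)
  byid <- stats::setNames(calls$essential, calls$item)
  # isozyme pair: neither D-lactate dehydrogenase gene is essential alone
  expect_false(byid[["g_ldh1"]])
  expect_false(byid[["g_ldh2"]])
  # a gene absent from every active pathway's GPR is never essential
  expect_false(byid[["g_eps"]])
  # confirm each essential call by explicit knockout
  wt <- solve_fba(TOY$model)$mu
  for (g in names(byid)[byid]) {
    dead <- which(!vapply(TOY$model$reactions$gpr, evaluate_gpr, TRUE,
                          knocked_out = g))
    m2 <- TOY$model
    m2$reactions$lower_bound[dead] <- 0
    m2$reactions$upper_bound[dead] <- 0
    mu <- solve_fba(m2)$mu
    if (is.na(mu)) mu <- 0
    expect_lt(mu, 0.2 * wt)
  }
})

test_that("reaction deletions match the generator's ground truth", {
  res <- single_reaction_deletion(TOY$model)
  essential <- res$calls$item[res$calls$essential]
  expect_setequal(essential, TOY$ground_truth$essential_reactions)
  expect_true("BIOMASS" %in% essential)
  # blocked reactions carry no flux, so deleting them changes nothing
  expect_false(any(c("ORPHS1", "ORPHS2", "EX_glyc_e") %in% essential))
  # pathway summary counts the essential set
  expect_equal(sum(res$pathway_summary$essential_reactions),
               length(essential))
})

test_that("adding nutrients never lowers the optimum", {
  med <- TOY$medium
  for (seed in 1:25) {
    set.seed(seed)
    keep <- sort(sample(nrow(med), sample(3:nrow(med), 1)))
    small <- medium(med[keep, , drop = FALSE])
    extra <- setdiff(seq_len(nrow(med)), keep)
    if (!length(extra)) next
    add <- extra[sample.int(length(extra), 1)]
    bigger <- medium(med[sort(c(keep, add)), , drop = FALSE])
    mu_small <- solve_fba(apply_medium(TOY$model, small))$mu
    mu_big <- solve_fba(apply_medium(TOY$model, bigger))$mu
    if (is.na(mu_small)) mu_small <- 0
    if (is.na(mu_big)) mu_big <- 0
    expect_gte(mu_big, mu_small - 1e-8)
  }
})

test_that("classification and metrics follow their definitions", {
  fx <- load_validation_fixture()
  out <- classify_outcomes(
    stats::setNames(fx$in_silico_paper, fx$item),
    stats::setNames(fx$in_vivo, fx$item))
  # the fixture's printed labels are reproduced row by row
  expect_equal(out$labels$result,
               fx$result_label[match(out$labels$item, fx$item)])
  cm <- out$confusion
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, nrow(fx))

  same <- stats::setNames(rep(c("growth", "no_growth"), 5), paste0("i", 1:10))
  out2 <- classify_outcomes(same, same)
  expect_equal(out2$confusion$fp + out2$confusion$fn, 0L)
  flipped <- ifelse(same == "growth", "no_growth", "growth")
  names(flipped) <- names(same)
  out3 <- classify_outcomes(same, flipped)
  expect_equal(out3$confusion$tp + out3$confusion$tn, 0L)
  expect_error(classify_outcomes(same, same[-1]), "no in-vivo label")

  m <- compute_metrics(confusion_matrix(31, 27, 1, 3))
  expect_equal(m$sensitivity, 31 / 34, tolerance = 1e-12)
  expect_equal(m$specificity, 27 / 28, tolerance = 1e-12)
  expect_equal(m$precision, 31 / 32, tolerance = 1e-12)
  expect_equal(m$npv, 27 / 30, tolerance = 1e-12)
  expect_equal(m$accuracy, 58 / 62, tolerance = 1e-12)
  expect_equal(m$f_score, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))

  perfect <- compute_metrics(confusion_matrix(10, 10, 0, 0))
  expect_true(all(unlist(perfect) == 1))
  # harmonic-mean identity: precision == sensitivity == p implies F = p
  eq <- compute_metrics(confusion_matrix(6, 1, 2, 2))
  expect_equal(eq$precision, eq$sensitivity)
  expect_equal(eq$f_score, eq$precision)
  # undefined metrics are NaN, never zero
  und <- compute_metrics(confusion_matrix(0, 5, 0, 0))
  expect_true(is.nan(und$sensitivity))
  expect_true(is.nan(und$precision))
})
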