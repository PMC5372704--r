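test_that("stoichiometric matrix places coefficients correctly", {
  m <- chain_model()
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(S["A", "R1"], -1)
  expect_equal(S["B", "R1"], 1)
  expect_equal(S["A", "EX_A"], -1)
  expect_equal(S["B", "EX_A"], 0)

  empty <- metabolic_model(
    data.frame(id = character(0), name = character(0),
               compartment = character(0)),
    data.frame(id = character(0), name = character(0),
               lower_bound = numeric(0), upper_bound = numeric(0),
               gpr = character(0), subsystem = character(0),
               kind = character(0)),
    stoichiometry = list())
  expect_equal(dim(build_stoichiometric_matrix(empty)), c(0L, 0L))
})

test_that("adding a reaction adds one column and preserves existing entries", {
  m <- chain_model()
  S0 <- build_stoichiometric_matrix(m)
  m2 <- add_reaction(m, "R2", c(B = -1), 0, 50)
  S1 <- build_stoichiometric_matrix(m2)
  expect_equal(ncol(S1), ncol(S0) + 1L)
  expect_equal(as.matrix(S1[, colnames(S0)]), as.matrix(S0))
})

test_that("toy network is carbon balanced outside exchanges and biomass", {
  m <- TOY$model
  carbon <- stats::setNames(m$metabolites$carbon, m$metabolites$id)
  for (rid in m$reactions$id) {
    kind <- m$reactions$kind[m$reactions$id == rid]
    if (kind %in% c("exchange", "biomass")) next
    s <- m$stoichiometry[[rid]]
    expect_equal(sum(s * carbon[names(s)]), 0, tolerance = 1e-9,
                 label = paste("carbon balance of", rid))
  }
})

test_that("GPR evaluation agrees with exhaustive truth tables", {
  exprs <- list(
    "g1 and g2",
    "g1 or g2",
    "(g1 and g2) or g3",
    "g1 and (g2 or g3) and g4",
    "((g1 or g2) and (g3 or g4))",
    "g1 AND g2 OR g3"   # case-insensitive keywords, or binds loosest
  )
  genes <- c("g1", "g2", "g3", "g4")
  eval_ast <- function(txt, present) {
    # independent evaluation: rewrite to an R logical expression
    r <- gsub("\\bAND\\b", "&&", txt, ignore.case = TRUE)
    r <- gsub("\\bOR\\b", "||", r, ignore.case = TRUE)
    env <- as.list(stats::setNames(genes %in% present, genes))
    eval(parse(text = r), envir = env)
  }
  for (txt in exprs) {
    for (mask in 0:15) {
      ko <- genes[bitwAnd(mask, 2^(0:3)) > 0]
      expect_equal(evaluate_gpr(txt, ko), eval_ast(txt, setdiff(genes, ko)),
                   label = sprintf("'%s' with ko {%s}", txt,
                                   paste(ko, collapse = ",")))
    }
  }
  expect_true(evaluate_gpr("", c("g1")))
  expect_true(evaluate_gpr(NA, c("g1")))
})

test_that("malformed GPR expressions raise parse errors", {
  expect_error(evaluate_gpr("g1 and", "g1"), "parse error")
  expect_error(evaluate_gpr("(g1 or g2", "g1"), "parse error")
  expect_error(evaluate_gpr("g1 g2", "g1"), "parse error")
  expect_error(evaluate_gpr("and g1", "g1"), "parse error")
})

test_that("metabolite connectivity equals a brute-force scan", {
  m <- chain_model()
  cn <- metabolite_connectivity(m)
  expect_equal(unname(cn["B"]), 2L)   # produced by R1, drained by BIO

  toy <- TOY$model
  cn <- metabolite_connectivity(toy)
  brute <- vapply(toy$metabolites$id, function(mid)
    sum(vapply(toy$stoichiometry, function(s) mid %in% names(s), TRUE)),
    integer(1))
  expect_equal(unname(cn[names(brute)]), unname(brute))
  expect_true(all(cn >= 0 & cn <= nrow(toy$reactions)))
})

test_that("model validation rejects broken structures", {
  m <- chain_model()
  bad <- m
  bad$stoichiometry$R1 <- c(A = -1, ZZZ = 1)
  expect_error(validate_model(bad), "undeclared metabolite")
  bad <- m
  bad$reactions$lower_bound[2] <- 5
  bad$reactions$upper_bound[2] <- 1
  expect_error(validate_model(bad), "lower bound exceeds")
  bad <- m
  bad$metabolites <- rbind(bad$metabolites, bad$metabolites[1, ])
  expect_error(validate_model(bad), "duplicate metabolite")
  bad <- m
  bad$stoichiometry$EX_A <- c(A = -1, B = 1)
  expect_error(validate_model(bad), "exactly one metabolite")
  expect_error(fix_flux(m, "NOPE", 0), "unknown reaction")
})

test_that("TSV round trip is byte-identical and preserves structure", {
  toy <- TOY$model
  p1 <- file.path(tempdir(), "toy_a")
  p2 <- file.path(tempdir(), "toy_b")
  write_model(toy, p1)
  back <- read_model(p1)
  expect_equal(back$reactions$id, toy$reactions$id)
  expect_equal(back$reactions$lower_bound, toy$reactions$lower_bound)
  expect_equal(back$reactions$gpr, toy$reactions$gpr)
  expect_equal(back$objective_id, toy$objective_id)
  for (rid in toy$reactions$id)
    expect_equal(back$stoichiometry[[rid]][names(toy$stoichiometry[[rid]])],
                 toy$stoichiometry[[rid]])
  write_model(back, p2)
  for (part in c("metabolites", "reactions", "genes")) {
    f1 <- readBin(paste0(p1, ".", part, ".tsv"), "raw", 1e6)
    f2 <- readBin(paste0(p2, ".", part, ".tsv"), "raw", 1e6)
    expect_identical(f1, f2, label = paste("byte identity of", part))
  }
})

test_that("SBML round trip preserves the model", {
  toy <- TOY$model
  f <- file.path(tempdir(), "toy.xml")
  write_model(toy, f, format = "sbml")
  back <- read_model(f, format = "sbml")
  expect_equal(back$reactions$id, toy$reactions$id)
  expect_equal(back$reactions$lower_bound, toy$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, toy$reactions$upper_bound)
  expect_equal(back$reactions$kind, toy$reactions$kind)
  expect_equal(back$objective_id, toy$objective_id)
  expect_equal(sort(back$genes$id), sort(toy$genes$id))
  expect_equal(back$metabolites$compartment, toy$metabolites$compartment)
  for (rid in toy$reactions$id) {
    s0 <- toy$stoichiometry[[rid]]
    s1 <- back$stoichiometry[[rid]]
    expect_setequal(names(s1), names(s0))
    expect_equal(s1[names(s0)], s0, label = paste("stoichiometry of", rid))
  }
  # gpr semantics survive (string form may gain parentheses)
  for (rid in toy$reactions$id) {
    g0 <- toy$reactions$gpr[toy$reactions$id == rid]
    g1 <- back$reactions$gpr[back$reactions$id == rid]
    if (!nzchar(g0)) {
      expect_false(nzchar(g1))
    } else {
      for (ko in c(list(character(0)), as.list(gpr_genes(g0))))
        expect_equal(evaluate_gpr(g1, ko), evaluate_gpr(g0, ko))
    }
  }
  # fba agreement on the round-tripped model
  s0 <- solve_fba(toy)
  s1 <- solve_fba(back)
  expect_equal(s1$mu, s0$mu, tolerance = 1e-9)
})

test_that("legacy SBML with kinetic-law bounds and notes is read", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="cyt"/><compartment id="ext" name="extracellular"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="A_e" compartment="ext"/>',
    '<species id="A_c" compartment="cyt"/>',
    '<species id="bnd" compartment="ext" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="A_e"/></listOfReactants>',
    '<listOfProducts><speciesReference species="bnd"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-7"/>',
    '<parameter id="UPPER_BOUND" value="99"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="T_A" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: gA or gB</p></body></notes>',
    '<listOfReactants><speciesReference species="A_e"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c" stoichiometry="2"/>',
    '</listOfProducts></reaction>',
    '</listOfReactions></model></sbml>')
  f <- file.path(tempdir(), "legacy.xml")
  writeLines(l2, f)
  expect_warning(m <- read_model_sbml(f), "lacks flux bounds")
  expect_equal(nrow(m$reactions), 2L)
  i <- match("EX_A", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -7)
  expect_equal(m$reactions$upper_bound[i], 99)
  expect_equal(m$reactions$kind[i], "exchange")   # boundary species dropped
  expect_equal(m$stoichiometry$EX_A, c(A_e = -1))
  j <- match("T_A", m$reactions$id)
  expect_equal(m$reactions$lower_bound[j], 0)     # irreversible default
  expect_equal(m$stoichiometry$T_A[c("A_e", "A_c")], c(A_e = -1, A_c = 2))
  expect_false(evaluate_gpr(m$reactions$gpr[j], c("gA", "gB")))
  expect_true(evaluate_gpr(m$reactions$gpr[j], "gA"))
})

test_that("reading rejects a reactions table without bounds", {
  p <- file.path(tempdir(), "nobounds")
  write_model(chain_model(), p)
  rf <- paste0(p, ".reactions.tsv")
  txt <- readLines(rf)
  txt[2] <- sub("-10\t0", "\t", txt[2])
  writeLines(txt, rf)
  expect_error(read_model(p), "lacks flux bounds")
})
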