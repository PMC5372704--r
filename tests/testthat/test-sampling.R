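test_that("sampling is deterministic for a fixed seed", {
  m <- fix_flux(TOY$model, "ATPM", 2.3)
  cfg <- sampler_config(n_points = 50, thinning_steps = 5, seed = 42)
  s1 <- hit_and_run_sample(m, cfg)
  s2 <- hit_and_run_sample(m, cfg)
  expect_identical(s1$samples, s2$samples)
  s3 <- hit_and_run_sample(m, sampler_config(n_points = 50,
                                             thinning_steps = 5, seed = 43))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("a point polytope yields identical samples", {
  m <- chain_model()
  m <- fix_flux(m, "EX_A", -4)
  m <- fix_flux(m, "R1", 4)
  m <- fix_flux(m, "BIO", 4)
  ss <- hit_and_run_sample(m, sampler_config(n_points = 20,
                                             thinning_steps = 2, seed = 1))
  expect_equal(unname(apply(ss$samples, 2, stats::sd)), rep(0, 3))
  expect_equal(unname(ss$samples[1, ]), c(-4, 4, 4))
})

test_that("box polytope samples are uniform on the free coordinate", {
  # isolated 2-reaction cycle: v1 = v2, both in [0, 10]; the single free
  # coordinate is uniform on [0, 10] under the stationary distribution
  m <- metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"),
               compartment = "intracellular"),
    data.frame(id = c("R1", "R2"), name = c("R1", "R2"),
               lower_bound = 0, upper_bound = 10, gpr = "", subsystem = "",
               kind = "intracellular"),
    list(R1 = c(A = -1, B = 1), R2 = c(B = -1, A = 1)))
  n <- 4000
  ss <- hit_and_run_sample(m, sampler_config(n_points = n,
                                             thinning_steps = 3, seed = 7,
                                             warmup_points = 200))
  v <- ss$samples[, "R1"]
  se <- sqrt(100 / 12 / n)   # sd of U(0,10) is 10/sqrt(12)
  expect_lt(abs(mean(v) - 5), 3 * se)
  expect_equal(ss$samples[, "R1"], ss$samples[, "R2"])
  expect_true(all(v >= -1e-9 & v <= 10 + 1e-9))
})

test_that("every sample satisfies mass balance and bounds", {
  m <- fix_flux(TOY$model, "ATPM", 2.3)
  ss <- hit_and_run_sample(m, sampler_config(n_points = 500,
                                             thinning_steps = 10, seed = 3))
  expect_lt(ss$feasibility_report$max_mass_balance_residual, 1e-6)
  expect_lt(ss$feasibility_report$max_bound_violation, 1e-6)
})

test_that("near-optimal constraint pins the objective window", {
  m <- TOY$model
  s <- solve_fba(m)
  near <- constrain_near_optimal(m, fraction = 0.9)
  i <- match("BIOMASS", near$reactions$id)
  expect_equal(near$reactions$lower_bound[i], 0.9 * s$mu, tolerance = 1e-9)
  expect_equal(near$reactions$upper_bound[i], s$mu, tolerance = 1e-9)
  ss <- hit_and_run_sample(near, sampler_config(n_points = 300,
                                                thinning_steps = 10,
                                                seed = 5))
  mu <- ss$samples[, "BIOMASS"]
  expect_true(all(mu >= 0.9 * s$mu - 1e-6 & mu <= s$mu + 1e-6))

  exact <- constrain_near_optimal(m, fraction = 1)
  j <- match("BIOMASS", exact$reactions$id)
  expect_equal(exact$reactions$lower_bound[j],
               exact$reactions$upper_bound[j])
  expect_error(constrain_near_optimal(m, fraction = 0), "fraction")
  expect_error(constrain_near_optimal(m, fraction = 1.2), "fraction")
})

test_that("sampling an empty polytope fails before any step", {
  m <- fix_flux(chain_model(), "EX_A", -8)
  m <- fix_flux(m, "BIO", c(0, 3))
  expect_error(hit_and_run_sample(m), "empty")
})

test_that("variable-reaction ranking is stable and complete", {
  near <- constrain_near_optimal(fix_flux(TOY$model, "ATPM", 2.3),
                                 fraction = 0.9)
  ss <- hit_and_run_sample(near, sampler_config(n_points = 400,
                                                thinning_steps = 10,
                                                seed = 11))
  k <- 15
  top <- top_variable_reactions(ss, TOY$model, k = k)
  expect_equal(nrow(top$ranking), k)
  expect_true(all(diff(top$ranking$flux_range) <= 1e-12))
  expect_equal(sum(top$pathway_frequency$count), k)
  # the polyol branch is the designed degree of freedom
  expect_true(any(c("MTLD", "ERYD", "TKT") %in% top$ranking$reaction_id))

  # all-identical samples: zero ranges, id-sorted ties
  point <- ss
  point$samples <- point$samples[rep(1, 10), , drop = FALSE]
  allk <- top_variable_reactions(point, TOY$model,
                                 k = ncol(point$samples))
  expect_equal(allk$ranking$flux_range, rep(0, ncol(point$samples)))
  expect_equal(allk$ranking$reaction_id, sort(colnames(point$samples)))
  expect_error(top_variable_reactions(ss, TOY$model,
                                      k = ncol(ss$samples) + 1), "exceeds")
})
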