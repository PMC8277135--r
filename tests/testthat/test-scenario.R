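# scenario evaluation, comparison, stressor ranking

test_that("run_scenario reports 6 mortality posteriors with a logged policy", {
  net <- generate_network(synthetic_config(seed = 2))
  expect_message(res <- run_scenario(net, scenario_A()),
                 "processing_return_technique resolved by policy")
  expect_s3_class(res, "scenario_result")
  expect_length(res$posteriors, 6)
  sums <- tapply(res$table$probability,
                 paste(res$table$group, res$table$kind), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_match(res$fingerprint, "mining_intensity=75% removed")
})

test_that("fixing all parents of a mortality node reproduces its CPT row", {
  net <- generate_network(synthetic_config(seed = 2))
  ev <- list(mining_intensity = "100% removed",
             depth_of_extracted_sediment = ">30 cm",
             processing_return_technique = "at the bottom",
             suspended_sediment = "high", sediment_deposition = "high",
             contaminant_release = "significant")
  sc <- scenario("pinned", decisions = ev[1:3], evidence = ev[4:6])
  res <- run_scenario(net, sc)
  want <- cpt_row(net$cpts$indirect_mortality_infauna, ev)
  expect_equal(res$posteriors$infauna.indirect$prob, want, tolerance = 1e-9)
})

test_that("scenario posteriors agree with the enumeration oracle", {
  # reduced single-group model so that full enumeration stays tractable
  scheme <- mortality_scheme()
  s_int <- variable_spec("mining_intensity", names(intensity_levels()), "decision")
  s_sus <- variable_spec("suspended_sediment", c("low", "medium", "high"))
  s_dir <- variable_spec("direct_mortality_infauna", scheme$label)
  s_ind <- variable_spec("indirect_mortality_infauna", scheme$label)
  s_tot <- variable_spec("total_mortality_infauna", scheme$label)
  cpts <- list(
    cpt("suspended_sediment", character(), s_sus$states, list(), c(0.3, 0.4, 0.3)),
    build_direct_mortality_cpt("direct_mortality_infauna"),
    random_cpt(s_ind, list(s_sus), seed = 17, monotone = TRUE),
    build_total_mortality_cpt("direct_mortality_infauna",
                              "indirect_mortality_infauna",
                              "total_mortality_infauna"))
  net <- build_network(
    list(s_int, s_sus, s_dir, s_ind, s_tot), cpts,
    groups = list(infauna = list(direct = "direct_mortality_infauna",
                                 indirect = "indirect_mortality_infauna",
                                 total = "total_mortality_infauna")))
  sc <- scenario("mini", decisions = list(mining_intensity = "75% removed"),
                 evidence = list(suspended_sediment = "high"))
  res <- run_scenario(net, sc)
  ev <- c(sc$decisions, sc$evidence)
  for (key in c("infauna.total", "infauna.indirect")) {
    node <- res$posteriors[[key]]$variable
    want <- enum_posterior(net, node, ev, policy = "uniform")
    expect_lt(max(abs(res$posteriors[[key]]$prob - want)), 1e-9)
  }
})

test_that("compare_scenarios stacks per-scenario tables and rejects duplicates", {
  net <- generate_network(synthetic_config(seed = 2))
  a1 <- scenario("A1", decisions = scenario_A()$decisions)
  a2 <- scenario("A2", decisions = scenario_A()$decisions)
  tab <- suppressMessages(compare_scenarios(net, list(a1, a2)))
  p1 <- tab$probability[tab$scenario == "A1"]
  p2 <- tab$probability[tab$scenario == "A2"]
  expect_equal(p1, p2)
  expect_error(compare_scenarios(net, list(a1, a1)), "duplicate scenario names")
})

test_that("known contaminant release never lowers the indirect upper tail", {
  net <- generate_network(synthetic_config(seed = 2, monotone = TRUE))
  base <- scenario("base", decisions = scenario_A()$decisions)
  contam <- scenario("contam", decisions = scenario_A()$decisions,
                     evidence = list(contaminant_release = "significant"))
  tab <- suppressMessages(compare_scenarios(net, list(base, contam)))
  for (g in benthic_groups()) {
    pb <- tab$probability[tab$scenario == "base" & tab$group == g &
                          tab$kind == "indirect"]
    pc <- tab$probability[tab$scenario == "contam" & tab$group == g &
                          tab$kind == "indirect"]
    # upper-tail probabilities P(class >= k) never lower with contamination
    expect_true(all(rev(cumsum(rev(pc))) >= rev(cumsum(rev(pb))) - 1e-9))
  }
})

test_that("scenario runs are bit-reproducible", {
  net <- generate_network(synthetic_config(seed = 8))
  r1 <- suppressMessages(run_scenario(net, scenario_A()))
  r2 <- suppressMessages(run_scenario(net, scenario_A()))
  expect_identical(r1$table, r2$table)
})

test_that("rank_stressors orders by effect size with extremes reported", {
  # constructed fixture: contaminant release carries the largest weight
  press <- list(
    variable_spec("suspended_sediment", c("low", "medium", "high")),
    variable_spec("contaminant_release", c("low", "significant")))
  mort <- variable_spec("indirect_mortality", sprintf("m%d", 1:5))
  rk <- influence_ranking(
    "indirect_mortality",
    list(suspended_sediment = list(direction = +1, weight = 0.5),
         contaminant_release = list(direction = +1, weight = 3)))
  cpts <- list(
    cpt("suspended_sediment", character(), press[[1]]$states, list(), rep(1 / 3, 3)),
    cpt("contaminant_release", character(), press[[2]]$states, list(), c(0.8, 0.2)),
    initialize_cpt(mort, press, rk))
  net <- build_network(c(press, list(mort)), cpts)
  rep <- rank_stressors(net, "indirect_mortality",
                        c("contaminant_release", "suspended_sediment"),
                        baseline = scenario("base"))
  expect_equal(rep$ranking$stressor[1], "contaminant_release")
  expect_true(all(rep$ranking$effect_size >= 0))
  expect_true(!is.unsorted(rev(rep$ranking$effect_size)))
  expect_equal(rep$ranking$worst_state[1], "significant")

  # disconnected stressor: warning and zero effect
  spare <- variable_spec("noise", c("low", "high"))
  net2 <- build_network(c(press, list(mort, spare)),
                        c(cpts, list(cpt("noise", character(), spare$states,
                                         list(), c(0.5, 0.5)))))
  expect_warning(rep2 <- rank_stressors(net2, "indirect_mortality",
                                        c("noise", "contaminant_release"),
                                        baseline = scenario("base")),
                 "not an ancestor")
  expect_equal(rep2$ranking$effect_size[rep2$ranking$stressor == "noise"], 0)

  # factorial sweep row count = product of stressor state counts
  rep3 <- rank_stressors(net, "indirect_mortality",
                         c("contaminant_release", "suspended_sediment"),
                         baseline = scenario("base"), sweep = TRUE)
  expect_equal(nrow(rep3$sweep), 2 * 3)
})

test_that("scenario files round-trip", {
  scs <- list(scenario_A(), scenario_B())
  f <- withr::local_tempfile()
  write_scenario_file(scs, f)
  back <- read_scenario_file(f)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$decisions, scenario_A()$decisions)
  expect_equal(back$B$evidence, scenario_B()$evidence)
  expect_error(read_scenario_file(withr::local_tempfile(lines = "set x = y")),
               "unrecognized|before any")
})
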