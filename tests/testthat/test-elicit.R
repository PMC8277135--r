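# influence-ranking CPT initialization, manual adjustment, random CPTs

five <- variable_spec("mortality", sprintf("m%d", 1:5))
par3 <- variable_spec("pressure", c("low", "medium", "high"))

test_that("zero influence falls back to the baseline row for row", {
  base <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  rk <- influence_ranking("mortality",
                          list(pressure = list(direction = +1, weight = 0)),
                          baseline = base)
  ct <- initialize_cpt(five, list(par3), rk)
  for (i in 1:3) expect_equal(unname(ct$table[i, ]), base)

  rk0 <- influence_ranking("mortality",
                           list(pressure = list(direction = +1, weight = 0)))
  expect_error(initialize_cpt(five, list(par3), rk0), "no baseline")
})

test_that("a positive parent at its maximum drives the mode to the top state", {
  rk <- influence_ranking("mortality",
                          list(pressure = list(direction = +1, weight = 2)),
                          spread = 0.5)
  ct <- initialize_cpt(five, list(par3), rk)
  expect_equal(unname(which.max(ct$table["high", ])), 5)
  expect_equal(unname(which.max(ct$table["low", ])), 1)
  # expected child index is nondecreasing in the parent state (monotone
  # elicitation property)
  ev <- as.vector(ct$table %*% seq_len(5))
  expect_true(all(diff(ev[match(c("low", "medium", "high"), rownames(ct$table))]) >= 0))
})

test_that("opposite equal influences cancel to the mid-score row", {
  pa <- variable_spec("A", c("low", "medium", "high"))
  pb <- variable_spec("B", c("low", "medium", "high"))
  rk2 <- influence_ranking("mortality",
                           list(A = list(direction = +1, weight = 1.5),
                                B = list(direction = -1, weight = 1.5)))
  ct2 <- initialize_cpt(five, list(pa, pb), rk2)
  # single positive parent at its (neutral) middle state
  rk1 <- influence_ranking("mortality",
                           list(A = list(direction = +1, weight = 1.5)))
  ct1 <- initialize_cpt(five, list(pa), rk1)
  expect_equal(unname(ct2$table["high|high", ]), unname(ct1$table["medium", ]),
               tolerance = 1e-12)
})

test_that("scoring is symmetric under permutation of identical parents", {
  pa <- variable_spec("A", c("low", "high"))
  pb <- variable_spec("B", c("low", "high"))
  rk_ab <- influence_ranking("mortality",
                             list(A = list(direction = +1, weight = 1),
                                  B = list(direction = +1, weight = 1)))
  ct_ab <- initialize_cpt(five, list(pa, pb), rk_ab)
  ct_ba <- initialize_cpt(five, list(pb, pa), rk_ab)
  # same content at corresponding combinations
  expect_equal(unname(ct_ab$table["low|high", ]), unname(ct_ba$table["high|low", ]))
  expect_equal(unname(ct_ab$table["high|high", ]), unname(ct_ba$table["high|high", ]))
})

test_that("nominal parents use per-state offsets", {
  tech <- variable_spec("return", c("at the surface", "at the bottom"))
  rk <- influence_ranking("mortality",
                          list(return = list(offsets = c(0, 1), weight = 1)))
  ct <- initialize_cpt(five, list(tech), rk)
  expect_equal(unname(which.max(ct$table["at the bottom", ])), 5)
  expect_equal(unname(which.max(ct$table["at the surface", ])), 1)
})

test_that("default spread avoids false certainty at the neutral score", {
  rk <- influence_ranking("mortality",
                          list(pressure = list(direction = +1, weight = 1)))
  ct <- initialize_cpt(five, list(par3), rk)
  expect_gte(sum(ct$table["medium", ] >= 0.05), 3)
})

test_that("initialized and generated rows always sum to 1 within 1e-9", {
  for (s in 1:10) {
    ct <- random_cpt(five, list(par3), seed = s, concentration = 0.5,
                     monotone = s %% 2 == 0)
    expect_true(all(abs(rowSums(ct$table) - 1) < 1e-9))
  }
})

test_that("adjust_cpt replaces exactly the named rows with an audit trail", {
  ct <- random_cpt(five, list(par3), seed = 3)
  new_row <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  adj <- adjust_cpt(ct, list(list(combo = list(pressure = "medium"), p = new_row)))
  expect_equal(unname(adj$table["medium", ]), new_row)
  expect_equal(adj$table[c("low", "high"), ], ct$table[c("low", "high"), ])
  expect_equal(attr(adj, "audit")$row, "medium")

  # empty override list is the identity
  expect_identical(adjust_cpt(ct, list())$table, ct$table)
  expect_error(adjust_cpt(ct, list(list(combo = list(pressure = "huge"),
                                        p = new_row))),
               "unknown parent combination")

  # adjusted table survives a model-file round trip verbatim
  spec_list <- list(par3, variable_spec("mortality", sprintf("m%d", 1:5)))
  prior <- cpt("pressure", character(), par3$states, list(), rep(1 / 3, 3))
  net <- build_network(spec_list, list(prior, adj))
  f <- withr::local_tempfile()
  write_model_file(net, f)
  expect_identical(read_model_file(f)$cpts$mortality$table, adj$table)

  audit_file <- withr::local_tempfile()
  write_cpt_audit(adj, audit_file)
  expect_match(readLines(audit_file)[2], "^medium\t")
})

test_that("random_cpt is seed-deterministic and flattens at high concentration", {
  a <- random_cpt(five, list(par3), seed = 42, concentration = 1)
  b <- random_cpt(five, list(par3), seed = 42, concentration = 1)
  expect_identical(a$table, b$table)
  flat <- random_cpt(five, list(par3), seed = 42, concentration = 1e6)
  expect_true(max(abs(flat$table - 0.2)) < 0.01)
})

test_that("monotone CPTs satisfy pairwise first-order stochastic dominance", {
  pa <- variable_spec("A", c("low", "medium", "high"))
  pb <- variable_spec("B", c("low", "high"))
  for (s in 1:10) {
    ct <- random_cpt(five, list(pa, pb), seed = 100 + s, monotone = TRUE)
    grid <- expand.grid(A = pa$states, B = pb$states, stringsAsFactors = FALSE)
    score <- (match(grid$A, pa$states) - 1) / 2 + (match(grid$B, pb$states) - 1)
    cdf <- t(apply(ct$table, 1, cumsum))
    for (i in seq_len(nrow(grid))) {
      for (j in seq_len(nrow(grid))) {
        if (score[i] < score[j]) {
          expect_true(all(cdf[j, ] <= cdf[i, ] + 1e-12))
        }
      }
    }
  }
})

test_that("influence rankings round-trip through their file format", {
  rk <- influence_ranking(
    "mortality",
    list(pressure = list(direction = +1, weight = 2.5),
         return = list(offsets = c(0.1, 0.9), weight = 1)),
    baseline = c(0.1, 0.2, 0.4, 0.2, 0.1), spread = 0.8)
  f <- withr::local_tempfile()
  write_ranking_file(rk, f)
  back <- read_ranking_file(f)
  expect_equal(unclass(back), unclass(rk), tolerance = 1e-15)
})
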