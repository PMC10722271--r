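test_that("plot layout hosts the requested two-tier design without duplicate centers", {
  cfg <- landscape_config(extent = c(0, 0, 16000, 12000), cell_size = 20,
                          correlation_length = 800, seed = 3)
  lay <- generate_plot_layout(cfg, 114, 277,
                              focal_zone = c(2000, 1500, 14000, 10500))
  expect_equal(nrow(lay), 391)
  expect_equal(sum(lay$tier == "coarse"), 114)
  expect_equal(sum(lay$tier == "fine"), 277)
  expect_equal(anyDuplicated(paste(lay$x, lay$y)), 0)
  # coarse plots on the kilometer grid, inside the extent
  co <- lay[lay$tier == "coarse", ]
  expect_true(all(co$x %% 1000 == 0 & co$y %% 1000 == 0))
  expect_true(all(lay$x > 0 & lay$x < 16000 & lay$y > 0 & lay$y < 12000))
  # fine plots on the half-kilometer grid inside the focal zone
  fi <- lay[lay$tier == "fine", ]
  expect_true(all(fi$x %% 500 == 0 & fi$y %% 500 == 0))
  expect_true(all(fi$x >= 2000 & fi$x <= 14000 & fi$y >= 1500 & fi$y <= 10500))
})

test_that("layout sizing errors name the achievable maximum and empty layouts work", {
  cfg <- tiny_config()
  expect_error(generate_plot_layout(cfg, 10^6, 0), "holds only")
  lay0 <- generate_plot_layout(cfg, 0, 0, focal_zone = c(200, 200, 800, 600))
  expect_equal(nrow(lay0), 0)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  s1 <- generate_predictor_stack(cfg)
  s2 <- generate_predictor_stack(cfg)
  expect_identical(s1, s2)
  e1 <- generate_risk_elements(cfg)
  e2 <- generate_risk_elements(cfg)
  expect_identical(e1, e2)
  l1 <- generate_plot_layout(cfg, 5, 8, focal_zone = c(200, 200, 800, 600),
                             coarse_spacing = 200, fine_spacing = 100)
  l2 <- generate_plot_layout(cfg, 5, 8, focal_zone = c(200, 200, 800, 600),
                             coarse_spacing = 200, fine_spacing = 100)
  expect_identical(l1, l2)
  c1 <- simulate_communities(l1, s1, ground_truth(), seed = 9)
  c2 <- simulate_communities(l2, s2, ground_truth(), seed = 9)
  expect_identical(c1, c2)
})

test_that("risk element counts, types and geometry kinds are honored", {
  cfg <- tiny_config()
  els <- generate_risk_elements(cfg, c(village = 2, factory = 1, road = 1,
                                       artificial_forest = 1,
                                       economic_forest = 1))
  expect_length(els, 6)
  expect_setequal(unique(vapply(els, `[[`, "", "element_type")),
                  c("village", "factory", "road", "artificial_forest",
                    "economic_forest"))
  kinds <- vapply(els, function(e) e$geometry$type, "")
  types <- vapply(els, `[[`, "", "element_type")
  expect_true(all(kinds[types %in% c("village", "factory")] == "point"))
  expect_true(all(kinds[types == "road"] == "polyline"))
  expect_true(all(kinds[grepl("forest", types)] == "polygon"))
  expect_length(generate_risk_elements(cfg, c(village = 0)), 0)
})

test_that("realized richness is truncated Poisson with the configured mean", {
  # all betas zero, intercept ln(10): compare the Monte-Carlo mean over
  # >= 2000 plots with the truncated-Poisson expectation by direct summation
  cfg <- landscape_config(extent = c(0, 0, 2000, 2000), cell_size = 20,
                          correlation_length = 100, n_climate = 1, n_soil = 1,
                          seed = 11)
  st <- generate_predictor_stack(cfg)
  lay <- generate_plot_layout(cfg, 0, 2209, focal_zone = c(20, 20, 1980, 1980),
                              fine_spacing = 40)
  expect_gte(nrow(lay), 2000)
  truth <- ground_truth(beta_richness = c(climate_01 = 0),
                        beta_evenness = c(climate_01 = 0),
                        intercept_richness = log(10))
  comm <- simulate_communities(lay, st, truth, species_pool = 120, seed = 21)
  S <- attr(comm, "realized_richness")
  expect_true(all(S >= 1 & S <= 120))
  k <- 0:120
  pk <- dpois(k, 10)
  expected <- sum(k[-1] * pk[-1]) / sum(pk[-1])   # E[X | 1 <= X <= 120]
  expect_equal(mean(S), expected, tolerance = 0.25)
})

test_that("abundance bookkeeping and evenness limits hold", {
  cfg <- tiny_config(seed = 2)
  st <- generate_predictor_stack(cfg)
  lay <- generate_plot_layout(cfg, 8, 10, focal_zone = c(200, 200, 800, 600),
                              coarse_spacing = 200, fine_spacing = 100)
  comm <- simulate_communities(lay, st, ground_truth(), species_pool = 60,
                               mean_extra_stems = 300, seed = 4)
  div <- compute_diversity_table(comm)
  S <- attr(comm, "realized_richness")
  expect_equal(div$richness, unname(S[div$plot_id]))
  expect_true(all(comm$abundance >= 1))

  # dominance ratio -> 1 gives near-equal abundances, so H -> ln(S)
  even_truth <- ground_truth(beta_evenness = c(climate_01 = 0),
                             intercept_evenness = 12)
  comm_even <- simulate_communities(lay, st, even_truth, species_pool = 60,
                                    mean_extra_stems = 5000, seed = 4)
  div_even <- compute_diversity_table(comm_even)
  expect_equal(div_even$shannon, log(div_even$richness), tolerance = 0.01)
})

test_that("an injected driver leaves a detectable positive signal in richness", {
  cfg <- landscape_config(extent = c(0, 0, 16000, 12000), cell_size = 20,
                          correlation_length = 800, seed = 7)
  st <- generate_predictor_stack(cfg)
  lay <- generate_plot_layout(cfg, 114, 277,
                              focal_zone = c(2000, 1500, 14000, 10500))
  truth <- ground_truth(beta_richness = c(climate_01 = 0.5),
                        beta_evenness = c(climate_01 = 0))
  comm <- simulate_communities(lay, st, truth, seed = 13)
  X <- extract_at_plots(st, lay)
  S <- attr(comm, "realized_richness")
  r_driver <- cor(X[, "climate_01"], log(S))
  expect_gt(r_driver, 0.3)
  nulls <- setdiff(colnames(X), c("climate_01"))
  r_null <- vapply(nulls, function(nm) abs(cor(X[, nm], log(S))), numeric(1))
  expect_gt(r_driver, max(r_null))
})

test_that("unknown ground-truth coefficients are rejected", {
  cfg <- tiny_config()
  st <- generate_predictor_stack(cfg)
  lay <- generate_plot_layout(cfg, 4, 0, coarse_spacing = 200)
  bad <- ground_truth(beta_richness = c(not_a_layer = 1))
  expect_error(simulate_communities(lay, st, bad, seed = 1),
               "unknown predictors")
})
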