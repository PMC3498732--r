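test_that("the sampling design has the 22-array replicate structure", {
  d <- design_spec()
  expect_equal(nrow(d), 22)
  expect_equal(sum(d$mode == "chemostat"), 14)
  chem <- table(d$growth_rate[d$mode == "chemostat"])
  expect_equal(unname(chem[as.character(c(0.2, 0.1, 0.05, 0.03, 0.025))]),
               c(3, 3, 2, 3, 3), ignore_attr = TRUE)
  ret <- d[d$mode == "retentostat", ]
  expect_equal(unique(ret$time_d), c(2, 9, 16, 22))
  expect_true(all(table(ret$time_d) == 2))
  # growth rate decreases strictly along the retentostat series
  by_day <- ret$growth_rate[!duplicated(ret$time_d)]
  expect_true(all(diff(by_day) < 0))
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("noise-free generation returns exact archetype shapes", {
  sim <- generate_expression(n_genes_per_archetype = 3, n_housekeeping = 2,
                             n_null = 2,
                             noise = noise_spec(replicate_cv = 0,
                                                housekeeping_cv = 0, seed = 1))
  m <- sim$matrix
  # replicates identical within each condition
  d <- sim$metadata
  for (mu in unique(d$growth_rate)) {
    cols <- d$sample_id[d$growth_rate == mu]
    expect_true(all(m[, cols] == m[, cols[1]]))
  }
  # mean-normalized profiles equal the archetype shape exactly
  prof <- mean_normalize_profiles(m, d)
  cond <- attr(prof, "conditions")
  arch <- default_archetypes()[[1]]
  shape <- archetype_mean(arch, cond$growth_rate)
  expect_equal(unname(prof["A1_g001", ]), shape / mean(shape),
               tolerance = 1e-12)
  # housekeeping and null genes are flat
  expect_true(all(abs(prof["HK_g001", ] - 1) < 1e-12))
  expect_equal(unname(colMeans(sim$matrix)), rep(300, 22), tolerance = 0.2)
  expect_error(generate_expression(n_genes_per_archetype = 0,
                                   n_housekeeping = 0, n_null = 0),
               "no genes")
})

test_that("replicate noise calibrates to the requested 14% CV", {
  sim <- generate_expression(n_genes_per_archetype = 0, n_housekeeping = 0,
                             n_null = 100, noise = noise_spec(seed = 17))
  m <- sim$matrix
  d <- sim$metadata
  key <- paste(d$mode, d$growth_rate, d$time_d)
  # pooled within-condition CV over 100 genes x 9 conditions
  cv2 <- num <- 0
  for (g in rownames(m)) for (cond in unique(key)) {
    v <- m[g, key == cond]
    cv2 <- cv2 + (length(v) - 1) * (sd(v) / mean(v))^2
    num <- num + length(v) - 1
  }
  cv_hat <- sqrt(cv2 / num)
  expect_gt(cv_hat, 0.11)
  expect_lt(cv_hat, 0.17)
})

test_that("housekeeping genes meet the stability criterion", {
  sim <- generate_expression(n_genes_per_archetype = 0, n_housekeeping = 60,
                             n_null = 0, noise = noise_spec(seed = 23))
  hk <- sim$truth$gene_id[sim$truth$class == "housekeeping"]
  expect_true(all(housekeeping_cv(sim$matrix, hk) < 0.20))
})

test_that("retentostat series reduces to the ideal trajectory and round-trips", {
  p <- retentostat_params()
  gen <- generate_retentostat_series(p, noise_cv = 0, v_inf = 1, seed = 1)
  expect_equal(gen$series$cx_total,
               predict_biomass(p, gen$series$time_h), tolerance = 1e-12)
  expect_true(all(gen$series$viability == 1))
  # fitting the noiseless ideal series recovers mu(528 h) near-exactly
  fit <- fit_biomass_curve(gen$series)
  prof <- specific_growth_rate(fit, gen$series)
  mu_hat <- prof$mu[prof$time_h == 528]
  mu_true <- gen$truth$mu[gen$truth$time_h == 528]
  expect_lt(abs(mu_hat / mu_true - 1), 1e-6)
  expect_error(generate_retentostat_series(p, lambda = -1), "lambda")
  expect_error(generate_retentostat_series(p, v_inf = 0), "v_inf")
  # viability loss inflates measured total biomass above viable biomass
  gen2 <- generate_retentostat_series(p, noise_cv = 0, v_inf = 0.8,
                                      lambda = 0.005, seed = 1)
  expect_true(all(gen2$truth$cx_total >= gen2$truth$cx_viable))
  expect_equal(gen2$truth$cx_viable,
               gen2$truth$viability * gen2$truth$cx_total, tolerance = 1e-12)
})

test_that("generators are bit-reproducible at a fixed seed", {
  a <- generate_expression(n_genes_per_archetype = 4, n_housekeeping = 2,
                           n_null = 10, noise = noise_spec(seed = 5))
  b <- generate_expression(n_genes_per_archetype = 4, n_housekeeping = 2,
                           n_null = 10, noise = noise_spec(seed = 5))
  expect_identical(a$matrix, b$matrix)
  s1 <- generate_retentostat_series(seed = 8)
  s2 <- generate_retentostat_series(seed = 8)
  expect_identical(s1$series$cx_total, s2$series$cx_total)
  p1 <- generate_promoters(paste0("g", 1:5), length = 100, seed = 3)
  p2 <- generate_promoters(paste0("g", 1:5), length = 100, seed = 3)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("planted gene sets are enriched at the stated odds", {
  sim <- generate_expression(n_genes_per_archetype = 200, n_housekeeping = 0,
                             n_null = 1800, noise = noise_spec(seed = 2))
  truth <- sim$truth
  gs <- generate_gene_sets(truth,
                           planted = data.frame(set_name = "planted",
                                                class = "rising_plateau",
                                                odds = 8),
                           n_decoys = 3, set_size = 150, seed = 6)
  cluster <- truth$gene_id[truth$class == "rising_plateau"]
  res <- hypergeometric_enrichment(cluster, gs$collection)
  expect_lt(res$p[res$set_name == "planted"], 1e-6)
  # unplanted decoys hover at EF ~ 1
  expect_true(all(abs(res$ef[grepl("decoy", res$set_name)] - 1) < 0.75))
  # odds 1 means no planting at all
  gs1 <- generate_gene_sets(truth,
                            planted = data.frame(set_name = "flat",
                                                 class = "rising_plateau",
                                                 odds = 1),
                            n_decoys = 0, set_size = 500, seed = 7)
  res1 <- hypergeometric_enrichment(cluster, gs1$collection)
  expect_lt(abs(res1$ef[res1$set_name == "flat"] - 1), 0.35)
  expect_warning(generate_gene_sets(truth, n_decoys = 1, set_size = 0),
                 "zero-size")
  expect_error(generate_gene_sets(truth, n_decoys = 1, set_size = 1e6),
               "exceeds")
})

test_that("promoter planting is deterministic and saturates at p = 1", {
  ids <- paste0("g", 1:40)
  proms <- generate_promoters(ids, length = 120, p_background = 0,
                              p_planted = 1, planted_genes = ids[1:20],
                              seed = 4)
  hits <- scan_motif(proms, "TCGTTYAG")
  expect_true(all(hits$hit[1:20]))
  expect_error(generate_promoters(ids, length = 4, motif = "TCGTTYAG"),
               "longer")
  expect_error(generate_promoters(ids, p_background = 0.5, p_planted = 0.2),
               "p_background")
})
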