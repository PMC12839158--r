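# Moment-calibrated synthetic cohorts.

test_that("default specs carry the published moments and group sizes", {
  sp <- default_specs()
  expect_equal(names(sp), c("Control", "Atorvastatin", "Rosuvastatin",
                            "NoStatin"))
  expect_equal(vapply(sp, function(s) s$n, integer(1)),
               c(Control = 50L, Atorvastatin = 19L, Rosuvastatin = 21L,
                 NoStatin = 12L))
  im <- sp$Control$index_moments
  expect_equal(im$mean[im$index == "o63bi"], 12.00)
  expect_equal(im$sd[im$index == "o63bi"], 4.94)
  am <- sp$Control$analyte_moments
  expect_true(all(am$mean > 0))
  expect_true(all(am$sd >= 0))
  # correlation: unit diagonal, symmetric, PSD
  for (s in sp) {
    expect_equal(unname(diag(s$correlation)), rep(1, nrow(s$correlation)))
    expect_equal(s$correlation, t(s$correlation))
    expect_true(min(eigen(s$correlation)$values) > 0)
  }
})

test_that("the lognormal moment match is exact in closed form", {
  # analytic mean/sd of exp(mu + sigma Z) equal the requested moments
  for (m in c(0.17, 1.97, 23.13)) {
    for (s in c(0.04, 0.68, 3.38)) {
      s2 <- log(1 + (s / m)^2)
      mu <- log(m) - s2 / 2
      expect_equal(exp(mu + s2 / 2), m)
      expect_equal(sqrt((exp(s2) - 1) * exp(2 * mu + s2)), s)
    }
  }
})

test_that("same seed gives identical cohorts; different seeds differ", {
  a <- generate_cohort(seed = 61)
  b <- generate_cohort(seed = 61)
  cc <- generate_cohort(seed = 62)
  expect_identical(a, b)
  expect_false(identical(a, cc))
  expect_equal(nrow(a), 50 + 19 + 21 + 12)
  # valid molar profiles: rows sum to 100
  an <- setdiff(names(a), c("sample_id", "group"))
  expect_equal(unname(rowSums(a[an])), rep(100, nrow(a)), tolerance = 1e-9)
})

test_that("empirical marginals converge to the spec moments (n = 1e5)", {
  specs <- default_specs()["Control"]
  big <- generate_cohort(specs, seed = 63, n_override = c(Control = 100000L))
  m <- specs$Control$analyte_moments
  for (j in seq_len(nrow(m))) {
    v <- big[[m$analyte[j]]]
    expect_equal(mean(v), m$mean[j], tolerance = 0.01)
    expect_equal(sd(v), m$sd[j], tolerance = 0.02)
  }
  # truncated-normal family: the resampling rule biases the mean upward by
  # exactly the truncated-normal correction s*phi(m/s)/Phi(m/s) (up to ~4%
  # for EPA); check against that closed form
  bigt <- generate_cohort(specs, seed = 64, n_override = c(Control = 50000L),
                          distribution = "truncated_normal")
  for (j in seq_len(nrow(m))) {
    a <- m$mean[j] / m$sd[j]
    trunc_mean <- m$mean[j] + m$sd[j] * dnorm(a) / pnorm(a)
    expect_equal(mean(bigt[[m$analyte[j]]]), trunc_mean, tolerance = 0.01)
  }
})

test_that("identity correlation yields empirically independent analytes", {
  specs <- default_specs()["Control"]
  specs$Control$correlation[] <- diag(nrow(specs$Control$correlation))
  big <- generate_cohort(specs, seed = 65, n_override = c(Control = 100000L))
  an <- specs$Control$analyte_moments$analyte
  cm <- cor(as.matrix(big[an]))
  offdiag <- cm[upper.tri(cm)]
  expect_true(all(abs(offdiag) < 0.02))
  # and the default within-block correlation is materially positive
  big2 <- generate_cohort(default_specs()["Control"], seed = 65,
                          n_override = c(Control = 50000L))
  expect_gt(cor(big2$`C18:0`, big2$`C18:1n-9`), 0.2)
})

test_that("index-scale cohorts hit the index moments and respect the seed", {
  sim <- generate_index_cohort(n_per_group = 50000,
                               indices = c("o63bi", "c18_ratio"), seed = 66)
  ctrl <- sim[sim$group == "Control", ]
  expect_equal(mean(ctrl$o63bi), 12.00, tolerance = 0.01)
  expect_equal(sd(ctrl$o63bi), 4.94, tolerance = 0.02)
  expect_identical(sim, generate_index_cohort(
    n_per_group = 50000, indices = c("o63bi", "c18_ratio"), seed = 66))
  expect_error(generate_index_cohort(indices = "dpa_dha", seed = 1),
               "no moments")
})

test_that("to_concentrations inverts to_molar_percent and totals do not leak into indices", {
  cohort <- generate_cohort(seed = 67)
  panel <- panel_with_other()
  conc <- to_concentrations(cohort, panel, seed = 68)
  back <- to_molar_percent(conc, panel)
  an <- setdiff(names(cohort), c("sample_id", "group"))
  for (a in an) expect_equal(back[[a]], cohort[[a]], tolerance = 1e-9)
  # scaling the molar pool x10 leaves all recovered indices unchanged
  conc10 <- to_concentrations(cohort, panel, total_nmol = c(110000, 22000),
                              seed = 68)
  idx1 <- compute_index_set(to_molar_percent(conc, panel),
                            c("c18_ratio", "o63bi", "omega3_status"))
  idx10 <- compute_index_set(to_molar_percent(conc10, panel),
                             c("c18_ratio", "o63bi", "omega3_status"))
  expect_equal(idx10$c18_ratio, idx1$c18_ratio, tolerance = 1e-9)
  expect_equal(idx10$o63bi, idx1$o63bi, tolerance = 1e-9)
  # two samples with equal composition but different totals -> equal indices
  twin <- cohort[c(1, 1), ]
  twin$sample_id <- c("t1", "t2")
  conc_twin <- to_concentrations(twin, panel, seed = 69)
  idx_twin <- compute_index_set(to_molar_percent(conc_twin, panel),
                                c("c18_ratio", "o63bi"))
  expect_equal(idx_twin$c18_ratio[1], idx_twin$c18_ratio[2])
  expect_equal(idx_twin$o63bi[1], idx_twin$o63bi[2])
})

test_that("pooled atherosclerosis membership follows the 19/21/12 composition", {
  set.seed(70)
  subs <- sample_as_subgroups(52000)
  tab <- table(subs) / length(subs)
  expect_equal(unname(tab[["Atorvastatin"]]), 19 / 52, tolerance = 0.02)
  expect_equal(unname(tab[["Rosuvastatin"]]), 21 / 52, tolerance = 0.02)
  expect_equal(unname(tab[["NoStatin"]]), 12 / 52, tolerance = 0.02)
})

test_that("a non-positive-definite correlation is rejected", {
  specs <- default_specs()["Control"]
  specs$Control$correlation[] <- 1  # rank-1, not PD
  expect_error(generate_cohort(specs, seed = 71), "positive definite")
})
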