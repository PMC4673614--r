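test_that("phenotype counts and fractions sum correctly", {
  st <- world_state(3)
  st$n_prolif[1, 1] <- 2L
  st$n_invasive[2, 2] <- 1L
  st$n_necrotic[3, 3] <- 3L
  pc <- phenotype_counts(st)
  expect_identical(pc$n_total, 6L)
  expect_equal(c(pc$frac_prolif, pc$frac_invasive, pc$frac_necrotic),
               c(1 / 3, 1 / 6, 1 / 2))
  expect_equal(pc$frac_prolif + pc$frac_invasive + pc$frac_necrotic, 1)
})

test_that("the front profile of a ring sits at the ring radius", {
  st <- ring_state(10)
  prof <- front_profile(st, 360)
  expect_true(all(abs(prof$front_radius - 10) <= 1))
  expect_lt(abs(mean_front_radius(prof) - 10), 0.5)

  founder <- world_state(9)
  founder$n_prolif[5, 5] <- 1L
  pf <- front_profile(founder, 360)
  expect_true(all(pf$front_radius == 0))
  expect_identical(mean_front_radius(pf), 0)
  expect_error(front_profile(world_state(9)), "no living cells")
})

test_that("roughness is the population standard deviation of bin radii", {
  prof <- two_level_profile(8, 12)
  expect_equal(surface_roughness(prof), 2)       # two-point distribution
  expect_equal(mean_front_radius(prof), 10)

  # radially symmetric fixture: discretisation bound
  expect_lte(surface_roughness(front_profile(ring_state(10), 360)), 0.5)
  expect_lte(surface_roughness(front_profile(ring_state(15), 360)), 0.5)

  # brute-force two-pass oracle on random profiles
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    r <- runif(n, 0, 30)
    prof_i <- tibble::tibble(bin = seq_len(n), angle = 0, front_radius = r)
    mu <- sum(r) / n
    oracle <- sqrt(sum((r - mu)^2) / n)
    expect_equal(surface_roughness(prof_i), oracle, tolerance = 1e-12)
  }
  expect_error(surface_roughness(two_level_profile()[1, ]), ">= 2")
})

test_that("OLS slope fits recover exact and noisy trends", {
  t <- 0:150
  expect_equal(as.numeric(fit_slope(t, 2 * t)), 2)
  expect_equal(as.numeric(fit_slope(t, rep(3, length(t)))), 0)
  set.seed(8)
  y <- 1.5 * t + rnorm(length(t), sd = 0.1)
  expect_lt(abs(fit_slope(t, y) - 1.5), 0.05)
  # invariance under time shift
  expect_equal(as.numeric(fit_slope(t + 100, y)),
               as.numeric(fit_slope(t, y)), tolerance = 1e-9)
  # burn-in discards early points
  y2 <- c(rep(50, 30), 2 * t[t >= 30])
  expect_equal(as.numeric(fit_slope(t, y2, burn_in = 30)), 2)
  expect_error(fit_slope(1, 1), ">= 2 points")

  expect_equal(as.numeric(fit_loglog_exponent(t, 0.3 * t^1.7, burn_in = 5)),
               1.7, tolerance = 1e-9)
})

test_that("sector RDFs are probability densities of radial distance", {
  st <- ring_state(20)
  rdf <- radial_distribution(st, bin_width = 2)
  for (s in 1:4) {
    g <- rdf[rdf$sector == s, ]
    expect_equal(sum(g$g) * 2, 1, tolerance = 1e-9)
    # ring fixture: all mass within one discretisation-width of r = 20
    expect_true(all(g$r_lo[g$g > 0] >= 16 & g$r_lo[g$g > 0] <= 22))
  }

  # exact ring along the axes only: single bin at g = 1/dr
  st2 <- world_state(51)
  ctr <- 26L
  st2$n_prolif[ctr, ctr + 20L] <- 1L
  st2$n_prolif[ctr + 20L, ctr] <- 1L
  rdf2 <- radial_distribution(st2, sector = 1, bin_width = 2)
  expect_identical(nrow(rdf2[rdf2$g > 0, ]), 1L)
  expect_equal(max(rdf2$g), 1 / 2)

  # all cells at the origin: mass concentrated in the first bin
  founder <- world_state(9)
  founder$n_prolif[5, 5] <- 3L
  rdf3 <- radial_distribution(founder, sector = 1)
  expect_equal(rdf3$g[rdf3$r_lo == 0] * 2, 1)

  expect_error(radial_distribution(st2, sector = 3), "no living cells")
  expect_error(radial_distribution(world_state(9)), "no living cells")
})

test_that("per-step records carry counts, front radius and roughness", {
  cfg <- tiny_config(L = 31L)
  st <- initialize_world(cfg)
  rec0 <- record_state(st, cfg)
  expect_identical(rec0$t, 0L)
  expect_identical(rec0$n_total, 1L)
  expect_identical(rec0$mean_front_radius, 0)
  expect_true(is.na(rec0$roughness))  # a single occupied bin has no spread

  for (i in 1:8) st <- step_world(st, cfg)
  rec <- record_state(st, cfg)
  expect_gt(rec$n_total, 1)
  expect_gt(rec$mean_front_radius, 0)
  expect_equal(rec$frac_prolif + rec$frac_invasive + rec$frac_necrotic, 1)
})

test_that("tidy and glance expose the run as tibbles", {
  sim <- run_simulation(tiny_config(L = 61L, t_max = 20L))
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), nrow(sim$records))
  gl <- glance(sim)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("n_total", "v", "v_r", "halt_reason") %in% names(gl)))
})
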