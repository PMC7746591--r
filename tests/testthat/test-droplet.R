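test_that("occupancy pmf matches the closed form and normalises", {
  expect_equal(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(0.5, 0), 0.6065, tolerance = 1e-4)
  expect_equal(poisson_pmf(0.033, 1), 0.033 * exp(-0.033), tolerance = 1e-12)
  # matches the reference density everywhere we care about
  for (lam in c(0.01, 0.033, 0.5, 2)) {
    ks <- 0:60
    expect_equal(poisson_pmf(lam, ks), dpois(ks, lam), tolerance = 1e-13)
    expect_equal(sum(poisson_pmf(lam, ks)), 1, tolerance = 1e-12)
  }
  expect_error(poisson_pmf(-1, 0), class = "cmcflow_domain_error")
  expect_error(poisson_pmf(1, -2), class = "cmcflow_domain_error")
})

test_that("expected occupied-droplet counts follow the Poisson closed forms", {
  # 33 cells over 1000 droplets: about 32 droplets with exactly one cell,
  # i.e. nearly every cell alone in its droplet
  e1 <- expected_occupied(33, 1000, "exactly_one")
  expect_equal(e1, 1000 * 0.033 * exp(-0.033), tolerance = 1e-12)
  expect_true(round(e1) >= 32 && round(e1) <= 33)
  expect_equal(expected_occupied(0, 1000, "at_least_one"), 0)
  expect_equal(expected_occupied(500, 1000, "at_least_one"),
               1000 * (1 - exp(-0.5)), tolerance = 1e-12)
  expect_error(expected_occupied(10, 0), class = "cmcflow_domain_error")
})

test_that("multiple-occupancy probability matches its closed form", {
  expect_equal(multi_occupancy_prob(0), 0)
  expect_equal(multi_occupancy_prob(0.5), 0.0902, tolerance = 1e-4)
  # agrees with the tail of the pmf
  expect_equal(multi_occupancy_prob(0.033),
               sum(poisson_pmf(0.033, 2:50)), tolerance = 1e-12)
  expect_error(multi_occupancy_prob(-0.1), class = "cmcflow_domain_error")
})

test_that("partitioning conserves cells and converges to Poisson occupancy", {
  expect_equal(partition_cells(0, 1000), rep(0L, 1000))
  set.seed(101)
  for (i in 1:20) expect_equal(sum(partition_cells(33, 1000)), 33)

  # mean occupied count over replicates approaches the analytic expectation
  set.seed(202)
  occ <- replicate(2000, sum(partition_cells(33, 1000) > 0))
  target <- expected_occupied(33, 1000, "at_least_one")
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - target), 3 * se)

  # occupancy histogram is Poisson: chi-square GOF not rejected at alpha=0.01
  set.seed(303)
  v <- partition_cells(5000, 1e5)
  lam <- 5000 / 1e5
  obs <- c(sum(v == 0), sum(v == 1), sum(v >= 2))
  p <- c(poisson_pmf(lam, 0), poisson_pmf(lam, 1),
         1 - sum(poisson_pmf(lam, 0:1)))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated runs classify blanks, single cells and crowded samples correctly", {
  # blank run: no waveforms above threshold for many consecutive seeds
  for (s in 1:100) {
    blank <- simulate_run(droplet_run_config(n_cells = 0, rng_seed = s))
    expect_identical(blank$raw_count, 0L)
  }

  # one bright cell is always found
  for (s in 1:20) {
    one <- simulate_run(droplet_run_config(n_cells = 1, rng_seed = s,
                                           amp_median_rel = 50))
    expect_identical(one$raw_count, 1L)
  }

  # crowded sample: positives equal occupied droplets (bright cells) and
  # undercount the true number
  r <- simulate_run(droplet_run_config(n_cells = 500, rng_seed = 7,
                                       amp_median_rel = 50))
  occupied <- sum(r$droplets$occupancy > 0)
  expect_equal(r$raw_count, occupied)
  expect_lt(r$raw_count, 500)
  # and the corrected estimate lands near the truth
  expect_lt(abs(r$corrected_count - 500) / 500, 0.1)

  # structural invariants of the per-droplet records
  thr <- r$config$threshold_multiplier * r$config$noise_floor
  expect_equal(r$droplets$positive, r$droplets$amplitude > thr)
  expect_equal(sum(r$droplets$occupancy), 500)
  expect_true(all(r$droplets$amplitude >= 0))

  # reproducible under the seed
  r2 <- simulate_run(droplet_run_config(n_cells = 500, rng_seed = 7,
                                        amp_median_rel = 50))
  expect_equal(r$droplets, r2$droplets)
})

test_that("occupancy correction inverts the expected-occupied map exactly", {
  expect_equal(corrected_count(0, 1000), 0)
  expect_equal(corrected_count(33, 1000), 33.56, tolerance = 1e-3)
  expect_equal(corrected_count(393, 1000), 499.23, tolerance = 1e-3)
  # analytic inverse: corrected_count(E[occupied | N]) == N
  for (n_cells in c(1, 33, 200, 800)) {
    m <- expected_occupied(n_cells, 1000, "at_least_one")
    expect_equal(-1000 * log(1 - m / 1000), n_cells, tolerance = 1e-9)
  }
  expect_error(corrected_count(1000, 1000), class = "cmcflow_saturation_error")
})

test_that("run results export to CSV and JSON with a config echo", {
  r <- simulate_run(droplet_run_config(n_cells = 5, rng_seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_run_result(r, csv_file = csv, json_file = js)
  per <- read.csv(csv)
  expect_equal(nrow(per), 1000)
  expect_equal(sum(per$occupancy), 5)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$raw_count, r$raw_count)
  expect_equal(summ$true_cells, 5)
  expect_equal(summ$config$threshold_multiplier, 3)
})

test_that("config validation rejects impossible instrument settings", {
  expect_error(droplet_run_config(n_cells = -1), class = "cmcflow_config_error")
  expect_error(droplet_run_config(5, noise_floor = 0),
               class = "cmcflow_config_error")
  expect_error(droplet_run_config(5, threshold_multiplier = 0),
               class = "cmcflow_config_error")
  expect_error(droplet_run_config(5, sample_volume = 0.5, droplet_volume = 1),
               class = "cmcflow_config_error")
  # residual partial droplet is discarded
  expect_equal(droplet_run_config(5, sample_volume = 1001.7)$n_droplets, 1001L)
})

test_that("noise floor estimation reflects the blank-run peak", {
  set.seed(99)
  nf <- estimate_noise_floor(noise_sd = 1, n_blank = 1000)
  # peak |N(0,1)| over 1000 draws concentrates near 3.2-3.5 sd
  expect_gt(nf, 2.5)
  expect_lt(nf, 5)
})
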