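test_that("clean simulations emit two directional peaks per contact", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 20, seed = 2,
                                           p_obs = 1, jitter_sd = 0,
                                           artifact_rate = 0))
  pairs <- methyl_distance_table(ds$methyls, d_max = ds$config$noe_cutoff)
  expect_equal(nrow(ds$noesy), 2L * nrow(pairs))
  expect_equal(nrow(ds$hmqc), 20L)
  # every NOESY peak maps to a true methyl pair
  expect_false(anyNA(ds$truth$noesy_map$id_a))
})

test_that("simulations are a pure function of the seed", {
  a <- simulate_methyl_dataset(sim_config(n_methyls = 15, seed = 9,
                                          artifact_rate = 0.1))
  b <- simulate_methyl_dataset(sim_config(n_methyls = 15, seed = 9,
                                          artifact_rate = 0.1))
  expect_identical(as.data.frame(a$noesy), as.data.frame(b$noesy))
  expect_identical(a$truth$shifts, b$truth$shifts)
  c_ <- simulate_methyl_dataset(sim_config(n_methyls = 15, seed = 10,
                                           artifact_rate = 0.1))
  expect_false(identical(as.data.frame(a$noesy), as.data.frame(c_$noesy)))
})

test_that("geometry respects packing and geminal constraints", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 40, seed = 4))
  m <- ds$methyls
  xyz <- as.matrix(m[, c("cx", "cy", "cz")])
  d <- as.matrix(dist(xyz))
  gem <- !is.na(m$geminal_id)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i >= j) next
      if (gem[i] && m$geminal_id[i] == m$id[j]) {
        expect_gte(d[i, j], 1.8); expect_lte(d[i, j], 3.0)
      } else {
        expect_gte(d[i, j], 3.5)
      }
    }
  }
  # protons ride 1.1 A from their carbon
  for (i in sample(nrow(m), 5)) {
    b <- sqrt(rowSums((m$protons[[i]] -
                         matrix(xyz[i, ], 3, 3, byrow = TRUE))^2))
    expect_equal(unname(b), rep(1.1, 3), tolerance = 1e-9)
  }
})

test_that("infeasible packing is reported", {
  expect_error(
    simulate_methyl_dataset(sim_config(n_methyls = 60, radius = 6, seed = 1)),
    "packing")
})

test_that("clean reciprocal peaks pass the reciprocity filter unchanged", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 25, seed = 6,
                                           unreciprocated_rate = 0))
  f <- filter_noesy(ds$noesy, min_sn = 0)
  expect_identical(as.data.frame(f), as.data.frame(ds$noesy))
})

test_that("unreciprocated and artifact peaks are largely removed by the filter", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 30, seed = 13,
                                           unreciprocated_rate = 0.3,
                                           artifact_rate = 0.2))
  f <- filter_noesy(ds$noesy, min_sn = 0)
  art <- ds$truth$noesy_map$peak_id[is.na(ds$truth$noesy_map$id_a)]
  expect_lt(sum(f$id %in% art), length(art) / 2)
  expect_lt(nrow(f), nrow(ds$noesy))
})

test_that("a single-point sweep equals a direct pipeline run", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 14, seed = 18))
  cfg <- optimizer_config(population = 15, runs = 4, iterations = 800,
                          generations = 6, stagnation = 3, seed = 5)
  sw <- sweep_parameters(ds, d_cut_grid = 5, p_noe_grid = 0.1, config = cfg)
  expect_equal(nrow(sw), 1L)
  direct <- run_methyl_pipeline(ds, config = cfg,
                                gen_config = generation_config(d_cut = 5,
                                                               p_noe = 0.1),
                                mode = "single")
  g <- glance(direct)
  expect_equal(sw$pct_strong, 100 * g$n_strong / g$n_methyls)
  expect_equal(sw$pct_explained, 100 * g$explained, tolerance = 1e-9)
})

test_that("a 2x2 sweep grid reports one row per grid point", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 12, seed = 19))
  cfg <- optimizer_config(population = 10, runs = 2, iterations = 400,
                          generations = 4, stagnation = 2, seed = 5)
  out_file <- file.path(tempdir(), "sweep.tsv")
  sw <- sweep_parameters(ds, d_cut_grid = c(4.5, 5.5),
                         p_noe_grid = c(0.1, 0.3), config = cfg,
                         out = out_file)
  expect_equal(nrow(sw), 4L)
  expect_true(file.exists(out_file))
  tab <- utils::read.delim(out_file)
  expect_equal(nrow(tab), 4L)
})

test_that("explained fraction grows with the expected-network cutoff", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 16, seed = 23))
  cfg <- optimizer_config(population = 15, runs = 3, iterations = 800,
                          generations = 6, stagnation = 3, seed = 7)
  sw <- sweep_parameters(ds, d_cut_grid = c(4.0, 6.0), p_noe_grid = 0.1,
                         config = cfg)
  expect_lte(sw$pct_explained[sw$d_cut == 4.0],
             sw$pct_explained[sw$d_cut == 6.0] + 1e-9)
})
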