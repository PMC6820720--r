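test_that("consensus shift and agreement fraction follow the kernel rule", {
  r <- consensus_shift(rep(23.1, 100), tol = 0.4)
  expect_equal(r$shift, 23.1)
  expect_equal(r$fraction, 1)

  vals <- c(rep(0.85, 85), rep(1.50, 15))
  r2 <- consensus_shift(vals, tol = 0.04)
  expect_equal(r2$shift, 0.85, tolerance = 1e-6)
  expect_equal(r2$fraction, 0.85)

  expect_true(is.na(consensus_shift(numeric(0), 0.4)$shift))
})

test_that("the kernel argmax matches a dense grid scan on bimodal data", {
  set.seed(33)
  for (i in 1:5) {
    vals <- c(rnorm(60, 22.8, 0.15), rnorm(40, 24.4, 0.25))
    tol <- 0.4
    r <- consensus_shift(vals, tol)
    grid <- seq(min(vals) - tol, max(vals) + tol, by = 1e-4)
    ks <- vapply(grid, function(x) sum(exp(-(vals - x)^2 / (2 * tol^2))), 0)
    expect_equal(r$shift, grid[which.max(ks)], tolerance = 2e-3)
  }
})

test_that("geminal redistribution sorts each run's pair jointly", {
  runs <- tibble::tibble(
    run = rep(1:4, each = 2), slot = rep(1:2, 4),
    shift_c = c(23, 25, 25, 23, 23, 25, 25, 23),
    shift_h = c(0.8, 1.1, 1.1, 0.8, 0.8, 1.1, 1.1, 0.8)
  )
  red <- consolidate_geminal(runs)
  expect_true(all(red$shift_c[red$slot == 1] == 23))
  expect_true(all(red$shift_h[red$slot == 1] == 0.8))
  # already ordered input is unchanged
  ordered <- runs[runs$shift_c[seq(1, 8, 2)] |> rep(each = 2) |> order(), ]
  red2 <- consolidate_geminal(red)
  expect_equal(red2$shift_c, red$shift_c)
  # runs with only one assigned methyl contribute nothing
  partial <- dplyr::bind_rows(runs, tibble::tibble(
    run = 5L, slot = 1L, shift_c = 24, shift_h = 0.9))
  red3 <- consolidate_geminal(partial)
  expect_false(5L %in% red3$run)
})

test_that("joint geminal consolidation keeps 1H attached to its 13C", {
  # two methyls whose C order and H order disagree: sorting nuclei
  # independently would pair the lower C with the lower H, which is wrong
  set.seed(7)
  n <- 100
  swap <- runif(n) < 0.5
  c1 <- 22.8; h1 <- 1.05; c2 <- 24.9; h2 <- 0.55
  runs <- tibble::tibble(
    run = rep(seq_len(n), each = 2), slot = rep(1:2, n),
    shift_c = as.vector(rbind(ifelse(swap, c2, c1), ifelse(swap, c1, c2))),
    shift_h = as.vector(rbind(ifelse(swap, h2, h1), ifelse(swap, h1, h2)))
  )
  red <- consolidate_geminal(runs)
  s1 <- red[red$slot == 1, ]
  cc <- consensus_shift(s1$shift_c, 0.4)
  ch <- consensus_shift(s1$shift_h, 0.04)
  expect_equal(cc$shift, c1, tolerance = 1e-6)
  expect_equal(ch$shift, h1, tolerance = 1e-6) # partner of the lower 13C
  # independent per-nucleus sorting would instead give min(h1, h2)
  h_indep <- consensus_shift(pmin(runs$shift_h[c(TRUE, FALSE)],
                                  runs$shift_h[c(FALSE, TRUE)]), 0.04)
  expect_equal(h_indep$shift, h2, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(ch$shift, h_indep$shift)))
})

make_run_shifts <- function(methyls, n_runs, shift_c, shift_h, noe = 2L) {
  dplyr::bind_rows(lapply(seq_len(n_runs), function(r) {
    tibble::tibble(run = r, methyl_id = methyls$id,
                   shift_c = shift_c, shift_h = shift_h,
                   noe_count = noe)
  }))
}

test_that("strength requires both run agreement and NOE support", {
  m <- toy_methyl_chain(2)
  rs <- make_run_shifts(m, 300, c(23.0, 25.0), c(0.8, 1.1), noe = 2L)
  cons <- consolidate_runs(rs, methyls = m, n_runs = 300)
  expect_true(all(cons$strength == "strong"))
  expect_equal(cons$fraction, c(1, 1))

  rs0 <- make_run_shifts(m, 300, c(23.0, 25.0), c(0.8, 1.1), noe = 0L)
  cons0 <- consolidate_runs(rs0, methyls = m, n_runs = 300)
  expect_true(all(cons0$strength == "weak")) # unanimity without NOEs
})

test_that("the strength threshold is exclusive and monotone", {
  m <- toy_methyl_chain(2)
  # methyl 1 agrees in 85% of runs, methyl 2 in 95%
  rs <- dplyr::bind_rows(lapply(1:100, function(r) {
    tibble::tibble(
      run = r, methyl_id = m$id,
      shift_c = c(ifelse(r <= 85, 23.0, 26.0), ifelse(r <= 95, 25.0, 21.0)),
      shift_h = c(0.8, 1.1), noe_count = 2L
    )
  }))
  c80 <- consolidate_runs(rs, methyls = m, n_runs = 100, threshold = 0.8)
  expect_identical(c80$strength, c("strong", "strong"))
  c90 <- consolidate_runs(rs, methyls = m, n_runs = 100, threshold = 0.9)
  expect_identical(c90$strength, c("weak", "strong"))

  for (th in c(0.5, 0.7, 0.85, 0.95)) {
    s_lo <- sum(consolidate_runs(rs, methyls = m, n_runs = 100,
                                 threshold = th)$strength == "strong")
    s_hi <- sum(consolidate_runs(rs, methyls = m, n_runs = 100,
                                 threshold = th + 0.04)$strength == "strong")
    expect_lte(s_hi, s_lo)
  }
})

test_that("evaluation classifies strong assignments against a reference", {
  m <- toy_methyl_chain(4)
  rs <- make_run_shifts(m, 50, c(23.0, 25.0, 21.0, 19.0),
                        c(0.8, 1.1, 0.6, 1.3))
  cons <- consolidate_runs(rs, methyls = m, n_runs = 50)
  ref <- tibble::tibble(
    id = seq_len(8),
    shift = as.vector(rbind(c(23.0, 25.0, 21.0, 19.0),
                            c(0.8, 1.1, 0.6, 1.3))),
    error = 0,
    atom = as.vector(rbind(m$carbon, m$proton_name)),
    resno = rep(m$resno, each = 2)
  )
  ev <- evaluate_vs_reference(cons, ref)
  expect_equal(ev$counts$erroneous, 0L)
  expect_equal(ev$counts$correct, 4L)

  # swapping two non-geminal reference entries creates two errors
  ref2 <- ref
  ref2$shift[ref2$resno == 1 & startsWith(ref2$atom, "C")] <- 21.0
  ref2$shift[ref2$resno == 3 & startsWith(ref2$atom, "C")] <- 23.0
  ev2 <- evaluate_vs_reference(cons, ref2)
  expect_equal(ev2$counts$erroneous, 2L)
  # bookkeeping: counts partition the strong set
  expect_equal(ev2$counts$correct + ev2$counts$erroneous +
                 ev2$counts$no_reference, ev2$counts$all_strong)

  # atoms without reference entries are counted separately
  ev3 <- evaluate_vs_reference(cons, ref[ref$resno != 2, ])
  expect_equal(ev3$counts$no_reference, 1L)
})

test_that("explained fraction averages mapped over measured NOESY peaks", {
  st <- tibble::tibble(run = 1:4, n_mapped_noesy = c(10, 8, 10, 0),
                       n_measured_noesy = 10)
  expect_equal(explained_fraction(st), mean(c(1, 0.8, 1, 0)))
  expect_equal(explained_fraction(tibble::tibble(run = 1, n_mapped_noesy = 10,
                                                 n_measured_noesy = 10)), 1)
})

test_that("reports carry the strong label, weak rows and shift list", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 10, seed = 21))
  typed <- attribute_noesy_types(ds$noesy, ds$hmqc, ds$typing)
  runs <- assign_runs(ds$methyls, ds$hmqc, ds$typing,
                      c(typed, list(ds$geminal)),
                      config = optimizer_config(population = 15, runs = 3,
                                                iterations = 600,
                                                generations = 6,
                                                stagnation = 3, seed = 1))
  cons <- consolidate_runs(runs)
  dir <- file.path(tempdir(), "reports")
  write_reports(cons, dir, runs = runs,
                evaluation = evaluate_vs_reference(cons, ds$reference))
  tab <- readLines(file.path(dir, "consol.tab"))
  expect_equal(length(tab), nrow(cons) + 1L) # weak rows are listed too
  if (any(cons$strength == "strong")) {
    expect_true(any(grepl("\\bstrong\\b", tab)))
  }
  prot <- read_shifts(file.path(dir, "consol.prot"))
  expect_equal(nrow(prot), 2L * nrow(cons))
  flya <- readLines(file.path(dir, "flya.txt"))
  expect_true(any(grepl("C13HSQC", flya)))
  counts <- strsplit(flya[grepl("C13HSQC", flya)], "\\s+")[[1]]
  expect_equal(as.integer(counts[3]), nrow(ds$hmqc)) # measured tally
  expect_true(file.exists(file.path(dir, "evaluation.tsv")))
})

test_that("the cutoff triplet never increases the strong-set error rate", {
  # noisy fixtures where a single arbitrary cutoff is fragile; pooled over
  # seeds, consolidating across the three cutoffs must not do worse
  err_trip <- 0; strong_trip <- 0
  err_sing <- 0; strong_sing <- 0
  for (s in seq_len(20)) {
    ds <- simulate_methyl_dataset(sim_config(
      n_methyls = 16, seed = 300 + s,
      p_obs = 0.85, artifact_rate = 0.15, jitter_sd = 0.3))
    cfg <- optimizer_config(population = 20, runs = 6, iterations = 1000,
                            generations = 8, stagnation = 4, seed = s)
    for (mode in c("triplet", "single")) {
      res <- run_methyl_pipeline(ds, config = cfg, mode = mode)
      g <- glance(res)
      if (mode == "triplet") {
        err_trip <- err_trip + g$n_erroneous
        strong_trip <- strong_trip + g$n_strong
      } else {
        err_sing <- err_sing + g$n_erroneous
        strong_sing <- strong_sing + g$n_strong
      }
    }
  }
  rate <- function(e, s) if (s > 0) e / s else 0
  expect_lte(rate(err_trip, strong_trip), rate(err_sing, strong_sing) + 1e-9)
})
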