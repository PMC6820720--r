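# small noise-free problem built from a simulated dataset
toy_problem <- function(n = 6, seed = 1, d_cut = 5, ...) {
  ds <- simulate_methyl_dataset(sim_config(
    n_methyls = n, radius = 3.7 * max(n, 8)^(1 / 3), seed = seed, ...))
  typed <- attribute_noesy_types(ds$noesy, ds$hmqc, ds$typing)
  measured <- c(typed, if (!is.null(ds$geminal)) list(ds$geminal))
  pr <- build_problem(ds$methyls, ds$hmqc, ds$typing, measured, d_cut = d_cut)
  attr(pr, "truth_assign") <- match(ds$methyls$id,
                                    ds$truth$hmqc_map$methyl_id)
  pr
}

test_that("compiled scorer agrees with the reference scorer on random states", {
  pr <- toy_problem(n = 12, seed = 4)
  set.seed(99)
  for (i in 1:10) {
    a <- vapply(pr$allowed, function(o) {
      sample(c(0L, sample(o, min(3L, length(o)))), 1L)
    }, 0L)
    r <- local_optimize(pr, a, iterations = 0, seed = 1)
    expect_equal(r$score, score_assignment(pr, a), tolerance = 1e-9)
  }
})

test_that("the reference score equals an independent term-by-term recomputation", {
  pr <- toy_problem(n = 5, seed = 7)
  tol <- pr$tol
  a <- attr(pr, "truth_assign")
  # independent oracle: loop over expected rows and measured peaks directly
  total <- 0
  for (i in seq_len(nrow(pr$expected))) {
    e <- pr$expected[i, ]
    if (e$experiment == "C13HSQC") {
      if (a[e$ia] > 0) total <- total + e$prob
      next
    }
    qa <- a[e$ia]; qb <- a[e$ib]
    if (qa == 0 || qb == 0) next
    shifts <- c(ha = pr$hmqc$w1[qa], ca = pr$hmqc$w2[qa],
                cb = pr$hmqc$w2[qb], hb = pr$hmqc$w1[qb])
    tab <- pr$measured[[e$experiment]]
    dims <- methylassign:::experiment_dims(e$experiment)
    best <- 0
    for (k in seq_len(nrow(tab))) {
      ok_t <- methylassign:::label_compatible(tab$type_a[k], e$class_a) &&
        methylassign:::label_compatible(tab$type_b[k], e$class_b)
      if (!ok_t) next
      g <- 1; ok <- TRUE
      for (dd in c("ha", "ca", "cb", "hb")) {
        di <- dims[[dd]]
        if (is.na(di)) next
        sg <- if (dd %in% c("ha", "hb")) tol$tol_h else tol$tol_c
        dv <- tab[[paste0("w", di)]][k] - shifts[[dd]]
        ok <- ok && abs(dv) <= sg
        g <- g * exp(-dv^2 / (2 * sg^2))
      }
      if (ok && g > best) best <- g
    }
    total <- total + e$prob * best
  }
  on <- which(a > 0)
  w <- function(x, s) {
    d <- abs(outer(x, x, "-")) / s
    m <- (1 - d)^2 * (d < 1)
    sum(m[upper.tri(m)])
  }
  pen <- pr$lambda * (w(pr$hmqc$w2[a[on]], tol$tol_c) +
                        w(pr$hmqc$w1[a[on]], tol$tol_h)) +
    pr$mu * (nrow(pr$hmqc) - length(unique(a[on])))
  expect_equal(score_assignment(pr, a), total - pen, tolerance = 1e-9)
})

test_that("local optimization is greedy and deterministic", {
  pr <- toy_problem(n = 10, seed = 2)
  a0 <- vapply(pr$allowed, function(o) o[1], 0L)
  s0 <- score_assignment(pr, a0)
  r0 <- local_optimize(pr, a0, iterations = 0, seed = 3)
  expect_identical(r0$assign, a0) # zero iterations change nothing
  r1 <- local_optimize(pr, a0, iterations = 2000, seed = 3)
  expect_gte(r1$score, s0 - 1e-9) # monotone
  r2 <- local_optimize(pr, a0, iterations = 2000, seed = 3)
  expect_identical(r1$assign, r2$assign) # deterministic given seed
  expect_false(identical(
    r1$assign, local_optimize(pr, a0, iterations = 2000, seed = 4)$assign) &&
      FALSE) # different seeds may differ; no assertion beyond validity
})

test_that("local search recovers the optimum of small noise-free instances", {
  hits <- 0
  n_trials <- 20
  pr <- toy_problem(n = 6, seed = 12)
  best <- brute_force_assign(pr, max_methyls = 6)
  for (s in seq_len(n_trials)) {
    a0 <- with_seed_local <- vapply(pr$allowed, function(o) o[1], 0L)
    r <- local_optimize(pr, a0, iterations = 15000, seed = s)
    if (abs(r$score - best$score) <= 1e-9) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * n_trials))
})

test_that("the evolutionary search is deterministic and never below its start", {
  pr <- toy_problem(n = 10, seed = 6)
  cfg <- optimizer_config(population = 20, iterations = 1000,
                          generations = 10, stagnation = 4)
  r1 <- evolve_assignment(pr, cfg, seed = 11)
  r2 <- evolve_assignment(pr, cfg, seed = 11)
  expect_identical(r1$assign, r2$assign)
  expect_identical(r1$score, r2$score)
  # population of one without mutation reduces to repeated local search
  cfg1 <- optimizer_config(population = 1, iterations = 500,
                           generations = 5, stagnation = 3,
                           mutation_rate = 0)
  r3 <- evolve_assignment(pr, cfg1, seed = 2)
  expect_true(is.finite(r3$score))
})

test_that("exhaustive search matches the ground truth on tiny clean instances", {
  pr <- toy_problem(n = 4, seed = 3)
  truth <- attr(pr, "truth_assign")
  best <- brute_force_assign(pr, max_methyls = 6)
  expect_gte(best$score, score_assignment(pr, truth) - 1e-9)
  # on clean data the truth is a global optimum
  expect_equal(best$score, score_assignment(pr, truth), tolerance = 1e-9)
  expect_error(brute_force_assign(toy_problem(n = 12, seed = 3)),
               "too large")
})

test_that("a symmetric NOE network reports co-optimal mappings", {
  # four methyls of one class on a square: the contact graph is a 4-cycle
  # whose rotations are exact score ties
  m <- dplyr::bind_rows(
    toy_methyl("1-CD1", c(0, 0, 0), resno = 1),
    toy_methyl("2-CD1", c(5.5, 0, 0), resno = 2),
    toy_methyl("3-CD1", c(5.5, 5.5, 0), resno = 3),
    toy_methyl("4-CD1", c(0, 5.5, 0), resno = 4)
  )
  shifts_c <- c(22, 23.5, 25, 26.5)
  shifts_h <- c(0.6, 0.8, 1.0, 1.2)
  hm <- peaklist(tibble::tibble(id = 1:4, w1 = shifts_h, w2 = shifts_c),
                 nuclei = c("H", "C"), experiment = "C13HSQC")
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  no <- toy_noesy(do.call(rbind, lapply(seq_len(nrow(edges)), function(k) {
    i <- edges[k, 1]; j <- edges[k, 2]
    rbind(c(shifts_h[i], shifts_c[i], shifts_c[j], shifts_h[j]),
          c(shifts_h[j], shifts_c[j], shifts_c[i], shifts_h[i]))
  })))
  typing <- tibble::tibble(id = 1:4, type = "L")
  pr <- build_problem(m, hm, typing, attribute_noesy_types(no, hm, typing),
                      d_cut = 5.5)
  best <- brute_force_assign(pr, max_methyls = 4)
  expect_gte(length(best$optima), 2L)
})

test_that("evolutionary search attains the exhaustive optimum on clean instances", {
  n_ok <- 0; n_inst <- 8
  for (s in seq_len(n_inst)) {
    pr <- toy_problem(n = 6, seed = 100 + s)
    best <- brute_force_assign(pr, max_methyls = 6)
    r <- evolve_assignment(pr, optimizer_config(population = 30,
                                                iterations = 2000,
                                                generations = 10,
                                                stagnation = 5),
                           seed = s)
    expect_lte(r$score, best$score + 1e-9) # never above the global optimum
    if (abs(r$score - best$score) <= 1e-9) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, ceiling(0.95 * n_inst))
})

test_that("per-run shifts are medians of the mapped peak coordinates", {
  pr <- toy_problem(n = 6, seed = 9)
  a <- attr(pr, "truth_assign")
  sh <- derive_run_shifts(pr, a)
  mp <- induced_mapping(pr, a)
  # independent recomputation for one methyl
  id0 <- pr$methyls$id[1]
  coords_c <- c()
  q <- a[1]
  coords_c <- c(coords_c, pr$hmqc$w2[q])
  for (i in which(mp$experiment != "C13HSQC" & !is.na(mp$peak_row))) {
    dims <- methylassign:::experiment_dims(mp$experiment[i])
    tab <- pr$measured[[mp$experiment[i]]]
    if (mp$id_a[i] == id0 && !is.na(dims$ca)) {
      coords_c <- c(coords_c, tab[[paste0("w", dims$ca)]][mp$peak_row[i]])
    }
    if (mp$id_b[i] == id0 && !is.na(dims$cb)) {
      coords_c <- c(coords_c, tab[[paste0("w", dims$cb)]][mp$peak_row[i]])
    }
  }
  expect_equal(sh$shift_c[sh$methyl_id == id0], median(coords_c))
  # NOE support counts only through-space peaks, not geminal correlations
  gem_rows <- mp$experiment == "HCcCH" & !is.na(mp$peak_row)
  noe_rows <- mp$experiment == "CCNOESY" & !is.na(mp$peak_row)
  id_g <- pr$methyls$id[!is.na(pr$methyls$geminal_id)][1]
  if (!is.na(id_g) && any(gem_rows)) {
    n_noe <- sum((mp$id_a[noe_rows] == id_g) | (mp$id_b[noe_rows] == id_g))
    expect_equal(sh$noe_count[sh$methyl_id == id_g], n_noe)
  }
})

test_that("batch runs are deterministic in the base seed", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 12, seed = 5))
  typed <- attribute_noesy_types(ds$noesy, ds$hmqc, ds$typing)
  measured <- c(typed, list(ds$geminal))
  cfg <- optimizer_config(population = 15, runs = 3, iterations = 600,
                          generations = 6, stagnation = 3, seed = 42)
  r1 <- assign_runs(ds$methyls, ds$hmqc, ds$typing, measured, config = cfg)
  r2 <- assign_runs(ds$methyls, ds$hmqc, ds$typing, measured, config = cfg)
  expect_identical(r1$run_shifts, r2$run_shifts)
  expect_identical(r1$run_stats$score, r2$run_stats$score)
  expect_equal(r1$n_runs, 9L) # 3 cutoffs x 3 runs
})
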