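#' Optimizer configuration
#'
#' Defaults follow established practice for NOESY-only assignment
#' optimization: population 200, a local-search budget of 15,000 proposals
#' per run (apportioned across the evolutionary generations), and 100
#' independent runs per distance cutoff.
#'
#' @param population evolutionary population size.
#' @param runs independent optimization runs per distance cutoff.
#' @param iterations total local-search proposals per run.
#' @param generations maximal number of generations.
#' @param stagnation stop after this many generations without improvement.
#' @param mutation_rate per-methyl mutation probability in offspring.
#' @param lambda weight of the chemical-shift degeneracy penalty.
#' @param mu weight of the completeness penalty on measured HMQC peaks
#'   left unexplained by the state.
#' @param seed base random seed; run `i` (counted across the cutoff
#'   triplet) uses seed `seed + i`.
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(population = 200, runs = 100, iterations = 15000,
                             generations = 40, stagnation = 10,
                             mutation_rate = 0.05, lambda = 0.05, mu = 0.3,
                             seed = 1) {
  stopifnot(population >= 1, runs >= 1, iterations >= 0, generations >= 1,
            stagnation >= 1, mutation_rate >= 0, mutation_rate <= 1,
            lambda >= 0, mu >= 0)
  structure(
    list(population = population, runs = runs, iterations = iterations,
         generations = generations, stagnation = stagnation,
         mutation_rate = mutation_rate, lambda = lambda, mu = mu,
         seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

label_compatible <- function(tag, class_letter) {
  tag == "?" | grepl(class_letter, tag, fixed = TRUE)
}

# per-experiment dimension roles: which w-column holds each side's nucleus
experiment_dims <- function(name) {
  def <- experiment_def(name)
  pick <- function(s, n) {
    i <- which(def$side == s & def$nuclei == n)
    if (length(i)) i[1] else NA_integer_
  }
  list(ndim = def$ndim, nuclei = def$nuclei, side = def$side,
       ha = pick("a", "H"), ca = pick("a", "C"),
       hb = pick("b", "H"), cb = pick("b", "C"))
}

#' Build an assignment problem
#'
#' Assembles everything one optimization run needs: the expected peak
#' network generated from the methyl geometry at a given distance cutoff,
#' the measured peak lists flattened per experiment type, the set of HMQC
#' peaks each methyl may map to (restricted by residue typing), and
#' precomputed best-match tables used by the optimizer.
#'
#' The assignment state is the mapping from methyl groups to HMQC peaks
#' (0 = unassigned); the atom chemical shifts implied by a state are the
#' coordinates of the mapped HMQC peak, and every NOESY/geminal expected
#' peak is mapped to the measured peak that maximizes its alignment score
#' under those shifts (or left unmapped if none lies within the
#' tolerances).
#'
#' @param methyls methyl table from [extract_methyl_groups()].
#' @param hmqc measured 2D HMQC [peaklist()].
#' @param typing typing tibble `(id, type)` for the HMQC peaks, or `NULL`
#'   (no residue-type restriction).
#' @param measured list of measured NOESY / geminal peak lists (e.g. the
#'   output of [attribute_noesy_types()], plus an `HCcCH` list); each must
#'   carry its experiment type attribute.
#' @param tol [tolerances()].
#' @param lambda degeneracy-penalty weight.
#' @param mu completeness-penalty weight (per unexplained measured HMQC
#'   peak).
#' @param config [generation_config()].
#' @param d_cut distance cutoff used for this problem (defaults to
#'   `config$d_cut`).
#' @return a `methyl_problem` object.
#' @export
build_problem <- function(methyls, hmqc, typing = NULL, measured = list(),
                          tol = tolerances(), lambda = 0.05, mu = 0.3,
                          config = generation_config(),
                          d_cut = config$d_cut) {
  if (nrow(hmqc) == 0L) stop("empty measured HMQC peak list")
  stopifnot(pl_ndim(hmqc) == 2L)
  if (!is.list(measured)) measured <- list(measured)

  # flatten measured lists per experiment type
  flat <- list()
  for (x in measured) {
    expm <- pl_experiment(x)
    if (is.na(expm)) stop("measured peak list '", pl_name(x),
                          "' lacks an experiment type")
    tab <- tibble::as_tibble(x)
    if (!"type_a" %in% names(tab)) tab$type_a <- "?"
    if (!"type_b" %in% names(tab)) tab$type_b <- "?"
    tab$.list <- pl_name(x) %||% expm
    flat[[expm]] <- dplyr::bind_rows(flat[[expm]], tab)
  }

  distances <- methyl_distance_table(methyls)
  expected <- generate_expected_hmqc(methyls)
  for (expm in names(flat)) {
    def <- experiment_def(expm)
    if (def$transfer == "noe") {
      expected <- dplyr::bind_rows(
        expected,
        generate_expected_noesy(methyls, config, experiment = expm,
                                d_cut = d_cut, distances = distances)
      )
    } else if (expm == "HCcCH") {
      expected <- dplyr::bind_rows(expected, generate_expected_geminal(methyls))
    }
  }

  labels <- if (is.null(typing)) {
    rep("?", nrow(hmqc))
  } else {
    typing <- tibble::as_tibble(typing)
    canonical_label(typing$type[match(hmqc$id, typing$id)])
  }
  allowed <- lapply(methyls$letter, function(l) {
    which(label_compatible(labels, l))
  })

  expected$ia <- match(expected$id_a, methyls$id)
  expected$ib <- match(expected$id_b, methyls$id)

  mt <- build_match_tables(expected, flat, hmqc, tol)

  structure(
    list(methyls = methyls, hmqc = hmqc, hmqc_labels = labels,
         measured = flat, expected = expected, allowed = allowed,
         tol = tol, lambda = lambda, mu = mu, d_cut = d_cut,
         match_keys = mt$keys, match_M = mt$M, match_A = mt$A,
         mat_id = mt$mat_id),
    class = "methyl_problem"
  )
}

#' @export
print.methyl_problem <- function(x, ...) {
  cat(sprintf(
    "<methyl_problem> %d methyls, %d HMQC peaks, %d expected peaks (d_cut %.1f A), measured: %s\n",
    nrow(x$methyls), nrow(x$hmqc), nrow(x$expected), x$d_cut,
    paste(sprintf("%s (%d)", names(x$measured),
                  vapply(x$measured, nrow, 0L)), collapse = ", ")
  ))
  invisible(x)
}

# precompute, per (experiment, class_a, class_b) key, the best achievable
# alignment factor and the corresponding measured-peak row for every ordered
# pair of HMQC peaks
build_match_tables <- function(expected, flat, hmqc, tol) {
  nq <- nrow(hmqc)
  noesy_rows <- which(expected$experiment != "C13HSQC")
  keys <- unique(paste(expected$experiment[noesy_rows],
                       expected$class_a[noesy_rows],
                       expected$class_b[noesy_rows], sep = "|"))
  M <- vector("list", length(keys))
  A <- vector("list", length(keys))
  names(M) <- names(A) <- keys
  hH <- hmqc$w1; hC <- hmqc$w2

  # per experiment: Gaussian alignment factor of each measured peak's donor
  # (a) and acceptor (b) side against every HMQC peak, zero outside the
  # tolerance box
  side_factors <- list()
  for (expm in unique(expected$experiment[noesy_rows])) {
    tab <- flat[[expm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    dims <- experiment_dims(expm)
    np <- nrow(tab)
    gfac <- function(hdim, cdim) {
      g <- matrix(1, np, nq)
      ok <- matrix(TRUE, np, nq)
      if (!is.na(hdim)) {
        d <- abs(outer(tab[[paste0("w", hdim)]], hH, "-"))
        g <- g * exp(-d^2 / (2 * tol$tol_h^2))
        ok <- ok & d <= tol$tol_h
      }
      if (!is.na(cdim)) {
        d <- abs(outer(tab[[paste0("w", cdim)]], hC, "-"))
        g <- g * exp(-d^2 / (2 * tol$tol_c^2))
        ok <- ok & d <= tol$tol_c
      }
      g[!ok] <- 0
      g
    }
    side_factors[[expm]] <- list(a = gfac(dims$ha, dims$ca),
                                 b = gfac(dims$hb, dims$cb))
  }

  for (k in seq_along(keys)) {
    parts <- strsplit(keys[k], "|", fixed = TRUE)[[1]]
    expm <- parts[1]; ca <- parts[2]; cb <- parts[3]
    Mk <- matrix(0, nq, nq)
    Ak <- matrix(0L, nq, nq)
    tab <- flat[[expm]]
    sf <- side_factors[[expm]]
    if (!is.null(tab) && nrow(tab) > 0L && !is.null(sf)) {
      rows_k <- which(label_compatible(tab$type_a, ca) &
                        label_compatible(tab$type_b, cb))
      for (p in rows_k) {
        qa <- which(sf$a[p, ] > 0)
        if (length(qa) == 0L) next
        qb <- which(sf$b[p, ] > 0)
        if (length(qb) == 0L) next
        gb <- sf$b[p, qb]
        for (a in qa) {
          g <- sf$a[p, a] * gb
          upd <- g > Mk[a, qb]
          if (any(upd)) {
            Mk[a, qb[upd]] <- g[upd]
            Ak[a, qb[upd]] <- p
          }
        }
      }
    }
    M[[k]] <- Mk
    A[[k]] <- Ak
  }
  mat_id <- rep(NA_integer_, nrow(expected))
  mat_id[noesy_rows] <- match(
    paste(expected$experiment[noesy_rows], expected$class_a[noesy_rows],
          expected$class_b[noesy_rows], sep = "|"), keys)
  list(keys = keys, M = M, A = A, mat_id = mat_id)
}

#' Score an assignment state
#'
#' Pure-R reference implementation of the scoring function: the sum over
#' mapped expected peaks of the observation probability times a Gaussian
#' alignment factor per dimension (sigma = the nucleus tolerance, deviation
#' taken from the atom shifts implied by the state), minus a chemical-shift
#' degeneracy penalty: `lambda` times the sum over same-nucleus atom pairs
#' whose state shifts differ by less than the tolerance of the proximity
#' weight `(1 - delta/tol)^2`. The weight is 1 when two atoms share a shift
#' exactly (e.g. two methyls mapped onto one peak) and decays to 0 at the
#' tolerance edge, so artificial shift doubling costs the full penalty
#' while naturally crowded but distinct shifts cost little. Every
#' NOESY/geminal expected peak is mapped to its best in-tolerance measured
#' peak (or left unmapped, contributing nothing). Computed by direct
#' enumeration over the measured peaks; the optimizer's compiled
#' incremental scorer is validated against this function.
#'
#' @param problem a `methyl_problem`.
#' @param assign integer vector: HMQC peak row per methyl, 0 = unassigned.
#' @return the score (higher is better).
#' @export
score_assignment <- function(problem, assign) {
  stopifnot(length(assign) == nrow(problem$methyls))
  tol <- problem$tol
  hH <- problem$hmqc$w1; hC <- problem$hmqc$w2
  exp_tab <- problem$expected
  total <- 0
  for (i in seq_len(nrow(exp_tab))) {
    if (exp_tab$experiment[i] == "C13HSQC") {
      if (assign[exp_tab$ia[i]] > 0L) total <- total + exp_tab$prob[i]
      next
    }
    qa <- assign[exp_tab$ia[i]]; qb <- assign[exp_tab$ib[i]]
    if (qa == 0L || qb == 0L) next
    tab <- problem$measured[[exp_tab$experiment[i]]]
    if (is.null(tab) || nrow(tab) == 0L) next
    ok <- label_compatible(tab$type_a, exp_tab$class_a[i]) &
      label_compatible(tab$type_b, exp_tab$class_b[i])
    dims <- experiment_dims(exp_tab$experiment[i])
    g <- rep(1, nrow(tab))
    add_dim <- function(g, ok, wcol, ref, sigma) {
      d <- tab[[wcol]] - ref
      list(g = g * exp(-d^2 / (2 * sigma^2)), ok = ok & abs(d) <= sigma)
    }
    if (!is.na(dims$ha)) { r <- add_dim(g, ok, paste0("w", dims$ha), hH[qa], tol$tol_h); g <- r$g; ok <- r$ok }
    if (!is.na(dims$ca)) { r <- add_dim(g, ok, paste0("w", dims$ca), hC[qa], tol$tol_c); g <- r$g; ok <- r$ok }
    if (!is.na(dims$hb)) { r <- add_dim(g, ok, paste0("w", dims$hb), hH[qb], tol$tol_h); g <- r$g; ok <- r$ok }
    if (!is.na(dims$cb)) { r <- add_dim(g, ok, paste0("w", dims$cb), hC[qb], tol$tol_c); g <- r$g; ok <- r$ok }
    if (any(ok)) total <- total + exp_tab$prob[i] * max(g[ok])
  }
  unused <- nrow(problem$hmqc) - length(unique(assign[assign > 0L]))
  total - problem$lambda * degeneracy_count(problem, assign) -
    problem$mu * unused
}

degeneracy_count <- function(problem, assign) {
  on <- which(assign > 0L)
  if (length(on) < 2L) return(0)
  w <- function(shifts, tol) {
    d <- abs(outer(shifts, shifts, "-")) / tol
    w <- (1 - d)^2 * (d < 1)
    sum(w[upper.tri(w)])
  }
  w(problem$hmqc$w2[assign[on]], problem$tol$tol_c) +
    w(problem$hmqc$w1[assign[on]], problem$tol$tol_h)
}

#' Expected-to-measured mapping induced by an assignment state
#'
#' @inheritParams score_assignment
#' @return tibble with one row per expected peak: the mapped measured-peak
#'   row (`NA` if unmapped) and its alignment factor.
#' @export
induced_mapping <- function(problem, assign) {
  exp_tab <- problem$expected
  n <- nrow(exp_tab)
  peak_row <- rep(NA_integer_, n)
  gfac <- rep(NA_real_, n)
  is_hmqc <- exp_tab$experiment == "C13HSQC"
  qa <- ifelse(is.na(exp_tab$ia), 0L, assign[pmax(exp_tab$ia, 1L)])
  qb <- ifelse(is.na(exp_tab$ib), 0L, assign[pmax(exp_tab$ib, 1L)])
  peak_row[is_hmqc & qa > 0L] <- qa[is_hmqc & qa > 0L] # HMQC row index
  gfac[is_hmqc & qa > 0L] <- 1
  idx <- which(!is_hmqc & qa > 0L & qb > 0L)
  for (k in unique(problem$mat_id[idx])) {
    rows <- idx[problem$mat_id[idx] == k]
    ij <- cbind(qa[rows], qb[rows])
    g <- problem$match_M[[k]][ij]
    p <- problem$match_A[[k]][ij]
    hit <- p > 0L
    peak_row[rows[hit]] <- p[hit]
    gfac[rows[hit]] <- g[hit]
  }
  tibble::tibble(
    experiment = exp_tab$experiment, id_a = exp_tab$id_a, id_b = exp_tab$id_b,
    prob = exp_tab$prob, peak_row = peak_row, g = gfac
  )
}

pack_problem <- function(problem) {
  exp_tab <- problem$expected
  # NOE degree of each methyl in the expected network and of each HMQC
  # peak in the measured network (used for degree-guided starts)
  noe_rows <- exp_tab$experiment != "C13HSQC"
  m_deg <- as.numeric(table(factor(
    c(exp_tab$ia[noe_rows], exp_tab$ib[noe_rows]),
    levels = seq_len(nrow(problem$methyls)))))
  q_deg <- rep(0, nrow(problem$hmqc))
  for (expm in names(problem$measured)) {
    tab <- problem$measured[[expm]]
    for (col in c("hmqc_a", "hmqc_b")) {
      if (col %in% names(tab)) {
        idx <- match(tab[[col]], problem$hmqc$id)
        idx <- idx[!is.na(idx)]
        if (length(idx)) {
          cnt <- table(factor(idx, levels = seq_len(nrow(problem$hmqc))))
          q_deg <- q_deg + as.numeric(cnt)
        }
      }
    }
  }
  list(
    n = nrow(problem$methyls),
    nq = nrow(problem$hmqc),
    allowed = lapply(problem$allowed, function(a) as.integer(a - 1L)),
    e_a = as.integer(ifelse(is.na(exp_tab$ia), -1L, exp_tab$ia - 1L)),
    e_b = as.integer(ifelse(is.na(exp_tab$ib), -1L, exp_tab$ib - 1L)),
    e_prob = as.numeric(exp_tab$prob),
    e_mat = as.integer(ifelse(is.na(problem$mat_id), -1L, problem$mat_id - 1L)),
    mats = problem$match_M,
    H = as.numeric(problem$hmqc$w1),
    C = as.numeric(problem$hmqc$w2),
    tol_h = problem$tol$tol_h,
    tol_c = problem$tol$tol_c,
    lambda = problem$lambda,
    mu = problem$mu,
    m_deg = m_deg,
    q_deg = q_deg
  )
}

#' Greedy local optimization of an assignment state
#'
#' Runs the stated number of random reassignment / unassignment / swap
#' proposals with greedy acceptance (a proposal is kept only if it does not
#' decrease the score), so the score trace is non-decreasing.
#'
#' @inheritParams score_assignment
#' @param iterations number of proposals.
#' @param seed random seed.
#' @return list with the optimized `assign` vector and its `score`.
#' @export
local_optimize <- function(problem, assign, iterations, seed = 1) {
  pk <- pack_problem(problem)
  res <- cpp_local_optimize(pk, as.integer(assign), as.integer(iterations),
                            as.integer(seed))
  list(assign = as.integer(res$assign), score = res$score)
}

#' Evolutionary optimization of the peak mapping
#'
#' Optimizes the methyl-to-HMQC-peak mapping with a generational
#' evolutionary algorithm: score-ranked tournament selection, per-methyl
#' uniform recombination, random remapping mutation, and greedy local
#' search applied to every offspring (the total local-search budget
#' `iterations` is apportioned across generations). Deterministic given the
#' seed. Stops after `generations` generations or when the best score has
#' stagnated.
#'
#' @param problem a `methyl_problem`.
#' @param config an [optimizer_config()].
#' @param seed random seed for this run.
#' @return list with `assign`, `score` and `generations` used.
#' @export
evolve_assignment <- function(problem, config = optimizer_config(), seed = 1) {
  if (all(vapply(problem$measured, nrow, 0L) == 0) &&
      length(problem$measured) == 0L && nrow(problem$hmqc) == 0L) {
    stop("no measured input")
  }
  pk <- pack_problem(problem)
  res <- cpp_evolve(pk, config$population, config$generations,
                    config$stagnation, config$iterations,
                    config$mutation_rate, as.integer(seed))
  list(assign = as.integer(res$assign), score = res$score,
       generations = res$generations)
}

#' Exhaustive assignment oracle for tiny problems
#'
#' Enumerates all residue-type-consistent injective mappings of methyls to
#' HMQC peaks (with unassigned allowed only when no peak is left), scores
#' each complete state with the independent reference scorer
#' [score_assignment()], and returns the global optimum together with all
#' co-optimal states. Refuses instances with more than `max_methyls`
#' methyls.
#'
#' @inheritParams score_assignment
#' @param max_methyls hard size limit (factorial search space).
#' @param tol_tie score tie tolerance for reporting co-optima.
#' @return list with `assign`, `score`, and `optima` (list of co-optimal
#'   assignment vectors, capped at 50).
#' @export
brute_force_assign <- function(problem, max_methyls = 8, tol_tie = 1e-9) {
  n <- nrow(problem$methyls)
  if (n > max_methyls) {
    stop("instance too large for exhaustive search (", n, " methyls)")
  }
  best <- list(score = -Inf, assign = NULL, optima = list())
  assign <- integer(n)
  used <- rep(FALSE, nrow(problem$hmqc))
  recurse <- function(m) {
    if (m > n) {
      s <- score_assignment(problem, assign)
      if (s > best$score + tol_tie) {
        best$score <<- s
        best$assign <<- assign
        best$optima <<- list(assign)
      } else if (abs(s - best$score) <= tol_tie &&
                 length(best$optima) < 50L) {
        best$optima <<- c(best$optima, list(assign))
      }
      return(invisible())
    }
    opts <- problem$allowed[[m]]
    opts <- opts[!used[opts]]
    if (length(opts) == 0L) opts <- 0L
    for (q in opts) {
      assign[m] <<- q
      if (q > 0L) used[q] <<- TRUE
      recurse(m + 1L)
      if (q > 0L) used[q] <<- FALSE
      assign[m] <<- 0L
    }
  }
  recurse(1L)
  best
}

#' Per-run chemical shifts and NOE support from a final state
#'
#' For every methyl assigned in the state, derives the \eqn{^{13}}C and
#' \eqn{^1}H shift as the median of the measured-peak coordinates mapped to
#' that atom (its HMQC peak plus the matching dimensions of every mapped
#' NOESY peak), and counts the mapped methyl-methyl NOESY peaks that
#' involve the methyl (geminal HCcCH correlations are not counted as NOE
#' support).
#'
#' @inheritParams score_assignment
#' @return tibble with one row per assigned methyl: `methyl_id`,
#'   `shift_c`, `shift_h`, `noe_count`, `n_peaks`.
#' @export
derive_run_shifts <- function(problem, assign) {
  mp <- induced_mapping(problem, assign)
  out <- list()
  hm <- which(mp$experiment == "C13HSQC" & !is.na(mp$peak_row))
  if (length(hm)) {
    out[[1]] <- data.frame(
      methyl_id = mp$id_a[hm],
      c_coord = problem$hmqc$w2[mp$peak_row[hm]],
      h_coord = problem$hmqc$w1[mp$peak_row[hm]],
      noe = FALSE, peak = paste0("HMQC:", mp$peak_row[hm])
    )
  }
  for (expm in names(problem$measured)) {
    rows <- which(mp$experiment == expm & !is.na(mp$peak_row))
    if (length(rows) == 0L) next
    tab <- problem$measured[[expm]]
    dims <- experiment_dims(expm)
    r <- mp$peak_row[rows]
    is_noe <- experiment_def(expm)$transfer == "noe"
    key <- paste0(expm, ":", r)
    getw <- function(d) if (is.na(d)) NA_real_ else tab[[paste0("w", d)]][r]
    out[[length(out) + 1L]] <- data.frame(
      methyl_id = mp$id_a[rows], c_coord = getw(dims$ca),
      h_coord = getw(dims$ha), noe = is_noe, peak = key
    )
    out[[length(out) + 1L]] <- data.frame(
      methyl_id = mp$id_b[rows], c_coord = getw(dims$cb),
      h_coord = getw(dims$hb), noe = is_noe, peak = key
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(methyl_id = character(), shift_c = numeric(),
                          shift_h = numeric(), noe_count = integer(),
                          n_peaks = integer()))
  }
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$methyl_id) |>
    dplyr::summarise(
      shift_c = median(.data$c_coord, na.rm = TRUE),
      shift_h = median(.data$h_coord, na.rm = TRUE),
      noe_count = length(unique(.data$peak[.data$noe])),
      n_peaks = dplyr::n(),
      .groups = "drop"
    )
}

#' Run the full batch of independent optimization runs
#'
#' Performs `config$runs` independent optimization runs for each distance
#' cutoff of the triplet `d_cut - 0.5, d_cut, d_cut + 0.5` (or for the
#' single cutoff in `"single"` mode), each from a different random start,
#' and derives per-run chemical shifts. Run `i` (counted across cutoffs)
#' uses seed `config$seed + i`, making the whole batch deterministic.
#'
#' @inheritParams build_problem
#' @param config an [optimizer_config()].
#' @param mode `"triplet"` (default) or `"single"` cutoff mode.
#' @return a `methyl_runs` object: list with `run_shifts` (one row per run
#'   and assigned methyl), `run_stats` (per-run score and explained-NOE
#'   counts), the methyl table, and the configurations used.
#' @export
assign_runs <- function(methyls, hmqc, typing = NULL, measured = list(),
                        config = optimizer_config(),
                        gen_config = generation_config(),
                        tol = tolerances(), mode = c("triplet", "single")) {
  mode <- match.arg(mode)
  cutoffs <- if (mode == "triplet") gen_config$cutoffs else gen_config$d_cut
  shift_rows <- list()
  stat_rows <- list()
  expected_counts <- list()
  run_id <- 0L
  for (ci in seq_along(cutoffs)) {
    problem <- build_problem(methyls, hmqc, typing, measured, tol = tol,
                             lambda = config$lambda, mu = config$mu,
                             config = gen_config,
                             d_cut = cutoffs[ci])
    n_noesy_measured <- sum(vapply(problem$measured, function(tab) {
      nrow(tab)
    }, 0L)[vapply(names(problem$measured), function(e)
      experiment_def(e)$transfer == "noe", TRUE)])
    expected_counts[[ci]] <- problem$expected |>
      dplyr::count(.data$experiment, name = "n_expected") |>
      dplyr::mutate(d_cut = cutoffs[ci])
    for (r in seq_len(config$runs)) {
      run_id <- run_id + 1L
      res <- evolve_assignment(problem, config,
                               seed = config$seed + run_id)
      shifts <- derive_run_shifts(problem, res$assign)
      if (nrow(shifts)) {
        shifts$run <- run_id
        shifts$d_cut <- cutoffs[ci]
        shift_rows[[run_id]] <- shifts
      }
      mp <- induced_mapping(problem, res$assign)
      noe_rows <- vapply(mp$experiment, function(e)
        e != "C13HSQC" && experiment_def(e)$transfer == "noe", TRUE)
      mapped_noesy <- length(unique(paste0(
        mp$experiment[noe_rows & !is.na(mp$peak_row)], ":",
        mp$peak_row[noe_rows & !is.na(mp$peak_row)])))
      stat_rows[[run_id]] <- tibble::tibble(
        run = run_id, d_cut = cutoffs[ci], score = res$score,
        generations = res$generations,
        n_mapped_noesy = mapped_noesy,
        n_measured_noesy = n_noesy_measured
      )
    }
  }
  structure(
    list(
      run_shifts = dplyr::bind_rows(shift_rows),
      run_stats = dplyr::bind_rows(stat_rows),
      methyls = methyls,
      expected_counts = dplyr::bind_rows(expected_counts),
      measured_counts = tibble::tibble(
        list_name = c("C13HSQC",
                      vapply(measured, function(x) pl_name(x) %||% "?", "")),
        n_measured = c(nrow(hmqc),
                       vapply(measured, nrow, 0L))
      ),
      n_runs = run_id, config = config, gen_config = gen_config,
      tol = tol, mode = mode
    ),
    class = "methyl_runs"
  )
}

#' @export
print.methyl_runs <- function(x, ...) {
  cat(sprintf("<methyl_runs> %d runs (%s mode), %d methyls, mean score %.2f\n",
              x$n_runs, x$mode, nrow(x$methyls), mean(x$run_stats$score)))
  invisible(x)
}
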