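#' Simulation configuration
#'
#' Defines a synthetic methyl-labeled protein benchmark: methyl carbons
#' packed in a sphere (minimum non-geminal separation 3.5 Angstrom,
#' geminal Leu/Val partners 1.8-3.0 Angstrom apart), per-type chemical
#' shifts drawn from the packaged statistics, and peak lists with
#' controllable imperfections (NOE observation dropout, coordinate jitter,
#' artifact peaks, missing HMQC peaks, unreciprocated NOEs).
#'
#' @param n_methyls number of methyl groups.
#' @param radius packing-sphere radius in Angstrom; the default
#'   \eqn{3.7 n^{1/3}} reproduces the methyl density of folded proteins
#'   (roughly 220 cubic Angstrom per methyl, i.e. about five NOE contacts
#'   per methyl within the observable range).
#' @param composition methyl fraction per residue-type letter.
#' @param noe_cutoff effective distance (Angstrom) below which a methyl
#'   pair gives rise to NOESY cross peaks.
#' @param p_obs observation probability of each directional NOESY peak.
#' @param jitter_sd coordinate jitter standard deviation, as a fraction of
#'   the matching tolerance of each nucleus.
#' @param artifact_rate artifact peaks added per real NOESY peak.
#' @param missing_hmqc_rate fraction of methyls absent from the HMQC list.
#' @param unreciprocated_rate probability that one direction of an
#'   observed reciprocal NOESY pair is deleted.
#' @param sn_meanlog,sn_sdlog log-normal signal-to-noise parameters. For
#'   NOESY peaks `sn_meanlog` is the log mean S/N of a 4 Angstrom contact;
#'   the mean decays with the inverse sixth power of the effective
#'   distance, consistent with the volume model, so distant contacts fall
#'   below typical S/N filters (artifacts use a weaker distribution).
#' @param include_geminal_list emit a geminal HCcCH correlation list?
#' @param experiment NOESY experiment type emitted.
#' @param seed random seed; the dataset is a pure function of the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_methyls = 50, radius = NULL,
                       composition = c(A = 0.2, I = 0.2, L = 0.3, V = 0.3),
                       noe_cutoff = 6, p_obs = 1, jitter_sd = 0,
                       artifact_rate = 0, missing_hmqc_rate = 0,
                       unreciprocated_rate = 0,
                       sn_meanlog = log(20), sn_sdlog = 0.6,
                       include_geminal_list = TRUE,
                       experiment = "CCNOESY", seed = 1) {
  stopifnot(n_methyls > 0, p_obs > 0, p_obs <= 1, jitter_sd >= 0,
            artifact_rate >= 0, missing_hmqc_rate >= 0,
            missing_hmqc_rate <= 1, unreciprocated_rate >= 0,
            unreciprocated_rate <= 1)
  composition <- composition / sum(composition)
  structure(
    list(n_methyls = n_methyls,
         radius = radius %||% (3.7 * n_methyls^(1 / 3)),
         composition = composition, noe_cutoff = noe_cutoff, p_obs = p_obs,
         jitter_sd = jitter_sd, artifact_rate = artifact_rate,
         missing_hmqc_rate = missing_hmqc_rate,
         unreciprocated_rate = unreciprocated_rate,
         sn_meanlog = sn_meanlog, sn_sdlog = sn_sdlog,
         include_geminal_list = include_geminal_list,
         experiment = experiment, seed = seed),
    class = "sim_config"
  )
}

sim_carbon_names <- list(
  A = c("CB"), I = c("CD1"), L = c("CD1", "CD2"), V = c("CG1", "CG2"),
  M = c("CE"), T = c("CG2")
)
sim_restypes <- c(A = "ALA", I = "ILE", L = "LEU", V = "VAL", M = "MET",
                  T = "THR")

random_unit <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) return(v / nv)
  }
}

#' Simulate a synthetic methyl NMR dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return a `methyl_simulation` list: `methyls` (geometry table in the
#'   [extract_methyl_groups()] schema), `hmqc`, `noesy` and optional
#'   `geminal` peak lists, the true `typing`, a `reference` shift table
#'   for evaluation, and `truth` (per-methyl shifts and the NOESY peak to
#'   methyl-pair map, `NA` for artifact peaks).
#' @export
simulate_methyl_dataset <- function(config = sim_config()) {
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  n <- config$n_methyls
  R <- config$radius

  # residue units (Leu/Val bring two methyls)
  letters_pool <- names(config$composition)
  units <- list()
  total <- 0L
  while (total < n) {
    l <- sample(letters_pool, 1L, prob = config$composition)
    size <- length(sim_carbon_names[[l]])
    if (total + size > n) {
      singles <- letters_pool[vapply(letters_pool, function(x)
        length(sim_carbon_names[[x]]) == 1L, TRUE)]
      if (length(singles) == 0L) break
      l <- sample(singles, 1L)
      size <- 1L
    }
    units[[length(units) + 1L]] <- l
    total <- total + size
  }

  # pack carbons in the sphere
  carbons <- matrix(numeric(0), ncol = 3)
  unit_of <- integer(0)
  sample_point <- function() {
    repeat {
      p <- runif(3, -R, R)
      if (sum(p^2) <= R^2) return(p)
    }
  }
  min_sep_ok <- function(p, exclude = integer(0)) {
    if (nrow(carbons) == 0L) return(TRUE)
    keep <- setdiff(seq_len(nrow(carbons)), exclude)
    if (length(keep) == 0L) return(TRUE)
    all(sqrt(rowSums((carbons[keep, , drop = FALSE] -
                        matrix(p, length(keep), 3, byrow = TRUE))^2)) >= 3.5)
  }
  for (u in seq_along(units)) {
    l <- units[[u]]
    n_c <- length(sim_carbon_names[[l]])
    placed <- FALSE
    for (attempt in seq_len(2000L)) {
      p1 <- sample_point()
      if (!min_sep_ok(p1)) next
      if (n_c == 1L) {
        carbons <- rbind(carbons, p1)
        unit_of <- c(unit_of, u)
        placed <- TRUE
        break
      }
      ok2 <- FALSE
      for (a2 in seq_len(50L)) {
        p2 <- p1 + random_unit() * runif(1, 1.8, 3.0)
        if (sum(p2^2) <= R^2 && min_sep_ok(p2)) { ok2 <- TRUE; break }
      }
      if (!ok2) next
      carbons <- rbind(carbons, p1, p2)
      unit_of <- c(unit_of, u, u)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("infeasible packing for ", n, " methyls in radius ", round(R, 1),
           " A; increase the radius")
    }
  }

  # methyl table
  rows <- list()
  for (u in seq_along(units)) {
    l <- units[[u]]
    idx <- which(unit_of == u)
    cn <- sim_carbon_names[[l]]
    for (k in seq_along(idx)) {
      cpos <- carbons[idx[k], ]
      stem <- cpos + 1.5 * random_unit()
      axis <- cpos - stem
      perp <- random_unit()
      perp <- perp - sum(perp * axis) * axis / sum(axis^2)
      ref <- stem + perp
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = paste0(u, "-", cn[k]), resno = u, restype = sim_restypes[[l]],
        carbon = cn[k], proton_name = paste0("Q", substring(cn[k], 2L)),
        letter = l,
        geminal_id = if (length(cn) == 2L)
          paste0(u, "-", cn[3L - k]) else NA_character_,
        cx = cpos[1], cy = cpos[2], cz = cpos[3],
        protons = list(build_methyl_protons(cpos, stem, ref))
      )
    }
  }
  methyls <- dplyr::bind_rows(rows)

  # true shifts per methyl
  stats_tab <- methyl_shift_stats()
  si <- match(paste(methyls$restype, methyls$carbon),
              paste(stats_tab$restype, stats_tab$carbon))
  truth_shifts <- tibble::tibble(
    methyl_id = methyls$id,
    shift_c = rnorm(nrow(methyls), stats_tab$c_mean[si], stats_tab$c_sd[si]),
    shift_h = rnorm(nrow(methyls), stats_tab$h_mean[si], stats_tab$h_sd[si])
  )
  tol <- tolerances()
  jC <- config$jitter_sd * tol$tol_c
  jH <- config$jitter_sd * tol$tol_h

  # HMQC list
  keep_h <- runif(nrow(methyls)) >= config$missing_hmqc_rate
  hm <- tibble::tibble(
    id = seq_len(sum(keep_h)),
    w1 = truth_shifts$shift_h[keep_h] + rnorm(sum(keep_h), 0, jH),
    w2 = truth_shifts$shift_c[keep_h] + rnorm(sum(keep_h), 0, jC),
    volume = 1e6, sn = rlnorm(sum(keep_h), config$sn_meanlog, config$sn_sdlog)
  )
  hmqc <- peaklist(hm, nuclei = c("H", "C"), name = "C13HSQC",
                   experiment = "C13HSQC")
  truth_hmqc <- tibble::tibble(peak_id = hm$id,
                               methyl_id = methyls$id[keep_h])
  type_label <- c(A = "A", I = "I", L = "LV", V = "LV", M = "M", T = "T")
  typing <- tibble::tibble(id = hm$id,
                           type = type_label[methyls$letter[keep_h]])

  # NOESY list (directional peaks for pairs under the cutoff)
  shift_of <- function(ids) {
    i <- match(ids, methyls$id)
    cbind(h = truth_shifts$shift_h[i], c = truth_shifts$shift_c[i])
  }
  pairs <- methyl_distance_table(methyls, d_max = config$noe_cutoff)
  dir_tab <- dplyr::bind_rows(
    tibble::tibble(id_a = pairs$id_a, id_b = pairs$id_b, d_eff = pairs$d_eff,
                   pair = seq_len(nrow(pairs))),
    tibble::tibble(id_a = pairs$id_b, id_b = pairs$id_a, d_eff = pairs$d_eff,
                   pair = seq_len(nrow(pairs)))
  )
  obs <- runif(nrow(dir_tab)) <= config$p_obs
  dir_tab <- dir_tab[obs, , drop = FALSE]
  # unreciprocated thinning of complete pairs
  if (config$unreciprocated_rate > 0 && nrow(dir_tab) > 0L) {
    cnt <- table(dir_tab$pair)
    complete <- as.integer(names(cnt)[cnt == 2L])
    drop_rows <- integer(0)
    for (pr in complete) {
      if (runif(1) < config$unreciprocated_rate) {
        i <- which(dir_tab$pair == pr)
        drop_rows <- c(drop_rows, sample(i, 1L))
      }
    }
    if (length(drop_rows)) dir_tab <- dir_tab[-drop_rows, , drop = FALSE]
  }
  a <- shift_of(dir_tab$id_a); b <- shift_of(dir_tab$id_b)
  nr <- nrow(dir_tab)
  no <- tibble::tibble(
    w1 = a[, "h"] + rnorm(nr, 0, jH), w2 = a[, "c"] + rnorm(nr, 0, jC),
    w3 = b[, "c"] + rnorm(nr, 0, jC), w4 = b[, "h"] + rnorm(nr, 0, jH),
    volume = 1e5 * (dir_tab$d_eff / 3)^-6,
    sn = rlnorm(nr, config$sn_meanlog + 6 * log(4 / dir_tab$d_eff),
                config$sn_sdlog)
  )
  n_art <- round(config$artifact_rate * nr)
  if (n_art > 0L) {
    art <- tibble::tibble(
      w1 = runif(n_art, min(no$w1), max(no$w1)),
      w2 = runif(n_art, min(no$w2), max(no$w2)),
      w3 = runif(n_art, min(no$w3), max(no$w3)),
      w4 = runif(n_art, min(no$w4), max(no$w4)),
      volume = 1e4,
      sn = rlnorm(n_art, log(3), config$sn_sdlog)
    )
    no <- dplyr::bind_rows(no, art)
  }
  no$id <- seq_len(nrow(no))
  noesy <- peaklist(no, nuclei = c("H", "C", "C", "H"), name = "CCNOESY",
                    experiment = config$experiment)
  noesy_map <- tibble::tibble(
    peak_id = no$id,
    id_a = c(dir_tab$id_a, rep(NA_character_, n_art)),
    id_b = c(dir_tab$id_b, rep(NA_character_, n_art))
  )

  # geminal HCcCH correlation list
  geminal <- NULL
  if (config$include_geminal_list) {
    gp <- methyls[!is.na(methyls$geminal_id), , drop = FALSE]
    if (nrow(gp) > 0L) {
      ga <- shift_of(gp$id); gb <- shift_of(gp$geminal_id)
      ng <- nrow(gp)
      gm <- tibble::tibble(
        id = seq_len(ng),
        w1 = ga[, "h"] + rnorm(ng, 0, jH), w2 = ga[, "c"] + rnorm(ng, 0, jC),
        w3 = gb[, "c"] + rnorm(ng, 0, jC), w4 = gb[, "h"] + rnorm(ng, 0, jH),
        volume = 1e6, sn = NA_real_
      )
      geminal <- peaklist(gm, nuclei = c("H", "C", "C", "H"),
                          name = "HCcCH", experiment = "HCcCH")
    }
  }

  reference <- tibble::tibble(
    id = seq_len(2L * nrow(methyls)),
    shift = as.vector(rbind(truth_shifts$shift_c, truth_shifts$shift_h)),
    error = 0,
    atom = as.vector(rbind(methyls$carbon, methyls$proton_name)),
    resno = rep(methyls$resno, each = 2L)
  )

  structure(
    list(methyls = methyls, hmqc = hmqc, noesy = noesy, geminal = geminal,
         typing = typing, reference = reference,
         truth = list(shifts = truth_shifts, hmqc_map = truth_hmqc,
                      noesy_map = noesy_map),
         config = config),
    class = "methyl_simulation"
  )
}

#' @export
print.methyl_simulation <- function(x, ...) {
  cat(sprintf(
    "<methyl_simulation> %d methyls (radius %.1f A), %d HMQC, %d NOESY%s peaks, seed %d\n",
    nrow(x$methyls), x$config$radius, nrow(x$hmqc), nrow(x$noesy),
    if (!is.null(x$geminal)) sprintf(", %d geminal", nrow(x$geminal)) else "",
    x$config$seed))
  invisible(x)
}

#' Parameter sweep over distance cutoff and NOE observation probability
#'
#' Runs the full prep / assign / consolidate / evaluate pipeline once per
#' grid point and tabulates the percentage of methyls assigned strong, the
#' correctness of the strong set against the ground-truth reference, and
#' the explained NOE fraction.
#'
#' @param dataset a `methyl_simulation`.
#' @param d_cut_grid distance cutoffs (Angstrom) to evaluate.
#' @param p_noe_grid expected-NOE observation probabilities to evaluate.
#' @param config reduced [optimizer_config()] used at every grid point.
#' @param mode cutoff mode passed to [assign_runs()] (single-cutoff by
#'   default, so each grid point probes exactly one `d_cut`).
#' @param threshold strong-classification threshold.
#' @param out optional TSV output path.
#' @return `methyl_sweep` tibble with one row per grid point.
#' @export
sweep_parameters <- function(dataset, d_cut_grid = c(4.5, 5.5),
                             p_noe_grid = c(0.1, 0.3),
                             config = optimizer_config(population = 30,
                                                       runs = 10,
                                                       iterations = 2000),
                             mode = "single", threshold = 0.8, out = NULL) {
  stopifnot(length(d_cut_grid) > 0, length(p_noe_grid) > 0)
  grid <- expand.grid(d_cut = d_cut_grid, p_noe = p_noe_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_methyl_pipeline(
      dataset, config = config,
      gen_config = generation_config(d_cut = grid$d_cut[i],
                                     p_noe = grid$p_noe[i]),
      mode = mode, threshold = threshold
    )
    g <- glance(res)
    tibble::tibble(
      d_cut = grid$d_cut[i], p_noe = grid$p_noe[i],
      pct_strong = 100 * g$n_strong / g$n_methyls,
      pct_correct = ifelse(g$n_strong > 0, 100 * g$n_correct / g$n_strong, NA),
      pct_erroneous = ifelse(g$n_strong > 0,
                             100 * g$n_erroneous / g$n_strong, NA),
      pct_explained = 100 * g$explained
    )
  })
  out_tab <- dplyr::bind_rows(rows)
  class(out_tab) <- c("methyl_sweep", class(out_tab))
  if (!is.null(out)) {
    utils::write.table(out_tab, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out_tab
}
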