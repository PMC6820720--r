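#' Consensus chemical shift from a set of run values
#'
#' The consensus shift is the global maximum of the sum of Gaussians
#' centered at the shift values obtained in the individual optimization
#' runs, with standard deviation equal to the matching tolerance. The
#' maximum is located over the input values refined by a local grid of
#' spacing `tol / 20`; ties break toward the lowest ppm. The agreement
#' fraction is the share of runs whose value lies within one tolerance of
#' the consensus.
#'
#' @param values shift values (ppm) from the individual runs.
#' @param tol matching tolerance for this nucleus (ppm); also the Gaussian
#'   standard deviation.
#' @param n_total total number of runs the fraction is computed against
#'   (defaults to `length(values)`; pass the pooled run count when some
#'   runs left the atom unassigned).
#' @return list with `shift` and `fraction`; `shift` is `NA` for empty
#'   input.
#' @export
consensus_shift <- function(values, tol, n_total = length(values)) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(list(shift = NA_real_, fraction = 0))
  }
  ksum <- function(x) {
    vapply(x, function(xi) sum(exp(-(values - xi)^2 / (2 * tol^2))), 0)
  }
  cand <- sort(unique(values))
  k1 <- ksum(cand)
  best <- cand[which.max(k1)] # which.max returns first = lowest ppm on ties
  grid <- seq(best - tol, best + tol, by = tol / 20)
  k2 <- ksum(grid)
  shift <- grid[which.max(k2)]
  list(shift = shift,
       fraction = sum(abs(values - shift) <= tol) / n_total)
}

#' Joint redistribution of geminal methyl shifts across runs
#'
#' For a prochiral Leu/Val methyl pair, individual runs may deliver the two
#' (\eqn{^{13}}C, \eqn{^1}H) shift pairs in either order since no
#' stereospecific assignment is attempted. Before consolidation the two
#' pairs of each run are sorted so that slot 1 receives the smaller and
#' slot 2 the larger shifts (ordered by \eqn{^{13}}C, ties by \eqn{^1}H),
#' keeping each \eqn{^1}H attached to its own \eqn{^{13}}C. Runs in which
#' only one methyl of the pair is assigned contribute nothing.
#'
#' @param pair_runs tibble with columns `run`, `slot` (1 or 2), `shift_c`,
#'   `shift_h` (one row per assigned methyl of the pair per run); extra
#'   columns are carried along.
#' @return tibble of the same shape with slot values redistributed.
#' @export
consolidate_geminal <- function(pair_runs) {
  pair_runs <- tibble::as_tibble(pair_runs)
  stopifnot(all(c("run", "slot", "shift_c", "shift_h") %in% names(pair_runs)))
  complete <- pair_runs |>
    dplyr::count(.data$run) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::pull(.data$run)
  out <- pair_runs[pair_runs$run %in% complete, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  out |>
    dplyr::group_by(.data$run) |>
    dplyr::arrange(.data$shift_c, .data$shift_h, .by_group = TRUE) |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$run, .data$slot)
}

#' Consolidate optimization runs into consensus assignments
#'
#' Pools all runs (3 x runs in triplet-cutoff mode), redistributes geminal
#' Leu/Val pairs jointly with [consolidate_geminal()], determines the
#' consensus \eqn{^{13}}C and \eqn{^1}H shift of every methyl with
#' [consensus_shift()], and classifies each assignment as `"strong"` when
#' the joint agreement fraction (runs with both nuclei within tolerance of
#' the consensus) exceeds `threshold` *and* at least one methyl-methyl NOE
#' supports the assignment, else `"weak"`.
#'
#' @param runs a `methyl_runs` object from [assign_runs()], or a run-shift
#'   tibble with columns `run`, `methyl_id`, `shift_c`, `shift_h`,
#'   `noe_count` (then `methyls`, `tol` and `n_runs` must be given).
#' @param methyls methyl table (defaults to the one inside `runs`).
#' @param tol [tolerances()].
#' @param threshold agreement-fraction threshold for a strong assignment
#'   (default 0.8, i.e. more than 80% of the runs; 0.9 is a stricter
#'   variant).
#' @param k_alternatives number of ambiguous alternative shifts reported.
#' @param n_runs pooled run count (defaults to the count inside `runs`).
#' @return a `methyl_consensus` tibble: one row per methyl with consensus
#'   shifts, agreement fraction, NOE support (median over the runs in
#'   which the methyl was assigned), strength label, and a list column of
#'   alternatives.
#' @export
consolidate_runs <- function(runs, methyls = NULL, tol = tolerances(),
                             threshold = 0.8, k_alternatives = 3,
                             n_runs = NULL) {
  if (inherits(runs, "methyl_runs")) {
    methyls <- methyls %||% runs$methyls
    tol <- runs$tol %||% tol
    n_runs <- n_runs %||% runs$n_runs
    shifts <- runs$run_shifts
  } else {
    shifts <- tibble::as_tibble(runs)
    if (is.null(methyls)) stop("methyls table required")
    if (is.null(n_runs)) n_runs <- length(unique(shifts$run))
  }
  if (!is.null(n_runs) && nrow(shifts) > 0L) {
    extra <- setdiff(unique(shifts$run), seq_len(n_runs))
    if (length(extra) && length(unique(shifts$run)) != n_runs) {
      warning("run batch size mismatch; proceeding with pooled runs")
      n_runs <- length(unique(shifts$run))
    }
  }

  # joint geminal redistribution
  pairs <- methyls[!is.na(methyls$geminal_id) &
                     methyls$id < methyls$geminal_id, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    ids <- c(pairs$id[i], pairs$geminal_id[i])
    sel <- shifts$methyl_id %in% ids
    sub <- shifts[sel, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub$slot <- match(sub$methyl_id, ids)
    red <- consolidate_geminal(sub)
    red$methyl_id <- ids[red$slot]
    red$slot <- NULL
    shifts <- dplyr::bind_rows(shifts[!sel, , drop = FALSE], red)
  }

  per_methyl <- lapply(seq_len(nrow(methyls)), function(i) {
    id <- methyls$id[i]
    sub <- shifts[shifts$methyl_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(tibble::tibble(
        methyl_id = id, shift_c = NA_real_, shift_h = NA_real_,
        fraction = 0, n_assigned = 0L, noe_support = 0,
        strength = "weak", alternatives = list(tibble::tibble())
      ))
    }
    cc <- consensus_shift(sub$shift_c, tol$tol_c, n_total = n_runs)
    ch <- consensus_shift(sub$shift_h, tol$tol_h, n_total = n_runs)
    agree <- abs(sub$shift_c - cc$shift) <= tol$tol_c &
      abs(sub$shift_h - ch$shift) <= tol$tol_h
    fraction <- sum(agree) / n_runs
    noe_support <- stats::median(sub$noe_count)
    strength <- if (fraction > threshold && noe_support >= 1) "strong" else "weak"
    alternatives <- consensus_alternatives(sub, cc$shift, tol, n_runs,
                                           k_alternatives)
    tibble::tibble(
      methyl_id = id, shift_c = cc$shift, shift_h = ch$shift,
      fraction = fraction, n_assigned = nrow(sub),
      noe_support = noe_support, strength = strength,
      alternatives = list(alternatives)
    )
  })
  out <- dplyr::bind_rows(per_methyl) |>
    dplyr::left_join(
      methyls |>
        dplyr::select("id", "resno", "restype", "carbon", "proton_name",
                      "geminal_id"),
      by = c(methyl_id = "id")
    )
  structure(out, n_runs = n_runs, threshold = threshold, tol = tol,
            class = c("methyl_consensus", class(tibble::tibble())))
}

# top-k alternative consensus positions outside the main window
consensus_alternatives <- function(sub, main_shift, tol, n_runs, k) {
  alt <- list()
  remaining <- sub[abs(sub$shift_c - main_shift) > tol$tol_c, , drop = FALSE]
  while (length(alt) < k && nrow(remaining) > 0L) {
    cc <- consensus_shift(remaining$shift_c, tol$tol_c, n_total = n_runs)
    within <- abs(remaining$shift_c - cc$shift) <= tol$tol_c
    alt[[length(alt) + 1L]] <- tibble::tibble(
      shift_c = cc$shift,
      shift_h = stats::median(remaining$shift_h[within]),
      fraction = sum(within) / n_runs
    )
    remaining <- remaining[!within, , drop = FALSE]
  }
  dplyr::bind_rows(alt)
}

#' @export
print.methyl_consensus <- function(x, ...) {
  cat(sprintf(
    "# methyl_consensus: %d methyls, %d strong (threshold %.2f, %d pooled runs)\n",
    nrow(x), sum(x$strength == "strong"), attr(x, "threshold"),
    attr(x, "n_runs")))
  NextMethod()
}

#' Evaluate consensus assignments against a reference shift list
#'
#' A strong assignment is counted `correct` when both its \eqn{^{13}}C and
#' \eqn{^1}H consensus shifts lie within the tolerances of the reference
#' shifts of the same atom, `erroneous` otherwise; strong atoms without a
#' reference entry are counted separately. Geminal pairs are compared as
#' ordered pairs after applying the same smaller/larger sorting to the
#' reference values, so no stereospecific claim is scored.
#'
#' @param consensus a `methyl_consensus` table.
#' @param reference shift list tibble from [read_shifts()] (carbon rows
#'   matched by atom name and residue number; proton rows by the
#'   pseudo-atom name, e.g. `QD1`).
#' @param tol [tolerances()].
#' @return a `methyl_evaluation` list with `counts` and a per-methyl
#'   `detail` table.
#' @export
evaluate_vs_reference <- function(consensus, reference, tol = tolerances()) {
  reference <- tibble::as_tibble(reference)
  ref_c <- reference[reference$atom %in% methyl_topology()$carbon, , drop = FALSE]
  ref_h <- reference[startsWith(reference$atom, "Q"), , drop = FALSE]
  ref_key <- function(atom, resno) paste0(resno, "-", atom)
  rc <- setNames(ref_c$shift, ref_key(ref_c$atom, ref_c$resno))
  rh <- setNames(ref_h$shift, ref_key(ref_h$atom, ref_h$resno))

  detail <- tibble::as_tibble(consensus)
  detail$ref_c <- unname(rc[paste0(detail$resno, "-", detail$carbon)])
  detail$ref_h <- unname(rh[paste0(detail$resno, "-", detail$proton_name)])

  # geminal reference pairs sorted like the consensus slots
  pairs <- detail[!is.na(detail$geminal_id) &
                    detail$methyl_id < detail$geminal_id, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    i1 <- which(detail$methyl_id == pairs$methyl_id[i])
    i2 <- which(detail$methyl_id == pairs$geminal_id[i])
    r1 <- c(detail$ref_c[i1], detail$ref_h[i1])
    r2 <- c(detail$ref_c[i2], detail$ref_h[i2])
    if (anyNA(c(r1, r2))) next
    if (r2[1] < r1[1] || (r2[1] == r1[1] && r2[2] < r1[2])) {
      detail$ref_c[i1] <- r2[1]; detail$ref_h[i1] <- r2[2]
      detail$ref_c[i2] <- r1[1]; detail$ref_h[i2] <- r1[2]
    }
  }

  detail$status <- dplyr::case_when(
    detail$strength != "strong" ~ "not-strong",
    is.na(detail$ref_c) | is.na(detail$ref_h) ~ "no-reference",
    abs(detail$shift_c - detail$ref_c) <= tol$tol_c &
      abs(detail$shift_h - detail$ref_h) <= tol$tol_h ~ "correct",
    TRUE ~ "erroneous"
  )
  counts <- tibble::tibble(
    all_strong = sum(detail$status != "not-strong"),
    correct = sum(detail$status == "correct"),
    erroneous = sum(detail$status == "erroneous"),
    no_reference = sum(detail$status == "no-reference")
  )
  structure(list(counts = counts, detail = detail),
            class = "methyl_evaluation")
}

#' @export
print.methyl_evaluation <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "<methyl_evaluation> strong: %d (correct %d, erroneous %d, no reference %d)\n",
    all_strong, correct, erroneous, no_reference)))
  invisible(x)
}

#' Fraction of measured NOESY peaks explained by the assignments
#'
#' Mean over runs of the share of measured methyl-methyl NOESY peaks that
#' the final mapping of the run accounts for.
#'
#' @param runs a `methyl_runs` object or its `run_stats` table.
#' @return fraction in \[0, 1\].
#' @export
explained_fraction <- function(runs) {
  stats_tab <- if (inherits(runs, "methyl_runs")) runs$run_stats else runs
  if (nrow(stats_tab) == 0L) return(NA_real_)
  ok <- stats_tab$n_measured_noesy > 0
  if (!any(ok)) return(NA_real_)
  mean(stats_tab$n_mapped_noesy[ok] / stats_tab$n_measured_noesy[ok])
}

#' Write consensus reports
#'
#' Writes `consol.prot` (consensus shift list; unassigned atoms as
#' 999.000), `consol.tab` (one row per methyl with shifts, agreement
#' percentage, the literal `strong` label where applicable, NOE support
#' and alternatives), `flya.txt` (expected / measured / assigned peak
#' counts per peak list) and, when an evaluation is supplied,
#' `evaluation.tsv`.
#'
#' @param consensus a `methyl_consensus` table.
#' @param dir output directory (created if missing).
#' @param runs optional `methyl_runs` object used for the peak-count
#'   statistics in `flya.txt`.
#' @param evaluation optional `methyl_evaluation`.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(consensus, dir, runs = NULL, evaluation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # consol.prot: carbon and proton pseudo-atom entries
  err_of <- function(frac) round((1 - frac) * 0.01, 3)
  prot <- tibble::tibble(
    id = seq_len(2L * nrow(consensus)),
    shift = as.vector(rbind(consensus$shift_c, consensus$shift_h)),
    error = 0,
    atom = as.vector(rbind(consensus$carbon, consensus$proton_name)),
    resno = rep(consensus$resno, each = 2L)
  )
  write_shifts(prot, file.path(dir, "consol.prot"))

  tab_lines <- vapply(seq_len(nrow(consensus)), function(i) {
    alts <- consensus$alternatives[[i]]
    alt_str <- if (nrow(alts)) {
      paste(sprintf("%.3f/%.3f(%d%%)", alts$shift_c, alts$shift_h,
                    round(100 * alts$fraction)), collapse = ",")
    } else "-"
    sprintf("%4d %-4s %-4s %8.3f %8.3f %5.1f %-6s %4.1f %s",
            consensus$resno[i], consensus$restype[i], consensus$carbon[i],
            ifelse(is.na(consensus$shift_c[i]), 999, consensus$shift_c[i]),
            ifelse(is.na(consensus$shift_h[i]), 999, consensus$shift_h[i]),
            100 * consensus$fraction[i],
            consensus$strength[i], consensus$noe_support[i], alt_str)
  }, "")
  writeLines(c(
    "# residue type methyl 13C 1H agree% strength NOEs alternatives",
    tab_lines
  ), file.path(dir, "consol.tab"))

  if (!is.null(runs)) {
    mid <- runs$expected_counts
    mid <- mid[mid$d_cut == sort(unique(mid$d_cut))[ceiling(length(unique(mid$d_cut)) / 2)], ]
    assigned <- runs$run_shifts |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop")
    lines <- c(
      "peaklist expected measured assigned",
      sprintf("%s %d %d %d", mid$experiment, mid$n_expected,
              vapply(mid$experiment, function(e) {
                i <- match(e, runs$measured_counts$list_name)
                if (is.na(i)) {
                  sum(runs$measured_counts$n_measured[
                    startsWith(runs$measured_counts$list_name, e)])
                } else {
                  runs$measured_counts$n_measured[i]
                }
              }, 0L),
              vapply(mid$experiment, function(e) {
                if (e == "C13HSQC") {
                  as.integer(round(stats::median(assigned$n)))
                } else {
                  as.integer(round(stats::median(runs$run_stats$n_mapped_noesy)))
                }
              }, 0L))
    )
    writeLines(lines, file.path(dir, "flya.txt"))
  }

  if (!is.null(evaluation)) {
    utils::write.table(
      evaluation$detail[, c("methyl_id", "resno", "restype", "carbon",
                            "shift_c", "shift_h", "fraction", "strength",
                            "status")],
      file.path(dir, "evaluation.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}
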