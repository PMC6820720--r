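#' Chemical-shift matching tolerances
#'
#' Defaults follow common methyl-TROSY practice: 0.4 ppm for \eqn{^{13}}C
#' and 0.04 ppm for \eqn{^1}H. The same tolerances are used for peak-list
#' preparation, assignment optimization, consensus consolidation and
#' evaluation.
#'
#' @param tol_c 13C tolerance (ppm).
#' @param tol_h 1H tolerance (ppm).
#' @return a `tolerances` list.
#' @export
tolerances <- function(tol_c = 0.4, tol_h = 0.04) {
  stopifnot(tol_c > 0, tol_h > 0)
  structure(list(tol_c = tol_c, tol_h = tol_h), class = "tolerances")
}

tol_for <- function(tol, nuclei) {
  ifelse(nuclei == "H", tol$tol_h, tol$tol_c)
}

# index pairs (w_H, w_C) of the donor (a) and acceptor (b) side of a NOESY
# peak list; NA where a side lacks that nucleus (3D experiments)
noesy_sides <- function(x) {
  nuc <- pl_nuclei(x)
  exp <- pl_experiment(x)
  if (!is.na(exp)) {
    def <- experiment_def(exp)
    side <- def$side; nuclei <- def$nuclei
  } else if (length(nuc) == 4L) {
    side <- c("a", "a", "b", "b"); nuclei <- nuc
  } else {
    stop("cannot infer NOESY side structure for list ", pl_name(x))
  }
  pick <- function(s, n) {
    i <- which(side == s & nuclei == n)
    if (length(i)) i[1] else NA_integer_
  }
  list(
    a = c(H = pick("a", "H"), C = pick("a", "C")),
    b = c(H = pick("b", "H"), C = pick("b", "C"))
  )
}

#' Filter a NOESY peak list for reciprocity and signal-to-noise
#'
#' Keeps only peaks whose signal-to-noise ratio is at least `min_sn` (peaks
#' without an S/N value pass) and whose donor/acceptor-transposed
#' coordinates match another S/N-passing peak within the tolerances.
#' Reciprocity is evaluated after the S/N cut, so a partner removed by S/N
#' also removes its mate. For 3D lists the transposition swaps the two
#' dimensions of the shared nucleus; the remaining dimension is
#' unconstrained by the partner.
#'
#' The filter is idempotent and symmetric under relabeling of the donor and
#' acceptor dimensions.
#'
#' @param noesy a NOESY [peaklist()] (3 or 4 dimensions).
#' @param min_sn signal-to-noise threshold (default 2).
#' @param tol [tolerances()].
#' @return the filtered peak list.
#' @export
filter_noesy <- function(noesy, min_sn = 2, tol = tolerances()) {
  nd <- pl_ndim(noesy)
  if (nd < 3L) stop("not a NOESY peak list: ", pl_name(noesy))
  if (nrow(noesy) == 0L) return(noesy)
  nuc <- pl_nuclei(noesy)
  w <- as.matrix(noesy[, paste0("w", seq_len(nd))])
  pass_sn <- is.na(noesy$sn) | noesy$sn >= min_sn

  # transposed coordinate pattern: 4D (HCCH) -> reverse; 3D -> swap the
  # duplicated nucleus's two dimensions, drop the unpaired dimension
  if (nd == 4L) {
    perm <- 4:1
    cmp_dims <- 1:4
  } else {
    dup_nuc <- names(which(table(nuc) == 2L))
    di <- which(nuc == dup_nuc)
    perm <- seq_len(3L)
    perm[di] <- rev(di)
    cmp_dims <- di
  }
  tols <- tol_for(tol, nuc)
  cand <- which(pass_sn)
  reciprocal <- rep(FALSE, nrow(noesy))
  for (i in cand) {
    target <- w[i, perm]
    ok <- rep(TRUE, length(cand))
    for (d in cmp_dims) {
      ok <- ok & abs(w[cand, d] - target[d]) <= tols[d]
    }
    reciprocal[i] <- any(ok)
  }
  pl_rewrap(noesy, noesy[pass_sn & reciprocal, , drop = FALSE])
}

canonical_label <- function(x) {
  vapply(x, function(l) {
    paste(sort(unique(strsplit(l, "")[[1]])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

pair_key <- function(la, lb) {
  a <- pmin(la, lb); b <- pmax(la, lb)
  paste0(a, b)
}

# best HMQC match for coordinate pairs; returns index (0 = none in
# tolerance) using the box metric max(|dH|/tol_h, |dC|/tol_c); ties broken
# by lower HMQC peak id
match_hmqc <- function(h_coord, c_coord, hmqc, tol) {
  n <- length(h_coord)
  ord <- order(hmqc$id)
  hh <- hmqc$w1[ord]; cc <- hmqc$w2[ord]
  idx <- integer(n)
  for (i in seq_len(n)) {
    dh <- if (is.na(h_coord[i])) 0 else abs(hh - h_coord[i]) / tol$tol_h
    dc <- if (is.na(c_coord[i])) 0 else abs(cc - c_coord[i]) / tol$tol_c
    d <- pmax(dh, dc)
    j <- which.min(d) # first minimum = lowest id after ordering
    idx[i] <- if (d[j] <= 1) ord[j] else 0L
  }
  idx
}

#' Attribute NOESY peaks to residue-type pairs
#'
#' Matches each side of every NOESY peak to the HMQC peak with the closest
#' chemical shifts (box metric, tolerance-scaled; ties broken by lower HMQC
#' peak id) and splits the list by the unordered residue-type pair of the
#' matched HMQC peaks. Peaks whose best match exceeds the tolerance on
#' either side go to an untyped catch-all list that is matched against all
#' types downstream.
#'
#' @param noesy NOESY [peaklist()].
#' @param hmqc 2D HMQC [peaklist()].
#' @param typing tibble `(id, type)` labeling every HMQC peak, e.g. from
#'   [bmrb_best_guess_typing()]; types are letter sets such as `"A"`,
#'   `"I"`, `"LV"`.
#' @param tol [tolerances()].
#' @return named list of peak lists keyed by type pair (e.g. `"LV"`,
#'   `"LL"`), plus `"untyped"` when present. Each peak carries its side
#'   labels (`type_a`, `type_b`) and matched HMQC ids (`hmqc_a`, `hmqc_b`).
#' @export
attribute_noesy_types <- function(noesy, hmqc, typing, tol = tolerances()) {
  if (nrow(hmqc) == 0L) stop("empty HMQC peak list")
  typing <- tibble::as_tibble(typing)
  stopifnot(all(c("id", "type") %in% names(typing)))
  if (!all(hmqc$id %in% typing$id)) stop("typing must cover every HMQC peak")
  labels <- canonical_label(typing$type[match(hmqc$id, typing$id)])
  sides <- noesy_sides(noesy)
  get_coord <- function(dim_idx) {
    if (is.na(dim_idx)) rep(NA_real_, nrow(noesy)) else noesy[[paste0("w", dim_idx)]]
  }
  ia <- match_hmqc(get_coord(sides$a["H"]), get_coord(sides$a["C"]), hmqc, tol)
  ib <- match_hmqc(get_coord(sides$b["H"]), get_coord(sides$b["C"]), hmqc, tol)
  typed <- ia > 0L & ib > 0L
  la <- ifelse(typed, labels[pmax(ia, 1L)], "?")
  lb <- ifelse(typed, labels[pmax(ib, 1L)], "?")
  out_tab <- noesy
  out_tab$type_a <- la
  out_tab$type_b <- lb
  out_tab$hmqc_a <- ifelse(typed, hmqc$id[pmax(ia, 1L)], NA_integer_)
  out_tab$hmqc_b <- ifelse(typed, hmqc$id[pmax(ib, 1L)], NA_integer_)
  key <- ifelse(typed, pair_key(la, lb), "untyped")
  base <- pl_experiment(noesy) %||% "NOESY"
  if (is.na(base)) base <- "NOESY"
  out <- lapply(split(seq_len(nrow(noesy)), key), function(i) {
    k <- key[i[1]]
    nm <- if (k == "untyped") paste0(base, "_untyped") else paste0(base, "_", k)
    pl_rewrap(noesy, out_tab[i, , drop = FALSE], name = nm)
  })
  out[order(names(out))]
}

#' Split an HMQC peak list by residue type
#'
#' Partitions the peaks by their typing label. Labels spanning several
#' candidate lists (e.g. `"ALV"`) duplicate the peak into each list with a
#' `shared_id` flag so that downstream consumers can use it at most once;
#' Leu and Val always share a joint `"LV"` list.
#'
#' @inheritParams attribute_noesy_types
#' @return named list of peak lists keyed by type label.
#' @export
split_hmqc_by_type <- function(hmqc, typing) {
  typing <- tibble::as_tibble(typing)
  labels <- canonical_label(typing$type[match(hmqc$id, typing$id)])
  candidate_lists <- function(label) {
    letters_ <- strsplit(label, "")[[1]]
    out <- character()
    if ("A" %in% letters_) out <- c(out, "A")
    if ("I" %in% letters_) out <- c(out, "I")
    if (any(c("L", "V") %in% letters_)) out <- c(out, "LV")
    if ("M" %in% letters_) out <- c(out, "M")
    if ("T" %in% letters_) out <- c(out, "T")
    out
  }
  rows <- list()
  for (i in seq_len(nrow(hmqc))) {
    lists <- candidate_lists(labels[i])
    for (l in lists) {
      r <- hmqc[i, , drop = FALSE]
      r$shared_id <- if (length(lists) > 1L) hmqc$id[i] else NA_integer_
      r$list_key <- l
      rows[[length(rows) + 1L]] <- r
    }
  }
  tab <- dplyr::bind_rows(rows)
  base <- pl_experiment(hmqc)
  if (is.na(base)) base <- "C13HSQC"
  lapply(split(tab, tab$list_key), function(part) {
    key <- part$list_key[1]
    part$list_key <- NULL
    pl_rewrap(hmqc, part, name = paste0(base, "_", key))
  })
}

#' Reference methyl chemical-shift statistics
#'
#' Packaged per-residue-type means and standard deviations of methyl
#' \eqn{^1}H and \eqn{^{13}}C chemical shifts, approximating published
#' database ranges. These are synthetic package constants used for
#' best-guess residue typing and for the simulator; no database is queried.
#'
#' @return tibble with columns `letter`, `restype`, `carbon`, `c_mean`,
#'   `c_sd`, `h_mean`, `h_sd`.
#' @export
methyl_shift_stats <- function() {
  tibble::tribble(
    ~letter, ~restype, ~carbon, ~c_mean, ~c_sd, ~h_mean, ~h_sd,
    "A", "ALA", "CB",  18.9, 1.8, 1.35, 0.26,
    "I", "ILE", "CD1", 13.4, 1.7, 0.69, 0.29,
    "I", "ILE", "CG2", 17.4, 1.4, 0.79, 0.27,
    "L", "LEU", "CD1", 24.6, 1.6, 0.76, 0.29,
    "L", "LEU", "CD2", 24.1, 1.7, 0.73, 0.29,
    "V", "VAL", "CG1", 21.5, 1.4, 0.83, 0.29,
    "V", "VAL", "CG2", 21.2, 1.5, 0.80, 0.29,
    "M", "MET", "CE",  17.1, 1.5, 1.89, 0.40,
    "T", "THR", "CG2", 21.6, 1.1, 1.16, 0.22
  )
}

# per-letter rectangular regions (mean +- sd over the letter's methyls)
typing_regions <- function(stats, letters_use) {
  stats |>
    dplyr::filter(.data$letter %in% letters_use) |>
    dplyr::group_by(.data$letter) |>
    dplyr::summarise(
      c_lo = min(.data$c_mean - .data$c_sd), c_hi = max(.data$c_mean + .data$c_sd),
      h_lo = min(.data$h_mean - .data$h_sd), h_hi = max(.data$h_mean + .data$h_sd),
      c_mid = mean(.data$c_mean), h_mid = mean(.data$h_mean),
      c_scale = mean(.data$c_sd), h_scale = mean(.data$h_sd),
      .groups = "drop"
    )
}

#' Best-guess residue typing of HMQC peaks from shift statistics
#'
#' Classifies each HMQC peak by the rectangular region (mean +- one
#' standard deviation of \eqn{^1}H and \eqn{^{13}}C shifts) of each methyl
#' residue type. Leu and Val are always merged into a joint `"LV"` type.
#' Ile delta-1 peaks are usually resolved by their upfield \eqn{^{13}}C
#' shifts. Peaks in the Ala / Leu-Val overlap region are resolved by
#' strategy: `"max-ala"` attributes overlap peaks to Ala (nearest to the
#' Ala mean first) until the expected Ala count from the sequence is
#' reached; `"ambiguous"` labels them `"ALV"`. Peaks outside all regions
#' are labelled with the nearest region and a warning is emitted.
#'
#' @param hmqc 2D HMQC [peaklist()].
#' @param stats shift statistics table ([methyl_shift_stats()] format).
#' @param sequence_counts named integer vector of expected methyl counts
#'   per letter (e.g. `c(A = 10, I = 5, L = 12, V = 8)`); its names also
#'   restrict which types are considered.
#' @param strategy overlap resolution strategy.
#' @return typing tibble `(id, type)`.
#' @export
bmrb_best_guess_typing <- function(hmqc, stats = methyl_shift_stats(),
                                   sequence_counts,
                                   strategy = c("ambiguous", "max-ala")) {
  strategy <- match.arg(strategy)
  letters_use <- intersect(c("A", "I", "L", "V", "M", "T"),
                           names(sequence_counts))
  reg <- typing_regions(stats, letters_use)
  # merge L and V into one joint region
  if (any(reg$letter %in% c("L", "V"))) {
    lv <- reg[reg$letter %in% c("L", "V"), , drop = FALSE]
    lv_row <- tibble::tibble(
      letter = "LV",
      c_lo = min(lv$c_lo), c_hi = max(lv$c_hi),
      h_lo = min(lv$h_lo), h_hi = max(lv$h_hi),
      c_mid = mean(lv$c_mid), h_mid = mean(lv$h_mid),
      c_scale = mean(lv$c_scale), h_scale = mean(lv$h_scale)
    )
    reg <- dplyr::bind_rows(reg[!reg$letter %in% c("L", "V"), ], lv_row)
  }
  h <- hmqc$w1; cc <- hmqc$w2
  inside <- sapply(seq_len(nrow(reg)), function(r) {
    cc >= reg$c_lo[r] & cc <= reg$c_hi[r] & h >= reg$h_lo[r] & h <= reg$h_hi[r]
  })
  inside <- matrix(inside, nrow = nrow(hmqc))
  dist_to <- function(r) {
    pmax(abs(cc - reg$c_mid[r]) / reg$c_scale[r],
         abs(h - reg$h_mid[r]) / reg$h_scale[r])
  }
  type <- character(nrow(hmqc))
  n_in <- rowSums(inside)
  for (i in seq_len(nrow(hmqc))) {
    hits <- reg$letter[inside[i, ]]
    if (length(hits) == 1L) {
      type[i] <- hits
    } else if (length(hits) == 0L) {
      d <- vapply(seq_len(nrow(reg)), function(r) dist_to(r)[i], 0)
      type[i] <- reg$letter[which.min(d)]
    } else {
      type[i] <- paste(sort(hits), collapse = "")
    }
  }
  if (any(n_in == 0L)) {
    warning(sum(n_in == 0L),
            " HMQC peak(s) outside all typing regions; nearest region used")
  }
  overlap <- type == "ALV"
  if (strategy == "max-ala" && any(overlap)) {
    n_ala_target <- sequence_counts[["A"]] %||% 0L
    n_ala_fixed <- sum(type == "A")
    n_take <- max(0L, min(sum(overlap), n_ala_target - n_ala_fixed))
    if (n_take > 0L) {
      ra <- which(reg$letter == "A")
      d_ala <- dist_to(ra)
      ord <- order(d_ala)
      take <- head(ord[ord %in% which(overlap)], n_take)
      type[take] <- "A"
    }
    type[type == "ALV"] <- "LV"
  }
  tibble::tibble(id = hmqc$id, type = canonical_label(type))
}
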