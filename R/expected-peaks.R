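#' Library of supported NMR experiment types
#'
#' Each entry defines the ordered spectral dimensions (nuclei and which of
#' the two methyls of a pair they belong to), the magnetization transfer
#' class, and the default observation probability of an expected peak.
#' NOESY-type experiments contain exactly one through-space (NOE) transfer;
#' the HMQC and the short-mixing-time geminal correlation (HCcCH) are
#' through-bond and carry probability 1.
#'
#' Dimension conventions: `CCNOESY` (4D) H_a, C_a, C_b, H_b; `CCNOESY3D`
#' (3D CCH) C_a, C_b, H_b; `C13NOESY` (3D HCH) H_a, C_b, H_b; `HCcCH` (4D)
#' like `CCNOESY` but restricted to geminal Leu/Val pairs; `C13HSQC` (2D
#' HMQC) H, C of a single methyl.
#'
#' @return tibble with columns `name`, `ndim`, `nuclei` (list), `side`
#'   (list; "a"/"b" per dimension), `transfer`, `probability`.
#' @export
experiment_library <- function() {
  tibble::tribble(
    ~name, ~ndim, ~nuclei, ~side, ~transfer, ~probability,
    "C13HSQC",   2L, list(c("H", "C")),           list(c("a", "a")),           "bond", 1,
    "CCNOESY",   4L, list(c("H", "C", "C", "H")), list(c("a", "a", "b", "b")), "noe",  0.1,
    "CCNOESY3D", 3L, list(c("C", "C", "H")),      list(c("a", "b", "b")),      "noe",  0.1,
    "C13NOESY",  3L, list(c("H", "C", "H")),      list(c("a", "b", "b")),      "noe",  0.1,
    "HCcCH",     4L, list(c("H", "C", "C", "H")), list(c("a", "a", "b", "b")), "bond", 1
  )
}

experiment_def <- function(name) {
  lib <- experiment_library()
  i <- match(name, lib$name)
  if (is.na(i)) stop("unknown experiment type: ", name)
  unwrap <- function(x) if (is.list(x)) x[[1L]] else x
  list(name = lib$name[i], ndim = lib$ndim[i],
       nuclei = unwrap(lib$nuclei[[i]]), side = unwrap(lib$side[[i]]),
       transfer = lib$transfer[i], probability = lib$probability[i])
}

#' Configuration for expected-peak generation
#'
#' @param d_cut NOE effective-distance cutoff in Angstrom. The assignment
#'   protocol uses the triplet `d_cut - 0.5`, `d_cut`, `d_cut + 0.5`.
#' @param p_noe observation probability attached to expected NOESY peaks
#'   (through-bond expected peaks always carry probability 1).
#' @param include_geminal_noes generate NOESY expected peaks between the
#'   two methyls of a Leu/Val pair (they are real short contacts)?
#' @param include_diagonal generate diagonal (self) NOESY peaks?
#' @return a `generation_config` list.
#' @export
generation_config <- function(d_cut = 5, p_noe = 0.1,
                              include_geminal_noes = TRUE,
                              include_diagonal = FALSE) {
  stopifnot(d_cut > 0, p_noe > 0, p_noe <= 1)
  structure(
    list(d_cut = d_cut, cutoffs = d_cut + c(-0.5, 0, 0.5), p_noe = p_noe,
         include_geminal_noes = include_geminal_noes,
         include_diagonal = include_diagonal),
    class = "generation_config"
  )
}

empty_expected <- function() {
  tibble::tibble(
    experiment = character(), id_a = character(), id_b = character(),
    class_a = character(), class_b = character(),
    prob = numeric(), d_eff = numeric()
  )
}

#' Expected 2D HMQC peaks
#'
#' One expected (1H, 13C) peak per labeled methyl group, probability 1.
#'
#' @param methyls methyl table from [extract_methyl_groups()].
#' @return expected-peak tibble.
#' @export
generate_expected_hmqc <- function(methyls) {
  if (nrow(methyls) == 0L) return(empty_expected())
  tibble::tibble(
    experiment = "C13HSQC", id_a = methyls$id, id_b = NA_character_,
    class_a = methyls$letter, class_b = NA_character_,
    prob = 1, d_eff = NA_real_
  )
}

#' Expected methyl-methyl NOESY peaks
#'
#' Generates one directional expected peak per ordered methyl pair whose
#' effective distance ([noe_effective_distance()]) does not exceed the
#' cutoff. The expected peak sets are nested in `d_cut`: raising the cutoff
#' only adds peaks.
#'
#' @param methyls methyl table.
#' @param config a [generation_config()].
#' @param experiment NOESY experiment name (see [experiment_library()]).
#' @param d_cut cutoff in Angstrom; defaults to `config$d_cut`.
#' @param distances optional precomputed [methyl_distance_table()] to avoid
#'   recomputing distances across the cutoff triplet.
#' @return expected-peak tibble with `d_eff` and the residue-type pair.
#' @export
generate_expected_noesy <- function(methyls, config = generation_config(),
                                    experiment = "CCNOESY",
                                    d_cut = config$d_cut,
                                    distances = NULL) {
  def <- experiment_def(experiment)
  if (def$transfer != "noe") stop(experiment, " is not a NOESY experiment")
  if (nrow(methyls) < 2L) return(empty_expected())
  if (is.null(distances)) distances <- methyl_distance_table(methyls)
  keep <- distances$d_eff <= d_cut
  if (!config$include_geminal_noes) keep <- keep & !distances$geminal
  pairs <- distances[keep, , drop = FALSE]
  cls <- setNames(methyls$letter, methyls$id)
  fwd <- tibble::tibble(
    experiment = experiment, id_a = pairs$id_a, id_b = pairs$id_b,
    class_a = unname(cls[pairs$id_a]), class_b = unname(cls[pairs$id_b]),
    prob = config$p_noe, d_eff = pairs$d_eff
  )
  rev <- fwd
  rev$id_a <- fwd$id_b; rev$id_b <- fwd$id_a
  rev$class_a <- fwd$class_b; rev$class_b <- fwd$class_a
  out <- dplyr::bind_rows(fwd, rev)
  if (config$include_diagonal) {
    diag <- tibble::tibble(
      experiment = experiment, id_a = methyls$id, id_b = methyls$id,
      class_a = methyls$letter, class_b = methyls$letter,
      prob = config$p_noe, d_eff = 0
    )
    out <- dplyr::bind_rows(out, diag)
  }
  out
}

#' Expected geminal-pair correlation peaks
#'
#' One expected peak per ordered geminal pair (Leu delta1/delta2, Val
#' gamma1/gamma2), probability 1, for the short-mixing-time HCcCH
#' experiment that correlates the two methyls of a doubly labeled Leu/Val
#' side chain. Pairs in which either methyl is excluded by the labeling
#' scheme produce no peak.
#'
#' @param methyls methyl table.
#' @return expected-peak tibble.
#' @export
generate_expected_geminal <- function(methyls) {
  if (nrow(methyls) == 0L) return(empty_expected())
  paired <- methyls[!is.na(methyls$geminal_id) &
                      methyls$geminal_id %in% methyls$id, , drop = FALSE]
  if (nrow(paired) == 0L) return(empty_expected())
  cls <- setNames(methyls$letter, methyls$id)
  tibble::tibble(
    experiment = "HCcCH", id_a = paired$id, id_b = paired$geminal_id,
    class_a = unname(cls[paired$id]), class_b = unname(cls[paired$geminal_id]),
    prob = 1, d_eff = NA_real_
  )
}
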