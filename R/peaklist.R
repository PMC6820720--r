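#' Construct a peak list
#'
#' A peak list is a tibble of peaks plus metadata: the per-dimension nuclei
#' (`"H"`/`"C"`), a provenance name (e.g. `"CCNOESY_LV"`), and the
#' experiment type it belongs to. Core columns are `id`, the ppm
#' coordinates `w1` ... `wN`, `volume`, `sn` (signal-to-noise), and the
#' assignment slots `a1` ... `aN` (atom ids, 0 = unassigned). Additional
#' columns (residue-type tags, matched HMQC ids) are preserved.
#'
#' @param peaks data frame of peaks; missing core columns are filled in.
#' @param nuclei character vector of per-dimension nuclei, e.g.
#'   `c("H","C","C","H")`.
#' @param name provenance label.
#' @param experiment experiment type from [experiment_library()] or `NA`.
#' @return a `peaklist` tibble.
#' @export
peaklist <- function(peaks, nuclei, name = NA_character_,
                     experiment = NA_character_) {
  nd <- length(nuclei)
  stopifnot(nd %in% 2:4, all(nuclei %in% c("H", "C")))
  peaks <- tibble::as_tibble(peaks)
  wcols <- paste0("w", seq_len(nd))
  acols <- paste0("a", seq_len(nd))
  missing_w <- setdiff(wcols, names(peaks))
  if (length(missing_w)) {
    stop("peak table lacks coordinate column(s): ",
         paste(missing_w, collapse = ", "))
  }
  if (!"id" %in% names(peaks)) peaks$id <- seq_len(nrow(peaks))
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids in list ", name)
  if (!"volume" %in% names(peaks)) peaks$volume <- rep(NA_real_, nrow(peaks))
  if (!"sn" %in% names(peaks)) peaks$sn <- rep(NA_real_, nrow(peaks))
  for (a in acols) {
    if (!a %in% names(peaks)) peaks[[a]] <- rep(0L, nrow(peaks))
  }
  extra <- setdiff(names(peaks), c("id", wcols, "volume", "sn", acols))
  peaks <- peaks[, c("id", wcols, "volume", "sn", acols, extra)]
  structure(
    peaks,
    nuclei = nuclei, name = name, experiment = experiment,
    class = c("peaklist", class(tibble::tibble()))
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("# peaklist '%s' (%s): %dD [%s], %d peaks\n",
              attr(x, "name") %||% "?", attr(x, "experiment") %||% "?",
              length(attr(x, "nuclei")), paste(attr(x, "nuclei"), collapse = ""),
              nrow(x)))
  NextMethod()
}

pl_ndim <- function(x) length(attr(x, "nuclei"))
pl_nuclei <- function(x) attr(x, "nuclei")
pl_experiment <- function(x) attr(x, "experiment")
pl_name <- function(x) attr(x, "name")

# rebuild a peaklist from a (possibly filtered) tibble, keeping metadata
pl_rewrap <- function(template, peaks, name = pl_name(template)) {
  peaklist(peaks, nuclei = pl_nuclei(template), name = name,
           experiment = pl_experiment(template))
}
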