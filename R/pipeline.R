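#' Run the full assignment protocol
#'
#' End-to-end orchestration: peak-list preparation (optional reciprocity +
#' signal-to-noise filtering, residue-type attribution of the NOESY
#' peaks), three series of independent optimization runs at the cutoff
#' triplet `d_cut - 0.5, d_cut, d_cut + 0.5` (or one series in single
#' mode), consolidation into consensus assignments, and optional
#' evaluation against a reference shift list. The result is a pure
#' function of the inputs, the configuration and the seed.
#'
#' @param dataset a `methyl_simulation` from [simulate_methyl_dataset()],
#'   or `NULL` when file inputs are given.
#' @param structure_file,sequence_file,labeling,hmqc_file,noesy_file,noesy_format,geminal_file
#'   file-based inputs: PDB structure, sequence file, labeling scheme, and
#'   peak lists (XEASY or Sparky).
#' @param typing HMQC residue typing: a tibble `(id, type)`, the string
#'   `"bmrb-ambig"` or `"bmrb-maxa"` for best-guess typing from shift
#'   statistics, or `NULL` for untyped.
#' @param reference optional reference shift table ([read_shifts()]
#'   schema) for evaluation; defaults to the simulation ground truth when
#'   a dataset is supplied.
#' @param filter apply [filter_noesy()] to the NOESY list?
#' @param min_sn signal-to-noise threshold for the filter.
#' @param config [optimizer_config()].
#' @param gen_config [generation_config()].
#' @param tol [tolerances()].
#' @param mode `"triplet"` or `"single"` cutoff mode.
#' @param threshold strong-classification threshold.
#' @param k_alternatives alternatives reported per methyl.
#' @param out optional output directory for `consol.prot`, `consol.tab`,
#'   `flya.txt`, `evaluation.tsv` and a log file.
#' @return a `methyl_pipeline` object; see [tidy()] and [glance()].
#' @export
run_methyl_pipeline <- function(dataset = NULL,
                                structure_file = NULL, sequence_file = NULL,
                                labeling = "AILV",
                                hmqc_file = NULL, noesy_file = NULL,
                                noesy_format = "xeasy", geminal_file = NULL,
                                typing = NULL, reference = NULL,
                                filter = TRUE, min_sn = 2,
                                config = optimizer_config(),
                                gen_config = generation_config(),
                                tol = tolerances(),
                                mode = c("triplet", "single"),
                                threshold = 0.8, k_alternatives = 3,
                                out = NULL) {
  mode <- match.arg(mode)
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "methyl_simulation"))
    methyls <- dataset$methyls
    hmqc <- dataset$hmqc
    noesy <- dataset$noesy
    geminal <- dataset$geminal
    typing <- typing %||% dataset$typing
    reference <- reference %||% dataset$reference
  } else {
    if (is.null(structure_file) || is.null(hmqc_file) || is.null(noesy_file)) {
      stop("either a dataset or structure/hmqc/noesy files must be given")
    }
    structure <- read_structure(structure_file)
    seq_tab <- if (!is.null(sequence_file)) read_sequence(sequence_file)
    methyls <- extract_methyl_groups(structure, seq_tab, labeling)
    hmqc <- read_peaklist(hmqc_file, noesy_format, nuclei = c("H", "C"),
                          experiment = "C13HSQC")
    noesy <- read_peaklist(noesy_file, noesy_format,
                           experiment = gen_config$experiment %||% "CCNOESY")
    geminal <- if (!is.null(geminal_file)) {
      read_peaklist(geminal_file, noesy_format,
                    nuclei = c("H", "C", "C", "H"), experiment = "HCcCH")
    }
  }
  if (nrow(methyls) == 0L) stop("no labeled methyl groups; nothing to assign")
  if (nrow(hmqc) == 0L) stop("empty HMQC peak list")

  if (is.character(typing)) {
    strategy <- switch(typing,
      "bmrb-ambig" = "ambiguous", "bmrb-maxa" = "max-ala",
      stop("unknown typing mode: ", typing))
    counts <- table(methyls$letter)
    typing <- bmrb_best_guess_typing(
      hmqc, sequence_counts = setNames(as.integer(counts), names(counts)),
      strategy = strategy)
  }

  if (filter) noesy <- filter_noesy(noesy, min_sn = min_sn, tol = tol)
  measured <- if (!is.null(typing)) {
    attribute_noesy_types(noesy, hmqc, typing, tol)
  } else {
    list(noesy)
  }
  if (!is.null(geminal)) measured <- c(measured, list(geminal = geminal))

  runs <- assign_runs(methyls, hmqc, typing, measured, config = config,
                      gen_config = gen_config, tol = tol, mode = mode)
  consensus <- consolidate_runs(runs, threshold = threshold,
                                k_alternatives = k_alternatives)
  evaluation <- if (!is.null(reference)) {
    evaluate_vs_reference(consensus, reference, tol)
  }
  explained <- explained_fraction(runs)

  result <- structure(
    list(consensus = consensus, evaluation = evaluation, runs = runs,
         explained = explained, config = config, gen_config = gen_config,
         tol = tol, mode = mode, threshold = threshold),
    class = "methyl_pipeline"
  )

  if (!is.null(out)) {
    write_reports(consensus, out, runs = runs, evaluation = evaluation)
    log_lines <- c(
      sprintf("methylassign pipeline log"),
      sprintf("mode: %s  d_cut: %s", mode,
              paste(if (mode == "triplet") gen_config$cutoffs else
                gen_config$d_cut, collapse = "/")),
      sprintf("p_noe: %g  tol: %g/%g ppm (C/H)", gen_config$p_noe,
              tol$tol_c, tol$tol_h),
      sprintf("runs per cutoff: %d  population: %d  iterations: %d",
              config$runs, config$population, config$iterations),
      sprintf("base seed: %d (run i uses seed base + i)", config$seed),
      sprintf("threshold: %g  methyls: %d  strong: %d", threshold,
              nrow(methyls), sum(consensus$strength == "strong"))
    )
    writeLines(log_lines, file.path(out, "pipeline.log"))
  }
  result
}

#' @export
print.methyl_pipeline <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<methyl_pipeline> %d methyls | %d runs | strong %d (correct %d, erroneous %d) | explained NOEs %.1f%%\n",
    g$n_methyls, g$n_runs, g$n_strong,
    g$n_correct %||% NA, g$n_erroneous %||% NA, 100 * g$explained))
  invisible(x)
}

#' @rdname run_methyl_pipeline
#' @param x a `methyl_pipeline`.
#' @param ... unused.
#' @export
tidy.methyl_pipeline <- function(x, ...) {
  out <- tibble::as_tibble(x$consensus)
  if (!is.null(x$evaluation)) {
    out$status <- x$evaluation$detail$status[
      match(out$methyl_id, x$evaluation$detail$methyl_id)]
  }
  out
}

#' @rdname run_methyl_pipeline
#' @export
glance.methyl_pipeline <- function(x, ...) {
  cons <- x$consensus
  ev <- x$evaluation
  tibble::tibble(
    n_methyls = nrow(cons),
    n_runs = x$runs$n_runs,
    n_strong = sum(cons$strength == "strong"),
    n_correct = if (!is.null(ev)) ev$counts$correct else NA_integer_,
    n_erroneous = if (!is.null(ev)) ev$counts$erroneous else NA_integer_,
    n_no_reference = if (!is.null(ev)) ev$counts$no_reference else NA_integer_,
    explained = x$explained,
    mean_score = mean(x$runs$run_stats$score)
  )
}
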