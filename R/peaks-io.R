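#' Read a peak list file
#'
#' Reads XEASY `.peaks` files (the native dialect written by
#' [write_peaklist()]) and Sparky `.list` exports. Sparky assignment labels
#' are parsed but peaks are treated as unassigned unless `keep_assignments`
#' is set (evaluation mode).
#'
#' @param path file path.
#' @param format `"xeasy"` or `"sparky"`.
#' @param nuclei per-dimension nuclei; for XEASY files with `#INAME`
#'   headers it is inferred, otherwise defaults to the methyl conventions
#'   for the given dimensionality (2D H/C, 3D C/C/H, 4D H/C/C/H).
#' @param experiment experiment type label to attach.
#' @param keep_assignments keep assignment ids found in the file?
#' @return a [peaklist()].
#' @export
read_peaklist <- function(path, format = c("xeasy", "sparky"), nuclei = NULL,
                          experiment = NA_character_,
                          keep_assignments = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  switch(format,
    xeasy = read_xeasy(lines, path, nuclei, experiment, keep_assignments),
    sparky = read_sparky(lines, path, nuclei, experiment)
  )
}

default_nuclei <- function(ndim) {
  switch(as.character(ndim),
    "2" = c("H", "C"),
    "3" = c("C", "C", "H"),
    "4" = c("H", "C", "C", "H"),
    stop("unsupported dimensionality: ", ndim)
  )
}

read_xeasy <- function(lines, path, nuclei, experiment, keep_assignments) {
  hdr <- grep("^#\\s*Number of dimensions", lines, value = TRUE)
  if (length(hdr) == 0L) {
    stop("not an XEASY peak list (missing dimensions header): ", path)
  }
  ndim <- as.integer(sub(".*Number of dimensions\\s+", "", hdr[1]))
  iname <- grep("^#INAME", lines, value = TRUE)
  if (is.null(nuclei)) {
    if (length(iname) == ndim) {
      nm <- vapply(strsplit(trimws(iname), "\\s+"), function(f) f[3], "")
      nuclei <- ifelse(grepl("^H", toupper(nm)), "H", "C")
    } else {
      nuclei <- default_nuclei(ndim)
    }
  }
  if (length(nuclei) != ndim) stop("dimension mismatch in ", path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  n_fields <- 1L + ndim + 6L + ndim
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < n_fields) {
      stop("malformed XEASY line ", which(lines == body[i])[1], " in ", path)
    }
    vals <- suppressWarnings(as.numeric(f[2:(1 + ndim)]))
    if (anyNA(vals)) {
      stop("malformed XEASY line ", which(lines == body[i])[1], " in ", path)
    }
    c(as.numeric(f[1]), vals,
      as.numeric(f[ndim + 4L]),                  # volume
      suppressWarnings(as.numeric(f[n_fields + 1L])), # optional S/N column
      as.numeric(f[(1L + ndim + 6L + 1L):n_fields]))  # assignments
  })
  if (length(rows) == 0L) {
    pk <- as.data.frame(matrix(numeric(0), ncol = 2L * ndim + 3L))
  } else {
    pk <- as.data.frame(do.call(rbind, rows))
  }
  names(pk) <- c("id", paste0("w", seq_len(ndim)), "volume", "sn",
                 paste0("a", seq_len(ndim)))
  pk$id <- as.integer(pk$id)
  for (a in paste0("a", seq_len(ndim))) {
    pk[[a]] <- if (keep_assignments) as.integer(pk[[a]]) else
      rep(0L, nrow(pk))
  }
  peaklist(pk, nuclei = nuclei,
           name = sub("\\.peaks$", "", basename(path)),
           experiment = experiment)
}

read_sparky <- function(lines, path, nuclei, experiment) {
  body <- lines[nzchar(trimws(lines))]
  body <- body[!grepl("^\\s*(Assignment|#)", body)]
  rows <- list()
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    ndim_i <- length(strsplit(f[1], "-")[[1]])
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (ndim_i < 2L || length(vals) < ndim_i || anyNA(vals[seq_len(ndim_i)])) {
      stop("malformed Sparky line ", i, " in ", path)
    }
    rows[[i]] <- list(ndim = ndim_i, w = vals[seq_len(ndim_i)],
                      extra = vals[-seq_len(ndim_i)])
  }
  if (length(rows) == 0L) stop("empty Sparky list: ", path)
  ndim <- rows[[1]]$ndim
  if (any(vapply(rows, function(r) r$ndim, 0L) != ndim)) {
    stop("inconsistent dimensionality in ", path)
  }
  if (is.null(nuclei)) nuclei <- default_nuclei(ndim)
  if (length(nuclei) != ndim) stop("dimension mismatch in ", path)
  w <- do.call(rbind, lapply(rows, function(r) r$w))
  pk <- as.data.frame(w)
  names(pk) <- paste0("w", seq_len(ndim))
  pk$id <- seq_len(nrow(pk))
  pk$volume <- vapply(rows, function(r)
    if (length(r$extra) >= 1L) r$extra[1] else NA_real_, 0)
  pk$sn <- vapply(rows, function(r)
    if (length(r$extra) >= 2L) r$extra[2] else NA_real_, 0)
  peaklist(pk, nuclei = nuclei,
           name = sub("\\.list$", "", basename(path)), experiment = experiment)
}

#' Write a peak list in XEASY format
#'
#' Dialect: a `# Number of dimensions N` header, `#INAME` lines naming the
#' dimensions, then one line per peak with id, N ppm values (3 decimals), a
#' color code, a spectrum-type character, volume (scientific notation),
#' volume error, integration flag, a literal 0, an optional S/N column is
#' appended after the assignment ids when present.
#'
#' @param x a [peaklist()].
#' @param path output path; conventionally `<experiment>_<type>.peaks`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  nd <- pl_ndim(x)
  nuc <- pl_nuclei(x)
  spec_char <- substring(pl_experiment(x) %||% "U", 1L, 1L)
  if (is.na(spec_char) || !nzchar(spec_char)) spec_char <- "U"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Number of dimensions %d", nd), con)
  dim_names <- paste0(nuc, seq_len(nd))
  writeLines(sprintf("#INAME %d %s", seq_len(nd), dim_names), con)
  if (nrow(x) > 0L) {
    w <- as.matrix(x[, paste0("w", seq_len(nd))])
    a <- as.matrix(x[, paste0("a", seq_len(nd))])
    vol <- ifelse(is.na(x$volume), 0, x$volume)
    lines <- vapply(seq_len(nrow(x)), function(i) {
      base <- sprintf(
        "%6d %s 1 %s %14.6e %9.2e e 0 %s",
        x$id[i],
        paste(sprintf("%8.3f", w[i, ]), collapse = " "),
        spec_char, vol[i], 0,
        paste(sprintf("%6d", a[i, ]), collapse = " ")
      )
      if (!is.na(x$sn[i])) base <- paste0(base, sprintf(" %10.3f", x$sn[i]))
      base
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read / write chemical-shift lists
#'
#' Plain whitespace-separated `.prot` columns: atom id, shift (ppm), error
#' (ppm), atom name, residue number. Unassigned atoms are written with
#' shift 999.000.
#'
#' @param path file path.
#' @return `read_shifts()`: tibble with columns `id`, `shift`, `error`,
#'   `atom`, `resno`.
#' @export
read_shifts <- function(path) {
  tab <- read.table(path, header = FALSE, col.names = c(
    "id", "shift", "error", "atom", "resno"
  ), colClasses = c("integer", "numeric", "numeric", "character", "integer"))
  out <- tibble::as_tibble(tab)
  if (anyDuplicated(out[, c("atom", "resno")])) {
    stop("duplicate atom/residue pair in shift list ", path)
  }
  out
}

#' @rdname read_shifts
#' @param x shift table with columns `id`, `shift`, `error`, `atom`,
#'   `resno`; `NA` shifts are written as 999.000.
#' @export
write_shifts <- function(x, path) {
  if (anyDuplicated(x[, c("atom", "resno")])) {
    stop("duplicate atom/residue pair in shift list")
  }
  shift <- ifelse(is.na(x$shift), 999, x$shift)
  err <- ifelse(is.na(x$error), 0, x$error)
  lines <- sprintf("%5d %8.3f %6.3f %-5s %4d",
                   x$id, shift, err, x$atom, x$resno)
  writeLines(lines, path)
  invisible(path)
}

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Read a protein sequence file
#'
#' One- or three-letter residue tokens (mixed case accepted), one or more
#' per line, with an optional leading integer giving the number of the
#' first residue.
#'
#' @param path file path.
#' @return tibble with columns `resno` and `restype` (three-letter).
#' @export
read_sequence <- function(path) {
  tok <- unlist(strsplit(trimws(readLines(path)), "\\s+"))
  tok <- tok[nzchar(tok) & !startsWith(tok, "#")]
  start <- 1L
  if (length(tok) && grepl("^[0-9]+$", tok[1])) {
    start <- as.integer(tok[1])
    tok <- tok[-1]
  }
  if (length(tok) == 0L) stop("empty sequence file: ", path)
  tok <- toupper(tok)
  res <- vapply(tok, function(t) {
    if (nchar(t) == 1L && t %in% names(AA3)) return(unname(AA3[t]))
    if (t %in% AA3) return(t)
    stop("unknown residue token: ", t)
  }, "")
  tibble::tibble(resno = seq_along(res) + start - 1L, restype = unname(res))
}
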