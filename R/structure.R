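#' Methyl topology of the labelable residue types
#'
#' One row per methyl group that can be isotope-labeled: the methyl carbon,
#' its stem atom (the single heavy-atom neighbor), a reference substituent
#' on the stem (used to orient ideal protons), and the geminal partner for
#' the prochiral Leu/Val pairs.
#'
#' @return tibble with columns `restype`, `letter`, `carbon`, `proton_name`,
#'   `stem`, `ref`, `selector`, `geminal`.
#' @export
methyl_topology <- function() {
  tibble::tribble(
    ~restype, ~letter, ~carbon, ~stem, ~ref, ~selector, ~geminal,
    "ALA", "A", "CB",  "CA", "N",  "b",  NA_character_,
    "ILE", "I", "CD1", "CG1", "CB", "d1", NA_character_,
    "ILE", "I", "CG2", "CB", "CA", "g2", NA_character_,
    "LEU", "L", "CD1", "CG", "CB", "d1", "CD2",
    "LEU", "L", "CD2", "CG", "CB", "d2", "CD1",
    "VAL", "V", "CG1", "CB", "CA", "g1", "CG2",
    "VAL", "V", "CG2", "CB", "CA", "g2", "CG1",
    "MET", "M", "CE",  "SD", "CG", "e",  NA_character_,
    "THR", "T", "CG2", "CB", "CA", "g2", NA_character_
  ) |>
    dplyr::mutate(proton_name = paste0("Q", substring(.data$carbon, 2L)))
}

# parse a labeling scheme string like "AILV", "ILV", "I(d1,g2)LV", "V(g1)"
# into a tibble (letter, selector); default selectors: Ile -> d1 only,
# Leu/Val -> both methyls, Ala/Met/Thr -> their single methyl
parse_labeling <- function(labeling) {
  topo <- methyl_topology()
  defaults <- list(
    A = "b", I = "d1", L = c("d1", "d2"), V = c("g1", "g2"),
    M = "e", T = "g2"
  )
  out <- list()
  rest <- labeling
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([AILVMT])(\\(([^)]*)\\))?", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop("cannot parse labeling scheme near: ", rest)
    }
    letter <- m[2]
    sels <- if (nzchar(m[4] %||% "")) {
      trimws(strsplit(m[4], ",")[[1]])
    } else {
      defaults[[letter]]
    }
    bad <- setdiff(sels, topo$selector[topo$letter == letter])
    if (length(bad)) {
      stop("unknown methyl selector(s) for ", letter, ": ",
           paste(bad, collapse = ", "))
    }
    out[[length(out) + 1L]] <- tibble::tibble(letter = letter, selector = sels)
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  dplyr::bind_rows(out) |> dplyr::distinct()
}

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns a plain atom table.
#' Alternate locations other than blank or 'A' are dropped; multiple chains
#' are collapsed into a single strictly increasing residue numbering.
#'
#' @param path path to a PDB file.
#' @return tibble with columns `atom`, `resno`, `restype`, `x`, `y`, `z`,
#'   `element`, `chain`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  out <- tibble::tibble(
    atom = at$elety,
    resno = at$resno,
    restype = toupper(at$resid),
    x = at$x, y = at$y, z = at$z,
    element = at$elesy %||% substring(at$elety, 1L, 1L),
    chain = at$chain
  )
  # collapse chains to one renumbered sequence, preserving order
  key <- paste(out$chain, out$resno)
  out$resno <- match(key, unique(key))
  out$chain <- NULL
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("non-finite coordinates in ", path)
  }
  out
}

#' Extract labeled methyl groups from a structure
#'
#' Builds one methyl-group record per labeled methyl: carbon position, the
#' three proton positions (taken from the structure when hydrogens are
#' present, otherwise constructed with ideal tetrahedral geometry by
#' [build_methyl_protons()]), the residue-type class used for peak-list
#' splitting, and the geminal partner link for Leu/Val pairs.
#'
#' @param structure atom table as returned by [read_structure()], or any
#'   data frame with columns `atom`, `resno`, `restype`, `x`, `y`, `z`.
#' @param sequence optional residue table (from [read_sequence()]) checked
#'   for consistency with the structure at methyl-bearing positions.
#' @param labeling labeling scheme string, e.g. `"AILV"`, `"ILV"`,
#'   `"I(d1,g2)LV"`. Ile defaults to the delta-1 methyl only.
#' @return tibble with one row per methyl group: `id`, `resno`, `restype`,
#'   `carbon`, `proton_name`, `letter`, `geminal_id`, `cx`, `cy`, `cz` and a
#'   list column `protons` of 3x3 coordinate matrices.
#' @export
extract_methyl_groups <- function(structure, sequence = NULL, labeling = "AILV") {
  structure <- tibble::as_tibble(structure)
  lab <- parse_labeling(labeling)
  topo <- methyl_topology() |>
    dplyr::inner_join(lab, by = c("letter", "selector"))

  if (!is.null(sequence)) {
    seq_tab <- tibble::as_tibble(sequence)
    res_struct <- structure |>
      dplyr::distinct(.data$resno, .data$restype) |>
      dplyr::filter(.data$restype %in% unique(topo$restype))
    chk <- dplyr::left_join(res_struct, seq_tab, by = "resno",
                            suffix = c("", ".seq"))
    bad <- chk |> dplyr::filter(!is.na(.data$restype.seq),
                                .data$restype != .data$restype.seq)
    if (nrow(bad)) {
      stop("sequence/structure mismatch at residue(s) ",
           paste(bad$resno, collapse = ", "))
    }
  }

  present_types <- unique(structure$restype)
  absent <- setdiff(unique(topo$restype), present_types)
  if (length(absent)) {
    warning("labeled residue type(s) absent from the structure: ",
            paste(absent, collapse = ", "))
  }

  residues <- structure |>
    dplyr::distinct(.data$resno, .data$restype) |>
    dplyr::filter(.data$restype %in% topo$restype)

  rows <- list()
  for (i in seq_len(nrow(residues))) {
    resno <- residues$resno[i]
    restype <- residues$restype[i]
    res_atoms <- structure[structure$resno == resno, , drop = FALSE]
    for (j in which(topo$restype == restype)) {
      cn <- topo$carbon[j]
      carbon <- res_atoms[res_atoms$atom == cn, , drop = FALSE]
      if (nrow(carbon) == 0L) {
        stop("missing methyl carbon ", cn, " in residue ", restype, " ", resno)
      }
      cpos <- c(carbon$x[1], carbon$y[1], carbon$z[1])
      protons <- find_methyl_hydrogens(res_atoms, cn)
      if (is.null(protons)) {
        stem <- res_atoms[res_atoms$atom == topo$stem[j], , drop = FALSE]
        ref <- res_atoms[res_atoms$atom == topo$ref[j], , drop = FALSE]
        if (nrow(stem) == 0L || nrow(ref) == 0L) {
          stop("missing stem/reference atom for methyl ", cn,
               " in residue ", restype, " ", resno)
        }
        protons <- build_methyl_protons(
          cpos,
          c(stem$x[1], stem$y[1], stem$z[1]),
          c(ref$x[1], ref$y[1], ref$z[1])
        )
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = paste0(resno, "-", cn),
        resno = resno, restype = restype,
        carbon = cn, proton_name = topo$proton_name[j],
        letter = topo$letter[j],
        geminal_id = if (is.na(topo$geminal[j])) NA_character_ else
          paste0(resno, "-", topo$geminal[j]),
        cx = cpos[1], cy = cpos[2], cz = cpos[3],
        protons = list(protons)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      id = character(), resno = integer(), restype = character(),
      carbon = character(), proton_name = character(), letter = character(),
      geminal_id = character(), cx = numeric(), cy = numeric(),
      cz = numeric(), protons = list()
    ))
  }
  # geminal links are only kept when both partners are labeled
  out$geminal_id[!is.na(out$geminal_id) & !(out$geminal_id %in% out$id)] <-
    NA_character_
  out
}

# methyl hydrogen naming in PDB files: HD11/HD12/HD13, 1HD1/2HD1/3HD1, ...
find_methyl_hydrogens <- function(res_atoms, carbon_name) {
  suffix <- substring(carbon_name, 2L) # e.g. "D1", "B", "E"
  pats <- c(
    paste0("^H", suffix, "[123]$"),
    paste0("^[123]H", suffix, "$")
  )
  for (p in pats) {
    h <- res_atoms[grepl(p, res_atoms$atom), , drop = FALSE]
    if (nrow(h) == 3L) {
      return(as.matrix(h[, c("x", "y", "z")]))
    }
  }
  NULL
}

#' Pairwise effective-distance table for a set of methyl groups
#'
#' @param methyls methyl table from [extract_methyl_groups()].
#' @param d_max optional upper bound; pairs beyond it are dropped.
#' @return tibble of unordered pairs `id_a`, `id_b` (a < b in table order)
#'   with their effective distance `d_eff` and a geminal flag.
#' @export
methyl_distance_table <- function(methyls, d_max = Inf) {
  n <- nrow(methyls)
  if (n < 2L) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          d_eff = numeric(), geminal = logical()))
  }
  # stack all protons (3 per methyl) and aggregate the r^-6 sums blockwise
  hp <- do.call(rbind, methyls$protons)
  d2 <- outer(rowSums(hp^2), rowSums(hp^2), "+") - 2 * tcrossprod(hp)
  d2[d2 < 1e-12] <- 1e-12
  inv6 <- d2^-3
  grp <- rep(seq_len(n), each = 3L)
  block <- rowsum(t(rowsum(inv6, grp)), grp) # n x n sums over 3x3 blocks
  deff <- block^(-1 / 6)
  pair_idx <- which(upper.tri(deff) & deff <= d_max, arr.ind = TRUE)
  if (nrow(pair_idx) == 0L) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          d_eff = numeric(), geminal = logical()))
  }
  i <- pair_idx[, 1]; j <- pair_idx[, 2]
  gem <- !is.na(methyls$geminal_id[i]) & methyls$geminal_id[i] == methyls$id[j]
  tibble::tibble(
    id_a = methyls$id[i], id_b = methyls$id[j],
    d_eff = deff[pair_idx], geminal = gem
  )[order(i, j), ]
}

#' Write methyl geometry as a minimal PDB file
#'
#' Writes one ATOM record per methyl carbon plus its three protons, using
#' standard methyl hydrogen names (e.g. `HD11`), so the file can be read
#' back by [read_structure()] and [extract_methyl_groups()]. Intended for
#' exporting simulated datasets; it is not a full structure writer.
#'
#' @param methyls methyl table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methyl_pdb <- function(methyls, path) {
  lines <- character()
  ser <- 0L
  fmt <- function(name, restype, resno, xyz) {
    nm <- if (nchar(name) >= 4L) name else sprintf(" %-3s", name)
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ser, nm, "", restype, "A", resno, "", xyz[1], xyz[2], xyz[3],
            1, 0, substring(name, 1L, 1L))
  }
  for (i in seq_len(nrow(methyls))) {
    m <- methyls[i, ]
    ser <- ser + 1L
    lines <- c(lines, fmt(m$carbon, m$restype, m$resno,
                          c(m$cx, m$cy, m$cz)))
    h <- m$protons[[1L]]
    hbase <- paste0("H", substring(m$carbon, 2L))
    for (k in 1:3) {
      ser <- ser + 1L
      lines <- c(lines, fmt(paste0(hbase, k), m$restype, m$resno, h[k, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
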