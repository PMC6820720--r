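# Fixtures are built in code; nothing is read from disk except the tiny
# packaged PDB fragment.

# a methyl group row in the extract_methyl_groups() schema
toy_methyl <- function(id, carbon_pos, letter = "L", resno = 1L,
                       carbon = "CD1", geminal_id = NA_character_,
                       axis = c(0, 0, -1)) {
  stem <- carbon_pos + 1.5 * axis / sqrt(sum(axis^2))
  perp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- perp - sum(perp * axis) * axis / sum(axis^2)
  restype <- c(A = "ALA", I = "ILE", L = "LEU", V = "VAL",
               M = "MET", T = "THR")[[letter]]
  tibble::tibble(
    id = id, resno = as.integer(resno), restype = restype, carbon = carbon,
    proton_name = paste0("Q", substring(carbon, 2L)), letter = letter,
    geminal_id = geminal_id,
    cx = carbon_pos[1], cy = carbon_pos[2], cz = carbon_pos[3],
    protons = list(build_methyl_protons(carbon_pos, stem, stem + perp))
  )
}

# n methyls of one class on a loose line, far enough apart to control which
# pairs fall under a NOESY cutoff
toy_methyl_chain <- function(n, spacing = 6, letter = "L") {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    toy_methyl(paste0(i, "-CD1"), c((i - 1) * spacing, 0, 0),
               letter = letter, resno = i)
  }))
}

# small 4D NOESY peak list from explicit coordinates
toy_noesy <- function(coords, sn = NULL, experiment = "CCNOESY") {
  df <- as.data.frame(coords)
  names(df) <- c("w1", "w2", "w3", "w4")
  df$id <- seq_len(nrow(df))
  df$sn <- sn %||% rep(NA_real_, nrow(df))
  peaklist(df, nuclei = c("H", "C", "C", "H"), name = "toy",
           experiment = experiment)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# standard reduced-budget optimizer configuration used across tests
test_opt_config <- function(...) {
  optimizer_config(population = 50, runs = 20, iterations = 3000,
                   generations = 20, stagnation = 8, ...)
}

# fraction of NOE-bearing methyls (after the standard filter) that are
# assigned strong, plus evaluation counts
coverage_summary <- function(dataset, result) {
  filtered <- filter_noesy(dataset$noesy)
  keep <- dataset$truth$noesy_map$peak_id %in% filtered$id
  nb <- unique(unlist(dataset$truth$noesy_map[keep, c("id_a", "id_b")]))
  nb <- nb[!is.na(nb)]
  tt <- tidy(result)
  g <- glance(result)
  list(
    coverage = sum(tt$strength == "strong" & tt$methyl_id %in% nb) / length(nb),
    n_strong = g$n_strong, n_correct = g$n_correct,
    n_erroneous = g$n_erroneous, explained = g$explained
  )
}
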