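test_that("reciprocity and signal-to-noise filtering follow the stated rules", {
  # reciprocal pair with good S/N: both kept
  pk <- toy_noesy(rbind(
    c(0.80, 23.0, 25.0, 1.10),
    c(1.10, 25.0, 23.0, 0.80),
    c(0.50, 20.0, 21.0, 0.60)   # lone unreciprocated peak
  ), sn = c(5, 5, 9))
  out <- filter_noesy(pk, min_sn = 2)
  expect_identical(out$id, 1:2)

  # reciprocity is re-evaluated after the S/N cut: a weak mate kills both
  pk2 <- toy_noesy(rbind(
    c(0.80, 23.0, 25.0, 1.10),
    c(1.10, 25.0, 23.0, 0.80)
  ), sn = c(5, 1.5))
  expect_equal(nrow(filter_noesy(pk2, min_sn = 2)), 0L)

  # peaks without S/N pass the S/N test
  pk3 <- toy_noesy(rbind(
    c(0.80, 23.0, 25.0, 1.10),
    c(1.10, 25.0, 23.0, 0.80)
  ))
  expect_equal(nrow(filter_noesy(pk3, min_sn = 2)), 2L)

  expect_error(filter_noesy(peaklist(tibble::tibble(w1 = 1, w2 = 20),
                                     nuclei = c("H", "C"))), "NOESY")
})

test_that("the NOESY filter is idempotent and transpose-symmetric", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 25, seed = 14,
                                           p_obs = 0.8,
                                           artifact_rate = 0.15,
                                           jitter_sd = 0.2))
  f1 <- filter_noesy(ds$noesy)
  f2 <- filter_noesy(f1)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  # relabel donor/acceptor dimensions (reverse all four) and refilter
  rev_tab <- tibble::as_tibble(ds$noesy)
  rev_tab[, c("w1", "w2", "w3", "w4")] <- rev_tab[, c("w4", "w3", "w2", "w1")]
  revd <- peaklist(rev_tab, nuclei = c("H", "C", "C", "H"),
                   experiment = "CCNOESY")
  fr <- filter_noesy(revd)
  expect_setequal(fr$id, f1$id)
})

test_that("NOESY peaks are attributed to the type pair of the nearest HMQC peaks", {
  hm <- peaklist(tibble::tibble(
    id = 1:3, w1 = c(0.80, 1.10, 0.50), w2 = c(23.0, 25.0, 13.2)
  ), nuclei = c("H", "C"), experiment = "C13HSQC")
  typing <- tibble::tibble(id = 1:3, type = c("L", "V", "I"))
  no <- toy_noesy(rbind(
    c(0.80, 23.0, 25.0, 1.10),  # L-V
    c(0.50, 13.2, 23.0, 0.80),  # I-L
    c(0.80, 23.0, 40.0, 5.00)   # acceptor matches nothing -> untyped
  ))
  out <- attribute_noesy_types(no, hm, typing)
  expect_setequal(names(out), c("IL", "LV", "untyped"))
  expect_identical(out$LV$id, 1L)
  expect_identical(out$IL$id, 2L)
  expect_identical(out$untyped$id, 3L)
  expect_identical(out$LV$type_a, "L")
  # conservation: no peak lost or duplicated
  expect_equal(sum(vapply(out, nrow, 0L)), nrow(no))
})

test_that("equidistant HMQC candidates break ties toward the lower peak id", {
  hm <- peaklist(tibble::tibble(
    id = c(7L, 2L), w1 = c(0.80, 0.82), w2 = c(23.0, 23.0)
  ), nuclei = c("H", "C"), experiment = "C13HSQC")
  typing <- tibble::tibble(id = c(7L, 2L), type = c("L", "V"))
  no <- toy_noesy(rbind(c(0.81, 23.0, 23.0, 0.81)))
  out <- attribute_noesy_types(no, hm, typing)
  # both sides tie between ids 2 and 7 at equal scaled distance -> id 2 (V)
  expect_identical(names(out), "VV")
  expect_identical(out$VV$hmqc_a, 2L)
})

test_that("type attribution agrees with an exhaustive nearest-match scan", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 20, seed = 31,
                                           jitter_sd = 0.3))
  tol <- tolerances()
  out <- attribute_noesy_types(ds$noesy, ds$hmqc, ds$typing, tol)
  flat <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  flat <- flat[order(flat$id), ]
  # independent brute-force scan over every peak and every HMQC candidate
  labels <- methylassign:::canonical_label(
    ds$typing$type[match(ds$hmqc$id, ds$typing$id)])
  nearest <- function(h, c_) {
    d <- pmax(abs(ds$hmqc$w1 - h) / tol$tol_h, abs(ds$hmqc$w2 - c_) / tol$tol_c)
    ord <- order(d, ds$hmqc$id)
    if (d[ord[1]] <= 1) ord[1] else 0L
  }
  for (i in seq_len(nrow(ds$noesy))) {
    ia <- nearest(ds$noesy$w1[i], ds$noesy$w2[i])
    ib <- nearest(ds$noesy$w4[i], ds$noesy$w3[i])
    row <- flat[flat$id == ds$noesy$id[i], ]
    if (ia == 0L || ib == 0L) {
      expect_identical(row$type_a, "?")
    } else {
      expect_identical(sort(c(row$type_a, row$type_b)),
                       sort(c(labels[ia], labels[ib])))
    }
  }
})

test_that("HMQC splitting duplicates ambiguous peaks with a shared flag", {
  hm <- peaklist(tibble::tibble(
    id = 1:4, w1 = c(1.3, 0.7, 0.5, 1.1), w2 = c(19, 24, 13.4, 20)
  ), nuclei = c("H", "C"), experiment = "C13HSQC")
  typing <- tibble::tibble(id = 1:4, type = c("A", "LV", "I", "ALV"))
  parts <- split_hmqc_by_type(hm, typing)
  expect_setequal(names(parts), c("A", "I", "LV"))
  expect_setequal(parts$A$id, c(1L, 4L))
  expect_setequal(parts$LV$id, c(2L, 4L))
  expect_identical(parts$I$id, 3L)
  # the ambiguous peak is flagged in both lists; unambiguous ones are not
  expect_identical(parts$A$shared_id[parts$A$id == 4L], 4L)
  expect_identical(parts$LV$shared_id[parts$LV$id == 4L], 4L)
  expect_true(is.na(parts$A$shared_id[parts$A$id == 1L]))
  # union of parts covers the input
  expect_setequal(unique(unlist(lapply(parts, function(p) p$id))), hm$id)
})

test_that("best-guess typing from shift statistics behaves by region", {
  counts <- c(A = 5, I = 5, L = 5, V = 5)
  hm <- peaklist(tibble::tibble(
    id = 1:3,
    w1 = c(0.69, 0.80, 1.10),
    w2 = c(13.5, 23.5, 20.0)  # Ile region, Leu/Val region, Ala/LV overlap
  ), nuclei = c("H", "C"), experiment = "C13HSQC")
  ty <- bmrb_best_guess_typing(hm, sequence_counts = counts,
                               strategy = "ambiguous")
  expect_identical(ty$type[1], "I")  # upfield 13C resolves Ile
  expect_identical(ty$type[2], "LV")
  expect_identical(ty$type[3], "ALV")

  ty2 <- bmrb_best_guess_typing(hm, sequence_counts = c(A = 1, I = 1, L = 1,
                                                        V = 1),
                                strategy = "max-ala")
  expect_identical(ty2$type[3], "A") # overlap peak attributed to Ala first

  far <- peaklist(tibble::tibble(id = 1L, w1 = 3.0, w2 = 40),
                  nuclei = c("H", "C"))
  expect_warning(bmrb_best_guess_typing(far, sequence_counts = counts),
                 "outside")
})

test_that("typing from simulated shifts is mostly correct outside overlaps", {
  ds <- simulate_methyl_dataset(sim_config(n_methyls = 60, seed = 77))
  ty <- suppressWarnings(
    bmrb_best_guess_typing(ds$hmqc,
                           sequence_counts = table(ds$methyls$letter),
                           strategy = "ambiguous"))
  truth_label <- ds$typing$type[match(ty$id, ds$typing$id)]
  unambig <- ty$type %in% c("A", "I", "LV")
  ok <- ty$type[unambig] == truth_label[unambig]
  expect_gte(mean(ok), 0.9)
})

test_that("3D NOESY lists are filtered and typed via their single-sided coordinates", {
  # 3D HCH list: dimensions H_a, C_b, H_b
  pk <- peaklist(tibble::tibble(
    id = 1:3,
    w1 = c(0.80, 1.10, 0.30),
    w2 = c(25.0, 23.0, 20.0),
    w3 = c(1.10, 0.80, 0.55),
    sn = c(6, 6, 6)
  ), nuclei = c("H", "C", "H"), experiment = "C13NOESY")
  f <- filter_noesy(pk, min_sn = 2)
  expect_setequal(f$id, 1:2) # peaks 1 and 2 are mutual transposes in 1H

  hm <- peaklist(tibble::tibble(
    id = 1:2, w1 = c(0.80, 1.10), w2 = c(23.0, 25.0)
  ), nuclei = c("H", "C"), experiment = "C13HSQC")
  typing <- tibble::tibble(id = 1:2, type = c("L", "V"))
  out <- attribute_noesy_types(f, hm, typing)
  # side a matched on 1H alone; side b on both nuclei
  expect_identical(names(out), "LV")
  expect_equal(nrow(out$LV), 2L)
})
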