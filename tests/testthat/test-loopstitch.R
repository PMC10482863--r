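# Loop annotations mirroring the P-loop ATP-binding cassette timeline:
# the P-loop (position 34) is the oldest loop, then 213, 80, 186 join in
# age order; 60..222 are replacement candidates. Spans are synthetic
# 3-residue stand-ins; ages follow the published chronology of the series.
ploop_fixture <- function() {
  labels <- c(34, 60, 68, 72, 80, 85, 110, 126, 151, 186, 213, 222)
  all_ages <- setNames(rep(0.5, length(labels)), labels)
  all_ages[c("34", "213", "80", "186")] <- c(0, 0.112, 0.146, 0.184)
  as_loop_annotations(data.frame(
    label = labels, start = labels, end = labels + 2,
    sequence = c("GKS", "ALV", "TRE", "DNI", "WCE", "MHK", "PQR", "FYA",
                 "LST", "GDE", "KVN", "ARW"),
    prototype = c("DS.EH.6.1.1", "DS.HE.1.1.1", "DS.BK.2.1.3",
                  "DS.HE.1.2.1", "DS.EH.2.1.58", "DS.HE.1.3.1",
                  "DS.HE.1.4.1", "DS.HE.1.5.1", "DS.HE.1.6.1",
                  "DS.HE.4.2.20", "DS.HE.2.2.4", "DS.BN.2.1.7"),
    age = unname(all_ages), stringsAsFactors = FALSE))
}

core_fixture <- function() {
  ann <- ploop_fixture()
  ann[ann$label %in% c(34, 80, 186, 213), ]
}

test_that("stitching reproduces the time-ordered growing-molecule series", {
  ints <- build_intermediates(core_fixture())
  expect_equal(ints$loop_sequence,
               c("34", "34|213", "34|80|213", "34|80|186|213"))
  expect_equal(ints$age, c(0, 0.112, 0.146, 0.184))
  # positional concatenation: labels ascend, lengths conserve
  expect_equal(ints$amino_sequence[4], paste0("GKS", "WCE", "GDE", "KVN"))
  expect_equal(nchar(ints$amino_sequence), 3 * ints$n_loops)
  # membership monotonicity
  members <- attr(ints, "members")
  for (i in seq_along(members)[-1])
    expect_true(all(members[[i - 1]] %in% members[[i]]))
})

test_that("single loops, ties and degenerate inputs behave", {
  one <- core_fixture()[1, ]
  ints <- build_intermediates(one)
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$loop_sequence, "34")

  # age ties enter the same intermediate together
  tied <- core_fixture()              # rows ordered by label: 34, 80, 186, 213
  tied$age <- c(0, 0.1, 0.1, 0.2)
  ti <- build_intermediates(tied)
  expect_equal(nrow(ti), 3L)
  expect_equal(ti$n_loops, c(1, 3, 4))

  expect_error(build_intermediates(core_fixture()[0, ]), "empty")
  bad <- core_fixture()
  bad$end[1] <- 100   # overlap + length mismatch
  expect_error(build_intermediates(bad), "length|overlap")
})

test_that("toy annotation concatenation conserves length", {
  ann <- as_loop_annotations(data.frame(
    label = c(1, 4, 6), start = c(1, 4, 6), end = c(3, 5, 7),
    sequence = c("AAA", "CC", "DD"),
    prototype = c("DS.HH.1.1.1", "DS.HH.1.2.1", "DS.HH.1.3.1"),
    age = c(0, 0.1, 0.2)))
  ints <- build_intermediates(ann)
  expect_equal(ints$amino_sequence[3], "AAACCDD")
  expect_equal(nchar(ints$amino_sequence[3]), 7L)
})

test_that("replacement variants keep positional order and reject violators", {
  ann <- ploop_fixture()
  v <- reshuffle_variants("34|80|186|213", slot = 2,
                          candidates = c(60, 68, 72, 85, 110, 126, 151),
                          annotations = ann)
  expect_equal(nrow(v), 7L)
  expect_equal(v$loop_sequence[1], "34|60|186|213")
  expect_true(all(vapply(strsplit(v$loop_sequence, "|", fixed = TRUE),
                         function(x) !is.unsorted(as.integer(x),
                                                  strictly = TRUE), TRUE)))
  # amino sequences are stitched from the annotation table
  expect_equal(v$amino_sequence[v$replacement == 60],
               paste0("GKS", "ALV", "GDE", "KVN"))

  v4 <- reshuffle_variants("34|80|186|213", slot = 4, candidates = 222,
                           annotations = ann)
  expect_equal(v4$loop_sequence, "34|80|186|222")

  # a candidate positioned before the slot's left neighbor is rejected
  expect_warning(
    bad <- reshuffle_variants("34|80|186|213", slot = 2, candidates = 20),
    "no admissible")
  expect_equal(nrow(bad), 0L)
  expect_equal(attr(bad, "rejected")$label, 20L)
  expect_warning(
    reshuffle_variants("34|80|186|213", slot = 3, candidates = 222),
    "no admissible")
  expect_error(reshuffle_variants("34|80|186|213", 9, 222), "slot")
})

test_that("FASTA export validates the alphabet and round trips", {
  ints <- build_intermediates(core_fixture())
  fa <- tempfile(fileext = ".fasta")
  write_fasta_series(ints, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(length(back), 4L)
  expect_equal(as.character(back[[4]]), ints$amino_sequence[4])
  expect_true(any(grepl("34|80|186|213", names(back), fixed = TRUE)))

  bad <- ints
  bad$amino_sequence[1] <- "GXS"
  expect_error(write_fasta_series(bad, fa), "non-amino")
})

test_that("generated toy annotations always stitch", {
  for (s in 1:3) {
    ann <- generate_toy_annotations(5, seed = s)
    expect_s3_class(ann, "ef_annotations")
    ints <- build_intermediates(ann)
    expect_equal(ints$n_loops[nrow(ints)], 5L)
    expect_identical(generate_toy_annotations(5, seed = s), ann)
  }
  single <- build_intermediates(generate_toy_annotations(1, seed = 4))
  expect_equal(nrow(single), 1L)
})
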