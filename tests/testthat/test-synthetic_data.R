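test_that("random constructs are reproducible and satisfy the k-mer distinctness contract", {
  c1 <- random_construct(398, rng_seed = 21)
  c2 <- random_construct(398, rng_seed = 21)
  expect_identical(c1$sense, c2$sense)
  expect_identical(nchar(c1$sense), 398L)
  expect_identical(nrow(dice(c1)), 378L)
  expect_error(random_construct(10, gc = 0.5), "length >= k")
})

test_that("construct GC content sits within 3 sd of the binomial expectation", {
  con <- random_construct(10000, gc = 0.5, rng_seed = 22, k = 21,
                          distinct_kmers = FALSE)
  gc_obs <- sum(strsplit(con$sense, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 5000), 3 * sqrt(10000 * 0.25))
  con7 <- random_construct(10000, gc = 0.7, rng_seed = 23, k = 21,
                           distinct_kmers = FALSE)
  gc7 <- sum(strsplit(con7$sense, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc7 - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
})

test_that("plant patterns draw mismatches from their defining position sets", {
  set.seed(24)
  for (i in 1:50) {
    expect_identical(plant_mismatch_positions("perfect"), integer(0))
    expect_true(plant_mismatch_positions("one_mm_seed") %in% 2:8)
    expect_true(plant_mismatch_positions("one_mm_nonseed") %in% c(1, 9:21))
    expect_true(all(plant_mismatch_positions("two_mm_nonseed") %in% 9:21))
    p16 <- plant_mismatch_positions("identity16")
    expect_identical(length(p16), 5L)
    expect_true(all(p16 %in% 9:21))
    expect_false(all(19:21 %in% p16))
    expect_identical(length(plant_mismatch_positions("decoy_identity14")), 7L)
  }
  expect_identical(plant_mismatch_positions("near18_2mm"), c(1L, 21L))
  expect_error(plant_mismatch_positions("bogus"), "unknown plant pattern")
})

test_that("planted sites re-extract from transcripts with exactly the recorded mismatches", {
  con <- random_construct(150, rng_seed = 25)
  synth <- build_synthetic_db(
    con, "perfect:2,one_mm_seed:2,two_mm_nonseed:2,identity16:2",
    n_background = 3, len_range = c(150, 400), rng_seed = 25)
  expect_identical(nrow(synth$truth), 8L)
  expect_identical(nrow(synth$db$records), 11L)
  for (i in seq_len(nrow(synth$truth))) {
    tr <- synth$truth[i, ]
    txp <- synth$db$records$residues[synth$db$records$id == tr$transcript_id]
    site <- substr(txp, tr$t_start, tr$t_end)
    guide_site <- if (tr$strand == "forward") site else oracle_revcomp(site)
    diff_pos <- which(strsplit(guide_site, "")[[1]] !=
                        strsplit(tr$source_residues, "")[[1]])
    mm <- if (nzchar(tr$mismatch_positions)) {
      as.integer(strsplit(tr$mismatch_positions, ",")[[1]])
    } else {
      integer(0)
    }
    expect_identical(diff_pos, mm)
  }
})

test_that("expected retention flags encode the pattern x preset x mode truth table", {
  con <- random_construct(120, rng_seed = 26)
  synth <- build_synthetic_db(con, "perfect:1,identity16:1,one_mm_seed:1",
                              n_background = 2, len_range = c(120, 300),
                              rng_seed = 26)
  tr <- synth$truth
  p <- tr[tr$pattern == "perfect", ]
  expect_true(p$expected_text_or_then_seed && p$expected_text_and_chain)
  expect_false(p$expected_chen_and_chain) # 26-nt stretch unsatisfiable
  i16 <- tr[tr$pattern == "identity16", ]
  expect_true(i16$expected_text_or_then_seed)
  expect_false(i16$expected_text_and_chain) # criterion 2 must fail
  s <- tr[tr$pattern == "one_mm_seed", ]
  expect_false(any(unlist(s[grep("^expected_", names(s))])))
})

test_that("the pipeline recovers every planted site expected to survive, with no false positives", {
  con <- random_construct(200, rng_seed = 27)
  synth <- build_synthetic_db(
    con, "perfect:3,one_mm_nonseed:3,one_mm_seed:3,decoy_identity14:3",
    n_background = 10, len_range = c(200, 700), rng_seed = 27)
  rec <- recovery_test(con, synth$db, synth$truth, filter_config())
  expect_identical(rec$sensitivity, 1)
  expect_identical(rec$false_positives, 0L)
  expect_identical(rec$seed_rejection_rate, 1)
  expect_identical(rec$n_expected, 6L) # perfect + one_mm_nonseed
})

test_that("an unattainable identity floor drives sensitivity to zero", {
  con <- random_construct(120, rng_seed = 28)
  synth <- build_synthetic_db(con, "perfect:3", n_background = 2,
                              len_range = c(120, 300), rng_seed = 28)
  rec <- recovery_test(con, synth$db, synth$truth,
                       filter_config(min_identities = 22L))
  expect_identical(rec$sensitivity, 0)
  expect_identical(rec$false_positives, 0L)
})

test_that("empty plant specs give an n/a sensitivity and clean background", {
  con <- random_construct(120, rng_seed = 29)
  synth <- build_synthetic_db(con, parse_plant_spec(""), n_background = 5,
                              len_range = c(120, 300), rng_seed = 29)
  expect_identical(nrow(synth$truth), 0L)
  rec <- recovery_test(con, synth$db, synth$truth, filter_config())
  expect_true(is.na(rec$sensitivity))
  expect_identical(rec$false_positives, 0L)
  # background cleanliness: no hit anywhere at the scan floor
  expect_identical(rec$funnel$counts[["input"]], 0L)
})

test_that("plant spec strings parse to the expected table", {
  sp <- parse_plant_spec("perfect:5,one_mm_seed:10")
  expect_identical(sp$pattern, c("perfect", "one_mm_seed"))
  expect_identical(sp$count, c(5L, 10L))
  expect_identical(nrow(parse_plant_spec("")), 0L)
})

test_that("synthetic study inputs write to disk and reload consistently", {
  con <- random_construct(120, rng_seed = 30)
  synth <- build_synthetic_db(con, "perfect:2", n_background = 2,
                              len_range = c(120, 250), rng_seed = 30)
  dir <- withr::local_tempdir()
  files <- write_synthetic_data(con, synth, dir, rng_seed = 30)
  expect_true(all(file.exists(files)))
  db_back <- read_fasta(file.path(dir, "db.fasta"))
  expect_identical(db_back$id, synth$db$records$id)
  expect_identical(db_back$residues, synth$db$records$residues)
  con_back <- read_fasta(file.path(dir, "construct.fasta"))
  expect_identical(con_back$residues, con$sense)
  truth_back <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(truth_back), 2L)
  expect_identical(truth_back$rng_seed, c(30L, 30L))
})
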