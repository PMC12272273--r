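frag_row <- function(residues, id = "f1", start = 1L) {
  data.frame(fragment_id = id, parent_id = "c", start = start,
             k = nchar(residues), residues = residues, orientation = "sense",
             fragment_index = 1L, stringsAsFactors = FALSE)
}

test_that("a verbatim planted fragment is found with perfect statistics", {
  set.seed(11)
  frag <- rand_seq(21)
  txp <- plant_in_background(frag, 1000, at = 101)
  hits <- scan_fragment(frag_row(frag), list(id = "t1", residues = txp),
                        min_identities = 16)
  exact <- hits[hits$t_start == 101 & hits$target_strand == "forward", ]
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$identities, 21L)
  expect_identical(exact$mismatches, "")
  expect_identical(exact$longest_perfect_run, 21L)
  expect_identical(exact$best_near_perfect, 21L)
  expect_identical(exact$t_end, 121L)
})

test_that("a single substitution at guide position 10 gives the derived statistics", {
  set.seed(12)
  frag <- rand_seq(21)
  ch <- strsplit(frag, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  site <- paste(ch, collapse = "")
  txp <- plant_in_background(site, 600, at = 200)
  hits <- scan_fragment(frag_row(frag), list(id = "t1", residues = txp),
                        min_identities = 16)
  h <- hits[hits$t_start == 200 & hits$target_strand == "forward", ]
  expect_identical(h$identities, 20L)
  expect_identical(h$mismatches, "10")
  expect_identical(h$longest_perfect_run, 11L) # stretch 11..21
  expect_identical(h$best_near_perfect, 21L)
})

test_that("reverse-strand placements are reported with guide-mapped mismatches", {
  set.seed(13)
  frag <- rand_seq(21)
  ch <- strsplit(frag, "")[[1]]
  ch[3] <- setdiff(c("A", "C", "G", "T"), ch[3])[1] # seed mismatch
  site <- oracle_revcomp(paste(ch, collapse = ""))
  txp <- plant_in_background(site, 500, at = 50)
  hits <- scan_fragment(frag_row(frag), list(id = "t1", residues = txp),
                        min_identities = 18)
  h <- hits[hits$t_start == 50 & hits$target_strand == "reverse", ]
  expect_identical(nrow(h), 1L)
  expect_identical(h$identities, 20L)
  expect_identical(h$mismatches, "3") # guide coordinates, not window coords
})

test_that("scan equals the naive position-by-position oracle on random pairs", {
  set.seed(14)
  for (i in 1:40) {
    frag <- rand_seq(21)
    txp <- rand_seq(sample(21:400, 1), gc = runif(1, 0.3, 0.7))
    thr <- sample(12:21, 1)
    hits <- scan_fragment(frag_row(frag), list(id = "t", residues = txp),
                          min_identities = thr)
    expect_identical(hit_key(hits), hit_key(oracle_scan(frag, txp, thr)))
  }
})

test_that("N bases never count as identities on either side", {
  frag <- paste(rep("A", 21), collapse = "")
  txp <- paste0(strrep("A", 10), "N", strrep("A", 20))
  hits <- scan_fragment(frag_row(frag), list(id = "t", residues = txp),
                        min_identities = 20)
  # every window covering the N has exactly one mismatch at the N
  covering <- hits[hits$identities == 20L &
                     hits$target_strand == "forward", ]
  expect_true(all(vapply(seq_len(nrow(covering)), function(i) {
    11L >= covering$t_start[i] && 11L <= covering$t_end[i]
  }, logical(1))))
  fragN <- paste0(strrep("A", 20), "N")
  hitsN <- scan_fragment(frag_row(fragN), list(id = "t", residues = strrep("A", 40)),
                         min_identities = 20)
  expect_true(all(hitsN$identities == 20L))
  expect_true(all(vapply(hitsN$mismatch_positions[hitsN$target_strand == "forward"],
                         identical, logical(1), 21L)))
})

test_that("strand symmetry: reverse-complementing the database mirrors the hit set", {
  set.seed(15)
  frag <- rand_seq(21)
  txp <- plant_in_background(frag, 300, at = 40)
  n <- nchar(txp)
  fwd <- scan_fragment(frag_row(frag), list(id = "t", residues = txp),
                       min_identities = 15)
  rev <- scan_fragment(frag_row(frag),
                       list(id = "t", residues = oracle_revcomp(txp)),
                       min_identities = 15)
  # bijection: each hit maps to (n - t_end + 1, opposite strand), identities kept
  flip <- function(df) {
    sort(paste(n - df$t_end + 1L,
               ifelse(df$target_strand == "forward", "reverse", "forward"),
               df$identities, df$mismatches, sep = "|"))
  }
  expect_identical(flip(fwd), hit_key(rev))
})

test_that("lowering the identity floor never removes a hit", {
  set.seed(16)
  frag <- rand_seq(21)
  txp <- rand_seq(800)
  prev <- NULL
  for (thr in c(18L, 15L, 12L, 10L)) {
    hits <- scan_fragment(frag_row(frag), list(id = "t", residues = txp),
                          min_identities = thr)
    if (!is.null(prev)) expect_true(all(prev %in% hit_key(hits)))
    prev <- hit_key(hits)
  }
})

test_that("run_statistics matches hand-derived and oracle values", {
  expect_identical(run_statistics(integer(0), 21, 2),
                   c(longest_perfect_run = 21L, best_near_perfect = 21L))
  expect_identical(run_statistics(10, 21, 2),
                   c(longest_perfect_run = 11L, best_near_perfect = 21L))
  # frozen from the exhaustive window oracle
  expect_identical(oracle_run_stats(c(2, 8, 15), 21, 2),
                   c(longest_perfect_run = 6L, best_near_perfect = 19L))
  expect_identical(run_statistics(c(2, 8, 15), 21, 2),
                   c(longest_perfect_run = 6L, best_near_perfect = 19L))
  expect_identical(run_statistics(c(2, 8, 15), 21, 1)[["best_near_perfect"]],
                   13L)
  expect_error(run_statistics(c(0, 5), 21, 2), "out of 1..k")
  expect_error(run_statistics(c(5, 22), 21, 2), "out of 1..k")
  expect_error(run_statistics(c(8, 5), 21, 2), "sorted")
})

test_that("run_statistics agrees with exhaustive enumeration on random sets", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(21:25, 1)
    n_mm <- sample(0:6, 1)
    pos <- sort(sample(seq_len(k), n_mm))
    m <- sample(0:3, 1)
    expect_identical(unname(run_statistics(pos, k, m)),
                     unname(oracle_run_stats(pos, k, m)))
  }
})

test_that("search_db dedupes, orders deterministically, and flags short transcripts", {
  set.seed(18)
  con <- random_construct(80, rng_seed = 18)
  frags <- dice(con)
  txp1 <- plant_in_background(frags$residues[5], 300, at = 100)
  db <- transcript_db(data.frame(
    id = c("tB", "tA", "short"),
    residues = c(rand_seq(250), txp1, rand_seq(10)),
    stringsAsFactors = FALSE), db_name = "unit_db")
  expect_warning(hits <- search_db(frags, db, filter_config()),
                 "shorter than k")
  expect_identical(attr(hits, "db_name"), "unit_db")
  expect_identical(attr(hits, "n_fragments"), nrow(frags))
  # global ordering: transcript_id then t_start
  expect_identical(order(hits$transcript_id, hits$t_start),
                   seq_len(nrow(hits)))
  key <- paste(hits$fragment_id, hits$transcript_id, hits$t_start,
               hits$target_strand)
  expect_false(any(duplicated(key)))
  # the planted fragment is recovered
  expect_true(any(hits$transcript_id == "tA" & hits$t_start == 100 &
                    hits$identities == 21L))
  expect_error(search_db(frags[0, ], db, filter_config()), "no fragments")
  empty_db <- transcript_db(data.frame(id = character(0),
                                       residues = character(0),
                                       stringsAsFactors = FALSE))
  expect_error(search_db(frags, empty_db, filter_config()),
               "empty transcript database")
})

test_that("duplicate fragments collapse to a single placement after dedup", {
  set.seed(19)
  homo <- dsrna_construct("h", strrep("A", 25))
  frags <- dice(homo, dedupe = FALSE) # 5 identical fragments
  db <- transcript_db(data.frame(id = "t",
                                 residues = plant_in_background(
                                   strrep("A", 21), 120, at = 30, gc = 0.9),
                                 stringsAsFactors = FALSE))
  hits <- search_db(frags, db, filter_config())
  key <- paste(hits$t_start, hits$target_strand)
  expect_false(any(duplicated(key)))
})

test_that("an identity floor above k yields an empty hit table", {
  con <- random_construct(60, rng_seed = 20)
  frags <- dice(con)
  db <- transcript_db(data.frame(id = "t", residues = con$sense,
                                 stringsAsFactors = FALSE))
  hits <- search_db(frags, db, filter_config(min_identities = 22L))
  expect_identical(nrow(hits), 0L)
})
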