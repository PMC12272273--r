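#' Generate a random dsRNA construct
#'
#' Stand-in for a real biopesticide construct (e.g. a ~400-nt dsRNA against
#' a fungal Dicer-like gene): i.i.d. bases at a configurable GC content.
#' With `distinct_kmers = TRUE` the sequence is regenerated until all its
#' k-mers are distinct, so the unique-fragment count law
#' (L - k + 1 fragments) is exact — at realistic lengths a collision is
#' already vanishingly rare and at most a couple of redraws occur.
#'
#' @param length Construct length in nt (default 398, a typical SIGS
#'   construct size).
#' @param gc GC fraction in (0, 1).
#' @param rng_seed Optional integer seed for reproducibility.
#' @param k k-mer length used for the distinctness check.
#' @param distinct_kmers Require all k-mers distinct.
#' @param identifier Construct name.
#' @return A [dsrna_construct()].
#' @export
random_construct <- function(length = 398L, gc = 0.5, rng_seed = NULL,
                             k = 21L, distinct_kmers = TRUE,
                             identifier = "synthetic_construct") {
  stopifnot(length >= k, gc > 0, gc < 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  repeat {
    sense <- paste(sample_bases(length, gc), collapse = "")
    if (!distinct_kmers) break
    starts <- seq_len(length - k + 1L)
    if (!anyDuplicated(substring(sense, starts, starts + k - 1L))) break
  }
  dsrna_construct(identifier, sense)
}

sample_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# ---- planted-site patterns ---------------------------------------------
#
# Each pattern is a deterministic construction rule on a source fragment,
# chosen to sit on a specific boundary of the filter funnel. Positions are
# guide coordinates (seed = 2..8). Patterns are defined at k = 21.

plant_patterns <- c("perfect", "one_mm_seed", "one_mm_nonseed",
                    "two_mm_nonseed", "near18_2mm", "identity16",
                    "decoy_identity14")

plant_mismatch_positions <- function(pattern) {
  switch(pattern,
    perfect = integer(0),
    # exactly one substitution inside the seed interval
    one_mm_seed = sample(2:8, 1L),
    # one substitution outside the seed (position 1 or 3' half)
    one_mm_nonseed = sample(c(1L, 9:21), 1L),
    two_mm_nonseed = sort(sample(9:21, 2L)),
    # both edges substituted: the 2-mismatch stretch spans the fragment
    near18_2mm = c(1L, 21L),
    # 5 substitutions in the 3' half -> exactly 16 identities; the rare
    # draw covering all of 19:21 is rejected so no 18-nt window with <= 2
    # mismatches can exist and criterion 2 deterministically fails
    identity16 = {
      repeat {
        p <- sort(sample(9:21, 5L))
        if (!all(19:21 %in% p)) break
      }
      p
    },
    # 7 substitutions: 14 identities, below every scan floor and preset
    decoy_identity14 = sort(sample(1:21, 7L)),
    stop("unknown plant pattern '", pattern, "'", call. = FALSE)
  )
}

# Expected retention per preset x combine mode, derived once from the
# pattern construction rules (closed form, independent of the pipeline):
#   - criterion 1 = (21 - n_mm) >= preset identity threshold
#   - criterion 2 at k=21 passes iff an 18/19-nt window holds <= 2
#     mismatches; true for every pattern with <= 2 mismatches, false for
#     identity16 (by its rejection constraint) and decoy; the chen preset's
#     26-nt stretch can never fire at k=21
#   - criterion 3 = no mismatch in 2..8
expected_retention_table <- function() {
  pat <- plant_patterns
  tab <- data.frame(
    pattern = pat,
    expected_text_or_then_seed    = pat %in% c("perfect", "one_mm_nonseed",
      "two_mm_nonseed", "near18_2mm", "identity16"),
    expected_figure6_or_then_seed = pat %in% c("perfect", "one_mm_nonseed",
      "two_mm_nonseed", "near18_2mm", "identity16"),
    expected_chen_or_then_seed    = pat %in% c("perfect", "one_mm_nonseed",
      "two_mm_nonseed", "near18_2mm", "identity16"),
    expected_text_and_chain       = pat %in% c("perfect", "one_mm_nonseed",
      "two_mm_nonseed", "near18_2mm"),
    expected_figure6_and_chain    = pat %in% c("perfect", "one_mm_nonseed",
      "two_mm_nonseed", "near18_2mm"),
    expected_chen_and_chain       = FALSE,
    stringsAsFactors = FALSE
  )
  tab
}

substitute_positions <- function(residues, positions) {
  ch <- strsplit(residues, "")[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Parse a plant specification string
#'
#' Turns `"perfect:5,one_mm_seed:10"` into the data.frame
#' [build_synthetic_db()] consumes (strand `"random"` for every entry).
#'
#' @param text Comma-separated `pattern:count` pairs.
#' @return data.frame with columns `pattern`, `count`, `strand`.
#' @export
parse_plant_spec <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(pattern = character(0), count = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(text, ",")[[1L]], ":")
  data.frame(
    pattern = vapply(parts, `[`, "", 1L),
    count = as.integer(vapply(parts, `[`, "", 2L)),
    strand = "random",
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic transcript database with planted off-target sites
#'
#' Emulates a non-target-organism transcript database: multi-record
#' sequences with lengths drawn from `len_range` at GC fraction `gc`, with
#' copies of construct fragments planted at controlled identity / mismatch
#' / seed structure (one site per transcript, on a recorded strand and
#' position) plus clean background transcripts. Ground truth, including the
#' expected retention of every site under every preset and combine mode, is
#' recorded at generation time from the pattern rules alone, never by
#' running the search pipeline — the truth table is an independent oracle.
#'
#' Background safety is enforced by patch-based rejection sampling: every
#' transcript is scanned against all fragments (both orientations) and any
#' window reaching `min_identities` identities that does not overlap the
#' planted site is re-rolled until the transcript is clean, so chance
#' background hits cannot occur at or above the scan floor.
#'
#' @param construct The [dsrna_construct()] whose fragments are planted.
#' @param specs data.frame with columns `pattern`, `count` and optionally
#'   `strand` (`"forward"`, `"reverse"` or `"random"`); or a spec string
#'   for [parse_plant_spec()].
#' @param n_background Number of clean background transcripts.
#' @param len_range Transcript length range in nt.
#' @param gc GC fraction of background sequence.
#' @param rng_seed Optional integer seed.
#' @param k Fragment length (patterns are defined at k = 21).
#' @param min_identities Scan floor used for the background cleanliness
#'   guarantee; use at least the floor of any config later screened.
#' @param max_retries Patch-rejection budget per transcript.
#' @return List with `db` (a [transcript_db()]) and `truth` (data.frame:
#'   `transcript_id`, `t_start`, `t_end`, `strand`, `source_fragment_id`,
#'   `source_residues`, `pattern`, `mismatch_positions`, plus one
#'   `expected_<preset>_<combine_mode>` column per funnel variant).
#' @export
build_synthetic_db <- function(construct, specs, n_background = 50L,
                               len_range = c(200L, 3000L), gc = 0.5,
                               rng_seed = NULL, k = 21L,
                               min_identities = 15L, max_retries = 50L) {
  if (is.character(specs)) specs <- parse_plant_spec(specs)
  stopifnot(inherits(construct, "dsrna_construct"),
            all(specs$pattern %in% plant_patterns))
  if (k != 21L) {
    stop("plant patterns are defined for k = 21", call. = FALSE)
  }
  if (is.null(specs$strand)) specs$strand <- "random"
  if (!is.null(rng_seed)) set.seed(rng_seed)

  fragments <- dice(construct, k = k)
  frag_fwd <- vapply(fragments$residues, encode_seq, integer(k),
                     USE.NAMES = FALSE)
  frag_rev <- vapply(reverse_complement(fragments$residues), encode_seq,
                     integer(k), USE.NAMES = FALSE)
  max_mm <- k - as.integer(min_identities)

  # windows (outside `protect`) matching any fragment on either strand at
  # >= min_identities; returns intervals to re-roll
  offending <- function(chars, protect) {
    enc <- encode_seq(paste(chars, collapse = ""))
    iv <- list()
    for (fm in list(frag_fwd, frag_rev)) {
      got <- .scan_batch_core(fm, enc, max_mm)
      for (s in got$t_start) {
        if (!is.null(protect) &&
            s <= protect[2L] && (s + k - 1L) >= protect[1L]) next
        iv[[length(iv) + 1L]] <- c(s, s + k - 1L)
      }
    }
    iv
  }

  make_transcript <- function(plant_site = NULL, plant_pos = NULL) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    chars <- sample_bases(len, gc)
    protect <- NULL
    if (!is.null(plant_site)) {
      if (is.null(plant_pos)) plant_pos <- sample.int(len - k + 1L, 1L)
      chars[plant_pos:(plant_pos + k - 1L)] <- strsplit(plant_site, "")[[1L]]
      protect <- c(plant_pos, plant_pos + k - 1L)
    }
    for (try in seq_len(max_retries)) {
      bad <- offending(chars, protect)
      if (!length(bad)) {
        return(list(residues = paste(chars, collapse = ""),
                    t_start = plant_pos))
      }
      for (iv in bad) {
        idx <- iv[1L]:iv[2L]
        if (!is.null(protect)) {
          idx <- idx[idx < protect[1L] | idx > protect[2L]]
        }
        chars[idx] <- sample_bases(length(idx), gc)
      }
    }
    stop("rejection sampling exceeded retry budget (", max_retries,
         "); background cannot be made clean at min_identities = ",
         min_identities, call. = FALSE)
  }

  exp_tab <- expected_retention_table()
  truth <- list()
  records <- list()
  idx <- 0L

  for (si in seq_len(nrow(specs))) {
    for (ci in seq_len(specs$count[si])) {
      idx <- idx + 1L
      pattern <- specs$pattern[si]
      fr <- fragments[sample.int(nrow(fragments), 1L), , drop = FALSE]
      mm <- as.integer(plant_mismatch_positions(pattern))
      guide_site <- substitute_positions(fr$residues, mm)
      strand <- specs$strand[si]
      if (strand == "random") strand <- sample(c("forward", "reverse"), 1L)
      site <- if (strand == "forward") guide_site else {
        reverse_complement(guide_site)
      }
      txp <- make_transcript(plant_site = site)
      tid <- sprintf("synthetic_t%03d_%s", idx, pattern)
      records[[idx]] <- data.frame(id = tid,
                                   description = paste("planted", pattern),
                                   residues = txp$residues,
                                   stringsAsFactors = FALSE)
      row <- data.frame(
        transcript_id = tid, t_start = txp$t_start,
        t_end = txp$t_start + k - 1L, strand = strand,
        source_fragment_id = fr$fragment_id,
        source_residues = fr$residues, pattern = pattern,
        mismatch_positions = paste(mm, collapse = ","),
        stringsAsFactors = FALSE
      )
      truth[[idx]] <- cbind(row, exp_tab[exp_tab$pattern == pattern,
                                         -1L, drop = FALSE])
    }
  }

  for (bi in seq_len(n_background)) {
    idx <- idx + 1L
    txp <- make_transcript()
    records[[idx]] <- data.frame(
      id = sprintf("synthetic_t%03d_background", idx),
      description = "background", residues = txp$residues,
      stringsAsFactors = FALSE)
  }

  truth <- if (length(truth)) {
    out <- do.call(rbind, truth)
    rownames(out) <- NULL
    out
  } else {
    cbind(data.frame(transcript_id = character(0), t_start = integer(0),
                     t_end = integer(0), strand = character(0),
                     source_fragment_id = character(0),
                     source_residues = character(0), pattern = character(0),
                     mismatch_positions = character(0),
                     stringsAsFactors = FALSE),
          expected_retention_table()[0, -1L, drop = FALSE])
  }
  db <- transcript_db(do.call(rbind, records), db_name = "synthetic_db")
  list(db = db, truth = truth)
}

#' Write synthetic study inputs to disk
#'
#' Emits `construct.fasta`, `db.fasta` and `truth.tsv` under `dir`.
#'
#' @param construct The [dsrna_construct()].
#' @param synth Result of [build_synthetic_db()].
#' @param dir Output directory (created if needed).
#' @param rng_seed Seed to record in the truth file header, if any.
#' @return Character vector of files written, invisibly.
#' @export
write_synthetic_data <- function(construct, synth, dir, rng_seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "construct.fasta")
  write_fasta(data.frame(id = construct$identifier,
                         residues = construct$sense,
                         stringsAsFactors = FALSE), f1)
  f2 <- file.path(dir, "db.fasta")
  write_fasta(synth$db$records, f2)
  f3 <- file.path(dir, "truth.tsv")
  truth <- synth$truth
  if (!is.null(rng_seed)) truth$rng_seed <- rng_seed
  write_tsv(truth, f3)
  invisible(c(f1, f2, f3))
}

#' Score pipeline recovery against planted ground truth
#'
#' Runs the full screen (fragmentation, search, funnel) on a synthetic
#' database and scores it against the truth table:
#'
#' * **sensitivity** — fraction of planted sites expected to be retained
#'   (under this config's preset / combine mode) whose exact placement
#'   (source fragment, transcript, start, strand) is retained;
#' * **false_positives** — retained hits whose placement does not overlap
#'   any planted interval (overlapping construct windows make shifted-
#'   fragment hits over a planted site inevitable, so attribution is by
#'   locus overlap);
#' * **seed_rejection_rate** — fraction of seed-mismatch plants whose
#'   exact placement was (correctly) not retained.
#'
#' @param construct The [dsrna_construct()] screened.
#' @param db The synthetic [transcript_db()].
#' @param truth Truth data.frame from [build_synthetic_db()].
#' @param config A [filter_config()]; its `min_identities` should not be
#'   below the floor the database was cleaned at.
#' @param hits Optional precomputed hit table from [search_db()] for this
#'   construct/database at a compatible scan floor, so several funnel
#'   variants can be scored on a single search.
#' @return An object of class `recovery_result`: list with `sensitivity`,
#'   `false_positives`, `n_expected`, `seed_rejection_rate`, the per-site
#'   `truth` table with `recovered` and `expected` columns attached, and
#'   the underlying `funnel_result`.
#' @export
recovery_test <- function(construct, db, truth, config = filter_config(),
                          hits = NULL) {
  if (is.null(hits)) {
    fragments <- enumerate_orientations(dice(construct, k = config$k),
                                        policy = config$orientation)
    hits <- search_db(fragments, db, config)
  }
  funnel <- apply_funnel(hits, config)
  dec <- funnel$decisions

  exp_col <- paste0("expected_", config$preset, "_", config$combine_mode)
  if (!exp_col %in% names(truth)) {
    stop("truth table lacks column ", exp_col, call. = FALSE)
  }
  truth$expected <- truth[[exp_col]]

  dec_key <- paste(dec$transcript_id, dec$t_start, dec$target_strand,
                   dec$fragment_id, sep = "\r")
  truth$recovered <- paste(truth$transcript_id, truth$t_start, truth$strand,
                           truth$source_fragment_id, sep = "\r") %in% dec_key

  n_expected <- sum(truth$expected)
  sensitivity <- if (n_expected) {
    sum(truth$recovered & truth$expected) / n_expected
  } else {
    NA_real_
  }

  # attribute each retained hit to a planted locus by interval overlap
  fp <- 0L
  if (nrow(dec)) {
    attributed <- vapply(seq_len(nrow(dec)), function(i) {
      tt <- truth[truth$transcript_id == dec$transcript_id[i], , drop = FALSE]
      any(dec$t_start[i] <= tt$t_end & dec$t_end[i] >= tt$t_start)
    }, logical(1))
    fp <- sum(!attributed)
  }

  seed_rows <- truth$pattern == "one_mm_seed"
  seed_rejection_rate <- if (any(seed_rows)) {
    mean(!truth$recovered[seed_rows])
  } else {
    NA_real_
  }

  structure(list(
    sensitivity = sensitivity,
    false_positives = fp,
    n_expected = n_expected,
    seed_rejection_rate = seed_rejection_rate,
    truth = truth,
    funnel = funnel
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("recovery_result: sensitivity ",
      ifelse(is.na(x$sensitivity), "n/a", format(x$sensitivity)),
      " (", x$n_expected, " expected sites), ", x$false_positives,
      " false positive(s), seed rejection ",
      ifelse(is.na(x$seed_rejection_rate), "n/a",
             format(x$seed_rejection_rate)), "\n", sep = "")
  invisible(x)
}
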