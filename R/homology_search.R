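#' Build a transcript database object
#'
#' @param records A data.frame with columns `id` and `residues` (e.g. from
#'   [read_fasta()]); a `description` column is kept for annotation joining.
#' @param db_name Name stamped into hits and reports.
#' @return An object of class `transcript_db`.
#' @export
transcript_db <- function(records, db_name = "db") {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate transcript identifiers in database '", db_name, "'",
         call. = FALSE)
  }
  if (nrow(records)) {
    records$residues <- normalize_residues(records$residues)
  }
  if (is.null(records$description)) {
    records$description <- character(nrow(records))
  }
  structure(list(records = records, db_name = db_name),
            class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("transcript_db '", x$db_name, "': ", nrow(x$records),
      " transcripts, lengths ", min(nchar(x$records$residues)), "-",
      max(nchar(x$records$residues)), " nt\n", sep = "")
  invisible(x)
}

#' Stretch statistics of a mismatch pattern
#'
#' Given the guide-coordinate positions of the mismatches in a full-length
#' gapless placement of a k-nt fragment, computes the two stretch statistics
#' the filter funnel reads: the longest contiguous perfectly matched run,
#' and the longest contiguous stretch containing at most `m` mismatches
#' ("near-perfect" stretch).
#'
#' @param mismatch_positions Sorted unique integer positions in 1..k.
#' @param k Fragment length.
#' @param m Mismatch budget for the near-perfect stretch (default 2).
#' @return Named numeric vector `c(longest_perfect_run, best_near_perfect)`.
#' @export
#' @examples
#' run_statistics(c(2, 8, 15), 21) # longest perfect run 6, near-perfect 19
run_statistics <- function(mismatch_positions, k, m = 2L) {
  k <- as.integer(k)
  pos <- as.integer(mismatch_positions)
  if (length(pos)) {
    if (any(pos < 1L | pos > k)) {
      stop("mismatch position out of 1..k", call. = FALSE)
    }
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("mismatch positions must be sorted and unique", call. = FALSE)
    }
  }
  # sentinel mismatches just outside the fragment bound every run
  ps <- c(0L, pos, k + 1L)
  lpr <- max(diff(ps) - 1L)
  n_mm <- length(pos)
  if (n_mm <= m) {
    bnp <- k
  } else {
    # maximal windows with <= m mismatches run between mismatch i and
    # mismatch i+m+1 (exclusive); slide that pair over the sorted list
    i <- seq_len(n_mm - m + 1L)
    bnp <- max(ps[i + m + 1L] - ps[i] - 1L)
  }
  c(longest_perfect_run = lpr, best_near_perfect = bnp)
}

# Hit table skeleton shared by scan paths.
empty_hits <- function() {
  df <- data.frame(
    fragment_id = character(0), parent_start = integer(0),
    orientation = character(0), transcript_id = character(0),
    t_start = integer(0), t_end = integer(0), target_strand = character(0),
    identities = integer(0), mismatches = character(0),
    longest_perfect_run = integer(0), best_near_perfect = integer(0),
    stringsAsFactors = FALSE
  )
  df$mismatch_positions <- list()
  df
}

# Assemble a hit data.frame from raw kernel output for one fragment row.
# rev_strand placements come from scanning the reverse complement of the
# fragment along the transcript forward strand; their kernel mismatch
# positions are in reverse-complement coordinates and are mapped back to
# guide coordinates (5' end of the guide = position 1).
build_hits <- function(frag_row, transcript_id, t_start, mm_list, strand, m) {
  k <- frag_row$k
  if (strand == "reverse") {
    mm_list <- lapply(mm_list, function(p) sort(k + 1L - p))
  }
  n <- length(t_start)
  stats <- vapply(mm_list, run_statistics, numeric(2), k = k, m = m)
  df <- data.frame(
    fragment_id = rep(frag_row$fragment_id, n),
    parent_start = rep(frag_row$start, n),
    orientation = rep(frag_row$orientation, n),
    transcript_id = rep(transcript_id, n),
    t_start = as.integer(t_start),
    t_end = as.integer(t_start) + k - 1L,
    target_strand = rep(strand, n),
    identities = k - lengths(mm_list),
    mismatches = vapply(mm_list, paste, "", collapse = ","),
    longest_perfect_run = as.integer(stats[1L, ]),
    best_near_perfect = as.integer(stats[2L, ]),
    stringsAsFactors = FALSE
  )
  df$mismatch_positions <- mm_list
  df
}

#' Scan one fragment against one transcript
#'
#' Evaluates every full-length gapless placement of the fragment on the
#' transcript forward strand, and of its reverse complement (reported as
#' `target_strand = "reverse"` with mismatch positions mapped back to guide
#' coordinates), keeping placements with at least `min_identities` matching
#' bases. This replaces a heuristic local aligner with an exhaustive scan:
#' for 21-nt queries every filter criterion is a function of a gapless
#' placement, and exhaustiveness removes seeding sensitivity.
#'
#' @param fragment One row of a fragment data.frame (from [dice()]).
#' @param transcript A list/row with `id` and `residues`, or a single
#'   sequence string.
#' @param min_identities Minimum identities (0..k) for a placement to be
#'   reported (default 15, the loosest identity bound any preset uses).
#' @param m Mismatch budget used for the `best_near_perfect` statistic.
#' @return Hit data.frame, sorted by identities descending then `t_start`
#'   ascending. Columns as in [search_db()]. Transcripts shorter than k
#'   yield an empty result with a warning.
#' @export
scan_fragment <- function(fragment, transcript, min_identities = 15L,
                          m = 2L) {
  if (is.character(transcript)) {
    transcript <- list(id = "transcript", residues = transcript)
  }
  k <- fragment$k
  if (min_identities < 0L) {
    stop("min_identities must be non-negative", call. = FALSE)
  }
  if (min_identities > k) {
    # an unattainable identity floor is a valid (if degenerate) setting
    return(empty_hits())
  }
  txp <- normalize_residues(transcript$residues)
  if (nchar(txp) < k) {
    warning("transcript '", transcript$id, "' shorter than k (",
            nchar(txp), " < ", k, "); skipped", call. = FALSE)
    return(empty_hits())
  }
  max_mm <- k - as.integer(min_identities)
  txp_enc <- encode_seq(txp)
  fwd <- .scan_core(encode_seq(fragment$residues), txp_enc, max_mm)
  rev <- .scan_core(encode_seq(reverse_complement(fragment$residues)),
                    txp_enc, max_mm)
  hits <- rbind(
    build_hits(fragment, transcript$id, fwd$t_start, fwd$mismatches,
               "forward", m),
    build_hits(fragment, transcript$id, rev$t_start, rev$mismatches,
               "reverse", m)
  )
  hits[order(-hits$identities, hits$t_start,
             match(hits$target_strand, c("forward", "reverse"))), ,
       drop = FALSE]
}

#' Search a fragment set against a transcript database
#'
#' Batch orchestration of [scan_fragment()] over all (fragment, transcript)
#' pairs. Hits are deduplicated on (fragment residues, transcript, start,
#' strand) so duplicate fragments produced with `dedupe = FALSE` cannot
#' inflate the hit table, and globally ordered by (transcript_id, t_start,
#' fragment_index) so reports are byte-reproducible.
#'
#' @param fragments Fragment data.frame ([dice()] /
#'   [enumerate_orientations()]).
#' @param db A [transcript_db()].
#' @param config A [filter_config()]; supplies `min_identities` (scan-time
#'   floor) and the near-perfect mismatch budget.
#' @param verbose Log per-database progress to stderr.
#' @return Hit data.frame with columns `fragment_id`, `parent_start`,
#'   `orientation`, `transcript_id`, `t_start`, `t_end`, `target_strand`,
#'   `identities`, `mismatches` (comma-joined guide positions),
#'   `longest_perfect_run`, `best_near_perfect`, plus a `mismatch_positions`
#'   list column. Attributes `db_name` and `n_fragments` record provenance.
#' @export
search_db <- function(fragments, db, config = filter_config(),
                      verbose = FALSE) {
  stopifnot(inherits(db, "transcript_db"))
  if (!nrow(fragments)) {
    stop("no fragments to search", call. = FALSE)
  }
  if (!nrow(db$records)) {
    stop("empty transcript database '", db$db_name, "'", call. = FALSE)
  }
  k <- unique(fragments$k)
  stopifnot(length(k) == 1L)
  max_mm <- k - config$min_identities
  m <- config$max_mismatches_in_stretch
  if (max_mm < 0L) {
    # identity floor above k: nothing can ever qualify
    hits <- empty_hits()
    attr(hits, "db_name") <- db$db_name
    attr(hits, "n_fragments") <- nrow(fragments)
    attr(hits, "k") <- k
    return(hits)
  }

  short <- nchar(db$records$residues) < k
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than k in '", db$db_name,
            "' skipped: ", paste(db$records$id[short], collapse = ", "),
            call. = FALSE)
  }

  # one k x n_frag matrix per strand; batch kernel call per transcript
  frag_fwd <- vapply(fragments$residues, encode_seq, integer(k),
                     USE.NAMES = FALSE)
  frag_rev <- vapply(reverse_complement(fragments$residues), encode_seq,
                     integer(k), USE.NAMES = FALSE)

  out <- list()
  for (ti in which(!short)) {
    txp_enc <- encode_seq(db$records$residues[ti])
    tid <- db$records$id[ti]
    for (strand in c("forward", "reverse")) {
      fm <- if (strand == "forward") frag_fwd else frag_rev
      res <- .scan_batch_core(fm, txp_enc, max_mm)
      if (!length(res$t_start)) next
      mm_list <- res$mismatches
      if (strand == "reverse") {
        mm_list <- lapply(mm_list, function(p) sort(k + 1L - p))
      }
      stats <- vapply(mm_list, run_statistics, numeric(2), k = k, m = m)
      fr <- res$frag
      df <- data.frame(
        fragment_id = fragments$fragment_id[fr],
        parent_start = fragments$start[fr],
        orientation = fragments$orientation[fr],
        transcript_id = rep(tid, length(fr)),
        t_start = res$t_start,
        t_end = res$t_start + k - 1L,
        target_strand = rep(strand, length(fr)),
        identities = k - lengths(mm_list),
        mismatches = vapply(mm_list, paste, "", collapse = ","),
        longest_perfect_run = as.integer(stats[1L, ]),
        best_near_perfect = as.integer(stats[2L, ]),
        stringsAsFactors = FALSE
      )
      df$mismatch_positions <- mm_list
      df$.fragment_index <- fragments$fragment_index[fr]
      df$.residues <- fragments$residues[fr]
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) {
    hits <- empty_hits()
  } else {
    hits <- do.call(rbind, out)
    dup <- duplicated(paste(hits$.residues, hits$transcript_id, hits$t_start,
                            hits$target_strand, sep = "\r"))
    hits <- hits[!dup, , drop = FALSE]
    hits <- hits[order(hits$transcript_id, hits$t_start,
                       hits$.fragment_index,
                       match(hits$target_strand, c("forward", "reverse"))), ,
                 drop = FALSE]
    hits$.fragment_index <- NULL
    hits$.residues <- NULL
    rownames(hits) <- NULL
  }
  if (verbose) {
    message("search_db['", db$db_name, "']: ", nrow(fragments),
            " fragments x ", sum(!short), " transcripts -> ", nrow(hits),
            " hits (identities >= ", config$min_identities, ")")
  }
  attr(hits, "db_name") <- db$db_name
  attr(hits, "n_fragments") <- nrow(fragments)
  attr(hits, "k") <- k
  hits
}

#' Write a hit table as TSV
#'
#' Fixed column order, header row, LF endings; the `mismatches` column holds
#' comma-joined guide coordinates.
#'
#' @param hits Hit data.frame from [search_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("fragment_id", "parent_start", "orientation", "transcript_id",
            "t_start", "t_end", "target_strand", "identities", "mismatches",
            "longest_perfect_run", "best_near_perfect")
  extra <- intersect(c("passes_identity", "passes_near_perfect",
                       "passes_seed", "retained", "class_label"),
                     names(hits))
  write_tsv(hits[, c(cols, extra), drop = FALSE], path)
}

# Shared TSV writer: tab-separated, header, UTF-8, LF, byte-stable.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t"))
  )
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
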