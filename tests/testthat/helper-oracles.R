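# Independent oracles and fixture builders. These deliberately share no
# code with the package internals: the comparator is a plain double loop
# over offsets, the stretch-statistic oracle enumerates every window, and
# the complement table is written out by hand.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Naive comparator: every full-length placement of the fragment on both
# transcript strands, position by position; N never matches. Returns the
# hit set with mismatch positions in guide coordinates.
oracle_scan <- function(frag, txp, min_identities) {
  k <- nchar(frag)
  n <- nchar(txp)
  out <- list()
  if (n < k) {
    return(data.frame(t_start = integer(0), target_strand = character(0),
                      identities = integer(0), mismatches = character(0),
                      stringsAsFactors = FALSE))
  }
  tc <- strsplit(txp, "")[[1]]
  for (strand in c("forward", "reverse")) {
    q <- if (strand == "forward") frag else oracle_revcomp(frag)
    qc <- strsplit(q, "")[[1]]
    for (off in seq_len(n - k + 1L)) {
      w <- tc[off:(off + k - 1L)]
      mm <- which(qc != w | qc == "N" | w == "N")
      if (k - length(mm) >= min_identities) {
        gm <- if (strand == "forward") mm else sort(k + 1L - mm)
        out[[length(out) + 1L]] <- data.frame(
          t_start = off, target_strand = strand,
          identities = k - length(mm),
          mismatches = paste(gm, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(t_start = integer(0), target_strand = character(0),
                      identities = integer(0), mismatches = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Exhaustive window enumeration of the two stretch statistics: every
# (i, j) window, mismatch counts via cumulative sums.
oracle_run_stats <- function(pos, k, m) {
  ind <- tabulate(pos, nbins = k)
  cs <- c(0L, cumsum(ind))
  i <- rep(seq_len(k), times = k - seq_len(k) + 1L)
  j <- unlist(lapply(seq_len(k), function(a) a:k))
  counts <- cs[j + 1L] - cs[i]
  len <- j - i + 1L
  c(longest_perfect_run = max(len[counts == 0L], 0L),
    best_near_perfect = max(len[counts <= m], 0L))
}

# Canonicalize a hit table for set comparison against the oracle.
hit_key <- function(df) {
  sort(paste(df$t_start, df$target_strand, df$identities, df$mismatches,
             sep = "|"))
}

# Minimal synthetic hit rows with the columns evaluate_criteria() needs.
make_hits <- function(mm_sets, k = 21L) {
  n <- length(mm_sets)
  stats <- vapply(mm_sets, run_statistics, numeric(2), k = k, m = 2L)
  df <- data.frame(
    fragment_id = sprintf("frag%03d", seq_len(n)),
    parent_start = seq_len(n),
    orientation = rep("sense", n),
    transcript_id = sprintf("t%03d", seq_len(n)),
    t_start = rep(1L, n), t_end = rep(k, n),
    target_strand = rep("forward", n),
    identities = k - lengths(mm_sets),
    mismatches = vapply(mm_sets, paste, "", collapse = ","),
    longest_perfect_run = as.integer(stats[1L, ]),
    best_near_perfect = as.integer(stats[2L, ]),
    stringsAsFactors = FALSE
  )
  df$mismatch_positions <- lapply(mm_sets, as.integer)
  df
}

# Small clean transcript database with one fragment planted verbatim.
plant_in_background <- function(frag, len, at, gc = 0.5) {
  k <- nchar(frag)
  chars <- strsplit(rand_seq(len, gc), "")[[1]]
  chars[at:(at + k - 1L)] <- strsplit(frag, "")[[1]]
  paste(chars, collapse = "")
}
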