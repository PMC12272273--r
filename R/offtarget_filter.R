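#' Filter-funnel configuration
#'
#' Bundles the thresholds of the three-tier off-target filter funnel:
#'
#' 1. overall identity: at least `min_total_identities` matching bases over
#'    the full k-nt placement (the "~80% similarity" rule, 16/21);
#' 2. near-perfect stretch: a contiguous stretch of at least
#'    `min_near_perfect_len` aligned positions containing at most
#'    `max_mismatches_in_stretch` mismatches;
#' 3. seed identity: no mismatch within guide positions
#'    `seed_start..seed_end` (closed interval, default 2-8) — perfect seed
#'    complementarity dominates both on- and off-target silencing.
#'
#' Three named presets ship: `"text"` (16/18, the default), `"figure6"`
#' (15/19, the mismatch-class summary convention), and `"chen"` (16/26, the
#' published dsRNA-level criteria these were adapted from; its 26-nt
#' near-perfect rule is recorded verbatim but can never fire on 21-nt
#' fragments, see the methods vignette). `combine_mode` selects how the
#' criteria compose: `"or_then_seed"` retains `(1 OR 2) AND 3`;
#' `"and_chain"` requires all three.
#'
#' @param preset `"text"`, `"figure6"` or `"chen"`; sets the two identity
#'   thresholds unless overridden explicitly.
#' @param min_total_identities Criterion 1 threshold (identities over k).
#' @param min_near_perfect_len Criterion 2 stretch length.
#' @param max_mismatches_in_stretch Mismatch budget inside the stretch.
#' @param seed_start,seed_end Seed interval in guide coordinates.
#' @param combine_mode `"or_then_seed"` (default) or `"and_chain"`.
#' @param min_identities Scan-time identity floor; hits below it are never
#'   materialized. Default 15, the loosest bound any preset can need.
#' @param k Fragment length the thresholds refer to.
#' @param orientation Fragment orientation policy for pipeline wrappers.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(preset = c("text", "figure6", "chen"),
                          min_total_identities = NULL,
                          min_near_perfect_len = NULL,
                          max_mismatches_in_stretch = 2L,
                          seed_start = 2L, seed_end = 8L,
                          combine_mode = c("or_then_seed", "and_chain"),
                          min_identities = 15L,
                          k = 21L,
                          orientation = c("both", "sense_only")) {
  preset <- match.arg(preset)
  combine_mode <- match.arg(combine_mode)
  orientation <- match.arg(orientation)
  defaults <- switch(preset,
    text    = c(16L, 18L),
    figure6 = c(15L, 19L),
    chen    = c(16L, 26L)
  )
  if (is.null(min_total_identities)) min_total_identities <- defaults[1L]
  if (is.null(min_near_perfect_len)) min_near_perfect_len <- defaults[2L]
  k <- as.integer(k)
  if (!(seed_start >= 1L && seed_start <= seed_end && seed_end <= k)) {
    stop("seed interval must satisfy 1 <= seed_start <= seed_end <= k",
         call. = FALSE)
  }
  if (min_total_identities > k) {
    stop("min_total_identities exceeds fragment length k", call. = FALSE)
  }
  structure(list(
    preset = preset,
    min_total_identities = as.integer(min_total_identities),
    min_near_perfect_len = as.integer(min_near_perfect_len),
    max_mismatches_in_stretch = as.integer(max_mismatches_in_stretch),
    seed_start = as.integer(seed_start),
    seed_end = as.integer(seed_end),
    combine_mode = combine_mode,
    min_identities = as.integer(min_identities),
    k = k,
    orientation = orientation
  ), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config [preset=", x$preset, ", combine=", x$combine_mode,
      "]\n  criterion 1: identities >= ", x$min_total_identities, "/", x$k,
      "\n  criterion 2: stretch >= ", x$min_near_perfect_len, " nt with <= ",
      x$max_mismatches_in_stretch, " mismatches",
      "\n  criterion 3: no mismatch in seed ", x$seed_start, "-", x$seed_end,
      "\n  scan floor : identities >= ", x$min_identities, "\n", sep = "")
  invisible(x)
}

#' Seed-region identity of a hit
#'
#' TRUE iff the hit has no mismatch within the seed interval
#' (`seed_start..seed_end`, guide coordinates of the fragment as oriented in
#' the hit; position 1 — the 5'-most guide base — is outside the default
#' seed 2-8).
#'
#' @param hit One hit row (or a list with `mismatch_positions`).
#' @param config A [filter_config()].
#' @return Logical flag.
#' @export
seed_identical <- function(hit, config = filter_config()) {
  mm <- hit$mismatch_positions
  if (is.list(mm)) mm <- mm[[1L]]
  !any(mm >= config$seed_start & mm <= config$seed_end)
}

#' Evaluate the funnel criteria on a hit table
#'
#' Appends per-criterion flags, the overall `retained` flag and the
#' mismatch-class label to a hit table. The class label follows the
#' convention `"<identities> bp (<span>), <n> mismatch(es)"` where the span
#' is the aligned region in guide coordinates (always `1-k` for full-length
#' placements).
#'
#' @param hits Hit data.frame from [search_db()] / [scan_fragment()].
#' @param config A [filter_config()].
#' @return `hits` with columns `passes_identity`, `passes_near_perfect`,
#'   `passes_seed`, `retained` and `class_label` appended.
#' @export
evaluate_criteria <- function(hits, config = filter_config()) {
  k <- if (nrow(hits)) {
    hits$t_end[1L] - hits$t_start[1L] + 1L
  } else {
    config$k
  }
  mm <- hits$mismatch_positions
  # recompute the near-perfect statistic when the configured budget differs
  # from the scan-time default stored on the hit table
  bnp <- if (identical(config$max_mismatches_in_stretch, 2L) &&
             !is.null(hits$best_near_perfect)) {
    hits$best_near_perfect
  } else {
    vapply(mm, function(p) run_statistics(p, k,
      config$max_mismatches_in_stretch)[["best_near_perfect"]], numeric(1))
  }
  hits$passes_identity <- hits$identities >= config$min_total_identities
  hits$passes_near_perfect <- bnp >= config$min_near_perfect_len
  hits$passes_seed <- !vapply(mm, function(p) {
    any(p >= config$seed_start & p <= config$seed_end)
  }, logical(1))
  hits$retained <- if (config$combine_mode == "or_then_seed") {
    (hits$passes_identity | hits$passes_near_perfect) & hits$passes_seed
  } else {
    hits$passes_identity & hits$passes_near_perfect & hits$passes_seed
  }
  n_mm <- lengths(mm)
  hits$class_label <- sprintf("%d bp (1–%d), %d mismatch%s",
                              hits$identities, k, n_mm,
                              ifelse(n_mm == 1L, "", "es"))
  hits
}

#' Apply the filter funnel to a hit table
#'
#' Runs [evaluate_criteria()] and splits the result into the retained
#' decisions (order preserved) and an audit tally of survivors at each
#' stage.
#'
#' @param hits Deduplicated hit data.frame.
#' @param config A [filter_config()].
#' @return An object of class `funnel_result`: list with `decisions` (the
#'   retained rows, criterion flags attached), `counts` (named vector:
#'   `input`, `crit1`, `crit2`, `crit1_or_2`, `seed`, `retained`) and
#'   `config`; `db_name`/`n_fragments` attributes are carried over from the
#'   hit table when present.
#' @export
apply_funnel <- function(hits, config = filter_config()) {
  dec <- evaluate_criteria(hits, config)
  counts <- c(
    input = nrow(dec),
    crit1 = sum(dec$passes_identity),
    crit2 = sum(dec$passes_near_perfect),
    crit1_or_2 = sum(dec$passes_identity | dec$passes_near_perfect),
    seed = sum(dec$passes_seed),
    retained = sum(dec$retained)
  )
  structure(list(
    decisions = dec[dec$retained, , drop = FALSE],
    counts = counts,
    config = config,
    db_name = attr(hits, "db_name"),
    n_fragments = attr(hits, "n_fragments"),
    k = attr(hits, "k")
  ), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("funnel_result [", x$config$preset, "/", x$config$combine_mode,
      "]: ", x$counts[["input"]], " hits -> ", x$counts[["retained"]],
      " retained\n", sep = "")
  invisible(x)
}

#' Write the funnel audit as JSON
#'
#' @param funnel A `funnel_result` from [apply_funnel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_funnel_audit <- function(funnel, path) {
  audit <- c(as.list(funnel$counts),
             list(preset = funnel$config$preset,
                  combine_mode = funnel$config$combine_mode))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(audit, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
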