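#' Mismatch-class distribution of retained decisions
#'
#' Groups retained hits by their class label
#' (`"<identities> bp (1–k), <n> mismatch(es)"`) — the summary convention
#' used to visualize how close the surviving off-target sites are to
#' perfect complementarity. Counts partition the retained set.
#'
#' @param decisions Retained decision data.frame (from [apply_funnel()]'s
#'   `decisions` element, or a `funnel_result`).
#' @return data.frame with columns `class_label` and `count`, ordered by
#'   count descending then label.
#' @export
class_distribution <- function(decisions) {
  if (inherits(decisions, "funnel_result")) decisions <- decisions$decisions
  if (!nrow(decisions)) {
    return(data.frame(class_label = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(decisions$class_label)
  out <- data.frame(class_label = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$class_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate funnel decisions into an off-target report
#'
#' Produces the two output shapes a risk screen reports: a per-transcript
#' table of retained off-target sites (how many sites, which fragments, the
#' best identity) and the mismatch-class distribution, alongside funnel
#' totals and a snapshot of the configuration used.
#'
#' @param funnel A `funnel_result` from [apply_funnel()].
#' @param db The [transcript_db()] that was searched (supplies annotation
#'   descriptions from the FASTA headers; must match the database the
#'   decisions came from).
#' @param construct_id Identifier of the screened construct.
#' @return An object of class `offtarget_report`: list with `db_name`,
#'   `construct_id`, `config`, `funnel_counts`, `per_transcript` (ordered
#'   by `n_retained_sites` descending then transcript id),
#'   `class_distribution`, and `totals` (`n_fragments`, `n_hits_prefilter`,
#'   `n_retained`).
#' @export
aggregate_report <- function(funnel, db, construct_id = "construct") {
  stopifnot(inherits(funnel, "funnel_result"), inherits(db, "transcript_db"))
  if (!is.null(funnel$db_name) && !identical(funnel$db_name, db$db_name)) {
    stop("decisions come from database '", funnel$db_name,
         "' but were aggregated against '", db$db_name, "'", call. = FALSE)
  }
  dec <- funnel$decisions
  if (nrow(dec)) {
    split_dec <- split(dec, dec$transcript_id)
    per_transcript <- data.frame(
      transcript_id = names(split_dec),
      n_retained_sites = vapply(split_dec, nrow, integer(1)),
      fragment_ids = vapply(split_dec, function(d) {
        paste(unique(d$fragment_id), collapse = ",")
      }, ""),
      best_identities = vapply(split_dec, function(d) {
        max(d$identities)
      }, integer(1)),
      stringsAsFactors = FALSE
    )
    per_transcript$description <- db$records$description[
      match(per_transcript$transcript_id, db$records$id)]
    per_transcript <- per_transcript[
      order(-per_transcript$n_retained_sites, per_transcript$transcript_id), ,
      drop = FALSE]
    rownames(per_transcript) <- NULL
  } else {
    per_transcript <- data.frame(
      transcript_id = character(0), n_retained_sites = integer(0),
      fragment_ids = character(0), best_identities = integer(0),
      description = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    db_name = db$db_name,
    construct_id = construct_id,
    config = funnel$config,
    funnel_counts = funnel$counts,
    per_transcript = per_transcript,
    class_distribution = class_distribution(dec),
    decisions = dec,
    totals = c(n_fragments = funnel$n_fragments %||% NA_integer_,
               n_hits_prefilter = funnel$counts[["input"]],
               n_retained = funnel$counts[["retained"]])
  ), class = "offtarget_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.offtarget_report <- function(x, ...) {
  cat("off-target report: construct '", x$construct_id, "' vs database '",
      x$db_name, "'\n", sep = "")
  cat("  preset ", x$config$preset, ", combine ", x$config$combine_mode,
      "\n", sep = "")
  cat("  fragments screened : ", x$totals[["n_fragments"]], "\n", sep = "")
  cat("  hits >= ", x$config$min_identities, " identities: ",
      x$totals[["n_hits_prefilter"]], "\n", sep = "")
  cat("  retained off-target sites: ", x$totals[["n_retained"]], " on ",
      nrow(x$per_transcript), " transcript(s)\n", sep = "")
  if (nrow(x$class_distribution)) {
    cat("  mismatch classes:\n")
    apply(x$class_distribution, 1L, function(r) {
      cat("    ", r[["class_label"]], ": ", r[["count"]], "\n", sep = "")
    })
  }
  invisible(x)
}

#' Write an off-target report to disk
#'
#' Emits `per_transcript.tsv`, `class_distribution.tsv`, `hits.tsv` (the
#' retained decisions with criterion flags), `funnel_audit.json` and
#' `report.json` (the full report, schema-versioned) under `dir`. Output is
#' byte-stable given identical inputs: fixed column orders, LF endings,
#' UTF-8.
#'
#' @param report An `offtarget_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "offtarget_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  if ("tsv" %in% formats) {
    f1 <- file.path(dir, "per_transcript.tsv")
    write_tsv(report$per_transcript, f1)
    f2 <- file.path(dir, "class_distribution.tsv")
    write_tsv(report$class_distribution, f2)
    f3 <- file.path(dir, "hits.tsv")
    write_hits_tsv(report$decisions, f3)
    written <- c(written, f1, f2, f3)
  }
  if ("json" %in% formats) {
    f4 <- file.path(dir, "funnel_audit.json")
    audit <- c(as.list(report$funnel_counts),
               list(preset = report$config$preset,
                    combine_mode = report$config$combine_mode))
    write_json_stable(audit, f4)
    f5 <- file.path(dir, "report.json")
    payload <- list(
      schema_version = "1.0",
      db_name = report$db_name,
      construct_id = report$construct_id,
      config = unclass(report$config),
      funnel_counts = as.list(report$funnel_counts),
      totals = as.list(report$totals),
      per_transcript = report$per_transcript,
      class_distribution = report$class_distribution
    )
    write_json_stable(payload, f5)
    written <- c(written, f4, f5)
  }
  invisible(written)
}

write_json_stable <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return Parsed list (data.frame-valued where the report held tables).
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Run the full off-target screen
#'
#' Convenience wrapper chaining fragmentation, orientation enumeration,
#' database search, the filter funnel and report aggregation; optionally
#' writes the report. This is the function the command-line entry point and
#' the reproducibility checks call.
#'
#' @param construct A [dsrna_construct()], a sequence string, or a path to
#'   a single-record FASTA file.
#' @param db A [transcript_db()] or a path to a multi-record FASTA file.
#' @param config A [filter_config()].
#' @param k Fragment length.
#' @param out_dir If non-NULL, [write_report()] destination.
#' @param verbose Log progress to stderr.
#' @return The `offtarget_report`.
#' @export
run_screen <- function(construct, db, config = filter_config(), k = 21L,
                       out_dir = NULL, verbose = FALSE) {
  if (is.character(construct) && file.exists(construct)) {
    rec <- read_fasta(construct)
    if (nrow(rec) != 1L) {
      stop("construct FASTA must contain exactly one record", call. = FALSE)
    }
    construct <- dsrna_construct(rec$id[1L], rec$residues[1L])
  } else if (is.character(construct)) {
    construct <- dsrna_construct("construct", construct)
  }
  if (is.character(db)) {
    db <- transcript_db(read_fasta(db),
                        db_name = sub("\\.[^.]*$", "", basename(db)))
  }
  fragments <- enumerate_orientations(dice(construct, k = k),
                                      policy = config$orientation)
  hits <- search_db(fragments, db, config, verbose = verbose)
  funnel <- apply_funnel(hits, config)
  report <- aggregate_report(funnel, db, construct_id = construct$identifier)
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}
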