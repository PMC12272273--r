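#' Create a dsRNA construct object
#'
#' Wraps the sense-strand sequence of a dsRNA construct. The construct is
#' the molecule a spray-induced-gene-silencing (SIGS) product delivers; its
#' Dicer products are what can silence off-target transcripts.
#'
#' @param identifier Construct name.
#' @param sense Sense-strand sequence (normalized on ingest).
#' @return An object of class `dsrna_construct`: a list with elements
#'   `identifier` and `sense`.
#' @export
dsrna_construct <- function(identifier, sense) {
  sense <- normalize_residues(sense)
  stopifnot(length(identifier) == 1L, length(sense) == 1L)
  structure(list(identifier = as.character(identifier), sense = sense),
            class = "dsrna_construct")
}

#' @export
print.dsrna_construct <- function(x, ...) {
  cat("dsRNA construct '", x$identifier, "': ", nchar(x$sense), " nt\n",
      sep = "")
  invisible(x)
}

#' Fragment a dsRNA construct into all k-mer windows (in silico Dicer)
#'
#' Dicer cleaves dsRNA into ~21-nt siRNAs without a universal sequence
#' preference, so the conservative emulation enumerates every window of
#' length `k` at 1-nt steps along the sense strand. With `dedupe = TRUE`
#' (the default) windows with identical residues collapse to their first
#' occurrence, giving the set of unique candidate siRNAs: a 398-nt construct
#' with all 21-mers distinct yields 398 - 21 + 1 = 378 unique fragments.
#'
#' @param construct A [dsrna_construct()], or a single sequence string.
#' @param k Fragment length in nt (default 21, the canonical siRNA length).
#'   Must be >= 8 so the fragment contains a full seed region (positions
#'   2-8).
#' @param dedupe Collapse duplicate residue strings to the first occurrence.
#' @return A data.frame of fragments with columns `fragment_id`,
#'   `parent_id`, `start` (1-based window start on the sense strand), `k`,
#'   `residues`, `orientation` (`"sense"`) and `fragment_index` (serial
#'   number in generation order). Positions within a fragment are numbered
#'   1..k from its 5' end ("guide coordinates") everywhere downstream.
#' @export
#' @examples
#' frags <- dice(dsrna_construct("c1", strrep("ACGTT", 10)), k = 21)
#' nrow(frags)
dice <- function(construct, k = 21L, dedupe = TRUE) {
  if (is.character(construct)) {
    construct <- dsrna_construct("construct", construct)
  }
  stopifnot(inherits(construct, "dsrna_construct"))
  k <- as.integer(k)
  if (k < 8L) {
    stop("k must be >= 8 so a fragment contains the full seed region (2-8)",
         call. = FALSE)
  }
  L <- nchar(construct$sense)
  if (L < k) {
    stop("construct shorter than fragment length (", L, " < ", k, ")",
         call. = FALSE)
  }
  starts <- seq_len(L - k + 1L)
  residues <- substring(construct$sense, starts, starts + k - 1L)
  if (dedupe) {
    keep <- !duplicated(residues)
    starts <- starts[keep]
    residues <- residues[keep]
  }
  data.frame(
    fragment_id = paste0(construct$identifier, "|start=", starts,
                         "|ori=sense"),
    parent_id = construct$identifier,
    start = starts,
    k = k,
    residues = residues,
    orientation = "sense",
    fragment_index = seq_along(starts),
    stringsAsFactors = FALSE
  )
}

#' Add antisense-strand fragments to a fragment set
#'
#' A dsRNA duplex is processed into siRNA duplexes, and either strand can be
#' loaded as the guide. `policy = "both"` (the recommended default
#' downstream) appends, for every sense fragment, an antisense fragment
#' whose residues are the reverse complement of the same parent window;
#' `policy = "sense_only"` returns the input unchanged, reproducing a
#' minimal sense-strand-only reading.
#'
#' @param fragments Fragment data.frame from [dice()].
#' @param policy `"both"` or `"sense_only"`.
#' @param dedupe Drop appended fragments whose residues duplicate an
#'   existing fragment (e.g. windows that are their own reverse complement).
#' @return Fragment data.frame; `fragment_index` renumbered in output order.
#' @export
enumerate_orientations <- function(fragments,
                                   policy = c("both", "sense_only"),
                                   dedupe = TRUE) {
  policy <- match.arg(policy)
  if (policy == "sense_only") {
    return(fragments)
  }
  anti <- fragments
  anti$residues <- reverse_complement(fragments$residues)
  anti$orientation <- "antisense"
  anti$fragment_id <- paste0(anti$parent_id, "|start=", anti$start,
                             "|ori=antisense")
  out <- rbind(fragments, anti)
  if (dedupe) {
    out <- out[!duplicated(out$residues), , drop = FALSE]
  }
  out$fragment_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export fragments as FASTA
#'
#' Headers encode provenance (`parent|start=<i>|ori=<orientation>`) so any
#' downstream tool can recover the window each siRNA candidate came from.
#'
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_fasta <- function(fragments, path) {
  write_fasta(data.frame(id = fragments$fragment_id,
                         residues = fragments$residues,
                         stringsAsFactors = FALSE), path)
}
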