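#' Read a multi-record FASTA file of nucleotide sequences
#'
#' Parses a FASTA file and normalizes every sequence to the DNA alphabet:
#' residues are upper-cased and U is converted to T on ingest (the construct
#' is RNA-derived but all matching is done in DNA space). Any character
#' outside `A, C, G, T, U, N` (after case folding) is rejected with an error
#' naming the record and line, as are duplicate identifiers, empty sequences
#' and sequence data appearing before the first header.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with one row per record and columns `id`,
#'   `description` (header text after the first whitespace, `""` if absent)
#'   and `residues`. Record order is preserved.
#' @seealso [write_fasta()], [reverse_complement()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 demo", "acgu", ">t2", "ACGTN"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  ids <- character(0)
  descs <- character(0)
  seqs <- list()
  cur <- NULL # index of record being accumulated

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      header <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) {
        stop("malformed FASTA header (empty identifier) at line ", i,
             call. = FALSE)
      }
      if (id %in% ids) {
        stop("duplicate FASTA identifier '", id, "' at line ", i,
             call. = FALSE)
      }
      if (!is.null(cur) && !nzchar(seqs[[cur]])) {
        stop("empty sequence for record '", ids[cur], "' (line ", i, ")",
             call. = FALSE)
      }
      ids <- c(ids, id)
      desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
      descs <- c(descs, desc)
      cur <- length(ids)
      seqs[[cur]] <- ""
    } else if (grepl("\\S", ln)) {
      if (is.null(cur)) {
        stop("sequence data before first FASTA header at line ", i,
             call. = FALSE)
      }
      chunk <- gsub("\\s", "", ln)
      bad <- regmatches(chunk, regexpr("[^ACGTUNacgtun]", chunk))
      if (length(bad) && nzchar(bad)) {
        stop("illegal character '", bad, "' in record '", ids[cur],
             "' at line ", i, call. = FALSE)
      }
      seqs[[cur]] <- paste0(seqs[[cur]], chunk)
    }
  }
  if (is.null(cur)) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  if (!nzchar(seqs[[cur]])) {
    stop("empty sequence for record '", ids[cur], "' (end of file)",
         call. = FALSE)
  }

  data.frame(
    id = ids,
    description = descs,
    residues = normalize_residues(unlist(seqs)),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' Output is byte-stable: 80-column wrapping, LF line endings, UTF-8.
#'
#' @param x A data.frame with columns `id` and `residues` (optionally
#'   `description`, appended to the header after a space), or a named
#'   character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- data.frame(id = names(x), residues = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  nm <- x$id
  if (!is.null(x$description)) {
    has_desc <- nzchar(x$description)
    nm[has_desc] <- paste(x$id[has_desc], x$description[has_desc])
  }
  set <- Biostrings::DNAStringSet(x$residues)
  names(set) <- nm
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`. Vectorized
#' over its input. Needed for antisense-strand handling: an siRNA duplex
#' contributes guides from both strands of the parent dsRNA.
#'
#' @param seq Character vector of sequences over `A, C, G, T, N`
#'   (lowercase and `U` accepted and normalized first).
#' @return Character vector of reverse complements, same length as `seq`.
#' @export
#' @examples
#' reverse_complement("AAAC") # "GTTT"
reverse_complement <- function(seq) {
  seq <- normalize_residues(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Normalize residues to the uppercase DNA alphabet
#'
#' Upper-cases, converts U to T, and rejects anything outside
#' `A, C, G, T, N`. Internal workhorse behind every sequence ingest point.
#'
#' @param residues Character vector of raw sequences.
#' @return Character vector of normalized sequences.
#' @keywords internal
normalize_residues <- function(residues) {
  if (!is.character(residues) || any(is.na(residues))) {
    stop("residues must be a character vector without NA", call. = FALSE)
  }
  out <- chartr("u", "t", residues)
  out <- toupper(out)
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1], regexpr("[^ACGTN]", out[bad][1]))
    stop("illegal character '", ch, "' in sequence", call. = FALSE)
  }
  if (any(!nzchar(out))) {
    stop("empty sequence", call. = FALSE)
  }
  out
}

# Integer encoding used by the compiled scan kernel: A=1 C=2 G=3 T=4 N=0.
# N never counts as an identity (conservative for risk screening).
encode_seq <- function(residues) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 0L
  lut[utf8ToInt(residues)]
}
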