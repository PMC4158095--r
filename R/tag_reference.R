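TAG_ANCHOR <- "CATG"
TAG_LENGTH <- 21L

#' Extract all CATG-anchored 21-mer tags from a sequence
#'
#' Models the NlaIII/MmeI digestion of the DGE-tag protocol in silico:
#' NlaIII recognises CATG and MmeI cuts 17 bp downstream of the site, so
#' every CATG occurrence with at least \code{min_downstream} following bases
#' yields one candidate tag of \code{CATG} plus the next 17 bases (21 bp
#' total).  Occurrences whose 17-base window contains a non-ACGT character
#' are skipped rather than raising an error.
#'
#' @param sequence A single DNA string.  Case-insensitive; characters
#'   outside A/C/G/T are permitted in the input but disqualify any tag
#'   window that contains them.
#' @param min_downstream Number of bases required downstream of the CATG
#'   anchor (default 17, the MmeI cut distance).
#' @return A data.frame with columns \code{offset} (0-based position of the
#'   C of CATG, ascending) and \code{tag} (the 21-mer), zero rows when the
#'   sequence has no usable site.
#' @examples
#' extract_tags(paste0("CATG", strrep("A", 17)))
#' @export
extract_tags <- function(sequence, min_downstream = 17L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  empty <- data.frame(offset = integer(0), tag = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) < 4L + min_downstream) return(empty)
  sequence <- toupper(sequence)
  hits <- gregexpr(TAG_ANCHOR, sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  starts <- as.integer(hits)                      # 1-based position of C
  starts <- starts[starts + 3L + min_downstream <= nchar(sequence)]
  if (length(starts) == 0L) return(empty)
  tags <- substring(sequence, starts, starts + 3L + min_downstream)
  keep <- !grepl("[^ACGT]", tags)
  data.frame(offset = starts[keep] - 1L, tag = tags[keep],
             stringsAsFactors = FALSE)
}

new_tag_db <- function(tags, sources, source_kind) {
  structure(list(source_kind = source_kind,
                 tags = tags,
                 sources = sources,
                 n_distinct_tags = length(tags)),
            class = "tag_db")
}

#' @export
print.tag_db <- function(x, ...) {
  cat(sprintf("Reference tag database (%s): %d distinct %d-mer tags\n",
              x$source_kind, x$n_distinct_tags, TAG_LENGTH))
  invisible(x)
}

# Collapse (tag, source) pairs into a tag_db.  Pairs need not be unique.
aggregate_tag_db <- function(tag, source, source_kind) {
  if (length(tag) == 0L) {
    return(new_tag_db(character(0), list(), source_kind))
  }
  pairs <- unique(data.frame(tag = tag, source = source,
                             stringsAsFactors = FALSE))
  sources <- split(pairs$source, pairs$tag)
  new_tag_db(names(sources), unname(sources), source_kind)
}

read_fasta_checked <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Build the transcript reference tag database
#'
#' Enumerates every possible CATG + 17 nt tag over all records of a
#' transcript FASTA, on the sense strand only (tags derive from mRNA).  A
#' tag occurring in several genes maps to all of them.
#'
#' @param fasta_path Path to a (possibly line-wrapped) multi-record FASTA;
#'   record ids must be unique.
#' @return An object of class \code{tag_db} with \code{source_kind
#'   = "transcript"}; sources are gene ids.
#' @export
build_transcript_db <- function(fasta_path) {
  seqs <- read_fasta_checked(fasta_path)
  per_rec <- lapply(as.character(seqs), extract_tags)
  n <- vapply(per_rec, nrow, integer(1))
  aggregate_tag_db(unlist(lapply(per_rec, `[[`, "tag"), use.names = FALSE),
                   rep(names(seqs), n), "transcript")
}

#' Build the genome reference tag database
#'
#' As \code{\link{build_transcript_db}} but tags are extracted from both
#' strands, and each source id records the sequence id, the 0-based
#' forward-strand offset of the leftmost base of the 21-mer window, and the
#' strand, formatted \code{"seqid:offset:strand"}.
#'
#' @inheritParams build_transcript_db
#' @return A \code{tag_db} with \code{source_kind = "genome"}.
#' @export
build_genome_db <- function(fasta_path) {
  seqs <- read_fasta_checked(fasta_path)
  tag <- character(0); src <- character(0)
  for (id in names(seqs)) {
    s <- as.character(seqs[[id]])
    len <- nchar(s)
    fwd <- extract_tags(s)
    rev <- extract_tags(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))
    tag <- c(tag, fwd$tag, rev$tag)
    src <- c(src,
             if (nrow(fwd)) paste(id, fwd$offset, "+", sep = ":"),
             if (nrow(rev)) paste(id, len - TAG_LENGTH - rev$offset, "-",
                                  sep = ":"))
  }
  aggregate_tag_db(tag, src, "genome")
}

# All Hamming-distance-1 variants of each query tag, mismatches restricted
# to the 17 nt suffix when anchor_strict.  Returns a data.frame
# (query_index, variant); queries themselves are not included.
tag_neighbourhood <- function(tags, anchor_strict = TRUE) {
  bases <- c("A", "C", "G", "T")
  pos <- if (anchor_strict) 5:TAG_LENGTH else 1:TAG_LENGTH
  n <- length(tags)
  qi <- integer(0); var <- character(0)
  for (p in pos) {
    orig <- substring(tags, p, p)
    for (b in bases) {
      keep <- orig != b
      if (!any(keep)) next
      v <- tags[keep]
      substring(v, p, p) <- b
      qi <- c(qi, which(keep))
      var <- c(var, v)
    }
  }
  data.frame(query_index = qi, variant = var, stringsAsFactors = FALSE)
}

# Vectorised lookup used by the mapping stage.  For each query tag, exact
# hits take priority; only queries without an exact hit are searched at
# Hamming distance 1 (within the suffix when anchor_strict).  Returns a
# list with per-query source lists and match types.
lookup_tags <- function(db, tags, max_mismatch = 1L, anchor_strict = TRUE) {
  stopifnot(inherits(db, "tag_db"))
  bad <- nchar(tags) != TAG_LENGTH
  if (any(bad)) {
    stop("query tag(s) of wrong length: ",
         paste(utils::head(tags[bad], 3L), collapse = ", "))
  }
  n <- length(tags)
  sources <- vector("list", n)
  type <- rep("none", n)
  hit <- match(tags, db$tags)
  exact <- !is.na(hit)
  sources[exact] <- db$sources[hit[exact]]
  type[exact] <- "exact"
  if (max_mismatch >= 1L && any(!exact)) {
    idx <- which(!exact)
    nb <- tag_neighbourhood(tags[idx], anchor_strict)
    m <- match(nb$variant, db$tags)
    found <- !is.na(m)
    if (any(found)) {
      per_query <- split(m[found], idx[nb$query_index[found]])
      for (k in names(per_query)) {
        i <- as.integer(k)
        sources[[i]] <- unique(unlist(db$sources[per_query[[k]]],
                                      use.names = FALSE))
        type[i] <- "mismatch"
      }
    }
  }
  list(sources = sources, match_type = type)
}

#' Look up a tag in a reference tag database
#'
#' Exact hits always take priority: the 1-mismatch neighbourhood is searched
#' only when the query has no exact hit, and (by default) mismatches are
#' tolerated only within the 17 nt suffix because the CATG anchor is
#' enzymatically defined.
#'
#' @param db A \code{tag_db}.
#' @param tag A single 21-character tag.
#' @param max_mismatch 0 or 1.
#' @param anchor_strict If TRUE (default) the CATG anchor must match
#'   exactly; set FALSE to allow a mismatch anywhere in the 21-mer.
#' @return A list with \code{sources} (character vector of source ids,
#'   empty when unmatched), \code{match_type} ("exact", "mismatch" or
#'   "none"), and \code{unambiguous} (TRUE when the sources are exactly one
#'   identifier).
#' @export
lookup <- function(db, tag, max_mismatch = 1L, anchor_strict = TRUE) {
  res <- lookup_tags(db, tag, max_mismatch, anchor_strict)
  src <- res$sources[[1L]]
  if (is.null(src)) src <- character(0)
  list(sources = src, match_type = res$match_type[1L],
       unambiguous = length(src) == 1L)
}

#' Write a reference tag database to TSV
#'
#' @param db A \code{tag_db}.
#' @param path Output path; columns \code{tag}, \code{source_kind},
#'   \code{source_ids} (comma-joined).
#' @export
write_tag_db <- function(db, path) {
  stopifnot(inherits(db, "tag_db"))
  utils::write.table(
    data.frame(tag = db$tags, source_kind = db$source_kind,
               source_ids = vapply(db$sources, paste, "", collapse = ","),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
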