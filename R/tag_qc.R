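# Filtering of raw tag reads into clean tag libraries, abundance profiling
# and sequencing-saturation analysis.

FILTER_REASONS <- c("empty", "adaptor_only", "anchor_missing",
                    "low_quality", "length", "singleton")

new_tag_library <- function(tags, raw_tags, distinct_raw, filter_counts,
                            library_id = NA_character_,
                            species = NA_character_, stage = NA_character_,
                            replicate = NA_integer_) {
  structure(list(library_id = library_id, species = species, stage = stage,
                 replicate = replicate, tags = tags,
                 raw_tags = raw_tags, clean_tags = sum(tags),
                 distinct_raw = distinct_raw, distinct_clean = length(tags),
                 filter_counts = filter_counts),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("Tag library %s (%s / %s / rep %s)\n",
              x$library_id, x$species, x$stage, x$replicate))
  cat(sprintf("  raw tags: %d  clean tags: %d (%.2f%%)  distinct clean: %d\n",
              x$raw_tags, x$clean_tags,
              if (x$raw_tags > 0) 100 * x$clean_tags / x$raw_tags else 0,
              x$distinct_clean))
  removed <- x$filter_counts[x$filter_counts > 0]
  if (length(removed))
    cat("  filtered:", paste(names(removed), removed, sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Filter raw tag records into a clean tag library
#'
#' Applies the clean-tag definition of the DGE protocol: adaptor-only and
#' empty records, low-quality records (any N base, or any base below
#' \code{quality_floor} when qualities are supplied), and records that are
#' not 21 bp after trimming are removed; the remainder is aggregated to
#' copy numbers and tags seen only once are dropped.  Reads longer than
#' 21 bp (e.g. raw 49 bp sequencer reads) are truncated to their first
#' 21 bases provided they start with the CATG anchor; reads that do not are
#' counted under filter reason \code{anchor_missing}.
#'
#' @param records Character vector of raw tag reads (21 bp tags or longer
#'   raw reads).
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   parallel to \code{records}.
#' @param adaptor Adaptor sequence; records exactly equal to it are counted
#'   as \code{adaptor_only}.
#' @param quality_floor Minimum acceptable Phred score when qualities are
#'   given (default 10).
#' @param library_id,species,stage,replicate Library metadata carried on
#'   the result.
#' @return A \code{tag_library}: clean tag copy numbers plus the full
#'   filtering account (raw = clean mass + removals).
#' @export
clean_library <- function(records, qualities = NULL,
                          adaptor = "TCGTATGCCGTCTTCTGCTTG",
                          quality_floor = 10L,
                          library_id = NA_character_,
                          species = NA_character_, stage = NA_character_,
                          replicate = NA_integer_) {
  stopifnot(is.character(records))
  if (!is.null(qualities)) stopifnot(length(qualities) == length(records))
  raw_tags <- length(records)
  records <- toupper(records)
  distinct_raw <- length(unique(records[!is.na(records) & records != ""]))
  filter_counts <- stats::setNames(integer(length(FILTER_REASONS)),
                                   FILTER_REASONS)
  drop <- function(mask, reason) {
    filter_counts[reason] <<- filter_counts[reason] + sum(mask)
    records <<- records[!mask]
    if (!is.null(qualities)) qualities <<- qualities[!mask]
  }

  drop(is.na(records) | records == "", "empty")
  drop(records == toupper(adaptor), "adaptor_only")

  # raw reads longer than one tag: keep the leading CATG..+17 window
  long <- nchar(records) > TAG_LENGTH
  no_anchor <- long & !startsWith(records, TAG_ANCHOR)
  drop(no_anchor, "anchor_missing")
  long <- nchar(records) > TAG_LENGTH
  records[long] <- substring(records[long], 1L, TAG_LENGTH)
  if (!is.null(qualities)) {
    qlong <- nchar(qualities) > TAG_LENGTH
    qualities[qlong] <- substring(qualities[qlong], 1L, TAG_LENGTH)
  }

  lowq <- grepl("[^ACGT]", records)
  if (!is.null(qualities) && length(records)) {
    minq <- vapply(qualities, function(q) {
      if (nchar(q) == 0L) return(Inf)
      min(utf8ToInt(q)) - 33L
    }, numeric(1), USE.NAMES = FALSE)
    lowq <- lowq | (minq < quality_floor)
  }
  drop(lowq, "low_quality")
  drop(nchar(records) != TAG_LENGTH, "length")

  counts <- table(records)
  singletons <- counts < 2L
  filter_counts["singleton"] <- sum(counts[singletons])
  counts <- counts[!singletons]
  tags <- stats::setNames(as.integer(counts), names(counts))
  new_tag_library(tags, raw_tags = raw_tags, distinct_raw = distinct_raw,
                  filter_counts = filter_counts, library_id = library_id,
                  species = species, stage = stage, replicate = replicate)
}

#' Build a tag library from pre-counted tags
#'
#' For inputs already aggregated to (tag, copy number); applies only the
#' copy-number and length filters.
#'
#' @param counts Named integer vector (names = tag sequences).
#' @inheritParams clean_library
#' @return A \code{tag_library}.
#' @export
library_from_counts <- function(counts, library_id = NA_character_,
                                species = NA_character_,
                                stage = NA_character_,
                                replicate = NA_integer_) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  raw <- sum(counts)
  distinct_raw <- sum(counts > 0)
  filter_counts <- stats::setNames(integer(length(FILTER_REASONS)),
                                   FILTER_REASONS)
  ok_len <- nchar(names(counts)) == TAG_LENGTH &
    !grepl("[^ACGT]", toupper(names(counts)))
  filter_counts["length"] <- sum(counts[!ok_len])
  counts <- counts[ok_len]
  single <- counts < 2L
  filter_counts["singleton"] <- sum(counts[single])
  counts <- counts[!single]
  new_tag_library(stats::setNames(as.integer(counts),
                                  toupper(names(counts))),
                  raw_tags = as.integer(raw), distinct_raw = distinct_raw,
                  filter_counts = filter_counts, library_id = library_id,
                  species = species, stage = stage, replicate = replicate)
}

#' Read a tag library from FASTQ or a two-column TSV
#'
#' @param path FASTQ (4-line records; extension .fastq/.fq) or TSV with
#'   columns tag and count.
#' @inheritParams clean_library
#' @param ... Passed to \code{\link{clean_library}} for FASTQ input.
#' @return A \code{tag_library}.
#' @export
read_tag_library <- function(path, library_id = NA_character_,
                             species = NA_character_,
                             stage = NA_character_,
                             replicate = NA_integer_, ...) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    clean_library(as.character(fq),
                  qualities = as.character(Biostrings::quality(fq)),
                  library_id = library_id, species = species, stage = stage,
                  replicate = replicate, ...)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("tag", "count") %in% names(tab)))
    library_from_counts(stats::setNames(tab$count, tab$tag),
                        library_id = library_id, species = species,
                        stage = stage, replicate = replicate)
  }
}

#' Tag abundance profile over copy-number bins
#'
#' Tabulates clean-tag mass and distinct-tag counts over copy-number bins,
#' reproducing the skewed picture typical of DGE libraries: a small number
#' of high-copy tags carries most of the sequenced mass while most distinct
#' tags sit at copy numbers 2-5.
#'
#' @param lib A \code{tag_library}.
#' @param breaks Lower bin edges (default \code{c(2, 6, 11, 21, 51, 101)},
#'   i.e. bins [2,5], [6,10], [11,20], [21,50], [51,100], >100).
#' @return data.frame with one row per bin: \code{bin}, \code{mass},
#'   \code{distinct}, \code{mass_fraction}, \code{distinct_fraction}.
#'   Fractions are of clean totals and each sum to 1 (all-zero for an empty
#'   library).
#' @export
abundance_profile <- function(lib, breaks = c(2, 6, 11, 21, 51, 101)) {
  stopifnot(inherits(lib, "tag_library"))
  upper <- c(breaks[-1L] - 1L, Inf)
  labels <- ifelse(is.finite(upper), paste0("[", breaks, ",", upper, "]"),
                   paste0(">", breaks - 1L))
  cn <- unname(lib$tags)
  bin <- findInterval(cn, breaks)
  mass <- distinct <- numeric(length(breaks))
  for (b in seq_along(breaks)) {
    sel <- bin == b
    mass[b] <- sum(cn[sel])
    distinct[b] <- sum(sel)
  }
  data.frame(bin = labels, mass = mass, distinct = distinct,
             mass_fraction = if (lib$clean_tags > 0) mass / lib$clean_tags
                             else 0 * mass,
             distinct_fraction = if (lib$distinct_clean > 0)
                                   distinct / lib$distinct_clean
                                 else 0 * distinct,
             stringsAsFactors = FALSE)
}

#' Sequencing saturation curve
#'
#' Subsamples the library (without replacement, nested so that each larger
#' sample contains every smaller one) at increasing depths and counts the
#' genes detected by at least one unambiguously mapped tag.  Nesting makes
#' the curve monotone non-decreasing exactly, not just in expectation; a
#' plateau indicates sequencing saturation.
#'
#' @param lib A clean \code{tag_library}.
#' @param db Transcript \code{tag_db}.
#' @param depths Ascending vector of subsampling depths (tag copies);
#'   depths beyond the library size are capped with a warning.
#' @param seed Integer seed for the subsampling permutation.
#' @param max_mismatch,anchor_strict Mapping options, as
#'   \code{\link{lookup}}.
#' @return data.frame with columns \code{depth} and \code{genes}.
#' @export
saturation_curve <- function(lib, db, depths, seed = 1L,
                             max_mismatch = 1L, anchor_strict = TRUE) {
  stopifnot(inherits(lib, "tag_library"), inherits(db, "tag_db"),
            !is.unsorted(depths))
  if (any(depths > lib$clean_tags)) {
    warning("depth(s) beyond library size capped at ", lib$clean_tags)
    depths <- pmin(depths, lib$clean_tags)
  }
  tags <- names(lib$tags)
  res <- lookup_tags(db, tags, max_mismatch, anchor_strict)
  unamb <- lengths(res$sources) == 1L
  gene <- rep(NA_character_, length(tags))
  gene[unamb] <- vapply(res$sources[unamb], `[[`, "", 1L)

  # permute tag copies once; a gene is detected at depth d iff the first
  # occurrence of one of its unambiguous tags falls within the first d draws
  expanded <- rep(seq_along(tags), unname(lib$tags))
  perm <- with_seed(seed, sample(expanded))
  first_pos <- rep(NA_integer_, length(tags))
  firsts <- !duplicated(perm)
  first_pos[perm[firsts]] <- which(firsts)
  ok <- !is.na(gene)
  gene_first <- tapply(first_pos[ok], gene[ok], min)
  genes_at <- vapply(depths, function(d) sum(gene_first <= d), numeric(1))
  data.frame(depth = depths, genes = as.integer(genes_at))
}

#' QC summary table for a set of libraries
#'
#' One row per library mirroring the classic raw/distinct/clean accounting.
#'
#' @param libs List of \code{tag_library} objects.
#' @return data.frame with raw, distinct raw, clean (with percentage),
#'   distinct clean (with percentage) and per-reason filter counts.
#' @export
qc_summary <- function(libs) {
  rows <- lapply(libs, function(l) {
    fc <- as.list(l$filter_counts)
    names(fc) <- paste0("filtered_", names(fc))
    c(list(library_id = l$library_id, species = l$species, stage = l$stage,
           replicate = l$replicate, raw_tags = l$raw_tags,
           distinct_raw = l$distinct_raw, clean_tags = l$clean_tags,
           clean_pct = if (l$raw_tags > 0)
             round(100 * l$clean_tags / l$raw_tags, 2) else NA_real_,
           distinct_clean = l$distinct_clean,
           distinct_clean_pct = if (l$distinct_raw > 0)
             round(100 * l$distinct_clean / l$distinct_raw, 2)
           else NA_real_),
      fc)
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
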