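# Mapping of clean tags to the transcript tag database (with genome
# fallback), per-gene unambiguous counts and TPM normalisation.

#' Map a clean tag library against the reference tag databases
#'
#' Each distinct clean tag is looked up in the transcript database (exact
#' match first, then a single mismatch in the 17 nt suffix).  Tags whose
#' hits fall in exactly one gene ("unambiguous" tags) contribute their full
#' copy number to that gene's count; tags hitting several genes count only
#' toward the all-mapped mass; tags with no transcript hit are looked up in
#' the genome database; whatever remains is "unknown" mass.  Ambiguous tags
#' are wholly excluded from gene counts — no fractional allocation.
#'
#' @param lib A clean \code{tag_library}.
#' @param tdb Transcript \code{tag_db}.
#' @param gdb Optional genome \code{tag_db}; when missing, the genome
#'   category is reported as NA and the unknown category absorbs the
#'   remainder.
#' @param max_mismatch,anchor_strict Lookup options (see
#'   \code{\link{lookup}}).
#' @return A list with \code{counts} (named numeric vector of unambiguous
#'   tag mass per gene, over the full gene universe of \code{tdb}) and
#'   \code{summary} (one-row data.frame of the mapping-category account:
#'   masses and percentages for gene-mapped, unambiguous, genome-mapped and
#'   unknown tags, plus detected gene counts).
#' @export
map_library <- function(lib, tdb, gdb = NULL, max_mismatch = 1L,
                        anchor_strict = TRUE) {
  stopifnot(inherits(lib, "tag_library"), inherits(tdb, "tag_db"),
            tdb$source_kind == "transcript")
  genes <- gene_universe(tdb)
  counts <- stats::setNames(numeric(length(genes)), genes)
  tags <- names(lib$tags)
  mass <- as.numeric(unname(lib$tags))
  clean <- lib$clean_tags

  if (length(tags)) {
    res <- lookup_tags(tdb, tags, max_mismatch, anchor_strict)
    nhit <- lengths(res$sources)
    unamb <- nhit == 1L
    ambig <- nhit > 1L
    if (any(unamb)) {
      g <- vapply(res$sources[unamb], `[[`, "", 1L)
      add <- tapply(mass[unamb], g, sum)
      counts[names(add)] <- counts[names(add)] + add
    }
    gene_mapped <- sum(mass[nhit > 0L])
    unambiguous_mass <- sum(mass[unamb])
    genes_any <- length(unique(unlist(res$sources, use.names = FALSE)))
    genes_unamb <- sum(counts > 0)

    rest <- nhit == 0L
    genome_mass <- NA_real_
    if (!is.null(gdb)) {
      stopifnot(inherits(gdb, "tag_db"))
      genome_mass <- 0
      if (any(rest)) {
        gres <- lookup_tags(gdb, tags[rest], max_mismatch, anchor_strict)
        genome_mass <- sum(mass[rest][lengths(gres$sources) > 0L])
      }
      unknown <- clean - gene_mapped - genome_mass
    } else {
      unknown <- clean - gene_mapped
    }
  } else {
    gene_mapped <- unambiguous_mass <- 0
    genes_any <- genes_unamb <- 0L
    genome_mass <- if (is.null(gdb)) NA_real_ else 0
    unknown <- 0
  }

  pct <- function(x) if (clean > 0) 100 * x / clean else NA_real_
  summary <- data.frame(
    library_id = lib$library_id, clean_tags = clean,
    gene_mapped_mass = gene_mapped, gene_mapped_pct = pct(gene_mapped),
    unambiguous_mass = unambiguous_mass,
    unambiguous_pct = pct(unambiguous_mass),
    genes_with_any_tag = genes_any,
    genes_with_unambiguous_tag = genes_unamb,
    genome_mapped_mass = genome_mass, genome_mapped_pct = pct(genome_mass),
    unknown_mass = unknown, unknown_pct = pct(unknown),
    stringsAsFactors = FALSE)
  list(counts = counts, summary = summary)
}

gene_universe <- function(tdb) {
  sort(unique(unlist(tdb$sources, use.names = FALSE)))
}

#' TPM normalisation of a tag count matrix
#'
#' Tags per million clean tags: each column is scaled by its library's
#' clean-tag total, \code{TPM = count / denominator * 1e6}.  The
#' denominator defaults to clean tags (not unambiguous mass), so column
#' sums of TPM equal \code{1e6 * unambiguous mass / clean tags}.
#'
#' @param counts genes x libraries numeric matrix.
#' @param denominators Per-library positive totals, one per column.
#' @return Matrix of TPM values, same dimnames as \code{counts}.
#' @export
tpm_normalize <- function(counts, denominators) {
  stopifnot(is.matrix(counts), length(denominators) == ncol(counts))
  if (any(denominators <= 0)) stop("denominators must be > 0")
  sweep(counts, 2L, denominators, "/") * 1e6
}

#' Build the genes x libraries expression matrix
#'
#' Maps every library (see \code{\link{map_library}}) and assembles the
#' unambiguous count matrix, its TPM normalisation and the per-library
#' mapping summary.
#'
#' @param libs List of clean \code{tag_library} objects.
#' @param tdb,gdb,max_mismatch,anchor_strict As \code{\link{map_library}}.
#' @return An object of class \code{tag_expr}: list with \code{counts},
#'   \code{tpm} (genes x libraries matrices), \code{denominators}
#'   (clean-tag totals), \code{design} (library metadata data.frame) and
#'   \code{mapping} (per-library mapping summary).
#' @export
build_expression_matrix <- function(libs, tdb, gdb = NULL,
                                    max_mismatch = 1L,
                                    anchor_strict = TRUE) {
  stopifnot(length(libs) > 0)
  ids <- vapply(libs, `[[`, "", "library_id")
  if (anyDuplicated(ids)) stop("duplicate library ids")
  mapped <- lapply(libs, map_library, tdb = tdb, gdb = gdb,
                   max_mismatch = max_mismatch,
                   anchor_strict = anchor_strict)
  counts <- do.call(cbind, lapply(mapped, `[[`, "counts"))
  colnames(counts) <- ids
  denominators <- stats::setNames(
    vapply(libs, `[[`, numeric(1), "clean_tags"), ids)
  design <- data.frame(
    library_id = ids,
    species = vapply(libs, `[[`, "", "species"),
    stage = vapply(libs, `[[`, "", "stage"),
    replicate = vapply(libs, function(l) as.integer(l$replicate),
                       integer(1)),
    stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 tpm = tpm_normalize(counts, denominators),
                 denominators = denominators, design = design,
                 mapping = do.call(rbind, lapply(mapped, `[[`, "summary"))),
            class = "tag_expr")
}

#' @export
print.tag_expr <- function(x, ...) {
  cat(sprintf("Tag expression matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  mean unambiguous mapping: %.2f%% of clean tags\n",
              mean(x$mapping$unambiguous_pct)))
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' One row per gene; per library one count column and one TPM column.
#'
#' @param expr A \code{tag_expr}.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "tag_expr"))
  out <- data.frame(gene = rownames(expr$counts), stringsAsFactors = FALSE)
  for (lib in colnames(expr$counts)) {
    out[[paste0(lib, "_count")]] <- expr$counts[, lib]
    out[[paste0(lib, "_tpm")]] <- expr$tpm[, lib]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pearson correlation of expression between replicate pairs
#'
#' Reproducibility check in the style of replicate TPM scatter plots:
#' Pearson R of TPM over genes for each (species, stage) replicate pair.
#'
#' @param expr A \code{tag_expr} whose design has two replicates per
#'   (species, stage).
#' @return data.frame with species, stage and the correlation \code{r}.
#' @export
replicate_correlation <- function(expr) {
  stopifnot(inherits(expr, "tag_expr"))
  d <- expr$design
  groups <- unique(d[, c("species", "stage")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    ids <- d$library_id[d$species == groups$species[i] &
                        d$stage == groups$stage[i]]
    if (length(ids) != 2L)
      stop("expected exactly 2 replicates for ", groups$species[i], "/",
           groups$stage[i])
    data.frame(species = groups$species[i], stage = groups$stage[i],
               r = stats::cor(expr$tpm[, ids[1L]], expr$tpm[, ids[2L]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
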