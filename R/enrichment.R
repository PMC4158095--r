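# Hypergeometric term enrichment of DEG sets against a user-supplied
# gene -> term annotation (GO terms, KEGG pathways or any other
# categorical annotation: the test is identical).

#' Read a gene -> term annotation table
#'
#' Expected TSV columns: \code{gene_id}, \code{term_id}, and optionally
#' \code{term_name} and \code{namespace}.  Standard GAF/OBO ingestion is
#' out of scope; convert such files to this four-column layout upstream.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with the four columns (missing optional columns
#'   filled with NA).
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "term_id") %in% names(tab)))
  if (is.null(tab$term_name)) tab$term_name <- NA_character_
  if (is.null(tab$namespace)) tab$namespace <- NA_character_
  unique(tab[, c("gene_id", "term_id", "term_name", "namespace")])
}

#' Hypergeometric enrichment of a DEG set
#'
#' For each annotated term, with N the number of genes carrying any
#' annotation, n the number of differentially expressed genes within those
#' N, M the number of genes annotated to the term and m the number of DEGs
#' among them, the enrichment P value is the hypergeometric upper tail
#' P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n).  Genes
#' lacking any annotation are excluded from both N and n.  P values are
#' adjusted across tested terms by Benjamini-Hochberg.
#'
#' @param degs Character vector of differentially expressed gene ids.
#' @param annotation data.frame as returned by
#'   \code{\link{read_annotation}}.
#' @param alpha_p,alpha_q Significance thresholds reported on the result
#'   (defaults 0.05 each).
#' @return data.frame sorted by P with one row per term: term_id,
#'   term_name, namespace, N, n, M, m, P, Q, significant.  Empty (with a
#'   warning) when no DEG carries an annotation.
#' @export
enrich <- function(degs, annotation, alpha_p = 0.05, alpha_q = 0.05) {
  stopifnot(is.character(degs) || length(degs) == 0,
            all(c("gene_id", "term_id") %in% names(annotation)))
  annotation <- unique(annotation[, intersect(
    c("gene_id", "term_id", "term_name", "namespace"), names(annotation))])
  universe <- unique(annotation$gene_id)
  N <- length(universe)
  degs <- unique(intersect(degs, universe))
  n <- length(degs)
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), N = integer(0),
                      n = integer(0), M = integer(0), m = integer(0),
                      P = numeric(0), Q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("no differentially expressed gene carries an annotation")
    return(empty)
  }
  terms <- split(annotation$gene_id, annotation$term_id)
  M <- lengths(lapply(terms, unique))
  m <- vapply(terms, function(g) length(intersect(unique(g), degs)),
              integer(1))
  keep <- M > 0L
  terms <- terms[keep]; M <- M[keep]; m <- m[keep]
  P <- stats::phyper(m - 1L, M, N - M, n, lower.tail = FALSE)
  Q <- stats::p.adjust(P, method = "BH")
  meta <- annotation[!duplicated(annotation$term_id), ]
  idx <- match(names(terms), meta$term_id)
  out <- data.frame(term_id = names(terms),
                    term_name = if (is.null(meta$term_name)) NA_character_
                                else meta$term_name[idx],
                    namespace = if (is.null(meta$namespace)) NA_character_
                                else meta$namespace[idx],
                    N = N, n = n, M = as.integer(M), m = as.integer(m),
                    P = P, Q = Q,
                    significant = P < alpha_p & Q < alpha_q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$P, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table to TSV
#'
#' @param result data.frame from \code{\link{enrich}}.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
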