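# Between-species expression log-ratio matrix and hierarchical clustering
# of gene expression patterns.

#' Genes x stages log2 expression ratio matrix between two species
#'
#' For each gene and stage, the TPM mean of the two biological replicates
#' is computed per species and the entry is
#' log2(mean_species1 / mean_species2).  A zero mean on either side is
#' replaced by 0.01 before the ratio so every entry is finite; which side
#' was substituted is recorded per cell.
#'
#' @param expr A \code{tag_expr} whose design holds both species at every
#'   stage with two replicates.
#' @param species1,species2 Species labels (numerator and denominator).
#' @param gene_set Optional character vector restricting the rows; genes
#'   absent from the matrix are an error.
#' @param zero_sub Substitution value for zero means (default 0.01).
#' @return A numeric matrix (genes x stages) of class \code{ratio_matrix}
#'   with attribute \code{substitutions}, a character matrix flagging each
#'   cell as "none", "num", "den" or "both".
#' @export
log_ratio_matrix <- function(expr, species1, species2, gene_set = NULL,
                             zero_sub = 0.01) {
  stopifnot(inherits(expr, "tag_expr"), zero_sub > 0)
  d <- expr$design
  stopifnot(all(c(species1, species2) %in% d$species))
  stages <- unique(d$stage)
  genes <- rownames(expr$tpm)
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, genes)
    if (length(missing))
      stop("gene(s) absent from expression matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    genes <- gene_set
  }
  ratio <- matrix(NA_real_, length(genes), length(stages),
                  dimnames = list(genes, stages))
  subs <- matrix("none", length(genes), length(stages),
                 dimnames = list(genes, stages))
  for (st in stages) {
    ids1 <- d$library_id[d$species == species1 & d$stage == st]
    ids2 <- d$library_id[d$species == species2 & d$stage == st]
    if (length(ids1) != 2L || length(ids2) != 2L)
      stop("expected 2 replicates per species at stage ", st)
    num <- rowMeans(expr$tpm[genes, ids1, drop = FALSE])
    den <- rowMeans(expr$tpm[genes, ids2, drop = FALSE])
    zn <- num == 0; zd <- den == 0
    subs[, st] <- ifelse(zn & zd, "both",
                         ifelse(zn, "num", ifelse(zd, "den", "none")))
    ratio[, st] <- log2(ifelse(zn, zero_sub, num) /
                        ifelse(zd, zero_sub, den))
  }
  structure(ratio, substitutions = subs, class = c("ratio_matrix",
                                                   class(ratio)))
}

#' Hierarchical clustering of a ratio matrix
#'
#' Deterministic agglomerative clustering of genes (rows), by default with
#' Euclidean distance and average linkage (the Cluster 3.0 conventions).
#'
#' @param mat Numeric matrix with >= 2 rows and finite entries (e.g. a
#'   \code{\link{log_ratio_matrix}} result).
#' @param linkage Agglomeration method passed to \code{\link[stats]{hclust}}
#'   (default "average").
#' @param distance Distance measure passed to \code{\link[stats]{dist}}
#'   (default "euclidean").
#' @return A list of class \code{tag_hclust}: \code{hclust} (the merge
#'   tree), \code{order} (leaf-ordered gene names), \code{heights} (the
#'   n - 1 merge heights).
#' @export
hierarchical_cluster <- function(mat, linkage = "average",
                                 distance = "euclidean") {
  mat <- unclass(mat)
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (!all(is.finite(mat))) stop("non-finite entries in ratio matrix")
  hc <- stats::hclust(stats::dist(mat, method = distance),
                      method = linkage)
  structure(list(hclust = hc, order = rownames(mat)[hc$order],
                 heights = hc$height),
            class = "tag_hclust")
}

#' @export
print.tag_hclust <- function(x, ...) {
  cat(sprintf("Gene dendrogram: %d leaves, %d merges (%s linkage)\n",
              length(x$order), length(x$heights),
              x$hclust$method))
  invisible(x)
}

#' Write a dendrogram in Newick format
#'
#' @param clust A \code{tag_hclust}.
#' @param path Output path.
#' @export
write_dendrogram <- function(clust, path) {
  stopifnot(inherits(clust, "tag_hclust"))
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Write a (leaf-ordered) ratio matrix to TSV
#'
#' @param mat A \code{ratio_matrix} (or plain matrix with rownames).
#' @param path Output path.
#' @param order Optional row order (e.g. \code{clust$order}) for heatmap
#'   tools.
#' @export
write_ratio_matrix <- function(mat, path, order = NULL) {
  m <- unclass(mat)
  if (!is.null(order)) m <- m[order, , drop = FALSE]
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE,
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
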