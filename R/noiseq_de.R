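# Noise-distribution differential expression.
#
# For a two-condition contrast with replicates, expression change per gene
# is summarised by M (log2 fold change of condition means) and D (absolute
# difference of condition means).  An empirical null — the "noise"
# distribution — is built by pooling |M*|,|D*| from every within-condition
# replicate-vs-replicate comparison across all genes, and the probability
# of differential expression is the fraction of noise pairs strictly
# dominated by the gene's own (|M|, |D|).

#' Define a two-condition contrast
#'
#' @param condition_1,condition_2 Character vectors of library ids (the
#'   replicates of each condition; at least 2 each are required for the
#'   noise distribution).
#' @param label Human-readable contrast name.
#' @return A list of class \code{tag_contrast}.
#' @export
tag_contrast <- function(condition_1, condition_2,
                         label = paste(paste(condition_1, collapse = "+"),
                                       "vs",
                                       paste(condition_2, collapse = "+"))) {
  stopifnot(length(condition_1) >= 1, length(condition_2) >= 1,
            !anyDuplicated(c(condition_1, condition_2)))
  structure(list(condition_1 = condition_1, condition_2 = condition_2,
                 label = label),
            class = "tag_contrast")
}

check_contrast <- function(expr, contrast) {
  stopifnot(inherits(expr, "tag_expr"), inherits(contrast, "tag_contrast"))
  missing <- setdiff(c(contrast$condition_1, contrast$condition_2),
                     colnames(expr$tpm))
  if (length(missing))
    stop("contrast references absent libraries: ",
         paste(missing, collapse = ", "))
}

#' Per-gene signal statistics M and D
#'
#' M is the log2 ratio of the condition means (condition 1 over
#' condition 2); zero means are replaced by \code{pseudo} before the ratio
#' so M stays finite.  D is the absolute difference of the raw
#' (unsmoothed) condition means.
#'
#' @param expr A \code{tag_expr} (expression in TPM).
#' @param contrast A \code{tag_contrast}.
#' @param pseudo Positive smoothing constant substituted for zero means
#'   (default 0.5 TPM).
#' @return data.frame with per-gene \code{mean1}, \code{mean2}, \code{M},
#'   \code{D}.
#' @export
signal_statistics <- function(expr, contrast, pseudo = 0.5) {
  check_contrast(expr, contrast)
  stopifnot(pseudo > 0)
  m1 <- rowMeans(expr$tpm[, contrast$condition_1, drop = FALSE])
  m2 <- rowMeans(expr$tpm[, contrast$condition_2, drop = FALSE])
  data.frame(gene = rownames(expr$tpm), mean1 = m1, mean2 = m2,
             M = log2(ifelse(m1 == 0, pseudo, m1) /
                      ifelse(m2 == 0, pseudo, m2)),
             D = abs(m1 - m2),
             row.names = rownames(expr$tpm), stringsAsFactors = FALSE)
}

#' Empirical noise distribution of (|M*|, |D*|)
#'
#' For every gene and every unordered pair of replicates within the same
#' condition, the replicate-vs-replicate M and D are computed with the same
#' zero smoothing as the signal, and their absolute values pooled across
#' both conditions and all genes.  With two replicates per condition this
#' yields two noise pairs per gene.
#'
#' @inheritParams signal_statistics
#' @return Two-column matrix (\code{absM}, \code{absD}), one row per
#'   pooled noise pair.
#' @export
noise_distribution <- function(expr, contrast, pseudo = 0.5) {
  check_contrast(expr, contrast)
  stopifnot(pseudo > 0)
  for (side in c("condition_1", "condition_2")) {
    if (length(contrast[[side]]) < 2L)
      stop("need >= 2 replicates in ", side, " (", contrast$label,
           ") for the noise distribution")
  }
  absM <- numeric(0); absD <- numeric(0)
  for (side in c("condition_1", "condition_2")) {
    reps <- contrast[[side]]
    for (a in seq_len(length(reps) - 1L)) {
      for (b in seq((a + 1L), length(reps))) {
        x <- expr$tpm[, reps[a]]
        y <- expr$tpm[, reps[b]]
        absM <- c(absM, abs(log2(ifelse(x == 0, pseudo, x) /
                                 ifelse(y == 0, pseudo, y))))
        absD <- c(absD, abs(x - y))
      }
    }
  }
  cbind(absM = absM, absD = absD)
}

#' Probability of differential expression
#'
#' \code{P1(g)} is the fraction of noise pairs strictly dominated by the
#' gene's signal: \code{#(|M*| < |M_g| & |D*| < |D_g|) / #noise}.  Strict
#' inequality, so ties do not count as exceedance and a gene with
#' M = D = 0 has P1 = 0.  The higher P1, the stronger the expression
#' change relative to replicate noise.
#'
#' @param signal data.frame from \code{\link{signal_statistics}} (columns
#'   \code{M}, \code{D}).
#' @param noise Matrix from \code{\link{noise_distribution}}; must be
#'   non-empty.
#' @return Numeric vector of P1 in [0, 1], one per signal row.
#' @export
de_probability <- function(signal, noise) {
  stopifnot(is.data.frame(signal), all(c("M", "D") %in% names(signal)))
  if (!is.matrix(noise) || nrow(noise) == 0L) stop("empty noise set")
  absM <- abs(signal$M); absD <- signal$D
  nM <- noise[, 1L]; nD <- noise[, 2L]
  k <- nrow(noise)
  vapply(seq_along(absM),
         function(g) sum(nM < absM[g] & nD < absD[g]) / k,
         numeric(1))
}

#' Fit the noise-distribution DE model for one contrast
#'
#' Convenience wrapper running \code{\link{signal_statistics}},
#' \code{\link{noise_distribution}}, \code{\link{de_probability}} and
#' \code{\link{call_degs}} in sequence.
#'
#' @inheritParams signal_statistics
#' @param q_threshold Probability threshold for calling differential
#'   expression (default 0.8, i.e. 4:1 odds of being differentially
#'   expressed).
#' @param m_threshold Minimum absolute log2 fold change (default 1).
#' @return An object of class \code{tag_de}: the per-gene table (gene,
#'   mean1, mean2, M, D, P1, P0, odds, significant, direction) with the
#'   contrast, thresholds and noise set as attributes.
#' @export
tag_de <- function(expr, contrast, pseudo = 0.5, q_threshold = 0.8,
                   m_threshold = 1) {
  signal <- signal_statistics(expr, contrast, pseudo)
  noise <- noise_distribution(expr, contrast, pseudo)
  signal$P1 <- de_probability(signal, noise)
  signal$P0 <- 1 - signal$P1
  signal$odds <- ifelse(signal$P0 > 0, signal$P1 / signal$P0, Inf)
  fit <- structure(signal, class = c("tag_de", "data.frame"),
                   contrast = contrast, pseudo = pseudo, noise = noise)
  call_degs(fit, q_threshold, m_threshold)
}

#' Apply the significance calling rule
#'
#' A gene is significant when \code{P1 >= q_threshold} and
#' \code{|M| >= m_threshold}; at the default threshold 0.8 this
#' corresponds to odds P1/P0 of at least 4:1.  Direction is the sign of M
#' (up in condition 1 when M > 0).
#'
#' @param fit A \code{tag_de} object (or data.frame with \code{M},
#'   \code{P1}).
#' @param q_threshold,m_threshold See \code{\link{tag_de}}.
#' @return The input with \code{significant} and \code{direction} columns
#'   refreshed and thresholds recorded in attributes.
#' @export
call_degs <- function(fit, q_threshold = 0.8, m_threshold = 1) {
  stopifnot(all(c("M", "P1") %in% names(fit)))
  fit$significant <- fit$P1 >= q_threshold & abs(fit$M) >= m_threshold
  fit$direction <- ifelse(!fit$significant, "ns",
                          ifelse(fit$M > 0, "up_condition_1",
                                 "up_condition_2"))
  attr(fit, "q_threshold") <- q_threshold
  attr(fit, "m_threshold") <- m_threshold
  fit
}

#' Up/down summary counts for a DE fit
#'
#' @param fit A \code{tag_de}.
#' @return data.frame with the contrast label, total significant genes and
#'   the split by direction.
#' @export
deg_counts <- function(fit) {
  stopifnot(inherits(fit, "tag_de"))
  data.frame(contrast = attr(fit, "contrast")$label,
             significant = sum(fit$significant),
             up_condition_1 = sum(fit$direction == "up_condition_1"),
             up_condition_2 = sum(fit$direction == "up_condition_2"),
             stringsAsFactors = FALSE)
}

#' Implied odds of a probability threshold
#'
#' The calling threshold on P1 translates to betting odds
#' \code{q / (1 - q)}: at the default q = 0.8 a flagged gene is at least
#' four times more likely to be differentially expressed than not.
#'
#' @param q_threshold Probability threshold in (0, 1).
#' @return The odds \code{q_threshold / (1 - q_threshold)}.
#' @export
threshold_odds <- function(q_threshold = 0.8) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  q_threshold / (1 - q_threshold)
}

#' @export
print.tag_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Noise-distribution DE fit: %s\n", ct$label))
  cat(sprintf("  %d genes, %d noise pairs; thresholds P1 >= %g, |M| >= %g\n",
              nrow(x), nrow(attr(x, "noise")), attr(x, "q_threshold"),
              attr(x, "m_threshold")))
  cat(sprintf("  significant: %d (%d up in %s, %d up in %s)\n",
              sum(x$significant), sum(x$direction == "up_condition_1"),
              paste(ct$condition_1, collapse = "+"),
              sum(x$direction == "up_condition_2"),
              paste(ct$condition_2, collapse = "+")))
  invisible(x)
}

#' @export
summary.tag_de <- function(object, ...) {
  top <- as.data.frame(object)[order(-object$P1, -abs(object$M)), ]
  res <- list(counts = deg_counts(object),
              top = utils::head(top[top$significant, ], 10L))
  class(res) <- "summary.tag_de"
  res
}

#' @export
print.summary.tag_de <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  if (nrow(x$top)) {
    cat("Top significant genes:\n")
    print(x$top[, c("gene", "mean1", "mean2", "M", "D", "P1", "direction")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a DE fit to TSV
#'
#' @param fit A \code{tag_de}.
#' @param path Output path.
#' @export
write_de_table <- function(fit, path) {
  stopifnot(inherits(fit, "tag_de"))
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
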