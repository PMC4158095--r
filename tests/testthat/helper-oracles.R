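# Independent brute-force oracles used to pin down expected values.

# Naive all-positions scan for CATG + 17 nt windows (no regex).
oracle_extract_tags <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- data.frame(offset = integer(0), tag = character(0),
                    stringsAsFactors = FALSE)
  if (n < 21) return(out)
  for (i in seq_len(n - 20)) {
    if (substr(seq, i, i + 3) == "CATG") {
      tag <- substr(seq, i, i + 20)
      if (!grepl("[^ACGT]", tag))
        out <- rbind(out, data.frame(offset = i - 1L, tag = tag,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Full Hamming scan over all stored tags; exact hits take priority, then
# distance-1 hits restricted to the suffix when anchor_strict.
oracle_lookup <- function(db, query, max_mismatch = 1, anchor_strict = TRUE) {
  d <- vapply(db$tags, hamming, numeric(1), b = query)
  if (any(d == 0)) {
    return(list(sources = sort(unique(unlist(db$sources[d == 0]))),
                match_type = "exact"))
  }
  if (max_mismatch >= 1) {
    ok <- d == 1
    if (anchor_strict) {
      ok <- ok & vapply(db$tags, function(t)
        substr(t, 1, 4) == substr(query, 1, 4), logical(1))
    }
    if (any(ok)) {
      return(list(sources = sort(unique(unlist(db$sources[ok]))),
                  match_type = "mismatch"))
    }
  }
  list(sources = character(0), match_type = "none")
}

# Double-loop exceedance count for the DE probability.
oracle_p1 <- function(absM, absD, noise) {
  vapply(seq_along(absM), function(g) {
    hits <- 0
    for (k in seq_len(nrow(noise))) {
      if (noise[k, 1] < absM[g] && noise[k, 2] < absD[g]) hits <- hits + 1
    }
    hits / nrow(noise)
  }, numeric(1))
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of n
# genes from a universe with M marked, count draws with >= m marked.
oracle_hyper_upper <- function(N, n, M, m) {
  draws <- utils::combn(N, n)
  marked <- seq_len(M)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= m)
  mean(hits)
}

# Naive O(n^3) agglomerative average-linkage clustering; returns the
# sorted merge heights.
oracle_upgma_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  active <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(1, 2); best_d <- Inf
    for (i in seq_len(length(active) - 1)) {
      for (j in seq((i + 1), length(active))) {
        dd <- mean(d[active[[i]], active[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  sort(heights)
}
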