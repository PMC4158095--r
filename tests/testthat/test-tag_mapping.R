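test_that("a tag unique to one gene contributes its full copy number", {
  set.seed(41)
  t1 <- random_tag()
  db <- build_transcript_db(write_tmp_fasta(
    c(G = transcript_with_tags(t1))))
  lib <- make_library(stats::setNames(100L, t1))
  res <- map_library(lib, db)
  expect_equal(unname(res$counts["G"]), 100)
  expect_equal(res$summary$unambiguous_pct, 100)
  expect_equal(res$summary$genes_with_unambiguous_tag, 1L)
})

test_that("ambiguous tags count toward mapped mass but no gene", {
  set.seed(42)
  t1 <- random_tag()
  db <- build_transcript_db(write_tmp_fasta(
    c(g1 = transcript_with_tags(t1), g2 = transcript_with_tags(t1))))
  lib <- make_library(stats::setNames(40L, t1))
  res <- map_library(lib, db)
  expect_equal(sum(res$counts), 0)
  expect_equal(res$summary$gene_mapped_mass, 40)
  expect_equal(res$summary$unambiguous_mass, 0)
  expect_equal(res$summary$genes_with_any_tag, 2L)
})

test_that("unmapped tags fall back to the genome db, remainder is unknown", {
  set.seed(43)
  t_gene <- random_tag(); t_genome <- random_tag(); t_unknown <- random_tag()
  stopifnot(!anyDuplicated(c(t_gene, t_genome, t_unknown)))
  tdb <- build_transcript_db(write_tmp_fasta(
    c(G = transcript_with_tags(t_gene))))
  gdb <- build_genome_db(write_tmp_fasta(
    c(chr = transcript_with_tags(c(t_gene, t_genome)))))
  # make the unknown tag >= 2 mismatches from everything stored
  while (lookup(tdb, t_unknown)$match_type != "none" ||
         lookup(gdb, t_unknown)$match_type != "none") {
    t_unknown <- random_tag()
  }
  lib <- make_library(stats::setNames(c(10L, 6L, 4L),
                                      c(t_gene, t_genome, t_unknown)))
  res <- map_library(lib, tdb, gdb)
  expect_equal(unname(res$counts["G"]), 10)
  expect_equal(res$summary$genome_mapped_mass, 6)
  expect_equal(res$summary$unknown_mass, 4)
  # mass conservation
  expect_equal(res$summary$gene_mapped_mass +
                 res$summary$genome_mapped_mass +
                 res$summary$unknown_mass,
               lib$clean_tags)
  # without a genome db the genome category is not assessed
  res2 <- map_library(lib, tdb)
  expect_true(is.na(res2$summary$genome_mapped_mass))
  expect_equal(res2$summary$unknown_mass, 10)
})

test_that("exact hits are assigned even when 1-mismatch neighbours exist elsewhere", {
  set.seed(44)
  t1 <- random_tag()
  t2 <- t1
  substr(t2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                substr(t2, 10, 10))[1]
  db <- build_transcript_db(write_tmp_fasta(
    c(g1 = transcript_with_tags(t1), g2 = transcript_with_tags(t2))))
  lib <- make_library(stats::setNames(8L, t1))
  res <- map_library(lib, db, max_mismatch = 1)
  expect_equal(unname(res$counts["g1"]), 8)
  expect_equal(unname(res$counts["g2"]), 0)
  # exact-hit assignments identical with mismatch search disabled
  res0 <- map_library(lib, db, max_mismatch = 0)
  expect_equal(res$counts, res0$counts)
})

test_that("tpm_normalize matches the defining formula and its invariances", {
  counts <- matrix(c(5, 0, 12, 3), 2, 2,
                   dimnames = list(c("g1", "g2"), c("L1", "L2")))
  tpm <- tpm_normalize(counts, c(5e6, 1e6))
  expect_equal(tpm["g1", "L1"], 1.0)
  expect_equal(tpm["g2", "L1"], 0)
  expect_equal(tpm["g1", "L2"], 12)
  # doubling counts and denominators leaves TPM unchanged
  expect_equal(tpm_normalize(2 * counts, 2 * c(5e6, 1e6)), tpm)
  # random matrix vs direct one-line recomputation
  set.seed(45)
  m <- matrix(rpois(30, 20), 6, 5)
  den <- runif(5, 1e4, 1e6)
  expect_equal(tpm_normalize(m, den),
               t(t(m) / den * 1e6))
  expect_error(tpm_normalize(m, c(den[-5], 0)), "denominators")
})

test_that("expression matrix columns satisfy the TPM identity", {
  set.seed(46)
  tags <- replicate(30, random_tag())
  genes <- paste0("g", rep(1:10, each = 3))
  db <- build_transcript_db(write_tmp_fasta(
    tapply(tags, genes, transcript_with_tags)))
  libs <- lapply(1:3, function(i)
    make_library(stats::setNames(sample(2:50, 30, replace = TRUE), tags),
                 library_id = paste0("L", i), replicate = i))
  expr <- build_expression_matrix(libs, db)
  for (j in seq_len(ncol(expr$tpm))) {
    expect_equal(expr$tpm[, j],
                 expr$counts[, j] / expr$denominators[j] * 1e6)
    expect_equal(sum(expr$tpm[, j]),
                 unname(1e6 * expr$mapping$unambiguous_mass[j] /
                          expr$denominators[j]),
                 tolerance = 1e-6)
  }
  # TSV round trip preserves counts
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(expr, path)
  tab <- read.delim(path)
  expect_equal(tab$L1_count, unname(expr$counts[, "L1"]))
})

test_that("mapping categories equal generator bookkeeping on a simulated experiment", {
  ss <- small_sim()
  ref <- ss$ref; sim <- ss$sim
  fa <- write_tmp_fasta(ref$transcripts_sp1)
  tdb <- build_transcript_db(fa)
  gfa <- write_tmp_fasta(ref$genome)
  gdb <- build_genome_db(gfa)
  d <- sim$design
  for (li in c(1L, 7L)) {  # one library per species
    lib <- clean_library(sim$reads[[li]], library_id = d$library_id[li],
                         species = d$species[li], stage = d$stage[li],
                         replicate = d$replicate[li])
    res <- map_library(lib, tdb, gdb)
    s <- res$summary
    expect_equal(s$gene_mapped_mass + s$genome_mapped_mass +
                   s$unknown_mass, lib$clean_tags)
    # for the reference species, contaminant reads are planted >= 2
    # mismatches from every reference tag, so unknown mass is at most the
    # contaminant + error read count; species 2 additionally loses tags
    # whose site diverged by >= 2 substitutions
    if (d$species[li] == "sp1") {
      expect_lte(s$unknown_mass,
                 sim$truth$contaminant_reads[li] +
                   sim$truth$error_reads[li])
    }
    # per-gene counts within planted-error slack of the generator truth
    diffs <- abs(res$counts[rownames(sim$truth$source_counts)] -
                   sim$truth$source_counts[, li])
    slack <- sim$truth$error_reads[li] +
      if (d$species[li] == "sp2") s$unknown_mass + s$genome_mapped_mass
      else 0
    expect_lte(sum(diffs), 2 * slack + sum(lib$filter_counts))
  }
})

test_that("error-free, contaminant-free, divergence-free reads map perfectly", {
  cfg <- sim_config(n_genes = 40L, depth = 3000,
                    gene_length_range = c(300L, 600L),
                    error_rate = 0, contaminant_fraction = 0,
                    divergence = 0, replicate_sdlog = 0.2, seed = 5L)
  ref <- simulate_reference(cfg)
  sim <- simulate_libraries(cfg, ref)
  tdb <- build_transcript_db(write_tmp_fasta(ref$transcripts_sp1))
  lib <- clean_library(sim$reads[[1L]])
  res <- map_library(lib, tdb)
  expect_equal(res$summary$unknown_mass, 0)
  expect_equal(res$summary$gene_mapped_mass, lib$clean_tags)
})

test_that("replicate_correlation computes per-pair Pearson R on TPM", {
  set.seed(47)
  tpm <- matrix(rlnorm(400, 3, 1), 100, 4,
                dimnames = list(paste0("g", 1:100),
                                c("A1", "A2", "B1", "B2")))
  expr <- make_expr(tpm, species = rep("sp1", 4),
                    stage = rep(c("nurse", "forager"), each = 2),
                    replicate = c(1, 2, 1, 2))
  rc <- replicate_correlation(expr)
  expect_equal(nrow(rc), 2L)
  expect_equal(rc$r[rc$stage == "nurse"], cor(tpm[, "A1"], tpm[, "A2"]))
})
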