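test_that("extract_tags enumerates every CATG site with a clean 17 nt window", {
  tag <- paste0("CATG", strrep("A", 17))
  expect_equal(extract_tags(tag),
               data.frame(offset = 0L, tag = tag,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(extract_tags(strrep("T", 60))), 0L)
  expect_equal(nrow(extract_tags("")), 0L)

  # 60 nt, 3 CATG sites, the last with only 10 nt downstream
  s <- paste0("AA", "CATG", strrep("G", 17),  # site at offset 2
              "CATG", strrep("T", 19),        # site at offset 23
              "CATG", strrep("A", 10))        # offset 46: too short
  expect_equal(nchar(s), 60)
  got <- extract_tags(s)
  expect_equal(got, oracle_extract_tags(s))
  expect_equal(nrow(got), 2L)
})

test_that("extract_tags skips windows with non-ACGT characters and is case-insensitive", {
  s <- paste0("CATG", "AAAAANAAAAAAAAAAA", "CATG", strrep("C", 17))
  got <- extract_tags(s)
  expect_equal(got$offset, 21L)
  expect_equal(extract_tags(tolower(s)), got)
})

test_that("extract_tags agrees with the naive all-positions scan on random sequences", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:200, 1),
                      replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
               collapse = "")
    expect_equal(extract_tags(s), oracle_extract_tags(s), info = s)
  }
})

test_that("transcript db unions tags over genes, sense strand only", {
  set.seed(21)
  shared <- random_tag()
  t1 <- random_tag(); t2 <- random_tag()
  fa <- write_tmp_fasta(c(g1 = transcript_with_tags(c(shared, t1)),
                          g2 = transcript_with_tags(c(shared, t2))))
  db <- build_transcript_db(fa)
  expect_s3_class(db, "tag_db")
  expect_equal(db$source_kind, "transcript")
  expect_setequal(db$sources[[match(shared, db$tags)]], c("g1", "g2"))
  # invariants: 21-mers, CATG anchor, ACGT only, non-empty sources
  expect_true(all(nchar(db$tags) == 21))
  expect_true(all(startsWith(db$tags, "CATG")))
  expect_false(any(grepl("[^ACGT]", db$tags)))
  expect_true(all(lengths(db$sources) >= 1))
})

test_that("transcript db counts distinct tags by hand-enumerated fixture", {
  set.seed(22)
  tags <- replicate(6, random_tag())
  stopifnot(!anyDuplicated(tags))
  fa <- write_tmp_fasta(c(g1 = transcript_with_tags(tags[1:2]),
                          g2 = transcript_with_tags(tags[3:4]),
                          g3 = transcript_with_tags(tags[5:6])))
  expect_equal(build_transcript_db(fa)$n_distinct_tags, 6L)
})

test_that("empty FASTA yields an empty db and duplicate ids error", {
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  db <- build_transcript_db(empty)
  expect_equal(db$n_distinct_tags, 0L)
  dup <- write_tmp_fasta(c(g1 = "CATGAAAAAAAAAAAAAAAAA",
                           g1 = "CATGCCCCCCCCCCCCCCCCC"))
  expect_error(build_transcript_db(dup), "duplicate")
})

test_that("genome db extracts both strands with positional sources", {
  tag <- "CATGAAACCCGGGTTTACGTA"
  # forward sequence contains only the reverse complement of the tag
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  expect_equal(nrow(extract_tags(rc)), 0L)  # no usable forward site
  fa <- write_tmp_fasta(c(chr = rc))
  db <- build_genome_db(fa)
  expect_true(tag %in% db$tags)
  src <- db$sources[[match(tag, db$tags)]]
  expect_equal(src, "chr:0:-")

  # forward-only record
  fa2 <- write_tmp_fasta(c(chr = tag))
  db2 <- build_genome_db(fa2)
  expect_equal(db2$sources[[match(tag, db2$tags)]], "chr:0:+")
})

test_that("a palindromic context yields one key with two source ids", {
  tag <- "CATGAAACCCGGGTTTACGTA"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  fa <- write_tmp_fasta(c(chr = paste0(tag, "TTTTT", rc)))
  db <- build_genome_db(fa)
  src <- db$sources[[match(tag, db$tags)]]
  expect_length(src, 2L)
  expect_setequal(substring(src, nchar(src)), c("+", "-"))
})

test_that("genome db key set is strand-symmetric", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  db_f <- build_genome_db(write_tmp_fasta(c(chr = s)))
  db_r <- build_genome_db(write_tmp_fasta(c(chr = rc)))
  expect_setequal(db_f$tags, db_r$tags)
})

test_that("lookup prioritises exact hits and reports ambiguity", {
  set.seed(24)
  t1 <- random_tag()
  fa <- write_tmp_fasta(c(g1 = transcript_with_tags(t1),
                          g2 = transcript_with_tags(t1)))
  db <- build_transcript_db(fa)
  hit <- lookup(db, t1)
  expect_equal(hit$match_type, "exact")
  expect_setequal(hit$sources, c("g1", "g2"))
  expect_false(hit$unambiguous)

  # mismatch at suffix position 5 (tag position 9)
  q <- t1
  substr(q, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(q, 9, 9))[1]
  hit1 <- lookup(db, q, max_mismatch = 1)
  expect_equal(hit1$match_type, "mismatch")
  expect_setequal(hit1$sources, c("g1", "g2"))
  expect_equal(lookup(db, q, max_mismatch = 0)$match_type, "none")

  expect_error(lookup(db, "CATGAA"), "length")
})

test_that("anchor mismatches are rejected unless anchor_strict is off", {
  set.seed(25)
  t1 <- random_tag()
  db <- build_transcript_db(write_tmp_fasta(
    c(g1 = transcript_with_tags(t1))))
  q <- t1
  substr(q, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(q, 2, 2))[1]
  expect_equal(lookup(db, q)$match_type, "none")
  expect_equal(lookup(db, q, anchor_strict = FALSE)$match_type,
               "mismatch")
})

test_that("lookup matches a brute-force Hamming scan on a randomized database", {
  set.seed(26)
  tags <- unique(replicate(50, random_tag()))
  genes <- sample(paste0("g", 1:20), length(tags), replace = TRUE)
  db <- build_transcript_db(write_tmp_fasta(
    tapply(tags, genes, transcript_with_tags)))
  queries <- c(sample(tags, 60, replace = TRUE),  # exact and near-exact
               replicate(140, random_tag()))
  queries <- vapply(queries, function(q) {
    if (runif(1) < 0.6) {
      p <- sample(5:21, 1)
      substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    q
  }, "")
  for (q in queries) {
    got <- lookup(db, q)
    exp <- oracle_lookup(db, q)
    expect_setequal(got$sources, exp$sources)
    expect_equal(got$match_type, exp$match_type, info = q)
    # exact-only results are a subset of 1-mismatch results
    got0 <- lookup(db, q, max_mismatch = 0)
    expect_true(all(got0$sources %in% got$sources))
  }
})

test_that("tag db TSV dump round-trips tags and sources", {
  set.seed(27)
  db <- build_transcript_db(write_tmp_fasta(
    c(g1 = transcript_with_tags(random_tag()))))
  path <- tempfile(fileext = ".tsv")
  write_tag_db(db, path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(tab$tag, db$tags)
  expect_equal(tab$source_kind, rep("transcript", db$n_distinct_tags))
})
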