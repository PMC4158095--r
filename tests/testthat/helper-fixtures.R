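# Small in-code fixtures shared across test files.

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

random_tag <- function() {
  paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                       collapse = ""))
}

# A transcript guaranteed to carry the given tags (joined by neutral
# spacers free of CATG).
transcript_with_tags <- function(tags) {
  paste0(paste(tags, collapse = "TTTTT"), "TTTTT")
}

# Tiny deterministic expression container for DE / ratio tests.
make_expr <- function(tpm, species, stage, replicate) {
  design <- data.frame(library_id = colnames(tpm), species = species,
                       stage = stage, replicate = replicate,
                       stringsAsFactors = FALSE)
  structure(list(counts = tpm, tpm = tpm,
                 denominators = stats::setNames(rep(1e6, ncol(tpm)),
                                                colnames(tpm)),
                 design = design, mapping = NULL),
            class = "tag_expr")
}

# Clean tag library straight from a named copy-number vector (bypasses
# filtering; all tags assumed valid 21-mers with copies >= 2).
make_library <- function(tags, library_id = "lib1", species = "sp1",
                         stage = "nurse", replicate = 1L) {
  lib <- library_from_counts(tags, library_id = library_id,
                             species = species, stage = stage,
                             replicate = replicate)
  stopifnot(lib$clean_tags == sum(tags))
  lib
}

# Default small-but-complete synthetic experiment reused by several
# integration tests (kept modest so the suite stays fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 120L, depth = 8000,
                        gene_length_range = c(300L, 800L), seed = 42L)
      ref <- simulate_reference(cfg)
      sim <- simulate_libraries(cfg, ref)
      cache <<- list(cfg = cfg, ref = ref, sim = sim)
    }
    cache
  }
})
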