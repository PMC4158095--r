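# Ground-truthed simulator of a two-species, three-stage, two-replicate
# DGE-tag experiment: reference transcriptome and genome, skewed gene
# abundances, planted stage and species effects, replicate dispersion,
# per-base sequencing error and unmappable contaminant tags.

SIM_STAGES <- c("newly_emerged", "nurse", "forager")
SIM_SPECIES <- c("sp1", "sp2")

#' Simulation configuration
#'
#' Defaults describe the study design the package targets: 2 species x 3
#' developmental stages x 2 replicates (12 libraries), a log-normal
#' abundance law whose heavy tail puts most sequenced mass into a few
#' high-copy tags, 10\% of genes with a planted 8-fold (|log2FC| = 3)
#' stage effect, 5\% with a planted 8-fold species effect, moderate
#' between-replicate dispersion, 0.1\% per-base sequencing error, 2\%
#' contaminant tags and 1\% sequence divergence between the two species'
#' transcripts.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max transcript length (bp).
#' @param depth Tags sequenced per library.
#' @param abundance_meanlog,abundance_sdlog Log-normal baseline abundance
#'   parameters (natural log).
#' @param stage_de_fraction,stage_effect_log2 Fraction of genes with a
#'   planted stage effect and its log2 magnitude; each affected gene is
#'   elevated at one stage (drawn with probabilities
#'   \code{stage_up_probs}) in both species.
#' @param stage_up_probs Probabilities that a stage-effect gene peaks at
#'   each of the three stages; default favours the newly-emerged stage and
#'   declines with age.
#' @param species_de_fraction,species_effect_log2 Fraction of genes with a
#'   planted species effect (random sign, applied to species 1 at every
#'   stage) and its log2 magnitude.
#' @param replicate_sdlog Between-replicate log-normal dispersion (natural
#'   log sd) applied per gene per library.
#' @param tag_site_decay Geometric decay of tag-site usage away from the
#'   3' end: the 3'-most CATG site of a transcript receives weight 1, the
#'   next one upstream \code{tag_site_decay}, and so on.  The anchored
#'   digestion makes the 3'-most site dominate in real libraries; values
#'   near 1 spread reads evenly over all sites.
#' @param error_rate Per-base sequencing error probability.
#' @param contaminant_fraction Fraction of reads drawn from tags at
#'   Hamming distance >= 2 from every reference tag (the "unknown" path).
#' @param divergence Per-base substitution rate deriving species-2
#'   transcripts from species 1.
#' @param bees_per_library Workers pooled per library (design metadata).
#' @param seed Mandatory integer seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L,
                       gene_length_range = c(400L, 2000L),
                       depth = 1e5,
                       abundance_meanlog = 1, abundance_sdlog = 1.5,
                       stage_de_fraction = 0.1, stage_effect_log2 = 3,
                       stage_up_probs = c(0.5, 0.3, 0.2),
                       species_de_fraction = 0.05,
                       species_effect_log2 = 3,
                       replicate_sdlog = 0.15,
                       tag_site_decay = 0.3,
                       error_rate = 0.001,
                       contaminant_fraction = 0.02,
                       divergence = 0.01,
                       bees_per_library = 60L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              depth = depth,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              stage_de_fraction = stage_de_fraction,
              stage_effect_log2 = stage_effect_log2,
              stage_up_probs = stage_up_probs / sum(stage_up_probs),
              species_de_fraction = species_de_fraction,
              species_effect_log2 = species_effect_log2,
              replicate_sdlog = replicate_sdlog,
              tag_site_decay = tag_site_decay,
              error_rate = error_rate,
              contaminant_fraction = contaminant_fraction,
              divergence = divergence,
              bees_per_library = as.integer(bees_per_library),
              seed = as.integer(seed))
  fracs <- c(cfg$stage_de_fraction, cfg$species_de_fraction,
             cfg$error_rate, cfg$contaminant_fraction, cfg$divergence)
  stopifnot(cfg$tag_site_decay > 0, cfg$tag_site_decay <= 1)
  stopifnot(all(fracs >= 0), all(fracs <= 1), cfg$depth >= 1,
            cfg$n_genes >= 1, cfg$replicate_sdlog >= 0,
            cfg$stage_de_fraction + cfg$species_de_fraction <= 1)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate the reference transcriptome and genome
#'
#' Random transcripts, each guaranteed at least one CATG + 17 nt tag site;
#' species-2 transcripts are derived from species 1 by point substitutions
#' at the configured divergence rate (modelling cross-species mapping
#' against a single reference); the genome embeds the species-1
#' transcripts in random intergenic sequence.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Optional directory; when given, writes
#'   \code{transcripts_sp1.fasta}, \code{transcripts_sp2.fasta} and
#'   \code{genome.fasta}.
#' @return A list of class \code{sim_reference}: \code{transcripts_sp1},
#'   \code{transcripts_sp2} (named character vectors), \code{genome}
#'   (single named sequence), and file paths when written.
#' @export
simulate_reference <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- with_seed(config$seed, {
    span <- config$gene_length_range[2L] - config$gene_length_range[1L] + 1L
    lens <- config$gene_length_range[1L] +
      sample.int(span, config$n_genes, replace = TRUE) - 1L
    tx <- vapply(lens, random_dna, "")
    # guarantee a usable tag site
    for (i in seq_along(tx)) {
      if (nrow(extract_tags(tx[i])) == 0L) {
        pos <- sample(seq_len(lens[i] - 20L), 1L)
        substring(tx[i], pos, pos + 3L) <- TAG_ANCHOR
      }
    }
    names(tx) <- sprintf("gene%04d", seq_along(tx))
    tx2 <- tx
    if (config$divergence > 0) {
      for (i in seq_along(tx2)) {
        k <- stats::rbinom(1L, nchar(tx2[i]), config$divergence)
        if (k > 0L)
          tx2[i] <- mutate_bases(tx2[i],
                                 sample.int(nchar(tx2[i]), k))
      }
    }
    spacers <- vapply(rep(300L, length(tx) + 1L), random_dna, "")
    genome <- paste0(paste0(spacers[-length(spacers)], tx, collapse = ""),
                     spacers[length(spacers)])
    names(genome) <- "chr1"
    list(transcripts_sp1 = tx, transcripts_sp2 = tx2, genome = genome)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ref$paths <- c(
      transcripts_sp1 = write_fasta(ref$transcripts_sp1,
                                    file.path(out_dir,
                                              "transcripts_sp1.fasta")),
      transcripts_sp2 = write_fasta(ref$transcripts_sp2,
                                    file.path(out_dir,
                                              "transcripts_sp2.fasta")),
      genome = write_fasta(ref$genome, file.path(out_dir, "genome.fasta")))
  }
  structure(ref, class = "sim_reference")
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

# Contaminant tag pool: CATG+17 21-mers at Hamming distance >= 2 from
# every tag of the supplied reference sequences.
contaminant_pool <- function(reference, n_pool) {
  ref_tags <- unique(c(
    extract_tags(paste(reference$transcripts_sp1, collapse = "N"))$tag,
    extract_tags(paste(reference$transcripts_sp2, collapse = "N"))$tag,
    extract_tags(unname(reference$genome))$tag,
    extract_tags(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(unname(reference$genome)))))$tag))
  pool <- character(0)
  while (length(pool) < n_pool) {
    cand <- unique(vapply(seq_len(2L * n_pool),
                          function(i) paste0(TAG_ANCHOR, random_dna(17L)),
                          ""))
    cand <- setdiff(cand, c(ref_tags, pool))
    if (length(cand) == 0L) next
    nb <- tag_neighbourhood(cand, anchor_strict = TRUE)
    hit <- nb$variant %in% ref_tags
    bad <- unique(nb$query_index[hit])
    if (length(bad)) cand <- cand[-bad]
    pool <- c(pool, cand)
  }
  pool[seq_len(n_pool)]
}

#' Simulate the twelve tag libraries with full ground truth
#'
#' Expected per-gene abundance in each library is baseline x stage effect
#' x species effect x a per-gene log-normal replicate factor; reads are
#' drawn multinomially from each gene's own tag set (species 2 reads come
#' from the diverged species-2 transcripts), contaminant reads from the
#' unknown-tag pool, and per-base errors are applied at the configured
#' rate.
#'
#' @param config A \code{sim_config}.
#' @param reference A \code{sim_reference}.
#' @param out_dir Optional directory; when given, writes one FASTQ per
#'   library, a design table TSV and per-gene truth TSV.
#' @return A list of class \code{sim_experiment} with \code{design}
#'   (data.frame: library_id, species, stage, replicate, fastq when
#'   written), \code{reads} (per library: character vector of raw reads),
#'   \code{truth}: list holding per-gene \code{baseline}, \code{stage_up}
#'   (NA or peak stage), \code{species_log2fc} (0 when unaffected),
#'   expected expression matrix \code{expected} (genes x 6
#'   species/stage conditions), per-library realized source-gene counts
#'   \code{source_counts}, per-read source annotations
#'   \code{read_sources}, and contaminant/error bookkeeping.
#' @export
simulate_libraries <- function(config, reference, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "sim_reference"))
  genes <- names(reference$transcripts_sp1)
  n <- length(genes)
  sim <- with_seed(config$seed + 1L, {
    baseline <- stats::rlnorm(n, config$abundance_meanlog,
                              config$abundance_sdlog)
    n_stage <- round(config$stage_de_fraction * n)
    n_species <- round(config$species_de_fraction * n)
    de_idx <- sample.int(n, n_stage + n_species)
    stage_idx <- de_idx[seq_len(n_stage)]
    species_idx <- setdiff(de_idx, stage_idx)
    stage_up <- rep(NA_character_, n)
    stage_up[stage_idx] <- sample(SIM_STAGES, n_stage, replace = TRUE,
                                  prob = config$stage_up_probs)
    species_log2fc <- rep(0, n)
    species_log2fc[species_idx] <- sample(c(-1, 1), n_species,
                                          replace = TRUE) *
      config$species_effect_log2

    conditions <- expand.grid(stage = SIM_STAGES, species = SIM_SPECIES,
                              stringsAsFactors = FALSE)[, 2:1]
    expected <- matrix(0, n, nrow(conditions),
                       dimnames = list(genes,
                                       paste(conditions$species,
                                             conditions$stage, sep = ".")))
    for (k in seq_len(nrow(conditions))) {
      w <- baseline
      up <- !is.na(stage_up) & stage_up == conditions$stage[k]
      w[up] <- w[up] * 2^config$stage_effect_log2
      if (conditions$species[k] == SIM_SPECIES[1L])
        w <- w * 2^species_log2fc
      expected[, k] <- w
    }

    tag_sets <- list(
      sp1 = lapply(reference$transcripts_sp1,
                   function(s) extract_tags(s)$tag),
      sp2 = lapply(reference$transcripts_sp2,
                   function(s) extract_tags(s)$tag))

    n_pool <- 200L
    pool <- if (config$contaminant_fraction > 0)
      contaminant_pool(reference, n_pool) else character(0)
    pool_w <- if (length(pool)) stats::rlnorm(length(pool), 0, 1)

    design <- expand.grid(replicate = 1:2, stage = SIM_STAGES,
                          species = SIM_SPECIES,
                          stringsAsFactors = FALSE)[, 3:1]
    design$library_id <- paste(design$species, design$stage,
                               design$replicate, sep = "_")

    reads <- vector("list", nrow(design))
    names(reads) <- design$library_id
    read_sources <- vector("list", nrow(design))
    names(read_sources) <- design$library_id
    source_counts <- matrix(0L, n, nrow(design),
                            dimnames = list(genes, design$library_id))
    contam_reads <- stats::setNames(integer(nrow(design)),
                                    design$library_id)
    error_reads <- stats::setNames(integer(nrow(design)),
                                   design$library_id)

    for (li in seq_len(nrow(design))) {
      sp <- design$species[li]
      cond <- paste(sp, design$stage[li], sep = ".")
      sets <- tag_sets[[sp]]
      w <- expected[, cond] *
        stats::rlnorm(n, 0, config$replicate_sdlog)
      # a transcript whose (possibly diverged) sequence lost every CATG
      # site emits no tags at all
      w[lengths(sets) == 0L] <- 0
      n_contam <- stats::rbinom(1L, config$depth,
                                config$contaminant_fraction)
      n_gene <- config$depth - n_contam
      gcounts <- as.integer(stats::rmultinom(1L, n_gene, w))
      source_counts[, li] <- gcounts
      lib_reads <- vector("list", n)
      for (g in which(gcounts > 0L)) {
        tg <- sets[[g]]
        if (length(tg) == 1L) {
          lib_reads[[g]] <- rep(tg, gcounts[g])
        } else {
          # 3'-most site dominates (anchored digestion); sites are in
          # ascending offset order so the last one carries weight 1
          site_w <- config$tag_site_decay^rev(seq_along(tg) - 1L)
          tc <- as.integer(stats::rmultinom(1L, gcounts[g], site_w))
          lib_reads[[g]] <- rep(tg, tc)
        }
      }
      src <- rep(genes, vapply(lib_reads, length, integer(1)))
      rd <- unlist(lib_reads, use.names = FALSE)
      if (n_contam > 0L) {
        cc <- as.integer(stats::rmultinom(1L, n_contam, pool_w))
        rd <- c(rd, rep(pool, cc))
        src <- c(src, rep(NA_character_, n_contam))
      }
      nerr <- stats::rbinom(length(rd), TAG_LENGTH, config$error_rate)
      err <- which(nerr > 0L)
      for (i in err) {
        rd[i] <- mutate_bases(rd[i], sample.int(TAG_LENGTH, nerr[i]))
      }
      perm <- sample.int(length(rd))
      reads[[li]] <- rd[perm]
      read_sources[[li]] <- data.frame(source_gene = src[perm],
                                       n_errors = nerr[perm],
                                       stringsAsFactors = FALSE)
      contam_reads[li] <- n_contam
      error_reads[li] <- length(err)
    }
    list(design = design[, c("library_id", "species", "stage",
                             "replicate")],
         reads = reads,
         truth = list(baseline = stats::setNames(baseline, genes),
                      stage_up = stats::setNames(stage_up, genes),
                      species_log2fc = stats::setNames(species_log2fc,
                                                       genes),
                      expected = expected,
                      source_counts = source_counts,
                      read_sources = read_sources,
                      contaminant_pool = pool,
                      contaminant_reads = contam_reads,
                      error_reads = error_reads))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sim$design$fastq <- file.path(out_dir,
                                  paste0(sim$design$library_id, ".fastq"))
    qual <- strrep("I", TAG_LENGTH)
    for (li in seq_len(nrow(sim$design))) {
      rd <- sim$reads[[li]]
      writeLines(paste0("@read", seq_along(rd), "\n", rd, "\n+\n", qual),
                 sim$design$fastq[li])
    }
    utils::write.table(sim$design, file.path(out_dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_tab <- data.frame(gene = genes,
                            baseline = sim$truth$baseline,
                            stage_up = sim$truth$stage_up,
                            species_log2fc = sim$truth$species_log2fc,
                            stringsAsFactors = FALSE)
    utils::write.table(truth_tab, file.path(out_dir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(sim, class = "sim_experiment")
}

#' Simulate a gene -> term annotation table
#'
#' Background terms are assigned at random; a few marker terms draw most
#' of their members from the planted stage-effect genes so that
#' enrichment of a recovered DEG set has signal to find.
#'
#' @param config A \code{sim_config}.
#' @param truth The \code{truth} element of a \code{sim_experiment}.
#' @param n_terms Number of background terms.
#' @param n_marker Number of DE-enriched marker terms.
#' @return data.frame with gene_id, term_id, term_name, namespace.
#' @export
simulate_annotation <- function(config, truth, n_terms = 30L,
                                n_marker = 3L) {
  stopifnot(inherits(config, "sim_config"))
  genes <- names(truth$baseline)
  with_seed(config$seed + 2L, {
    rows <- list()
    for (t in seq_len(n_terms)) {
      members <- sample(genes, max(5L, stats::rbinom(1L, length(genes),
                                                     0.03)))
      rows[[t]] <- data.frame(gene_id = members,
                              term_id = sprintf("TERM:%04d", t),
                              term_name = sprintf("background process %d",
                                                  t),
                              namespace = "biological_process",
                              stringsAsFactors = FALSE)
    }
    de_genes <- genes[!is.na(truth$stage_up)]
    for (t in seq_len(n_marker)) {
      k_de <- min(length(de_genes), 30L)
      members <- unique(c(sample(de_genes, k_de),
                          sample(genes, 10L)))
      rows[[n_terms + t]] <- data.frame(
        gene_id = members,
        term_id = sprintf("TERM:M%02d", t),
        term_name = sprintf("stage-regulated module %d", t),
        namespace = "biological_process",
        stringsAsFactors = FALSE)
    }
    unique(do.call(rbind, rows))
  })
}

#' Run the planted-effect recovery study
#'
#' Simulates a complete experiment from \code{config}, runs the analysis
#' (reference db, tag cleaning, mapping, TPM, noise-distribution DE on
#' every within-species stage contrast) and scores recovery of the
#' planted stage effects against ground truth.  A planted gene counts as
#' recovered when it is called significant in at least one contrast where
#' it is truly differentially expressed; a null gene counts as a false
#' positive when it is called in any contrast where it is not.
#' Between-species contrasts are excluded from scoring because
#' cross-species mapping loss (sequence divergence against a single
#' reference) systematically distorts them — the same caveat that applies
#' to real cross-species tag mapping.
#'
#' @param config A \code{sim_config}.
#' @param q_threshold,m_threshold Calling thresholds (defaults 0.8 and 1).
#' @return List: \code{sensitivity}, \code{false_positive_proportion}
#'   (gene-level, as above), \code{pair_sensitivity} and \code{pair_fpp}
#'   (per gene-contrast pair), \code{replicate_r} (per-pair TPM Pearson
#'   correlations), \code{clean_pct} and \code{unambiguous_pct} ranges,
#'   plus the fitted objects (\code{expr}, \code{fits}, \code{sim}).
#' @export
recovery_study <- function(config, q_threshold = 0.8, m_threshold = 1) {
  stopifnot(inherits(config, "sim_config"))
  ref <- simulate_reference(config)
  sim <- simulate_libraries(config, ref)
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa))
  write_fasta(ref$transcripts_sp1, fa)
  tdb <- build_transcript_db(fa)
  d <- sim$design
  libs <- lapply(seq_len(nrow(d)), function(i)
    clean_library(sim$reads[[i]], library_id = d$library_id[i],
                  species = d$species[i], stage = d$stage[i],
                  replicate = d$replicate[i]))
  expr <- build_expression_matrix(libs, tdb)

  genes <- rownames(expr$tpm)
  hit_true <- hit_false <- stats::setNames(rep(FALSE, length(genes)),
                                           genes)
  tp <- fp <- nde <- nnull <- 0L
  fits <- list()
  for (sp in unique(d$species)) {
    for (i in 1:2) {
      for (j in (i + 1L):3L) {
        s1 <- SIM_STAGES[i]; s2 <- SIM_STAGES[j]
        ct <- tag_contrast(d$library_id[d$species == sp & d$stage == s1],
                           d$library_id[d$species == sp & d$stage == s2],
                           sprintf("%s: %s vs %s", sp, s1, s2))
        fit <- tag_de(expr, ct, q_threshold = q_threshold,
                      m_threshold = m_threshold)
        truth <- true_stage_de(sim$truth, s1, s2)[fit$gene]
        tp <- tp + sum(fit$significant & truth)
        fp <- fp + sum(fit$significant & !truth)
        nde <- nde + sum(truth); nnull <- nnull + sum(!truth)
        hit_true[fit$gene[fit$significant & truth]] <- TRUE
        hit_false[fit$gene[fit$significant & !truth]] <- TRUE
        fits[[ct$label]] <- fit
      }
    }
  }
  planted <- names(which(!is.na(sim$truth$stage_up)))
  nulls <- setdiff(genes, planted)
  qc <- qc_summary(libs)
  list(sensitivity = mean(hit_true[planted]),
       false_positive_proportion = mean(hit_false[nulls]),
       pair_sensitivity = tp / nde,
       pair_fpp = fp / nnull,
       replicate_r = replicate_correlation(expr)$r,
       clean_pct = qc$clean_pct,
       unambiguous_pct = expr$mapping$unambiguous_pct,
       expr = expr, fits = fits, sim = sim)
}

#' Expected true DE status for a stage contrast
#'
#' Derives, from planted truth, which genes are truly differentially
#' expressed between two stages (within species; stage effects are shared
#' by both species).
#'
#' @param truth The \code{truth} element of a \code{sim_experiment}.
#' @param stage1,stage2 Stage labels of the contrast.
#' @return Logical vector over genes: TRUE when the gene's planted peak
#'   stage is exactly one of the two stages.
#' @export
true_stage_de <- function(truth, stage1, stage2) {
  up <- truth$stage_up
  !is.na(up) & (up == stage1 | up == stage2)
}
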