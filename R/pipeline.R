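# End-to-end pipeline: configuration and design validation, stage
# orchestration, DEG overlap accounting and output writing.

#' Validate an experiment design table
#'
#' Checks the libraries form a full species x stage x replicate factorial
#' and reports the design arithmetic, including the total number of pooled
#' workers when each library pools \code{bees_per_library} individuals
#' (60 per library in the classic 2 x 3 x 2 gland study, i.e. 720
#' workers).
#'
#' @param design data.frame with columns library_id, species, stage,
#'   replicate.
#' @param bees_per_library Individuals pooled per library (default 60).
#' @return List: n_species, n_stages, n_replicates, n_libraries,
#'   pooled_workers.
#' @export
validate_design <- function(design, bees_per_library = 60L) {
  need <- c("library_id", "species", "stage", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$library_id)) stop("duplicate library ids")
  tab <- table(design$species, design$stage)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
    stop("design is not a full species x stage factorial")
  n_rep <- unique(as.vector(tab))
  list(n_species = nrow(tab), n_stages = ncol(tab), n_replicates = n_rep,
       n_libraries = nrow(design),
       pooled_workers = nrow(design) * bees_per_library)
}

#' Pipeline configuration
#'
#' Bundles all stage parameters; unknown arguments are rejected.
#'
#' @param transcript_fasta,genome_fasta Reference FASTA paths (genome
#'   optional).
#' @param design data.frame (library_id, species, stage, replicate, and a
#'   \code{path} or \code{fastq} column locating each library's reads or
#'   counts).
#' @param annotation Optional annotation data.frame or TSV path for
#'   enrichment.
#' @param out_dir Output directory.
#' @param quality_floor,max_mismatch,anchor_strict,pseudo,q_threshold,
#'   m_threshold,alpha_p,alpha_q,linkage,distance,zero_sub Stage
#'   parameters, as documented on the stage functions.
#' @param bees_per_library Design metadata (see
#'   \code{\link{validate_design}}).
#' @param seed Seed for the saturation subsampling.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(transcript_fasta, genome_fasta = NULL,
                            design, annotation = NULL, out_dir,
                            quality_floor = 10L, max_mismatch = 1L,
                            anchor_strict = TRUE, pseudo = 0.5,
                            q_threshold = 0.8, m_threshold = 1,
                            alpha_p = 0.05, alpha_q = 0.05,
                            linkage = "average", distance = "euclidean",
                            zero_sub = 0.01, bees_per_library = 60L,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_design(cfg$design, cfg$bees_per_library)
  stopifnot(file.exists(cfg$transcript_fasta),
            is.null(cfg$genome_fasta) || file.exists(cfg$genome_fasta),
            cfg$q_threshold > 0, cfg$q_threshold < 1,
            cfg$m_threshold >= 0, cfg$pseudo > 0,
            cfg$max_mismatch %in% c(0L, 1L))
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may contain any \code{\link{pipeline_config}} argument;
#' \code{design} and \code{annotation} are given as TSV paths.  Unknown
#' keys are rejected.
#'
#' @param path YAML config path.
#' @param overrides Named list of values taking precedence over the file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.character(raw$design))
    raw$design <- utils::read.delim(raw$design, stringsAsFactors = FALSE)
  do.call(pipeline_config, raw)
}

stage_contrasts <- function(design) {
  species <- unique(design$species)
  stages <- unique(design$stage)
  contrasts <- list()
  for (sp in species) {
    for (i in seq_len(length(stages) - 1L)) {
      for (j in seq((i + 1L), length(stages))) {
        c1 <- design$library_id[design$species == sp &
                                design$stage == stages[i]]
        c2 <- design$library_id[design$species == sp &
                                design$stage == stages[j]]
        contrasts[[length(contrasts) + 1L]] <-
          tag_contrast(c1, c2, sprintf("%s: %s vs %s", sp, stages[i],
                                       stages[j]))
      }
    }
  }
  contrasts
}

species_contrasts <- function(design) {
  species <- unique(design$species)
  if (length(species) != 2L) return(list())
  lapply(unique(design$stage), function(st) {
    c1 <- design$library_id[design$species == species[1L] &
                            design$stage == st]
    c2 <- design$library_id[design$species == species[2L] &
                            design$stage == st]
    tag_contrast(c1, c2, sprintf("%s vs %s at %s", species[1L],
                                 species[2L], st))
  })
}

# Set-algebra summary of DEG membership across a list of fits.
deg_overlap <- function(fits) {
  sets <- lapply(fits, function(f) f$gene[f$significant])
  names(sets) <- vapply(fits, function(f) attr(f, "contrast")$label, "")
  all_genes <- unique(unlist(sets, use.names = FALSE))
  list(per_contrast = lengths(sets),
       union = length(all_genes),
       intersection = if (length(sets))
         length(Reduce(intersect, sets)) else 0L,
       sets = sets)
}

#' Run the full DGE-tag pipeline
#'
#' Builds the reference tag databases, cleans and maps every library,
#' quantifies TPM, fits the noise-distribution DE model for every
#' within-species stage contrast and every between-species stage contrast,
#' summarises DEG overlaps, runs enrichment when an annotation is
#' supplied, and computes the between-species log-ratio matrix with its
#' dendrogram.  All outputs are written as TSV (plus Newick) under
#' \code{config$out_dir} together with a run log; every output directory
#' carries the config hash so reruns are identifiable.  The pipeline is a
#' pure function of (inputs, config, seed).
#'
#' @param config A \code{pipeline_config}.
#' @return (Invisibly) a list with the in-memory results: \code{libs},
#'   \code{qc}, \code{expr}, \code{saturation}, \code{fits_stage},
#'   \code{fits_species}, \code{overlap_stage}, \code{overlap_species},
#'   \code{enrichment}, \code{ratio}, \code{clustering},
#'   \code{config_hash}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, fmt, ...) {
    msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                   stage, sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  hash <- config_hash(config)
  writeLines(hash, file.path(config$out_dir, "config.hash"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logf(stage, "FAILED: %s", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tdb <- run_stage("build-db", build_transcript_db(config$transcript_fasta))
  gdb <- if (!is.null(config$genome_fasta))
    run_stage("build-db", build_genome_db(config$genome_fasta)) else NULL
  logf("build-db", "transcript tags=%d genome tags=%s",
       tdb$n_distinct_tags,
       if (is.null(gdb)) "NA" else gdb$n_distinct_tags)

  path_col <- if (!is.null(config$design$path)) "path" else "fastq"
  libs <- run_stage("qc", lapply(seq_len(nrow(config$design)), function(i) {
    d <- config$design[i, ]
    read_tag_library(d[[path_col]], library_id = d$library_id,
                     species = d$species, stage = d$stage,
                     replicate = d$replicate,
                     quality_floor = config$quality_floor)
  }))
  qc <- qc_summary(libs)
  utils::write.table(qc, file.path(config$out_dir, "qc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (l in libs) logf("qc", "%s raw=%d clean=%d", l$library_id,
                       l$raw_tags, l$clean_tags)

  expr <- run_stage("map", build_expression_matrix(
    libs, tdb, gdb, max_mismatch = config$max_mismatch,
    anchor_strict = config$anchor_strict))
  utils::write.table(expr$mapping,
                     file.path(config$out_dir, "mapping_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(expr,
                          file.path(config$out_dir,
                                    "expression_matrix.tsv"))
  logf("map", "genes=%d mean unambiguous%%=%.2f", nrow(expr$counts),
       mean(expr$mapping$unambiguous_pct))

  sat <- run_stage("qc", {
    l1 <- libs[[1L]]
    depths <- unique(round(seq(0, l1$clean_tags, length.out = 21L)))
    saturation_curve(l1, tdb, depths, seed = config$seed,
                     max_mismatch = config$max_mismatch,
                     anchor_strict = config$anchor_strict)
  })
  utils::write.table(sat, file.path(config$out_dir, "saturation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fit_all <- function(contrasts) {
    fits <- lapply(contrasts, function(ct)
      tag_de(expr, ct, pseudo = config$pseudo,
             q_threshold = config$q_threshold,
             m_threshold = config$m_threshold))
    for (f in fits) {
      label <- gsub("[^A-Za-z0-9]+", "_", attr(f, "contrast")$label)
      write_de_table(f, file.path(config$out_dir,
                                  paste0("de_", label, ".tsv")))
      logf("de", "%s significant=%d", attr(f, "contrast")$label,
           sum(f$significant))
    }
    fits
  }
  fits_stage <- run_stage("de", fit_all(stage_contrasts(config$design)))
  fits_species <- run_stage("de", fit_all(species_contrasts(config$design)))

  overlap_stage <- deg_overlap(fits_stage)
  overlap_species <- deg_overlap(fits_species)
  overlap_tab <- rbind(
    data.frame(set = names(overlap_stage$per_contrast),
               degs = as.integer(overlap_stage$per_contrast)),
    data.frame(set = c("stage contrasts: union",
                       "stage contrasts: intersection",
                       "species contrasts: union",
                       "species contrasts: intersection"),
               degs = c(overlap_stage$union, overlap_stage$intersection,
                        overlap_species$union,
                        overlap_species$intersection)),
    data.frame(set = names(overlap_species$per_contrast),
               degs = as.integer(overlap_species$per_contrast)))
  utils::write.table(overlap_tab,
                     file.path(config$out_dir, "deg_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enr <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (is.character(config$annotation))
      read_annotation(config$annotation) else config$annotation
    degs <- unique(unlist(overlap_stage$sets, use.names = FALSE))
    enr <- run_stage("enrich",
                     enrich(degs, ann, alpha_p = config$alpha_p,
                            alpha_q = config$alpha_q))
    write_enrichment(enr, file.path(config$out_dir, "enrichment.tsv"))
    logf("enrich", "terms=%d significant=%d", nrow(enr),
         sum(enr$significant))
  }

  ratio <- clustering <- NULL
  species <- unique(config$design$species)
  if (length(species) == 2L) {
    gene_set <- unique(unlist(overlap_species$sets, use.names = FALSE))
    if (length(gene_set) >= 2L) {
      ratio <- run_stage("cluster", log_ratio_matrix(
        expr, species[1L], species[2L], gene_set = gene_set,
        zero_sub = config$zero_sub))
      clustering <- run_stage("cluster", hierarchical_cluster(
        ratio, linkage = config$linkage, distance = config$distance))
      write_ratio_matrix(ratio,
                         file.path(config$out_dir, "ratio_matrix.tsv"))
      write_ratio_matrix(ratio,
                         file.path(config$out_dir,
                                   "ratio_matrix_leaf_ordered.tsv"),
                         order = clustering$order)
      write_dendrogram(clustering,
                       file.path(config$out_dir, "dendrogram.nwk"))
      logf("cluster", "genes=%d", nrow(ratio))
    }
  }

  logf("done", "outputs in %s (config %s)", config$out_dir, hash)
  invisible(list(libs = libs, qc = qc, expr = expr, saturation = sat,
                 fits_stage = fits_stage, fits_species = fits_species,
                 overlap_stage = overlap_stage,
                 overlap_species = overlap_species, enrichment = enr,
                 ratio = ratio, clustering = clustering,
                 config_hash = hash))
}

# md5 of the deparsed config (paths included) — identifies a run.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
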