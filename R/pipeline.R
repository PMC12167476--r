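#' Count category membership of a hit list
#'
#' Classifies every hit gene with [classify_lnc_category()] against the
#' supplied annotation and tabulates the categories. Classification is a
#' partition, so the counts always sum to the number of hits.
#'
#' @param hit_gene_ids character vector of hit gene ids.
#' @param annotation a [gene_annotation()] (or coercible data.frame)
#'   containing every hit gene.
#' @param ... passed to [classify_annotation()] (window sizes).
#' @return Named integer vector over the five categories (antisense,
#'   intergenic, intronic, bidirectional, protein_coding).
#' @export
summarize_categories <- function(hit_gene_ids, annotation, ...) {
  levels <- c("antisense", "intergenic", "intronic", "bidirectional",
              "protein_coding")
  if (length(hit_gene_ids) == 0L) {
    return(structure(integer(length(levels)), names = levels))
  }
  cl <- classify_annotation(annotation, gene_ids = hit_gene_ids, ...)
  tab <- table(factor(cl$category, levels = levels))
  structure(as.integer(tab), names = levels)
}

pipeline_defaults <- list(
  endpoint = NULL, reference = "plasmid", tau = 3, k = 3L,
  n_resamples = 10000L, pseudocount = 1, min_reference_count = 10,
  trim5 = 0L, seed = 1L, verbose = TRUE)

log_line <- function(con, verbose, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  if (verbose) message(msg)
}

# serialize a gene_scores frame to TSV (top-k guide lfcs joined by commas)
write_scores_tsv <- function(scores, path) {
  df <- as.data.frame(scores)
  if (!is.null(df$topk_lfcs)) {
    df$topk_lfcs <- vapply(df$topk_lfcs, function(v) {
      paste(format(v, digits = 15, trim = TRUE), collapse = ",")
    }, character(1L))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full dropout-screen pipeline
#'
#' End-to-end driver: reads the library, obtains counts (from a counts
#' TSV, a [count_table()], or by counting FASTQ files), scores genes
#' against the NTC null, ranks dropout and enrichment hits, and -- when
#' an annotation is given -- classifies hits into lncRNA genomic
#' categories. All outputs are plain TSV for diffability; every
#' parameter and seed is recorded in `run.log`. Outputs other than the
#' log are byte-identical across reruns of the same configuration.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   * `library`: path to a library TSV or a [guide_library()];
#'   * `counts`: path to a counts TSV or a [count_table()], **or**
#'     `fastqs`: named list of per-sample FASTQ paths (counted with
#'     `trim5`) together with `reference` naming the plasmid sample;
#'   * `annotation`: optional gene BED6 path / [gene_annotation()]
#'     (optionally `exon_bed`);
#'   * `out_dir`: output directory;
#'   * `endpoint` (default: first non-reference sample), `tau`, `k`,
#'     `n_resamples`, `pseudocount`, `min_reference_count`, `trim5`,
#'     `seed`, `verbose` -- all optional, defaulting to the scoring
#'     defaults.
#' @return Invisibly, a list with `scores`, `phenotypes`, `hits_dropout`,
#'   `hits_enrichment`, `categories` (or `NULL`), `category_summary`
#'   (or `NULL`), and `files` (paths written).
#' @export
run_screen_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults, config)
  if (is.null(cfg$out_dir)) stop_("config must give `out_dir`")
  if (is.null(cfg$library)) stop_("config must give `library`")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  log_line(con, cfg$verbose, "crisprdrop pipeline run ",
           format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  for (p in c("endpoint", "reference", "tau", "k", "n_resamples",
              "pseudocount", "min_reference_count", "trim5", "seed")) {
    log_line(con, FALSE, "param ", p, " = ",
             if (is.null(cfg[[p]])) "NULL" else format(cfg[[p]]))
  }

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(con, cfg$verbose, "[", name, "] ERROR: ", conditionMessage(e))
      stop_("[", name, "] ", conditionMessage(e))
    })
  }

  library <- step("library", {
    if (inherits(cfg$library, "guide_library")) cfg$library
    else read_library_tsv(cfg$library)
  })
  log_line(con, cfg$verbose, "[library] ", nrow(library), " guides")

  table <- step("count", {
    if (!is.null(cfg$counts)) {
      if (inherits(cfg$counts, "count_table")) cfg$counts
      else read_counts(cfg$counts)
    } else if (!is.null(cfg$fastqs)) {
      if (is.null(cfg$reference) || !cfg$reference %in% names(cfg$fastqs)) {
        stop_("`reference` must name one of the fastq samples")
      }
      maps <- lapply(cfg$fastqs, function(fq) {
        count_spacers(fq, library, trim5 = cfg$trim5)$counts
      })
      assemble_count_table(maps, library, cfg$reference)
    } else {
      stop_("config must give `counts` or `fastqs`")
    }
  })
  log_line(con, cfg$verbose, "[count] ", nrow(table$counts), " guides x ",
           ncol(table$counts), " samples (reference ", table$reference, ")")

  endpoint <- cfg$endpoint
  if (is.null(endpoint)) {
    endpoint <- setdiff(colnames(table$counts), table$reference)[1L]
  }
  scores <- step("score", {
    score_screen(table, library, endpoint, tau = cfg$tau, k = cfg$k,
                 n_resamples = cfg$n_resamples, seed = cfg$seed,
                 pseudocount = cfg$pseudocount,
                 min_reference_count = cfg$min_reference_count)
  })
  null <- attr(scores, "null")
  log_line(con, cfg$verbose, sprintf(
    "[score] endpoint %s: %d genes scored; null mu = %.4f sigma = %.4f",
    endpoint, sum(scores$scored), null$mu, null$sigma))

  hits_drop <- rank_hits(scores, "dropout")
  hits_enr <- rank_hits(scores, "enrichment")
  log_line(con, cfg$verbose, "[rank] ", nrow(hits_drop), " dropout hits, ",
           nrow(hits_enr), " enrichment hits")

  files <- c(
    phenotypes = file.path(cfg$out_dir, "guide_phenotypes.tsv"),
    scores = file.path(cfg$out_dir, "gene_scores.tsv"),
    hits_dropout = file.path(cfg$out_dir, "ranked_hits_dropout.tsv"),
    hits_enrichment = file.path(cfg$out_dir, "ranked_hits_enrichment.tsv"))
  phen <- attr(scores, "phenotypes")
  utils::write.table(phen, files["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_scores_tsv(scores, files["scores"])
  write_scores_tsv(hits_drop, files["hits_dropout"])
  write_scores_tsv(hits_enr, files["hits_enrichment"])

  categories <- NULL; cat_summary <- NULL
  if (!is.null(cfg$annotation)) {
    ann <- step("annotation", {
      if (inherits(cfg$annotation, "gene_annotation")) cfg$annotation
      else read_annotation_bed(cfg$annotation, cfg$exon_bed)
    })
    hit_ids <- hits_drop$gene_id
    categories <- step("categories", {
      if (length(hit_ids) > 0L) classify_annotation(ann, hit_ids)
      else data.frame(gene_id = character(0), category = character(0))
    })
    cat_summary <- summarize_categories(hit_ids, ann)
    files["categories"] <- file.path(cfg$out_dir, "hit_categories.tsv")
    files["category_summary"] <- file.path(cfg$out_dir,
                                           "category_summary.tsv")
    utils::write.table(categories, files["categories"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(category = names(cat_summary),
                                  n_hits = as.integer(cat_summary)),
                       files["category_summary"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_line(con, cfg$verbose, "[categories] ",
             paste(sprintf("%s=%d", names(cat_summary), cat_summary),
                   collapse = " "))
  }
  log_line(con, cfg$verbose, "done; outputs in ", cfg$out_dir)
  invisible(list(scores = scores, phenotypes = phen,
                 hits_dropout = hits_drop, hits_enrichment = hits_enr,
                 categories = categories, category_summary = cat_summary,
                 files = files))
}
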