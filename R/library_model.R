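#' sgRNA library design
#'
#' Validates and classes a table of guide records as a `guide_library`.
#' Each guide carries a unique id, its spacer (the 19-20 nt protospacer-
#' matching sequence used for read counting), a guide class, and the gene
#' it targets. Non-targeting controls (NTCs) match nowhere in the genome
#' and must have an empty `target_gene_id`; they supply the empirical null
#' for gene scoring.
#'
#' @param guides data.frame with columns `guide_id`, `spacer`,
#'   `guide_class` (one of `"tss_targeting"`, `"non_targeting"`,
#'   `"positive_control"`), `target_gene_id`.
#' @param guides_per_gene designed number of guides per targeted TSS
#'   (default 10); stored as an attribute and used as the default
#'   pseudo-gene size when building the NTC null.
#' @param duplicate_spacers `"error"` (default) rejects libraries with
#'   duplicated spacer sequences -- exact-match counting cannot
#'   disambiguate them -- while `"warn"` downgrades to a warning.
#' @return A `guide_library`: the validated data.frame with attribute
#'   `guides_per_gene`.
#' @examples
#' lib <- guide_library(data.frame(
#'   guide_id = c("g1", "g2", "ntc1"),
#'   spacer = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT",
#'              "GGGGACGTACGTACGTACGT"),
#'   guide_class = c("tss_targeting", "tss_targeting", "non_targeting"),
#'   target_gene_id = c("LNC1", "LNC1", "")))
#' @export
guide_library <- function(guides, guides_per_gene = 10L,
                          duplicate_spacers = c("error", "warn")) {
  duplicate_spacers <- match.arg(duplicate_spacers)
  required <- c("guide_id", "spacer", "guide_class", "target_gene_id")
  if (!is.data.frame(guides) || !all(required %in% names(guides))) {
    stop_("`guides` must be a data.frame with columns ",
          paste(required, collapse = ", "))
  }
  if (!is_count(guides_per_gene) || guides_per_gene < 1) {
    stop_("`guides_per_gene` must be a positive integer")
  }
  guides <- as.data.frame(guides[required], stringsAsFactors = FALSE)
  guides$target_gene_id[is.na(guides$target_gene_id)] <- ""

  if (anyDuplicated(guides$guide_id)) {
    stop_("duplicate guide_id: ",
          paste(unique(guides$guide_id[duplicated(guides$guide_id)]),
                collapse = ", "))
  }
  bad_spacer <- !grepl("^[ACGT]{19,20}$", guides$spacer)
  if (any(bad_spacer)) {
    stop_("invalid spacer (must be 19-20 nt uppercase ACGT) for guide(s): ",
          paste(utils::head(guides$guide_id[bad_spacer], 5L), collapse = ", "))
  }
  valid_cls <- c("tss_targeting", "non_targeting", "positive_control")
  if (!all(guides$guide_class %in% valid_cls)) {
    stop_("guide_class must be one of ", paste(valid_cls, collapse = ", "))
  }
  ntc <- guides$guide_class == "non_targeting"
  if (any(ntc & nzchar(guides$target_gene_id))) {
    stop_("non_targeting guides must have an empty target_gene_id")
  }
  if (any(!ntc & !nzchar(guides$target_gene_id))) {
    stop_("targeting guides must have a non-empty target_gene_id")
  }
  if (anyDuplicated(guides$spacer)) {
    dups <- unique(guides$spacer[duplicated(guides$spacer)])
    msg <- paste0("duplicated spacer sequence(s): ",
                  paste(utils::head(dups, 3L), collapse = ", "))
    if (duplicate_spacers == "error") stop_(msg) else warning(msg)
  }
  rownames(guides) <- NULL
  structure(guides,
            guides_per_gene = as.integer(guides_per_gene),
            class = c("guide_library", "data.frame"))
}

#' @export
print.guide_library <- function(x, ...) {
  tab <- table(x$guide_class)
  n_genes <- length(unique(x$target_gene_id[nzchar(x$target_gene_id)]))
  cat(sprintf("sgRNA library: %d guides, %d target genes (%d designed guides/gene)\n",
              nrow(x), n_genes, attr(x, "guides_per_gene")))
  for (cls in names(tab)) cat(sprintf("  %-16s %d\n", cls, tab[[cls]]))
  invisible(x)
}

# unique random 20-mers; regenerates collisions until unique
random_spacers <- function(n, len = 20L) {
  if (n == 0L) return(character(0))
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  sp <- draw(n)
  while (anyDuplicated(sp)) {
    i <- which(duplicated(sp))
    sp[i] <- draw(length(i))
  }
  sp
}

#' Build a synthetic sgRNA library with the screen's design composition
#'
#' Generates a library shaped like a TSS-targeting CRISPRi lncRNA screen:
#' `n_lnc_genes` lncRNA targets with `guides_per_gene` guides each,
#' `n_ntc` non-targeting controls, and `n_positive_genes` protein-coding
#' positive-control genes with `guides_per_gene` guides each. The default
#' arguments reproduce the design used for a genome-scale monocyte
#' screen: 2342 lncRNAs x 10 guides + 700 NTCs + 50 positive-control
#' genes x 10 guides (24,620 guides, ~25,000).
#'
#' Spacers are unique random 20-mers drawn deterministically from `seed`.
#'
#' @param n_lnc_genes number of lncRNA target genes.
#' @param guides_per_gene guides designed per targeted TSS.
#' @param n_ntc number of non-targeting control guides.
#' @param n_positive_genes number of positive-control protein-coding genes.
#' @param seed integer seed for spacer generation.
#' @return A [guide_library].
#' @examples
#' lib <- build_default_library(n_lnc_genes = 5, n_ntc = 10,
#'                              n_positive_genes = 1, seed = 1)
#' nrow(lib)  # 5*10 + 10 + 1*10 = 70
#' @export
build_default_library <- function(n_lnc_genes = 2342L, guides_per_gene = 10L,
                                  n_ntc = 700L, n_positive_genes = 50L,
                                  seed = 1L) {
  for (arg in list(n_lnc_genes, guides_per_gene, n_ntc, n_positive_genes)) {
    if (!is_count(arg)) stop_("library composition counts must be non-negative integers")
  }
  if (guides_per_gene < 1) stop_("`guides_per_gene` must be >= 1")

  lnc_genes <- if (n_lnc_genes > 0) sprintf("LNC%04d", seq_len(n_lnc_genes)) else character(0)
  pos_genes <- if (n_positive_genes > 0) sprintf("PC%03d", seq_len(n_positive_genes)) else character(0)

  gene_of <- c(rep(lnc_genes, each = guides_per_gene),
               rep("", n_ntc),
               rep(pos_genes, each = guides_per_gene))
  cls <- c(rep("tss_targeting", n_lnc_genes * guides_per_gene),
           rep("non_targeting", n_ntc),
           rep("positive_control", n_positive_genes * guides_per_gene))
  guide_ids_of <- function(genes) {
    if (length(genes) == 0L) return(character(0))
    paste0(rep(genes, each = guides_per_gene), "_g",
           rep(seq_len(guides_per_gene), times = length(genes)))
  }
  ids <- c(guide_ids_of(lnc_genes),
           if (n_ntc > 0) sprintf("NTC%04d", seq_len(n_ntc)) else character(0),
           guide_ids_of(pos_genes))

  spacers <- with_seed(seed, random_spacers(length(ids)))
  guide_library(data.frame(guide_id = ids, spacer = spacers,
                           guide_class = cls, target_gene_id = gene_of,
                           stringsAsFactors = FALSE),
                guides_per_gene = guides_per_gene)
}

#' Read / write a guide library as TSV
#'
#' Tab-separated with header columns `guide_id`, `spacer`, `guide_class`,
#' `target_gene_id`.
#'
#' @param path file path.
#' @param ... passed to [guide_library()] (e.g. `duplicate_spacers`).
#' @return [read_library_tsv()] returns a [guide_library];
#'   [write_library_tsv()] returns `path` invisibly.
#' @export
read_library_tsv <- function(path, ...) {
  df <- utils::read.delim(path, colClasses = "character")
  guide_library(df, ...)
}

#' @rdname read_library_tsv
#' @param library a [guide_library].
#' @export
write_library_tsv <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
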