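#' Gene annotation table
#'
#' Validates a table of gene intervals for lncRNA category classification.
#' Coordinates are 0-based half-open (BED convention); the transcription
#' start site (TSS) of a `+` strand gene is `start`, of a `-` strand gene
#' `end - 1`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `biotype` (`"protein_coding"`,
#'   `"lncRNA"`, or `"other"`), and optionally `exons` (a list column of
#'   two-column start/end matrices, used for the intronic rule).
#' @return A `gene_annotation` data.frame with a derived `tss` column.
#' @export
gene_annotation <- function(genes) {
  required <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!is.data.frame(genes) || !all(required %in% names(genes))) {
    stop_("`genes` must be a data.frame with columns ",
          paste(required, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop_("duplicate gene_id in annotation")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop_("gene intervals must satisfy 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop_("strand must be '+' or '-'")
  if (!all(genes$biotype %in% c("protein_coding", "lncRNA", "other"))) {
    stop_("biotype must be protein_coding, lncRNA, or other")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (is.null(genes$exons)) {
    genes$exons <- replicate(nrow(genes), NULL, simplify = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex)) next
    ex <- matrix(as.numeric(ex), ncol = 2L)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] >= ex[, 2L]) ||
        any(ex[, 1L] < genes$start[i]) || any(ex[, 2L] > genes$end[i]) ||
        (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))) {
      stop_("exons of gene ", genes$gene_id[i],
            " must be disjoint, sorted, and within the gene interval")
    }
    genes$exons[[i]] <- ex
  }
  rownames(genes) <- NULL
  structure(genes[c(required, "tss", "exons")],
            class = c("gene_annotation", "data.frame"))
}

# intron intervals (0-based half-open) between consecutive exons
introns_of <- function(exons) {
  if (is.null(exons) || nrow(exons) < 2L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  cbind(exons[-nrow(exons), 2L], exons[-1L, 1L])
}

#' Classify a lncRNA into its genomic category
#'
#' Assigns exactly one category relative to neighboring genes on the same
#' chromosome, by precedence:
#'
#' 1. `protein_coding` -- the gene's own biotype is protein-coding
#'    (re-annotated loci).
#' 2. `antisense` -- the lncRNA overlaps a neighbor's interval on the
#'    opposite strand (transcribed from the same locus in the opposite
#'    direction).
#' 3. `intronic` -- the lncRNA lies fully within one intron of a
#'    neighbor.
#' 4. `bidirectional` -- its TSS is within `bidirectional_window` bp of
#'    an opposite-strand neighbor's TSS, without overlap (shared
#'    divergent promoter).
#' 5. `intergenic` -- no overlap with any neighbor and every neighbor TSS
#'    at least `intergenic_min_distance` bp away (own promoter).
#'
#' Overlap-based labels dominate distance-based ones; a gene satisfying
#' none of the rules raises an error naming it, so classification is a
#' partition of any input set it accepts.
#'
#' @param lnc single-row [gene_annotation()] (or a list with the same
#'   fields) for the gene to classify.
#' @param neighbors [gene_annotation()] rows on the same chromosome
#'   (the gene itself is ignored if present).
#' @param bidirectional_window max TSS-to-TSS distance in bp for the
#'   bidirectional call (default 1000).
#' @param intergenic_min_distance min TSS-to-TSS distance in bp required
#'   for the intergenic call (default 1000).
#' @return One of `"protein_coding"`, `"antisense"`, `"intronic"`,
#'   `"bidirectional"`, `"intergenic"`.
#' @export
classify_lnc_category <- function(lnc, neighbors,
                                  bidirectional_window = 1000,
                                  intergenic_min_distance = 1000) {
  if (is.data.frame(lnc)) {
    if (nrow(lnc) != 1L) stop_("`lnc` must be a single gene")
    lnc <- as.list(lnc)
    lnc$exons <- lnc$exons[[1L]]
  }
  if (is.null(lnc$tss)) {
    lnc$tss <- if (lnc$strand == "+") lnc$start else lnc$end - 1L
  }
  if (bidirectional_window <= 0 || intergenic_min_distance <= 0) {
    stop_("classification windows must be positive")
  }
  if (identical(lnc$biotype, "protein_coding")) return("protein_coding")

  nb <- as.data.frame(neighbors, stringsAsFactors = FALSE)
  nb <- nb[nb$gene_id != lnc$gene_id, , drop = FALSE]
  if (nrow(nb) > 0L && any(nb$chrom != lnc$chrom)) {
    stop_("neighbors of ", lnc$gene_id, " must be on chromosome ", lnc$chrom)
  }
  if (is.null(nb$tss) && nrow(nb) > 0L) {
    nb$tss <- ifelse(nb$strand == "+", nb$start, nb$end - 1L)
  }

  overlap <- nb$start < lnc$end & lnc$start < nb$end
  opposite <- nb$strand != lnc$strand
  if (any(overlap & opposite)) return("antisense")

  exlist <- if (is.null(nb$exons)) replicate(nrow(nb), NULL, simplify = FALSE) else nb$exons
  for (i in seq_len(nrow(nb))) {
    intr <- introns_of(exlist[[i]])
    if (nrow(intr) > 0L &&
        any(intr[, 1L] <= lnc$start & lnc$end <= intr[, 2L])) {
      return("intronic")
    }
  }

  tss_dist <- abs(nb$tss - lnc$tss)
  if (any(opposite & !overlap & tss_dist <= bidirectional_window)) {
    return("bidirectional")
  }
  if (!any(overlap) &&
      (nrow(nb) == 0L || min(tss_dist) >= intergenic_min_distance)) {
    return("intergenic")
  }
  stop_("cannot classify gene ", lnc$gene_id,
        ": no category rule applies (same-strand overlap or promoter ",
        "closer than ", intergenic_min_distance, " bp without a ",
        "bidirectional partner)")
}

#' Classify every gene of an annotation
#'
#' Applies [classify_lnc_category()] to each requested gene, using all
#' other genes on the same chromosome as its neighbors.
#'
#' @param annotation a [gene_annotation()].
#' @param gene_ids genes to classify (default: all).
#' @inheritParams classify_lnc_category
#' @return data.frame with columns `gene_id`, `category`.
#' @export
classify_annotation <- function(annotation, gene_ids = NULL,
                                bidirectional_window = 1000,
                                intergenic_min_distance = 1000) {
  ann <- gene_annotation(annotation)
  if (is.null(gene_ids)) gene_ids <- ann$gene_id
  missing <- setdiff(gene_ids, ann$gene_id)
  if (length(missing) > 0L) {
    stop_("gene(s) absent from annotation: ", paste(missing, collapse = ", "))
  }
  cat_of <- vapply(gene_ids, function(g) {
    i <- match(g, ann$gene_id)
    nb <- ann[ann$chrom == ann$chrom[i] & ann$gene_id != g, , drop = FALSE]
    classify_lnc_category(ann[i, , drop = FALSE], nb,
                          bidirectional_window, intergenic_min_distance)
  }, character(1L))
  data.frame(gene_id = gene_ids, category = unname(cat_of),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation from BED-style TSV
#'
#' `genes_bed` is a BED6-style table (no header) with columns chrom,
#' start, end, gene_id, biotype, strand; `exon_bed` optionally supplies
#' exon intervals as chrom, start, end, gene_id.
#'
#' @param genes_bed path to the gene BED6 file.
#' @param exon_bed optional path to an exon BED file.
#' @return A [gene_annotation()].
#' @export
read_annotation_bed <- function(genes_bed, exon_bed = NULL) {
  g <- utils::read.delim(genes_bed, header = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "gene_id", "biotype", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"))
  df <- g[c("gene_id", "chrom", "start", "end", "strand", "biotype")]
  if (!is.null(exon_bed)) {
    ex <- utils::read.delim(exon_bed, header = FALSE,
                            col.names = c("chrom", "start", "end", "gene_id"))
    sp <- split(ex, ex$gene_id)
    df$exons <- lapply(df$gene_id, function(g) {
      e <- sp[[g]]
      if (is.null(e)) NULL else cbind(e$start, e$end)
    })
  }
  gene_annotation(df)
}

#' Read a gene annotation from GTF
#'
#' Convenience importer mapping GTF `gene` and `exon` records onto the
#' annotation table; requires the rtracklayer package. Biotypes other
#' than `protein_coding` and `lncRNA` map to `"other"`; GTF's 1-based
#' closed coordinates are converted to 0-based half-open.
#'
#' @param path GTF file.
#' @return A [gene_annotation()].
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_("read_annotation_gtf() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  biotype_col <- intersect(c("gene_biotype", "gene_type"), names(meta))[1L]
  if (is.na(biotype_col)) stop_("GTF lacks a gene_biotype/gene_type attribute")
  is_gene <- meta$type == "gene"
  genes <- gr[is_gene]
  gm <- S4Vectors::mcols(genes)
  bt <- as.character(gm[[biotype_col]])
  bt[!bt %in% c("protein_coding", "lncRNA")] <- "other"
  exons <- gr[meta$type == "exon"]
  ex_by <- split(data.frame(start = BiocGenerics::start(exons) - 1L,
                            end = BiocGenerics::end(exons)),
                 as.character(S4Vectors::mcols(exons)$gene_id))
  df <- data.frame(gene_id = as.character(gm$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = BiocGenerics::start(genes) - 1L,
                   end = BiocGenerics::end(genes),
                   strand = as.character(BiocGenerics::strand(genes)),
                   biotype = bt, stringsAsFactors = FALSE)
  df$exons <- lapply(df$gene_id, function(g) {
    e <- ex_by[[g]]
    if (is.null(e)) NULL else {
      e <- e[order(e$start), ]
      # merge overlapping exon records from multiple transcripts
      out <- list()
      cur <- c(e$start[1L], e$end[1L])
      for (i in seq_len(nrow(e))[-1L]) {
        if (e$start[i] <= cur[2L]) cur[2L] <- max(cur[2L], e$end[i])
        else { out[[length(out) + 1L]] <- cur; cur <- c(e$start[i], e$end[i]) }
      }
      out[[length(out) + 1L]] <- cur
      do.call(rbind, out)
    }
  })
  gene_annotation(df)
}
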