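#' Collapse FASTQ reads to per-guide spacer counts
#'
#' Each read is matched by extracting the substring
#' `[trim5, trim5 + spacer_len)` and requiring it to equal a library
#' spacer exactly (zero mismatches). A read contributes to at most one
#' guide; reads matching no spacer -- including reads shorter than
#' `trim5 + spacer_len` -- are tallied as unmatched, so
#' `sum(counts) + unmatched` always equals the number of reads.
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param library a [guide_library()].
#' @param trim5 bases to skip at the 5' end before the spacer (default 0).
#' @param spacer_len spacer length; defaults to the library's spacer
#'   length (must be uniform).
#' @param revcomp also search the reverse complement of each read that
#'   fails to match in the forward orientation (default `FALSE`).
#' @return list with `counts` (named integer vector over all library
#'   guides), `unmatched`, and `n_reads`.
#' @export
count_spacers <- function(fastq, library, trim5 = 0L, spacer_len = NULL,
                          revcomp = FALSE) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  if (nrow(library) == 0L) stop_("cannot count against an empty library")
  if (!is_count(trim5)) stop_("`trim5` must be a non-negative integer")
  lens <- unique(nchar(library$spacer))
  if (is.null(spacer_len)) {
    if (length(lens) != 1L) {
      stop_("library has mixed spacer lengths; give `spacer_len` explicitly")
    }
    spacer_len <- lens
  }
  if (!spacer_len %in% lens) {
    stop_("`spacer_len` (", spacer_len, ") does not match library spacer lengths (",
          paste(lens, collapse = ", "), ")")
  }

  zero <- structure(integer(nrow(library)), names = library$guide_id)
  if (!file.exists(fastq)) stop_("FASTQ file not found: ", fastq)
  lines <- readLines(fastq, warn = FALSE)  # transparently gunzips
  n <- length(lines)
  if (n == 0L) return(list(counts = zero, unmatched = 0L, n_reads = 0L))
  # 4-line records: @id / sequence / + / qualities
  if (n %% 4L != 0L) {
    stop_("malformed FASTQ '", fastq, "': truncated record ",
          n %/% 4L + 1L, " (file has ", n, " lines)")
  }
  heads <- seq.int(1L, n, by = 4L)
  bad <- which(!startsWith(lines[heads], "@") |
                 !startsWith(lines[heads + 2L], "+") |
                 nchar(lines[heads + 1L]) != nchar(lines[heads + 3L]))
  if (length(bad) > 0L) {
    stop_("malformed FASTQ '", fastq, "': record ", bad[1L],
          " is not a valid @/sequence/+/quality block")
  }
  seqs <- lines[heads + 1L]
  n_reads <- length(seqs)

  window <- substr(seqs, trim5 + 1L, trim5 + spacer_len)
  idx <- match(window, library$spacer)
  idx[nchar(window) < spacer_len] <- NA_integer_
  if (revcomp && anyNA(idx)) {
    miss <- which(is.na(idx))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[miss])))
    rcw <- substr(rc, trim5 + 1L, trim5 + spacer_len)
    ridx <- match(rcw, library$spacer)
    ridx[nchar(rcw) < spacer_len] <- NA_integer_
    idx[miss] <- ridx
  }
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$guide_id
  list(counts = counts, unmatched = sum(is.na(idx)), n_reads = n_reads)
}

#' Guide-by-sample count table
#'
#' Container for non-negative integer sgRNA counts with a designated
#' reference sample (the plasmid pool the screen endpoint is compared
#' against).
#'
#' @param counts integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample ids).
#' @param reference_sample column holding the plasmid-pool counts.
#' @return A `count_table` (list with elements `counts`, `reference`).
#' @export
count_table <- function(counts, reference_sample) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("`counts` needs guide rownames and sample colnames")
  }
  if (anyDuplicated(colnames(counts))) stop_("duplicate sample ids")
  if (anyDuplicated(rownames(counts))) stop_("duplicate guide ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_("counts must be non-negative integers")
  }
  if (!reference_sample %in% colnames(counts)) {
    stop_("reference sample '", reference_sample, "' not among samples: ",
          paste(colnames(counts), collapse = ", "))
  }
  storage.mode(counts) <- "numeric"
  structure(list(counts = counts, reference = reference_sample),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count table: %d guides x %d samples (reference: %s)\n",
              nrow(x$counts), ncol(x$counts), x$reference))
  cat("  depth:", paste(sprintf("%s=%.0f", colnames(x$counts),
                                colSums(x$counts)), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble per-sample count maps into a count table
#'
#' Guides absent from a sample's map get count 0; column order follows
#' the order of `maps`.
#'
#' @param maps named list (names = sample ids) of named count vectors.
#' @param library a [guide_library()]; every map's guide set must be a
#'   subset of the library's.
#' @param reference_sample which sample is the plasmid pool.
#' @return A [count_table()].
#' @export
assemble_count_table <- function(maps, library, reference_sample) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    stop_("`maps` must be a named list of per-sample count vectors")
  }
  if (anyDuplicated(names(maps))) stop_("duplicate sample_id in `maps`")
  mat <- matrix(0, nrow = nrow(library), ncol = length(maps),
                dimnames = list(library$guide_id, names(maps)))
  for (s in names(maps)) {
    m <- maps[[s]]
    unknown <- setdiff(names(m), library$guide_id)
    if (length(unknown) > 0L) {
      stop_("sample '", s, "' has guide ids not in the library: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
    }
    mat[names(m), s] <- m
  }
  count_table(mat, reference_sample)
}

#' Read / write a count table as TSV
#'
#' Plain tab-separated file with a `#reference=<sample_id>` comment line,
#' then a header (`guide_id` plus one column per sample). The round trip
#' `write_counts()` then `read_counts()` is exact.
#'
#' @param path file path.
#' @return [read_counts()] returns a [count_table()].
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#reference=")) {
    stop_("counts file lacks the '#reference=<sample_id>' header line")
  }
  ref <- sub("^#reference=", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  count_table(mat, ref)
}

#' @rdname read_counts
#' @param table a [count_table()].
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#reference=", table$reference), con)
  df <- data.frame(guide_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
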