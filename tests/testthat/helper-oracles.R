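# Independent oracles and fixture builders used across tests.

# Brute-force two-sided Mann-Whitney p by enumerating every assignment of
# the pooled values to the two groups and counting concordant pairs
# directly (ties count 1/2). Independent of the rank-based implementation.
mw_brute_force <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  # pairwise win matrix: 1 if pool[i] beats pool[j], 1/2 on a tie
  CM <- outer(pool, pool, ">") + 0.5 * outer(pool, pool, "==")
  diag(CM) <- 0
  u_of <- function(i) sum(CM[i, -i])
  u_obs <- u_of(seq_len(n))
  us <- apply(combn(n + m, n), 2L, u_of)
  mu <- n * m / 2
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Monte-Carlo oracle for the NTC pseudo-gene null mean: draws pseudo-genes
# one at a time and scores them with head/tail selection rather than the
# package's vectorized sort pipeline.
null_mu_oracle <- function(ntc_lfcs, size, k, n_resamples, seed) {
  set.seed(seed)
  scores <- vapply(seq_len(n_resamples), function(i) {
    v <- sort(sample(ntc_lfcs, size))
    if (median(v) > 0) mean(tail(v, k)) else mean(head(v, k))
  }, numeric(1))
  mean(scores)
}

# Deterministic unique 20-mers for hand-built libraries.
random_spacers_for_test <- function(n) {
  stopifnot(n <= 100)
  base <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                      c = c("A", "C", "G", "T"))
  prefix <- do.call(paste0, base)[seq_len(n)]
  paste0(prefix, strrep("ACGTA", 4), "GG")[seq_len(n)] |>
    substr(1, 20)
}

# Small library for quantify/score tests: n_genes lncRNA genes plus NTCs.
toy_library <- function(n_genes = 3, guides_per_gene = 4, n_ntc = 6,
                        seed = 42) {
  build_default_library(n_lnc_genes = n_genes,
                        guides_per_gene = guides_per_gene,
                        n_ntc = n_ntc, n_positive_genes = 0, seed = seed)
}

# Annotation fixture with a requested number of genes per category.
# Each classified gene sits in its own 1 Mb block on chr1 together with
# the partner gene its category needs; blocks are far enough apart that
# genes never interact across blocks.
make_category_annotation <- function(n_antisense = 0, n_intergenic = 0,
                                     n_protein = 0, n_intronic = 0,
                                     n_bidirectional = 0) {
  rows <- list(); hits <- character(0); expected <- character(0)
  block <- 0L
  add <- function(gene_id, start, end, strand, biotype, exons = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, chrom = "chr1", start = start, end = end,
      strand = strand, biotype = biotype, stringsAsFactors = FALSE)
    attr(rows[[length(rows)]], "exons") <<- exons
  }
  place <- function(kind, i) {
    base <- block * 1000000L; block <<- block + 1L
    id <- sprintf("%s_%02d", kind, i)
    partner <- paste0(id, "_nb")
    if (kind == "antisense") {
      add(partner, base + 9000, base + 15000, "+", "protein_coding")
      add(id, base + 10000, base + 12000, "-", "lncRNA")
    } else if (kind == "intergenic") {
      add(partner, base + 55000, base + 57000, "+", "protein_coding")
      add(id, base + 50000, base + 51000, "+", "lncRNA")
    } else if (kind == "protein") {
      add(id, base + 10000, base + 12000, "+", "protein_coding")
    } else if (kind == "intronic") {
      add(partner, base + 15000, base + 30000, "+", "protein_coding",
          exons = cbind(c(base + 15000, base + 25000),
                        c(base + 20000, base + 30000)))
      add(id, base + 21000, base + 21800, "+", "lncRNA")
    } else if (kind == "bidirectional") {
      add(partner, base + 10000, base + 12000, "+", "protein_coding")
      add(id, base + 8000, base + 9900, "-", "lncRNA")
    }
    hits <<- c(hits, id)
    expected <<- c(expected,
                   if (kind == "protein") "protein_coding" else kind)
  }
  for (i in seq_len(n_antisense)) place("antisense", i)
  for (i in seq_len(n_intergenic)) place("intergenic", i)
  for (i in seq_len(n_protein)) place("protein", i)
  for (i in seq_len(n_intronic)) place("intronic", i)
  for (i in seq_len(n_bidirectional)) place("bidirectional", i)
  df <- do.call(rbind, rows)
  df$exons <- lapply(rows, attr, "exons")
  list(annotation = gene_annotation(df), hits = hits, expected = expected)
}

# Library + neutral simulated screen at the calibration conditions used
# throughout: 200 lncRNA genes x 10 guides, 100 NTCs, coverage 1000,
# depth 500 reads/guide.
calibration_library <- function() {
  build_default_library(n_lnc_genes = 200, guides_per_gene = 10,
                        n_ntc = 100, n_positive_genes = 0, seed = 1000)
}
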