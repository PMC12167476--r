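#' Median-normalize a count table against the plasmid pool
#'
#' Rescales every sample so its median guide count equals the reference
#' (plasmid-pool) median:
#' `normalized(g, s) = raw(g, s) * median(reference) / median(s)`.
#' The reference column is left unchanged. This removes sequencing-depth
#' differences between samples while keeping counts on the familiar
#' reference read scale.
#'
#' @param table a [count_table()] of raw counts.
#' @return A `count_table` whose `counts` are normalized (numeric) and
#'   which carries the raw matrix in `$raw`.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "count_table"))
  raw <- table$counts
  med <- apply(raw, 2L, stats::median)
  zero <- med == 0
  if (any(zero)) {
    stop_("cannot median-normalize: zero median count in sample(s) ",
          paste(colnames(raw)[zero], collapse = ", "))
  }
  norm <- sweep(raw, 2L, med[table$reference] / med, `*`)
  structure(list(counts = norm, reference = table$reference, raw = raw),
            class = "count_table")
}

#' Per-guide log2 fold change of an endpoint vs the plasmid pool
#'
#' Computes, per guide,
#' `lfc = log2((norm_endpoint + pseudocount) / (norm_reference + pseudocount))`
#' on median-normalized counts. Guides with fewer than
#' `min_reference_count` raw reads in the plasmid pool are poorly
#' represented before selection and produce unstable fold changes; they
#' get `passed_filter = FALSE` and are excluded from gene scoring.
#'
#' @param table a [count_table()] (raw; normalized internally).
#' @param library a [guide_library()] matching the table's guides.
#' @param endpoint sample id of the screen endpoint (e.g. `"day21"`);
#'   must differ from the reference.
#' @param pseudocount added to both normalized counts (default 1 read).
#' @param min_reference_count minimum raw reads in the reference column
#'   (default 10).
#' @return data.frame (one row per guide): `guide_id`, `guide_class`,
#'   `target_gene_id`, `raw_reference`, `norm_reference`,
#'   `norm_endpoint`, `lfc`, `passed_filter`.
#' @export
guide_lfc <- function(table, library, endpoint, pseudocount = 1,
                      min_reference_count = 10) {
  stopifnot(inherits(table, "count_table"))
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  if (!endpoint %in% colnames(table$counts)) {
    stop_("unknown endpoint sample '", endpoint, "'")
  }
  if (endpoint == table$reference) {
    stop_("endpoint must differ from the reference sample")
  }
  if (!is_number(pseudocount) || pseudocount <= 0) {
    stop_("`pseudocount` must be > 0")
  }
  if (!is_count(min_reference_count)) {
    stop_("`min_reference_count` must be a non-negative integer")
  }
  if (!setequal(rownames(table$counts), library$guide_id)) {
    stop_("count table guides do not match the library")
  }
  nt <- if (is.null(table$raw)) median_normalize(table) else table
  norm <- nt$counts[library$guide_id, , drop = FALSE]
  raw <- nt$raw[library$guide_id, , drop = FALSE]

  raw_ref <- raw[, nt$reference]
  lfc <- log2((norm[, endpoint] + pseudocount) /
              (norm[, nt$reference] + pseudocount))
  data.frame(guide_id = library$guide_id,
             guide_class = library$guide_class,
             target_gene_id = library$target_gene_id,
             raw_reference = unname(raw_ref),
             norm_reference = unname(norm[, nt$reference]),
             norm_endpoint = unname(norm[, endpoint]),
             lfc = unname(lfc),
             passed_filter = unname(raw_ref >= min_reference_count),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test of a gene's guide fold changes vs the NTC pool
#'
#' Rank-sum comparison of a gene's guide log2 fold changes against the
#' non-targeting-control fold changes. When the number of distinct group
#' assignments `choose(n+m, n)` is at most `max_exact`, the two-sided
#' p-value is exact: every assignment is enumerated (mid-ranks for ties)
#' and `p = P(|U' - nm/2| >= |U - nm/2|)`. Otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param gene_lfcs numeric, fold changes of the gene's guides (>= 2).
#' @param ntc_lfcs numeric, fold changes of the NTC guides (>= 2).
#' @param max_exact largest `choose(n+m, n)` for which the exact
#'   enumeration is used (default 1e5).
#' @return list with `u` (U statistic of the gene group), `p` (two-sided
#'   p-value in (0, 1]), and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_gene(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_gene <- function(gene_lfcs, ntc_lfcs, max_exact = 1e5) {
  n <- length(gene_lfcs); m <- length(ntc_lfcs)
  if (n < 2L || m < 2L) stop_("both groups need at least 2 values")
  if (anyNA(gene_lfcs) || anyNA(ntc_lfcs)) stop_("fold changes contain NA")
  r <- rank(c(gene_lfcs, ntc_lfcs))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  n_comb <- choose(n + m, n)
  if (n_comb <= max_exact) {
    cmb <- utils::combn(n + m, n)
    us <- colSums(matrix(r[cmb], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    tt <- table(r)
    tie_term <- sum(tt^3 - tt)
    sig2 <- n * m / 12 * ((n + m + 1) - tie_term / ((n + m) * (n + m - 1)))
    if (sig2 <= 0) {            # all values identical
      p <- 1
    } else {
      d <- u - mu
      z <- (d - sign(d) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p = max(p, .Machine$double.xmin), method = method)
}

#' Empirical null from non-targeting-control pseudo-genes
#'
#' Builds the null distribution of the gene-level top-k statistic by
#' repeatedly drawing `pseudo_gene_size` NTC fold changes without
#' replacement ("pseudo-genes") and scoring each exactly as a real gene
#' is scored -- mean of its `k` most extreme fold changes in the sign of
#' its own median.
#'
#' The mean `mu` and standard deviation `sigma` of the resampled scores
#' standardize gene-level statistics into z-scores. Because pseudo-gene
#' direction follows the sign of the median, the null assumes the NTC
#' fold changes are centered; [score_screen()] re-centers all fold
#' changes at the NTC median before building the null, so both
#' directions are represented equally. Per-direction moments
#' (`mu_dir`/`sigma_dir`) are stored as diagnostics.
#'
#' @param ntc_lfcs fold changes of NTC guides that passed the filter.
#' @param pseudo_gene_size guides per pseudo-gene; use the library's
#'   guides-per-gene (default 10).
#' @param k top-k guides aggregated (default 3).
#' @param n_resamples number of pseudo-genes (default 10000, minimum 100).
#' @param seed integer seed; the null is deterministic given the seed.
#' @return An `ntc_null`: list with `pseudo_gene_scores`, `mu`, `sigma`,
#'   `k`, `pseudo_gene_size`, `n_resamples`, `seed`.
#' @export
build_ntc_null <- function(ntc_lfcs, pseudo_gene_size = 10L, k = 3L,
                           n_resamples = 10000L, seed = 1L) {
  ntc_lfcs <- ntc_lfcs[is.finite(ntc_lfcs)]
  if (!is_count(pseudo_gene_size) || pseudo_gene_size < 1) {
    stop_("`pseudo_gene_size` must be a positive integer")
  }
  if (pseudo_gene_size > length(ntc_lfcs)) {
    stop_("`pseudo_gene_size` exceeds the number of usable NTC fold changes (",
          length(ntc_lfcs), ")")
  }
  if (!is_count(k) || k < 1 || k > pseudo_gene_size) {
    stop_("`k` must be in 1..pseudo_gene_size")
  }
  if (!is_count(n_resamples) || n_resamples < 100) {
    stop_("`n_resamples` must be at least 100")
  }
  vals <- with_seed(seed, {
    idx <- replicate(n_resamples, sample.int(length(ntc_lfcs),
                                             pseudo_gene_size))
    matrix(ntc_lfcs[idx], nrow = pseudo_gene_size)
  })
  sorted <- apply(vals, 2L, sort)
  sz <- pseudo_gene_size
  med <- if (sz %% 2L == 1L) sorted[(sz + 1L) / 2L, ] else
    (sorted[sz / 2L, ] + sorted[sz / 2L + 1L, ]) / 2
  bottom <- colMeans(sorted[seq_len(k), , drop = FALSE])
  top <- colMeans(sorted[seq.int(sz - k + 1L, sz), , drop = FALSE])
  dir <- ifelse(med > 0, 1L, -1L)
  scores <- ifelse(dir > 0L, top, bottom)
  sigma <- stats::sd(scores)
  if (!is.finite(sigma) || sigma < .Machine$double.eps^0.5) {
    stop_("degenerate NTC null (sigma ~ 0): the NTC fold changes have no ",
          "spread; supply more varied NTCs or more resamples")
  }
  moments_of <- function(d, fallback) {
    s <- scores[dir == d]
    if (length(s) < 30L || stats::sd(s) < .Machine$double.eps^0.5) {
      s <- fallback
    }
    c(mu = mean(s), sigma = stats::sd(s))
  }
  m_neg <- moments_of(-1L, bottom)
  m_pos <- moments_of(1L, top)
  structure(list(pseudo_gene_scores = scores,
                 pseudo_gene_directions = dir,
                 mu = mean(scores), sigma = sigma,
                 mu_dir = c(`-1` = unname(m_neg["mu"]),
                            `1` = unname(m_pos["mu"])),
                 sigma_dir = c(`-1` = unname(m_neg["sigma"]),
                               `1` = unname(m_pos["sigma"])),
                 k = as.integer(k),
                 pseudo_gene_size = as.integer(pseudo_gene_size),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "ntc_null")
}

#' @export
print.ntc_null <- function(x, ...) {
  cat(sprintf(paste0("NTC pseudo-gene null: mu = %.4f, sigma = %.4f ",
                     "(%d resamples of %d guides, top-%d)\n"),
              x$mu, x$sigma, x$n_resamples, x$pseudo_gene_size, x$k))
  cat(sprintf("  dropout direction:    mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu_dir[["-1"]], x$sigma_dir[["-1"]],
              sum(x$pseudo_gene_directions == -1L)))
  cat(sprintf("  enrichment direction: mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu_dir[["1"]], x$sigma_dir[["1"]],
              sum(x$pseudo_gene_directions == 1L)))
  invisible(x)
}

# direction (sign of median, ties -> -1 = dropout) and mean of the k
# most extreme values in that direction
topk_stat <- function(lfcs, k, presorted = FALSE) {
  if (!presorted) lfcs <- sort(lfcs)
  n <- length(lfcs)
  med <- if (n %% 2L == 1L) lfcs[(n + 1L) / 2L] else
    (lfcs[n / 2L] + lfcs[n / 2L + 1L]) / 2
  direction <- if (med > 0) 1L else -1L
  topk <- if (direction < 0L) lfcs[seq_len(k)] else lfcs[seq.int(n - k + 1L, n)]
  list(direction = direction, topk_mean = mean(topk), topk = topk)
}

#' Score one gene against the NTC null
#'
#' The gene's phenotype is the mean fold change of its `k` most extreme
#' guides in its dominant direction (sign of the median guide fold
#' change; ties default to dropout). The z-score standardizes that
#' statistic against the NTC pseudo-gene null; genes with `z < -tau` are
#' positive regulators of growth (their guides dropped out), genes with
#' `z > tau` negative regulators. A Mann-Whitney U test against the NTC
#' fold changes accompanies the z-score.
#'
#' @param gene_lfcs fold changes of the gene's usable guides.
#' @param null an [build_ntc_null()] result.
#' @param ntc_lfcs NTC fold changes for the Mann-Whitney test.
#' @param tau z threshold magnitude (default 3).
#' @param max_exact passed to [mann_whitney_gene()].
#' @return One-row data.frame: `n_guides_used`, `direction`,
#'   `topk_mean_lfc`, `z`, `u_stat`, `p_value`, `hit_class`, `scored`,
#'   plus the top-k guide fold changes as a list column `topk_lfcs`.
#' @export
score_gene <- function(gene_lfcs, null, ntc_lfcs, tau = 3, max_exact = 1e5) {
  stopifnot(inherits(null, "ntc_null"))
  if (!is_number(tau) || tau <= 0) stop_("`tau` must be > 0")
  gene_lfcs <- gene_lfcs[is.finite(gene_lfcs)]
  n <- length(gene_lfcs)
  if (n < max(null$k, 2L)) {
    return(data.frame(n_guides_used = n, direction = NA_integer_,
                      topk_mean_lfc = NA_real_, z = NA_real_,
                      u_stat = NA_real_, p_value = NA_real_,
                      hit_class = NA_character_, scored = FALSE,
                      topk_lfcs = I(list(numeric(0))),
                      stringsAsFactors = FALSE))
  }
  ts <- topk_stat(gene_lfcs, null$k)
  z <- (ts$topk_mean - null$mu) / null$sigma
  hit <- if (z < -tau) "positive_regulator"
         else if (z > tau) "negative_regulator" else "none"
  mw <- mann_whitney_gene(gene_lfcs, ntc_lfcs, max_exact = max_exact)
  data.frame(n_guides_used = n, direction = ts$direction,
             topk_mean_lfc = ts$topk_mean, z = z,
             u_stat = mw$u, p_value = mw$p, hit_class = hit, scored = TRUE,
             topk_lfcs = I(list(ts$topk)), stringsAsFactors = FALSE)
}

#' Score every gene of a screen
#'
#' Full gene-level scoring: median normalization, per-guide fold
#' changes, re-centering of all fold changes at the NTC median (the NTC
#' population defines "no effect"), NTC pseudo-gene null, and per-gene
#' top-k z-scores with Mann-Whitney p-values. Benjamini-Hochberg
#' q-values are attached for information; hit calls use the z threshold
#' only. The phenotype table attached as attribute `phenotypes` carries
#' both the raw `lfc` and the `lfc_centered` used for scoring.
#'
#' @param table raw [count_table()].
#' @param library matching [guide_library()].
#' @param endpoint endpoint sample id.
#' @param tau z threshold magnitude (default 3).
#' @param k top-k guides per gene (default 3).
#' @param n_resamples pseudo-genes for the null (default 10000).
#' @param seed seed for the null resampling.
#' @param pseudocount,min_reference_count passed to [guide_lfc()].
#' @param max_exact passed to [mann_whitney_gene()].
#' @return A `gene_scores` data.frame (one row per target gene):
#'   `gene_id`, `gene_class`, scoring columns of [score_gene()], and
#'   `bh_q`. The phenotype table and null are attached as attributes
#'   `phenotypes` and `null`.
#' @export
score_screen <- function(table, library, endpoint, tau = 3, k = 3L,
                         n_resamples = 10000L, seed = 1L, pseudocount = 1,
                         min_reference_count = 10, max_exact = 1e5) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  phen <- guide_lfc(table, library, endpoint, pseudocount,
                    min_reference_count)
  usable <- phen$passed_filter & is.finite(phen$lfc)
  if (sum(usable & phen$guide_class == "non_targeting") < 2L) {
    stop_("need at least 2 usable non-targeting-control guides")
  }
  # re-center all fold changes at the NTC median: the NTC population
  # defines "no effect", and with an appreciable dropout burden the
  # endpoint median normalization shifts every surviving guide's lfc
  # slightly; centering keeps the pseudo-gene null balanced between
  # directions
  ntc_center <- stats::median(
    phen$lfc[usable & phen$guide_class == "non_targeting"])
  phen$lfc_centered <- phen$lfc - ntc_center
  ntc_lfcs <- phen$lfc_centered[usable & phen$guide_class == "non_targeting"]
  null <- build_ntc_null(ntc_lfcs,
                         pseudo_gene_size = min(attr(library, "guides_per_gene"),
                                                length(ntc_lfcs)),
                         k = k, n_resamples = n_resamples, seed = seed)
  is_target <- phen$guide_class != "non_targeting"
  genes <- unique(phen$target_gene_id[is_target])
  rows <- lapply(genes, function(g) {
    gi <- usable & phen$target_gene_id == g & is_target
    score_gene(phen$lfc_centered[gi], null, ntc_lfcs, tau = tau,
               max_exact = max_exact)
  })
  out <- do.call(rbind, rows)
  cls <- library$guide_class[match(genes, library$target_gene_id)]
  out <- cbind(data.frame(gene_id = genes,
                          gene_class = cls, stringsAsFactors = FALSE), out)
  out$bh_q <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  structure(out, phenotypes = phen, null = null, tau = tau,
            class = c("gene_scores", "data.frame"))
}

#' Rank hits of a screen
#'
#' Filters scored genes to the requested hit class -- `"dropout"` keeps
#' positive regulators of growth (z < -tau), `"enrichment"` keeps
#' negative regulators (z > tau) -- and orders them by z (ascending for
#' dropout, descending for enrichment). Ties in z break by smaller
#' Mann-Whitney p-value, then lexicographic gene id. Each hit carries the
#' fold changes of its top-k guides as columns `top_lfc_1..k`.
#'
#' @param scores a `gene_scores` data.frame from [score_screen()] (or
#'   rows built with [score_gene()] plus a `gene_id` column).
#' @param direction `"dropout"` (default) or `"enrichment"`.
#' @return data.frame of ranked hits with a `rank` column.
#' @export
rank_hits <- function(scores, direction = c("dropout", "enrichment")) {
  direction <- match.arg(direction)
  want <- if (direction == "dropout") "positive_regulator" else "negative_regulator"
  hits <- scores[!is.na(scores$hit_class) & scores$hit_class == want, ,
                 drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$rank <- integer(0)
    return(as.data.frame(hits))
  }
  zkey <- if (direction == "dropout") hits$z else -hits$z
  ord <- order(zkey, hits$p_value, hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  if (!is.null(hits$topk_lfcs)) {
    kmax <- max(lengths(hits$topk_lfcs))
    for (j in seq_len(kmax)) {
      hits[[paste0("top_lfc_", j)]] <-
        vapply(hits$topk_lfcs, function(v) {
          if (length(v) >= j) sort(v)[if (direction == "dropout") j else length(v) - j + 1L]
          else NA_real_
        }, numeric(1L))
    }
  }
  rownames(hits) <- NULL
  as.data.frame(hits)
}
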