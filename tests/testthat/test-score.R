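make_ct <- function(ref, endpoint, guide_ids = NULL) {
  n <- length(ref)
  if (is.null(guide_ids)) guide_ids <- sprintf("g%02d", seq_len(n))
  count_table(matrix(c(ref, endpoint), ncol = 2,
                     dimnames = list(guide_ids, c("plasmid", "day21"))),
              "plasmid")
}

test_that("median normalization rescales to the reference median", {
  ct <- make_ct(ref = c(30, 50, 60, 70, 120),       # median 60
                endpoint = c(10, 20, 30, 40, 100))  # median 30
  nt <- median_normalize(ct)
  expect_equal(unname(nt$counts[, "day21"]), c(20, 40, 60, 80, 200))
  expect_equal(unname(nt$counts[, "plasmid"]), c(30, 50, 60, 70, 120))
  # a sample identical to the reference is unchanged
  ct2 <- make_ct(ref = c(10, 20, 30), endpoint = c(10, 20, 30))
  expect_equal(median_normalize(ct2)$counts, ct2$counts)
  # zero median is a named error
  ct3 <- make_ct(ref = c(10, 20, 30), endpoint = c(0, 0, 5))
  expect_error(median_normalize(ct3), "day21")
})

test_that("guide_lfc applies the log2 pseudocount formula and filter", {
  lib <- guide_library(data.frame(
    guide_id = sprintf("g%02d", 1:5),
    spacer = random_spacers_for_test(5),
    guide_class = "tss_targeting",
    target_gene_id = paste0("G", 1:5)), guides_per_gene = 1)
  # both sample medians are 20, so normalization is the identity
  ct <- make_ct(ref = c(15, 10, 20, 30, 40), endpoint = c(63, 12, 20, 30, 10))
  phen <- guide_lfc(ct, lib, "day21", pseudocount = 1,
                    min_reference_count = 10)
  expect_equal(phen$lfc[1], log2(64 / 16))  # = 2
  expect_equal(phen$lfc[3:4], c(0, 0))      # identical counts -> lfc 0
  expect_true(all(phen$passed_filter))

  # endpoint 0 vs reference 1023 -> exactly -10 (medians arranged equal)
  ct2 <- make_ct(ref = c(1023, 2, 50, 98, 10), endpoint = c(0, 2, 50, 98, 1030))
  phen2 <- guide_lfc(ct2, lib, "day21")
  expect_equal(phen2$lfc[1], -10)

  # guides under the raw reference threshold are filtered
  ct3 <- make_ct(ref = c(9, 10, 30, 50, 70), endpoint = c(9, 10, 30, 50, 70))
  phen3 <- guide_lfc(ct3, lib, "day21", min_reference_count = 10)
  expect_equal(phen3$passed_filter, c(FALSE, TRUE, TRUE, TRUE, TRUE))

  expect_error(guide_lfc(ct, lib, "day99"), "unknown endpoint")
  expect_error(guide_lfc(ct, lib, "plasmid"), "differ from the reference")
})

test_that("Mann-Whitney matches frozen enumeration values and the oracle", {
  r1 <- mann_whitney_gene(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$u, 0)
  expect_equal(r1$p, 2 / 20)
  expect_equal(r1$method, "exact")

  r2 <- mann_whitney_gene(c(-2.0, -1.8, -1.5), c(0.1, -0.1, 0.2, 0.0, -0.05))
  expect_equal(r2$u, 0)
  expect_equal(r2$p, 2 / 56)

  # label symmetry of the two-sided p
  x <- c(0.3, -1.2, 0.8, 2.0); y <- c(-0.4, 0.1, 1.1)
  expect_equal(mann_whitney_gene(x, y)$p, mann_whitney_gene(y, x)$p)

  # random instances vs the independent pair-counting oracle, with ties
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    vals <- if (i %% 2 == 0) sample(1:4, n + m, replace = TRUE)
            else rnorm(n + m)
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    got <- mann_whitney_gene(x, y)
    want <- mw_brute_force(x, y)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p)
  }

  # tie-free exact p agrees with the base-R exact rank-sum test
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney_gene(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }

  # large groups switch to the tie-corrected normal approximation
  set.seed(3)
  big <- mann_whitney_gene(rnorm(10), rnorm(700))
  expect_equal(big$method, "normal")
  expect_true(big$p > 0 && big$p <= 1)

  expect_error(mann_whitney_gene(1, c(1, 2)), "at least 2")
})

test_that("NTC null is seeded, degenerate-safe, and matches the MC oracle", {
  set.seed(21)
  ntc <- rnorm(300)
  a <- build_ntc_null(ntc, pseudo_gene_size = 10, k = 3,
                      n_resamples = 500, seed = 5)
  b <- build_ntc_null(ntc, pseudo_gene_size = 10, k = 3,
                      n_resamples = 500, seed = 5)
  expect_identical(a[c("mu", "sigma", "pseudo_gene_scores")],
                   b[c("mu", "sigma", "pseudo_gene_scores")])
  expect_true(a$sigma > 0)

  expect_error(build_ntc_null(rep(0.4, 50), n_resamples = 500, seed = 1),
               "degenerate")
  expect_error(build_ntc_null(ntc, pseudo_gene_size = 400, seed = 1),
               "exceeds")
  expect_error(build_ntc_null(ntc, n_resamples = 50, seed = 1),
               "at least 100")

  # mean of the null against an independently coded Monte-Carlo oracle
  null <- build_ntc_null(ntc, pseudo_gene_size = 10, k = 3,
                         n_resamples = 10000, seed = 2)
  mu_oracle <- null_mu_oracle(ntc, size = 10, k = 3,
                              n_resamples = 100000, seed = 3)
  expect_lt(abs(null$mu - mu_oracle), 0.05)
})

test_that("score_gene standardizes the top-k statistic and calls hits", {
  set.seed(1)
  ntc <- rnorm(200)
  null <- build_ntc_null(ntc, 10, 3, 1000, seed = 1)

  # z formula: plant a gene whose top-3 mean is exactly mu - 3.5 sigma
  target <- null$mu - 3.5 * null$sigma
  g <- rep(target, 10)
  s <- score_gene(g, null, ntc)
  expect_equal(s$topk_mean_lfc, target)
  expect_equal(s$z, -3.5)
  expect_equal(s$hit_class, "positive_regulator")
  expect_equal(s$direction, -1L)

  s_up <- score_gene(rep(null$mu + 3.2 * null$sigma, 10), null, ntc)
  expect_equal(s_up$hit_class, "negative_regulator")
  s_none <- score_gene(rep(null$mu - 2.9 * null$sigma, 10), null, ntc)
  expect_equal(s_none$hit_class, "none")

  # top-k = mean of the k most extreme guides in the dominant direction
  g2 <- c(-4, -3, -2, 0.1, 0.2, -0.1, -0.2, 0.3, -0.3, 0.05)
  s2 <- score_gene(g2, null, ntc)
  expect_equal(s2$topk_mean_lfc, mean(c(-4, -3, -2)))
  # dominant positive direction uses the top, not the bottom
  g3 <- c(4, 3, 2, rep(0.5, 7))
  s3 <- score_gene(g3, null, ntc)
  expect_equal(s3$direction, 1L)
  expect_equal(s3$topk_mean_lfc, mean(c(4, 3, 2)))

  # fewer than k usable guides -> unscored, not an error
  s4 <- score_gene(c(-1, -2), null, ntc)
  expect_false(s4$scored)
  expect_true(is.na(s4$z))
})

test_that("decreasing every guide lfc strictly decreases top-k mean and z", {
  set.seed(8)
  ntc <- rnorm(150)
  null <- build_ntc_null(ntc, 10, 3, 500, seed = 4)
  for (i in 1:10) {
    g <- rnorm(10)
    s <- score_gene(g, null, ntc)
    s_lower <- score_gene(g - runif(1, 0.1, 2), null, ntc)
    expect_lt(s_lower$topk_mean_lfc, s$topk_mean_lfc)
    expect_lt(s_lower$z, s$z)
  }
})

test_that("rank_hits filters by class, sorts by z, and breaks ties", {
  scores <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    n_guides_used = 10, direction = -1L,
    topk_mean_lfc = c(-5, -3.5, -2, -3.5, 4),
    z = c(-5, -3.5, -2, -3.5, 4),
    u_stat = 1, p_value = c(0.001, 0.02, 0.2, 0.01, 0.001),
    hit_class = c("positive_regulator", "positive_regulator", "none",
                  "positive_regulator", "negative_regulator"),
    scored = TRUE, stringsAsFactors = FALSE)
  ranked <- rank_hits(scores, "dropout")
  expect_equal(ranked$gene_id, c("gA", "gD", "gB"))  # tie -3.5 by p-value
  expect_equal(ranked$rank, 1:3)
  enr <- rank_hits(scores, "enrichment")
  expect_equal(enr$gene_id, "gE")
  expect_equal(nrow(rank_hits(scores[0, ], "dropout")), 0)

  # lexicographic gene id breaks exact (z, p) ties
  tie <- scores[c(2, 4), ]
  tie$p_value <- 0.05
  expect_equal(rank_hits(tie, "dropout")$gene_id, c("gB", "gD"))
})

test_that("score_screen is deterministic and attaches a usable null", {
  lib <- build_default_library(10, 10, 30, 0, seed = 2)
  sim <- simulate_screen(lib, config = sim_config(seed = 9))
  s1 <- score_screen(sim$table, lib, "day21", n_resamples = 500, seed = 3)
  s2 <- score_screen(sim$table, lib, "day21", n_resamples = 500, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_s3_class(attr(s1, "null"), "ntc_null")
  expect_equal(nrow(s1), 10)
  expect_true(all(s1$bh_q >= s1$p_value - 1e-12))
})
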