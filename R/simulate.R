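#' Simulation configuration for a synthetic dropout screen
#'
#' Defaults mirror the screen's stated conditions: infection at MOI 0.3,
#' >1000 cells per guide at infection, 21 days of growth, and deep
#' endpoint sequencing (500 reads per guide unless `depth` is given).
#'
#' @param seed master integer seed; every stochastic stage derives from it.
#' @param moi multiplicity of infection in (0, 1] (default 0.3). MOI
#'   enters only as a thinning of founding cells by the probability that
#'   an infected cell carries a single integration,
#'   `moi * exp(-moi) / (1 - exp(-moi))`.
#' @param coverage cells per guide at infection (default 1000).
#' @param days growth duration in days (default 21).
#' @param doubling_time_days doubling time of unperturbed cells (default 1).
#' @param depth sequencing reads per sample; `NULL` (default) means
#'   500 x library size.
#' @param dispersion overdispersion of count sampling (>= 0, default 0).
#'   0 gives multinomial sampling; > 0 a Dirichlet-multinomial with
#'   concentration `proportions / dispersion`, approaching multinomial
#'   as dispersion tends to 0.
#' @param plasmid_lognormal_sigma log-normal sigma of plasmid guide
#'   abundances (default 0.5), emulating uneven library cloning.
#' @param guide_active_fraction probability that a targeting guide is
#'   effective at all (default 0.7): guide design against predicted TSSs
#'   leaves a fraction of guides inert.
#' @param knockdown_given_active knockdown strength of an effective
#'   guide in (0, 1] (default 0.9).
#' @param n_endpoint number of independent endpoint columns (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, moi = 0.3, coverage = 1000,
                       days = 21, doubling_time_days = 1, depth = NULL,
                       dispersion = 0, plasmid_lognormal_sigma = 0.5,
                       guide_active_fraction = 0.7,
                       knockdown_given_active = 0.9, n_endpoint = 1L) {
  stopifnot(is_number(moi), moi > 0, moi <= 1,
            is_number(coverage), coverage > 0,
            is_number(days), days >= 0,
            is_number(doubling_time_days), doubling_time_days > 0,
            is.null(depth) || (is_count(depth) && depth > 0),
            is_number(dispersion), dispersion >= 0,
            is_number(plasmid_lognormal_sigma), plasmid_lognormal_sigma >= 0,
            is_number(guide_active_fraction), guide_active_fraction >= 0,
            guide_active_fraction <= 1,
            is_number(knockdown_given_active), knockdown_given_active > 0,
            knockdown_given_active <= 1,
            is_count(n_endpoint), n_endpoint >= 1)
  structure(list(seed = as.integer(seed), moi = moi, coverage = coverage,
                 days = days, doubling_time_days = doubling_time_days,
                 depth = depth, dispersion = dispersion,
                 plasmid_lognormal_sigma = plasmid_lognormal_sigma,
                 guide_active_fraction = guide_active_fraction,
                 knockdown_given_active = knockdown_given_active,
                 n_endpoint = as.integer(n_endpoint)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror [sim_config()] arguments; unknown fields error.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0L) {
    stop_("unknown simulation config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' Ground truth for a simulated screen
#'
#' Planted per-gene fitness effects and per-guide efficacies. A gene
#' effect is the fractional growth-rate deficit when fully perturbed
#' (0 = neutral, 1 = growth arrested); a guide's realized knockdown is
#' `gene_effect * guide_efficacy`. Targeting guides are effective with
#' probability `guide_active_fraction` (efficacy
#' `knockdown_given_active`) and inert otherwise; NTC guides always have
#' efficacy 0.
#'
#' @param library a [guide_library()].
#' @param gene_effect named numeric vector in `[0, 1]` over (a subset
#'   of) target genes; unnamed genes default to 0 (neutral).
#' @param config a [sim_config()] supplying the efficacy model and seed.
#' @return A `sim_truth`: list with `gene_effect` (named, all target
#'   genes) and `guide_efficacy` (named, all guides).
#' @export
sim_truth <- function(library, gene_effect = NULL, config = sim_config()) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  genes <- unique(library$target_gene_id[nzchar(library$target_gene_id)])
  eff <- structure(numeric(length(genes)), names = genes)
  if (!is.null(gene_effect)) {
    if (is.null(names(gene_effect))) stop_("`gene_effect` must be named")
    unknown <- setdiff(names(gene_effect), genes)
    if (length(unknown) > 0L) {
      stop_("gene_effect names not in the library: ",
            paste(unknown, collapse = ", "))
    }
    if (any(gene_effect < 0 | gene_effect > 1)) {
      stop_("gene effects must lie in [0, 1]")
    }
    eff[names(gene_effect)] <- gene_effect
  }
  targeting <- library$guide_class != "non_targeting"
  active <- with_seed(config$seed + 1L,
                      stats::rbinom(nrow(library), 1L,
                                    config$guide_active_fraction))
  ge <- ifelse(targeting, active * config$knockdown_given_active, 0)
  structure(list(gene_effect = eff,
                 guide_efficacy = structure(ge, names = library$guide_id)),
            class = "sim_truth")
}

#' Simulate a pooled CRISPRi dropout screen
#'
#' Generative model of the screen in five seeded stages:
#' 1. plasmid guide abundances `a_g` proportional to
#'    LogNormal(0, `plasmid_lognormal_sigma`);
#' 2. founding cells per guide Poisson(`coverage * single_fraction *
#'    a_g / mean(a)`), where `single_fraction` is the MOI thinning --
#'    guides drawing zero founders are lost (library bottlenecking);
#' 3. deterministic exponential growth of expected clone sizes with rate
#'    `ln(2)/doubling_time * (1 - gene_effect * guide_efficacy)`;
#' 4. endpoint expected cells `founders * exp(rate * days)`;
#' 5. sequencing: multinomial sampling of `depth` reads from the
#'    relative abundances (Dirichlet-multinomial when `dispersion > 0`).
#'
#' @param library a [guide_library()].
#' @param truth a [sim_truth()] covering every guide and gene of the
#'   library.
#' @param config a [sim_config()].
#' @return list with `table` (a [count_table()] with a `plasmid`
#'   reference column and `day<days>` endpoint column(s)) and `truth`.
#' @export
simulate_screen <- function(library, truth = NULL, config = sim_config()) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- sim_truth(library, config = config)
  stopifnot(inherits(truth, "sim_truth"))
  genes <- unique(library$target_gene_id[nzchar(library$target_gene_id)])
  missing_g <- setdiff(genes, names(truth$gene_effect))
  missing_u <- setdiff(library$guide_id, names(truth$guide_efficacy))
  if (length(missing_g) > 0L || length(missing_u) > 0L) {
    stop_("truth does not cover the library; missing: ",
          paste(utils::head(c(missing_g, missing_u), 5L), collapse = ", "))
  }
  G <- nrow(library)
  depth <- if (is.null(config$depth)) 500 * G else config$depth

  gene_eff <- ifelse(nzchar(library$target_gene_id),
                     truth$gene_effect[library$target_gene_id], 0)
  eff <- truth$guide_efficacy[library$guide_id]
  rate <- log(2) / config$doubling_time_days * (1 - gene_eff * eff)

  seeds <- derive_seeds(config$seed, 3L + config$n_endpoint)
  a <- with_seed(seeds[1L],
                 stats::rlnorm(G, 0, config$plasmid_lognormal_sigma))
  single_frac <- config$moi * exp(-config$moi) / (1 - exp(-config$moi))
  founders <- with_seed(seeds[2L],
                        stats::rpois(G, config$coverage * single_frac *
                                          a / mean(a)))
  # growth on a log scale relative to the fastest clone, to avoid
  # overflow of exp(rate * days) at long durations
  log_n <- log(pmax(founders, 0)) + rate * config$days
  log_n[founders == 0] <- -Inf

  sample_counts <- function(weights_log, s) {
    p <- exp(weights_log - max(weights_log[is.finite(weights_log)]))
    p[!is.finite(p)] <- 0
    if (sum(p) == 0) stop_("no surviving cells to sequence")
    p <- p / sum(p)
    with_seed(s, {
      if (config$dispersion > 0) {
        alpha <- p / config$dispersion
        w <- stats::rgamma(G, shape = alpha)
        if (sum(w) == 0) w <- p
        p <- w / sum(w)
      }
      as.numeric(stats::rmultinom(1L, size = depth, prob = p))
    })
  }
  plasmid <- sample_counts(log(a), seeds[3L])
  endpoints <- vapply(seq_len(config$n_endpoint), function(j) {
    sample_counts(log_n, seeds[3L + j])
  }, numeric(G))
  ep_names <- if (config$n_endpoint == 1L) sprintf("day%g", config$days)
              else sprintf("day%g_r%d", config$days, seq_len(config$n_endpoint))
  mat <- cbind(plasmid, endpoints)
  dimnames(mat) <- list(library$guide_id, c("plasmid", ep_names))
  list(table = count_table(mat, "plasmid"), truth = truth)
}

#' Write a count table out as synthetic FASTQ
#'
#' Emits exactly `count(g, s)` reads per guide and sample, each read
#' being `context` followed by the guide's spacer, so
#' [count_spacers()] with `trim5 = nchar(context)` recovers the table
#' exactly (round-trip identity).
#'
#' @param table a [count_table()].
#' @param library the matching [guide_library()].
#' @param dir output directory (created if needed).
#' @param context 5' sequence prepended to every spacer (default none).
#' @return Named character vector of FASTQ paths, one per sample.
#' @export
write_fastq <- function(table, library, dir, context = "") {
  stopifnot(inherits(table, "count_table"))
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- table$counts[library$guide_id, , drop = FALSE]
  paths <- character(0)
  for (s in colnames(counts)) {
    path <- file.path(dir, paste0(s, ".fastq"))
    n <- counts[, s]
    idx <- rep.int(seq_along(n), n)
    seqs <- paste0(context, library$spacer[idx])
    if (length(idx) > 0L) {
      lines <- as.vector(rbind(
        sprintf("@%s_read%d", s, seq_along(idx)),
        seqs, "+", strrep("I", nchar(seqs))))
    } else {
      lines <- character(0)
    }
    writeLines(lines, path)
    paths[s] <- path
  }
  paths
}

#' Detection power and false-positive rate over a grid of effect sizes
#'
#' For each planted effect size and replicate, simulates a screen with
#' `n_planted` genes planted at that effect, scores it, and records the
#' fraction of planted genes called positive regulators (power) and the
#' fraction of neutral genes called either hit class (false-positive
#' rate), with binomial Monte-Carlo standard errors pooled over
#' replicates.
#'
#' @param library a [guide_library()].
#' @param effects numeric vector of growth-rate deficits in `[0, 1]`.
#' @param config a [sim_config()]; its seed drives the whole grid.
#' @param n_planted genes planted per replicate (default 20).
#' @param replicates simulation replicates per effect size (>= 10).
#' @param tau z threshold (default 3).
#' @param n_resamples pseudo-genes per null (default 2000; smaller than
#'   the scoring default because each grid cell rebuilds its null).
#' @return data.frame: `effect`, `power`, `power_se`, `fpr`, `fpr_se`,
#'   `n_planted_total`, `n_neutral_total`.
#' @export
power_grid <- function(library, effects, config = sim_config(),
                       n_planted = 20L, replicates = 10L, tau = 3,
                       n_resamples = 2000L) {
  if (!inherits(library, "guide_library")) library <- guide_library(library)
  if (!is_count(replicates) || replicates < 10) {
    stop_("`replicates` must be at least 10")
  }
  genes <- unique(library$target_gene_id[
    library$guide_class == "tss_targeting"])
  if (n_planted > length(genes)) stop_("`n_planted` exceeds lncRNA gene count")
  rows <- lapply(seq_along(effects), function(ei) {
    e <- effects[ei]
    seeds <- derive_seeds(config$seed + ei, replicates)
    det <- integer(0); neut <- integer(0)
    for (j in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- seeds[j]
      planted <- with_seed(seeds[j] + 1L, sample(genes, n_planted))
      truth <- sim_truth(library,
                         gene_effect = structure(rep(e, n_planted),
                                                 names = planted),
                         config = cfg)
      sim <- simulate_screen(library, truth, cfg)
      endpoint <- setdiff(colnames(sim$table$counts), "plasmid")[1L]
      sc <- score_screen(sim$table, library, endpoint, tau = tau,
                         n_resamples = n_resamples, seed = seeds[j])
      sc <- sc[sc$scored, , drop = FALSE]
      is_planted <- if (e > 0) sc$gene_id %in% planted else
        rep(FALSE, nrow(sc))
      det <- c(det, as.integer(sc$z[is_planted] <= -tau))
      neut <- c(neut, as.integer(sc$hit_class[!is_planted &
                                              sc$gene_class == "tss_targeting"]
                                 != "none"))
    }
    pw <- mean(det); fp <- mean(neut)
    data.frame(effect = e,
               power = if (e > 0) pw else NA_real_,
               power_se = if (e > 0) sqrt(pw * (1 - pw) / length(det))
                          else NA_real_,
               fpr = fp, fpr_se = sqrt(fp * (1 - fp) / length(neut)),
               n_planted_total = length(det), n_neutral_total = length(neut))
  })
  do.call(rbind, rows)
}
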