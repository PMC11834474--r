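# Seeded synthetic-data generators that plant known pathway effects. Bulk:
# two latent pathway activities drawn from a two-component Gaussian mixture
# (so cutoff-based stratification has a meaningful target), signature genes
# loading on each, and a target gene (IDO1) with main plus interaction
# effects and Gaussian noise. Single cell: boolean GLI/STAT1 program states
# with configurable dependence, IDO1 positivity conditional on the joint
# state, Bernoulli capture of marker transcripts. A seed is mandatory;
# every component draws from its own deterministic sub-stream so adding
# genes never perturbs sample-level draws.

#' Bulk RNA-seq simulation configuration
#'
#' Defaults emulate the mixed skin-cancer cohort the analysis was designed
#' for: 83 samples of which about 59 are Hedgehog-high (the tumor
#' fraction), IL6 activity split evenly across both, clearly separated
#' activity mixture components (means -1/+1, within-component sd 0.5), and
#' 20 signature genes per pathway over a background of 200 noise genes.
#'
#' @param n_samples number of samples.
#' @param n_signature_genes signature genes per pathway.
#' @param n_background_genes pure-noise background genes.
#' @param p_hh_high,p_il6_high mixing fractions of the "high" mixture
#'   component for each pathway.
#' @param activity_means means of the low/high activity components.
#' @param activity_sd within-component standard deviation.
#' @param loading coefficient of the latent activity in each signature
#'   gene.
#' @param beta target-gene coefficients, named `intercept`, `hh`, `il6`,
#'   `interaction`: the target is
#'   `intercept + hh * a_HH + il6 * [IL6 high] + interaction * a_HH * [IL6 high] + noise`.
#' @param noise_sd Gaussian noise sd for signature genes and the target.
#' @param library_size_range range of simulated library sizes (Poisson
#'   count layer only).
#' @param count_model `"gaussian"` emits log2-cpm-scale values directly
#'   (the scale the downstream analysis operates on); `"poisson"` inverts
#'   them through sampled library sizes into an integer count matrix to
#'   exercise normalization end to end.
#' @param target_gene name given to the planted target gene.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_samples = 83,
                            n_signature_genes = 20,
                            n_background_genes = 200,
                            p_hh_high = 59 / 83,
                            p_il6_high = 0.5,
                            activity_means = c(low = -1, high = 1),
                            activity_sd = 0.5,
                            loading = 1,
                            beta = c(intercept = 4, hh = 1, il6 = 1,
                                     interaction = 1.5),
                            noise_sd = 0.5,
                            library_size_range = c(5e6, 2e7),
                            count_model = c("gaussian", "poisson"),
                            target_gene = "IDO1") {
  count_model <- match.arg(count_model)
  stopifnot(n_samples >= 2, n_signature_genes >= 1,
            activity_sd > 0, noise_sd >= 0,
            p_hh_high > 0, p_hh_high < 1, p_il6_high > 0, p_il6_high < 1,
            all(c("intercept", "hh", "il6", "interaction") %in% names(beta)))
  structure(as.list(environment()), class = "bulk_sim_config")
}

#' Simulate a bulk expression dataset with planted pathway effects
#'
#' @param config a [bulk_sim_config()].
#' @param seed integer seed; mandatory so every dataset is reproducible.
#' @return list with `data` (log2-cpm-scale matrix, or an integer count
#'   matrix for the Poisson layer), `data_type` (`"expression"` or
#'   `"counts"`), `gene_sets` (the HH and IL6 signature [gene_set()]s) and
#'   `truth` (a `synthetic_truth` record holding the per-sample latent
#'   activities, mixture components, configuration and seed).
#' @examples
#' sim <- simulate_bulk(bulk_sim_config(n_samples = 20), seed = 1)
#' dim(sim$data)
#' @export
simulate_bulk <- function(config = bulk_sim_config(), seed) {
  stopifnot(inherits(config, "bulk_sim_config"))
  if (missing(seed)) stop2("a seed is mandatory: pass an integer 'seed'")
  n <- config$n_samples
  sample_ids <- sprintf("sample_%03d", seq_len(n))

  # sub-stream 1: sample-level latents
  set.seed(substream_seed(seed, 1L))
  hh_comp <- stats::rbinom(n, 1, config$p_hh_high)
  il6_comp <- stats::rbinom(n, 1, config$p_il6_high)
  mu <- config$activity_means
  a_hh <- stats::rnorm(n, ifelse(hh_comp == 1, mu[["high"]], mu[["low"]]),
                       config$activity_sd)
  a_il6 <- stats::rnorm(n, ifelse(il6_comp == 1, mu[["high"]], mu[["low"]]),
                        config$activity_sd)
  lib_sizes <- round(stats::runif(n, config$library_size_range[1],
                                  config$library_size_range[2]))

  hh_genes <- sprintf("HHS%03d", seq_len(config$n_signature_genes))
  il6_genes <- sprintf("IL6S%03d", seq_len(config$n_signature_genes))
  bg_genes <- if (config$n_background_genes > 0) {
    sprintf("BG%04d", seq_len(config$n_background_genes))
  } else character(0)
  gene_ids <- c(config$target_gene, hh_genes, il6_genes, bg_genes)

  # sub-stream 2: gene-level baselines
  set.seed(substream_seed(seed, 2L))
  baselines <- stats::runif(length(gene_ids), 2, 8)
  names(baselines) <- gene_ids

  # sub-stream 3: expression noise
  set.seed(substream_seed(seed, 3L))
  expr <- matrix(stats::rnorm(length(gene_ids) * n, sd = config$noise_sd),
                 nrow = length(gene_ids),
                 dimnames = list(gene_ids, sample_ids))
  expr <- expr + baselines
  b <- config$beta
  expr[config$target_gene, ] <- expr[config$target_gene, ] +
    b[["hh"]] * a_hh + b[["il6"]] * il6_comp +
    b[["interaction"]] * a_hh * il6_comp + (b[["intercept"]] - baselines[1])
  expr[hh_genes, ] <- expr[hh_genes, ] +
    config$loading * rep(a_hh, each = length(hh_genes))
  expr[il6_genes, ] <- expr[il6_genes, ] +
    config$loading * rep(a_il6, each = length(il6_genes))

  if (config$count_model == "poisson") {
    # invert log2-cpm-scale values into counts through the library sizes
    set.seed(substream_seed(seed, 4L))
    cpm <- 2^expr
    props <- sweep(cpm, 2, colSums(cpm), "/")
    lam <- sweep(props, 2, lib_sizes, "*")
    data <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))
    data_type <- "counts"
  } else {
    data <- expr
    data_type <- "expression"
  }

  truth <- structure(list(
    activities = data.frame(sample_id = sample_ids,
                            hh_activity = a_hh, hh_component = hh_comp,
                            il6_activity = a_il6, il6_component = il6_comp,
                            library_size = lib_sizes,
                            stringsAsFactors = FALSE),
    beta = b, config = config, seed = seed), class = "synthetic_truth")
  list(data = data, data_type = data_type,
       gene_sets = list(HH = gene_set("HH", hh_genes, "synthetic HH signature"),
                        IL6 = gene_set("IL6", il6_genes, "synthetic IL6 signature")),
       truth = truth)
}

# Joint probability P(both programs active) for given marginals and odds
# ratio (Plackett construction).
joint_prob_from_or <- function(p1, p2, theta) {
  if (theta == 1) return(p1 * p2)
  s <- 1 + (p1 + p2) * (theta - 1)
  (s - sqrt(s^2 - 4 * theta * (theta - 1) * p1 * p2)) / (2 * (theta - 1))
}

#' Single-cell simulation configuration
#'
#' Defaults describe a melanoma-like tumor cell population: 5,000 cells,
#' 30% GLI-program-active and 30% STAT1-program-active cells (independent
#' programs unless `program_or` differs from 1), IDO1 positivity strongly
#' concentrated in double-active cells (60% vs 5% elsewhere), and partial
#' transcript capture for the marker genes (dropout), the main feature of
#' real droplet data the generator reproduces.
#'
#' @param n_cells number of tumor cells.
#' @param p_gli,p_stat1 marginal probabilities of the GLI and STAT1
#'   programs being active.
#' @param program_or odds ratio coupling the two program states (1 =
#'   independent).
#' @param p_ido1 conditional IDO1-positivity probabilities per joint
#'   (GLI, STAT1) state, named `p00`, `p10`, `p01`, `p11`.
#' @param capture per-gene transcript capture probability given the
#'   driving program is active; inactive programs give structural zeros,
#'   so imperfect capture lowers sensitivity but never specificity.
#' @param n_background_genes extra program-independent noise genes.
#' @param p_background expression probability of each background gene.
#' @return an `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cells = 5000,
                          p_gli = 0.3, p_stat1 = 0.3,
                          program_or = 1,
                          p_ido1 = c(p00 = 0.05, p10 = 0.05,
                                     p01 = 0.05, p11 = 0.6),
                          capture = c(GLI1 = 0.6, GLI2 = 0.6, GLI3 = 0.6,
                                      STAT1 = 0.8, IRF1 = 0.8),
                          n_background_genes = 4,
                          p_background = 0.5) {
  stopifnot(n_cells >= 1, p_gli > 0, p_gli < 1, p_stat1 > 0, p_stat1 < 1,
            program_or > 0,
            all(c("p00", "p10", "p01", "p11") %in% names(p_ido1)),
            all(p_ido1 >= 0 & p_ido1 <= 1),
            all(capture >= 0 & capture <= 1),
            all(c("GLI1", "GLI2", "GLI3", "STAT1", "IRF1") %in% names(capture)))
  structure(as.list(environment()), class = "sc_sim_config")
}

#' Population odds ratio planted by a single-cell configuration
#'
#' The odds ratio between IDO1 positivity and GLI/STAT1 double activity
#' implied by the configured state frequencies and conditional
#' probabilities — the value the estimated odds ratio should converge to
#' when transcript capture is perfect.
#'
#' @param config an [sc_sim_config()].
#' @return positive number (possibly `Inf`).
#' @export
planted_coactivity_or <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  pi11 <- joint_prob_from_or(config$p_gli, config$p_stat1, config$program_or)
  pi10 <- config$p_gli - pi11
  pi01 <- config$p_stat1 - pi11
  pi00 <- 1 - pi11 - pi10 - pi01
  p <- config$p_ido1
  p_not <- (pi00 * p[["p00"]] + pi10 * p[["p10"]] + pi01 * p[["p01"]]) /
    (pi00 + pi10 + pi01)
  (p[["p11"]] / (1 - p[["p11"]])) / (p_not / (1 - p_not))
}

#' Simulate a sparse single-cell dataset with planted co-activity
#'
#' Draws per-cell boolean (GLI, STAT1) program states with the configured
#' dependence, IDO1 positivity from the state-conditional probability, and
#' emits marker counts: each GLI gene is captured independently with its
#' capture probability when the GLI program is active (likewise STAT1 and
#' IRF1 for the STAT1 program); IDO1 transcripts are emitted exactly when
#' the cell is latently positive. All cells are annotated `"Tumor"`.
#'
#' @param config an [sc_sim_config()].
#' @param seed integer seed; mandatory.
#' @return list with `cells` (a [sparse_cell_matrix()]) and `truth`
#'   (latent per-cell states, the planted population odds ratio, config,
#'   seed).
#' @export
simulate_cells <- function(config = sc_sim_config(), seed) {
  stopifnot(inherits(config, "sc_sim_config"))
  if (missing(seed)) stop2("a seed is mandatory: pass an integer 'seed'")
  n <- config$n_cells
  cell_ids <- sprintf("cell_%05d", seq_len(n))

  # sub-stream 1: latent program states and IDO1 positivity
  set.seed(substream_seed(seed, 11L))
  pi11 <- joint_prob_from_or(config$p_gli, config$p_stat1, config$program_or)
  u <- stats::runif(n)
  pi10 <- config$p_gli - pi11
  pi01 <- config$p_stat1 - pi11
  state <- findInterval(u, cumsum(c(pi11, pi10, pi01)))  # 0=11, 1=10, 2=01, 3=00
  gli <- state %in% c(0L, 1L)
  stat1 <- state %in% c(0L, 2L)
  p_state <- config$p_ido1[c("p11", "p10", "p01", "p00")][state + 1L]
  ido1 <- stats::runif(n) < p_state

  # sub-stream 2: transcript capture
  set.seed(substream_seed(seed, 12L))
  cap <- config$capture
  detected <- rbind(
    GLI1 = gli & stats::runif(n) < cap[["GLI1"]],
    GLI2 = gli & stats::runif(n) < cap[["GLI2"]],
    GLI3 = gli & stats::runif(n) < cap[["GLI3"]],
    STAT1 = stat1 & stats::runif(n) < cap[["STAT1"]],
    IRF1 = stat1 & stats::runif(n) < cap[["IRF1"]],
    IDO1 = ido1)

  # sub-stream 3: count magnitudes and background genes
  set.seed(substream_seed(seed, 13L))
  counts <- matrix(0, nrow(detected), n,
                   dimnames = list(rownames(detected), cell_ids))
  counts[detected] <- 1 + stats::rpois(sum(detected), 1)
  if (config$n_background_genes > 0) {
    bg <- matrix(0, config$n_background_genes, n,
                 dimnames = list(sprintf("BG%03d", seq_len(config$n_background_genes)),
                                 cell_ids))
    on <- matrix(stats::runif(length(bg)) < config$p_background, nrow(bg))
    bg[on] <- 1 + stats::rpois(sum(on), 1)
    counts <- rbind(counts, bg)
  }
  ann <- stats::setNames(rep("Tumor", n), cell_ids)
  cells <- sparse_cell_matrix(counts, ann)
  truth <- structure(list(
    states = data.frame(cell_id = cell_ids, gli = gli, stat1 = stat1,
                        ido1 = ido1, stringsAsFactors = FALSE),
    planted_or = planted_coactivity_or(config),
    config = config, seed = seed), class = "synthetic_truth")
  list(cells = cells, truth = truth)
}
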