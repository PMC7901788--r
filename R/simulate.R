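#' Configuration for the multi-batch simulator
#'
#' Bundles and validates the parameters of the synthetic study the package
#' is tested against: several cohorts measured on platforms with distinct
#' monotone intensity distortions and incomplete miRNA coverage, a planted
#' two-group differential-expression signal, and (optionally) a paired gene
#' matrix with anti-correlated targets of one pivot miRNA.
#'
#' Defaults describe a three-cohort study of 240 tumour samples (80 per
#' batch) with balanced two-group labels (40 per group per batch), 300 miRNAs
#' of which 10% carry a standardized shift of d = 1 pooled-SD units,
#' within-group noise of 1 log2 unit, and 20% of miRNAs missing from each
#' platform; the paired gene matrix holds 2000 genes with 30 true targets
#' coupled to the pivot at rho = -0.6.
#'
#' @param n_mirnas Number of miRNAs.
#' @param batches data.frame with columns `batch_id`, `n_samples`,
#'   `frac_missing` (fraction of miRNAs absent from the platform), and
#'   distortion coefficients `a`, `b`, `c` of the monotone map
#'   `x -> a + b*x + c*x^2`.
#' @param group_fraction Fraction of each batch's samples assigned to group
#'   `"g1"` (the rest are `"g2"`); scalar or one value per batch.
#' @param de_fraction Fraction of miRNAs with a planted group effect.
#' @param effect_d Planted effect size in pooled-SD (= `noise_sd`) units.
#' @param noise_sd Within-group standard deviation, log2 units.
#' @param baseline_mean,baseline_sd Distribution of per-miRNA baseline
#'   means, log2 units.
#' @param n_genes,n_targets,rho Paired gene matrix: size, number of true
#'   targets of the pivot, and miRNA-target coupling (negative =
#'   anti-correlated).
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_mirnas = 300L,
                       batches = data.frame(
                         batch_id = c("batchA", "batchB", "batchC"),
                         n_samples = c(80L, 80L, 80L),
                         frac_missing = 0.2,
                         a = c(0, 5, -3),
                         b = c(1, 0.75, 1.35),
                         c = c(0, 0.012, -0.006),
                         stringsAsFactors = FALSE),
                       group_fraction = 0.5,
                       de_fraction = 0.1,
                       effect_d = 1.0,
                       noise_sd = 1.0,
                       baseline_mean = 8, baseline_sd = 2,
                       n_genes = 2000L, n_targets = 30L, rho = -0.6,
                       seed = 1L) {
  stopifnot(is.data.frame(batches), nrow(batches) >= 1L,
            all(c("batch_id", "n_samples", "frac_missing", "a", "b", "c")
                %in% colnames(batches)))
  if (any(batches$frac_missing < 0 | batches$frac_missing >= 1))
    stop("frac_missing must lie in [0, 1)")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (any(batches$b <= 0)) stop("distortion slope b must be positive")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  group_fraction <- rep_len(group_fraction, nrow(batches))
  if (any(group_fraction < 0 | group_fraction > 1))
    stop("group_fraction must lie in [0, 1]")
  structure(list(n_mirnas = as.integer(n_mirnas), batches = batches,
                 group_fraction = group_fraction,
                 de_fraction = de_fraction, effect_d = effect_d,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets), rho = rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-batch miRNA study with known ground truth
#'
#' Draws per-miRNA baseline means once, plants a two-group shift of
#' `effect_d * noise_sd` (random sign) in a `de_fraction` subset of miRNAs,
#' adds Gaussian within-group noise, applies each batch's monotone quadratic
#' intensity distortion, and finally drops a random `frac_missing` subset of
#' miRNAs from each batch entirely (platform-level missingness). Each
#' distortion is checked to be strictly increasing on the realized value
#' range. Identical config and seed give identical output.
#'
#' @param config A [sim_config()].
#' @return List with `cohorts` (named list of per-batch matrices, ready for
#'   [merge_cohorts()]), `samples` (data.frame `sample_id`, `batch`,
#'   `group`) and `truth` (data.frame `mirna_id`, `effect` in log2 units,
#'   positive = up in group `"g1"`).
#' @export
simulate_joint <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_rng(config$seed, {
    mirnas <- sprintf("mir-%03d", seq_len(config$n_mirnas))
    baseline <- stats::rnorm(config$n_mirnas, config$baseline_mean,
                             config$baseline_sd)
    n_de <- round(config$de_fraction * config$n_mirnas)
    de_idx <- if (n_de > 0L) sample.int(config$n_mirnas, n_de) else integer(0)
    effect <- numeric(config$n_mirnas)
    # up- and down-regulation planted in (near-)equal numbers: rank-based
    # normalization assumes globally balanced shifts, and two-group clinical
    # contrasts move miRNAs in both directions
    signs <- rep_len(c(1, -1), n_de)
    effect[de_idx] <- sample(signs) * config$effect_d * config$noise_sd

    cohorts <- list()
    sample_rows <- list()
    for (bi in seq_len(nrow(config$batches))) {
      b <- config$batches[bi, ]
      n <- b$n_samples
      sid <- sprintf("%s_s%02d", b$batch_id, seq_len(n))
      n_g1 <- round(config$group_fraction[bi] * n)
      grp <- c(rep("g1", n_g1), rep("g2", n - n_g1))
      shift <- outer(effect, as.numeric(grp == "g1"))
      vals <- baseline + shift +
        matrix(stats::rnorm(config$n_mirnas * n, 0, config$noise_sd),
               config$n_mirnas, n)
      distorted <- b$a + b$b * vals + b$c * vals^2
      slope <- b$b + 2 * b$c * range(vals)
      if (any(slope <= 0))
        stop("distortion for ", b$batch_id,
             " is not increasing on the generated range")
      dimnames(distorted) <- list(mirnas, sid)
      n_drop <- round(b$frac_missing * config$n_mirnas)
      keep <- seq_len(config$n_mirnas)
      if (n_drop > 0L)
        keep <- sort(sample.int(config$n_mirnas, config$n_mirnas - n_drop))
      cohorts[[b$batch_id]] <- distorted[keep, , drop = FALSE]
      sample_rows[[bi]] <- data.frame(sample_id = sid, batch = b$batch_id,
                                      group = grp, stringsAsFactors = FALSE)
    }
    list(cohorts = cohorts,
         samples = do.call(rbind, sample_rows),
         truth = data.frame(mirna_id = mirnas[de_idx],
                            effect = effect[de_idx],
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a gene matrix paired to a simulated miRNA study
#'
#' Generates `n_genes` genes over the same samples; `n_targets` of them are
#' true targets of the pivot miRNA, constructed as
#' `rho * (-z_pivot) + sqrt(1 - rho^2) * noise` (so `rho = -0.6` couples
#' targets negatively to the pivot), the rest independent noise. Values are
#' shifted to a typical log2 expression scale.
#'
#' @param config A [sim_config()]; `n_genes`, `n_targets`, `rho` and `seed`
#'   are used (the gene seed is offset so the miRNA draw is not reused).
#' @param sim Output of [simulate_joint()].
#' @param pivot Pivot miRNA id; default the first truth-table miRNA, falling
#'   back to the first simulated miRNA under a null configuration.
#' @return List with `genes` (matrix genes x samples), `targets` (character
#'   vector of true target gene ids) and `pivot`.
#' @export
simulate_paired_genes <- function(config, sim, pivot = NULL) {
  stopifnot(inherits(config, "sim_config"))
  joint <- merge_cohorts(sim$cohorts)
  if (is.null(pivot))
    pivot <- if (nrow(sim$truth)) sim$truth$mirna_id[1L] else
      rownames(joint$values)[1L]
  if (!pivot %in% rownames(joint$values)) stop("pivot '", pivot, "' absent")
  pv <- joint$values[pivot, ]
  ok <- !is.na(pv)
  if (sum(ok) < 3L) stop("pivot measured in fewer than 3 samples")
  z <- as.numeric(scale(pv[ok]))
  local_rng(config$seed + 1000003L, {
    genes <- sprintf("gene-%04d", seq_len(config$n_genes))
    targets <- sample(genes, config$n_targets)
    m <- matrix(stats::rnorm(config$n_genes * sum(ok)), config$n_genes,
                sum(ok), dimnames = list(genes, names(pv)[ok]))
    is_t <- genes %in% targets
    coup <- abs(config$rho)
    sgn <- sign(config$rho)
    if (coup > 0)
      m[is_t, ] <- sgn * coup * matrix(z, sum(is_t), sum(ok), byrow = TRUE) +
        sqrt(1 - coup^2) * m[is_t, ]
    list(genes = m + 6, targets = targets, pivot = pivot)
  })
}

#' Build a ranked target-candidate list from simulation truth
#'
#' Emulates an in-silico target-prediction ranking over the full gene
#' universe. For the pivot (`informative = TRUE`, default) the true targets
#' occupy the top ranks (in seeded random order) followed by all background
#' genes; with `informative = FALSE` the whole universe is shuffled — the
#' candidate list of a miRNA with no real targets in the data, the natural
#' decoy for specificity checks.
#'
#' @param gene_sim Output of [simulate_paired_genes()].
#' @param seed Integer seed for the shuffles.
#' @param informative Put true targets on top (default) or shuffle
#'   everything.
#' @return Character vector of gene ids, best candidate first.
#' @export
simulate_target_ranking <- function(gene_sim, seed = 1L,
                                    informative = TRUE) {
  genes <- rownames(gene_sim$genes)
  local_rng(seed, {
    if (informative)
      c(sample(gene_sim$targets),
        sample(setdiff(genes, gene_sim$targets)))
    else sample(genes)
  })
}
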