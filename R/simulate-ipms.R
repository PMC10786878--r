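# Synthetic IP-MS data with the statistical structure the pipeline assumes:
# bait-enriched spiked interactors, intensity-dependent (MNAR) missingness,
# contaminant and low-evidence rows, paired bait/control replicates.

#' Configuration for a simulated IP-MS experiment
#'
#' Defaults are the reference simulation conditions used throughout the test
#' suite: a desk-scale experiment of 5,000 proteins with 50 spiked
#' interactors at 2 log2 units of enrichment, replicate noise of 0.5 log2
#' units, and 20% intensity-dependent missingness.
#'
#' @param n_proteins Total number of protein rows.
#' @param n_true_interactors Number of spiked true interactors.
#' @param n_bait_reps,n_ctrl_reps Bait / control replicate counts.
#' @param effect_size Mean log2(bait/control) enrichment of the spiked
#'   interactors and the bait itself (log2 units).
#' @param noise_sd SD of a replicate log2 fold change (log2 units). Each cell
#'   receives independent log2 noise of SD `noise_sd / sqrt(2)`, so a
#'   bait-minus-control replicate log2FC has SD exactly `noise_sd`.
#' @param missing_rate Target overall missing fraction in `[0, 1)`.
#' @param mnar_steepness Slope of the logistic intensity-dependent missingness
#'   (per log2 unit); 0 gives missing-completely-at-random.
#' @param n_contaminants Number of keratin-style contaminant rows.
#' @param n_low_peptide Number of rows supported by a single unique peptide.
#' @param background_logfc_sd SD of an optional reproducible per-protein
#'   non-specific background enrichment (log2 units; default 0). Real IP-MS
#'   background binders show protein-specific, replicate-reproducible
#'   deviations from the controls; setting this > 0 emulates that (and the
#'   replicate-correlation QC metric it drives) while keeping the expected
#'   log2FC of non-interactors at 0.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return An `ipms_sim_config` list.
#' @export
ipms_sim_config <- function(n_proteins = 5000, n_true_interactors = 50,
                            n_bait_reps = 2, n_ctrl_reps = 2,
                            effect_size = 2, noise_sd = 0.5,
                            missing_rate = 0.2, mnar_steepness = 2,
                            n_contaminants = 10, n_low_peptide = 10,
                            background_logfc_sd = 0, seed = 1L) {
  assert_count(n_proteins, "n_proteins", min = 1)
  assert_count(n_true_interactors, "n_true_interactors")
  assert_count(n_bait_reps, "n_bait_reps", min = 1)
  assert_count(n_ctrl_reps, "n_ctrl_reps", min = 1)
  assert_count(n_contaminants, "n_contaminants")
  assert_count(n_low_peptide, "n_low_peptide")
  assert_prob(missing_rate, "missing_rate", hi_open = TRUE)
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is.numeric(background_logfc_sd) || background_logfc_sd < 0) {
    stopf("'background_logfc_sd' must be >= 0")
  }
  if (!is.numeric(mnar_steepness) || mnar_steepness < 0) {
    stopf("'mnar_steepness' must be >= 0")
  }
  # +1 reserves a row for the bait protein itself
  if (n_true_interactors + n_contaminants + n_low_peptide + 1 > n_proteins) {
    stopf("n_true_interactors + n_contaminants + n_low_peptide must leave room in n_proteins")
  }
  structure(list(
    n_proteins = n_proteins, n_true_interactors = n_true_interactors,
    n_bait_reps = n_bait_reps, n_ctrl_reps = n_ctrl_reps,
    effect_size = effect_size, noise_sd = noise_sd,
    missing_rate = missing_rate, mnar_steepness = mnar_steepness,
    n_contaminants = n_contaminants, n_low_peptide = n_low_peptide,
    background_logfc_sd = background_logfc_sd,
    seed = as.integer(seed)), class = "ipms_sim_config")
}

# Calibrate the logistic missingness midpoint v0 by bisection so the expected
# overall missing fraction equals `rate`.
calibrate_mnar_midpoint <- function(v, steepness, rate) {
  if (rate <= 0) return(-Inf)
  if (steepness == 0) return(NA_real_)  # MCAR: constant probability
  f <- function(v0) mean(stats::plogis(-steepness * (v - v0))) - rate
  lo <- min(v) - 200 / steepness
  hi <- max(v) + 200 / steepness
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate one IP-MS experiment
#'
#' Generates a raw-scale intensity matrix with paired bait/control replicates.
#' Log2 intensities are Normal(base_g, noise_sd / sqrt(2)) around per-protein
#' baselines base_g ~ Normal(25, 2) (a typical MS1 magnitude); the bait and
#' the spiked interactors are shifted by `effect_size` in the bait samples,
#' and an optional reproducible background component (`background_logfc_sd`)
#' shifts the remaining proteins by gene-specific amounts. Missingness
#' is logistic in the underlying log2 intensity with slope `mnar_steepness`,
#' calibrated so the expected overall missing fraction equals `missing_rate`
#' (low-abundance proteins go missing preferentially: missing-not-at-random).
#'
#' @param config An [ipms_sim_config()].
#' @param dataset_id,cell_type,ip_method,facility Labels carried in sample
#'   metadata.
#' @return A list with elements `table` (a [quant_table()]) and `truth`
#'   (data.frame of `protein_id`, `gene_symbol`, `is_interactor`, `is_bait`).
#' @export
simulate_ipms_dataset <- function(config, dataset_id = "sim1",
                                  cell_type = "EC", ip_method = "endogenous",
                                  facility = "simfac") {
  stopifnot(inherits(config, "ipms_sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    nb <- config$n_bait_reps
    nc <- config$n_ctrl_reps
    ids <- sprintf("P%05d", seq_len(n))
    genes <- sprintf("GENE%05d", seq_len(n))

    # row 1 is the bait; special rows drawn from the remainder
    bait_row <- 1L
    genes[bait_row] <- paste0("BAIT_", toupper(dataset_id))
    pool <- setdiff(seq_len(n), bait_row)
    pick <- sample(pool, config$n_true_interactors + config$n_contaminants +
                     config$n_low_peptide)
    true_rows <- pick[seq_len(config$n_true_interactors)]
    cont_rows <- pick[config$n_true_interactors + seq_len(config$n_contaminants)]
    lowpep_rows <- pick[config$n_true_interactors + config$n_contaminants +
                          seq_len(config$n_low_peptide)]
    if (length(cont_rows)) {
      genes[cont_rows] <- c(sprintf("KRT%d", seq_along(cont_rows) %% 40 + 1),
                            sprintf("KRTAP%d-1", seq_along(cont_rows)))[seq_along(cont_rows)]
      genes[cont_rows] <- make.unique(genes[cont_rows], sep = "_")
    }
    unique_peptides <- sample(2:20, n, replace = TRUE)
    unique_peptides[lowpep_rows] <- 1L

    base <- stats::rnorm(n, mean = 25, sd = 2)
    shift <- numeric(n)
    shift[c(bait_row, true_rows)] <- config$effect_size
    if (config$background_logfc_sd > 0) {
      bg_rows <- setdiff(seq_len(n), c(bait_row, true_rows))
      shift[bg_rows] <- stats::rnorm(length(bg_rows),
                                     sd = config$background_logfc_sd)
    }

    m <- nb + nc
    cell_sd <- config$noise_sd / sqrt(2)
    v <- matrix(stats::rnorm(n * m, sd = cell_sd), n, m) + base
    v[, seq_len(nb)] <- v[, seq_len(nb)] + shift  # bait columns first

    # MNAR mask on the underlying log2 intensities
    if (config$missing_rate > 0) {
      if (config$mnar_steepness == 0) {
        pmiss <- matrix(config$missing_rate, n, m)
      } else {
        v0 <- calibrate_mnar_midpoint(as.vector(v), config$mnar_steepness,
                                      config$missing_rate)
        pmiss <- stats::plogis(-config$mnar_steepness * (v - v0))
      }
      drop <- matrix(stats::runif(n * m), n, m) < pmiss
      v[drop] <- NA_real_
    }

    intens <- 2^v
    samples <- data.frame(
      sample_id = c(sprintf("%s_bait_rep%d", dataset_id, seq_len(nb)),
                    sprintf("%s_ctrl_rep%d", dataset_id, seq_len(nc))),
      role = rep(c("bait", "control"), c(nb, nc)),
      replicate = c(seq_len(nb), seq_len(nc)),
      dataset_id = dataset_id, cell_type = cell_type,
      ip_method = ip_method, facility = facility,
      stringsAsFactors = FALSE)
    proteins <- data.frame(
      protein_id = ids, gene_symbol = genes,
      unique_peptides = unique_peptides, species_flag = "human",
      stringsAsFactors = FALSE)

    truth <- data.frame(
      protein_id = ids[c(bait_row, true_rows)],
      gene_symbol = genes[c(bait_row, true_rows)],
      is_interactor = c(FALSE, rep(TRUE, length(true_rows))),
      is_bait = c(TRUE, rep(FALSE, length(true_rows))),
      stringsAsFactors = FALSE)

    list(table = quant_table(proteins, intens, samples,
                             bait_gene = genes[bait_row]),
         truth = truth)
  })
}
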