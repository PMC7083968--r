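#' Generate a synthetic multi-drug, multi-cell-line combination screen
#'
#' Produces a long-format screen shaped like the large public oncology
#' combination screens: every drug
#' pair tested in a 4x4 combination checkerboard plus single-agent
#' dose-response ladders, across a panel of cell lines, with fractional
#' viability responses.  The generator plants structure that the
#' screen-analysis layer is designed to recover:
#'
#' * **mechanism classes** — drugs are assigned to classes; each class has
#'   a latent per-cell-line potency profile and a drug's log10 dose of
#'   median effect correlates with its class profile across cell lines
#'   (correlation `potency_cor` within class, 0 across classes);
#' * **interaction structure** — the BRAID `kappa` of a pair depends on the
#'   two drugs' classes via `class_kappa` (plus small per-experiment
#'   jitter), so interaction profiles carry class information;
#' * **slope heterogeneity** — Hill slopes are drawn per drug independently
#'   of class, with additional log-normal variation across cell lines (as
#'   real dose-response curves show); slope-driven metrics (Bliss volume)
#'   therefore vary with slope, not mechanism;
#' * **inactive compounds** — optionally, drugs whose maximal killing is
#'   only 10%, used to exercise the activity filter and the null-compound
#'   similarity correction;
#' * **expression coupling** — an accompanying gene x cell-line expression
#'   matrix in which `n_coupled_genes` genes are linearly coupled to the
#'   class-1 potency profile (the designated per-cell-line sensitivity
#'   score); the remaining genes are independent noise.
#'
#' @param n_drugs number of drugs (named Drug01, Drug02, ...).
#' @param n_cell_lines number of cell lines (CL01, ...).
#' @param n_classes number of mechanism classes (drugs assigned
#'   round-robin).
#' @param class_kappa `n_classes x n_classes` symmetric matrix of BRAID
#'   `kappa` values per class pair; the default (for up to 6 classes) is a
#'   fixed signed matrix in which the first two classes share an identical
#'   interaction signature.  Interaction profiles are therefore informative
#'   about mechanism but cannot resolve every class on their own — some
#'   classes are separable only through potency covariation, as observed
#'   in real screens where efficacy-based clustering resolves more
#'   mechanism classes than interaction alone.
#' @param potency_cor within-class correlation of log-potency profiles
#'   across cell lines.
#' @param potency_sd sd of log10 IDM across cell lines (log10 uM units).
#' @param slope_range range of per-drug Hill slopes.
#' @param slope_cell_sd sd of the log of the per-cell-line slope
#'   multiplier around each drug's base slope.
#' @param kappa_jitter_sd sd of per-experiment kappa jitter.
#' @param noise_sd Gaussian viability noise sd.
#' @param replicates_single,replicates_combo replicates per single-agent
#'   and combination measurement.
#' @param max_kill_range range of per-drug maximal killing fractions
#'   (drawn uniformly); real screens mix full cytotoxics with partial
#'   responders, and partial maximal effects are a documented source of
#'   index-metric bias.
#' @param inactive_drugs how many drugs (taken from the end of the list)
#'   are nearly inactive (10% maximal killing).
#' @param combo_concs 4-point combination ladder (uM).
#' @param single_concs single-agent ladder (uM).
#' @param n_genes,n_coupled_genes expression matrix dimensions and number
#'   of genes coupled to the sensitivity score.
#' @param expr_beta linear coefficient of the coupled genes.
#' @param seed integer seed (required for reproducibility).
#' @return a list of class `synthetic_screen` with elements `screen` (the
#'   long table: `drugA`, `drugB`, `cell_line`, `concA_uM`, `concB_uM`,
#'   `viability`, `replicate`; single-agent rows have `drugB = NA` and
#'   `concB_uM = 0`), `expression` (genes x cell lines), `classes` (named
#'   character vector), and `truth` (planted parameters).
#' @export
generate_synthetic_screen <- function(n_drugs = 16, n_cell_lines = 12,
                                      n_classes = 4, class_kappa = NULL,
                                      potency_cor = 0.9, potency_sd = 0.3,
                                      slope_range = c(0.5, 4),
                                      slope_cell_sd = 0.5,
                                      kappa_jitter_sd = 0.25,
                                      noise_sd = 0.05,
                                      replicates_single = 4,
                                      replicates_combo = 2,
                                      max_kill_range = c(0.75, 1),
                                      inactive_drugs = 0,
                                      combo_concs = dilution_series(32, 4, 4, "max"),
                                      single_concs = dilution_series(32, 9, 2, "max"),
                                      n_genes = 300, n_coupled_genes = 5,
                                      expr_beta = 3, seed = NULL) {
  maybe_seed(seed)
  drugs <- sprintf("Drug%02d", seq_len(n_drugs))
  cells <- sprintf("CL%02d", seq_len(n_cell_lines))
  classes <- stats::setNames(
    sprintf("Class%d", rep_len(seq_len(n_classes), n_drugs)), drugs)
  if (is.null(class_kappa)) {
    # fixed signed interaction structure spanning antagonism to synergy;
    # classes 1 and 2 share a row, so interaction alone cannot separate
    # them (sign variation matters because cosine similarity is
    # sign-sensitive)
    base <- matrix(c(
      1.5,  1.5, -0.5,  0.5,  1.0, -1.0,
      1.5,  1.5, -0.5,  0.5,  1.0, -1.0,
     -0.5, -0.5,  2.0,  1.0, -1.0,  0.0,
      0.5,  0.5,  1.0, -1.0,  0.5,  2.0,
      1.0,  1.0, -1.0,  0.5,  2.5, -0.5,
     -1.0, -1.0,  0.0,  2.0, -0.5,  1.0), 6, 6)
    if (n_classes > 6)
      stop("supply 'class_kappa' explicitly for more than 6 classes")
    class_kappa <- base[seq_len(n_classes), seq_len(n_classes),
                        drop = FALSE]
  }
  if (!isTRUE(all.equal(class_kappa, t(class_kappa))))
    stop("'class_kappa' must be symmetric")
  if (nrow(class_kappa) != n_classes)
    stop("'class_kappa' must be n_classes x n_classes")

  class_id <- as.integer(sub("Class", "", classes))
  # latent class potency profiles and drug-level deviations (log10 uM)
  z_class <- matrix(stats::rnorm(n_classes * n_cell_lines), n_classes,
                    n_cell_lines)
  eps <- matrix(stats::rnorm(n_drugs * n_cell_lines), n_drugs, n_cell_lines)
  log10_idm <- potency_sd * (sqrt(potency_cor) * z_class[class_id, ] +
                             sqrt(1 - potency_cor) * eps)
  dimnames(log10_idm) <- list(drugs, cells)
  slopes <- stats::setNames(
    stats::runif(n_drugs, slope_range[1], slope_range[2]), drugs)
  slope_mat <- outer(slopes, rep(1, n_cell_lines)) *
    exp(matrix(stats::rnorm(n_drugs * n_cell_lines, 0, slope_cell_sd),
               n_drugs, n_cell_lines))
  dimnames(slope_mat) <- list(drugs, cells)
  max_kill <- stats::setNames(
    stats::runif(n_drugs, max_kill_range[1], max_kill_range[2]), drugs)
  if (inactive_drugs > 0)
    max_kill[seq(n_drugs - inactive_drugs + 1, n_drugs)] <- 0.1

  rows <- vector("list", 0)
  # single-agent series: one per (drug, cell line)
  for (d in drugs) for (cl in cells) {
    p <- hill_params(10^log10_idm[d, cl], slope_mat[d, cl],
                     e0 = 1, ef = 1 - max_kill[[d]])
    dose <- rep(single_concs, times = replicates_single)
    v <- hill_effect(p, dose) + stats::rnorm(length(dose), 0, noise_sd)
    rows[[length(rows) + 1]] <- data.frame(
      drugA = d, drugB = NA_character_, cell_line = cl,
      concA_uM = dose, concB_uM = 0, viability = v,
      replicate = rep(seq_len(replicates_single),
                      each = length(single_concs)))
  }
  # combination checkerboards
  grid <- expand.grid(concA_uM = combo_concs, concB_uM = combo_concs,
                      KEEP.OUT.ATTRS = FALSE)
  pair_kappa <- list()
  for (i in seq_len(n_drugs - 1)) for (j in seq(i + 1, n_drugs)) {
    dA <- drugs[i]; dB <- drugs[j]
    kap_base <- class_kappa[class_id[i], class_id[j]]
    for (cl in cells) {
      kap <- max(kap_base + stats::rnorm(1, 0, kappa_jitter_sd), -1.9)
      pair_kappa[[paste(dA, dB, cl, sep = "|")]] <- kap
      bp <- braid_params(
        idmA = 10^log10_idm[dA, cl], idmB = 10^log10_idm[dB, cl],
        na = slope_mat[dA, cl], nb = slope_mat[dB, cl], kappa = kap,
        e0 = 1, efA = 1 - max_kill[[dA]], efB = 1 - max_kill[[dB]])
      ga <- rep(grid$concA_uM, times = replicates_combo)
      gb <- rep(grid$concB_uM, times = replicates_combo)
      v <- braid_effect(bp, ga, gb) + stats::rnorm(length(ga), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        drugA = dA, drugB = dB, cell_line = cl,
        concA_uM = ga, concB_uM = gb, viability = v,
        replicate = rep(seq_len(replicates_combo), each = nrow(grid)))
    }
  }
  screen <- do.call(rbind, rows)

  # expression matrix coupled to the class-1 potency profile: higher score
  # = more sensitive (lower log10 IDM), so couple to -z
  score <- stats::setNames(-z_class[1, ], cells)
  genes <- sprintf("G%04d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_cell_lines), n_genes,
                 n_cell_lines, dimnames = list(genes, cells))
  coupled <- genes[seq_len(min(n_coupled_genes, n_genes))]
  for (g in coupled)
    expr[g, ] <- expr_beta * score + stats::rnorm(n_cell_lines, 0, 1)

  structure(list(
    screen = screen,
    expression = expr,
    classes = classes,
    truth = list(log10_idm = log10_idm, slopes = slopes,
                 slope_mat = slope_mat,
                 class_kappa = class_kappa, pair_kappa = pair_kappa,
                 sensitivity_score = score, coupled_genes = coupled,
                 max_kill = max_kill, expr_beta = expr_beta)
  ), class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "Synthetic screen: %d drugs (%d classes), %d cell lines, %d rows\n",
    length(x$classes), length(unique(x$classes)),
    length(unique(x$screen$cell_line)), nrow(x$screen)))
  invisible(x)
}
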