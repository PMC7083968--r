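#' Per-combination metric table for a screen
#'
#' Fits every (drugA, drugB, cell line) combination in a long-format screen
#' with the full 8-parameter BRAID model and derives the complete metric
#' panel: BRAID `kappa` (optionally with a bootstrap interval), the index
#' of achievable efficacy (IAE, limits at the highest combination
#' concentrations, threshold 0.5 survival), Bliss volume from the fitted
#' single-agent curves (with effects constrained to viability 1 at zero
#' dose and 0 at infinite dose), the Combination Index from the main
#' diagonal of the combination checkerboard at the 50% viability level,
#' and single-agent Hill slopes and potency indices.  Because screen
#' responses are normalised fractional viability, the surface baseline is
#' held at viability 1 (the remaining seven parameters are estimated).
#' Per-combination fit
#' failures are recorded and flagged; the pipeline continues.
#'
#' @param screen a screen long table (see [generate_synthetic_screen()] or
#'   [read_screen_csv()]): columns `drugA`, `drugB`, `cell_line`,
#'   `concA_uM`, `concB_uM`, `viability`, `replicate`; single-agent rows
#'   carry `drugB = NA`, `concB_uM = 0`.
#' @param n_boot bootstrap resamples for per-combination `kappa` intervals
#'   (0 = point estimates only, the default for large screens).
#' @param seed optional seed for the bootstrap streams.
#' @param iae_threshold survival threshold of the IAE (default 0.5).
#' @param kappa_max absolute bound beyond which a fitted `kappa` is treated
#'   as unidentifiable and recorded as `NA` (runaway estimates arise when
#'   one agent shows little activity inside the tested dose range; the
#'   strongest interactions reported in real screens are an order of
#'   magnitude smaller).
#' @return a `data.frame` (MetricTable): one row per combination with
#'   columns `drugA`, `drugB`, `cell_line`, `kappa`, `kappa_lo`,
#'   `kappa_hi`, `log10_iae`, `bliss_volume`, `ci50`, `hillA`, `hillB`,
#'   `hill_product`, `potencyA`, `potencyB`, `low_information`, `fit_ok`.
#' @export
compute_metric_table <- function(screen, n_boot = 0, seed = NULL,
                                 iae_threshold = 0.5, kappa_max = 15) {
  if (inherits(screen, "synthetic_screen")) screen <- screen$screen
  maybe_seed(seed)
  single <- screen[is.na(screen$drugB), ]
  combos <- screen[!is.na(screen$drugB), ]
  if (!nrow(combos)) stop("no combination rows in screen")

  # cache single-agent fits per (drug, cell line), viability-constrained
  sa_key <- unique(single[c("drugA", "cell_line")])
  sa_fits <- stats::setNames(vector("list", nrow(sa_key)),
                             paste(sa_key$drugA, sa_key$cell_line, sep = "|"))
  sa_max <- numeric(0)
  for (r in seq_len(nrow(sa_key))) {
    key <- names(sa_fits)[r]
    rows <- single[single$drugA == sa_key$drugA[r] &
                   single$cell_line == sa_key$cell_line[r], ]
    sa_max[key] <- max(rows$concA_uM)
    sa_fits[[key]] <- try(fit_hill_ls(
      dose_response_data(rows$concA_uM, rows$viability, rows$replicate),
      fix_bounds = c(1, 0)), silent = TRUE)
  }

  ids <- unique(combos[c("drugA", "drugB", "cell_line")])
  out <- vector("list", nrow(ids))
  for (r in seq_len(nrow(ids))) {
    dA <- ids$drugA[r]; dB <- ids$drugB[r]; cl <- ids$cell_line[r]
    chk <- combos[combos$drugA == dA & combos$drugB == dB &
                  combos$cell_line == cl, ]
    keyA <- paste(dA, cl, sep = "|"); keyB <- paste(dB, cl, sep = "|")
    fA <- sa_fits[[keyA]]; fB <- sa_fits[[keyB]]
    saA <- single[single$drugA == dA & single$cell_line == cl, ]
    saB <- single[single$drugA == dB & single$cell_line == cl, ]
    chk_df <- data.frame(dA = chk$concA_uM, dB = chk$concB_uM,
                         response = chk$viability,
                         replicate = chk$replicate)
    row <- data.frame(drugA = dA, drugB = dB, cell_line = cl,
                      kappa = NA_real_, kappa_lo = NA_real_,
                      kappa_hi = NA_real_, log10_iae = NA_real_,
                      bliss_volume = NA_real_, ci50 = NA_real_,
                      hillA = NA_real_, hillB = NA_real_,
                      hill_product = NA_real_, potencyA = NA_real_,
                      potencyB = NA_real_, low_information = NA,
                      fit_ok = FALSE)

    dat <- rbind(chk_df,
                 data.frame(dA = saA$concA_uM, dB = 0,
                            response = saA$viability,
                            replicate = saA$replicate),
                 data.frame(dA = 0, dB = saB$concA_uM,
                            response = saB$viability,
                            replicate = saB$replicate))
    bfit <- try(fit_braid(dat, n_boot = n_boot, fix_e0 = 1), silent = TRUE)
    if (!inherits(bfit, "try-error")) {
      limits <- c(max(chk$concA_uM), max(chk$concB_uM))
      iae <- compute_iae(bfit$params, limits, iae_threshold)
      # kappa stuck at an optimizer bound or beyond any plausible
      # interaction strength marks an unidentifiable fit (typically a
      # drug inactive in-range); drop the value but keep the row
      row$kappa <- if (isTRUE(bfit$kappa_at_bound) ||
                       abs(bfit$params$kappa) > kappa_max) NA_real_ else
        bfit$params$kappa
      row$kappa_lo <- bfit$kappa_ci[1]; row$kappa_hi <- bfit$kappa_ci[2]
      row$log10_iae <- iae$log10_iae
      row$low_information <- bfit$low_information
      row$fit_ok <- TRUE
    }
    if (!inherits(fA, "try-error") && !inherits(fB, "try-error")) {
      row$bliss_volume <- bliss_volume(chk_df, fA, fB, scale = "viability")
      row$hillA <- fA$n; row$hillB <- fB$n
      row$hill_product <- hill_product(fA, fB)
      row$potencyA <- potency_index(fA, sa_max[keyA], level = 0.5)
      row$potencyB <- potency_index(fB, sa_max[keyB], level = 0.5)
      ci <- try({
        dg <- extract_diagonals(chk_df, k = 1)[[1]]
        fd <- fit_hill_ls(
          dose_response_data(dg$total, dg$response, dg$replicate),
          fix_bounds = c(1, 0))
        combination_index(fA, fB, fd, 0.5, attr(dg, "ratio"))
      }, silent = TRUE)
      if (!inherits(ci, "try-error")) row$ci50 <- ci
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}

metric_value <- function(table, metric) {
  switch(metric,
    bliss = table$bliss_volume,
    kappa = table$kappa,
    ci    = -log10(table$ci50),  # synergy positive, like the other metrics
    iae   = table$log10_iae,
    stop("unknown metric '", metric, "'"))
}

#' Correlation between interaction metric and Hill-slope product
#'
#' Quantifies slope-driven bias in a screen: the Pearson correlation
#' between the log Hill-slope product of each combination and its
#' interaction metric.  The CI axis is inverted (`-log10 CI`) so synergy
#' is positive for every metric; a slope-independent metric should show
#' `r` near 0.
#'
#' @param table a [compute_metric_table()] result.
#' @param metric `"bliss"`, `"ci"` or `"kappa"`.
#' @param drop_classes optional character vector of class labels to
#'   remove first (requires `classes`).
#' @param classes optional named vector drug -> class label.
#' @return Pearson `r` (NA with a warning when degenerate).
#' @export
slope_bias_correlation <- function(table, metric = c("bliss", "ci", "kappa"),
                                   drop_classes = NULL, classes = NULL) {
  metric <- match.arg(metric)
  if (!is.null(drop_classes)) {
    if (is.null(classes)) stop("'classes' required to drop classes")
    dropd <- names(classes)[classes %in% drop_classes]
    table <- table[!(table$drugA %in% dropd) & !(table$drugB %in% dropd), ]
  }
  x <- log(table$hill_product)
  y <- metric_value(table, metric)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 combinations with finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("degenerate variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Interaction profile of a drug
#'
#' The ordered vector of a metric's values for every combination involving
#' the drug, indexed by (partner drug, cell line) context.  Two drugs'
#' profiles are compared only over shared contexts.
#'
#' @param table a [compute_metric_table()] result.
#' @param metric one of `"bliss"`, `"ci"`, `"kappa"`, `"iae"`,
#'   `"potency"`.
#' @param drug drug name.
#' @return data frame (`partner`, `cell_line`, `value`), class `profile`.
#' @export
build_profiles <- function(table, metric, drug) {
  inA <- table$drugA == drug
  inB <- table$drugB == drug
  if (!any(inA | inB)) stop("drug '", drug, "' not present in table")
  val <- if (metric == "potency") {
    c(table$potencyA[inA], table$potencyB[inB])
  } else {
    v <- metric_value(table, metric)
    c(v[inA], v[inB])
  }
  out <- data.frame(
    partner = c(table$drugB[inA], table$drugA[inB]),
    cell_line = c(table$cell_line[inA], table$cell_line[inB]),
    value = val)
  out <- out[order(out$partner, out$cell_line), ]
  structure(out, class = c("profile", "data.frame"), drug = drug,
            metric = metric)
}

join_profiles <- function(pA, pB) {
  m <- merge(pA, pB, by = c("partner", "cell_line"),
             suffixes = c("_a", "_b"))
  m[is.finite(m$value_a) & is.finite(m$value_b), ]
}

#' Similarity between two interaction profiles
#'
#' Pairwise similarity over shared (partner, cell line) contexts; contexts
#' present for only one drug are excluded.  Interaction metrics (Bliss,
#' CI, `kappa`) use cosine similarity, which is sensitive to the sign of
#' the values; potency uses Pearson correlation of log-transformed values;
#' IAE uses Pearson correlation, optionally minus a null-compound
#' correction supplied by the caller (see [similarity_matrix()]).
#'
#' @param pA,pB [build_profiles()] results.
#' @param method `"cosine"`, `"pearson"` or `"pearson_log"`.
#' @param min_shared minimum number of shared contexts.
#' @return similarity in \[-1, 1\], or `NA` when undefined.
#' @export
profile_similarity <- function(pA, pB,
                               method = c("cosine", "pearson", "pearson_log"),
                               min_shared = 3) {
  method <- match.arg(method)
  m <- join_profiles(pA, pB)
  if (nrow(m) < min_shared) return(NA_real_)
  x <- m$value_a; y <- m$value_b
  if (method == "pearson_log") { x <- log(x); y <- log(y) }
  if (method == "cosine") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(NA_real_)
    sum(x * y) / (nx * ny)
  } else {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
}

# profile of partner single-agent activity (log10 potency of the partner
# in the context cell line) aligned to a drug's profile: the expected IAE
# pattern of a completely inactive compound
null_activity_profile <- function(table, drug) {
  inA <- table$drugA == drug
  inB <- table$drugB == drug
  out <- data.frame(
    partner = c(table$drugB[inA], table$drugA[inB]),
    cell_line = c(table$cell_line[inA], table$cell_line[inB]),
    value = log10(c(table$potencyB[inA], table$potencyA[inB])))
  out <- out[order(out$partner, out$cell_line), ]
  structure(out, class = c("profile", "data.frame"))
}

#' Pairwise similarity matrix of interaction profiles
#'
#' Builds all drugs' profiles for a metric and computes the pairwise
#' similarity matrix: cosine for interaction metrics, Pearson on logs for
#' potency, and for IAE, Pearson minus the null-compound correction — the
#' mean, over the two compounds, of the correlation between each
#' compound's IAE profile and the profile implied by partner single-agent
#' activity alone.  Inactive compounds track their partners' activity, so
#' without the correction they show misleadingly high mutual similarity.
#'
#' @param table a [compute_metric_table()] result.
#' @param metric `"bliss"`, `"ci"`, `"kappa"`, `"potency"`, or `"iae"`.
#' @param drugs drugs to include (default: all in the table).
#' @param min_shared minimum shared contexts per pair.
#' @return symmetric matrix with drug names as dimnames (diagonal 1).
#' @export
similarity_matrix <- function(table, metric, drugs = NULL, min_shared = 3) {
  if (is.null(drugs)) drugs <- sort(unique(c(table$drugA, table$drugB)))
  method <- switch(metric, potency = "pearson_log", iae = "pearson",
                   "cosine")
  profs <- lapply(drugs, function(d) build_profiles(table, metric, d))
  names(profs) <- drugs
  null_corr <- rep(0, length(drugs))
  if (metric == "iae") {
    null_corr <- vapply(drugs, function(d) {
      m <- join_profiles(profs[[d]], null_activity_profile(table, d))
      if (nrow(m) < min_shared || stats::sd(m$value_a) == 0 ||
          stats::sd(m$value_b) == 0) return(0)
      stats::cor(m$value_a, m$value_b)
    }, numeric(1))
  }
  n <- length(drugs)
  S <- matrix(1, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- profile_similarity(profs[[i]], profs[[j]], method, min_shared)
    if (metric == "iae" && is.finite(s))
      s <- s - mean(c(null_corr[i], null_corr[j]))
    S[i, j] <- S[j, i] <- s
  }
  S
}

#' Average-similarity agglomerative clustering
#'
#' Hierarchical clustering of a similarity matrix by greedy agglomeration:
#' starting from singleton clusters, at each step the two clusters whose
#' merge maximises the average pairwise similarity between their
#' compounds are combined (average linkage on similarity).  Ties are
#' broken lexicographically by member names for reproducibility.  The
#' merge history induces one partition at every level from `n` clusters
#' down to 1.
#'
#' @param S symmetric similarity matrix with dimnames (NA entries are
#'   treated as the minimum observed similarity).
#' @return object of class `similarity_dendrogram`: list with `labels`,
#'   `merges` (data frame of merged cluster compositions and their
#'   average similarity), and `partitions` (list: `partitions[[k]]` is the
#'   named membership vector at the `k`-cluster level).
#' @export
cluster_by_similarity <- function(S) {
  if (!isTRUE(all.equal(S, t(S)))) stop("'S' must be symmetric")
  labels <- rownames(S)
  n <- length(labels)
  if (any(is.na(S))) S[is.na(S)] <- min(S, na.rm = TRUE)
  clusters <- as.list(seq_len(n))
  partitions <- vector("list", n)
  membership <- stats::setNames(seq_len(n), labels)
  partitions[[n]] <- membership
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- NULL; best_sim <- -Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        sim <- mean(S[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(min(labels[clusters[[a]]]),
                            min(labels[clusters[[b]]]))), collapse = "|")
        if (sim > best_sim ||
            (sim == best_sim && !is.null(best) && key < best$key)) {
          best_sim <- sim
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    merges[[step]] <- data.frame(
      members = paste(sort(labels[merged]), collapse = ","),
      similarity = best_sim)
    clusters[[best$a]] <- merged
    clusters[[best$b]] <- NULL
    membership <- stats::setNames(rep(NA_integer_, n), labels)
    for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    partitions[[n - step]] <- membership
  }
  structure(list(labels = labels,
                 merges = do.call(rbind, merges),
                 partitions = partitions),
            class = "similarity_dendrogram")
}

#' @export
print.similarity_dendrogram <- function(x, ...) {
  cat(sprintf("Similarity dendrogram of %d items (%d merges)\n",
              length(x$labels), nrow(x$merges)))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table of pair counts.
#'
#' @param a,b partition label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(0)
  (sum_ij - expected) / denom
}

#' Mean adjusted Rand index of a dendrogram against a classification
#'
#' Scores every partition the dendrogram induces (from `n` clusters down
#' to 1) against a reference classification with the adjusted Rand index
#' and returns the mean — an overall agreement measure across scales.
#'
#' @param dendro a [cluster_by_similarity()] result.
#' @param classes named vector drug -> class covering the clustered drugs.
#' @return list with `mean_ari` and `ari_by_level` (named by cluster
#'   count).
#' @export
mean_adjusted_rand <- function(dendro, classes) {
  if (!all(dendro$labels %in% names(classes)))
    stop("'classes' must cover all clustered drugs")
  cls <- classes[dendro$labels]
  ari <- vapply(seq_along(dendro$partitions), function(k)
    adjusted_rand_index(dendro$partitions[[k]][dendro$labels], cls),
    numeric(1))
  list(mean_ari = mean(ari),
       ari_by_level = stats::setNames(ari, seq_along(ari)))
}

#' Filter out inactive drugs
#'
#' Interaction values of nearly inactive compounds are unstable and
#' disrupt clustering.  Drops drugs whose mean maximal killing — one
#' minus the mean viability at the highest single-agent concentration,
#' averaged over cell lines — is below the threshold.
#'
#' @param screen a screen long table (or `synthetic_screen`).
#' @param threshold minimum mean maximal killing fraction (default 0.25).
#' @return character vector of retained drug names.
#' @export
activity_filter <- function(screen, threshold = 0.25) {
  if (inherits(screen, "synthetic_screen")) screen <- screen$screen
  single <- screen[is.na(screen$drugB), ]
  if (!nrow(single)) stop("no single-agent rows in screen")
  drugs <- unique(single$drugA)
  keep <- vapply(drugs, function(d) {
    rows <- single[single$drugA == d, ]
    kill <- vapply(split(rows, rows$cell_line), function(rr) {
      1 - mean(rr$viability[rr$concA_uM == max(rr$concA_uM)])
    }, numeric(1))
    mean(kill) >= threshold
  }, logical(1))
  sort(drugs[keep])
}

#' Relative sensitivity between two anchor drugs
#'
#' For each cell line, the mean difference of log10 IAE between matched
#' combinations of two anchor drugs (same partner, same cell line):
#' `mean(log10 IAE(drugY combos) - log10 IAE(drugX combos))`.  Positive
#' scores mean drugY combinations need more of the tested dose range
#' (higher IAE is *better* efficacy, so positive = drugY more effective);
#' a score of +1 corresponds to a uniform 10-fold IAE ratio in favour of
#' drugY.  Cell lines with no shared partners are omitted.
#'
#' @param table a [compute_metric_table()] result.
#' @param drugX,drugY anchor drugs.
#' @return named numeric vector: per-cell-line score.
#' @export
relative_sensitivity <- function(table, drugX, drugY) {
  pX <- build_profiles(table, "iae", drugX)
  pY <- build_profiles(table, "iae", drugY)
  pX <- pX[pX$partner != drugY, ]
  pY <- pY[pY$partner != drugX, ]
  m <- join_profiles(pX, pY)
  if (!nrow(m)) stop("no shared (partner, cell line) contexts")
  diffs <- split(m$value_b - m$value_a, m$cell_line)
  vapply(diffs, mean, numeric(1))
}

#' Matrix of log10 IAE values for one anchor drug
#'
#' Convenience reshaper: cell lines x partner drugs, entries log10 IAE of
#' the (anchor, partner) combination in that cell line.
#'
#' @param table a [compute_metric_table()] result.
#' @param drug anchor drug.
#' @return numeric matrix (rows: cell lines, cols: partners).
#' @export
iae_profile_matrix <- function(table, drug) {
  p <- build_profiles(table, "iae", drug)
  cells <- sort(unique(p$cell_line))
  partners <- sort(unique(p$partner))
  M <- matrix(NA_real_, length(cells), length(partners),
              dimnames = list(cells, partners))
  M[cbind(match(p$cell_line, cells), match(p$partner, partners))] <- p$value
  M
}

#' Project cell lines onto a phenotype axis
#'
#' Given a cell-lines x combinations matrix of log10 IAE values and two
#' reference cell lines (e.g. an isogenic pair differing in one genetic
#' feature), projects every cell line onto the difference axis
#' `v = row(ref_minus) - row(ref_plus)`:
#' `coordinate = ((row - row(ref_plus)) . v) / (v . v)`.
#' The references anchor the scale at 0 (`ref_plus`) and 1 (`ref_minus`);
#' coordinates beyond 1 indicate a phenotype more extreme than the
#' deficient reference.  Combinations with missing values in any line are
#' excluded.
#'
#' @param iae_matrix matrix, rows = cell lines (named), cols =
#'   combinations.
#' @param ref_plus,ref_minus row names of the two reference lines.
#' @return named numeric vector of per-cell-line coordinates.
#' @export
phenotype_projection <- function(iae_matrix, ref_plus, ref_minus) {
  if (!all(c(ref_plus, ref_minus) %in% rownames(iae_matrix)))
    stop("reference cell lines not found in matrix")
  complete <- colSums(is.na(iae_matrix)) == 0
  M <- iae_matrix[, complete, drop = FALSE]
  v <- M[ref_minus, ] - M[ref_plus, ]
  vv <- sum(v^2)
  if (vv == 0) stop("reference rows are identical: zero phenotype axis")
  apply(M, 1, function(row) sum((row - M[ref_plus, ]) * v) / vv)
}

#' Rank genes by linear association with a sensitivity score
#'
#' Regresses each gene's expression on a per-cell-line score (simple
#' linear regression over shared cell lines) and ranks genes by the
#' magnitude of the linear coefficient — the genes whose expression
#' changes most, in either direction, along the score.  Each slope is also
#' reported as a z-score against the all-gene slope distribution.  Using
#' the coefficient magnitude rather than the correlation avoids rewarding
#' small noisy expression changes that correlate by chance.
#'
#' @param scores named per-cell-line numeric vector (e.g. from
#'   [relative_sensitivity()] or [phenotype_projection()]).
#' @param expr genes x cell-lines expression matrix.
#' @param k number of top genes to return (all if `k` exceeds the gene
#'   count).
#' @return data frame (`gene`, `slope`, `z`, `rank`) of the top `k` genes
#'   by `|slope|`, with the full slope table as attribute `all_slopes`.
#' @export
rank_expression_association <- function(scores, expr, k = 11) {
  shared <- intersect(names(scores), colnames(expr))
  if (length(shared) < 5) stop("need at least 5 shared cell lines")
  s <- scores[shared]
  X <- expr[, shared, drop = FALSE]
  sc <- s - mean(s)
  denom <- sum(sc^2)
  if (denom == 0) stop("sensitivity score has zero variance")
  Xc <- X - rowMeans(X)
  slopes <- as.vector(Xc %*% sc) / denom
  names(slopes) <- rownames(X)
  z <- (slopes - mean(slopes)) / stats::sd(slopes)
  ord <- order(abs(slopes), decreasing = TRUE)
  k <- min(k, length(slopes))
  out <- data.frame(gene = names(slopes)[ord][seq_len(k)],
                    slope = slopes[ord][seq_len(k)],
                    z = z[ord][seq_len(k)],
                    rank = seq_len(k), row.names = NULL)
  attr(out, "all_slopes") <- slopes
  out
}
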