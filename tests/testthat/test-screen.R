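# a small, fast synthetic screen shared across tests in this file
small_screen <- function(seed = 77, ...) {
  generate_synthetic_screen(n_drugs = 8, n_cell_lines = 6, n_classes = 2,
                            n_genes = 60, seed = seed, ...)
}

test_that("the synthetic screen generator is seed-reproducible", {
  s1 <- small_screen()
  s2 <- small_screen()
  expect_identical(s1$screen, s2$screen)
  expect_identical(s1$expression, s2$expression)
  expect_error(generate_synthetic_screen(class_kappa = matrix(1, 2, 2),
                                         n_classes = 4, seed = 1),
               "n_classes")
})

test_that("planted potency structure appears in the screen", {
  syn <- small_screen()
  idm <- syn$truth$log10_idm
  cls <- syn$classes
  same <- c(); diff <- c()
  for (i in 1:(nrow(idm) - 1)) for (j in (i + 1):nrow(idm)) {
    r <- cor(idm[i, ], idm[j, ])
    if (cls[i] == cls[j]) same <- c(same, r) else diff <- c(diff, r)
  }
  expect_gt(mean(same), mean(diff))
})

test_that("metric table recovers a strongly planted synergistic class pair", {
  kap <- matrix(0, 2, 2); kap[1, 2] <- kap[2, 1] <- 3
  syn <- small_screen(seed = 78, class_kappa = kap)
  mt <- compute_metric_table(syn)
  cls <- syn$classes
  cross <- cls[mt$drugA] != cls[mt$drugB]
  expect_gt(mean(mt$kappa[cross], na.rm = TRUE), 1.5)
  expect_lt(abs(mean(mt$kappa[!cross], na.rm = TRUE)), 0.75)
  # planted synergy shows up in Bliss volumes too (synergy positive)
  expect_gt(mean(mt$bliss_volume[cross]), mean(mt$bliss_volume[!cross]))
})

test_that("an inactive drug is flagged and filtered", {
  syn <- small_screen(seed = 79, inactive_drugs = 1)
  kept <- activity_filter(syn)
  expect_false("Drug08" %in% kept)
  expect_setequal(kept, sprintf("Drug%02d", 1:7))
  mt <- compute_metric_table(syn)
  inert <- mt$drugA == "Drug08" | mt$drugB == "Drug08"
  expect_true(all(mt$potencyB[mt$drugB == "Drug08"] == 1))
  expect_gt(mean(mt$low_information[inert]), mean(mt$low_information[!inert]))
})

test_that("profiles keep the promised bookkeeping", {
  syn <- small_screen()
  mt <- compute_metric_table(syn)
  p <- build_profiles(mt, "kappa", "Drug01")
  # every combination involving the drug appears once per context
  expect_equal(nrow(p), 7 * 6)
  expect_false("Drug01" %in% p$partner)
  expect_error(build_profiles(mt, "kappa", "DrugXX"), "not present")
  # removing one context from one drug drops it from the comparison only
  mt_drop <- mt[!(mt$drugA == "Drug01" & mt$drugB == "Drug02" &
                  mt$cell_line == "CL01"), ]
  pA <- build_profiles(mt_drop, "kappa", "Drug01")
  pB <- build_profiles(mt_drop, "kappa", "Drug03")
  m <- merge(pA, pB, by = c("partner", "cell_line"))
  expect_false(any(m$partner == "Drug02" & m$cell_line == "CL01"))
})

test_that("profile similarity behaves like cosine on shared contexts", {
  p <- structure(data.frame(partner = rep(c("X", "Y"), each = 3),
                            cell_line = rep(c("a", "b", "c"), 2),
                            value = c(1, 2, 3, -1, 0.5, 2)),
                 class = c("profile", "data.frame"))
  expect_equal(profile_similarity(p, p, "cosine"), 1)
  pneg <- p; pneg$value <- -p$value
  expect_equal(profile_similarity(p, pneg, "cosine"), -1)
  # invariant to positive rescaling
  p2 <- p; p2$value <- 3.7 * p$value
  expect_equal(profile_similarity(p, p2, "cosine"), 1)
  # too few shared contexts -> undefined
  expect_true(is.na(profile_similarity(p[1:2, ], p[1:2, ], "cosine")))
})

test_that("the null-compound correction neutralises an inactive drug", {
  # wide potency spread so combination efficacy is partner-driven, the
  # condition under which inactive compounds mimic each other
  syn <- generate_synthetic_screen(n_drugs = 9, n_cell_lines = 8,
                                   n_classes = 3, n_genes = 20,
                                   potency_sd = 0.8,
                                   inactive_drugs = 2, seed = 83)
  mt <- compute_metric_table(syn)
  inert <- c("Drug08", "Drug09")
  profs <- lapply(inert, function(d) build_profiles(mt, "iae", d))
  raw <- profile_similarity(profs[[1]], profs[[2]], "pearson")
  S <- similarity_matrix(mt, "iae", drugs = sort(unique(c(mt$drugA, mt$drugB))))
  corrected <- S["Drug08", "Drug09"]
  # inactive compounds track partner activity: high raw correlation that
  # the correction removes
  expect_gt(raw, 0.5)
  expect_lt(corrected, raw - 0.3)
})

test_that("greedy agglomeration merges the most similar pair first", {
  S <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.2,
                0.1, 0.2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dn <- cluster_by_similarity(S)
  expect_equal(dn$merges$members[1], "a,b")
  expect_equal(nrow(dn$merges), 2)
  expect_equal(dn$partitions[[2]][["a"]], dn$partitions[[2]][["b"]])
})

test_that("block-diagonal similarity recovers planted classes intact", {
  drugs <- letters[1:6]
  S <- matrix(0.05, 6, 6, dimnames = list(drugs, drugs))
  S[1:3, 1:3] <- 0.8; S[4:6, 4:6] <- 0.8; diag(S) <- 1
  dn <- cluster_by_similarity(S)
  p2 <- dn$partitions[[2]]
  expect_equal(length(unique(p2[1:3])), 1)
  expect_equal(length(unique(p2[4:6])), 1)
  expect_false(p2[["a"]] == p2[["d"]])
})

test_that("the adjusted Rand index matches independent oracles", {
  # brute-force pair-counting oracle on small partitions
  ari_brute <- function(a, b) {
    n <- length(a)
    s00 <- s01 <- s10 <- s11 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
    tot <- s11 + s10 + s01 + s00
    exp_idx <- (s11 + s10) * (s11 + s01) / tot
    max_idx <- ((s11 + s10) + (s11 + s01)) / 2
    if (max_idx == exp_idx) return(0)
    (s11 - exp_idx) / (max_idx - exp_idx)
  }
  set.seed(55)
  for (i in 1:20) {
    a <- sample(1:3, 8, replace = TRUE)
    b <- sample(1:3, 8, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_brute(a, b))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    for (i in 1:10) {
      a <- sample(1:4, 12, replace = TRUE)
      b <- sample(1:4, 12, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  }
})

test_that("mean adjusted Rand scores every dendrogram level", {
  S <- matrix(0.05, 6, 6,
              dimnames = list(letters[1:6], letters[1:6]))
  S[1:3, 1:3] <- 0.8; S[4:6, 4:6] <- 0.8; diag(S) <- 1
  dn <- cluster_by_similarity(S)
  classes <- setNames(rep(c("X", "Y"), each = 3), letters[1:6])
  res <- mean_adjusted_rand(dn, classes)
  expect_length(res$ari_by_level, 6)
  expect_equal(res$ari_by_level[["2"]], 1)   # exact recovery at 2 clusters
  expect_equal(res$mean_ari, mean(res$ari_by_level))
  expect_error(mean_adjusted_rand(dn, classes[1:3]), "cover")
})

test_that("relative sensitivity averages matched log10 IAE differences", {
  syn <- small_screen()
  mt <- compute_metric_table(syn)
  # identical anchor: zero everywhere
  rs_self <- relative_sensitivity(mt, "Drug01", "Drug01")
  expect_true(all(abs(rs_self) < 1e-12))
  # hand-built table where drug Y's combos have exactly 10x the IAE of
  # the matched drug X combos: score +1 (and -1 with roles swapped)
  ctx <- expand.grid(partner = c("P1", "P2"), cell_line = c("c1", "c2", "c3"),
                     stringsAsFactors = FALSE)
  base_iae <- seq_len(nrow(ctx)) / 2
  toy <- rbind(
    data.frame(drugA = "X", drugB = ctx$partner, cell_line = ctx$cell_line,
               log10_iae = base_iae),
    data.frame(drugA = "Y", drugB = ctx$partner, cell_line = ctx$cell_line,
               log10_iae = base_iae + 1))
  toy[c("kappa", "bliss_volume", "ci50", "hillA", "hillB", "hill_product",
        "potencyA", "potencyB")] <- 1
  rs <- relative_sensitivity(toy, "X", "Y")
  expect_equal(unname(rs), rep(1, 3), tolerance = 1e-12)
  rs_sw <- relative_sensitivity(toy, "Y", "X")
  expect_equal(unname(rs_sw), rep(-1, 3), tolerance = 1e-12)
})

test_that("phenotype projection anchors the references at 0 and 1", {
  set.seed(66)
  base <- matrix(rnorm(5 * 8), 5, 8,
                 dimnames = list(paste0("CL", 1:5), paste0("combo", 1:8)))
  v <- rnorm(8)
  M <- base
  M["CL2", ] <- M["CL1", ] + v          # the deficient reference
  M["CL3", ] <- M["CL1", ] + 2 * v      # hyper-deficient line
  coords <- phenotype_projection(M, "CL1", "CL2")
  expect_equal(coords[["CL1"]], 0)
  expect_equal(coords[["CL2"]], 1)
  expect_equal(coords[["CL3"]], 2)
  # affine equivariance: constant combo-wise offsets leave coords unchanged
  M2 <- sweep(M, 2, rnorm(8), "+")
  expect_equal(phenotype_projection(M2, "CL1", "CL2"), coords)
  # NA columns are excluded, identical refs are an error
  M3 <- M; M3["CL4", 1] <- NA
  expect_silent(phenotype_projection(M3, "CL1", "CL2"))
  M4 <- M; M4["CL2", ] <- M4["CL1", ]
  expect_error(phenotype_projection(M4, "CL1", "CL2"), "zero")
})

test_that("expression association ranks the planted gene first", {
  syn <- small_screen(seed = 85)
  scores <- syn$truth$sensitivity_score
  rk <- rank_expression_association(scores, syn$expression, k = 11)
  expect_true(rk$gene[1] %in% syn$truth$coupled_genes)
  expect_true(all(syn$truth$coupled_genes %in% rk$gene))
  expect_gt(abs(rk$z[1]), 2)
  # k larger than the gene count returns the full ranking
  rk_all <- rank_expression_association(scores, syn$expression, k = 1e6)
  expect_equal(nrow(rk_all), nrow(syn$expression))
  expect_error(rank_expression_association(scores[1:3], syn$expression),
               "at least 5")
})

test_that("slope-bias correlation carries the Bliss slope artefact", {
  syn <- small_screen(seed = 86)
  mt <- compute_metric_table(syn)
  r_bliss <- slope_bias_correlation(mt, "bliss")
  expect_gt(r_bliss, 0)
  # class-removal recomputes on the remaining rows
  r_drop <- slope_bias_correlation(mt, "bliss", drop_classes = "Class1",
                                   classes = syn$classes)
  keep <- !(mt$drugA %in% names(syn$classes)[syn$classes == "Class1"] |
            mt$drugB %in% names(syn$classes)[syn$classes == "Class1"])
  expect_equal(r_drop, cor(log(mt$hill_product[keep]),
                           mt$bliss_volume[keep],
                           use = "complete.obs"))
  # a slope-independent metric shows no correlation by construction
  mt_null <- mt
  set.seed(1); mt_null$bliss_volume <- rnorm(nrow(mt))
  expect_lt(abs(slope_bias_correlation(mt_null, "bliss")), 0.15)
})
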