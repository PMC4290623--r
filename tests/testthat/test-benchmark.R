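inv3 <- data.frame(complex_id = c("x1", "x2", "x3"),
                   protein_id = c("P1", "P1", "P2"),
                   compound_id = c("C1", "C2", "C1"),
                   stringsAsFactors = FALSE)

test_that("grouping applies union-find, the density filter and the merge rule", {
  g <- build_groups(inv3)
  expect_length(g, 1)
  expect_equal(g[[1]]$density, 3 / 4)   # 3 complexes over 2x2 combinations

  # density exactly 0.5: a 3-protein x 4-compound spanning tree (6 of 12
  # combinations present) sits on the keep side of the boundary
  inv_half <- data.frame(
    complex_id = paste0("y", 1:6),
    protein_id = c("Q1", "Q1", "Q1", "Q1", "Q2", "Q3"),
    compound_id = c("D1", "D2", "D3", "D4", "D1", "D1"))
  g2 <- build_groups(rbind(inv3, inv_half))
  expect_length(g2, 2)
  expect_true(any(vapply(g2, function(x) x$density == 0.5, TRUE)))

  # just below: 3 proteins x 5 compounds with 7 complexes (7/15) is dropped
  inv_low <- data.frame(
    complex_id = paste0("w", 1:7),
    protein_id = c(rep("R1", 5), "R2", "R3"),
    compound_id = c(paste0("E", 1:5), "E1", "E1"))
  expect_length(build_groups(inv_low), 0)

  # single complex on its own: density 1, kept
  g3 <- build_groups(data.frame(complex_id = "z", protein_id = "R",
                                compound_id = "E"))
  expect_equal(g3[[1]]$density, 1)
})

test_that("groups overlapping in exactly half their proteins are not merged", {
  mk <- function(p, c, x) homopharma:::.pc_group(p, c, x)
  a <- mk(c("P1", "P2"), c("C1"), c("a1", "a2"))
  b <- mk(c("P2", "P3"), c("C2"), c("b1", "b2"))     # overlap = 1/2 exactly
  expect_length(homopharma:::merge_pc_groups(list(a, b)), 2)
  c2 <- mk(c("P2", "P3", "P4"), c("C2"), c("c1"))    # overlap 1/2 of smaller? no: 1/2 vs min(2,3)=2 -> 0.5
  expect_length(homopharma:::merge_pc_groups(list(a, c2)), 2)
  d <- mk(c("P1", "P2", "P5"), c("C3"), c("d1"))     # overlap with a = 2/min(2,3) = 1 > 0.5
  expect_length(homopharma:::merge_pc_groups(list(a, d)), 1)
})

test_that("grouping is invariant to record order", {
  set.seed(20)
  inv <- data.frame(
    complex_id = paste0("k", 1:12),
    protein_id = sample(paste0("P", 1:4), 12, TRUE),
    compound_id = sample(paste0("C", 1:4), 12, TRUE))
  canon <- function(groups)
    sort(vapply(groups, function(g) paste(g$complexes, collapse = ","), ""))
  base <- canon(build_groups(inv))
  for (rep in 1:5)
    expect_equal(canon(build_groups(inv[sample(12), ])), base)
})

test_that("pair labels match closed-form combinatorics", {
  groups <- list(homopharma:::.pc_group("P1", "C1", c("a", "b", "c")))
  lp <- label_pairs(groups, c("a", "b", "c", "d"))
  cnt <- attr(lp, "counts")
  expect_equal(unname(cnt["positive"]), 3L)   # C(3,2)
  expect_equal(unname(cnt["negative"]), 3L)   # 3 * 1 outsider
  expect_equal(nrow(lp), 6)

  lp0 <- label_pairs(list(), c("a", "b", "c"))
  expect_true(all(lp0$label == "negative"))

  # planted sizes: positives = sum C(ni,2), negatives = rest
  sizes <- c(4, 3, 5)
  ids <- unlist(lapply(seq_along(sizes), function(g)
    paste0("g", g, "_", seq_len(sizes[g]))))
  groups2 <- lapply(seq_along(sizes), function(g)
    homopharma:::.pc_group("P", "C", paste0("g", g, "_", seq_len(sizes[g]))))
  lp2 <- label_pairs(groups2, ids)
  expect_equal(unname(attr(lp2, "counts")["positive"]),
               sum(choose(sizes, 2)))
  expect_equal(sum(attr(lp2, "counts")), choose(sum(sizes), 2))
})

test_that("precision/recall/F sweep matches a brute-force confusion matrix", {
  set.seed(21)
  n <- 200
  ids <- t(combn(paste0("c", 1:21), 2))[1:n, ]
  labels <- data.frame(id1 = ids[, 1], id2 = ids[, 2],
                       label = sample(c("positive", "negative"), n, TRUE))
  scores <- data.frame(id1 = ids[, 1], id2 = ids[, 2], score = runif(n))
  sw <- prf_sweep(scores, labels)
  y <- labels$label == "positive"
  for (r in sample(nrow(sw), 25)) {
    t <- sw$threshold[r]
    pred <- scores$score >= t
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    expect_equal(sw$tp[r], tp)
    expect_equal(sw$precision[r], if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(sw$recall[r], tp / (tp + fn))
  }
  # recall is non-increasing in the threshold on tie-free scores
  expect_true(all(diff(sw$recall) <= 1e-12))
  # harmonic mean check: P = R = 0.5 -> F = 0.5
  expect_equal(2 * 0.5 * 0.5 / (0.5 + 0.5), 0.5)
  lab_perfect <- data.frame(id1 = c("a", "a"), id2 = c("b", "c"),
                            label = c("positive", "negative"))
  sc_perfect <- data.frame(id1 = c("a", "a"), id2 = c("b", "c"),
                           score = c(0.9, 0.1))
  swp <- prf_sweep(sc_perfect, lab_perfect, thresholds = 0.5)
  expect_equal(swp$f_measure, 1)
})

test_that("ROC staircase and AUC agree with the rank-statistic oracle", {
  lab <- function(y) data.frame(id1 = paste0("a", seq_along(y)),
                                id2 = paste0("b", seq_along(y)),
                                label = ifelse(y, "positive", "negative"))
  sco <- function(s, y) data.frame(id1 = paste0("a", seq_along(y)),
                                   id2 = paste0("b", seq_along(y)), score = s)
  y <- c(rep(TRUE, 4), rep(FALSE, 4))
  s_perf <- c(9:6, 4:1)
  expect_equal(roc_curve(sco(s_perf, y), lab(y))$auc, 1)
  s_tied <- rep(1, 8)
  expect_equal(roc_curve(sco(s_tied, y), lab(y))$auc, 0.5)

  set.seed(22)
  y20 <- sample(c(TRUE, FALSE), 20, TRUE, prob = c(0.4, 0.6))
  y20[1:2] <- c(TRUE, FALSE)
  s20 <- round(runif(20), 1)   # ties on purpose
  r <- roc_curve(sco(s20, y20), lab(y20))
  expect_equal(r$auc, mw_auc(s20, y20), tolerance = 1e-12)
  # complement property for tie-free scores
  s_free <- seq(0.01, 0.99, length.out = 20)
  a1 <- roc_curve(sco(s_free, y20), lab(y20))$auc
  a2 <- roc_curve(sco(-s_free, y20), lab(y20))$auc
  expect_equal(a1 + a2, 1)

  expect_error(roc_curve(sco(s20, rep(TRUE, 20)), lab(rep(TRUE, 20))),
               "positive and negative")
  # agreement with an established implementation
  p <- pROC::roc(response = y20, predictor = s20, quiet = TRUE,
                 direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
})

test_that("measure comparison ranks a perfect measure first and validates input", {
  inv <- data.frame(complex_id = paste0("c", 1:6),
                    protein_id = rep(c("P1", "P2"), each = 3),
                    compound_id = rep(c("C1", "C2"), each = 3))
  lp <- label_pairs(build_groups(inv), inv$complex_id)
  perfect <- data.frame(id1 = lp$id1, id2 = lp$id2,
                        score = ifelse(lp$label == "positive", 1, 0))
  set.seed(23)
  noise1 <- data.frame(id1 = lp$id1, id2 = lp$id2, score = runif(nrow(lp)))
  noise2 <- data.frame(id1 = lp$id1, id2 = lp$id2,
                       score = 10^-(runif(nrow(lp)) * 20))
  rep_ <- compare_measures(inv, protein_scores = noise2,
                           compound_scores = noise1,
                           interaction_scores = perfect)
  auc <- setNames(rep_$auc$auc, rep_$auc$measure)
  expect_equal(unname(auc["interaction"]), 1)
  expect_gte(auc["interaction"], max(auc))

  same <- compare_measures(inv, protein_scores = perfect,
                           compound_scores = perfect,
                           interaction_scores = perfect,
                           protein_is_evalue = FALSE)
  expect_equal(same$roc$protein$points, same$roc$compound$points)

  expect_error(compare_measures(inv, noise2[-1, ], noise1, perfect),
               "missing")
})
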