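test_that("conservation weights count complexes per channel", {
  m0 <- matrix(0, 10, 6)
  m_hb <- m0; m_hb[7, 3] <- 1           # hbond.mainchain at column 7
  profs <- lapply(1:4, function(i) profile_from_matrix(m_hb, paste0("p", i)))
  W <- conservation_weights(profs)
  expect_equal(W$N, 4)
  expect_equal(unname(W$W[7, 3]), 1.0)
  expect_equal(W$f, W$W * W$N)

  profs2 <- c(profs[1:2],
              lapply(3:4, function(i) profile_from_matrix(m0, paste0("p", i))))
  expect_equal(unname(conservation_weights(profs2)$W[7, 3]), 0.5)
  expect_equal(sum(conservation_weights(profs2)$W), 0.5)  # absent keys are zero

  bad <- c(profs[1], list(profile_from_matrix(matrix(0, 5, 6), "q")))
  expect_error(conservation_weights(bad), "frame")
})

test_that("interaction similarity reduces to set Jaccard for unit weights", {
  W1 <- matrix(1, 1, 3)
  A <- profile_from_matrix(matrix(c(1, 1, 0), 1), "A")
  B <- profile_from_matrix(matrix(c(1, 0, 1), 1), "B")
  expect_equal(interaction_similarity(A, B, W1), 1 / 3)
  expect_equal(interaction_similarity(A, A, W1), 1)
  C <- profile_from_matrix(matrix(c(0, 0, 1), 1), "C")
  D <- profile_from_matrix(matrix(c(1, 1, 0), 1), "D")
  expect_equal(interaction_similarity(C, D, W1), 0)

  set.seed(11)
  for (rep in 1:200) {
    a <- random_profile(6, 6, 0.4, "a")
    b <- random_profile(6, 6, 0.4, "b")
    expect_equal(interaction_similarity(a, b, matrix(1, 6, 6)),
                 jaccard_oracle(as.numeric(a$mat), as.numeric(b$mat)),
                 tolerance = 1e-12)
  }
})

test_that("the weighted worked example evaluates exactly", {
  A <- profile_from_matrix(matrix(c(1, 0), 1), "A")
  B <- profile_from_matrix(matrix(c(1, 1), 1), "B")
  W <- matrix(c(0.5, 1.0), 1)
  # 0.25 / (0.25 + 1.25 - 0.25)
  expect_identical(interaction_similarity(A, B, W), 0.2)
})

test_that("similarity is scale-covariant in the weights for binary profiles", {
  set.seed(12)
  for (rep in 1:50) {
    a <- random_profile(5, 6, 0.4, "a")
    b <- random_profile(5, 6, 0.4, "b")
    W <- matrix(runif(30, 0.1, 1), 5, 6)
    s1 <- interaction_similarity(a, b, W)
    s2 <- interaction_similarity(a, b, 3.7 * W)
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("shared channels never decrease and unique channels never increase Sc", {
  set.seed(13)
  for (rep in 1:50) {
    a <- random_profile(6, 6, 0.3, "a")
    b <- random_profile(6, 6, 0.3, "b")
    W <- matrix(runif(36, 0.1, 1), 6, 6)
    s0 <- interaction_similarity(a, b, W)
    zero <- which(a$mat == 0 & b$mat == 0)
    if (length(zero)) {
      k <- sample(zero, 1)
      a2 <- a; b2 <- b
      a2$mat[k] <- 1; b2$mat[k] <- 1          # shared channel added
      expect_gte(interaction_similarity(a2, b2, W) - s0, -1e-12)
      a3 <- a; a3$mat[k] <- 1                  # channel unique to A
      expect_lte(interaction_similarity(a3, b, W) - s0, 1e-12)
    }
  }
})

test_that("the similarity matrix is symmetric with unit diagonal and oracle-exact", {
  set.seed(14)
  profs <- lapply(1:10, function(i) random_profile(6, 6, 0.4, paste0("p", i)))
  profs[[2]] <- profs[[1]]; profs[[2]]$complex_id <- "p2"   # duplicate profile
  S <- similarity_matrix(profs, W = matrix(1, 6, 6))
  expect_equal(S, t(S))
  expect_equal(S["p1", "p2"], 1)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(S[i, j], jaccard_oracle(as.numeric(profs[[i]]$mat),
                                         as.numeric(profs[[j]]$mat)))
})

test_that("clustering splits clean blocks and honours k and singleton input", {
  ids <- paste0("c", 1:6)
  S <- matrix(0, 6, 6, dimnames = list(ids, ids))
  S[1:3, 1:3] <- 1; S[4:6, 4:6] <- 1
  cl <- cluster_profiles(S)
  expect_equal(length(unique(cl$groups)), 2)
  expect_equal(length(unique(cl$groups[1:3])), 1)
  cl1 <- cluster_profiles(S, k = 1)
  expect_equal(length(unique(cl1$groups)), 1)
  single <- cluster_profiles(matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(single$groups, c(x = 1L))
  expect_null(single$hclust)
})

test_that("column clustering recovers transposed planted blocks", {
  m1 <- matrix(0, 4, 6); m1[1, 1:3] <- 1
  m2 <- matrix(0, 4, 6); m2[2, 4:6] <- 1
  profs <- c(lapply(1:3, function(i) profile_from_matrix(m1, paste0("a", i))),
             lapply(1:3, function(i) profile_from_matrix(m2, paste0("b", i))))
  cc <- cluster_columns(profs)
  expect_equal(length(cc$channels), 6)
  grp <- cutree(cc$hclust, k = 2)
  blocks <- split(names(grp), grp)
  expect_true(all(startsWith(blocks[[grp[["1|electrostatic.mainchain"]]]], "1|")))
  # single active channel: no dendrogram
  one <- cluster_columns(list(profile_from_matrix(m1[, 1, drop = FALSE], "x"),
                              profile_from_matrix(m1[, 1, drop = FALSE], "y")))
  expect_null(one$hclust)
})

test_that("the pipeline groups rigid copies together and reports drop provenance", {
  plant <- data.frame(position = c(2, 5, 8),
                      itype = c("hbond", "electrostatic", "vdw"),
                      chain_part = c("mainchain", "sidechain", "sidechain"))
  q <- make_pocket_complex("q", plant, seed = 40)
  copies <- lapply(1:3, function(i) {
    pk <- make_pocket_complex(paste0("copy", i), plant, seed = 40 + i,
                              rigid = TRUE)
    pk$record
  })
  ids <- c("q", paste0("copy", 1:3))
  aln <- msa(ids, rep(chain_sequence(q$record)$sequence, 4))
  cmp <- lapply(ids, function(i) parse_compound("CCNCCO", id = i))
  names(cmp) <- ids
  fit <- homopharma(q$record, copies, compounds = cmp, aln = aln)
  expect_s3_class(fit, "homopharma")
  expect_equal(length(unique(fit$groups)), 1)
  expect_equal(nrow(fit$drops$rmsd), 0)
  expect_equal(nrow(fit$drops$compound), 0)

  # a distorted candidate is dropped by RMSD, a dissimilar compound by topology
  distorted <- make_pocket_complex("faraway", plant, seed = 77)$record
  distorted$protein$z <- distorted$protein$z +
    (distorted$protein$resno > 7) * 10
  cmp2 <- c(cmp, list(faraway = parse_compound("CCNCCO", id = "faraway"),
                      oddball = parse_compound("c1ccccc1c2ccccc2",
                                               id = "oddball")))
  oddball <- make_pocket_complex("oddball", plant, seed = 78, rigid = TRUE)$record
  aln2 <- msa(c(ids, "faraway", "oddball"),
              rep(chain_sequence(q$record)$sequence, 6))
  fit2 <- homopharma(q$record, c(copies, list(distorted, oddball)),
                     compounds = cmp2, aln = aln2)
  expect_equal(fit2$drops$rmsd$complex_id, "faraway")
  expect_equal(fit2$drops$compound$complex_id, "oddball")
  expect_setequal(names(fit2$groups), ids)

  # no candidates at all: singleton result with a warning
  expect_warning(
    fit3 <- homopharma(q$record, list(), compounds = cmp["q"], aln = aln),
    "fewer than 2")
  expect_equal(fit3$groups, c(q = 1L))
})

test_that("summary, prediction and exports work on a fitted object", {
  scen <- make_homopharma_scenario(scenario_spec(seed = 5, n_groups = 2,
                                                 complexes_per_group = 4,
                                                 pocket_size = 10))
  fit <- run_scenario(scen)
  s <- summary(fit)
  expect_gt(s$mean_within, s$mean_between)
  expect_output(print(fit), "Homopharma result")

  pred <- predict(fit, fit$profiles[[2]])
  expect_equal(pred$group, unname(fit$groups[fit$profiles[[2]]$complex_id]))

  gj <- tempfile(fileext = ".json")
  write_groups_json(fit, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(length(parsed$groups), length(unique(fit$groups)))

  nwk <- tempfile(fileext = ".nwk")
  write_newick(fit$row_hclust, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, names(fit$groups))
})
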