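# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quaternion (Horn) superposition, Floyd-Warshall
# atom-pair enumeration, set-Jaccard, and brute-force confusion matrices.

# Horn's closed-form quaternion superposition; returns the optimal RMSD
quat_rmsd <- function(q, p) {
  qc <- sweep(q, 2, colMeans(q)); pc <- sweep(p, 2, colMeans(p))
  M <- crossprod(pc, qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(qc^2) + sum(pc^2)
  sqrt(max(ss - 2 * lam, 0) / nrow(q))
}

# random proper rotation matrix
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# brute-force atom-pair fingerprint: double loop over atoms with
# Floyd-Warshall all-pairs shortest paths; types recomputed from bonds
brute_ap <- function(g) {
  n <- nrow(g$atoms)
  deg <- integer(n); pi_ <- numeric(n); arom <- logical(n)
  D <- matrix(Inf, n, n); diag(D) <- 0
  if (nrow(g$bonds)) for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]; o <- g$bonds$order[r]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    if (o == 2) { pi_[i] <- pi_[i] + 1; pi_[j] <- pi_[j] + 1 }
    if (o == 3) { pi_[i] <- pi_[i] + 2; pi_[j] <- pi_[j] + 2 }
    if (o == 4) { arom[i] <- TRUE; arom[j] <- TRUE }
    D[i, j] <- D[j, i] <- 1
  }
  pi_[arom & pi_ == 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  types <- sprintf("%s.%d.%d", g$atoms$element, deg, as.integer(pi_))
  keys <- character(0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (!is.finite(D[i, j])) next
    ab <- sort(c(types[i], types[j]))
    keys <- c(keys, paste(ab[1], ab[2], D[i, j], sep = "|"))
  }
  tab <- table(keys)
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

# set-Jaccard of two binary vectors
jaccard_oracle <- function(a, b) {
  sa <- which(a > 0); sb <- which(b > 0)
  u <- union(sa, sb)
  if (!length(u)) return(0)
  length(intersect(sa, sb)) / length(u)
}

# minimal InteractionProfile-shaped object from a matrix
profile_from_matrix <- function(mat, id = "p") {
  colnames(mat) <- c("electrostatic.mainchain", "electrostatic.sidechain",
                     "hbond.mainchain", "hbond.sidechain",
                     "vdw.mainchain", "vdw.sidechain")[seq_len(ncol(mat))]
  structure(list(complex_id = id, mat = mat, mode = "binary",
                 n_events = sum(mat)), class = "InteractionProfile")
}

# random binary profile on a fixed frame
random_profile <- function(ncolumns = 8, nchannels = 6, density = 0.3,
                           id = "p") {
  m <- matrix(as.numeric(stats::runif(ncolumns * nchannels) < density),
              ncolumns, nchannels)
  profile_from_matrix(m, id)
}

# Mann-Whitney AUC oracle with midranks for ties
mw_auc <- function(scores, positive) {
  r <- rank(scores)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

fixture_path <- function(...) testthat::test_path("fixtures", ...)

ccd_graph <- function(id) {
  parse_compound(system.file("extdata", "ccd", paste0(id, ".sdf"),
                             package = "homopharma"), id = id)
}
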