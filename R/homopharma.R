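# Conservation weights, conservation-weighted interaction similarity,
# two-way hierarchical clustering and the end-to-end pipeline.
#
# With N member complexes, f_ik = number of complexes showing interaction
# type k at alignment column i, the conservation weight is W_ik = f_ik / N.
# The similarity of two profiles A, B with weighted channels a_i = A_i W_i,
# b_i = B_i W_i is the Tanimoto form
#   Sc(A,B) = sum(a b) / (sum(a^2) + sum(b^2) - sum(a b)),
# which reduces to the set Jaccard index for binary profiles with unit
# weights.

#' Conservation weights over interaction channels
#'
#' @param profiles list of \code{InteractionProfile} sharing one alignment
#'   frame (identical matrix dimensions).
#' @return \code{ConservationWeights}: list with \code{N}, \code{f} (complex
#'   counts per channel) and \code{W = f / N}.
#' @export
conservation_weights <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  dims <- vapply(profiles, function(p) dim(p$mat), c(1, 1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("profiles do not share one alignment frame (differing dimensions)")
  f <- Reduce(`+`, lapply(profiles, function(p) (p$mat > 0) * 1))
  N <- length(profiles)
  structure(list(N = N, f = f, W = f / N), class = "ConservationWeights")
}

#' @export
print.ConservationWeights <- function(x, ...) {
  cat(sprintf("ConservationWeights: N = %d complexes, %d columns x %d channels, %d active channels\n",
              x$N, nrow(x$W), ncol(x$W), sum(x$f > 0)))
  invisible(x)
}

.weighted_vec <- function(profile, W, collapse_types = FALSE) {
  v <- profile$mat * W
  if (collapse_types) {
    part <- sub("^.*\\.", "", colnames(v))
    v <- cbind(rowSums(v[, part == "mainchain", drop = FALSE]),
               rowSums(v[, part == "sidechain", drop = FALSE]))
  }
  as.numeric(v)
}

#' Conservation-weighted interaction similarity
#'
#' @param A,B \code{InteractionProfile} objects.
#' @param W a \code{\link{conservation_weights}} object (or a numeric matrix
#'   of the same shape as the profile matrices).
#' @param collapse_types sum the three interaction types per column/chain part
#'   before scoring (alternative reading of the per-position weight).
#' @return similarity score in [0, 1]; 0 when both weighted vectors vanish.
#' @export
interaction_similarity <- function(A, B, W, collapse_types = FALSE) {
  Wm <- if (inherits(W, "ConservationWeights")) W$W else W
  if (!all(dim(A$mat) == dim(Wm)) || !all(dim(B$mat) == dim(Wm)))
    stop("profiles and weights do not share one alignment frame")
  a <- .weighted_vec(A, Wm, collapse_types)
  b <- .weighted_vec(B, Wm, collapse_types)
  ab <- sum(a * b)
  den <- sum(a^2) + sum(b^2) - ab
  if (den <= 0) return(0)
  ab / den
}

#' Pairwise interaction-similarity matrix
#'
#' @param profiles list of \code{InteractionProfile} (>= 2), shared frame.
#' @param W \code{\link{conservation_weights}}; computed from the profiles
#'   when missing.
#' @param collapse_types see \code{\link{interaction_similarity}}.
#' @return symmetric similarity matrix with complex ids as dimnames; the
#'   diagonal is 1 for complexes with at least one weighted interaction.
#' @export
similarity_matrix <- function(profiles, W = NULL, collapse_types = FALSE) {
  stopifnot(length(profiles) >= 2)
  if (is.null(W)) W <- conservation_weights(profiles)
  Wm <- if (inherits(W, "ConservationWeights")) W$W else W
  ids <- vapply(profiles, function(p) p$complex_id, "")
  vecs <- lapply(profiles, .weighted_vec, W = Wm, collapse_types = collapse_types)
  n <- length(vecs)
  sq <- vapply(vecs, function(v) sum(v^2), 0)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(S) <- ifelse(sq > 0, 1, 0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ab <- sum(vecs[[i]] * vecs[[j]])
    den <- sq[i] + sq[j] - ab
    S[i, j] <- S[j, i] <- if (den <= 0) 0 else ab / den
  }
  S
}

#' Cluster complexes by interaction similarity
#'
#' Average-linkage (UPGMA by default) agglomerative clustering on the
#' distance 1 - Sc, cut either at a similarity threshold (default 0.6: merges
#' at distance <= 0.4 stay together) or into k groups.
#'
#' @param S similarity matrix from \code{\link{similarity_matrix}}.
#' @param linkage linkage method passed to \code{\link[stats]{hclust}}.
#' @param cut_similarity similarity threshold defining the cut.
#' @param k number of groups (overrides \code{cut_similarity} when given).
#' @return list with \code{groups} (named integer vector), \code{hclust}
#'   (\code{NULL} for a single complex) and the cut used.
#' @export
cluster_profiles <- function(S, linkage = "average", cut_similarity = 0.6,
                             k = NULL) {
  ids <- rownames(S)
  if (nrow(S) == 1)
    return(list(groups = stats::setNames(1L, ids), hclust = NULL,
                cut = if (is.null(k)) cut_similarity else k))
  D <- stats::as.dist(1 - S)
  hc <- stats::hclust(D, method = linkage)
  groups <- if (is.null(k)) stats::cutree(hc, h = 1 - cut_similarity)
  else stats::cutree(hc, k = min(k, nrow(S)))
  list(groups = groups, hclust = hc,
       cut = if (is.null(k)) cut_similarity else k)
}

#' Cluster interaction channels (the second way of the two-way clustering)
#'
#' Applies the same Tanimoto-form similarity and linkage to the transposed
#' weighted profile matrix (channels as objects, complexes as features). Used
#' for heat-map column ordering only, never for group assignment.
#'
#' @param profiles list of \code{InteractionProfile}.
#' @param W \code{\link{conservation_weights}}; computed when missing.
#' @param linkage linkage method.
#' @param active_only cluster only channels that are nonzero in at least one
#'   profile (default), since all-zero channels carry no ordering signal.
#' @return list with \code{hclust} (or \code{NULL} when fewer than 2
#'   channels), \code{channels} (labels "column|itype.part") and the channel
#'   matrix.
#' @export
cluster_columns <- function(profiles, W = NULL, linkage = "average",
                            active_only = TRUE) {
  if (is.null(W)) W <- conservation_weights(profiles)
  Wm <- if (inherits(W, "ConservationWeights")) W$W else W
  M <- do.call(rbind, lapply(profiles, .weighted_vec, W = Wm))  # complexes x channels
  rownames(M) <- vapply(profiles, function(p) p$complex_id, "")
  nc <- ncol(Wm); nr <- nrow(Wm)
  labels <- as.vector(outer(seq_len(nr), colnames(Wm),
                            function(i, ch) paste(i, ch, sep = "|")))
  colnames(M) <- labels
  if (active_only) M <- M[, colSums(M) > 0, drop = FALSE]
  if (ncol(M) < 2)
    return(list(hclust = NULL, channels = colnames(M), matrix = M))
  n <- ncol(M)
  S <- matrix(0, n, n, dimnames = list(colnames(M), colnames(M)))
  sq <- colSums(M^2)
  diag(S) <- ifelse(sq > 0, 1, 0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ab <- sum(M[, i] * M[, j])
    den <- sq[i] + sq[j] - ab
    S[i, j] <- S[j, i] <- if (den <= 0) 0 else ab / den
  }
  hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
  list(hclust = hc, channels = colnames(M), matrix = M)
}

#' Pipeline configuration
#'
#' All tunables of the group-identification pipeline with their defaults:
#' RMSD reservation at 3 Angstrom over CA atoms, compound-topology
#' reservation at Tanimoto 0.6, binary interaction profiles, average-linkage
#' clustering cut at interaction similarity 0.6. Unknown keys are rejected.
#'
#' @param ... overrides for any default field.
#' @return list of class \code{"homopharma_config"}.
#' @export
homopharma_config <- function(...) {
  cfg <- list(rmsd_cutoff = 3.0, atom_set = "CA",
              compound_threshold = 0.6, cut_similarity = 0.6, k = NULL,
              linkage = "average", mode = "binary", collapse_types = FALSE,
              params = interaction_params(), filter = filter_config(),
              report_threshold = 0.5)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "homopharma_config")
}

#' Identify groups of complexes sharing conserved interactions
#'
#' End-to-end pipeline. Candidates are reserved by superposition RMSD onto
#' the query, then by compound topology similarity to the query's compound;
#' interaction profiles of the surviving complexes are scored with
#' conservation weights and clustered two-way into groups.
#'
#' @param query a \code{ComplexRecord}.
#' @param candidates list of \code{ComplexRecord}, or elements of
#'   \code{list(record =, correspondence =)} when residue numbering differs
#'   from the query.
#' @param compounds named list of \code{CompoundGraph}, one per complex id
#'   (query included).
#' @param aln an \code{\link{msa}} with one row per complex; \code{rows} maps
#'   complex ids to row ids.
#' @param rows named character vector complex id -> alignment row id;
#'   defaults to the complex ids themselves.
#' @param config a \code{\link{homopharma_config}}.
#' @return object of class \code{"homopharma"}: groups, similarity matrix,
#'   conservation weights, profiles, row/column dendrograms, per-group
#'   conserved channels, and per-stage drop provenance.
#' @export
homopharma <- function(query, candidates, compounds, aln, rows = NULL,
                       config = homopharma_config()) {
  cl <- match.call()
  if (!inherits(config, "homopharma_config")) stop("config must be a homopharma_config")
  # Step 1: RMSD reservation
  rr <- rmsd_reserve(query, candidates, cutoff = config$rmsd_cutoff,
                     atom_set = config$atom_set)
  surviving <- c(stats::setNames(list(query), query$complex_id),
                 lapply(rr$reserved, `[[`, "record"))
  drops <- list(rmsd = rr$table[!rr$table$reserved, , drop = FALSE])
  # Step 2: compound-topology reservation against the query's compound
  if (is.null(compounds[[query$complex_id]]))
    stop("no compound supplied for the query complex ", query$complex_id)
  cand_ids <- setdiff(names(surviving), query$complex_id)
  missing_cmp <- cand_ids[!cand_ids %in% names(compounds)]
  if (length(missing_cmp))
    stop("no compound supplied for: ", paste(missing_cmp, collapse = ", "))
  if (length(cand_ids)) {
    rs <- reserve_by_similarity(compounds[cand_ids],
                                references = compounds[query$complex_id],
                                threshold = config$compound_threshold)
    drops$compound <- rs$dropped
    surviving <- surviving[c(query$complex_id, rs$reserved$complex_id)]
  } else {
    drops$compound <- data.frame(complex_id = character(0),
                                 best_reference = character(0),
                                 score = numeric(0))
  }
  # Step 3: profiles, weights, similarity, two-way clustering
  if (is.null(rows))
    rows <- stats::setNames(names(surviving), names(surviving))
  profiles <- lapply(surviving, function(rec)
    interaction_profile(rec, aln, row_id = rows[[rec$complex_id]],
                        params = config$params, mode = config$mode))
  if (length(profiles) < 2) {
    warning("fewer than 2 complexes survive the filters; no clustering performed")
    W1 <- conservation_weights(profiles)
    res <- list(groups = stats::setNames(1L, names(profiles)),
                similarity = matrix(1, 1, 1,
                                    dimnames = list(names(profiles), names(profiles))),
                weights = W1, profiles = profiles, row_hclust = NULL,
                col_hclust = NULL,
                conserved = .conserved_channels(profiles,
                                                stats::setNames(1L, names(profiles)),
                                                config$report_threshold),
                drops = drops, config = config, call = cl)
    return(structure(res, class = "homopharma"))
  }
  W <- conservation_weights(profiles)
  S <- similarity_matrix(profiles, W, collapse_types = config$collapse_types)
  clu <- cluster_profiles(S, linkage = config$linkage,
                          cut_similarity = config$cut_similarity, k = config$k)
  colclu <- cluster_columns(profiles, W, linkage = config$linkage)
  structure(list(groups = clu$groups, similarity = S, weights = W,
                 profiles = profiles, row_hclust = clu$hclust,
                 col_hclust = colclu$hclust,
                 conserved = .conserved_channels(profiles, clu$groups,
                                                 config$report_threshold),
                 drops = drops, config = config, call = cl),
            class = "homopharma")
}

# per-group conserved channels: recompute weights within each group and
# report channels at or above the threshold
.conserved_channels <- function(profiles, groups, threshold) {
  ids <- vapply(profiles, function(p) p$complex_id, "")
  out <- list()
  for (g in sort(unique(groups))) {
    member <- names(groups)[groups == g]
    Wg <- conservation_weights(profiles[match(member, ids)])
    nz <- which(Wg$W >= threshold & Wg$f > 0, arr.ind = TRUE)
    out[[as.character(g)]] <- data.frame(
      column = nz[, 1],
      channel = colnames(Wg$W)[nz[, 2]],
      weight = Wg$W[nz], stringsAsFactors = FALSE)
  }
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
print.homopharma <- function(x, ...) {
  n <- length(x$groups)
  ng <- length(unique(x$groups))
  cat(sprintf("Homopharma result: %d complexes in %d group(s)\n", n, ng))
  cat(sprintf("  dropped: %d by RMSD filter, %d by compound similarity\n",
              nrow(x$drops$rmsd), nrow(x$drops$compound)))
  for (g in sort(unique(x$groups)))
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$groups)[x$groups == g], collapse = ", ")))
  invisible(x)
}

#' @export
summary.homopharma <- function(object, ...) {
  x <- object
  gsizes <- table(x$groups)
  s <- list(n_complexes = length(x$groups),
            n_groups = length(gsizes),
            group_sizes = as.integer(gsizes),
            mean_within = NA_real_, mean_between = NA_real_,
            n_dropped_rmsd = nrow(x$drops$rmsd),
            n_dropped_compound = nrow(x$drops$compound),
            conserved = x$conserved)
  if (length(x$groups) >= 2) {
    same <- outer(x$groups, x$groups, `==`)
    ut <- upper.tri(x$similarity)
    if (any(same & ut)) s$mean_within <- mean(x$similarity[same & ut])
    if (any(!same & ut)) s$mean_between <- mean(x$similarity[!same & ut])
  }
  class(s) <- "summary.homopharma"
  s
}

#' @export
print.summary.homopharma <- function(x, ...) {
  cat(sprintf("%d complexes, %d group(s) (sizes: %s)\n", x$n_complexes,
              x$n_groups, paste(x$group_sizes, collapse = ", ")))
  cat(sprintf("mean within-group Sc:  %s\n",
              ifelse(is.na(x$mean_within), "-", sprintf("%.3f", x$mean_within))))
  cat(sprintf("mean between-group Sc: %s\n",
              ifelse(is.na(x$mean_between), "-", sprintf("%.3f", x$mean_between))))
  cat(sprintf("dropped: %d (RMSD), %d (compound topology)\n",
              x$n_dropped_rmsd, x$n_dropped_compound))
  for (g in names(x$conserved)) {
    tab <- x$conserved[[g]]
    cat(sprintf("group %s: %d conserved channel(s)\n", g, nrow(tab)))
  }
  invisible(x)
}

#' Assign new interaction profiles to existing groups
#'
#' A new complex joins the group with the highest mean conservation-weighted
#' similarity to the group members (weights from the fitted object).
#'
#' @param object a \code{homopharma} result.
#' @param newprofiles list of \code{InteractionProfile} on the same alignment
#'   frame.
#' @param ... unused.
#' @return data.frame: complex_id, group, mean_similarity.
#' @export
predict.homopharma <- function(object, newprofiles, ...) {
  if (inherits(newprofiles, "InteractionProfile"))
    newprofiles <- list(newprofiles)
  ids <- vapply(object$profiles, function(p) p$complex_id, "")
  rows <- lapply(newprofiles, function(np) {
    sims <- vapply(object$profiles, function(p)
      interaction_similarity(np, p, object$weights,
                             collapse_types = object$config$collapse_types), 0)
    means <- tapply(sims, object$groups[ids], mean)
    data.frame(complex_id = np$complex_id,
               group = as.integer(names(means)[which.max(means)]),
               mean_similarity = max(means), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heat map of the two-way clustered interaction profiles
#'
#' Rows are complexes, columns are active interaction channels, both ordered
#' by their dendrograms; cell values are conservation-weighted interactions.
#'
#' @param x a \code{homopharma} result.
#' @param ... passed to \code{\link[stats]{heatmap}}.
#' @export
plot.homopharma <- function(x, ...) {
  cc <- cluster_columns(x$profiles, x$weights)
  M <- cc$matrix
  if (nrow(M) < 2 || ncol(M) < 2) {
    stop("need at least 2 complexes and 2 active channels to draw a heat map")
  }
  rowv <- if (!is.null(x$row_hclust)) stats::as.dendrogram(x$row_hclust) else NA
  colv <- if (!is.null(cc$hclust)) stats::as.dendrogram(cc$hclust) else NA
  stats::heatmap(M, Rowv = rowv, Colv = colv, scale = "none",
                 col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Export groups as JSON
#'
#' @param x a \code{homopharma} result.
#' @param path output path.
#' @export
write_groups_json <- function(x, path) {
  groups <- lapply(sort(unique(x$groups)), function(g)
    list(group = g, members = names(x$groups)[x$groups == g]))
  jsonlite::write_json(list(schema_version = "1.0", groups = groups),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a dendrogram as Newick with merge heights
#'
#' @param hc an \code{hclust} object.
#' @param path output path.
#' @export
write_newick <- function(hc, path) {
  n <- length(hc$labels)
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.6f", hc$labels[-i], parent_h))
    h <- hc$height[i]
    sprintf("(%s,%s):%.6f", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
            parent_h - h)
  }
  root <- length(hc$height)
  txt <- paste0("(", node(hc$merge[root, 1], hc$height[root]), ",",
                node(hc$merge[root, 2], hc$height[root]), ");")
  writeLines(txt, path)
  invisible(path)
}
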