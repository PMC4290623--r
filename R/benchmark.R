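# Validation benchmark: protein-compound grouping rules, positive/negative
# pair labelling, precision/recall/F sweeps and ROC comparison of protein,
# compound and interaction similarity.

#' Read a complex inventory
#'
#' @param path TSV with header columns complex_id, protein_id, compound_id.
#' @return data.frame inventory.
#' @export
read_inventory <- function(path) {
  inv <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("complex_id", "protein_id", "compound_id")
  if (!all(need %in% names(inv)))
    stop("inventory needs columns: ", paste(need, collapse = ", "))
  inv
}

.pc_group <- function(proteins, compounds, complexes) {
  structure(list(proteins = sort(unique(proteins)),
                 compounds = sort(unique(compounds)),
                 complexes = sort(unique(complexes)),
                 density = length(unique(complexes)) /
                   (length(unique(proteins)) * length(unique(compounds)))),
            class = "PCGroup")
}

#' @export
print.PCGroup <- function(x, ...) {
  cat(sprintf("PCGroup: %d proteins x %d compounds, %d complexes (density %.2f)\n",
              length(x$proteins), length(x$compounds), length(x$complexes),
              x$density))
  invisible(x)
}

# overlap fraction of the smaller set
.overlap_frac <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

# iteratively merge groups whose protein or compound overlap exceeds 50% of
# the smaller set; most-overlapping pair first, until fixpoint
merge_pc_groups <- function(groups, frac = 0.5) {
  repeat {
    n <- length(groups)
    if (n < 2) break
    best <- c(0, 0, 0)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ov <- max(.overlap_frac(groups[[i]]$proteins, groups[[j]]$proteins),
                .overlap_frac(groups[[i]]$compounds, groups[[j]]$compounds))
      if (ov > best[1]) best <- c(ov, i, j)
    }
    if (best[1] <= frac) break   # strict inequality required to merge
    i <- best[2]; j <- best[3]
    merged <- .pc_group(c(groups[[i]]$proteins, groups[[j]]$proteins),
                        c(groups[[i]]$compounds, groups[[j]]$compounds),
                        c(groups[[i]]$complexes, groups[[j]]$complexes))
    groups <- c(groups[-c(i, j)], list(merged))
  }
  groups
}

#' Build validation protein-compound groups
#'
#' (1) Union-find over records sharing a protein or a compound yields initial
#' groups; (2) groups whose complex count is below 50\% of all possible
#' protein-compound combinations (density < 0.5) are dropped; (3) remaining
#' groups overlapping in more than 50\% of the smaller group's proteins or
#' compounds are merged, most-overlapping pair first, to a fixpoint. The
#' result is deterministic and invariant to record order.
#'
#' @param inventory data.frame with columns complex_id, protein_id,
#'   compound_id.
#' @param min_density density threshold for step 2 (kept when >= threshold).
#' @param merge_frac overlap fraction for step 3 (merged when > threshold).
#' @return list of \code{PCGroup}.
#' @export
build_groups <- function(inventory, min_density = 0.5, merge_frac = 0.5) {
  inv <- inventory[order(inventory$complex_id), , drop = FALSE]
  n <- nrow(inv)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- max(ri, rj)
  }
  for (key in list(inv$protein_id, inv$compound_id)) {
    for (grp in split(seq_len(n), key)) {
      if (length(grp) > 1) for (k in seq(2, length(grp)))
        union_(grp[1], grp[k])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(seq_len(n), roots)
  groups <- lapply(comps, function(ii)
    .pc_group(inv$protein_id[ii], inv$compound_id[ii], inv$complex_id[ii]))
  names(groups) <- NULL
  groups <- groups[vapply(groups, function(g) g$density >= min_density, TRUE)]
  merge_pc_groups(groups, frac = merge_frac)
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Label all complex pairs as positive or negative
#'
#' A pair is positive when both complexes belong to one final group.
#'
#' @param groups list of \code{PCGroup} (disjoint complexes).
#' @param complexes character vector: the universe of complex ids.
#' @return data.frame id1, id2, label; attribute \code{counts} holds the
#'   positive/negative totals.
#' @export
label_pairs <- function(groups, complexes) {
  complexes <- sort(unique(complexes))
  member <- stats::setNames(rep(NA_integer_, length(complexes)), complexes)
  for (g in seq_along(groups)) {
    ids <- intersect(groups[[g]]$complexes, complexes)
    if (any(!is.na(member[ids]))) stop("groups are not disjoint")
    member[ids] <- g
  }
  if (length(complexes) < 2)
    return(structure(data.frame(id1 = character(0), id2 = character(0),
                                label = character(0)),
                     counts = c(positive = 0L, negative = 0L)))
  idx <- utils::combn(complexes, 2)
  g1 <- member[idx[1, ]]; g2 <- member[idx[2, ]]
  lab <- ifelse(!is.na(g1) & !is.na(g2) & g1 == g2, "positive", "negative")
  out <- data.frame(id1 = idx[1, ], id2 = idx[2, ], label = lab,
                    stringsAsFactors = FALSE)
  structure(out, counts = c(positive = sum(lab == "positive"),
                            negative = sum(lab == "negative")))
}

# join pair scores onto labelled pairs; error listing missing pairs
.join_scores <- function(labels, scores) {
  key_l <- .pair_key(labels$id1, labels$id2)
  key_s <- .pair_key(scores$id1, scores$id2)
  m <- match(key_l, key_s)
  if (anyNA(m))
    stop("scores missing for pair(s): ",
         paste(utils::head(key_l[is.na(m)], 10), collapse = ", "))
  scores$score[m]
}

#' Precision / recall / F-measure threshold sweep
#'
#' Predicted positive when score >= threshold; F = 2PR/(P+R) and 0 when
#' P + R = 0.
#'
#' @param scores data.frame id1, id2, score covering all labelled pairs.
#' @param labels data.frame from \code{\link{label_pairs}}.
#' @param thresholds numeric grid; defaults to the unique scores.
#' @return data.frame threshold, tp, fp, fn, precision, recall, f_measure;
#'   attribute \code{best} holds the argmax-F row.
#' @export
prf_sweep <- function(scores, labels, thresholds = NULL) {
  s <- .join_scores(labels, scores)
  y <- labels$label == "positive"
  if (is.null(thresholds)) thresholds <- sort(unique(s))
  rows <- lapply(thresholds, function(t) {
    pred <- s >= t
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f_measure = f)
  })
  out <- do.call(rbind, rows)
  structure(out, best = out[which.max(out$f_measure), , drop = FALSE])
}

#' ROC curve and AUC
#'
#' Threshold-sorted staircase with simultaneous steps at tied scores; AUC by
#' the trapezoid rule (equal to the Mann-Whitney statistic).
#'
#' @param scores data.frame id1, id2, score.
#' @param labels data.frame from \code{\link{label_pairs}}; needs at least
#'   one positive and one negative pair.
#' @return list with \code{points} (data.frame fpr, tpr) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  s <- .join_scores(labels, scores)
  y <- labels$label == "positive"
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0)
    stop("ROC undefined: need both positive and negative pairs (got ",
         np, " positives, ", nn, " negatives)")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # cumulative counts at each distinct threshold (ties step together)
  last <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumsum(y)[last] / np)
  fpr <- c(0, cumsum(!y)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Compare protein, compound and interaction similarity by ROC
#'
#' Builds the labelled pairs from the inventory and overlays one ROC per
#' similarity measure. Protein scores given as BLAST e-values are compared on
#' the -log10 scale (\code{protein_is_evalue = TRUE}); operating points are
#' marked at the binary decision thresholds (e-value 1e-10, topology 0.6,
#' interaction similarity 0.6 by default).
#'
#' @param inventory data.frame complex_id / protein_id / compound_id.
#' @param protein_scores,compound_scores,interaction_scores data.frames
#'   id1, id2, score covering all labelled pairs.
#' @param protein_is_evalue transform protein scores by -log10.
#' @param operating_points named numeric vector of decision thresholds on the
#'   (transformed) score scales.
#' @return list with \code{labels}, per-measure \code{roc}, \code{auc} table
#'   and the operating points.
#' @export
compare_measures <- function(inventory, protein_scores, compound_scores,
                             interaction_scores, protein_is_evalue = TRUE,
                             operating_points = c(protein = 10,
                                                  compound = 0.6,
                                                  interaction = 0.6)) {
  groups <- build_groups(inventory)
  labels <- label_pairs(groups, inventory$complex_id)
  if (protein_is_evalue)
    protein_scores$score <- -log10(pmax(protein_scores$score, 1e-300))
  measures <- list(protein = protein_scores, compound = compound_scores,
                   interaction = interaction_scores)
  rocs <- lapply(measures, roc_curve, labels = labels)
  auc <- data.frame(measure = names(rocs),
                    auc = vapply(rocs, `[[`, 0, "auc"))
  ops <- lapply(names(measures), function(m) {
    sw <- prf_sweep(measures[[m]], labels,
                    thresholds = operating_points[[m]])
    cbind(measure = m, sw)
  })
  list(labels = labels, roc = rocs, auc = auc,
       operating_points = do.call(rbind, ops))
}
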