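#' Region-overlap metrics for a mask pair
#'
#' Pixel-count overlap metrics between a ground-truth foreground `S1` and a
#' predicted foreground `S2` with overlap `O = S1 & S2`:
#' Jaccard similarity `JS = N(O) / N(S1 | S2)`, Dice coefficient
#' `DSC = 2 N(O) / (N(S1) + N(S2))`, and the ratios
#' `RFP = N(S1 \ O) / N(S1)` and `RFN = N(S2 \ O) / N(S2)`.
#'
#' The RFP/RFN ratios are implemented exactly as defined above even though
#' the naming is reversed relative to common usage (`S1 \ O` is the missed
#' part of the truth, conventionally a false-negative set); the formulas are
#' authoritative here.
#'
#' @param truth logical matrix: ground-truth foreground, nonempty.
#' @param pred logical matrix: predicted foreground, nonempty, same shape.
#' @return one-row data.frame with columns `js`, `dice`, `rfp`, `rfn`,
#'   `n_truth`, `n_pred`, `n_overlap`.
#' @export
overlap <- function(truth, pred) {
  if (!is.matrix(truth) || !is.logical(truth) ||
      !is.matrix(pred) || !is.logical(pred) || !all(dim(truth) == dim(pred)))
    stop_invalid("`truth` and `pred` must be logical matrices of the same shape",
                 "nbracm_invalid_input")
  n1 <- sum(truth); n2 <- sum(pred)
  if (n1 == 0L || n2 == 0L)
    stop_invalid("empty mask: overlap ratios are undefined", "nbracm_empty_mask")
  no <- sum(truth & pred)
  nu <- n1 + n2 - no
  data.frame(js = no / nu,
             dice = 2 * no / (n1 + n2),
             rfp = (n1 - no) / n1,
             rfn = (n2 - no) / n2,
             n_truth = n1, n_pred = n2, n_overlap = no)
}

#' Per-label overlap reports for two labelings
#'
#' Pairs the labels of a predicted labeling with the ground-truth labels by
#' greedy maximal overlap on the contingency table (ties broken toward the
#' smaller label ids) and computes [overlap()] for each matched pair.
#' Truth labels left unmatched are reported with `js = 0` and `pred_label =
#' NA`.
#'
#' @param truth_labels integer matrix of ground-truth labels.
#' @param pred_labels integer matrix of predicted labels, same shape.
#' @return data.frame with one row per truth label: `truth_label`,
#'   `pred_label`, and the [overlap()] columns.
#' @export
per_label_overlap <- function(truth_labels, pred_labels) {
  if (!all(dim(truth_labels) == dim(pred_labels)))
    stop_invalid("labelings must have the same shape", "nbracm_invalid_input")
  tl <- sort(unique(as.vector(truth_labels)))
  pl <- sort(unique(as.vector(pred_labels)))
  ct <- matrix(0L, length(tl), length(pl), dimnames = list(tl, pl))
  tab <- table(factor(truth_labels, levels = tl), factor(pred_labels, levels = pl))
  ct[] <- as.integer(tab)
  pairs <- data.frame(truth_label = tl, pred_label = NA_integer_)
  avail_t <- rep(TRUE, length(tl)); avail_p <- rep(TRUE, length(pl))
  work <- ct
  repeat {
    work2 <- work
    work2[!avail_t, ] <- -1L
    work2[, !avail_p] <- -1L
    if (max(work2) <= 0L) break
    # greedy: largest overlap first; which.max scans column-major so ties go
    # to the smaller truth label then the smaller predicted label
    ij <- arrayInd(which.max(work2), dim(work2))
    pairs$pred_label[ij[1L]] <- pl[ij[2L]]
    avail_t[ij[1L]] <- FALSE
    avail_p[ij[2L]] <- FALSE
    if (!any(avail_t) || !any(avail_p)) break
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t_id <- pairs$truth_label[i]; p_id <- pairs$pred_label[i]
    if (is.na(p_id)) {
      data.frame(truth_label = t_id, pred_label = NA_integer_, js = 0,
                 dice = 0, rfp = 1, rfn = NA_real_,
                 n_truth = sum(truth_labels == t_id), n_pred = 0L,
                 n_overlap = 0L)
    } else {
      rep_ <- overlap(truth_labels == t_id, pred_labels == p_id)
      cbind(data.frame(truth_label = t_id, pred_label = p_id), rep_)
    }
  })
  do.call(rbind, rows)
}

#' Misclassified-pixel count after optimal label matching
#'
#' Matches predicted labels to truth labels as in [per_label_overlap()] and
#' counts the pixels whose matched predicted label differs from the truth.
#'
#' @inheritParams per_label_overlap
#' @return integer count of misclassified pixels.
#' @export
misclassified_pixels <- function(truth_labels, pred_labels) {
  rep_ <- per_label_overlap(truth_labels, pred_labels)
  matched <- rep_[!is.na(rep_$pred_label), , drop = FALSE]
  sum(truth_labels >= 0) - sum(matched$n_overlap)
}
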