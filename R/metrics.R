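#' Match reconstructed spikes to ground truth
#'
#' One-to-one matching within a tolerance radius `delta` (Euclidean
#' distance in physical units, strictly below `delta`). The default
#' matcher sorts all candidate pairs globally by distance and accepts
#' greedily while both endpoints are free; `method = "optimal"` computes a
#' maximum-cardinality matching on the threshold graph (augmenting paths)
#' and serves as the reference for the greedy rule. Matched reconstructed
#' spikes are true positives (TP); unmatched reconstructed spikes are
#' false positives (FP); unmatched ground-truth spikes are false negatives
#' (FN).
#'
#' @param gt,rec [dirac_measure()] ground truth and reconstruction.
#' @param delta tolerance radius `> 0`.
#' @param method `"greedy"` (default, deterministic) or `"optimal"`.
#' @return list of class `match_result` with `pairs` (data frame `gt`,
#'   `rec`, `distance`), `n_tp`, `n_fp`, `n_fn`, `delta`.
#' @export
match_spikes <- function(gt, rec, delta, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(delta > 0)
  n_gt <- gt$n
  n_rec <- rec$n
  pairs <- data.frame(gt = integer(0), rec = integer(0), distance = numeric(0))
  if (n_gt > 0L && n_rec > 0L) {
    D <- matrix(0, n_gt, n_rec)
    for (i in seq_len(n_gt))
      D[i, ] <- sqrt(colSums((t(rec$positions) - gt$positions[i, ])^2))
    ok <- which(D < delta, arr.ind = TRUE)
    if (nrow(ok) > 0L) {
      if (method == "greedy") {
        ord <- order(D[ok])
        used_gt <- rep(FALSE, n_gt)
        used_rec <- rep(FALSE, n_rec)
        sel <- list()
        for (r in ord) {
          i <- ok[r, 1L]; j <- ok[r, 2L]
          if (!used_gt[i] && !used_rec[j]) {
            used_gt[i] <- TRUE; used_rec[j] <- TRUE
            sel[[length(sel) + 1L]] <- c(i, j)
          }
        }
        if (length(sel) > 0L) {
          selm <- do.call(rbind, sel)
          pairs <- data.frame(gt = selm[, 1L], rec = selm[, 2L],
                              distance = D[selm])
        }
      } else {
        match_of <- max_bipartite_match(D < delta, n_gt, n_rec)
        sel <- which(match_of > 0L)
        pairs <- data.frame(gt = sel, rec = match_of[sel],
                            distance = D[cbind(sel, match_of[sel])])
      }
    }
  }
  structure(list(pairs = pairs, n_tp = nrow(pairs),
                 n_fp = n_rec - nrow(pairs), n_fn = n_gt - nrow(pairs),
                 delta = delta),
            class = "match_result")
}

# maximum-cardinality bipartite matching via augmenting paths on the
# adjacency matrix A (n_gt x n_rec logical); returns, per gt index, the
# matched rec index (0 = unmatched)
max_bipartite_match <- function(A, n_gt, n_rec) {
  match_rec <- integer(n_rec)   # rec -> gt
  try_augment <- function(i, seen) {
    for (j in which(A[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_rec[j] == 0L || Recall(match_rec[j], seen)) {
        match_rec[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(n_gt)) try_augment(i, rep(FALSE, n_rec))
  match_gt <- integer(n_gt)
  match_gt[match_rec[match_rec > 0L]] <- which(match_rec > 0L)
  match_gt
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (delta = %g)\n",
              x$n_tp, x$n_fp, x$n_fn, x$delta))
  invisible(x)
}

#' Jaccard detection index
#'
#' \eqn{Jac_\delta = \#TP / (\#TP + \#FP + \#FN) \in [0, 1]}; 1 iff the
#' reconstruction matches the ground truth one-to-one within the radius.
#' When both measures are empty the index is defined as 1 (nothing to
#' detect, nothing detected).
#'
#' @param match a [match_spikes()] result.
#' @return the index in `[0, 1]`.
#' @export
jaccard <- function(match) {
  tot <- match$n_tp + match$n_fp + match$n_fn
  if (tot == 0L) return(1)
  match$n_tp / tot
}

#' RMSE of matched positions
#'
#' Root mean square of the Euclidean position error over matched pairs
#' (for `d > 1` the norm of the position difference enters the square).
#'
#' @param match a [match_spikes()] result with at least one pair.
#' @param gt,rec the measures passed to [match_spikes()].
#' @return the RMSE (physical units); errors when there are no pairs.
#' @export
rmse_positions <- function(match, gt, rec) {
  if (match$n_tp == 0L) stop("position RMSE undefined without matched pairs")
  sqrt(mean(match$pairs$distance^2))
}

#' RMSE of matched amplitudes
#'
#' @inheritParams rmse_positions
#' @return root mean square of `a_rec - a_gt` over matched pairs.
#' @export
rmse_amplitudes <- function(match, gt, rec) {
  if (match$n_tp == 0L) stop("amplitude RMSE undefined without matched pairs")
  da <- rec$amplitudes[match$pairs$rec] - gt$amplitudes[match$pairs$gt]
  sqrt(mean(da^2))
}

#' One-call evaluation of a reconstruction
#'
#' @param gt,rec ground truth and reconstructed [dirac_measure()]s.
#' @param delta tolerance radius.
#' @return a one-row data frame with `tp`, `fp`, `fn`, `jaccard`, `rmse_x`,
#'   `rmse_a` (RMSEs are `NA` when no spikes matched).
#' @export
evaluate_spikes <- function(gt, rec, delta = 0.05) {
  mt <- match_spikes(gt, rec, delta)
  data.frame(
    tp = mt$n_tp, fp = mt$n_fp, fn = mt$n_fn, jaccard = jaccard(mt),
    rmse_x = if (mt$n_tp > 0L) rmse_positions(mt, gt, rec) else NA_real_,
    rmse_a = if (mt$n_tp > 0L) rmse_amplitudes(mt, gt, rec) else NA_real_)
}
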