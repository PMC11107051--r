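# Evaluation protocols: in-center five-fold group cross-validation and
# leave-one-center-out (LOCO) cross-center adaptation.

#' Build a data-partitioning plan
#'
#' For `"in_center_5fold"`, cases are grouped by `id` (all volumes of a case
#' stay together) and groups are assigned to folds at random under the seed;
#' every case appears in exactly one test fold. For `"cross_center_loco"`,
#' each center in turn is the (unlabeled) target domain and the remaining
#' centers form the labeled source domain.
#'
#' @param ids case identifiers (one per case).
#' @param centers center label per case.
#' @param protocol `"in_center_5fold"` or `"cross_center_loco"`.
#' @param n_folds number of folds for the in-center protocol.
#' @param seed fold-assignment seed.
#' @return An object of class `split_plan`: a data.frame with columns
#'   `id`, `center`, `fold`.
#' @export
split_plan <- function(ids, centers,
                       protocol = c("in_center_5fold", "cross_center_loco"),
                       n_folds = 5L, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(length(ids) == length(centers))
  if (protocol == "in_center_5fold") {
    groups <- unique(ids)
    stopifnot(length(groups) >= n_folds)
    gf <- with_seed(seed, {
      perm <- sample(as.character(groups))
      stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
    })
    fold <- unname(gf[as.character(ids)])
  } else {
    if (length(unique(centers)) < 2)
      stop("leave-one-center-out needs at least 2 centers")
    fold <- as.character(centers)
  }
  structure(data.frame(id = ids, center = centers, fold = fold,
                       stringsAsFactors = FALSE),
            protocol = protocol, class = c("split_plan", "data.frame"))
}

#' Run a full evaluation protocol
#'
#' In-center: one supervised training per fold on the other folds, evaluated
#' on the held-out fold. Cross-center LOCO: for each center, adversarial
#' adaptation with the remaining centers as labeled source and the held-out
#' center as unlabeled target (its masks are stripped before training and
#' used only for evaluation).
#'
#' @param plan a [split_plan()].
#' @param cfg a [train_config()].
#' @param data list of cases `list(volume, mask, id, center)` in the order
#'   of the plan rows.
#' @param verbose forwarded to the trainers.
#' @return Named list (one element per fold/center) of lists with `report`
#'   (a [metrics_report()]) and `checkpoint`.
#' @export
run_protocol <- function(plan, cfg, data, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"), nrow(plan) == length(data))
  protocol <- attr(plan, "protocol")
  folds <- sort(unique(plan$fold))
  out <- lapply(folds, function(f) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    if (length(test_idx) < 1 || length(train_idx) < 1)
      stop("fold ", f, " has an empty train or test set")
    ck <- if (protocol == "in_center_5fold") {
      train_supervised(cfg, data[train_idx], verbose)
    } else {
      train_hcada(cfg, data[train_idx], unlabeled_set(data[test_idx]), verbose)
    }
    rep <- evaluate_checkpoint(ck, data[test_idx], ids = plan$id[test_idx])
    list(report = rep, checkpoint = ck)
  })
  names(out) <- paste0(if (protocol == "in_center_5fold") "fold_" else "target_",
                       folds)
  out
}
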