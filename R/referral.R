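#' Vectorize a dynamic network state
#'
#' Maps the cumulative network state of a trajectory at one step to the
#' binary feature vector used by the referral model: `n` node-existence
#' indicators in the order of `node_order`, followed by the
#' `n (n - 1) / 2` upper-triangle edge indicators in row-major (i < j)
#' order, indices aligned to the complete interaction network.
#'
#' @param state A list with elements `nodes` (character vector of nodes
#'   present) and `edges` (two-column character matrix of edges present).
#' @param node_order Character vector fixing the node universe and order.
#' @return A named 0/1 integer vector of length
#'   `length(node_order) * (length(node_order) + 1) / 2`.
#' @examples
#' vectorize_state(list(nodes = c("a", "b"),
#'                      edges = rbind(c("a", "b"))),
#'                 node_order = c("a", "b", "c"))
#' @export
vectorize_state <- function(state, node_order) {
  n <- length(node_order)
  unknown <- setdiff(state$nodes, node_order)
  if (length(unknown) > 0) {
    stop("state mentions node(s) outside the universe: ",
         paste(unknown, collapse = ", "))
  }
  v <- as.integer(node_order %in% state$nodes)
  names(v) <- node_order
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  edge_names <- paste(node_order[ut[, 1]], node_order[ut[, 2]], sep = "|")
  e <- integer(nrow(ut))
  names(e) <- edge_names
  edges <- state$edges
  if (!is.null(edges) && nrow(edges) > 0) {
    labs <- apply(edges, 1, function(p) edge_label(p[1], p[2]))
    # edge_label sorts endpoints; universe edge names use node_order order
    canon <- paste(pmin(match(edges[, 1], node_order),
                        match(edges[, 2], node_order)),
                   pmax(match(edges[, 1], node_order),
                        match(edges[, 2], node_order)))
    universe_keys <- paste(ut[, 1], ut[, 2])
    hit <- match(canon, universe_keys)
    if (anyNA(hit)) stop("state edge outside the universe: ",
                         paste(labs[is.na(hit)], collapse = ", "))
    e[hit] <- 1L
  }
  c(v, e)
}

#' Dynamic network states labelled at the referral point
#'
#' For each patient with a referral action, iteratively grows a cumulative
#' clinical interaction network along the trajectory: state t contains the
#' nodes and (policy-filtered) edges of interactions 1..t. States run from
#' the first interaction up to and including the interaction that
#' precipitated the referral; that final state is labelled 1 and all
#' earlier states 0, so each referred patient contributes exactly one
#' positive label. Later interactions are discarded. Patients without the
#' referral action are excluded with a message.
#'
#' @param log An `event_log` (MHOA-only patients already excluded).
#' @param referral_action Action string marking the referral (default
#'   `"Referral to Emergency Psychiatry"`).
#' @param node_order Node universe; defaults to the sorted node set of
#'   [build_interaction_network()] on `log`.
#' @return An object of class `labeled_states`: a list with `x` (binary
#'   state matrix, one row per state), `y` (0/1 labels), `patient`, `step`,
#'   `node_order` and `feature_names`.
#' @export
build_dynamic_states <- function(log,
                                 referral_action = "Referral to Emergency Psychiatry",
                                 node_order = NULL) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  if (is.null(node_order)) {
    net <- build_interaction_network(log)
    node_order <- sort(igraph::V(net)$name)
  }
  patients <- unique(rec$patient)
  referred <- patients[vapply(patients, function(p) {
    any(rec$action[rec$patient == p] == referral_action)
  }, logical(1))]
  dropped <- setdiff(patients, referred)
  if (length(dropped) > 0) {
    message(length(dropped), " patient(s) without action \"", referral_action,
            "\" excluded from the referral dataset")
  }
  if (length(referred) == 0) stop("no patient carries the referral action")
  rows <- list()
  y <- integer(0)
  pat <- character(0)
  step <- integer(0)
  for (p in referred) {
    r <- rec[rec$patient == p, , drop = FALSE]
    ref_at <- which(r$action == referral_action)[1]
    nodes <- character(0)
    edges <- matrix(character(0), ncol = 2)
    for (t in seq_len(ref_at)) {
      nodes <- union(nodes, c(r$agents[[t]], r$info_systems[[t]]))
      edges <- unique(rbind(edges,
                            edges_from_interaction(r$agents[[t]],
                                                   r$info_systems[[t]],
                                                   log$catalog)))
      rows[[length(rows) + 1]] <-
        vectorize_state(list(nodes = nodes, edges = edges), node_order)
      y <- c(y, if (t == ref_at) 1L else 0L)
      pat <- c(pat, p)
      step <- c(step, t)
    }
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  structure(list(x = x, y = y, patient = pat, step = step,
                 node_order = node_order,
                 feature_names = colnames(x)),
            class = "labeled_states")
}

#' @export
print.labeled_states <- function(x, ...) {
  cat("Labelled dynamic network states:", nrow(x$x), "states from",
      length(unique(x$patient)), "patients;",
      sum(x$y), "positive (referral) labels;",
      ncol(x$x), "features\n")
  invisible(x)
}

#' Grouped resampling splits
#'
#' Randomly re-sampled train/test splits that assign whole patients to one
#' side, so no trajectory is split between training and test. Splits whose
#' test (or training) rows lack one of the two classes are rejected and
#' redrawn, since balanced accuracy would be undefined. Randomness comes
#' from R's global RNG.
#'
#' @param dataset A [build_dynamic_states()] result.
#' @param n_splits Number of splits (default 10000).
#' @param test_fraction Fraction of patients assigned to the test side.
#' @return A list of splits, each a list with integer row indices `train`
#'   and `test`; the number of rejected draws is attached as attribute
#'   `n_rejected`.
#' @export
grouped_resample_splits <- function(dataset, n_splits = 10000,
                                    test_fraction = 0.2) {
  stopifnot(inherits(dataset, "labeled_states"))
  patients <- unique(dataset$patient)
  n_test <- max(1L, round(test_fraction * length(patients)))
  if (n_test >= length(patients)) stop("too few patients to split")
  splits <- vector("list", n_splits)
  rejected <- 0L
  for (k in seq_len(n_splits)) {
    repeat {
      test_patients <- sample(patients, n_test)
      test <- which(dataset$patient %in% test_patients)
      train <- which(!dataset$patient %in% test_patients)
      if (length(unique(dataset$y[test])) == 2 &&
          length(unique(dataset$y[train])) == 2) break
      rejected <- rejected + 1L
      if (rejected > 100 * n_splits + 100) {
        stop("could not draw class-complete splits; too few ",
             "negative or positive states")
      }
    }
    splits[[k]] <- list(train = train, test = test)
  }
  attr(splits, "n_rejected") <- rejected
  splits
}

#' Random oversampling of the minority class
#'
#' Duplicates whole minority-class rows, sampled with replacement, until
#' both classes have equal counts. Applied to each training split before
#' fitting to counter the class imbalance of referral labels.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @return A list with the augmented `x` and `y`.
#' @export
oversample_minority <- function(x, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  pool <- which(y == minority)
  extra <- sample(pool, need, replace = TRUE)
  list(x = rbind(x, x[extra, , drop = FALSE]), y = c(y, y[extra]))
}

#' Permutation feature importance for the referral model
#'
#' For each resampling split: oversample the training rows, fit the
#' Bernoulli naive Bayes model, record the baseline balanced accuracy on
#' the test rows, then for each feature permute that feature's column
#' within the test partition once and record the drop in balanced accuracy
#' (baseline minus permuted score; negative values are reported as-is).
#' Per-feature means and empirical 95\% intervals are taken over splits,
#' and the distribution of baseline scores is returned.
#'
#' @param dataset A [build_dynamic_states()] result.
#' @param n_splits Number of grouped resampling splits (default 10000).
#' @param test_fraction Passed to [grouped_resample_splits()].
#' @param seed Optional seed for the whole procedure.
#' @return An object of class `importance_report`: a list with `importance`
#'   (data frame: feature, mean_importance, lower95, upper95), `baseline`
#'   (per-split balanced accuracies), `mean_balanced_accuracy` and
#'   `n_splits`.
#' @export
permutation_importance <- function(dataset, n_splits = 10000,
                                   test_fraction = 0.2, seed = NULL) {
  stopifnot(inherits(dataset, "labeled_states"))
  if (!is.null(seed)) set.seed(seed)
  splits <- grouped_resample_splits(dataset, n_splits, test_fraction)
  nf <- ncol(dataset$x)
  imp <- matrix(NA_real_, nf, n_splits,
                dimnames = list(colnames(dataset$x), NULL))
  baseline <- numeric(n_splits)
  bal <- function(pred, y) {
    pos <- y == 1L
    (mean(pred[pos] == 1L) + mean(pred[!pos] == 0L)) / 2
  }
  for (k in seq_len(n_splits)) {
    sp <- splits[[k]]
    tr <- oversample_minority(dataset$x[sp$train, , drop = FALSE],
                              dataset$y[sp$train])
    fit <- fit_bernoulli_nb(tr$x, tr$y)
    xt <- dataset$x[sp$test, , drop = FALSE]
    yt <- dataset$y[sp$test]
    margin <- nb_margin(fit, xt)
    baseline[k] <- bal(as.integer(margin > 0), yt)
    # per-feature margin weights: permuting column f shifts the margin by
    # (x_perm - x) * w_f, so no refit or full re-scoring is needed
    w <- (log(fit$prob1[, "1"]) - log(1 - fit$prob1[, "1"])) -
         (log(fit$prob1[, "0"]) - log(1 - fit$prob1[, "0"]))
    nt <- length(yt)
    for (f in seq_len(nf)) {
      xf <- xt[, f]
      perm <- xf[sample.int(nt)]
      m2 <- margin + (perm - xf) * w[f]
      imp[f, k] <- baseline[k] - bal(as.integer(m2 > 0), yt)
    }
  }
  importance <- data.frame(
    feature = rownames(imp),
    mean_importance = rowMeans(imp),
    lower95 = apply(imp, 1, quantile, 0.025),
    upper95 = apply(imp, 1, quantile, 0.975),
    stringsAsFactors = FALSE
  )
  importance <- importance[order(-importance$mean_importance), ]
  rownames(importance) <- NULL
  structure(list(importance = importance, baseline = baseline,
                 mean_balanced_accuracy = mean(baseline),
                 n_splits = n_splits,
                 n_rejected_splits = attr(splits, "n_rejected")),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, n = 10, ...) {
  cat(sprintf(
    "Referral model over %d grouped splits: mean balanced accuracy %.3f\n",
    x$n_splits, x$mean_balanced_accuracy))
  cat("Top features by mean permutation importance:\n")
  print(head(x$importance, n), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export an importance report as CSV
#'
#' Columns: feature (node name or `"nodeA|nodeB"`), mean importance,
#' empirical 95\% bounds and the number of splits.
#'
#' @param report An `importance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(report, path) {
  out <- report$importance
  out$n_splits <- report$n_splits
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
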