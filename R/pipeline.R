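#' Stratified train/test split of a labelled spectra set
#'
#' Splits each class at the requested ratio (rounded per class), sampling
#' without replacement. With the defaults of a 6 x 67 set and ratio 2:1 this
#' yields 270 training and 132 test spectra (45/22 per class).
#'
#' @param x a labelled [spectra_set()].
#' @param ratio length-2 numeric `c(train, test)` ratio (default `c(2, 1)`).
#' @param seed optional integer seed for the within-class sampling.
#' @return List with `spectra_set` components `train` and `test`; the two
#'   are disjoint and their union is `x`.
#' @export
split_train_test <- function(x, ratio = c(2, 1), seed = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(x$labels)) stop("split requires a labelled spectra set")
  if (length(ratio) != 2 || any(ratio < 0) || sum(ratio) <= 0) {
    stop("'ratio' must be two non-negative numbers")
  }
  if (!is.null(seed)) set.seed(seed)
  frac <- ratio[1] / sum(ratio)
  train_idx <- integer(0)
  for (cl in sort(unique(x$labels))) {
    idx <- which(x$labels == cl)
    n_tr <- round(length(idx) * frac)
    if (n_tr < 1 || n_tr >= length(idx)) {
      stop(sprintf("ratio leaves class %d without train or test samples", cl))
    }
    train_idx <- c(train_idx, sort(sample(idx, n_tr)))
  }
  train_idx <- sort(train_idx)
  list(train = x[train_idx], test = x[-train_idx])
}

#' Chained initialization of the fuzzy clusterers
#'
#' The protocol initializes FCM with the first sample of each class, in
#' class order, of the set being clustered; FCM is run to convergence and
#' its converged centers serve as the initial centers of both KHM and GK.
#' Because each seed center comes from a distinct known class, cluster `i`
#' corresponds to class `i` under this initialization (the basis of the
#' fixed-order cluster-to-class matching).
#'
#' @param scores matrix of reduced-dimension samples (e.g. OLDA scores).
#' @param labels class labels of `scores`; all of `1..n_clusters` must occur.
#' @param params a [fuzzy_params()].
#' @return List with `fcm_init` (the seed centers, one per class),
#'   `fcm` (the converged FCM `fuzzy_partition`), and `khm_init` / `gk_init`
#'   (both the converged FCM centers).
#' @export
chain_initialize <- function(scores, labels, params = fuzzy_params()) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  stopifnot(nrow(scores) == length(labels))
  nc <- params$n_clusters
  present <- sort(unique(labels))
  if (!all(seq_len(nc) %in% present)) {
    stop(sprintf("all classes 1..%d must be represented to seed the centers", nc))
  }
  first_idx <- vapply(seq_len(nc), function(cl) which(labels == cl)[1], 1L)
  fcm_init <- scores[first_idx, , drop = FALSE]
  fcm <- fuzzy_cluster(scores, fcm_init, method = "fcm", params = params)
  list(fcm_init = fcm_init, fcm = fcm,
       khm_init = fcm$V, gk_init = fcm$V)
}

# all permutations of 1..k (k! rows); exact optimal matching is exhaustive
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  dimnames(out) <- NULL
  out
}

#' Match clusters to classes and count misclassifications
#'
#' @param pred integer cluster assignments, `1..k`.
#' @param truth integer class labels, `1..k`.
#' @param mode `"fixed"` maps cluster `i` to class `i` (valid when the
#'   clusterer was seeded with one sample per class in class order);
#'   `"optimal"` finds the one-to-one cluster-to-class assignment minimizing
#'   the misclassification count by exhaustive search over permutations
#'   (exact; `k <= 8`).
#' @return List with `mapping` (class assigned to each cluster),
#'   `misclassification` count, `accuracy` in percent, and the k x k
#'   `confusion` matrix (rows true classes, columns predicted classes after
#'   mapping).
#' @export
match_clusters <- function(pred, truth, mode = c("fixed", "optimal")) {
  mode <- match.arg(mode)
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(length(pred) == length(truth))
  k <- max(pred, truth)
  counts <- table(factor(pred, levels = seq_len(k)),
                  factor(truth, levels = seq_len(k)))  # cluster x class
  if (mode == "fixed") {
    mapping <- seq_len(k)
  } else {
    if (k > 8) stop("exhaustive optimal matching supports up to 8 clusters")
    perms <- permutations(k)
    hits <- apply(perms, 1, function(pm) {
      sum(counts[cbind(seq_len(k), pm)])
    })
    mapping <- as.integer(perms[which.max(hits), ])
  }
  mapped <- mapping[pred]
  mis <- sum(mapped != truth)
  confusion <- table(true = factor(truth, levels = seq_len(k)),
                     predicted = factor(mapped, levels = seq_len(k)))
  list(mapping = mapping, misclassification = mis,
       accuracy = 100 * (length(truth) - mis) / length(truth),
       confusion = unclass(confusion))
}

#' Run the full spectra-to-storage-class protocol
#'
#' Orchestrates the study pipeline on a labelled spectra set: stratified
#' train/test split, optional multiplicative scatter correction (reference
#' fitted on the chosen scope, training split by default), OLDA fitted on
#' the training split, projection of the clustered set, chained
#' initialization (FCM seeded one-sample-per-class, KHM and GK from the
#' converged FCM centers), hard assignment by maximum membership, and
#' cluster-to-class matching.
#'
#' @param dataset a labelled [spectra_set()] (e.g. from
#'   [simulate_spectra()]).
#' @param preprocessing `"msc"` or `"none"`.
#' @param n_components OLDA components (default 5 for 6 classes).
#' @param algorithms subset of `c("fcm", "khm", "gk")` to report. FCM is
#'   always fitted (it anchors the chained initialization) but reported only
#'   if requested.
#' @param split_ratio train:test ratio, default `c(2, 1)`.
#' @param split_seed seed for the stratified split.
#' @param cluster_params a [fuzzy_params()].
#' @param matching `"fixed"` or `"optimal"` (see [match_clusters()]).
#' @param cluster_on `"test"` (default: cluster the projected test split) or
#'   `"all"` (cluster train and test jointly).
#' @param msc_scope fit the MSC reference on `"train"` (default, no leakage)
#'   or `"all"` spectra.
#' @return An object of class `eval_report`: list with `results` (per
#'   algorithm: `n_iter`, `converged`, `misclassification`, `accuracy`,
#'   `mapping`, `confusion`), `settings`, `olda` (the fitted model), and
#'   `detail` (scores, labels and partitions of the clustered set).
#' @examples
#' \donttest{
#' s <- simulate_spectra(well_separated_config(seed = 7))
#' rep <- run_pipeline(s, split_seed = 7)
#' rep
#' }
#' @export
run_pipeline <- function(dataset,
                         preprocessing = c("msc", "none"),
                         n_components = 5,
                         algorithms = c("fcm", "khm", "gk"),
                         split_ratio = c(2, 1),
                         split_seed = NULL,
                         cluster_params = fuzzy_params(),
                         matching = c("fixed", "optimal"),
                         cluster_on = c("test", "all"),
                         msc_scope = c("train", "all")) {
  preprocessing <- match.arg(preprocessing)
  matching <- match.arg(matching)
  cluster_on <- match.arg(cluster_on)
  msc_scope <- match.arg(msc_scope)
  algorithms <- match.arg(algorithms, c("fcm", "khm", "gk"),
                          several.ok = TRUE)
  stopifnot(inherits(dataset, "spectra_set"), !is.null(dataset$labels))

  sp <- split_train_test(dataset, ratio = split_ratio, seed = split_seed)
  train <- sp$train; test <- sp$test

  if (preprocessing == "msc") {
    ref <- msc_reference(if (msc_scope == "train") train else dataset)
    train <- msc(train, reference = ref)$spectra
    test <- msc(test, reference = ref)$spectra
  }

  model <- olda(train$absorbance, train$labels, n_components = n_components)
  if (cluster_on == "test") {
    cl_scores <- predict(model, test)
    cl_labels <- test$labels
  } else {
    cl_scores <- rbind(predict(model, train), predict(model, test))
    cl_labels <- c(train$labels, test$labels)
  }

  init <- chain_initialize(cl_scores, cl_labels, params = cluster_params)
  partitions <- list(fcm = init$fcm)
  if ("khm" %in% algorithms) {
    partitions$khm <- fuzzy_cluster(cl_scores, init$khm_init, "khm",
                                    params = cluster_params)
  }
  if ("gk" %in% algorithms) {
    partitions$gk <- fuzzy_cluster(cl_scores, init$gk_init, "gk",
                                   params = cluster_params)
  }

  results <- list()
  for (alg in algorithms) {
    part <- partitions[[alg]]
    mt <- match_clusters(assign_labels(part), cl_labels, mode = matching)
    results[[alg]] <- list(n_iter = part$n_iter,
                           converged = part$converged,
                           misclassification = mt$misclassification,
                           accuracy = mt$accuracy,
                           mapping = mt$mapping,
                           confusion = mt$confusion)
  }

  structure(
    list(results = results,
         settings = list(preprocessing = preprocessing,
                         n_components = model$n_components,
                         algorithms = algorithms,
                         split_ratio = split_ratio,
                         split_seed = split_seed,
                         matching = matching,
                         cluster_on = cluster_on,
                         msc_scope = msc_scope,
                         n_train = n_spectra(sp$train),
                         n_test = n_spectra(sp$test),
                         n_clustered = nrow(cl_scores),
                         cluster_params = cluster_params),
         olda = model,
         detail = list(scores = cl_scores, labels = cl_labels,
                       partitions = partitions)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Spectra classification pipeline (%s preprocessing, %d OLDA components)\n",
              s$preprocessing, s$n_components))
  cat(sprintf("  split %d train / %d test; clustering %d samples (%s), %s matching\n",
              s$n_train, s$n_test, s$n_clustered, s$cluster_on, s$matching))
  tab <- do.call(rbind, lapply(names(x$results), function(alg) {
    r <- x$results[[alg]]
    data.frame(Method = toupper(alg), Iterations = r$n_iter,
               Misclassified = r$misclassification,
               Accuracy = sprintf("%.2f%%", r$accuracy))
  }))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  for (alg in names(object$results)) {
    cat("\nConfusion (", toupper(alg), "), rows = true class:\n", sep = "")
    print(object$results[[alg]]$confusion)
  }
  invisible(object)
}
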