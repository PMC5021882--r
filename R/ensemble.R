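#' Cross-validation report for one feature group
#'
#' Holds per-classifier cross-validated Q accuracies for one feature group
#' and the selected (argmax) entry. Normally produced by
#' [cross_validate_roster()]; the constructor is exported so reports from
#' other sources can be fed through the same selection rule.
#'
#' @param group_name feature group the report refers to.
#' @param classifiers character vector of roster names, in roster order.
#' @param accuracies matching vector of cross-validated accuracies
#'   (fractions in \[0, 1\] or percentages; only the ordering matters for
#'   selection).
#' @return an object of class `cv_report` with fields `group_name`,
#'   `entries` (data.frame `classifier`, `cv_accuracy`) and `selected`.
#' @export
cv_report <- function(group_name, classifiers, accuracies) {
  if (length(classifiers) != length(accuracies) || !length(classifiers)) {
    stop_("'classifiers' and 'accuracies' must be nonempty and equal length")
  }
  entries <- data.frame(classifier = as.character(classifiers),
                        cv_accuracy = as.numeric(accuracies),
                        stringsAsFactors = FALSE)
  structure(list(group_name = group_name, entries = entries,
                 selected = select_classifier(entries)),
            class = "cv_report")
}

#' Selection rule: highest cross-validated accuracy wins
#'
#' Strict argmax over the report entries; ties are broken toward the
#' earliest roster position.
#'
#' @param report a [cv_report()] or its `entries` data.frame.
#' @return the selected classifier name.
#' @export
select_classifier <- function(report) {
  entries <- if (inherits(report, "cv_report")) report$entries else report
  entries$classifier[[which.max(entries$cv_accuracy)]]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (selected: %s)\n", x$group_name, x$selected))
  e <- x$entries
  e$classifier <- ifelse(e$classifier == x$selected,
                         paste0(e$classifier, " *"), e$classifier)
  print(e, row.names = FALSE)
  invisible(x)
}

check_labels <- function(features, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(rownames(features), names(labels))
    if (length(miss)) {
      stop_("unlabelled sample(s): ", paste(head(miss, 5), collapse = ", "))
    }
    labels <- labels[rownames(features)]
  } else if (length(labels) != nrow(features)) {
    stop_("'labels' length does not match the number of samples")
  }
  as.character(labels)
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into folds, so every fold sees every class when class sizes
# allow it
stratified_folds <- function(labels, k_folds, seed) {
  classes <- unique(labels)
  if (length(classes) < 2L) stop_("need at least two classes")
  min_class <- min(table(labels))
  if (min_class < 2L) stop_("every class needs at least two samples")
  k <- k_folds
  if (min_class < k_folds) {
    k <- max(2L, min_class)
    warning("reducing folds from ", k_folds, " to ", k,
            " (smallest class has ", min_class, " members)", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  list(fold = fold, k = k)
}

#' Cross-validate a classifier roster on one feature group
#'
#' Runs a stratified, seeded k-fold cross-validation and scores every
#' roster entry on the identical splits by pooled out-of-fold Q accuracy
#' (total correct over total tested). The entry with the highest accuracy
#' is selected; ties go to the earlier roster position.
#'
#' @param features a [feature_matrix()].
#' @param labels class labels: named by sample id, or positional.
#' @param roster list of [classifier_spec()] objects (default
#'   [default_roster()]).
#' @param k_folds folds (default 5); reduced with a warning when the
#'   smallest class has fewer members, never below 2.
#' @param seed integer seed controlling the split and each model fit.
#' @return a [cv_report()].
#' @export
cross_validate_roster <- function(features, labels, roster = default_roster(),
                                  k_folds = 5, seed = 1) {
  if (!length(roster)) stop_("empty classifier roster")
  labels <- check_labels(features, labels)
  class_labels <- sort(unique(labels))
  y <- factor(labels, levels = class_labels)
  x <- unclass(features)
  fo <- stratified_folds(labels, k_folds, seed)
  acc <- numeric(length(roster))
  nm <- vapply(roster, `[[`, "", "name")
  for (si in seq_along(roster)) {
    spec <- roster[[si]]
    correct <- 0L
    for (f in seq_len(fo$k)) {
      tr <- fo$fold != f
      model <- with_seed(seed + 131L * si + f,
                         spec$fit(x[tr, , drop = FALSE], y[tr]))
      p <- spec$predict_prob(model, x[!tr, , drop = FALSE], class_labels)
      pred <- class_labels[apply(p, 1L, which.max)]
      correct <- correct + sum(pred == labels[!tr])
    }
    acc[[si]] <- correct / length(labels)
  }
  cv_report(group_name = group_name(features), classifiers = nm,
            accuracies = acc)
}

#' Train the multi-view ensemble
#'
#' For each feature group: cross-validate the roster
#' ([cross_validate_roster()]), select the winning classifier, and refit it
#' on the full training matrix. The result carries one fitted model per
#' group plus the audit trail of CV reports.
#'
#' @param feature_groups named list of [feature_matrix()] objects sharing
#'   identical sample ids and ordering.
#' @param labels class labels (named by sample id, or positional in the
#'   shared sample order).
#' @inheritParams cross_validate_roster
#' @return an object of class `profold_ensemble` with fields
#'   `class_labels`, `groups_used`, `per_group` (selected spec + fitted
#'   model per group), `cv_reports` and `seed`.
#' @export
train_ensemble <- function(feature_groups, labels, roster = default_roster(),
                           k_folds = 5, seed = 1) {
  if (!length(feature_groups)) stop_("need at least one feature group")
  if (is.null(names(feature_groups)) || any(!nzchar(names(feature_groups)))) {
    stop_("'feature_groups' must be a named list")
  }
  ref_ids <- rownames(feature_groups[[1L]])
  for (g in names(feature_groups)) {
    if (!identical(rownames(feature_groups[[g]]), ref_ids)) {
      stop_("sample ids of group '", g, "' do not match group '",
            names(feature_groups)[[1L]], "'")
    }
  }
  labels <- check_labels(feature_groups[[1L]], labels)
  class_labels <- sort(unique(labels))
  y <- factor(labels, levels = class_labels)
  per_group <- list()
  cv_reports <- list()
  for (gi in seq_along(feature_groups)) {
    g <- names(feature_groups)[[gi]]
    rep_ <- cross_validate_roster(feature_groups[[g]], labels, roster,
                                  k_folds = k_folds, seed = seed)
    spec <- roster[[match(rep_$selected,
                          vapply(roster, `[[`, "", "name"))]]
    model <- with_seed(seed + 7919L * gi,
                       spec$fit(unclass(feature_groups[[g]]), y))
    per_group[[g]] <- list(spec = spec, model = model,
                           classifier = spec$name,
                           n_features = ncol(feature_groups[[g]]))
    cv_reports[[g]] <- rep_
  }
  structure(list(class_labels = class_labels,
                 groups_used = names(feature_groups),
                 per_group = per_group, cv_reports = cv_reports,
                 seed = seed),
            class = "profold_ensemble")
}

#' @export
print.profold_ensemble <- function(x, ...) {
  cat(sprintf("<profold_ensemble> %d classes, groups: %s\n",
              length(x$class_labels), paste(x$groups_used, collapse = ", ")))
  for (g in x$groups_used) {
    cat(sprintf("  %-8s -> %s\n", g, x$per_group[[g]]$classifier))
  }
  invisible(x)
}

#' Predict fold classes by probability averaging
#'
#' Each per-group model produces a class-probability row per sample; the
#' ensemble prediction is the class with the highest across-group average
#' probability (ties go to the lowest class index).
#'
#' @param object a trained [train_ensemble()] result.
#' @param feature_groups named list of [feature_matrix()] objects covering
#'   `object$groups_used` (identical sample ids across groups).
#' @param allow_missing_groups permit prediction from a subset of the
#'   trained groups (the average then runs over the groups present);
#'   default FALSE.
#' @param ... unused.
#' @return a list with `labels` (named character vector), `prob` (n x k
#'   averaged probability matrix) and `per_group_prob`.
#' @export
predict.profold_ensemble <- function(object, feature_groups,
                                     allow_missing_groups = FALSE, ...) {
  missing <- setdiff(object$groups_used, names(feature_groups))
  if (length(missing) && !allow_missing_groups) {
    stop_("missing feature group(s): ", paste(missing, collapse = ", "))
  }
  use <- intersect(object$groups_used, names(feature_groups))
  if (!length(use)) stop_("no usable feature groups supplied")
  ref_ids <- rownames(feature_groups[[use[[1L]]]])
  per_group_prob <- list()
  for (g in use) {
    fm <- feature_groups[[g]]
    if (!identical(rownames(fm), ref_ids)) {
      stop_("sample ids of group '", g, "' do not match")
    }
    if (ncol(fm) != object$per_group[[g]]$n_features) {
      stop_("group '", g, "' has ", ncol(fm), " features; the model was ",
            "trained with ", object$per_group[[g]]$n_features)
    }
    entry <- object$per_group[[g]]
    p <- entry$spec$predict_prob(entry$model, unclass(fm),
                                 object$class_labels)
    rownames(p) <- ref_ids
    per_group_prob[[g]] <- p
  }
  avg <- Reduce(`+`, per_group_prob) / length(per_group_prob)
  labels <- object$class_labels[apply(avg, 1L, which.max)]
  list(labels = setNames(labels, ref_ids), prob = avg,
       per_group_prob = per_group_prob)
}

#' Overall and per-class Q accuracy
#'
#' Q = C / N where N is the number of test proteins and C the number
#' classified correctly; per class i, accuracy is c_i / n_i.
#'
#' @param y_true true class labels.
#' @param y_pred predicted class labels (same length).
#' @param class_labels optional fixed class ordering; defaults to the
#'   sorted union of `y_true` and `y_pred`.
#' @return an object of class `evaluation_result`: fields `class_labels`,
#'   `n`, `c`, `per_class_accuracy`, `N`, `C`, `Q`, `k`.
#' @examples
#' q_accuracy(c("a", "a", "b"), c("a", "b", "b"))$Q
#' @export
q_accuracy <- function(y_true, y_pred, class_labels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop_("'y_true' and 'y_pred' must be nonempty and equal length")
  }
  if (is.null(class_labels)) class_labels <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), class_labels)
  if (length(unknown)) {
    stop_("label(s) not in class_labels: ", paste(unknown, collapse = ", "))
  }
  n <- as.numeric(table(factor(y_true, levels = class_labels)))
  c_ <- as.numeric(table(factor(y_true[y_true == y_pred],
                                levels = class_labels)))
  structure(list(class_labels = class_labels,
                 n = setNames(n, class_labels),
                 c = setNames(c_, class_labels),
                 per_class_accuracy = setNames(ifelse(n > 0, c_ / n, NA_real_),
                                               class_labels),
                 N = sum(n), C = sum(c_), Q = sum(c_) / sum(n),
                 k = length(class_labels)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> Q = %.4f (%d/%d over %d classes)\n",
              x$Q, x$C, x$N, x$k))
  print(data.frame(class = x$class_labels, n = x$n, correct = x$c,
                   accuracy = round(x$per_class_accuracy, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Save / load a trained ensemble bundle
#'
#' `save_ensemble` writes a directory holding a JSON manifest (class
#' labels, groups, selected classifier names, seed, package version) and
#' one serialized model per feature group. `load_ensemble` restores the
#' ensemble, verifying that every group named in the manifest has its
#' model artifact.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param dir bundle directory (created if needed).
#' @return `save_ensemble`: `dir` invisibly; `load_ensemble`: a
#'   `profold_ensemble`.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "profold_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "profoldr-ensemble",
    version = as.character(utils::packageVersion("profoldr")),
    class_labels = ensemble$class_labels,
    groups_used = ensemble$groups_used,
    selected = lapply(ensemble$per_group, `[[`, "classifier"),
    seed = ensemble$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (g in ensemble$groups_used) {
    saveRDS(ensemble$per_group[[g]], file.path(dir, paste0("model_", g, ".rds")))
  }
  saveRDS(ensemble$cv_reports, file.path(dir, "cv_reports.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "profoldr-ensemble")) {
    stop_("not an ensemble bundle: ", dir)
  }
  per_group <- list()
  for (g in manifest$groups_used) {
    p <- file.path(dir, paste0("model_", g, ".rds"))
    if (!file.exists(p)) stop_("model artifact missing for group '", g, "'")
    per_group[[g]] <- readRDS(p)
    if (!identical(per_group[[g]]$classifier, manifest$selected[[g]])) {
      stop_("manifest/model mismatch for group '", g, "'")
    }
  }
  cv_path <- file.path(dir, "cv_reports.rds")
  cv_reports <- if (file.exists(cv_path)) readRDS(cv_path) else list()
  structure(list(class_labels = manifest$class_labels,
                 groups_used = manifest$groups_used,
                 per_group = per_group, cv_reports = cv_reports,
                 seed = manifest$seed),
            class = "profold_ensemble")
}

#' Concatenate feature groups into one wide matrix
#'
#' Joins the per-group blocks column-wise over the shared sample ids.
#' Mainly a comparison mode: training a single roster member on the
#' concatenation is the conventional alternative to per-group selection
#' plus probability averaging.
#'
#' @param feature_groups named list of [feature_matrix()] objects with
#'   identical sample ids.
#' @return a [feature_matrix()] with group name `"concat"`.
#' @export
concat_feature_groups <- function(feature_groups) {
  ref_ids <- rownames(feature_groups[[1L]])
  for (g in names(feature_groups)) {
    if (!identical(rownames(feature_groups[[g]]), ref_ids)) {
      stop_("sample ids of group '", g, "' do not match")
    }
  }
  feature_matrix(do.call(cbind, lapply(feature_groups, unclass)),
                 group_name = "concat")
}
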