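#' Define a base classifier for the roster
#'
#' A classifier spec couples a unique roster name with a training function
#' and a probability-prediction function. The ensemble machinery is
#' agnostic to what sits behind the two functions, so rosters are
#' configuration: swap, drop or add entries freely.
#'
#' @param name unique roster identifier.
#' @param fit `function(x, y)` taking a numeric matrix and a factor (levels
#'   = the fixed class ordering) and returning a fitted model object.
#' @param predict_prob `function(model, x, class_labels)` returning an
#'   n x k matrix of class probabilities with columns in `class_labels`
#'   order. Rows are renormalized defensively by the caller.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, fit, predict_prob) {
  if (!is_string(name) || !nzchar(name)) stop_("'name' must be a nonempty string")
  stopifnot(is.function(fit), is.function(predict_prob))
  structure(list(name = name, fit = fit, predict_prob = predict_prob),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s\n", x$name))
  invisible(x)
}

# reorder/complete a probability matrix to the fixed class ordering and
# renormalize rows to sum to 1 (uniform fallback for degenerate rows)
align_probabilities <- function(p, class_labels) {
  p <- as.matrix(p)
  out <- matrix(0, nrow = nrow(p), ncol = length(class_labels),
                dimnames = list(rownames(p), class_labels))
  common <- intersect(colnames(p), class_labels)
  out[, common] <- p[, common, drop = FALSE]
  out[!is.finite(out)] <- 0
  rs <- rowSums(out)
  bad <- rs <= 0
  if (any(bad)) out[bad, ] <- 1 / length(class_labels)
  rs[bad] <- 1
  out / rs
}

# drop zero-variance columns (lda and multinom choke on them); the kept
# column set is stored with the model so prediction sees the same space
drop_constant <- function(x) {
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  if (!any(keep)) keep[1L] <- TRUE
  which(keep)
}

#' Built-in classifier roster
#'
#' Six base classifiers spanning the major model families used for fold
#' recognition (tree ensembles, kernel SVM, multinomial logistic,
#' naive Bayes, linear discriminant, decision tree). These are pragmatic
#' analogues of the commonly used WEKA learners, not clones of them;
#' hyperparameters are fixed here and any entry can be replaced via
#' [classifier_spec()].
#'
#' @param ntree trees for the random forest (default 200).
#' @return named list of [classifier_spec()] objects, in roster order
#'   (ties in cross-validated accuracy are broken toward the earlier
#'   entry).
#' @export
default_roster <- function(ntree = 200) {
  list(
    random_forest = classifier_spec(
      "random_forest",
      fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree),
      predict_prob = function(model, x, class_labels) {
        align_probabilities(predict(model, x, type = "prob"), class_labels)
      }
    ),
    svm_rbf = classifier_spec(
      "svm_rbf",
      fit = function(x, y) {
        keep <- drop_constant(x)
        m <- e1071::svm(x[, keep, drop = FALSE], y, probability = TRUE,
                        kernel = "radial")
        list(model = m, keep = keep)
      },
      predict_prob = function(model, x, class_labels) {
        pr <- predict(model$model, x[, model$keep, drop = FALSE],
                      probability = TRUE)
        align_probabilities(attr(pr, "probabilities"), class_labels)
      }
    ),
    multinom_logistic = classifier_spec(
      "multinom_logistic",
      fit = function(x, y) {
        keep <- drop_constant(x)
        df <- data.frame(x[, keep, drop = FALSE], check.names = FALSE)
        m <- nnet::multinom(y ~ ., data = cbind(df, y = y), trace = FALSE,
                            MaxNWts = 1e5, decay = 0.01, maxit = 200)
        list(model = m, keep = keep, levels = levels(y))
      },
      predict_prob = function(model, x, class_labels) {
        df <- data.frame(x[, model$keep, drop = FALSE], check.names = FALSE)
        p <- predict(model$model, newdata = df, type = "probs")
        if (is.null(dim(p))) {  # two-class fits return P(level 2)
          p <- cbind(1 - p, p)
          colnames(p) <- model$levels
        }
        align_probabilities(p, class_labels)
      }
    ),
    naive_bayes = classifier_spec(
      "naive_bayes",
      fit = function(x, y) {
        keep <- drop_constant(x)
        m <- e1071::naiveBayes(x[, keep, drop = FALSE], y)
        list(model = m, keep = keep)
      },
      predict_prob = function(model, x, class_labels) {
        p <- predict(model$model, x[, model$keep, drop = FALSE], type = "raw")
        align_probabilities(p, class_labels)
      }
    ),
    lda = classifier_spec(
      "lda",
      fit = function(x, y) {
        keep <- drop_constant(x)
        # collinearity is routine when descriptors outnumber samples;
        # lda still returns a usable rank-reduced fit
        m <- withCallingHandlers(
          MASS::lda(x[, keep, drop = FALSE], grouping = y),
          warning = function(w) {
            if (grepl("collinear", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        list(model = m, keep = keep)
      },
      predict_prob = function(model, x, class_labels) {
        p <- predict(model$model, x[, model$keep, drop = FALSE])$posterior
        align_probabilities(p, class_labels)
      }
    ),
    cart = classifier_spec(
      "cart",
      fit = function(x, y) {
        df <- data.frame(x, check.names = FALSE)
        rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class")
      },
      predict_prob = function(model, x, class_labels) {
        df <- data.frame(x, check.names = FALSE)
        align_probabilities(predict(model, newdata = df, type = "prob"),
                            class_labels)
      }
    )
  )
}
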