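# Independent brute-force oracles: every computation here is a plain
# position-by-position loop, deliberately sharing no code with the package
# implementations it checks.

SS_STATES <- c("G", "H", "I", "E", "B", "T", "S", "L")
SS_GROUP <- c(G = 1, H = 1, I = 1, E = 2, B = 2, T = 3, S = 3, L = 4)
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# maximal-run scan: returns count of runs (length >= 2) of `target` and the
# total number of positions inside them
scan_runs <- function(sym, target) {
  n <- length(sym)
  cnt <- 0
  inside <- 0
  i <- 1
  while (i <= n) {
    if (sym[[i]] == target) {
      j <- i
      while (j < n && sym[[j + 1]] == target) j <- j + 1
      if (j - i + 1 >= 2) {
        cnt <- cnt + 1
        inside <- inside + (j - i + 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  c(count = cnt, inside = inside)
}

oracle_dssp_features <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- numeric(8)
  for (k in seq_along(SS_STATES)) {
    for (c in ch) if (c == SS_STATES[[k]]) comp[[k]] <- comp[[k]] + 1
  }
  comp <- comp / n
  gcomp <- numeric(4)
  for (c in ch) gcomp[[SS_GROUP[[c]]]] <- gcomp[[SS_GROUP[[c]]]] + 1
  gcomp <- gcomp / n
  runs <- t(sapply(SS_STATES, function(st) scan_runs(ch, st)))
  gch <- as.character(SS_GROUP[ch])
  gruns <- t(sapply(as.character(1:4), function(g) scan_runs(gch, g)))
  alt <- numeric(4)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ga <- SS_GROUP[[ch[[i]]]]
      gb <- SS_GROUP[[ch[[i + 1]]]]
      if (ga != gb) {
        alt[[ga]] <- alt[[ga]] + 1
        alt[[gb]] <- alt[[gb]] + 1
      }
    }
    alt <- alt / (n - 1)
  }
  unname(c(comp, gcomp, runs[, "count"], gruns[, "count"],
           runs[, "inside"] / n, gruns[, "inside"] / n, alt))
}

# CTD blocks for one grouping (list of three character vectors)
oracle_ctd <- function(seq, groups) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch %in% AA20]
  n <- length(ch)
  g <- integer(n)
  for (i in seq_len(n)) {
    for (k in 1:3) if (ch[[i]] %in% groups[[k]]) g[[i]] <- k
  }
  comp <- numeric(3)
  for (x in g) comp[[x]] <- comp[[x]] + 1
  comp <- comp / n
  trans <- numeric(3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (k in 1:3) {
        p <- pairs[[k]]
        if ((g[[i]] == p[[1]] && g[[i + 1]] == p[[2]]) ||
            (g[[i]] == p[[2]] && g[[i + 1]] == p[[1]])) {
          trans[[k]] <- trans[[k]] + 1
        }
      }
    }
    trans <- trans / (n - 1)
  }
  dist <- numeric(0)
  for (k in 1:3) {
    pos <- which(g == k)
    block <- numeric(5)
    if (length(pos) > 0) {
      ng <- length(pos)
      block[[1]] <- pos[[1]] / n
      qi <- c(0.25, 0.5, 0.75, 1)
      for (m in 1:4) block[[m + 1]] <- pos[[ceiling(qi[[m]] * ng)]] / n
    }
    dist <- c(dist, block)
  }
  list(composition = comp, transition = trans, distribution = dist)
}

oracle_q <- function(y_true, y_pred, classes) {
  n <- numeric(length(classes))
  c_ <- numeric(length(classes))
  for (i in seq_along(y_true)) {
    k <- which(classes == y_true[[i]])
    n[[k]] <- n[[k]] + 1
    if (y_true[[i]] == y_pred[[i]]) c_[[k]] <- c_[[k]] + 1
  }
  list(n = n, c = c_, Q = sum(c_) / sum(n))
}

# -- random-input generators used across property tests --------------------

rand_ss <- function(len) paste(sample(SS_STATES, len, replace = TRUE),
                               collapse = "")
rand_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                collapse = "")

# -- toy classifiers for selection/averaging tests -------------------------

# 1-nearest-neighbour memorizer: near-perfect out of fold on separable data
nn_memorizer_spec <- function() {
  classifier_spec(
    "nn_memorizer",
    fit = function(x, y) list(x = x, y = as.character(y)),
    predict_prob = function(model, x, class_labels) {
      p <- matrix(0, nrow(x), length(class_labels),
                  dimnames = list(rownames(x), class_labels))
      for (i in seq_len(nrow(x))) {
        d <- rowSums(sweep(model$x, 2, x[i, ])^2)
        p[i, model$y[[which.min(d)]]] <- 1
      }
      p
    }
  )
}

# uninformative classifier: uniform posterior over the classes
uniform_guess_spec <- function() {
  classifier_spec(
    "uniform_guess",
    fit = function(x, y) NULL,
    predict_prob = function(model, x, class_labels) {
      matrix(1 / length(class_labels), nrow(x), length(class_labels),
             dimnames = list(rownames(x), class_labels))
    }
  )
}

# ensemble whose per-group models return fixed, precomputed probability
# rows (matched by sample id); used to test the averaging rule in isolation
make_fixed_ensemble <- function(prob_mats, class_labels) {
  per_group <- lapply(prob_mats, function(pm) {
    list(
      spec = classifier_spec(
        "fixed",
        fit = function(x, y) NULL,
        predict_prob = function(model, x, cls) {
          model$probs[rownames(x), cls, drop = FALSE]
        }
      ),
      model = list(probs = pm), classifier = "fixed", n_features = 1L
    )
  })
  structure(list(class_labels = class_labels, groups_used = names(prob_mats),
                 per_group = per_group, cv_reports = list(), seed = 0),
            class = "profold_ensemble")
}

# single-column feature matrices carrying only sample ids, for use with
# make_fixed_ensemble
id_only_groups <- function(groups, ids) {
  out <- list()
  for (g in groups) {
    out[[g]] <- feature_matrix(
      matrix(0, length(ids), 1, dimnames = list(ids, "x")), g)
  }
  out
}

# the ten-entry reference CV report (roster names and printed 5-fold CV
# accuracies of the benchmark study) used to check the selection rule
reference_cv_reports <- function() {
  roster <- c("LMT", "RandomForest", "LibSVM", "SimpleLogistic",
              "RotationForest", "SMO", "NaiveBayes", "RandomTree", "FT",
              "SimpleCart")
  list(
    DSSP   = cv_report("DSSP", roster,
                       c(43.0, 51.3, 46.4, 43.0, 49.7, 36.4, 43.4, 32.8, 42.4, 37.7)),
    AAsCPP = cv_report("AAsCPP", roster,
                       c(32.5, 35.4, 34.4, 32.5, 27.7, 34.4, 28.3, 11.6, 34.4, 20.6)),
    PSSM   = cv_report("PSSM", roster,
                       c(56.3, 53.7, 57.2, 55.9, 56.1, 30.2, 42.4, 29.6, 49.5, 33.4)),
    FunD   = cv_report("FunD", roster,
                       c(42.1, 43.1, 21.2, 43.1, 41.8, 38.9, 38.3, 39.9, 44.1, 34.7))
  )
}

fast_roster <- function() default_roster()[c("random_forest", "lda", "cart")]
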