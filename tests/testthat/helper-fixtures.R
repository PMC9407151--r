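# Shared fixtures and independent oracles (brute force / enumeration),
# kept deliberately naive so they stay independent of the package's
# optimized code paths.

# Wrap a named list of planes as a feature_stack without running filters.
make_stack <- function(planes) {
  nms <- names(planes)
  d <- dim(planes[[1]])
  arr <- array(0, c(d, length(planes)), dimnames = list(NULL, NULL, nms))
  for (i in seq_along(planes)) arr[, , i] <- planes[[i]]
  structure(list(planes = arr, feature_names = nms, dims = d),
            class = "feature_stack")
}

# A two-region, perfectly separable image: left half dark, right half
# bright, plus a trace of deterministic ripple so features are not
# literally constant.
separable_image <- function(nr = 40, nc = 40) {
  base <- matrix(0.15, nr, nc)
  base[, (nc %/% 2 + 1):nc] <- 0.85
  ripple <- 0.01 * sin(outer(seq_len(nr), seq_len(nc), "+"))
  gray_image(pmin(pmax(base + ripple, 0), 1))
}

# Labels for separable_image: n pixels per side, away from the border.
separable_labels <- function(nr = 40, nc = 40, n = 50, seed = 42) {
  set.seed(seed)
  half <- nc %/% 2
  pick <- function(cols) {
    g <- expand.grid(row = 3:(nr - 4), col = cols)
    g[sample(nrow(g), n), ]
  }
  left <- pick(3:(half - 2))
  right <- pick((half + 2):(nc - 4))
  label_set(list(dark = cbind(left$row, left$col),
                 bright = cbind(right$row, right$col)),
            dims = c(nr, nc))
}

# Brute-force spatial cross-correlation with reflect padding (the slow
# oracle behind the FFT and separable paths).
brute_correlate <- function(img, kern) {
  kr <- (nrow(kern) - 1) %/% 2
  kc <- (ncol(kern) - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  ridx <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          s <- s + kern[a + kr + 1, b + kc + 1] *
            img[ridx(i + a, nr), ridx(j + b, nc)]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Exhaustive best-Gini-split search over every feature and every midpoint
# threshold (the enumeration oracle for single-tree split choices).
exhaustive_best_split <- function(X, y, K) {
  best <- NULL
  n <- length(y)
  gini <- function(yy) {
    p <- tabulate(yy, K) / length(yy)
    1 - sum(p^2)
  }
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      l <- X[, f] < thr
      w <- (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / n
      if (is.null(best) || w < best$gini - 1e-12) {
        best <- list(feature = f, thr = thr, gini = w)
      }
    }
  }
  best
}

# Trapezoid AUC by direct enumeration over all thresholds (oracle).
brute_auc <- function(scores_pos, scores_neg) {
  # probability a random positive outranks a random negative (ties = 1/2):
  # the Mann-Whitney statistic, equal to trapezoid AUC.
  s <- 0
  for (p in scores_pos) {
    for (q in scores_neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(scores_pos) * length(scores_neg))
}
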