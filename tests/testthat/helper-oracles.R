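# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they validate.

# Exhaustive enumeration of all global alignments with affine gaps
# (gap of length L costs open + L * extend). The recursion walks every
# monotone alignment path, tracking whether the previous move opened a
# gap, and returns the maximal score.
brute_align_score <- function(a, b, match = 5, mismatch = -4,
                              open = 10, ext = 0.1) {
  a <- strsplit(chartr("U", "T", a), "")[[1]]
  b <- strsplit(chartr("U", "T", b), "")[[1]]
  n <- length(a)
  m <- length(b)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      cost <- if (last == 1L) ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, 1L))
    }
    if (j <= m) {
      cost <- if (last == 2L) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# AUC by explicit enumeration of all positive/negative pairs (ties 0.5).
pair_auc <- function(scores, positive) {
  pos <- scores[as.logical(positive)]
  neg <- scores[!as.logical(positive)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Plain Newton-Raphson (iteratively reweighted least squares) logistic
# regression, written independently of stats::glm.
irls_logistic <- function(x, y, max_iter = 200L, tol = 1e-12) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(crossprod(X, w * X), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
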