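# Shared helpers: small deterministic tables and independent mini-oracles.

toy_survey <- function(n = 3) {
  tab <- make_fixture("tiny8")
  out <- tab[seq_len(n), , drop = FALSE]
  validate_survey(out, attr(tab, "codebook"))
}

write_survey_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  write_table(tab, path)
  path
}

# brute-force MWI by explicit summation (independent of compute_mwi)
mwi_by_hand <- function(d) {
  k <- length(d)
  s1 <- 0; s2 <- 0
  for (j in seq_len(k)) {
    s1 <- s1 + d[j]^2
    s2 <- s2 + (1 - d[j])^2
  }
  0.5 * (sqrt(s1) / sqrt(k) + 1 - sqrt(s2) / sqrt(k))
}

# align signs of coordinate matrix B to A, per column
sign_align <- function(A, B) {
  for (s in seq_len(ncol(A))) {
    if (sum(abs(A[, s] - B[, s])) > sum(abs(A[, s] + B[, s])))
      B[, s] <- -B[, s]
  }
  B
}

# exhaustive best binary split: every threshold and every category subset
brute_force_best_gain <- function(X, y) {
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  total <- sse(y)
  best <- 0
  for (v in names(X)) {
    x <- X[[v]]
    if (is.numeric(x)) {
      for (t in sort(unique(x))) {
        left <- x <= t
        if (any(left) && any(!left))
          best <- max(best, total - sse(y[left]) - sse(y[!left]))
      }
    } else {
      lev <- unique(as.character(x))
      L <- length(lev)
      if (L >= 2) {
        for (mask in 1:(2^L - 2)) {
          inset <- lev[bitwAnd(mask, 2^(seq_len(L) - 1)) > 0]
          left <- as.character(x) %in% inset
          if (any(left) && any(!left))
            best <- max(best, total - sse(y[left]) - sse(y[!left]))
        }
      }
    }
  }
  best
}

tree_depth <- function(node) {
  if (is.null(node$split)) 1L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_leaves <- function(node) {
  if (is.null(node$split)) list(node)
  else c(tree_leaves(node$left), tree_leaves(node$right))
}
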