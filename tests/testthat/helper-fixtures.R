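# small count-object builders and independent brute-force oracles used
# across the suite

make_counts <- function(endo, pos = NULL, neg = NULL) {
  # endo/pos/neg: matrices (rows are probes); default controls are benign
  n_s <- ncol(endo)
  if (is.null(pos))
    pos <- matrix(rep(c(1000, 250), each = n_s), nrow = 2, byrow = TRUE,
                  dimnames = list(c("POS_A", "POS_B"), colnames(endo)))
  if (is.null(neg))
    neg <- matrix(rep(c(4, 6), each = n_s), nrow = 2, byrow = TRUE,
                  dimnames = list(c("NEG_01", "NEG_02"), colnames(endo)))
  m <- rbind(pos, neg, endo)
  ncounter_counts(m, rep(c("Positive", "Negative", "Endogenous"),
                         c(nrow(pos), nrow(neg), nrow(endo))))
}

endo_matrix <- function(values, n_probes, n_samples, prefix = "miR") {
  matrix(values, nrow = n_probes, ncol = n_samples,
         dimnames = list(sprintf("%s-%03d", prefix, seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

two_group_metadata <- function(nA, nB, groups = c("OS", "Ob")) {
  data.frame(sample_id = sprintf("s%02d", seq_len(nA + nB)),
             group = rep(groups, c(nA, nB)),
             stringsAsFactors = FALSE)
}

# brute-force quantile normalization: enumerates every ordering of each
# column consistent with sorting (ties permuted among their positions) and
# averages the induced reference assignments
bf_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  n <- nrow(m)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- perms[apply(perms, 1, function(p) !is.unsorted(col[p])), , drop = FALSE]
    acc <- matrix(0, n, nrow(ok))
    for (r in seq_len(nrow(ok))) acc[ok[r, ], r] <- ref
    out[, j] <- rowMeans(acc)
  }
  out
}

# brute-force average-linkage clustering on a precomputed distance matrix:
# O(n^3) direct recomputation of cluster-to-cluster mean distances; returns
# the cophenetic distance matrix, which characterizes the dendrogram
bf_average_cophenetic <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  ch <- matrix(0, n, n)
  while (length(active) > 1) {
    best <- NULL; bmin <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        i <- active[a]; j <- active[b]
        d <- mean(D[members[[i]], members[[j]]])
        if (d < bmin) { bmin <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ch[members[[i]], members[[j]]] <- bmin
    ch[members[[j]], members[[i]]] <- bmin
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  ch
}

# closed-form pooled-variance two-sample t-test p-value
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), na + nb - 2)
}
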