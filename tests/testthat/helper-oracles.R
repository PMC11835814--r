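# Independent brute-force oracles used to cross-check the package's
# implementations. Each oracle takes a different computational route than
# the function it checks.

# bout count and sizes from an explicit scan over the gap list
oracle_segment <- function(onset, offset, threshold) {
  n <- length(onset)
  sizes <- integer(0)
  cur <- 1L
  if (n > 1) {
    for (i in 2:n) {
      if (onset[i] - offset[i - 1] >= threshold) {
        sizes <- c(sizes, cur)
        cur <- 1L
      } else {
        cur <- cur + 1L
      }
    }
  }
  c(sizes, cur)
}

# cross-singer overlap by brute-force time discretization
oracle_overlap_grid <- function(on1, off1, on2, off2, step = 1e-3) {
  lo <- min(on1, on2)
  hi <- max(off1, off2)
  grid <- seq(lo + step / 2, hi, by = step)
  in1 <- rep(FALSE, length(grid))
  for (i in seq_along(on1)) in1 <- in1 | (grid > on1[i] & grid < off1[i])
  in2 <- rep(FALSE, length(grid))
  for (i in seq_along(on2)) in2 <- in2 | (grid > on2[i] & grid < off2[i])
  sum(in1 & in2) * step
}

# successor counts at a branch syllable by a position-by-position scan
oracle_transition_counts <- function(bout_labels, branch) {
  out <- character(0)
  for (lb in bout_labels) {
    for (i in seq_along(lb)) {
      if (lb[i] == branch) {
        out <- c(out, if (i < length(lb)) lb[i + 1] else "END")
      }
    }
  }
  out
}

# per-bout transition entropy via an explicit contingency table
oracle_te <- function(labels, base = 2, include_end = TRUE) {
  from <- labels
  to <- c(labels[-1], "END")
  if (!include_end) {
    from <- from[-length(from)]
    to <- to[-length(to)]
    if (length(from) == 0) return(0)
  }
  tab <- table(from, to)
  n <- sum(tab)
  te <- 0
  for (i in rownames(tab)) {
    row <- tab[i, ]
    row <- row[row > 0]
    p <- row / sum(row)
    te <- te + (-sum(p * log(p, base = base))) * sum(tab[i, ]) / n
  }
  te
}

# windowed recount of a binned learning curve
oracle_binned <- function(bout_labels, branch, target, bin_size) {
  n_bins <- ceiling(length(bout_labels) / bin_size)
  tp <- rep(NA_real_, n_bins)
  nr <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1) * bin_size + 1):min(b * bin_size, length(bout_labels))
    succ <- oracle_transition_counts(bout_labels[idx], branch)
    nr[b] <- length(succ)
    if (length(succ) > 0) tp[b] <- mean(succ == target)
  }
  data.frame(bin = seq_len(n_bins), tp_target = tp, n_renditions = nr)
}

# leftmost non-overlapping chunk matches: enumerate all match positions
# vectorized, then filter greedily
oracle_chunk_starts <- function(labels, chunk) {
  k <- length(chunk)
  n <- length(labels)
  if (n < k) return(integer(0))
  cand <- which(vapply(seq_len(n - k + 1),
                       function(i) all(labels[i:(i + k - 1)] == chunk),
                       TRUE))
  keep <- integer(0)
  last_end <- 0L
  for (i in cand) {
    if (i > last_end) {
      keep <- c(keep, i)
      last_end <- i + k - 1L
    }
  }
  keep
}

# two-proportion chi-square from the 2x2 contingency formula
oracle_prop_chisq <- function(k1, n1, k2, n2, continuity = FALSE) {
  O <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  yates <- if (continuity) min(0.5, abs(O[1, 1] - E[1, 1])) else 0
  stat <- sum((abs(O - E) - yates)^2 / E)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# one-way ANOVA from explicit sums of squares, plus Tukey-Kramer pairwise
oracle_oneway <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  N <- length(values)
  m <- mean(values)
  mg <- tapply(values, group, mean)
  ng <- tabulate(group)
  ssb <- sum(ng * (mg - m)^2)
  ssw <- sum((values - mg[group])^2)
  fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  s2 <- ssw / (N - k)
  pairs <- utils::combn(levels(group), 2)
  p_adj <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    q <- abs(mg[i] - mg[j]) / sqrt(s2 / 2 * (1 / ng[levels(group) == i] +
                                               1 / ng[levels(group) == j]))
    stats::ptukey(q, k, N - k, lower.tail = FALSE)
  })
  list(statistic = fstat,
       p = stats::pf(fstat, k - 1, N - k, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw,
       pairwise_p = p_adj,
       pairwise = paste(pairs[2, ], pairs[1, ], sep = "-"))
}

# main-effects least squares via hand-built dummy design and normal
# equations; per-factor F from full-vs-reduced residual sums of squares
oracle_nway <- function(values, factors) {
  factors <- lapply(factors, factor)
  dummy_cols <- function(f) {
    lv <- levels(f)
    if (length(lv) < 2) return(NULL)
    sapply(lv[-1], function(l) as.numeric(f == l))
  }
  blocks <- lapply(factors, dummy_cols)
  X_full <- cbind(1, do.call(cbind, blocks))
  fit_rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% values)
    sum((values - X %*% beta)^2)
  }
  rss_full <- fit_rss(X_full)
  df_res <- length(values) - ncol(X_full)
  out <- list()
  for (f in names(factors)) {
    others <- do.call(cbind, blocks[setdiff(names(factors), f)])
    X_red <- cbind(1, others)
    rss_red <- fit_rss(X_red)
    df_f <- ncol(blocks[[f]])
    fstat <- ((rss_red - rss_full) / df_f) / (rss_full / df_res)
    out[[f]] <- list(statistic = fstat, df = c(df_f, df_res),
                     p = stats::pf(fstat, df_f, df_res, lower.tail = FALSE))
  }
  out
}

# paired t from the closed-form statistic and t CDF
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), n - 1))
}

# Pearson r from the product-moment formula and its t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = r, df = n - 2, p = 2 * stats::pt(-abs(t), n - 2))
}
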