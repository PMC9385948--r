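# Independent brute-force oracles used to validate the package's
# implementations on small instances. These are deliberately naive
# (nested loops, closed-form sums) and share no code with the package.

brute_silhouette <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- as.integer(factor(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# cophenetic distance of each leaf pair = height of the merge where their
# subtrees first join
brute_cophenetic_matrix <- function(hc) {
  n <- length(hc$height) + 1L
  members <- vector("list", nrow(hc$merge))
  cm <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    grp <- lapply(kids, function(kk) if (kk < 0) -kk else members[[kk]])
    for (i in grp[[1]]) for (j in grp[[2]]) {
      cm[i, j] <- cm[j, i] <- hc$height[k]
    }
    members[[k]] <- c(grp[[1]], grp[[2]])
  }
  cm
}

brute_cophenetic_cor <- function(d, hc) {
  D <- as.matrix(d)
  CM <- brute_cophenetic_matrix(hc)
  lt <- lower.tri(D)
  cor(D[lt], CM[lt])
}

brute_inconsistency <- function(merge, height, depth = 2) {
  n_links <- nrow(merge)
  descend <- function(link, d) {
    set <- link
    frontier <- link
    while (d > 1 && length(frontier) > 0) {
      nxt <- c()
      for (fr in frontier) {
        for (kid in merge[fr, ]) if (kid > 0) nxt <- c(nxt, kid)
      }
      set <- c(set, nxt)
      frontier <- nxt
      d <- d - 1
    }
    set
  }
  vapply(seq_len(n_links), function(i) {
    hh <- height[descend(i, depth)]
    if (length(hh) < 2 || sd(hh) == 0) 0 else (height[i] - mean(hh)) / sd(hh)
  }, numeric(1))
}

brute_chisq <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

brute_binom_upper_tail <- function(x, n, p) {
  # P(X >= x) by direct probability-mass summation
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2))
}

# minimum-WSS 2-partition by exhaustive enumeration
brute_best_2partition <- function(X) {
  n <- nrow(X)
  best <- NULL
  best_wss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2) next
    wss <- sum(vapply(unique(lab), function(cl) {
      Xi <- X[lab == cl, , drop = FALSE]
      sum(sweep(Xi, 2, colMeans(Xi))^2)
    }, numeric(1)))
    if (wss < best_wss) { best_wss <- wss; best <- lab }
  }
  list(labels = best, wss = best_wss)
}

# small helper: do two labelings describe the same partition?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
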