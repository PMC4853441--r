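# Independent from-scratch oracles used to cross-check the implementation.
# These deliberately use different formulations than the package code.

# pooled-variance two-sample t via the textbook formula (group vectors)
oracle_pooled_t <- function(intact, lesioned) {
  n0 <- length(intact); n1 <- length(lesioned)
  sp2 <- ((n0 - 1) * var(intact) + (n1 - 1) * var(lesioned)) / (n0 + n1 - 2)
  (mean(intact) - mean(lesioned)) / sqrt(sp2 * (1 / n0 + 1 / n1))
}

# Brunner-Munzel via placement counts (double loop over pairs), following the
# placements formulation rather than combined midranks
oracle_bm <- function(x, y) {
  # x = lesioned, y = intact; positive statistic = y tends larger
  m <- length(x); n <- length(y)
  place_x <- vapply(x, function(xi) sum(y < xi) + 0.5 * sum(y == xi), numeric(1))
  place_y <- vapply(y, function(yi) sum(x < yi) + 0.5 * sum(x == yi), numeric(1))
  p_hat <- mean(place_y) / m            # P(X < Y) + .5 P(=)
  sx2 <- var(place_x) / n^2
  sy2 <- var(place_y) / m^2
  se <- sqrt(sx2 / m + sy2 / n)
  if (se == 0) return(list(statistic = if (p_hat == 0.5) 0 else sign(p_hat - 0.5) * Inf,
                           df = NA_real_, p_hat = p_hat))
  df <- (sx2 / m + sy2 / n)^2 /
    ((sx2 / m)^2 / (m - 1) + (sy2 / n)^2 / (n - 1))
  list(statistic = (p_hat - 0.5) / se, df = df, p_hat = p_hat)
}

# Pearson r and two-tailed p from the closed-form definitions
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by explicit loop over the sorted p values
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) k_star <- k
  cutoff <- if (k_star > 0) p[ord[k_star]] else 0
  list(cutoff = cutoff, significant = p <= cutoff & k_star > 0)
}

# 6-connected component count by breadth-first search over lesion voxels
oracle_n_components <- function(voxels) {
  dims <- dim(voxels)
  idx <- which(voxels == 1L)
  if (length(idx) == 0) return(0L)
  remaining <- rep(TRUE, length(idx))
  names(remaining) <- idx
  lookup <- new.env()
  for (v in idx) assign(as.character(v), TRUE, envir = lookup)
  neighbors <- function(v) {
    sub <- arrayInd(v, dims)
    out <- integer(0)
    for (a in 1:3) for (d in c(-1L, 1L)) {
      s <- sub; s[a] <- s[a] + d
      if (s[a] >= 1 && s[a] <= dims[a]) {
        out <- c(out, s[1] + dims[1] * (s[2] - 1 + dims[2] * (s[3] - 1)))
      }
    }
    out
  }
  seen <- character(0)
  ncomp <- 0L
  for (v in idx) {
    key <- as.character(v)
    if (key %in% seen) next
    ncomp <- ncomp + 1L
    queue <- v
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ck <- as.character(cur)
      if (ck %in% seen) next
      seen <- c(seen, ck)
      for (nb in neighbors(cur)) {
        nk <- as.character(nb)
        if (!is.null(lookup[[nk]]) && !(nk %in% seen)) queue <- c(queue, nb)
      }
    }
  }
  ncomp
}
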