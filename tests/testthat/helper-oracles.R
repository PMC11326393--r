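# Independent brute-force / enumeration oracles used across test files.
# These deliberately share no code with the implementation paths they check.

# Construct a phenotype_table directly from coordinates + phenotype labels,
# bypassing intensity thresholding (for spatial tests).
make_pheno <- function(x, y, phenotype) {
  n <- length(x)
  out <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)), x_um = x, y_um = y,
    pheno_DAPI = rep(TRUE, n),
    pheno_CD4 = phenotype == "CD4",
    pheno_CD8 = phenotype %in% c("CD8", "TCF1_CD8"),
    pheno_MHCII = phenotype == "MHCII",
    pheno_TCF1_CD8 = phenotype == "TCF1_CD8"
  )
  class(out) <- c("phenotype_table", "data.frame")
  out
}

# O(n * w) per-window recount: every cell against every window rectangle,
# half-open [lo, hi) on both axes.
oracle_window_counts <- function(x, y, cx, cy, side) {
  h <- side / 2
  counts <- matrix(0L, length(cx), length(cy))
  for (i in seq_along(cx)) {
    for (j in seq_along(cy)) {
      counts[i, j] <- sum(x >= cx[i] - h & x < cx[i] + h &
                            y >= cy[j] - h & y < cy[j] + h)
    }
  }
  counts
}

# O(n^2) nearest-neighbor distances.
oracle_nn <- function(fx, fy, tx, ty, exclude = NULL) {
  vapply(seq_along(fx), function(i) {
    d2 <- (tx - fx[i])^2 + (ty - fy[i])^2
    if (!is.null(exclude) && !is.na(exclude[i])) d2[exclude[i]] <- Inf
    sqrt(min(d2))
  }, numeric(1))
}

# Full outcome-path enumeration of a two-stage design: every (x1, x2) pair
# with exact binomial probabilities.
oracle_simon_reject <- function(n1, r1, n_total, r, p) {
  n2 <- n_total - n1
  total <- 0
  for (x1 in 0:n1) {
    if (x1 <= r1) next  # stopped for futility, never rejects
    for (x2 in 0:n2) {
      if (x1 + x2 >= r) {
        total <- total + dbinom(x1, n1, p) * dbinom(x2, n2, p)
      }
    }
  }
  total
}

# Step-by-step hand product-limit estimator at a landmark time.
oracle_km <- function(time, event, at_time) {
  s <- 1
  for (t in sort(unique(time[event == 1 & time <= at_time]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments of
# the (mid-)ranked absolute differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact rank-sum two-sided p by enumerating all assignments of the pooled
# ranks to group A (no-ties case).
oracle_ranksum_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(length(pooled), m)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact Spearman permutation p (two-sided, |rho| >= |rho_obs|) plus rho,
# computed from scratch with explicit rank formulas.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho_of <- function(yy) {
    num <- sum((rx - mean(rx)) * (yy - mean(yy)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((yy - mean(yy))^2))
    num / den
  }
  rho_obs <- rho_of(ry)
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(permute(seq_len(n)), function(p) rho_of(ry[p]), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}
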