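# Baseline-anchored fold changes, rank-based tests, Spearman correlation
# against tumor-size change, and ctDNA detection/variant summaries.
#
# Testing conventions: rank procedures use mid-ranks for ties; the signed-
# rank test drops zero differences; per-analyte P values are reported
# unadjusted (matching the per-comparison convention of trial figure
# legends) with a clearly-labelled Holm-adjusted column alongside.

#' Fold changes of analyte trajectories versus patient baseline
#'
#' Each patient's baseline value anchors that patient's trajectory: the
#' fold change at a timepoint is value(t) / value(baseline). Pairs with a
#' missing or zero baseline are excluded (never a division by zero) and
#' listed in the `excluded` attribute.
#'
#' @param panel Data.frame `patient_id, timepoint, analyte, value` with
#'   timepoints among `baseline`, `W6D1`, `PostTx`, `PostSx`.
#' @return Data.frame `patient_id, timepoint, analyte, fold` of class
#'   `fold_change_matrix`; baseline rows have fold 1 by construction.
#'   `attr(, "excluded")` is a data.frame of dropped (patient, analyte)
#'   pairs.
#' @examples
#' coh <- generate_cohort(17, seed = 1)
#' fc <- fold_changes(coh$panel)
#' with(fc[fc$analyte == "VEGF" & fc$timepoint == "W6D1", ], median(fold))
#' @export
fold_changes <- function(panel) {
  need <- c("patient_id", "timepoint", "analyte", "value")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$value < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  base <- panel[panel$timepoint == "baseline", ]
  key <- function(d) paste(d$patient_id, d$analyte, sep = "\r")
  base_val <- stats::setNames(base$value, key(base))
  b <- base_val[key(panel)]
  usable <- !is.na(b) & b > 0
  excluded <- unique(panel[!usable, c("patient_id", "analyte")])
  if (nrow(excluded) > 0) {
    warning(nrow(excluded),
            " (patient, analyte) pair(s) excluded: missing or zero baseline",
            call. = FALSE)
  }
  out <- panel[usable, c("patient_id", "timepoint", "analyte")]
  out$fold <- panel$value[usable] / b[usable]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("fold_change_matrix", "data.frame")
  out
}

# Exact null distribution of the doubled signed-rank statistic 2*W+ under
# random sign flips, by convolution. Works with mid-ranks (doubling makes
# the support integral). Returns P(2W+ = 0..sum(2r)).
signed_rank_null <- function(ranks2) {
  f <- 1
  for (s in ranks2) {
    g <- numeric(length(f) + s)
    g[seq_along(f)] <- f / 2
    g[seq_along(f) + s] <- g[seq_along(f) + s] + f / 2
    f <- g
  }
  f
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Zero differences are dropped; ties receive mid-ranks. The null
#' distribution is exact (full sign-flip convolution, valid under ties) for
#' up to `exact_max` non-zero pairs, and a tie-corrected normal
#' approximation above.
#'
#' @param x_baseline,x_timepoint Paired measurement vectors.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List: `statistic` (W+, the positive-rank sum), `n` (non-zero
#'   pairs), `p_value` (two-sided), `method`.
#' @examples
#' paired_signed_rank(rep(0, 6), 1:6)$p_value  # 2 / 2^6
#' @export
paired_signed_rank <- function(x_baseline, x_timepoint, exact_max = 25L) {
  stopifnot(length(x_baseline) == length(x_timepoint))
  d <- x_timepoint - x_baseline
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    null <- signed_rank_null(round(2 * r))
    w2 <- round(2 * w)
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact sign-flip distribution"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    if (w == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "tie-corrected normal approximation"
  }
  list(statistic = w, n = n, p_value = p, method = method)
}

#' Mann-Whitney rank-sum test for two independent groups
#'
#' Exact null distribution when the smaller group has at most `exact_max`
#' observations and there are no ties; tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact_max Largest min(n) for the exact path (default 8).
#' @return List: `statistic` (U for `group_a`), `p_value` (two-sided),
#'   `method`.
#' @examples
#' rank_sum_twogroup(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
rank_sum_twogroup <- function(group_a, group_b, exact_max = 8L) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && min(m, n) <= exact_max) {
    p_le <- stats::pwilcox(u, m, n)
    p_ge <- 1 - if (u >= 1) stats::pwilcox(u - 1, m, n) else 0
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * n / 2
    N <- m + n
    tie_tab <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- if (sig2 > 0) (u - mu - sign(u - mu) * 0.5) / sqrt(sig2) else 0
    if (u == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "tie-corrected normal approximation"
  }
  list(statistic = u, p_value = p, method = method)
}

# All permutations of 1..n as an (n! x n) matrix; n <= 9 supported.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation of a biomarker against tumor-size change
#'
#' Correlation on mid-ranks. The P value uses the t approximation by
#' default; for n <= 9 an exact full-permutation P value is available.
#'
#' @param values Named (by patient) or positional biomarker values.
#' @param pct_change Percent tumor-size change, aligned to `values` (by
#'   name when both are named).
#' @param p_method `"t-approximation"` (default) or `"permutation"`
#'   (requires n <= 9).
#' @return List: `rho`, `n`, `p_value`, `p_method`.
#' @export
spearman_vs_tumor_change <- function(values, pct_change,
                                     p_method = c("t-approximation",
                                                  "permutation")) {
  p_method <- match.arg(p_method)
  if (!is.null(names(values)) && !is.null(names(pct_change))) {
    common <- intersect(names(values), names(pct_change))
    values <- values[common]
    pct_change <- pct_change[common]
  }
  ok <- !is.na(values) & !is.na(pct_change)
  x <- values[ok]; y <- pct_change[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "permutation") {
    if (n > 9) stop("permutation p-value supported for n <= 9", call. = FALSE)
    perms <- all_permutations(n)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    mx <- mean(rx); my <- mean(ry)
    # rho under permutation P of the y-ranks: cor(rx, ry[P]) via raw sums
    s_perm <- apply(perms, 1, function(p) sum(rx * ry[p]))
    rho_perm <- (s_perm / n - mx * my) / (sx * sy) * n / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, n = n, p_value = p, p_method = p_method)
}

#' Per-analyte paired tests of a timepoint against baseline
#'
#' Runs [paired_signed_rank()] for every analyte between baseline and the
#' given timepoint on complete pairs, reporting unadjusted P values plus a
#' Holm-adjusted column (an extension beyond the per-comparison convention,
#' labelled as such).
#'
#' @param panel Data.frame `patient_id, timepoint, analyte, value`.
#' @param timepoint Timepoint to compare against baseline.
#' @return Data.frame `analyte, n_pairs, statistic, p_value, p_holm,
#'   median_fold`.
#' @export
panel_tests <- function(panel, timepoint = "W6D1") {
  analytes <- sort(unique(panel$analyte))
  rows <- lapply(analytes, function(a) {
    sub <- panel[panel$analyte == a, ]
    b <- sub[sub$timepoint == "baseline", ]
    t <- sub[sub$timepoint == timepoint, ]
    ids <- intersect(b$patient_id, t$patient_id)
    bv <- b$value[match(ids, b$patient_id)]
    tv <- t$value[match(ids, t$patient_id)]
    keep <- !is.na(bv) & !is.na(tv)
    bv <- bv[keep]; tv <- tv[keep]
    res <- tryCatch(paired_signed_rank(bv, tv),
                    error = function(e) list(statistic = NA, p_value = NA))
    med_fold <- if (any(bv > 0)) stats::median(tv[bv > 0] / bv[bv > 0]) else NA
    data.frame(analyte = a, n_pairs = sum(keep), statistic = res$statistic,
               p_value = res$p_value, median_fold = med_fold)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out[, c("analyte", "n_pairs", "statistic", "p_value", "p_holm",
          "median_fold")]
}

#' Per-timepoint ctDNA detection rates
#'
#' @param flags Data.frame `patient_id, timepoint, detected` (logical).
#' @return Data.frame `timepoint, k, n, percent` with one row per timepoint
#'   plus a pooled `overall` row; percents are k/n * 100 rounded half-up to
#'   one decimal.
#' @examples
#' f <- data.frame(patient_id = 1:13, timepoint = "baseline",
#'                 detected = c(rep(TRUE, 4), rep(FALSE, 9)))
#' detection_rates(f)  # baseline 30.8
#' @export
detection_rates <- function(flags) {
  stopifnot(all(c("patient_id", "timepoint", "detected") %in% names(flags)))
  if (!is.logical(flags$detected)) {
    stop("detected must be logical", call. = FALSE)
  }
  tps <- unique(flags$timepoint)
  order_ref <- c("baseline", "W6D1", "PostTx", "PostSx")
  tps <- c(intersect(order_ref, tps), setdiff(tps, order_ref))
  rows <- lapply(tps, function(tp) {
    f <- flags[flags$timepoint == tp, ]
    data.frame(timepoint = tp, k = sum(f$detected), n = nrow(f))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(timepoint = "overall",
                               k = sum(flags$detected), n = nrow(flags)))
  out$percent <- round_half_up(100 * out$k / out$n, 1)
  out
}

#' Summarize a ctDNA somatic-variant table
#'
#' @param variants Data.frame `patient_id, timepoint, gene, nt_change,
#'   aa_change, vaf_percent`.
#' @return List: `per_gene` (named counts), `per_timepoint` (named counts),
#'   `max_vaf`, `oncomap` (logical patient x gene matrix, TRUE when the
#'   gene was detected in that patient at any timepoint), `n_variants`.
#' @export
variant_summary <- function(variants) {
  if (nrow(variants) == 0) {
    return(list(per_gene = integer(0), per_timepoint = integer(0),
                max_vaf = NA_real_,
                oncomap = matrix(FALSE, 0, 0), n_variants = 0L))
  }
  vaf <- suppressWarnings(as.numeric(variants$vaf_percent))
  bad <- which(is.na(vaf) | vaf < 0 | vaf > 100)
  if (length(bad) > 0) {
    stop("parse error: malformed VAF in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(variants$gene))) {
    stop("parse error: empty gene symbol", call. = FALSE)
  }
  per_gene <- table(variants$gene)
  per_tp <- table(variants$timepoint)
  pts <- unique(as.character(variants$patient_id))
  genes <- sort(unique(variants$gene))
  onc <- matrix(FALSE, length(pts), length(genes),
                dimnames = list(pts, genes))
  for (i in seq_len(nrow(variants))) {
    onc[as.character(variants$patient_id[i]), variants$gene[i]] <- TRUE
  }
  list(per_gene = c(per_gene), per_timepoint = c(per_tp),
       max_vaf = max(vaf), oncomap = onc, n_variants = nrow(variants))
}
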