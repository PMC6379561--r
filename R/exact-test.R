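#' Negative binomial conditional exact test for two groups
#'
#' The two-group exact test for overdispersed counts used per genomic
#' window (and per transcript): sample counts are rescaled to a common
#' effective library size (geometric mean of effective sizes) and
#' rounded, group sums A (n1 samples) and B (n2 samples) are modeled
#' under the null as negative binomial with means n1 mu and n2 mu and
#' dispersions phi/n1 and phi/n2, and, conditional on the total
#' T = A + B, the two-sided p-value sums the probabilities of all splits
#' (a, T - a) no more probable than the observed one (probability-mass
#' ordering, ties included), normalized by the total split mass.
#' phi = 0 degenerates to the Poisson limit, where the conditional law
#' of A given T is exactly binomial.
#'
#' @param counts A matrix (features x samples), or a single feature's
#'   numeric vector of counts.
#' @param groups Sample->group mapping; the first level is the
#'   reference (control) group.
#' @param norm Optional [normalization_factors()] result; computed from
#'   `counts` if omitted (requires a matrix).
#' @param dispersion Common dispersion phi >= 0.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' m <- rbind(w1 = c(10, 12, 9, 30, 28, 35))
#' colnames(m) <- c(paste0("c", 1:3), paste0("e", 1:3))
#' g <- setNames(rep(c("control", "exposure"), each = 3), colnames(m))
#' nb_exact_test(m, g, dispersion = 0.1)
nb_exact_test <- function(counts, groups, norm = NULL, dispersion = 0) {
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  g <- resolve_groups(groups, colnames(m))
  if (nlevels(g) != 2L) abort("Exactly two groups are required.")
  if (any(m < 0)) abort("Counts must be non-negative.")
  scaled <- rescale_to_common_size(m, norm)
  a <- rowSums(scaled[, g == levels(g)[1], drop = FALSE])
  b <- rowSums(scaled[, g == levels(g)[2], drop = FALSE])
  n1 <- sum(g == levels(g)[1])
  n2 <- sum(g == levels(g)[2])
  vapply(seq_along(a), function(i) {
    exact_split_p(a[i], b[i], n1, n2, dispersion)
  }, numeric(1))
}

# Rescale counts to the geometric-mean effective library size, rounded.
rescale_to_common_size <- function(m, norm) {
  if (is.null(norm)) {
    if (ncol(m) < 2L) abort("Need a normalization result or >= 2 samples.")
    norm <- normalization_factors(m)
  }
  eff <- norm$effective_size[match(colnames(m), norm$sample)]
  if (anyNA(eff)) abort("Normalization result lacks some samples.")
  common <- geometric_mean(eff)
  round(sweep(m, 2, common / eff, `*`))
}

# Conditional two-sided exact p for one feature's group sums.
exact_split_p <- function(a, b, n1, n2, phi, rel_err = 1 + 1e-7) {
  tt <- a + b
  if (tt == 0) return(1)
  mu <- tt / (n1 + n2)
  xs <- 0:tt
  if (phi == 0) {
    pa <- dpois(xs, n1 * mu)
    pb <- dpois(xs, n2 * mu)
  } else {
    pa <- dnbinom(xs, mu = n1 * mu, size = n1 / phi)
    pb <- dnbinom(xs, mu = n2 * mu, size = n2 / phi)
  }
  joint <- pa * rev(pb)
  total <- sum(joint)
  if (total <= 0) return(1)
  p_obs <- joint[a + 1L]
  min(1, sum(joint[joint <= p_obs * rel_err]) / total)
}

#' Signed log2 fold change of normalized group means
#'
#' log2 of (exposure mean + pseudo) / (control mean + pseudo) on the
#' common normalized scale; positive values indicate an increase in the
#' exposure group. The pseudo-count keeps the ratio finite when either
#' group mean is zero.
#'
#' @inheritParams nb_exact_test
#' @param pseudo Pseudo-count added to both means (default 0.5).
#' @return Numeric vector of signed log2 fold changes.
#' @export
log2_fold_change <- function(counts, groups, norm = NULL, pseudo = 0.5) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  g <- resolve_groups(groups, colnames(m))
  if (nlevels(g) != 2L) abort("Exactly two groups are required.")
  mm <- group_means_normalized(m, g, norm)
  log2((mm$exposure + pseudo) / (mm$control + pseudo))
}

# Normalized (not rounded) group means on the common scale; first group
# level is treated as control, second as exposure.
group_means_normalized <- function(m, g, norm) {
  if (is.null(norm)) norm <- normalization_factors(m)
  eff <- norm$effective_size[match(colnames(m), norm$sample)]
  common <- geometric_mean(eff)
  nm <- sweep(m, 2, common / eff, `*`)
  list(control = unname(rowMeans(nm[, g == levels(g)[1],
                                    drop = FALSE])),
       exposure = unname(rowMeans(nm[, g == levels(g)[2],
                                     drop = FALSE])))
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' q_(i) = min over j >= i of p_(j) * n / j, capped at 1, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  n <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Differential-coverage test over all windows
#'
#' Runs the full per-window pipeline on a window count matrix:
#' normalization, common-dispersion estimation, the conditional
#' negative binomial exact test, signed log2 fold change and BH FDR.
#'
#' @param window_counts A `window_counts` object (or matrix with a
#'   `windows` tibble passed separately via `windows`).
#' @param groups Sample->group mapping with levels control/exposure.
#' @param dispersion Optional fixed phi; estimated when `NULL`.
#' @param min_total_count Drop windows whose total raw count across
#'   samples is below this (default 0: keep all).
#' @param windows Window tibble when `window_counts` is a bare matrix.
#' @return Tibble with the window columns plus `p_value`, `fdr`,
#'   `log2fc`, `mean_control`, `mean_exposure`, `dispersion_used`.
#' @export
test_windows <- function(window_counts, groups, dispersion = NULL,
                         min_total_count = 0, windows = NULL) {
  if (inherits(window_counts, "window_counts")) {
    windows <- window_counts$windows
    m <- window_counts$counts
  } else {
    m <- as_count_matrix(window_counts)
    if (is.null(windows)) {
      windows <- tibble(feature = rownames(m) %||%
                          paste0("f", seq_len(nrow(m))))
    }
  }
  g <- resolve_groups(groups, colnames(m),
                      levels = c("control", "exposure"))
  keep <- rowSums(m) >= min_total_count
  windows <- windows[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  norm <- normalization_factors(m)
  phi <- dispersion %||%
    as.numeric(estimate_common_dispersion(m, g, norm))
  p <- nb_exact_test(m, g, norm, dispersion = phi)
  mm <- group_means_normalized(m, g, norm)
  windows |>
    mutate(p_value = p,
           fdr = bh_fdr(p),
           log2fc = log2((mm$exposure + 0.5) / (mm$control + 0.5)),
           mean_control = mm$control,
           mean_exposure = mm$exposure,
           dispersion_used = phi)
}
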