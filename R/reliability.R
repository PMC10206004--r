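#' Krippendorff's alpha with an ordinal metric
#'
#' Chance-corrected inter-rater agreement computed from the coincidence
#' matrix, tolerating missing cells: units with at least two non-missing
#' ratings contribute, each pairable value weighted by 1/(m_u - 1). The
#' ordinal difference function is the squared cumulative-margin distance
#' between categories. N/A-family codes (`na_codes`, default 0 and 0.5)
#' are treated as missing for this computation.
#'
#' @param matrix numeric units x raters matrix; `NA` marks missing cells
#' @param level measurement level; only `"ordinal"` is implemented
#' @param na_codes values recoded to missing before computing
#' @return alpha (scalar, at most 1)
#' @export
krippendorff_alpha <- function(matrix, level = "ordinal",
                               na_codes = c(0, 0.5)) {
  level <- match.arg(level, "ordinal")
  m <- as.matrix(matrix)
  m[m %in% na_codes] <- NA
  if (ncol(m) < 2L) stop_contract("at least 2 raters required")
  vals <- sort(unique(stats::na.omit(as.vector(m))))
  if (!length(vals)) stop_contract("all ratings missing; alpha undefined")
  k <- length(vals)
  idx <- matrix(match(m, vals), nrow = nrow(m))

  # coincidence matrix
  o <- matrix(0, k, k)
  for (u in seq_len(nrow(idx))) {
    vu <- idx[u, ]
    vu <- vu[!is.na(vu)]
    mu <- length(vu)
    if (mu < 2L) next
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) o[vu[i], vu[j]] <- o[vu[i], vu[j]] + 1 / (mu - 1)
    }
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  if (n < 2) stop_contract("fewer than two pairable ratings; alpha undefined")

  # ordinal distance: squared sum of margins between the two categories
  delta2 <- matrix(0, k, k)
  for (c1 in seq_len(k)) for (c2 in seq_len(k)) {
    if (c1 == c2) next
    lo <- min(c1, c2); hi <- max(c1, c2)
    delta2[c1, c2] <- (sum(n_c[lo:hi]) - (n_c[c1] + n_c[c2]) / 2)^2
  }
  do_ <- sum(o * delta2) / n
  de_ <- sum(outer(n_c, n_c) * delta2) / (n * (n - 1))
  if (de_ == 0) {
    # no expected disagreement (a single category in use): perfect
    # agreement iff no observed disagreement either
    if (do_ == 0) return(1)
    stop_contract("degenerate rating distribution; alpha undefined")
  }
  1 - do_ / de_
}

#' ICC(2,k): two-way random effects, average measures
#'
#' Computed from the ANOVA mean squares of the units x raters grid after
#' listwise deletion of units with any missing or N/A-family value.
#' Significance is the F test of the row (unit) effect.
#'
#' @param matrix numeric units x raters matrix
#' @param na_codes values treated as not evaluable (dropped listwise)
#' @return list with `icc`, `p`, `n_units`, `k_raters`
#' @export
icc_2k <- function(matrix, na_codes = c(0, 0.5)) {
  m <- as.matrix(matrix)
  m[m %in% na_codes] <- NA
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop_contract("fewer than 3 complete units; ICC undefined")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0) {
    stop_contract("no between-unit variance; ICC degenerate")
  }
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  f <- msr / mse
  p <- if (is.infinite(f) || mse == 0) 0
       else stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p, n_units = n, k_raters = k)
}

#' Per-category Dice coefficients between two raters
#'
#' For each category c: `2 * |both raters = c| / (|r1 = c| + |r2 = c|)`.
#' Categories absent from both raters are omitted.
#'
#' @param r1,r2 equal-length rating vectors (any atomic type)
#' @return named numeric vector of Dice coefficients
#' @export
dice_per_category <- function(r1, r2) {
  if (length(r1) != length(r2)) {
    stop_contract("rating vectors must have equal length")
  }
  cats <- sort(unique(c(r1, r2)))
  out <- vapply(cats, function(ct) {
    a <- r1 == ct; b <- r2 == ct
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NA_real_)
    2 * sum(a & b) / denom
  }, 0)
  names(out) <- as.character(cats)
  out[!is.na(out)]
}

#' Spearman rank correlation on evaluable pairs
#'
#' Excludes pairs where either value is an N/A-family code, then runs the
#' rank correlation with midrank ties and a two-sided p-value.
#'
#' @param x,y paired ordinal vectors
#' @param na_codes codes excluded as not evaluable
#' @return list with `rho`, `p`, `n`
#' @export
spearman_rho <- function(x, y, na_codes = c(0, 0.5)) {
  keep <- !(x %in% na_codes) & !(y %in% na_codes) & !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_contract("fewer than 3 evaluable pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_contract("constant vector; correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
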