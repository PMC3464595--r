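## Differential expression of miRNA counts between two libraries:
## per-million normalization, zero revision, log2 fold-change, and the
## Audic-Claverie exact test on raw counts.

#' Normalize a raw count to reads per million
#'
#' normalized expression = count / total clean reads * 1e6.  Reported tables
#' round to 2 decimals; this function returns full precision.
#'
#' @param count raw read count(s), >= 0
#' @param total clean-read total of the library, > 0
#' @return reads-per-million value(s)
#' @examples
#' normalize_rpm(21, 21985053)   # 0.9552 -> prints as 0.96
#' @export
normalize_rpm <- function(count, total) {
  if (any(total <= 0)) stop("normalize_rpm: total must be positive")
  if (any(count < 0)) stop("normalize_rpm: counts must be non-negative")
  count / total * 1e6
}

#' Revise zero expression values and flag low-expression pairs
#'
#' A normalized value of exactly 0 is revised to 0.01 so that fold-changes
#' stay finite.  A pair in which BOTH values are below 1 (after revision) is
#' excluded from differential analysis as too lowly expressed.
#'
#' @param norm_x,norm_y normalized expression in library 1 and 2 (vectors)
#' @return data.frame with columns \code{norm_x}, \code{norm_y},
#'   \code{excluded}
#' @export
revise_low <- function(norm_x, norm_y) {
  stopifnot(length(norm_x) == length(norm_y))
  if (any(norm_x < 0) || any(norm_y < 0)) stop("revise_low: values must be >= 0")
  norm_x[norm_x == 0] <- 0.01
  norm_y[norm_y == 0] <- 0.01
  data.frame(norm_x = norm_x, norm_y = norm_y,
             excluded = norm_x < 1 & norm_y < 1)
}

#' Log2 fold-change between two normalized values
#'
#' fold-change = log2(norm_y / norm_x), i.e. log2(treatment / control).
#' Zero values must have been revised first (\code{\link{revise_low}}).
#'
#' @param norm_x,norm_y positive normalized expression values
#' @return log2 ratio(s)
#' @export
log2_fold_change <- function(norm_x, norm_y) {
  if (any(norm_x <= 0) || any(norm_y <= 0)) {
    stop("log2_fold_change: inputs must be positive; run revise_low first")
  }
  log2(norm_y / norm_x)
}

## log P(gamma | x) for the Audic-Claverie conditional distribution:
## p(gamma|x) = r^gamma * (x+gamma)! / (x! gamma! (1+r)^(x+gamma+1)),
## r = N2/N1.  Vectorized over gamma, evaluated in log space.
ac_log_pgamma <- function(gamma, x, r) {
  gamma * log(r) + lgamma(x + gamma + 1) - lgamma(x + 1) - lgamma(gamma + 1) -
    (x + gamma + 1) * log1p(r)
}

## Kahan-compensated sum of exp(logp) over a vector, in blocks to bound
## memory for very large y.
ac_tail_sum <- function(x, r, from, to) {
  if (to < from) return(0)
  s <- 0
  comp <- 0
  block <- 1e6
  lo <- from
  while (lo <= to) {
    hi <- min(lo + block - 1, to)
    vals <- exp(ac_log_pgamma(lo:hi, x, r))
    for (v in sum(vals)) { # single block total, compensated accumulate
      y2 <- v - comp
      t2 <- s + y2
      comp <- (t2 - s) - y2
      s <- t2
    }
    lo <- hi + 1
  }
  s
}

#' Audic-Claverie p-value for a count difference between two libraries
#'
#' Exact test for whether raw counts \code{x} and \code{y} of the same tag in
#' two sequencing libraries (clean-read totals \code{N1} and \code{N2}) are
#' consistent with equal underlying expression.  Conditional on \code{x}, the
#' count in library 2 follows
#' \deqn{p(\gamma|x) = r^{\gamma}\,(x+\gamma)!\,/\,(x!\,\gamma!\,(1+r)^{x+\gamma+1})}
#' with \eqn{r = N_2/N_1}.  The lower tail is \eqn{C=\sum_{\gamma\le y}
#' p(\gamma|x)}, the upper tail \eqn{D=\sum_{\gamma\ge y} p(\gamma|x)}
#' (evaluated as \eqn{1-\sum_{\gamma<y}} with compensated summation); the
#' two-sided p-value is \eqn{\min(1, 2\min(C, D))}.  Both tails include the
#' observed \code{y}, so the test is conservative.  All terms are computed
#' through \code{lgamma} in log space, so large library counts are safe.
#'
#' Because the choice of conditioning library is arbitrary, the default
#' p-value averages the two conditioning orientations (on \code{x} and, with
#' the ratio inverted, on \code{y}); the average is exactly invariant under a
#' library swap.  \code{orientation} exposes the raw single-orientation
#' forms.
#'
#' @param x,y non-negative integer raw counts in library 1 and 2
#' @param N1,N2 clean-read totals of library 1 and 2
#' @param orientation \code{"average"} (default), or condition on \code{"x"}
#'   or \code{"y"} only
#' @param tails if \code{TRUE} return a list with the orientation-x tails and
#'   both orientation p-values alongside the reported p-value
#' @return two-sided p-value in (0, 1], or a list when \code{tails = TRUE}
#' @examples
#' ac_pvalue(5, 50, 1e6, 1e6)
#' @export
ac_pvalue <- function(x, y, N1, N2, orientation = c("average", "x", "y"),
                      tails = FALSE) {
  orientation <- match.arg(orientation)
  if (length(x) != 1 || length(y) != 1) stop("ac_pvalue: x and y must be scalars")
  if (x < 0 || y < 0) stop("ac_pvalue: counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("ac_pvalue: library totals must be positive")
  if (x != round(x) || y != round(y)) stop("ac_pvalue: counts must be integers")
  one_sided <- function(x, y, r) {
    lower <- min(1, ac_tail_sum(x, r, 0, y))
    upper <- if (y == 0) 1 else max(0, 1 - ac_tail_sum(x, r, 0, y - 1))
    list(p = min(1, 2 * min(lower, upper)), lower = lower, upper = upper)
  }
  ox <- one_sided(x, y, N2 / N1)
  oy <- one_sided(y, x, N1 / N2)
  p <- switch(orientation,
              average = (ox$p + oy$p) / 2,
              x = ox$p, y = oy$p)
  if (tails) {
    list(p = p, lower = ox$lower, upper = ox$upper,
         p_cond_x = ox$p, p_cond_y = oy$p)
  } else {
    p
  }
}

#' Build and call differential expression records
#'
#' Runs the full differential pipeline on a table of per-tag raw counts:
#' normalization to reads per million, zero revision, exclusion of pairs with
#' both values below 1, log2 fold-change, Audic-Claverie p-value on the raw
#' counts, and the significance call.  A record is significant when the
#' linear fold-change exceeds \code{fold_threshold} (in either direction) and
#' the p-value is below \code{alpha}; \code{sig_label} is \code{"**"} below
#' 0.01 and \code{"*"} below \code{alpha}.
#'
#' @param counts data.frame with columns \code{name}, \code{x} (library 1 raw
#'   count) and \code{y} (library 2 raw count)
#' @param N1,N2 clean-read totals of the two libraries
#' @param fold_threshold linear fold-change threshold (default 1.5)
#' @param alpha significance level (default 0.05)
#' @param fold_on \code{"linear"} compares \code{max(ratio, 1/ratio)} with
#'   \code{fold_threshold}; \code{"log2"} compares \code{|log2fc|}
#' @return data.frame of DE records: \code{name, x, y, norm_x, norm_y,
#'   log2fc, pvalue, mode, sig_label, significant, excluded}; excluded
#'   records carry \code{NA} fold-change and p-value
#' @export
call_differential <- function(counts, N1, N2, fold_threshold = 1.5,
                              alpha = 0.05, fold_on = c("linear", "log2")) {
  fold_on <- match.arg(fold_on)
  stopifnot(all(c("name", "x", "y") %in% names(counts)))
  n <- nrow(counts)
  norm_x <- normalize_rpm(counts$x, N1)
  norm_y <- normalize_rpm(counts$y, N2)
  rv <- revise_low(norm_x, norm_y)
  log2fc <- pvalue <- rep(NA_real_, n)
  mode <- rep(NA_character_, n)
  sig <- rep(FALSE, n)
  keep <- !rv$excluded
  if (any(keep)) {
    log2fc[keep] <- log2_fold_change(rv$norm_x[keep], rv$norm_y[keep])
    pvalue[keep] <- vapply(which(keep), function(i) {
      ac_pvalue(counts$x[i], counts$y[i], N1, N2)
    }, numeric(1))
    mode[keep] <- ifelse(log2fc[keep] > 0, "Up", "Down")
    fold_ok <- if (fold_on == "linear") {
      ratio <- rv$norm_y[keep] / rv$norm_x[keep]
      pmax(ratio, 1 / ratio) > fold_threshold
    } else {
      abs(log2fc[keep]) > log2(fold_threshold)
    }
    sig[keep] <- fold_ok & pvalue[keep] < alpha
  }
  sig_label <- rep("", n)
  sig_label[sig & pvalue < alpha] <- "*"
  sig_label[sig & pvalue < 0.01] <- "**"
  data.frame(
    name = counts$name, x = counts$x, y = counts$y,
    norm_x = rv$norm_x, norm_y = rv$norm_y,
    log2fc = log2fc, pvalue = pvalue, mode = mode,
    sig_label = sig_label, significant = sig, excluded = rv$excluded,
    stringsAsFactors = FALSE
  )
}

#' Format DE records as a report table
#'
#' Rounds normalized values and fold-changes to 2 decimals (half-up) for the
#' printed table; the input records keep full precision.
#'
#' @param records output of \code{\link{call_differential}}
#' @return data.frame ready for TSV export
#' @export
format_de_table <- function(records) {
  data.frame(
    name = records$name,
    counts_1 = records$x, normalised_1 = round_half_up(records$norm_x, 2),
    counts_2 = records$y, normalised_2 = round_half_up(records$norm_y, 2),
    log2fc = round_half_up(records$log2fc, 2),
    pvalue = signif(records$pvalue, 3),
    mode = records$mode, sig_label = records$sig_label,
    stringsAsFactors = FALSE
  )
}
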