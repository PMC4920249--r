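#' Pair common peaks between two samples
#'
#' Finds all pairs of peaks overlapping by at least one base between sample A
#' and sample B, carrying each sample's own count into the pair. A peak
#' overlapping k peaks in the other sample yields k pairs. For every pair the
#' minus (`m = count_a - count_b`) and average (`a = (count_a + count_b)/2`)
#' coordinates are computed on the raw, non-log counts — the coordinates the
#' MA normalization model is fitted in.
#'
#' @param peaks_a,peaks_b Data frames with `chrom`, `start`, `end`, `count`.
#' @return A tibble with one row per overlapping pair: indices into each
#'   input (`index_a`, `index_b`), both regions' coordinates, `count_a`,
#'   `count_b`, `m` and `a`.
#' @export
common_peaks <- function(peaks_a, peaks_b) {
  pa <- validate_intervals(peaks_a, "peaks_a")
  pb <- validate_intervals(peaks_b, "peaks_b")
  for (nm in list(c("peaks_a", "count"), c("peaks_b", "count"))) {
    obj <- if (nm[1] == "peaks_a") pa else pb
    if (nrow(obj) > 0 && !"count" %in% names(obj)) {
      abort(sprintf("`%s` needs a `count` column", nm[1]))
    }
  }
  empty <- tibble(
    index_a = integer(), index_b = integer(),
    chrom = character(), start_a = numeric(), end_a = numeric(),
    start_b = numeric(), end_b = numeric(),
    count_a = numeric(), count_b = numeric(), m = numeric(), a = numeric()
  )
  if (nrow(pa) == 0 || nrow(pb) == 0) return(empty)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges(pa), as_granges(pb),
    minoverlap = 1L, ignore.strand = TRUE
  ))
  if (length(hits) == 0) return(empty)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  tibble(
    index_a = i, index_b = j,
    chrom = pa$chrom[i],
    start_a = pa$start[i], end_a = pa$end[i],
    start_b = pb$start[j], end_b = pb$end[j],
    count_a = pa$count[i], count_b = pb$count[j],
    m = pa$count[i] - pb$count[j],
    a = (pa$count[i] + pb$count[j]) / 2
  )
}

#' Fit the minus-average normalization model
#'
#' Fits the linear model `m = beta0 + beta1 * a` on the non-log count
#' difference (M) versus count average (A) over peaks common to two samples.
#' This is the non-log variant of MAnorm-style between-sample normalization:
#' the fitted trend captures the systematic count bias of sample B relative
#' to sample A and is later subtracted out by [ma_normalize()].
#'
#' `method = "robust"` uses iteratively reweighted M-estimation with Huber
#' weights (tuning constant 1.345, convergence tolerance 1e-8, at most 50
#' iterations); `method = "ols"` is the ordinary least-squares solution. The
#' robust fit downweights genuinely differential peaks so they do not drag
#' the normalization line; it is the default.
#'
#' @param pairs Output of [common_peaks()] (or any data frame with `m` and
#'   `a` columns).
#' @param method `"robust"` or `"ols"`.
#' @param min_common Minimum number of common-peak pairs required (default
#'   10); below this the fit refuses rather than extrapolating.
#' @return An object of class `ma_model`: list with `intercept`, `slope`,
#'   `method`, `n_common`. Supports [tidy()] and [glance()].
#' @export
fit_ma_model <- function(pairs, method = c("robust", "ols"), min_common = 10) {
  method <- match.arg(method)
  if (!is.data.frame(pairs) || !all(c("m", "a") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns `m` and `a`")
  }
  if (nrow(pairs) < min_common) {
    abort(sprintf(
      "insufficient common peaks: %d pairs, need at least %d",
      nrow(pairs), min_common
    ))
  }
  if (stats::var(pairs$a) == 0) {
    abort("zero variance in the average coordinate `a`: model is unidentifiable")
  }
  ols <- lm(m ~ a, data = pairs)
  if (method == "ols") {
    cf <- coef(ols)
    sigma <- stats::sigma(ols)
  } else if (sum(abs(stats::residuals(ols))) < 1e-10) {
    # perfect linear relation: the M-estimate coincides with OLS, and the
    # IRLS scale estimate would degenerate at 0
    cf <- coef(ols)
    sigma <- 0
  } else {
    fit <- MASS::rlm(m ~ a,
      data = pairs, psi = MASS::psi.huber, k = 1.345,
      maxit = 50, acc = 1e-8
    )
    cf <- coef(fit)
    sigma <- fit$s
  }
  structure(
    list(
      intercept = unname(cf[1]), slope = unname(cf[2]),
      method = method, n_common = nrow(pairs), sigma = sigma
    ),
    class = "ma_model"
  )
}

#' @export
print.ma_model <- function(x, ...) {
  cat(sprintf(
    "MA normalization model (%s fit, %d common peaks)\n  m = %.4f + %.4f * a\n",
    x$method, x$n_common, x$intercept, x$slope
  ))
  invisible(x)
}

#' @rdname fit_ma_model
#' @param x An `ma_model` object.
#' @param ... Unused.
#' @export
tidy.ma_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "a"), estimate = c(x$intercept, x$slope))
}

#' @rdname fit_ma_model
#' @export
glance.ma_model <- function(x, ...) {
  tibble(
    n_common = x$n_common, method = x$method,
    intercept = x$intercept, slope = x$slope, sigma = x$sigma
  )
}

#' Adjust sample-B counts with a fitted MA model
#'
#' Applies the fitted minus-average trend to sample B: each region's count
#' becomes `count + (beta0 + beta1 * a_i)`, floored at zero. For regions that
#' took part in common-peak pairs, `a_i` is the mean of the pair average
#' coordinates the region participated in; regions unique to sample B fall
#' back to `a_i = count` and are flagged `paired = FALSE`. After adjustment,
#' refitting the model on the common pairs yields an intercept and slope at
#' numerical zero.
#'
#' @param peaks_b Data frame of sample-B peaks with a `count` column.
#' @param model A fitted [fit_ma_model()] object.
#' @param pairs Output of [common_peaks()] used for the fit; pass `NULL` to
#'   treat every region as unpaired.
#' @return `peaks_b` with added columns `a_used`, `paired` and
#'   `adjusted_count`.
#' @export
ma_normalize <- function(peaks_b, model, pairs = NULL) {
  if (!inherits(model, "ma_model")) abort("`model` must be an `ma_model`")
  pb <- validate_intervals(peaks_b, "peaks_b")
  if (nrow(pb) > 0 && !"count" %in% names(pb)) {
    abort("`peaks_b` needs a `count` column")
  }
  out <- as_tibble(peaks_b)
  if (nrow(out) == 0) {
    return(mutate(out,
      a_used = numeric(0), paired = logical(0), adjusted_count = numeric(0)
    ))
  }
  a_used <- pb$count
  paired <- rep(FALSE, nrow(pb))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    by_b <- pairs |>
      group_by(.data$index_b) |>
      summarise(a_mean = mean(.data$a), .groups = "drop")
    a_used[by_b$index_b] <- by_b$a_mean
    paired[by_b$index_b] <- TRUE
  }
  mutate(out,
    a_used = a_used,
    paired = paired,
    adjusted_count = pmax(0, .data$count + model$intercept + model$slope * a_used)
  )
}

#' One-step MA normalization of two peak sets
#'
#' Convenience wrapper: pairs the common peaks, fits the MA model, and
#' adjusts sample B toward sample A (the reference).
#'
#' @inheritParams common_peaks
#' @inheritParams fit_ma_model
#' @return A list with elements `pairs`, `model` and `adjusted` (sample B
#'   with `adjusted_count`).
#' @export
manorm <- function(peaks_a, peaks_b, method = c("robust", "ols"),
                   min_common = 10) {
  pairs <- common_peaks(peaks_a, peaks_b)
  model <- fit_ma_model(pairs, method = method, min_common = min_common)
  adjusted <- ma_normalize(peaks_b, model, pairs)
  list(pairs = pairs, model = model, adjusted = adjusted)
}
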