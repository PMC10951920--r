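#' Equal-width bins over the pooled range of all conditions
#'
#' Frequency distributions from different conditions are only comparable
#' when binned on a common scale, so the edges span the min..max of the
#' values pooled across every condition. Bins are left-inclusive /
#' right-exclusive except the last, which is right-inclusive so the pooled
#' maximum is counted.
#'
#' @param values numeric vector: all values from all conditions combined.
#' @param n_bins number of bins (10 for confinement ratios, 12 for
#'   diffusion coefficients in the motivating analysis).
#' @return object of class `binning_scheme`: list with `edges` (length
#'   n_bins + 1), `n_bins`, and an empty `categories` slot.
#' @export
pooled_range_bins <- function(values, n_bins) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop_gliotrack("need >= 2 distinct values to define a range",
                   "gliotrack_validation_error")
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  structure(list(edges = edges, n_bins = as.integer(n_bins),
                 categories = NULL),
            class = "binning_scheme")
}

#' Explicit-edge binning scheme
#'
#' @param edges strictly increasing breakpoints.
#' @return a `binning_scheme`.
#' @export
binning_scheme <- function(edges) {
  if (any(diff(edges) <= 0))
    stop_gliotrack("edges must be strictly increasing",
                   "gliotrack_validation_error")
  structure(list(edges = edges, n_bins = length(edges) - 1L,
                 categories = NULL),
            class = "binning_scheme")
}

bin_index <- function(values, scheme) {
  e <- scheme$edges
  i <- findInterval(values, e, rightmost.closed = TRUE)
  i[values < e[1] | values > e[length(e)]] <- NA_integer_
  i
}

#' Frequency distribution over a binning scheme
#'
#' Percent of the particle population per bin. `drop_first_bin` mirrors the
#' plotting convention for heavily zero-inflated quantities: the first bin
#' is excluded from the *graphed* percentages only, while `n_total` (the
#' denominator and the statistical population) still includes it. Values
#' outside the edges are counted in `n_out_of_range`.
#'
#' @param values numeric vector.
#' @param scheme a [binning_scheme()].
#' @param drop_first_bin exclude bin 1 from the graphed output
#'   (default FALSE).
#' @return object of class `frequency_distribution`: list with `counts`,
#'   `percent` (of n_total, all bins), `graphed` (data.frame of the bins
#'   shown, honouring `drop_first_bin`), `n_total`, `n_out_of_range`.
#' @export
frequency_distribution <- function(values, scheme, drop_first_bin = FALSE) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (!length(values))
    stop_gliotrack("no values to bin (n_total = 0)",
                   "gliotrack_validation_error")
  i <- bin_index(values, scheme)
  counts <- tabulate(i[!is.na(i)], nbins = scheme$n_bins)
  n_total <- length(values)
  percent <- 100 * counts / n_total
  shown <- if (drop_first_bin) seq_len(scheme$n_bins)[-1] else
    seq_len(scheme$n_bins)
  graphed <- data.frame(bin = shown,
                        lower = scheme$edges[shown],
                        upper = scheme$edges[shown + 1L],
                        percent = percent[shown])
  structure(list(scheme = scheme, counts = counts, percent = percent,
                 graphed = graphed, n_total = n_total,
                 n_out_of_range = sum(is.na(i)),
                 drop_first_bin = drop_first_bin),
            class = "frequency_distribution")
}

#' Attach qualitative category labels to bins
#'
#' Splits the bins into three contiguous groups (e.g. slow / intermediate /
#' fast diffusion, or high / medium / light confinement). Categories are a
#' visualization aid only: no statistic in this package consumes them, so
#' changing the boundaries cannot change any test result.
#'
#' @param scheme a [binning_scheme()].
#' @param boundaries integer pair (b1, b2): bins 1..b1 get the first label,
#'   b1+1..b2 the second, b2+1..n_bins the third. Default: equal thirds.
#' @param labels category names, length 3.
#' @return the scheme with a `categories` character vector (one label per
#'   bin).
#' @export
assign_categories <- function(scheme,
                              boundaries = round(scheme$n_bins * c(1, 2) / 3),
                              labels = c("slow", "intermediate", "fast")) {
  stopifnot(inherits(scheme, "binning_scheme"))
  b1 <- boundaries[1]; b2 <- boundaries[2]
  if (!(b1 >= 1 && b2 > b1 && b2 < scheme$n_bins))
    stop_gliotrack("boundaries must split the bins into 3 contiguous non-empty groups",
                   "gliotrack_config_error")
  scheme$categories <- c(rep(labels[1], b1), rep(labels[2], b2 - b1),
                         rep(labels[3], scheme$n_bins - b2))
  scheme
}

#' Fraction of values falling in a labelled category
#'
#' @param values numeric vector.
#' @param scheme a [binning_scheme()] with categories assigned.
#' @param label which category.
#' @return fraction of in-range values whose bin carries `label`.
#' @export
category_fraction <- function(values, scheme, label) {
  if (is.null(scheme$categories))
    stop_gliotrack("scheme has no categories; call assign_categories() first",
                   "gliotrack_config_error")
  i <- bin_index(values, scheme)
  i <- i[!is.na(i)]
  if (!length(i)) return(0)
  mean(scheme$categories[i] == label)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function, evaluable at arbitrary points
#' (a thin wrapper over [stats::ecdf()]).
#'
#' @param values numeric vector, length >= 1.
#' @return a function F(x) with F(x) = P(X <= x), max 1.
#' @export
ecdf_fun <- function(values) {
  if (!length(values))
    stop_gliotrack("ecdf needs >= 1 value", "gliotrack_validation_error")
  stats::ecdf(values)
}
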