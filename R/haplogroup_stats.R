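#' Sample-size-weighted pooling of haplogroup frequencies
#'
#' Pooled frequency of a haplogroup over several population groups:
#' `sum(n_i * f_i) / sum(n_i)`, reported at one decimal place — the
#' convention of published frequency tables. The pooled value is a convex
#' combination and always lies between the smallest and largest input.
#'
#' @param freqs Per-group frequencies in percent.
#' @param sizes Per-group sample sizes (positive).
#' @param digits Decimal places for the report (default 1).
#' @return Pooled frequency (%).
#' @export
pooled_frequency <- function(freqs, sizes, digits = 1) {
  if (length(freqs) != length(sizes)) stop("freqs and sizes differ in length")
  if (length(freqs) == 0L) stop("at least one group is required")
  if (any(sizes <= 0)) stop("sizes must be positive")
  round(sum(sizes * freqs) / sum(sizes), digits)
}

#' Chi-squared homogeneity test of haplogroup spectra
#'
#' Pearson chi-squared test of homogeneity on a populations x haplogroups
#' contingency table of counts, df = (r-1)(c-1), no continuity correction.
#' Haplogroup categories whose expected count under homogeneity falls
#' below 1 in any cell are merged into an `"other"` column before testing,
#' so the large-sample approximation is not applied to near-empty
#' categories.
#'
#' @param counts Matrix of non-negative integer counts, rows = populations,
#'   columns = haplogroups (at least 2 x 2).
#' @return List: `statistic`, `df`, `p_value`, `table_used` (the table
#'   actually tested, after merging), `merged` (names of merged columns).
#' @export
chi2_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 populations and 2 haplogroups")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero table")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("hg", seq_len(ncol(counts)))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low <- which(apply(expected, 2L, min) < 1)
  merged <- character()
  if (length(low) && length(low) < ncol(counts)) {
    merged <- colnames(counts)[low]
    other <- rowSums(counts[, low, drop = FALSE])
    counts <- cbind(counts[, -low, drop = FALSE], other = other)
  }
  if (ncol(counts) < 2L) stop("fewer than 2 haplogroup categories after merging")
  # degenerate but legal inputs (e.g. proportional rows) give statistic 0
  tst <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(tst$statistic), df = unname(tst$parameter),
       p_value = unname(tst$p.value), table_used = counts, merged = merged)
}

#' Share of a haplogroup's carriers on two branches
#'
#' `(freq_a + freq_b) / total * 100`, integer-rounded: the percentage of a
#' haplogroup's carriers accounted for by two of its branches.
#'
#' @param freq_a,freq_b Branch frequencies (%).
#' @param total Total haplogroup frequency (%), positive.
#' @return Integer percentage.
#' @export
branch_share <- function(freq_a, freq_b, total) {
  if (any(total <= 0)) stop("total frequency must be positive")
  round((freq_a + freq_b) / total * 100)
}

#' Read a haplogroup frequency table
#'
#' Expects a TSV with a `haplogroup` column followed by one column per
#' population group; a row with haplogroup `n` carries the per-group sample
#' sizes. Frequencies are percentages. Cells above 100 are impossible and
#' flagged with a warning (likely misprints, e.g. a lost decimal point) —
#' they are reported, never silently corrected.
#'
#' @param path TSV path.
#' @return List of class `freq_table`: `freq` (matrix haplogroups x groups,
#'   %), `sizes` (named per-group n), `flagged` (impossible cells).
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"haplogroup" %in% names(df)) stop("missing haplogroup column")
  n_row <- df$haplogroup == "n"
  if (!any(n_row)) stop("missing sample-size row (haplogroup == 'n')")
  groups <- setdiff(names(df), "haplogroup")
  sizes <- unlist(df[n_row, groups][1, ])
  f <- as.matrix(df[!n_row, groups, drop = FALSE])
  rownames(f) <- df$haplogroup[!n_row]
  bad <- which(f > 100, arr.ind = TRUE)
  flagged <- if (nrow(bad)) tibble::tibble(
    haplogroup = rownames(f)[bad[, 1]], group = groups[bad[, 2]],
    value = f[bad]) else tibble::tibble(
      haplogroup = character(), group = character(), value = numeric())
  if (nrow(flagged))
    warning(nrow(flagged), " frequency cell(s) exceed 100% (probable misprint): ",
            paste(sprintf("%s/%s=%g", flagged$haplogroup, flagged$group,
                          flagged$value), collapse = ", "))
  structure(list(freq = f, sizes = sizes, groups = groups, flagged = flagged),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d haplogroups x %d groups (n = %s)\n",
              nrow(x$freq), length(x$groups),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}
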