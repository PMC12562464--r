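#' Construct a haplotype set
#'
#' A haplotype set couples a matrix of integer repeat counts (one row per
#' sample, one column per expanded panel locus, `NA` for missing calls) with
#' per-sample metadata and the [locus_panel] the repeats refer to. It is the
#' container every downstream stage (networks, dating, cluster screening)
#' accepts.
#'
#' @param repeats Integer matrix, rows = samples, columns = `panel$loci`.
#' @param meta Data frame with one row per sample: `sample_id` (unique),
#'   `population`, `district`, `ancient` (logical), `ancient_date`
#'   (free-text date range, `""` for modern samples) and `snp_branch` (Y-SNP
#'   branch label, possibly hierarchical with `>` separators, `""` if
#'   untyped). Missing metadata columns are filled with defaults.
#' @param panel A [locus_panel].
#' @param provenance Free-text source note.
#' @return Object of class `haplotype_set`.
#' @export
haplotype_set <- function(repeats, meta, panel, provenance = "") {
  stopifnot(inherits(panel, "locus_panel"))
  repeats <- as.matrix(repeats)
  if (is.null(colnames(repeats)) || !identical(colnames(repeats), panel$loci)) {
    if (!is.null(colnames(repeats)) && all(panel$loci %in% colnames(repeats)))
      repeats <- repeats[, panel$loci, drop = FALSE]
    else stop("repeat matrix columns must match the panel loci")
  }
  storage.mode(repeats) <- "integer"
  meta <- tibble::as_tibble(meta)
  if (!"sample_id" %in% names(meta)) stop("meta must contain sample_id")
  meta$sample_id <- as.character(meta$sample_id)
  if (nrow(meta) != nrow(repeats))
    stop("meta and repeats disagree on the number of samples")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  for (cl in c("population", "district", "snp_branch", "ancient_date"))
    if (!cl %in% names(meta)) meta[[cl]] <- ""
  if (!"ancient" %in% names(meta)) meta$ancient <- FALSE
  meta$ancient <- as.logical(meta$ancient)
  rownames(repeats) <- meta$sample_id
  structure(list(panel = panel, repeats = repeats,
                 meta = meta[, c("sample_id", "population", "district",
                                 "ancient", "ancient_date", "snp_branch")],
                 provenance = provenance),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes x %d loci\n",
              nrow(x$repeats), x$panel$L))
  tab <- table(x$meta$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (any(x$meta$ancient)) cat("  ancient samples:", sum(x$meta$ancient), "\n")
  invisible(x)
}

#' Number of haplotypes in a set
#' @param hs A [haplotype_set].
#' @export
n_haplotypes <- function(hs) nrow(hs$repeats)

#' Subset a haplotype set by row index or sample id
#' @param hs A [haplotype_set].
#' @param i Integer/logical index or character sample ids.
#' @export
subset_haplotypes <- function(hs, i) {
  if (is.character(i)) i <- match(i, hs$meta$sample_id)
  haplotype_set(hs$repeats[i, , drop = FALSE], hs$meta[i, , drop = FALSE],
                hs$panel, hs$provenance)
}

#' Read a Y-STR haplotype table
#'
#' Reads a delimited text table (TSV or CSV, auto-detected from the header
#' line) with one row per sample. Expected columns: `sample_id`, optional
#' `population`, `district`, `ancient`, `snp_branch`, then one column per
#' panel marker. Multi-copy markers hold both repeat values joined by `-`
#' (e.g. `"11-14"`); a lone value is taken as homoallelic. Alleles that are
#' not positive integers (intermediate alleles such as `"15.2"`,
#' micro-variants, blanks) are recorded as missing at that locus — never
#' rounded — and reported in a single warning; the full list is kept in the
#' set's `parse_log` attribute.
#'
#' @param path Path to the table.
#' @param panel A [locus_panel] (default: the 37-locus panel).
#' @return A [haplotype_set]. Unknown columns raise a warning and are
#'   ignored; a duplicated `sample_id` or an empty file is an error.
#' @export
read_haplotypes <- function(path, panel = default_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty haplotype file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("haplotype file contains no samples: ", path)
  if (!"sample_id" %in% names(df)) stop("missing required column sample_id")
  meta_cols <- c("sample_id", "population", "district", "ancient",
                 "ancient_date", "snp_branch")
  unknown <- setdiff(names(df), c(meta_cols, panel$columns))
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(panel$columns, names(df))
  if (length(absent))
    warning("panel marker(s) absent from table, treated as missing: ",
            paste(absent, collapse = ", "))

  n <- nrow(df)
  rep_mat <- matrix(NA_integer_, n, panel$L, dimnames = list(NULL, panel$loci))
  log <- list()
  parse_int <- function(x) {
    ok <- grepl("^\\s*[0-9]+\\s*$", x)
    out <- rep(NA_integer_, length(x))
    out[ok] <- as.integer(x[ok])
    out
  }
  for (cl in intersect(panel$columns, names(df))) {
    raw <- trimws(df[[cl]])
    if (cl %in% panel$multicopy) {
      parts <- strsplit(raw, "-", fixed = TRUE)
      vals <- lapply(parts, parse_int)
      bad <- vapply(seq_len(n), function(i) {
        nz <- nzchar(raw[i])
        nz && (anyNA(vals[[i]]) || length(vals[[i]]) > 2L)
      }, logical(1))
      for (i in seq_len(n)) {
        if (!nzchar(raw[i]) || bad[i]) next
        v <- sort(vals[[i]])
        if (length(v) == 1L) v <- c(v, v)
        rep_mat[i, paste0(cl, c("a", "b"))] <- v
      }
      if (any(bad))
        log[[cl]] <- data.frame(sample_id = df$sample_id[bad], locus = cl,
                                value = raw[bad])
    } else {
      v <- parse_int(raw)
      bad <- nzchar(raw) & is.na(v)
      rep_mat[, cl] <- v
      if (any(bad))
        log[[cl]] <- data.frame(sample_id = df$sample_id[bad], locus = cl,
                                value = raw[bad])
    }
  }
  plog <- if (length(log)) do.call(rbind, log) else
    data.frame(sample_id = character(), locus = character(), value = character())
  if (nrow(plog))
    warning(sprintf("%d allele(s) were not positive integers and were set missing (see attr(, 'parse_log'))",
                    nrow(plog)))
  meta <- tibble::tibble(
    sample_id = df$sample_id,
    population = if ("population" %in% names(df)) df$population else "",
    district = if ("district" %in% names(df)) df$district else "",
    snp_branch = if ("snp_branch" %in% names(df)) df$snp_branch else "")
  anc_raw <- if ("ancient" %in% names(df)) trimws(df$ancient) else rep("", n)
  meta$ancient <- !(anc_raw %in% c("", "0", "no", "NO", "FALSE", "false", "NA"))
  meta$ancient_date <- ifelse(meta$ancient &
                                !(anc_raw %in% c("1", "yes", "YES", "TRUE", "true")),
                              anc_raw, "")
  hs <- haplotype_set(rep_mat, meta, panel, provenance = path)
  attr(hs, "parse_log") <- plog
  hs
}

#' Write a haplotype set to a TSV file
#'
#' Inverse of [read_haplotypes()]: multi-copy alleles are joined with `-`,
#' missing alleles written as empty fields. A write-then-read round trip
#' reproduces repeats, metadata and panel assignment exactly.
#'
#' @param hs A [haplotype_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hs, path) {
  stopifnot(inherits(hs, "haplotype_set"))
  p <- hs$panel
  out <- data.frame(sample_id = hs$meta$sample_id,
                    population = hs$meta$population,
                    district = hs$meta$district,
                    ancient = ifelse(hs$meta$ancient,
                                     ifelse(nzchar(hs$meta$ancient_date),
                                            hs$meta$ancient_date, "yes"), ""),
                    snp_branch = hs$meta$snp_branch,
                    check.names = FALSE, stringsAsFactors = FALSE)
  fmt <- function(v) ifelse(is.na(v), "", as.character(v))
  for (cl in p$columns) {
    if (cl %in% p$multicopy) {
      a <- hs$repeats[, paste0(cl, "a")]
      b <- hs$repeats[, paste0(cl, "b")]
      out[[cl]] <- ifelse(is.na(a) & is.na(b), "",
                   ifelse(is.na(b), fmt(a),
                   ifelse(is.na(a), fmt(b), paste0(a, "-", b))))
    } else out[[cl]] <- fmt(hs$repeats[, cl])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a haplotype set
#'
#' Report-only check of the data-model invariants: per-locus missingness,
#' per-population sample counts, and individual repeat values violating the
#' positive-integer requirement. A set with zero errors is accepted by all
#' downstream operations. Validation is idempotent and has no side effects.
#'
#' @param hs A [haplotype_set].
#' @return Object of class `strclock_validation`: list with `errors`
#'   (tibble: sample_id, locus, problem), `locus_missingness`,
#'   `population_counts` and `n_errors`.
#' @export
validate_haplotypes <- function(hs) {
  stopifnot(inherits(hs, "haplotype_set"))
  rep_mat <- hs$repeats
  bad <- which(!is.na(rep_mat) & rep_mat <= 0L, arr.ind = TRUE)
  errors <- tibble::tibble(
    sample_id = hs$meta$sample_id[bad[, 1]],
    locus = colnames(rep_mat)[bad[, 2]],
    problem = sprintf("non-positive repeat count (%d)", rep_mat[bad]))
  miss <- colSums(is.na(rep_mat))
  tab <- table(hs$meta$population)
  structure(list(
    errors = errors,
    n_errors = nrow(errors),
    locus_missingness = tibble::tibble(
      locus = colnames(rep_mat), n_missing = as.integer(miss),
      pct_missing = round(100 * miss / nrow(rep_mat), 1)),
    population_counts = tibble::tibble(
      population = names(tab), n = as.integer(tab)),
    n_samples = nrow(rep_mat)),
    class = "strclock_validation")
}

#' @export
print.strclock_validation <- function(x, ...) {
  cat(sprintf("<validation> %d samples, %d error(s)\n", x$n_samples, x$n_errors))
  if (x$n_errors) print(x$errors)
  cat("population counts:\n")
  print(x$population_counts)
  invisible(x)
}
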