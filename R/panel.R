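#' Define a Y-STR locus panel
#'
#' A locus panel names the markers a haplotype is typed at, carries the
#' per-locus mutation rate used by both molecular clocks, and records which
#' markers are multi-copy (DYS385-type markers that report two repeat values
#' from duplicated loci). Multi-copy markers are expanded internally into
#' sorted per-copy pseudo-loci (`<name>a`, `<name>b`); each copy counts as
#' one locus in `L`, which is the convention under which a 37-marker panel
#' with DYS385 a/b and DYF387S1 a/b comprises 33 single-copy markers plus
#' two duplicated ones.
#'
#' @param loci Character vector of marker (column) names, unique.
#' @param mu Per-locus mutation rate in mutations/locus/generation. Either a
#'   single value applied uniformly (default 0.0039, the average rate for a
#'   37-marker Y-STR panel) or a vector named by marker.
#' @param multicopy Character vector of marker names carrying two repeat
#'   values (subset of `loci`).
#' @return An object of class `locus_panel` with fields `columns` (marker
#'   names as they appear in haplotype tables), `multicopy`, `loci` (expanded
#'   per-copy locus names), `mu` (named rate per expanded locus) and `L`
#'   (expanded locus count).
#' @examples
#' p <- locus_panel(c("DYS19", "DYS385"), multicopy = "DYS385")
#' p$L  # 3: DYS19, DYS385a, DYS385b
#' @export
locus_panel <- function(loci, mu = 0.0039, multicopy = character()) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (length(loci) == 0L) stop("panel must contain at least one locus")
  if (!all(multicopy %in% loci)) stop("multicopy markers must be panel loci")
  expanded <- unlist(lapply(loci, function(l) {
    if (l %in% multicopy) paste0(l, c("a", "b")) else l
  }), use.names = FALSE)
  if (length(mu) == 1L) {
    mu_exp <- stats::setNames(rep(as.numeric(mu), length(expanded)), expanded)
  } else {
    if (is.null(names(mu)) || !all(loci %in% names(mu)))
      stop("a vector `mu` must be named by marker and cover every locus")
    col_of <- column_of_locus(expanded, loci, multicopy)
    mu_exp <- stats::setNames(as.numeric(mu[col_of]), expanded)
  }
  if (any(!is.finite(mu_exp)) || any(mu_exp <= 0))
    stop("all mutation rates must be positive")
  structure(
    list(columns = loci, multicopy = as.character(multicopy),
         loci = expanded, mu = mu_exp, L = length(expanded)),
    class = "locus_panel")
}

# map expanded locus names back to their table column
column_of_locus <- function(expanded, columns, multicopy) {
  out <- expanded
  for (m in multicopy) out[out %in% paste0(m, c("a", "b"))] <- m
  stopifnot(all(out %in% columns))
  out
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("<locus_panel> %d markers (%d loci incl. multicopy copies)\n",
              length(x$columns), x$L))
  cat(sprintf("  mean mutation rate: %.4g /locus/generation\n", mean(x$mu)))
  if (length(x$multicopy))
    cat("  multicopy:", paste(x$multicopy, collapse = ", "), "\n")
  invisible(x)
}

#' Default 37-locus Y-STR panel
#'
#' The union of the Yfiler Plus and PowerPlex Y23 marker sets plus eight
#' additional single markers (DYS504, DYS525, DYS552, DYS505, DYS537,
#' DYS445, Y-GATA-A10, GGAAT1B07), for 37 loci in total counting the two
#' copies of DYS385 and DYF387S1. The panel definition ships as a plain-text
#' configuration file and is fully user-overridable; the uniform average
#' mutation rate is 0.0039 per locus per generation.
#'
#' @return A [locus_panel].
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "panel_37.yaml", package = "strclock"))
}

#' Read / write a locus panel configuration file
#'
#' The panel file is YAML: top-level `mu` (uniform default rate) and `loci`,
#' a list of entries with `name`, optional `mu` override and optional
#' `multicopy: true` flag.
#'
#' @param path File path.
#' @return `read_panel()` returns a [locus_panel]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$loci)) stop("panel file has no `loci` entry")
  nm <- vapply(y$loci, function(e) as.character(e[["name"]]), character(1))
  base_mu <- if (is.null(y[["mu"]])) 0.0039 else as.numeric(y[["mu"]])
  mu <- vapply(y$loci, function(e)
    if (is.null(e[["mu"]])) base_mu else as.numeric(e[["mu"]]), numeric(1))
  mc <- nm[vapply(y$loci, function(e) isTRUE(e[["multicopy"]]), logical(1))]
  locus_panel(nm, mu = stats::setNames(mu, nm), multicopy = mc)
}

#' @rdname read_panel
#' @param panel A [locus_panel].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "locus_panel"))
  col_mu <- panel$mu[match_first_copy(panel)]
  entries <- lapply(seq_along(panel$columns), function(i) {
    e <- list(name = panel$columns[i], mu = unname(col_mu[i]))
    if (panel$columns[i] %in% panel$multicopy) e$multicopy <- TRUE
    e
  })
  yaml::write_yaml(list(mu = unname(mean(panel$mu)), loci = entries), path)
  invisible(path)
}

# index of the first expanded locus for each table column
match_first_copy <- function(panel) {
  vapply(panel$columns, function(cl) {
    if (cl %in% panel$multicopy) match(paste0(cl, "a"), panel$loci)
    else match(cl, panel$loci)
  }, integer(1))
}
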