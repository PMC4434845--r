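#' Pairwise gene-set overlap with a focal disease
#'
#' Counts, for every non-focal disease in the catalog, how many of its risk
#' genes are shared with the focal disease's set.
#'
#' @param catalog disease gene catalog (named list of gene-symbol vectors).
#' @param focal focal disease label, present in \code{catalog}.
#' @return named integer vector over the other diseases, in catalog order.
#' @export
pairwise_overlap <- function(catalog, focal) {
  catalog <- check_catalog(catalog)
  if (!focal %in% names(catalog))
    stop(sprintf("unknown focal disease: %s", focal), call. = FALSE)
  others <- setdiff(names(catalog), focal)
  fg <- catalog[[focal]]
  vapply(catalog[others], function(g) length(intersect(fg, g)), 0L)
}

#' Classify focal genes by how many other diseases share them
#'
#' Each focal gene is classified by the number of \emph{other} disease sets
#' containing it: 0 others = unique to the focal disease; 1--2 others =
#' shared with at most two; 3 or more = shared with more than two. The three
#' classes partition the focal set. Set \code{include_focal = TRUE} to count
#' the focal set itself as one of the sharing diseases (shifting the class
#' boundaries accordingly).
#'
#' @inheritParams pairwise_overlap
#' @param include_focal count the focal disease itself in the sharing tally
#'   (default \code{FALSE}: only other diseases are counted).
#' @return an \code{"overlap_summary"}: list with \code{focal},
#'   \code{per_disease_overlap}, \code{unique_to_focal},
#'   \code{shared_at_most_two}, \code{shared_more_than_two}, and
#'   \code{classes} (named integer: sharing count per focal gene).
#' @export
sharing_classes <- function(catalog, focal, include_focal = FALSE) {
  catalog <- check_catalog(catalog)
  if (!focal %in% names(catalog))
    stop(sprintf("unknown focal disease: %s", focal), call. = FALSE)
  others <- setdiff(names(catalog), focal)
  fg <- catalog[[focal]]
  n_other <- vapply(fg, function(g)
    sum(vapply(catalog[others], function(s) g %in% s, FALSE)), 0L)
  tally <- n_other + if (include_focal) 1L else 0L
  structure(list(
    focal = focal,
    per_disease_overlap = pairwise_overlap(catalog, focal),
    unique_to_focal = sum(tally == 0L),
    shared_at_most_two = sum(tally >= 1L & tally <= 2L),
    shared_more_than_two = sum(tally >= 3L),
    classes = stats::setNames(tally, fg)
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap summary for %s (%d genes)\n", x$focal,
              length(x$classes)))
  cat(sprintf("  unique to %s:          %d\n", x$focal, x$unique_to_focal))
  cat(sprintf("  shared with <= 2 others: %d\n", x$shared_at_most_two))
  cat(sprintf("  shared with > 2 others:  %d\n", x$shared_more_than_two))
  cat("  pairwise overlaps:\n")
  ov <- sort(x$per_disease_overlap, decreasing = TRUE)
  for (d in names(ov)) cat(sprintf("    %-6s %d\n", d, ov[[d]]))
  invisible(x)
}

#' Disjoint seed/test sets for network comparison
#'
#' Returns the focal seed set A unchanged and the comparison set B with all
#' genes shared with A removed, so downstream connectivity is not biased by
#' shared risk genes. Errors if the exclusion empties B (a degenerate
#' comparison with nothing left to test).
#'
#' @inheritParams pairwise_overlap
#' @param a label of the focal (seed) disease.
#' @param b label of the comparison disease.
#' @return list with character vectors \code{A} and \code{B};
#'   \code{A} and \code{B} are disjoint.
#' @export
deconfounded_pair <- function(catalog, a, b) {
  catalog <- check_catalog(catalog)
  if (identical(a, b)) stop("a and b must differ", call. = FALSE)
  for (d in c(a, b)) if (!d %in% names(catalog))
    stop(sprintf("unknown disease: %s", d), call. = FALSE)
  A <- catalog[[a]]
  B <- setdiff(catalog[[b]], A)
  if (length(B) == 0L)
    stop(sprintf("degenerate comparison: all %s genes overlap %s", b, a),
         call. = FALSE)
  list(A = A, B = B)
}
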