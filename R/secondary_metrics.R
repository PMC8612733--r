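#' Normalize a list of gene/protein identifiers into a set
#'
#' Trims whitespace, upper-cases, drops empties, and de-duplicates.
#' Duplicates (after normalization) are reported via a message so the
#' collapse is auditable. No alias or ortholog resolution is attempted; an
#' optional user-supplied alias map is applied before normalization.
#'
#' @param raw Character vector of raw identifiers.
#' @param name Set name.
#' @param alias_map Optional named character vector mapping raw ids to
#'   replacement ids, applied case-insensitively before normalization.
#' @return A `gene_set`: list with `name` and sorted unique `ids`.
#' @export
normalize_ids <- function(raw, name = "set", alias_map = NULL) {
  if (length(raw) == 0L) stop("empty identifier list", call. = FALSE)
  ids <- toupper(trimws(as.character(raw)))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (length(ids) == 0L) {
    stop("no usable identifiers after trimming", call. = FALSE)
  }
  if (!is.null(alias_map)) {
    am <- stats::setNames(toupper(unname(alias_map)), toupper(names(alias_map)))
    hit <- ids %in% names(am)
    ids[hit] <- am[ids[hit]]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    message(sprintf("normalize_ids('%s'): collapsed %d duplicate id(s): %s",
                    name, length(dup),
                    paste(utils::head(dup, 5), collapse = ", ")))
  }
  structure(list(name = name, ids = sort(unique(ids))), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d ids\n", x$name, length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Gene-set overlap
#'
#' Exact intersection of two normalized identifier sets, with the percentage
#' expressed relative to the reference set size (e.g. the fraction of a
#' published P-body proteome recovered in an interactome or an exosome
#' proteome).
#'
#' @param query,reference [normalize_ids()] results (`gene_set` objects).
#' @return An `overlap_result`: list with `query_name`, `reference_name`,
#'   `n_query`, `n_reference`, `n_intersect`, `pct_of_reference`
#'   (`100 * n_intersect / n_reference`), and the `shared` ids.
#' @export
overlap <- function(query, reference) {
  stopifnot(inherits(query, "gene_set"), inherits(reference, "gene_set"))
  if (length(reference$ids) == 0L) {
    stop("empty reference set", call. = FALSE)
  }
  shared <- intersect(query$ids, reference$ids)
  structure(list(query_name = query$name, reference_name = reference$name,
                 n_query = length(query$ids),
                 n_reference = length(reference$ids),
                 n_intersect = length(shared),
                 pct_of_reference = 100 * length(shared) / length(reference$ids),
                 shared = shared),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> %s vs %s: %d / %d reference ids shared (%.1f%%)\n",
              x$query_name, x$reference_name, x$n_intersect, x$n_reference,
              x$pct_of_reference))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(query = x$query_name, reference = x$reference_name,
             n_query = x$n_query, n_reference = x$n_reference,
             n_intersect = x$n_intersect,
             pct_of_reference = x$pct_of_reference)
}

#' Relative enrichment from two fold changes
#'
#' Ratio of the exosome/cell fold change in a condition of interest (e.g.
#' protein over-expression) to the exosome/cell fold change in the control,
#' i.e. how much more a species is enriched in exosomes under the condition.
#'
#' @param fc_condition,fc_control Positive fold changes (exosome over cell).
#' @return An `enrichment_result`: list with both fold changes and
#'   `relative_enrichment = fc_condition / fc_control`.
#' @export
relative_enrichment <- function(fc_condition, fc_control) {
  if (!is.finite(fc_condition) || !is.finite(fc_control) ||
      fc_condition <= 0 || fc_control <= 0) {
    stop("fold changes must be finite and > 0", call. = FALSE)
  }
  structure(list(fc_exo_over_cell_condition = fc_condition,
                 fc_exo_over_cell_control = fc_control,
                 relative_enrichment = fc_condition / fc_control),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> condition FC %.3g / control FC %.3g = %.3g\n",
              x$fc_exo_over_cell_condition, x$fc_exo_over_cell_control,
              x$relative_enrichment))
  invisible(x)
}

#' Fold change from qPCR cycle thresholds
#'
#' Exosome-over-cell fold change computed as `2^(ct_cell - ct_exo)`.
#' Measurements with a Ct above `ct_max` (default 40) are regarded as
#' negative: they are flagged and given no numeric fold change. Vectorized.
#'
#' @param ct_exo,ct_cell Cycle-threshold values (> 0, finite).
#' @param ct_max Ct above which a measurement is called negative
#'   (default 40).
#' @return Data frame with `ct_exo`, `ct_cell`, `fold_change` (`NA` when
#'   negative), `negative` (logical).
#' @examples
#' fold_change_from_ct(27, 30)$fold_change  # 2^3 = 8
#' @export
fold_change_from_ct <- function(ct_exo, ct_cell, ct_max = 40) {
  if (length(ct_exo) != length(ct_cell)) {
    stop("ct_exo and ct_cell must have equal lengths", call. = FALSE)
  }
  if (any(!is.finite(ct_exo)) || any(!is.finite(ct_cell))) {
    stop("non-finite Ct value", call. = FALSE)
  }
  if (any(ct_exo <= 0) || any(ct_cell <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  negative <- ct_exo > ct_max | ct_cell > ct_max
  fc <- ifelse(negative, NA_real_, 2^(ct_cell - ct_exo))
  data.frame(ct_exo = ct_exo, ct_cell = ct_cell, fold_change = fc,
             negative = negative)
}
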