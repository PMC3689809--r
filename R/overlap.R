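#' Overlap of the up-regulated gene set with a reference set
#'
#' Counts how many genes of an external reference set (e.g. a proteome or
#' microarray study) are supported by the up-regulated set, by exact
#' identifier intersection (identifiers are whitespace-trimmed at
#' construction; no homolog mapping is performed).
#'
#' @param upregulated A `gene_set` of up-regulated genes.
#' @param reference A `gene_set` to compare against.
#' @return Data frame with one row: `reference_name`, `n_reference`,
#'   `n_supported`, `fraction` (`NA` for an empty reference).
#' @examples
#' up <- gene_set("up", c("a", "b", "c", "d"))
#' ref <- gene_set("study", c("c", "d", "e"))
#' overlap_counts(up, ref)
#' @export
overlap_counts <- function(upregulated, reference) {
  stopifnot(inherits(upregulated, "gene_set"), inherits(reference, "gene_set"))
  n_ref <- length(reference$members)
  n_sup <- length(intersect(upregulated$members, reference$members))
  data.frame(reference_name = reference$name,
             n_reference = n_ref,
             n_supported = n_sup,
             fraction = if (n_ref > 0) n_sup / n_ref else NA_real_,
             stringsAsFactors = FALSE)
}

#' Overlap table against several reference sets
#'
#' One [overlap_counts()] row per reference, in input order.
#'
#' @param upregulated A `gene_set` of up-regulated genes.
#' @param references List of `gene_set` objects with unique names.
#' @return Data frame with columns as in [overlap_counts()].
#' @export
overlap_table <- function(upregulated, references) {
  stopifnot(is.list(references))
  nms <- vapply(references, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate reference set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (length(references) == 0L) {
    return(data.frame(reference_name = character(0),
                      n_reference = integer(0), n_supported = integer(0),
                      fraction = numeric(0)))
  }
  do.call(rbind, lapply(references, overlap_counts, upregulated = upregulated))
}
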