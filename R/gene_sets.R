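#' Gene-set catalog
#'
#' Named gene sets together with the universe of scorable genes.
#' Members are deduplicated; sets with no member in the universe are an
#' error at scoring time, not at construction (the universe may be
#' widened later).
#'
#' @param sets named list of character vectors.
#' @param universe character vector of all scorable gene symbols.
#' @param provenance free-text provenance tag.
#' @param descriptions optional named character vector (GMT description
#'   field), one per set.
#' @return object of class `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, universe, provenance = "",
                             descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyNA(names(sets)),
            all(nzchar(names(sets))))
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(sets = sets, universe = unique(as.character(universe)),
         provenance = provenance,
         descriptions = descriptions[names(sets)]),
    class = "gene_set_catalog"
  )
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d sets, universe %d genes (%s)\n",
              length(x$sets), length(x$universe), x$provenance))
  invisible(x)
}

#' @export
length.gene_set_catalog <- function(x) length(x$sets)

# members of `set_name` restricted to the universe; error if empty
catalog_members <- function(catalog, set_name) {
  if (!set_name %in% names(catalog$sets))
    stop("unknown gene set '", set_name, "'")
  g <- intersect(catalog$sets[[set_name]], catalog$universe)
  if (length(g) == 0)
    stop("gene set '", set_name, "' has no member in the universe")
  g
}
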