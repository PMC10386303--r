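## GO-term frequency profiles per depth layer: pooled occurrence counts,
## the top-term display matrix, and layer-exclusive term sets.

#' Pool GO-term occurrence counts by depth layer
#'
#' Counts, for every GO term, the total number of annotation rows carried
#' by reads belonging to each layer's samples.  Reads annotated with
#' several terms contribute one occurrence per annotation row.  Counts are
#' raw occurrences, not normalized by layer sequencing depth; pass
#' `normalize = "per-million"` to rescale each layer to occurrences per
#' million annotation rows.
#'
#' @param annotations Either a data frame with columns `sample_id`,
#'   `read_id`, `term_id`, or a named list (names are sample ids) of
#'   per-sample annotation data frames as returned by
#'   [read_go_annotations()].
#' @param metadata Metadata data frame covering every annotated sample.
#' @param normalize `"none"` (default) or `"per-million"`.
#' @return An integer (or double, when normalized) matrix, terms as rows
#'   (sorted by term id) and the three layers as columns; a term absent
#'   from a layer has count 0.  The attribute `layers_present` lists the
#'   layers that actually had samples in the metadata.
#' @export
term_frequencies <- function(annotations, metadata,
                             normalize = c("none", "per-million")) {
  normalize <- match.arg(normalize)
  if (is.list(annotations) && !is.data.frame(annotations)) {
    if (is.null(names(annotations))) {
      stop("a list of annotation tables must be named by sample id",
           call. = FALSE)
    }
    annotations <- do.call(rbind, lapply(names(annotations), function(sid) {
      a <- annotations[[sid]]
      if (nrow(a) == 0L) return(NULL)
      data.frame(sample_id = sid, a, stringsAsFactors = FALSE)
    }))
    if (is.null(annotations)) {
      annotations <- data.frame(sample_id = character(),
                                read_id = character(),
                                term_id = character())
    }
  }
  layer_of <- stats::setNames(metadata$layer, metadata$sample_id)
  unknown <- setdiff(unique(annotations$sample_id), names(layer_of))
  if (length(unknown) > 0L) {
    stop("annotations reference sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  terms <- sort(unique(annotations$term_id))
  freq <- matrix(0L, nrow = length(terms), ncol = length(LAYERS),
                 dimnames = list(terms, LAYERS))
  if (nrow(annotations) > 0L) {
    tab <- table(annotations$term_id,
                 factor(layer_of[annotations$sample_id], levels = LAYERS))
    freq[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  if (normalize == "per-million") {
    totals <- colSums(freq)
    freq <- sweep(freq, 2L, pmax(totals, 1L), "/") * 1e6
  }
  attr(freq, "layers_present") <- intersect(LAYERS, unique(metadata$layer))
  freq
}

#' Matrix of the most frequent GO terms, log10-transformed
#'
#' Selects the display terms either as the `n` terms with the largest
#' summed count across layers (`scope = "overall"`) or as the union of
#' each layer's top `n` (`scope = "per_layer"`).  Ties are broken by term
#' id.  Cell values are `log10(count + 1)` so that zero counts map to 0;
#' the raw count matrix is attached as attribute `raw`.
#'
#' @param freq Term-by-layer count matrix from [term_frequencies()].
#' @param n Number of terms (default 50).
#' @param scope `"overall"` (default) or `"per_layer"`.
#' @return A numeric matrix (selected terms x layers), rows ordered by
#'   descending overall count with ties by term id.
#' @export
top_terms_matrix <- function(freq, n = 50, scope = c("overall", "per_layer")) {
  scope <- match.arg(scope)
  if (nrow(freq) == 0L) {
    stop("empty frequency table", call. = FALSE)
  }
  overall <- rowSums(freq)
  if (scope == "overall") {
    if (nrow(freq) < n) {
      warning("only ", nrow(freq), " terms available; returning all",
              call. = FALSE)
      n <- nrow(freq)
    }
    keep <- rownames(freq)[order(-overall, rownames(freq))][seq_len(n)]
  } else {
    keep <- character()
    for (layer in colnames(freq)) {
      ord <- rownames(freq)[order(-freq[, layer], rownames(freq))]
      ord <- ord[freq[ord, layer] > 0]
      keep <- union(keep, utils::head(ord, n))
    }
    if (length(keep) == 0L) keep <- rownames(freq)
  }
  keep <- keep[order(-overall[keep], keep)]
  raw <- freq[keep, , drop = FALSE]
  out <- log10(raw + 1)
  attr(out, "raw") <- raw
  out
}

#' Layer-exclusive GO terms
#'
#' A term is exclusive to a layer when its occurrence count is positive in
#' that layer and exactly zero in both others.  Exclusive sets are
#' pairwise disjoint by construction.
#'
#' @param freq Term-by-layer count matrix from [term_frequencies()]
#'   covering the three canonical layers; a layer that had no samples is
#'   treated as all-zero with a warning.
#' @return An object of class `exclusivity_report`: a list with `sets`
#'   (per-layer sorted character vectors of exclusive term ids) and
#'   `counts` (named integer vector of set sizes).
#' @export
exclusive_terms <- function(freq) {
  if (!all(LAYERS %in% colnames(freq))) {
    stop("frequency table must cover the layers ",
         paste(LAYERS, collapse = ", "), call. = FALSE)
  }
  present <- attr(freq, "layers_present") %||% LAYERS
  absent <- setdiff(LAYERS, present)
  if (length(absent) > 0L) {
    warning("layer(s) without samples treated as all-zero: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(LAYERS, function(layer) {
    others <- setdiff(LAYERS, layer)
    sel <- freq[, layer] > 0 & rowSums(freq[, others, drop = FALSE]) == 0
    sort(rownames(freq)[sel])
  })
  names(sets) <- LAYERS
  structure(
    list(sets = sets,
         counts = vapply(sets, length, integer(1))),
    class = "exclusivity_report")
}

#' @export
print.exclusivity_report <- function(x, ...) {
  cat("<exclusivity_report>",
      paste(sprintf("%s: %d", names(x$counts), x$counts), collapse = ", "),
      "exclusive term(s)\n")
  invisible(x)
}
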