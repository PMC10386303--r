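## Alpha diversity: abundance index, Shannon-Wiener index (nats) and its
## normalization by the taxon pool observed across all samples.

#' Abundance index of a sample
#'
#' The abundance index is the total number of reads taxonomically
#' attributed in a sample.  By default only reads assigned a name at the
#' profile's analysis rank are counted; reads attributed to higher nodes of
#' the taxonomy can be included with `count_unassigned`.
#'
#' @param profile A [taxonomic_profile()].
#' @param count_unassigned Also count reads lacking a name at the analysis
#'   rank (default `FALSE`, for consistency with the proportions entering
#'   the diversity index).
#' @return A non-negative integer.
#' @export
abundance_index <- function(profile, count_unassigned = FALSE) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  n <- sum(profile$counts)
  if (count_unassigned) n <- n + profile$unassigned_at_rank
  as.integer(n)
}

#' Shannon-Wiener diversity index
#'
#' For a sample with taxon proportions `p_i = count_i / sum(counts)` the
#' index is `H = -sum(p_i * log(p_i))`, computed with the natural
#' logarithm (values are in nats).  `H` grows with both richness (the
#' number of taxa) and evenness (how uniform the proportions are); a
#' single-taxon sample has `H = 0` and a perfectly even sample of `S` taxa
#' has `H = log(S)`.
#'
#' @param counts Named (or unnamed) vector of strictly positive taxon
#'   counts; proportions work too since the index is scale-invariant.
#' @return The index, a non-negative real.
#' @examples
#' shannon_wiener(c(A = 9, B = 1))        # 0.325083
#' shannon_wiener(rep(1, 4))              # log(4)
#' @export
shannon_wiener <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) {
    stop("diversity is undefined for an empty profile", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all counts must be finite and strictly positive", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Normalize a Shannon-Wiener index by the cross-sample taxon pool
#'
#' Divides `H` by `log(M)`, where `M` is the total number of distinct taxa
#' observed across all samples under comparison, bounding the diversity
#' index to `[0, 1]` and making samples with different richness
#' comparable.  The ratio is independent of the logarithm base used, as
#' long as index and normalizer share it.
#'
#' @param swi A non-negative Shannon-Wiener index.
#' @param M Total number of distinct taxa across all samples; must be at
#'   least 2 for the normalizer `log(M)` to be positive.
#' @return The normalized index in `[0, 1]` (values can exceed 1 only if
#'   `swi` was computed over more than `M` taxa, which the table-level
#'   wrapper [diversity_table()] rules out).
#' @export
normalized_swi <- function(swi, M) {
  if (M < 2) {
    stop("normalization requires M >= 2 (log(M) must be positive)",
         call. = FALSE)
  }
  if (any(swi < 0)) {
    stop("swi must be non-negative", call. = FALSE)
  }
  swi / log(M)
}

#' Per-sample diversity table over a set of profiles
#'
#' Computes, for every sample: the abundance index, the richness `S` (taxa
#' with positive count), the Shannon-Wiener index `H` in nats, and the
#' normalized index `H / log(M)` where `M` counts the distinct taxon names
#' with positive count in the union of all profiles.  `M` is the observed
#' pool, not a database size.
#'
#' @param profiles A list of [taxonomic_profile()] objects sharing one
#'   aggregation rank.
#' @param count_unassigned Passed to [abundance_index()].
#' @return A data frame of class `diversity_table` with columns
#'   `sample_id`, `abundance_index`, `richness`, `swi`, `normalized_swi`,
#'   and attribute `M`.
#' @export
diversity_table <- function(profiles, count_unassigned = FALSE) {
  if (length(profiles) == 0L) {
    stop("at least one profile is required", call. = FALSE)
  }
  ok <- vapply(profiles, inherits, TRUE, "taxonomic_profile")
  if (!all(ok)) {
    stop("profiles must be taxonomic_profile objects", call. = FALSE)
  }
  ranks <- unique(vapply(profiles, `[[`, "", "rank"))
  if (length(ranks) != 1L) {
    stop("all profiles must share one aggregation rank; got: ",
         paste(ranks, collapse = ", "), call. = FALSE)
  }
  pool <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  M <- length(pool)
  if (M < 2L) {
    stop("fewer than 2 distinct taxa across all samples; ",
         "normalized diversity is undefined", call. = FALSE)
  }
  rows <- lapply(profiles, function(p) {
    s <- length(p$counts)
    h <- if (s == 0L) NA_real_ else shannon_wiener(p$counts)
    data.frame(sample_id = p$sample_id,
               abundance_index = abundance_index(p, count_unassigned),
               richness = s,
               swi = h,
               normalized_swi = if (is.na(h)) NA_real_ else
                 normalized_swi(h, M),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "M") <- M
  class(out) <- c("diversity_table", class(out))
  out
}
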