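## Domain/species proportion profiles and the layer-wise statistics:
## Wilcoxon rank-sum tests with Bonferroni correction over layer pairs.

#' Per-sample domain proportions
#'
#' Converts superkingdom-rank profiles into per-sample proportions over the
#' closed domain set Archaea/Bacteria/Viruses.  Reads classified to other
#' superkingdoms (e.g. Eukaryota) are dropped and the remaining proportions
#' renormalized, with a warning.  Samples with no reads in the three
#' domains are excluded with a warning.
#'
#' @param profiles List of [taxonomic_profile()] objects at rank
#'   `superkingdom`.
#' @param metadata Optional metadata data frame (from [read_metadata()]);
#'   when given, `station`, `layer` and `ocean` are joined onto the result.
#' @return A data frame with columns `sample_id`, `Archaea`, `Bacteria`,
#'   `Viruses` (each row summing to 1) plus any joined metadata columns.
#' @export
domain_proportions <- function(profiles, metadata = NULL) {
  ranks <- unique(vapply(profiles, `[[`, "", "rank"))
  if (!identical(ranks, "superkingdom")) {
    stop("domain proportions require profiles aggregated at superkingdom",
         call. = FALSE)
  }
  dropped <- character()
  rows <- list()
  for (p in profiles) {
    extra <- setdiff(names(p$counts), DOMAINS)
    if (length(extra) > 0L) dropped <- union(dropped, extra)
    counts <- p$counts[intersect(DOMAINS, names(p$counts))]
    total <- sum(counts)
    if (total == 0) {
      warning("sample '", p$sample_id, "' has no reads in ",
              paste(DOMAINS, collapse = "/"), "; excluded", call. = FALSE)
      next
    }
    props <- stats::setNames(numeric(length(DOMAINS)), DOMAINS)
    props[names(counts)] <- counts / total
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = p$sample_id, as.list(props), stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L) {
    warning("categories outside the domain set dropped and proportions ",
            "renormalized: ", paste(sort(dropped), collapse = ", "),
            call. = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no sample retained any reads in the three domains", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    out <- merge(out, metadata, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Most abundant species and per-sample proportions
#'
#' Ranks species by their total read count over all samples, keeps the top
#' `n` (ties at the boundary broken by taxon-name lexicographic order) and
#' returns per-sample proportions over these species plus an `other`
#' bucket, each row summing to 1.
#'
#' @param profiles List of species-rank [taxonomic_profile()] objects.
#' @param n Number of species to keep (default 10).
#' @return A list with `species` (ranked character vector) and
#'   `proportions` (data frame: `sample_id`, one column per top species,
#'   and `other`).
#' @export
top_species <- function(profiles, n = 10) {
  ranks <- unique(vapply(profiles, `[[`, "", "rank"))
  if (!identical(ranks, "species")) {
    stop("top_species requires species-rank profiles", call. = FALSE)
  }
  totals <- list()
  for (p in profiles) {
    for (nm in names(p$counts)) {
      totals[[nm]] <- (totals[[nm]] %||% 0L) + p$counts[[nm]]
    }
  }
  totals <- unlist(totals)
  if (length(totals) < n) {
    warning("only ", length(totals), " species observed; returning all",
            call. = FALSE)
    n <- length(totals)
  }
  ord <- order(-totals, names(totals))
  top <- names(totals)[ord][seq_len(n)]
  rows <- lapply(profiles, function(p) {
    tot <- sum(p$counts)
    props <- stats::setNames(numeric(length(top)), top)
    hit <- intersect(top, names(p$counts))
    if (tot > 0) props[hit] <- p$counts[hit] / tot
    df <- data.frame(sample_id = p$sample_id, as.list(props),
                     other = max(0, 1 - sum(props)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(species = top, proportions = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares the locations of two samples.  In `exact` mode (or `auto` mode
#' with `min(n1, n2) <= 10` and no ties) the p-value comes from the exact
#' null distribution of the rank-sum statistic; otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#' When every pooled value is identical the test is degenerate and returns
#' p = 1 with a warning.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @return A list of class `rank_sum_test`: `statistic` (the rank-sum
#'   statistic `W` of `x` in the pooled ranking, minimum
#'   `n_x (n_x + 1) / 2`), `p_value`, `method` (`"exact"`, `"normal"` or
#'   `"degenerate"`), `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) {
    stop("samples contain non-finite values", call. = FALSE)
  }
  result <- function(statistic, p, method) {
    structure(list(statistic = unname(statistic), p_value = unname(p),
                   method = method, n_x = length(x), n_y = length(y)),
              class = "rank_sum_test")
  }
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; test is degenerate",
            call. = FALSE)
    return(result(length(x) * (length(x) + length(y) + 1) / 2, 1,
                  "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- mode == "exact" ||
    (mode == "auto" && min(length(x), length(y)) <= 10L && !ties)
  if (use_exact && ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    use_exact <- FALSE
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  ## wilcox.test reports the Mann-Whitney U of x; shift to the rank-sum W
  w <- wt$statistic + length(x) * (length(x) + 1) / 2
  result(w, min(1, wt$p.value), if (use_exact) "exact" else "normal")
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1, preserving
#' order.  The family size defaults to the number of p-values but can be
#' set explicitly when some family members were not computed.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m Family size (default `length(p_values)`).
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("family size m cannot be smaller than the number of p-values",
         call. = FALSE)
  }
  pmin(1, m * p)
}

#' Significance stars for adjusted p-values
#'
#' `ns` for p > 0.05, then `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001),
#' `****` (<= 0.0001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else if (pi <= 5e-2) "*"
    else "ns"
  }, "")
}

#' Pairwise depth-layer comparisons of a per-sample statistic
#'
#' Runs the Wilcoxon rank-sum test on every pair of depth layers
#' (SRF-DCM, SRF-MES, DCM-MES) for a per-sample response such as the
#' normalized diversity index, the abundance index or a domain proportion,
#' and applies a Bonferroni correction whose family is the set of
#' comparisons actually performed.  Layers with fewer than 2 samples are
#' skipped with a warning, shrinking the family accordingly.
#'
#' @param values Named numeric vector (names are sample ids) or a data
#'   frame with columns `sample_id` and the response named by `column`.
#' @param metadata Metadata data frame with `sample_id` and a grouping
#'   column (default `layer`).
#' @param column Response column name when `values` is a data frame.
#' @param group_by Metadata column defining the groups (default
#'   `"layer"`; e.g. `"ocean"` for inter-ocean comparisons).
#' @param mode Test mode, see [wilcoxon_rank_sum()].
#' @return A data frame with one row per comparison: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p_raw`, `p_adjusted`, `significance`,
#'   `method`.
#' @export
compare_layers <- function(values, metadata, column = NULL,
                           group_by = "layer",
                           mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (is.data.frame(values)) {
    if (is.null(column)) {
      stop("specify `column` when values is a data frame", call. = FALSE)
    }
    values <- stats::setNames(values[[column]], values$sample_id)
  }
  if (is.null(names(values))) {
    stop("values must be named by sample id", call. = FALSE)
  }
  if (!group_by %in% names(metadata)) {
    stop("metadata has no column '", group_by, "'", call. = FALSE)
  }
  groups <- stats::setNames(metadata[[group_by]], metadata$sample_id)
  common <- intersect(names(values), names(groups))
  values <- values[common]
  groups <- groups[common]
  levels_present <- if (group_by == "layer") {
    intersect(LAYERS, unique(groups))
  } else {
    sort(unique(groups))
  }
  if (length(levels_present) < 2L) {
    stop("need at least two groups with samples to compare", call. = FALSE)
  }
  pairs <- utils::combn(levels_present, 2L, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    xa <- values[groups == pr[1L]]
    xb <- values[groups == pr[2L]]
    if (length(xa) < 2L || length(xb) < 2L) {
      warning("comparison ", pr[1L], "-", pr[2L],
              " skipped: fewer than 2 samples in a group", call. = FALSE)
      next
    }
    tst <- wilcoxon_rank_sum(xa, xb, mode = mode)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = pr[1L], group_b = pr[2L],
      n_a = tst$n_x, n_b = tst$n_y,
      statistic = tst$statistic, p_raw = tst$p_value,
      method = tst$method, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no comparison could be performed", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = nrow(out))
  out$significance <- significance_stars(out$p_adjusted)
  out <- out[c("group_a", "group_b", "n_a", "n_b", "statistic",
               "p_raw", "p_adjusted", "significance", "method")]
  rownames(out) <- NULL
  out
}
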