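## Readers and writers for every external table the pipeline touches.
## All on-disk products are UTF-8 TSV with "NA" as the missing-value token.

#' Read a Kaiju-style per-read classification table
#'
#' Parses the tab-separated output of the Kaiju classifier, optionally
#' augmented with named lineages (the `kaiju-addTaxonNames` dialect).  Each
#' row describes one read: a single-character classification flag (`C` or
#' `U`), the read identifier, the NCBI taxon id, and - when present - a
#' fourth column holding the semicolon-delimited lineage names at the seven
#' canonical ranks (superkingdom through species).  Columns beyond the
#' fourth are ignored.  The file has no header line.
#'
#' Rows flagged classified but carrying taxon id 0 are demoted to
#' unclassified with a warning; unclassified rows never carry a lineage.
#'
#' @param path Path to the classification TSV.
#' @return A data frame with one row per read and columns `status`
#'   (`"classified"`/`"unclassified"`), `read_id`, `taxon_id`, and one
#'   column per rank in [RANKS] (`NA` where the lineage lacks the rank).
#'   Row order matches the file.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("C\tr1\t1280\tBacteria; Bacillota; Bacilli; Caryophanales; Staphylococcaceae; Staphylococcus; Staphylococcus aureus;",
#'              "U\tr2\t0"), f)
#' read_kaiju_table(f)
#' @export
read_kaiju_table <- function(path) {
  if (!file.exists(path)) {
    stop("classification file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty classification file: ", path, call. = FALSE)
    return(empty_kaiju_frame())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 3L)
  if (length(bad) > 0L) {
    stop("malformed row (fewer than 3 columns) at line ", bad[1L],
         " of ", path, call. = FALSE)
  }
  status_raw <- vapply(parts, `[[`, "", 1L)
  unknown <- which(!status_raw %in% c("C", "U"))
  if (length(unknown) > 0L) {
    stop("unknown classification flag '", status_raw[unknown[1L]],
         "' at line ", unknown[1L], " of ", path, call. = FALSE)
  }
  read_id <- vapply(parts, `[[`, "", 2L)
  taxon_chr <- vapply(parts, `[[`, "", 3L)
  taxon_id <- suppressWarnings(as.integer(taxon_chr))
  bad_tax <- which(is.na(taxon_id) | taxon_id < 0L)
  if (length(bad_tax) > 0L) {
    stop("non-integer or negative taxon id '", taxon_chr[bad_tax[1L]],
         "' at line ", bad_tax[1L], " of ", path, call. = FALSE)
  }
  status <- ifelse(status_raw == "C", "classified", "unclassified")

  ## classified rows with taxon id 0 cannot be trusted
  demote <- status == "classified" & taxon_id == 0L
  if (any(demote)) {
    warning(sum(demote), " row(s) flagged classified with taxon id 0 ",
            "treated as unclassified in ", path, call. = FALSE)
    status[demote] <- "unclassified"
  }

  lineage <- matrix(NA_character_, nrow = length(lines), ncol = length(RANKS),
                    dimnames = list(NULL, RANKS))
  has_names <- nfield >= 4L & status == "classified"
  for (i in which(has_names)) {
    lin <- parse_lineage(parts[[i]][[4L]])
    if (is.null(lin)) {
      stop("lineage with more than ", length(RANKS), " ranks at line ", i,
           " of ", path, call. = FALSE)
    }
    lineage[i, ] <- lin
  }
  out <- data.frame(status = status, read_id = read_id, taxon_id = taxon_id,
                    lineage, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_kaiju_frame <- function() {
  cols <- c(list(status = character(), read_id = character(),
                 taxon_id = integer()),
            stats::setNames(rep(list(character()), length(RANKS)), RANKS))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

## Split a semicolon-delimited lineage string into the 7 canonical ranks.
## Trailing empty field after the final ";" is dropped; surrounding
## whitespace stripped; "NA" or empty fields become NA.  Returns NULL if
## more than 7 ranks are present.
parse_lineage <- function(x) {
  fields <- strsplit(x, ";", fixed = TRUE)[[1L]]
  fields <- trimws(fields)
  ## drop trailing empties produced by a terminal ";"
  while (length(fields) > 0L && !nzchar(fields[length(fields)])) {
    fields <- fields[-length(fields)]
  }
  if (length(fields) > length(RANKS)) {
    return(NULL)
  }
  fields[!nzchar(fields) | fields == "NA"] <- NA_character_
  c(fields, rep(NA_character_, length(RANKS) - length(fields)))
}

#' Read a sample-metadata table
#'
#' The metadata TSV must carry a header with the columns `sample_id`,
#' `station`, `layer` and `ocean`.  Layers are validated against the closed
#' set [LAYERS]; sample ids must be unique.
#'
#' @param path Path to the metadata TSV.
#' @return A data frame with columns `sample_id`, `station`, `layer`,
#'   `ocean`, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path, call. = FALSE)
  }
  md <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("sample_id", "station", "layer", "ocean")
  missing <- setdiff(needed, names(md))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md <- md[needed]
  bad <- which(!md$layer %in% LAYERS)
  if (length(bad) > 0L) {
    stop("unknown layer '", md$layer[bad[1L]], "' for sample '",
         md$sample_id[bad[1L]], "' (row ", bad[1L], "); expected one of ",
         paste(LAYERS, collapse = ", "), call. = FALSE)
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  md
}

#' Aggregate classified reads into a taxonomic profile at one rank
#'
#' Unclassified reads are excluded entirely.  Classified reads carrying a
#' name at `rank` are counted under that name; classified reads whose
#' lineage stops above `rank` (reads attributed to higher nodes of the
#' taxonomy) are tallied in `unassigned_at_rank`.  The classified-read
#' count is conserved: `sum(counts) + unassigned_at_rank` equals the number
#' of classified reads.
#'
#' @param reads A data frame as returned by [read_kaiju_table()].
#' @param rank One of [RANKS].
#' @param sample_id Optional sample identifier stored in the profile.
#' @return An object of class `taxonomic_profile`: a list with elements
#'   `sample_id`, `rank`, `counts` (named integer vector, all positive),
#'   `unassigned_at_rank` and `n_classified`.
#' @export
aggregate_profile <- function(reads, rank, sample_id = NA_character_) {
  if (!rank %in% RANKS) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(RANKS, collapse = ", "), call. = FALSE)
  }
  cl <- reads[reads$status == "classified", , drop = FALSE]
  names_at_rank <- cl[[rank]]
  tab <- table(names_at_rank, useNA = "no")
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts))]
  taxonomic_profile(sample_id = sample_id, rank = rank, counts = counts,
                    unassigned_at_rank = sum(is.na(names_at_rank)))
}

#' Construct a taxonomic profile
#'
#' Low-level constructor used by [aggregate_profile()] and the synthetic
#' generator.  Validates the conservation invariant.
#'
#' @param sample_id Sample identifier.
#' @param rank Aggregation rank, one of [RANKS].
#' @param counts Named integer vector of strictly positive read counts.
#' @param unassigned_at_rank Classified reads lacking a name at `rank`.
#' @return An object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(sample_id, rank, counts,
                              unassigned_at_rank = 0L) {
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (length(counts) > 0 && is.null(names(counts))) {
    stop("counts must be a named vector", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, rank = rank, counts = counts,
         unassigned_at_rank = as.integer(unassigned_at_rank),
         n_classified = sum(counts) + as.integer(unassigned_at_rank)),
    class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("<taxonomic_profile> sample", x$sample_id, "at rank", x$rank, "\n")
  cat("  ", length(x$counts), "taxa,", sum(x$counts), "reads assigned,",
      x$unassigned_at_rank, "at higher nodes\n")
  invisible(x)
}

#' Read per-read Gene Ontology annotations
#'
#' A two-column TSV mapping `read_id` to a GO term id of the form
#' `GO:NNNNNNN`.  A read may appear on several rows (one per annotation);
#' all rows are kept.  A header line `read_id<TAB>term_id` is tolerated and
#' skipped.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame with columns `read_id` and `term_id`.
#' @export
read_go_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  offset <- 0L
  if (length(lines) > 0L && identical(lines[1L], "read_id\tterm_id")) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed annotation row at line ", bad[1L] + offset, " of ",
         path, call. = FALSE)
  }
  read_id <- vapply(parts, `[[`, "", 1L)
  term_id <- vapply(parts, `[[`, "", 2L)
  bad_go <- which(!grepl("^GO:[0-9]{7}$", term_id))
  if (length(bad_go) > 0L) {
    stop("malformed GO identifier '", term_id[bad_go[1L]], "' at line ",
         bad_go[1L] + offset, " of ", path, call. = FALSE)
  }
  data.frame(read_id = read_id, term_id = term_id, stringsAsFactors = FALSE)
}

#' Write a tabular analysis product as TSV
#'
#' All analysis products are written as UTF-8, tab-separated tables with a
#' header line and a newline-terminated final line.  Missing values are
#' rendered as `NA`; floating-point columns are rendered with 6 significant
#' digits so products round-trip through their matching readers within
#' rendering precision.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file when `rows` has no
#'   rows (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, allow_empty = FALSE) {
  if (!is.data.frame(rows)) {
    stop("rows must be a data frame", call. = FALSE)
  }
  if (nrow(rows) == 0L && !allow_empty) {
    stop("refusing to write an empty table to ", path,
         " (use allow_empty = TRUE)", call. = FALSE)
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- signif(out[[j]], 6)
      out[[j]] <- ifelse(is.na(v), NA_character_,
                         formatC(v, format = "g", digits = 6))
    }
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) {
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE)
                  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
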