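## One-shot orchestration: classification tables -> profiles -> diversity
## -> UPGMA/Mojena groups -> layer comparisons -> functional profiles,
## behind a single validated configuration.

PIPELINE_KEYS <- c("classification_dir", "metadata", "annotations_dir",
                   "output_dir", "rank", "mojena_k", "cluster_features",
                   "top_species_n", "top_terms_n", "terms_scope",
                   "count_unassigned_in_abundance", "seed")

#' Build a pipeline configuration programmatically
#'
#' @param classification_dir Directory of per-sample Kaiju-style tables
#'   named `<sample_id>.kaiju.tsv` (a bare `<sample_id>.tsv` also works).
#' @param metadata Path to the metadata TSV.
#' @param output_dir Directory for all products (created if needed).
#' @param annotations_dir Optional directory of per-sample GO annotation
#'   tables named `<sample_id>.go.tsv`.
#' @param rank Analysis rank for diversity (default `"species"`).
#' @param mojena_k Mojena constant (default 1.25).
#' @param cluster_features `"normalized_swi"` (cluster on the scalar
#'   diversity index, the default) or `"taxon_profile"` (cluster on
#'   per-taxon relative-abundance vectors).
#' @param top_species_n Species kept in the composition profile (10).
#' @param top_terms_n GO terms kept in the display matrix (50).
#' @param terms_scope `"overall"` or `"per_layer"`, see
#'   [top_terms_matrix()].
#' @param count_unassigned_in_abundance Include higher-node reads in the
#'   abundance index (default `FALSE`).
#' @param seed Integer recorded in the manifest for provenance; the
#'   pipeline itself is deterministic given its inputs.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(classification_dir, metadata, output_dir,
                            annotations_dir = NULL,
                            rank = "species", mojena_k = 1.25,
                            cluster_features = "normalized_swi",
                            top_species_n = 10L, top_terms_n = 50L,
                            terms_scope = "overall",
                            count_unassigned_in_abundance = FALSE,
                            seed = 1L) {
  cfg <- structure(
    list(classification_dir = classification_dir, metadata = metadata,
         annotations_dir = annotations_dir, output_dir = output_dir,
         rank = rank, mojena_k = as.numeric(mojena_k),
         cluster_features = cluster_features,
         top_species_n = as.integer(top_species_n),
         top_terms_n = as.integer(top_terms_n),
         terms_scope = terms_scope,
         count_unassigned_in_abundance =
           isTRUE(count_unassigned_in_abundance),
         seed = as.integer(seed)),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!dir.exists(cfg$classification_dir)) {
    stop("config validation: classification_dir does not exist: ",
         cfg$classification_dir, call. = FALSE)
  }
  if (!file.exists(cfg$metadata)) {
    stop("config validation: metadata file does not exist: ",
         cfg$metadata, call. = FALSE)
  }
  if (!is.null(cfg$annotations_dir) && !dir.exists(cfg$annotations_dir)) {
    stop("config validation: annotations_dir does not exist: ",
         cfg$annotations_dir, call. = FALSE)
  }
  if (!cfg$rank %in% RANKS) {
    stop("config validation: unknown rank '", cfg$rank, "'", call. = FALSE)
  }
  if (!is.finite(cfg$mojena_k) || cfg$mojena_k <= 0) {
    stop("config validation: mojena_k must be positive", call. = FALSE)
  }
  if (!cfg$cluster_features %in% c("normalized_swi", "taxon_profile")) {
    stop("config validation: cluster_features must be 'normalized_swi' ",
         "or 'taxon_profile'", call. = FALSE)
  }
  if (cfg$top_species_n < 1L || cfg$top_terms_n < 1L) {
    stop("config validation: top_species_n and top_terms_n must be ",
         "positive", call. = FALSE)
  }
  if (!cfg$terms_scope %in% c("overall", "per_layer")) {
    stop("config validation: terms_scope must be 'overall' or 'per_layer'",
         call. = FALSE)
  }
  cfg
}

#' Read and validate a pipeline configuration file
#'
#' The file is YAML-style key-value text.  Unknown keys are an error (no
#' silent typos); missing optional keys are filled with their defaults and
#' the effective configuration is echoed to the log when the pipeline
#' runs.
#'
#' @param path Path to the configuration file.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("classification_dir", "metadata", "output_dir")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full depth-layer analysis pipeline
#'
#' Executes every stage in order - input parsing, taxonomic aggregation,
#' diversity, UPGMA clustering with the Mojena cut, layer-wise statistics,
#' and (when annotations are configured) GO-term profiling - and writes
#' all products to the output directory: `diversity.tsv`, `groups.tsv`,
#' `tree.nwk`, `domain_proportions.tsv`, `top_species.tsv`, `tests.tsv`,
#' `terms.tsv`, `exclusive.tsv`, plus `manifest.json` and a `run.log`.
#' Identical configuration and inputs produce byte-identical products
#' (the manifest deliberately records no timestamps).
#'
#' @param config A `pipeline_config`, or the path to a configuration file
#'   understood by [validate_config()].
#' @return Invisibly, the manifest as a list (stage row counts, product
#'   paths, number of groups, the taxon pool size `M`, configuration
#'   echo and hash).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  cat(NULL, file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  manifest <- list(package_version =
                     as.character(utils::packageVersion("depthdiv")),
                   config = unclass(cfg),
                   products = list(), stages = list(), status = "running")
  finish_stage <- function(name, rows) {
    manifest$stages[[name]] <<- list(rows = rows)
    logmsg("stage ", name, ": ", rows, " row(s)")
  }
  product <- function(name, path, rows) {
    manifest$products[[name]] <<- list(file = basename(path), rows = rows)
  }
  fail <- function(stage, e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    write_manifest(manifest, cfg$output_dir)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  ## ---- inputs ------------------------------------------------------
  inputs <- run_stage("inputs", {
    metadata <- read_metadata(cfg$metadata)
    files <- list.files(cfg$classification_dir,
                        pattern = "\\.tsv$", full.names = TRUE)
    sids <- sub("\\.kaiju\\.tsv$|\\.tsv$", "", basename(files))
    names(files) <- sids
    missing <- setdiff(metadata$sample_id, sids)
    if (length(missing) > 0L) {
      stop("no classification table for sample(s): ",
           paste(missing, collapse = ", "))
    }
    reads <- lapply(files[metadata$sample_id], read_kaiju_table)
    finish_stage("inputs", sum(vapply(reads, nrow, 0L)))
    list(metadata = metadata, reads = reads)
  })
  metadata <- inputs$metadata

  ## ---- taxonomic profiles -----------------------------------------
  profiles <- run_stage("profiles", {
    pr <- lapply(metadata$sample_id, function(sid)
      aggregate_profile(inputs$reads[[sid]], cfg$rank, sample_id = sid))
    finish_stage("profiles", length(pr))
    pr
  })
  sk_profiles <- run_stage("profiles", lapply(
    metadata$sample_id, function(sid)
      aggregate_profile(inputs$reads[[sid]], "superkingdom",
                        sample_id = sid)))

  ## ---- diversity ---------------------------------------------------
  div <- run_stage("diversity", {
    d <- diversity_table(profiles,
                         count_unassigned = cfg$count_unassigned_in_abundance)
    p <- file.path(cfg$output_dir, "diversity.tsv")
    write_table(as.data.frame(d), p)
    product("diversity", p, nrow(d))
    finish_stage("diversity", nrow(d))
    d
  })
  manifest$M <- attr(div, "M")

  ## ---- clustering --------------------------------------------------
  groups <- run_stage("clustering", {
    features <- if (cfg$cluster_features == "normalized_swi") {
      stats::setNames(div$normalized_swi, div$sample_id)
    } else {
      taxa <- sort(unique(unlist(lapply(profiles, function(p)
        names(p$counts)))))
      vecs <- lapply(profiles, function(p) {
        v <- stats::setNames(numeric(length(taxa)), taxa)
        v[names(p$counts)] <- p$counts / sum(p$counts)
        v
      })
      names(vecs) <- vapply(profiles, `[[`, "", "sample_id")
      vecs
    }
    dm <- euclidean_distances(features)
    dendro <- upgma(dm)
    cut <- mojena_cut(dendro, k = cfg$mojena_k)
    gt <- cut$assignment
    gt$n_groups <- cut$n_groups
    gt$theta <- cut$theta
    gt$alpha_mean <- cut$alpha_mean
    gt$alpha_sd <- cut$alpha_sd
    p <- file.path(cfg$output_dir, "groups.tsv")
    write_table(gt, p)
    product("groups", p, nrow(gt))
    pn <- file.path(cfg$output_dir, "tree.nwk")
    writeLines(to_newick(dendro), pn, useBytes = TRUE)
    product("tree", pn, dendro$n)
    finish_stage("clustering", nrow(gt))
    cut
  })
  manifest$n_groups <- groups$n_groups

  ## ---- composition -------------------------------------------------
  run_stage("composition", {
    dp <- domain_proportions(sk_profiles, metadata)
    p <- file.path(cfg$output_dir, "domain_proportions.tsv")
    write_table(dp, p)
    product("domain_proportions", p, nrow(dp))

    if (cfg$rank == "species") {
      ts <- top_species(profiles, n = cfg$top_species_n)
      pt <- file.path(cfg$output_dir, "top_species.tsv")
      write_table(ts$proportions, pt)
      product("top_species", pt, nrow(ts$proportions))
    }

    tests <- list(
      cbind(response = "normalized_swi",
            compare_layers(div, metadata, column = "normalized_swi")),
      cbind(response = "abundance_index",
            compare_layers(stats::setNames(as.numeric(div$abundance_index),
                                           div$sample_id), metadata)))
    for (d in DOMAINS) {
      tests[[length(tests) + 1L]] <-
        cbind(response = paste0("proportion_", d),
              compare_layers(dp, metadata, column = d))
    }
    tests <- do.call(rbind, tests)
    p2 <- file.path(cfg$output_dir, "tests.tsv")
    write_table(tests, p2)
    product("tests", p2, nrow(tests))
    finish_stage("composition", nrow(tests))
  })

  ## ---- functional --------------------------------------------------
  if (!is.null(cfg$annotations_dir)) {
    run_stage("functional", {
      afiles <- list.files(cfg$annotations_dir, pattern = "\\.tsv$",
                           full.names = TRUE)
      sids <- sub("\\.go\\.tsv$|\\.tsv$", "", basename(afiles))
      ann <- lapply(afiles, read_go_annotations)
      names(ann) <- sids
      freq <- term_frequencies(ann, metadata)
      mat <- top_terms_matrix(freq, n = cfg$top_terms_n,
                              scope = cfg$terms_scope)
      raw <- attr(mat, "raw")
      terms_df <- data.frame(term_id = rownames(mat),
                             raw, log10 = unclass(mat),
                             check.names = TRUE, stringsAsFactors = FALSE)
      p <- file.path(cfg$output_dir, "terms.tsv")
      write_table(terms_df, p)
      product("terms", p, nrow(terms_df))

      excl <- exclusive_terms(freq)
      excl_df <- do.call(rbind, lapply(LAYERS, function(layer) {
        if (length(excl$sets[[layer]]) == 0L) return(NULL)
        data.frame(layer = layer, term_id = excl$sets[[layer]],
                   stringsAsFactors = FALSE)
      }))
      if (is.null(excl_df)) {
        excl_df <- data.frame(layer = character(), term_id = character())
      }
      p2 <- file.path(cfg$output_dir, "exclusive.tsv")
      write_table(excl_df, p2, allow_empty = TRUE)
      product("exclusive", p2, nrow(excl_df))
      finish_stage("functional", sum(freq))
    })
  }

  manifest$status <- "complete"
  write_manifest(manifest, cfg$output_dir)
  logmsg("pipeline complete: ", length(manifest$products), " product(s)")
  invisible(manifest)
}

## The manifest omits timestamps and the output location on purpose:
## reruns with the same inputs must be byte-identical wherever they land.
write_manifest <- function(manifest, output_dir) {
  cfg_echo <- manifest$config
  cfg_echo$output_dir <- NULL
  cfg_lines <- vapply(names(cfg_echo), function(k)
    paste0(k, ": ", paste(format(cfg_echo[[k]]), collapse = ",")), "")
  tmp <- file.path(output_dir, "effective_config.txt")
  writeLines(cfg_lines, tmp, useBytes = TRUE)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  manifest$config <- as.list(cfg_echo)
  class(manifest$config) <- NULL
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}
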