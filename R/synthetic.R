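## Seeded synthetic multi-station, multi-layer community generator.
## Emits exactly the tables the readers consume, together with the planted
## ground truth, so every downstream stage can be verified end to end.

#' Build a generator configuration
#'
#' All knobs of the synthetic community generator.  Defaults (see
#' [default_config()]) emulate the statistical structure of tropical-ocean
#' shotgun metagenomes sampled at three depth layers: read totals spanning
#' roughly 5e4-4e7, normalized diversity around 0.4-0.65, an archaeal
#' share that grows with depth while the viral share shrinks, a more
#' species-rich mesopelagic layer, and depth-layer-exclusive GO terms.
#'
#' @param n_stations Number of collection stations.
#' @param samples_per_station_layer Named integer vector (`SRF`, `DCM`,
#'   `MES`): replicates per station and layer.
#' @param species_pool_size Named integer vector over [DOMAINS]: size of
#'   the global species pool per domain.
#' @param richness_by_layer Named integer vector: distinct species drawn
#'   per sample in each layer.
#' @param lognormal_sigma Log-scale standard deviation of the species
#'   abundance distribution (larger = less even communities).
#' @param domain_mix_by_layer 3x3 numeric matrix, layers as rows
#'   (`SRF`/`DCM`/`MES`) and [DOMAINS] as columns; each row sums to 1 and
#'   fixes the share of classified reads per domain.
#' @param read_total_range Length-2 vector: classified read totals are
#'   drawn log-uniformly from this range.
#' @param unclassified_fraction Fraction of all emitted rows flagged
#'   unclassified (status `U`).
#' @param go_terms_shared Number of GO terms common to all layers.
#' @param go_terms_exclusive_by_layer Named integer vector: GO terms
#'   planted exclusively in each layer.
#' @param go_term_probs Probabilities that a classified read carries 0, 1
#'   or 2 GO annotations.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_stations,
                             samples_per_station_layer,
                             species_pool_size,
                             richness_by_layer,
                             lognormal_sigma,
                             domain_mix_by_layer,
                             read_total_range,
                             unclassified_fraction = 0.10,
                             go_terms_shared = 200L,
                             go_terms_exclusive_by_layer =
                               c(SRF = 24L, DCM = 53L, MES = 10L),
                             go_term_probs = c(0.3, 0.5, 0.2),
                             seed = 1L) {
  cfg <- structure(
    list(n_stations = as.integer(n_stations),
         samples_per_station_layer =
           as_named_int(samples_per_station_layer, LAYERS),
         species_pool_size = as_named_int(species_pool_size, DOMAINS),
         richness_by_layer = as_named_int(richness_by_layer, LAYERS),
         lognormal_sigma = as.numeric(lognormal_sigma),
         domain_mix_by_layer = as_mix_matrix(domain_mix_by_layer),
         read_total_range = as.numeric(read_total_range),
         unclassified_fraction = as.numeric(unclassified_fraction),
         go_terms_shared = as.integer(go_terms_shared),
         go_terms_exclusive_by_layer =
           as_named_int(go_terms_exclusive_by_layer, LAYERS),
         go_term_probs = as.numeric(go_term_probs),
         seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
}

as_named_int <- function(x, want) {
  if (is.null(names(x))) names(x) <- want[seq_along(x)]
  if (!all(want %in% names(x))) {
    stop("expected entries named ", paste(want, collapse = ", "),
         call. = FALSE)
  }
  v <- as.integer(x[want])
  names(v) <- want
  v
}

as_mix_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- LAYERS
  if (is.null(colnames(m))) colnames(m) <- DOMAINS
  m[LAYERS, DOMAINS, drop = FALSE]
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_stations < 1L) stop("n_stations must be positive", call. = FALSE)
  if (any(cfg$samples_per_station_layer < 1L)) {
    stop("samples_per_station_layer must be positive", call. = FALSE)
  }
  if (any(cfg$species_pool_size < 1L) || any(cfg$richness_by_layer < 1L)) {
    stop("species pools and richness must be positive", call. = FALSE)
  }
  if (cfg$lognormal_sigma <= 0) {
    stop("lognormal_sigma must be positive", call. = FALSE)
  }
  rs <- rowSums(cfg$domain_mix_by_layer)
  if (any(abs(rs - 1) > 1e-9) || any(cfg$domain_mix_by_layer < 0)) {
    stop("each domain mix row must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (length(cfg$read_total_range) != 2L ||
      any(cfg$read_total_range < 1) ||
      cfg$read_total_range[1L] > cfg$read_total_range[2L]) {
    stop("read_total_range must be (min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (cfg$unclassified_fraction < 0 || cfg$unclassified_fraction >= 1) {
    stop("unclassified_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$go_terms_shared < 1L || any(cfg$go_terms_exclusive_by_layer < 0L)) {
    stop("GO term counts must be non-negative (shared pool >= 1)",
         call. = FALSE)
  }
  if (length(cfg$go_term_probs) != 3L || any(cfg$go_term_probs < 0) ||
      abs(sum(cfg$go_term_probs) - 1) > 1e-9) {
    stop("go_term_probs must be 3 probabilities summing to 1", call. = FALSE)
  }
  ## every layer's per-domain species draw must fit inside the pools
  for (layer in LAYERS) {
    alloc <- allocate_richness(cfg$richness_by_layer[[layer]],
                               cfg$domain_mix_by_layer[layer, ])
    over <- alloc > cfg$species_pool_size
    if (any(over)) {
      stop("richness for layer ", layer, " exceeds the ",
           paste(DOMAINS[over], collapse = ", "), " species pool",
           call. = FALSE)
    }
  }
  cfg
}

#' Default generator configuration
#'
#' Eight stations, three replicates per station and layer (72 samples),
#' classified read totals drawn log-uniformly from 5e4 to 4e7, a
#' log-normal species abundance distribution (sigma 1.5) over a pool of
#' 300 bacterial, 100 archaeal and 150 viral species, per-sample richness
#' of 60 species in SRF and DCM versus 150 in MES, archaeal read share
#' rising with depth (3% / 5% / 13%) while the viral share falls
#' (18% / 17% / 3%), and 200 shared GO terms plus 24/53/10 terms exclusive
#' to SRF/DCM/MES.  Under these settings per-sample normalized diversity
#' falls roughly in [0.35, 0.70] with the mesopelagic layer clearly more
#' diverse than the two photic layers.
#'
#' @param seed Integer seed (default 1).
#' @return A `generator_config`.
#' @export
default_config <- function(seed = 1L) {
  generator_config(
    n_stations = 8L,
    samples_per_station_layer = c(SRF = 3L, DCM = 3L, MES = 3L),
    species_pool_size = c(Archaea = 100L, Bacteria = 300L, Viruses = 150L),
    richness_by_layer = c(SRF = 60L, DCM = 60L, MES = 150L),
    lognormal_sigma = 1.5,
    domain_mix_by_layer = matrix(
      c(0.03, 0.79, 0.18,
        0.05, 0.78, 0.17,
        0.13, 0.84, 0.03),
      nrow = 3, byrow = TRUE, dimnames = list(LAYERS, DOMAINS)),
    read_total_range = c(5e4, 4e7),
    seed = seed)
}

## Largest-remainder allocation of a sample's richness across domains,
## guaranteeing at least one species for every domain with positive mix.
allocate_richness <- function(S, mix) {
  raw <- S * mix
  alloc <- floor(raw)
  rem <- S - sum(alloc)
  if (rem > 0) {
    extra <- order(-(raw - alloc), seq_along(raw))[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  need <- which(mix > 0 & alloc == 0)
  for (i in need) {
    donor <- which.max(alloc)
    alloc[donor] <- alloc[donor] - 1
    alloc[i] <- 1
  }
  if (any(alloc < 0) || sum(mix > 0) > S) {
    stop("richness too small to cover every domain with positive mix",
         call. = FALSE)
  }
  stats::setNames(as.integer(alloc), names(mix))
}

## Species pool with fabricated but structurally realistic lineages.
build_species_pool <- function(pool_size) {
  rows <- list()
  tax_base <- 1000L
  for (d in DOMAINS) {
    n <- pool_size[[d]]
    idx <- seq_len(n)
    genus <- sprintf("%s_genus_%03d", d, ceiling(idx / 5))
    rows[[d]] <- data.frame(
      species = sprintf("%s_sp_%04d", d, idx),
      superkingdom = d,
      phylum = sprintf("%s_phylum_%02d", d, (idx - 1L) %% 8L + 1L),
      class = sprintf("%s_class_%02d", d, (idx - 1L) %% 16L + 1L),
      order = sprintf("%s_order_%02d", d, (idx - 1L) %% 24L + 1L),
      family = sprintf("%s_family_%03d", d, ceiling(idx / 10)),
      genus = genus,
      taxon_id = tax_base + idx,
      stringsAsFactors = FALSE)
    tax_base <- tax_base + n + 1000L
  }
  pool <- do.call(rbind, rows)
  rownames(pool) <- NULL
  pool
}

## Disjoint GO term pools: one shared block plus one exclusive block per
## layer, numbered consecutively.
build_go_pools <- function(cfg) {
  nxt <- 1L
  take <- function(n) {
    ids <- sprintf("GO:%07d", seq.int(nxt, length.out = n))
    nxt <<- nxt + n
    ids
  }
  shared <- take(cfg$go_terms_shared)
  exclusive <- lapply(stats::setNames(LAYERS, LAYERS), function(layer)
    take(cfg$go_terms_exclusive_by_layer[[layer]]))
  list(shared = shared, exclusive = exclusive)
}

#' Generate a synthetic multi-station, multi-layer dataset
#'
#' For every station x layer x replicate the generator draws a classified
#' read total log-uniformly from `read_total_range`, samples the layer's
#' species set per domain from the global pools, assigns species relative
#' abundances from a log-normal distribution scaled within domains by the
#' layer's domain mix, and draws per-species read counts from a
#' multinomial over those proportions.  Unclassified rows are added so
#' that they make up `unclassified_fraction` of all emitted rows.  GO
#' annotations give each classified read 0-2 terms from the layer's pool
#' (shared terms plus that layer's exclusive terms); every pool term is
#' guaranteed at least one occurrence in its layer so the planted
#' exclusivity sets are exactly recoverable.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given, the classification
#'   tables (`classifications/<sample>.kaiju.tsv`), metadata
#'   (`metadata.tsv`), GO annotations (`annotations/<sample>.go.tsv`) and
#'   a `ground_truth.json` sidecar are written there.
#' @param materialize_reads Emit per-read classification rows and GO
#'   annotations (default `TRUE` when writing to disk, `FALSE` otherwise).
#'   When `FALSE` only the per-sample species count vectors are produced,
#'   which is much faster at large read totals.
#' @return A list with elements `metadata` (data frame), `counts` (named
#'   list of per-sample species count vectors), `domain_counts` (named
#'   list of per-sample domain read counts), `reads` and `annotations`
#'   (named lists of data frames, `NULL` unless materialized),
#'   `ground_truth`, and `paths` when written to disk.
#' @export
generate_dataset <- function(config, out_dir = NULL,
                             materialize_reads = !is.null(out_dir)) {
  cfg <- validate_generator_config(config)
  if (!is.null(out_dir) && !materialize_reads) {
    stop("writing a dataset to disk requires materialize_reads = TRUE",
         call. = FALSE)
  }
  set.seed(cfg$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  pool <- build_species_pool(cfg$species_pool_size)
  go <- build_go_pools(cfg)
  oceans <- c("Indian", "South Atlantic", "South Pacific")

  meta_rows <- list()
  counts <- list()
  domain_counts <- list()
  reads <- if (materialize_reads) list() else NULL
  annotations <- if (materialize_reads) list() else NULL
  truth_samples <- list()
  species_sets <- list()

  for (s in seq_len(cfg$n_stations)) {
    station <- sprintf("%03d", s)
    ocean <- oceans[(s - 1L) %% length(oceans) + 1L]
    for (layer in LAYERS) {
      mix <- cfg$domain_mix_by_layer[layer, ]
      alloc <- allocate_richness(cfg$richness_by_layer[[layer]], mix)
      for (r in seq_len(cfg$samples_per_station_layer[[layer]])) {
        sid <- sprintf("T%s-%s-%d", station, layer, r)
        total <- round(exp(stats::runif(
          1, log(cfg$read_total_range[1L]), log(cfg$read_total_range[2L]))))

        ## species set and relative abundances, domain block by block
        sp_idx <- integer(); p <- numeric()
        for (d in DOMAINS) {
          if (alloc[[d]] == 0L) next
          in_domain <- which(pool$superkingdom == d)
          pick <- sort(sample(in_domain, alloc[[d]]))
          w <- stats::rlnorm(length(pick), 0, cfg$lognormal_sigma)
          sp_idx <- c(sp_idx, pick)
          p <- c(p, mix[[d]] * w / sum(w))
        }
        p <- p / sum(p)   # guard against dropped zero-mix domains
        cnt <- stats::rmultinom(1, total, p)[, 1L]
        names(cnt) <- pool$species[sp_idx]
        keep <- cnt > 0
        counts[[sid]] <- cnt[keep]
        domain_counts[[sid]] <- vapply(
          stats::setNames(DOMAINS, DOMAINS),
          function(d) sum(cnt[pool$superkingdom[sp_idx] == d]), numeric(1))

        meta_rows[[sid]] <- data.frame(
          sample_id = sid, station = station, layer = layer, ocean = ocean,
          stringsAsFactors = FALSE)
        truth_samples[[sid]] <- data.frame(
          sample_id = sid, station = station, layer = layer,
          read_total = total, richness_drawn = length(sp_idx),
          stringsAsFactors = FALSE)
        species_sets[[sid]] <- pool$species[sp_idx]

        if (materialize_reads) {
          reads[[sid]] <- materialize_sample_reads(sid, cnt[keep],
                                                   pool[sp_idx[keep], ],
                                                   cfg$unclassified_fraction)
          cl_ids <- reads[[sid]]$read_id[reads[[sid]]$status == "classified"]
          annotations[[sid]] <- draw_annotations(
            cl_ids, c(go$shared, go$exclusive[[layer]]), cfg$go_term_probs)
        }
      }
    }
  }

  if (materialize_reads) {
    annotations <- top_up_layer_terms(annotations, reads, meta_rows, go)
  }

  metadata <- do.call(rbind, meta_rows)
  rownames(metadata) <- NULL
  ground_truth <- list(
    seed = cfg$seed,
    samples = {
      ts <- do.call(rbind, truth_samples); rownames(ts) <- NULL; ts
    },
    species_sets = species_sets,
    domain_mix_by_layer = cfg$domain_mix_by_layer,
    richness_by_layer = cfg$richness_by_layer,
    go_shared = go$shared,
    go_exclusive = go$exclusive)

  out <- list(metadata = metadata, counts = counts,
              domain_counts = domain_counts, reads = reads,
              annotations = annotations, ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    out$paths <- write_dataset(out, out_dir)
  }
  out
}

## One read row per classified read (grouped by species), plus enough
## status-U rows that they form `unclassified_fraction` of all rows.
materialize_sample_reads <- function(sid, cnt, lineages, unclassified_frac) {
  idx <- rep(seq_along(cnt), cnt)
  n_cl <- length(idx)
  n_un <- if (unclassified_frac > 0) {
    round(n_cl * unclassified_frac / (1 - unclassified_frac))
  } else 0L
  lin_cols <- lineages[idx, c(RANKS[-7L]), drop = FALSE]
  df <- data.frame(
    status = c(rep("classified", n_cl), rep("unclassified", n_un)),
    read_id = sprintf("%s_r%07d", sid, seq_len(n_cl + n_un)),
    taxon_id = c(lineages$taxon_id[idx], rep(0L, n_un)),
    stringsAsFactors = FALSE)
  for (rk in RANKS[-7L]) {
    df[[rk]] <- c(lin_cols[[rk]], rep(NA_character_, n_un))
  }
  df$species <- c(lineages$species[idx], rep(NA_character_, n_un))
  rownames(df) <- NULL
  df
}

## 0-2 GO terms per classified read, drawn uniformly from the layer pool.
draw_annotations <- function(read_ids, pool, probs) {
  k <- sample(0:2, length(read_ids), replace = TRUE, prob = probs)
  n <- sum(k)
  if (n == 0L) {
    return(data.frame(read_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(read_id = rep(read_ids, k),
             term_id = sample(pool, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## Guarantee every term of a layer's pool occurs at least once in that
## layer, so exclusivity is exactly the planted design.
top_up_layer_terms <- function(annotations, reads, meta_rows, go) {
  layer_of <- vapply(meta_rows, function(m) m$layer, "")
  for (layer in LAYERS) {
    sids <- names(layer_of)[layer_of == layer]
    if (length(sids) == 0L) next
    pool_terms <- c(go$shared, go$exclusive[[layer]])
    seen <- unique(unlist(lapply(sids, function(sid)
      annotations[[sid]]$term_id), use.names = FALSE))
    missing <- setdiff(pool_terms, seen)
    if (length(missing) == 0L) next
    host <- sids[1L]
    host_reads <- reads[[host]]$read_id[reads[[host]]$status == "classified"]
    extra <- data.frame(
      read_id = sample(host_reads, length(missing), replace = TRUE),
      term_id = missing, stringsAsFactors = FALSE)
    annotations[[host]] <- rbind(annotations[[host]], extra)
  }
  annotations
}

## Serialize a generated dataset in exactly the formats the readers parse.
write_dataset <- function(ds, out_dir) {
  cls_dir <- file.path(out_dir, "classifications")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)

  paths <- list(metadata = file.path(out_dir, "metadata.tsv"),
                ground_truth = file.path(out_dir, "ground_truth.json"),
                classifications = character(), annotations = character())
  write_table(ds$metadata, paths$metadata)

  for (sid in names(ds$reads)) {
    df <- ds$reads[[sid]]
    lineage <- apply(df[RANKS], 1L, function(v) {
      if (all(is.na(v))) return(NA_character_)
      paste0(paste(ifelse(is.na(v), "NA", v), collapse = "; "), ";")
    })
    flag <- ifelse(df$status == "classified", "C", "U")
    lines <- ifelse(is.na(lineage),
                    paste(flag, df$read_id, df$taxon_id, sep = "\t"),
                    paste(flag, df$read_id, df$taxon_id, lineage, sep = "\t"))
    p <- file.path(cls_dir, paste0(sid, ".kaiju.tsv"))
    writeLines(lines, p, useBytes = TRUE)
    paths$classifications[sid] <- p

    a <- ds$annotations[[sid]]
    pa <- file.path(ann_dir, paste0(sid, ".go.tsv"))
    writeLines(paste(a$read_id, a$term_id, sep = "\t"), pa, useBytes = TRUE)
    paths$annotations[sid] <- pa
  }
  jsonlite::write_json(ds$ground_truth, paths$ground_truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

#' Taxonomic profiles from generated count vectors
#'
#' Convenience bridge from the generator's in-memory representation to the
#' analysis functions: wraps each per-sample species count vector (or
#' domain count vector) as a [taxonomic_profile()].
#'
#' @param counts Named list of named count vectors (e.g. `$counts` or
#'   `$domain_counts` from [generate_dataset()]).
#' @param rank Rank the counts are aggregated at.
#' @return A list of `taxonomic_profile` objects.
#' @export
profiles_from_counts <- function(counts, rank = "species") {
  lapply(names(counts), function(sid) {
    cnt <- counts[[sid]]
    taxonomic_profile(sample_id = sid, rank = rank,
                      counts = cnt[cnt > 0])
  })
}
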