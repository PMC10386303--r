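test_that("configuration invariants are enforced", {
  expect_s3_class(default_config(), "generator_config")

  bad_mix <- matrix(c(0.5, 0.4, 0.2,
                      0.05, 0.78, 0.17,
                      0.13, 0.84, 0.03),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(LAYERS, DOMAINS))
  expect_error(
    generator_config(1, c(SRF = 1, DCM = 1, MES = 1),
                     c(Archaea = 10, Bacteria = 10, Viruses = 10),
                     c(SRF = 5, DCM = 5, MES = 5), 1, bad_mix,
                     c(100, 100)),
    "sum to 1")

  ok_mix <- matrix(rep(c(0.2, 0.6, 0.2), 3), nrow = 3, byrow = TRUE,
                   dimnames = list(LAYERS, DOMAINS))
  expect_error(
    generator_config(1, c(SRF = 1, DCM = 1, MES = 1),
                     c(Archaea = 2, Bacteria = 5, Viruses = 2),
                     c(SRF = 40, DCM = 5, MES = 5), 1, ok_mix,
                     c(100, 100)),
    "exceeds the")

  expect_error(
    generator_config(1, c(SRF = 1, DCM = 1, MES = 1),
                     c(Archaea = 10, Bacteria = 10, Viruses = 10),
                     c(SRF = 5, DCM = 5, MES = 5), 1, ok_mix,
                     c(1000, 100)),
    "read_total_range")
})

test_that("identical seeds give byte-identical datasets", {
  cfg <- small_config(seed = 7, read_total = 400, n_stations = 1L,
                      samples = c(SRF = 1L, DCM = 1L, MES = 1L))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  ## a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  unlink(d3, recursive = TRUE)
  cfg3 <- small_config(seed = 8, read_total = 400, n_stations = 1L,
                       samples = c(SRF = 1L, DCM = 1L, MES = 1L))
  generate_dataset(cfg3, out_dir = d3)
  f3 <- list.files(d3, recursive = TRUE, full.names = TRUE)
  expect_false(all(tools::md5sum(f1) == tools::md5sum(f3)))
})

test_that("emitted classified rows honour the drawn read totals", {
  ds <- generate_dataset(small_config(seed = 21, read_total = 700,
                                      n_stations = 1L,
                                      samples = c(SRF = 1L, DCM = 1L,
                                                  MES = 1L)),
                         materialize_reads = TRUE)
  truth <- ds$ground_truth$samples
  for (i in seq_len(nrow(truth))) {
    sid <- truth$sample_id[i]
    expect_equal(sum(ds$reads[[sid]]$status == "classified"),
                 truth$read_total[i])
    expect_equal(sum(ds$counts[[sid]]), truth$read_total[i])
  }
  ## unclassified rows approximate the configured 10% of all rows
  r <- ds$reads[[truth$sample_id[1]]]
  expect_equal(mean(r$status == "unclassified"), 0.1, tolerance = 0.01)
})

test_that("planted domain mixes are recovered within multinomial error", {
  mix <- matrix(c(0.03, 0.79, 0.18,
                  0.05, 0.78, 0.17,
                  0.25, 0.70, 0.05),   # Archaea, Bacteria, Viruses
                nrow = 3, byrow = TRUE,
                dimnames = list(LAYERS, DOMAINS))
  cfg <- generator_config(
    n_stations = 1L, samples_per_station_layer = c(SRF = 1, DCM = 1, MES = 1),
    species_pool_size = c(Archaea = 40L, Bacteria = 120L, Viruses = 60L),
    richness_by_layer = c(SRF = 25L, DCM = 25L, MES = 60L),
    lognormal_sigma = 1.5, domain_mix_by_layer = mix,
    read_total_range = c(1e5, 1e5), seed = 99)
  ds <- generate_dataset(cfg, materialize_reads = FALSE)
  mes <- ds$domain_counts[["T001-MES-1"]]
  expect_equal(mes[["Archaea"]] / sum(mes), 0.25, tolerance = 0.01)
  expect_equal(mes[["Viruses"]] / sum(mes), 0.05, tolerance = 0.01)
})

test_that("a threefold mesopelagic richness raises mean normalized diversity", {
  diffs <- numeric(20)
  for (i in 1:20) {
    cfg <- generator_config(
      n_stations = 1L,
      samples_per_station_layer = c(SRF = 1, DCM = 1, MES = 1),
      species_pool_size = c(Archaea = 60L, Bacteria = 200L, Viruses = 90L),
      richness_by_layer = c(SRF = 30L, DCM = 30L, MES = 90L),
      lognormal_sigma = 1.5,
      domain_mix_by_layer = default_config()$domain_mix_by_layer,
      read_total_range = c(5000, 5000), seed = 5000 + i)
    ds <- generate_dataset(cfg, materialize_reads = FALSE)
    div <- diversity_table(profiles_from_counts(ds$counts))
    layer <- stats::setNames(ds$metadata$layer,
                             ds$metadata$sample_id)[div$sample_id]
    diffs[i] <- mean(div$normalized_swi[layer == "MES"]) -
      mean(div$normalized_swi[layer == "SRF"])
  }
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("default configuration plants the documented study conditions", {
  ds <- generate_dataset(default_config(seed = 17),
                         materialize_reads = FALSE)
  truth <- ds$ground_truth$samples
  expect_equal(nrow(truth), 8 * 3 * 3)
  expect_true(all(truth$read_total >= 1e4))
  expect_true(all(truth$read_total >= 5e4 & truth$read_total <= 4e7))

  div <- diversity_table(profiles_from_counts(ds$counts))
  ## diversity lands roughly in the documented band: the bulk inside
  ## [0.35, 0.70], stray samples allowed a little slack
  expect_gte(mean(div$normalized_swi >= 0.35 & div$normalized_swi <= 0.70),
             0.9)
  expect_true(all(div$normalized_swi > 0.2 & div$normalized_swi < 0.75))
  expect_true(stats::median(div$normalized_swi) > 0.4 &&
              stats::median(div$normalized_swi) < 0.65)

  layer <- stats::setNames(ds$metadata$layer,
                           ds$metadata$sample_id)
  arch <- vapply(ds$domain_counts, function(x) x[["Archaea"]] / sum(x),
                 numeric(1))
  vir <- vapply(ds$domain_counts, function(x) x[["Viruses"]] / sum(x),
                numeric(1))
  lay <- layer[names(arch)]
  ## archaeal share grows with depth, viral share shrinks
  expect_lt(mean(arch[lay == "SRF"]), mean(arch[lay == "DCM"]))
  expect_lt(mean(arch[lay == "DCM"]), mean(arch[lay == "MES"]))
  expect_gt(mean(vir[lay == "DCM"]), mean(vir[lay == "MES"]))
  ## the mesopelagic layer is the most diverse
  dl <- layer[div$sample_id]
  expect_gt(mean(div$normalized_swi[dl == "MES"]),
            mean(div$normalized_swi[dl == "SRF"]))
})

test_that("ground-truth GO pools are disjoint and fully planted", {
  ds <- generate_dataset(small_config(seed = 33, read_total = 500,
                                      n_stations = 1L,
                                      samples = c(SRF = 1L, DCM = 1L,
                                                  MES = 1L)),
                         materialize_reads = TRUE)
  gt <- ds$ground_truth
  pools <- c(list(gt$go_shared), gt$go_exclusive)
  all_terms <- unlist(pools)
  expect_equal(anyDuplicated(all_terms), 0L)
  ## every planted term occurs somewhere in its layer
  layer_of <- stats::setNames(ds$metadata$layer, ds$metadata$sample_id)
  for (layer in LAYERS) {
    seen <- unique(unlist(lapply(
      names(ds$annotations)[layer_of[names(ds$annotations)] == layer],
      function(sid) ds$annotations[[sid]]$term_id)))
    expect_true(all(c(gt$go_shared, gt$go_exclusive[[layer]]) %in% seen))
    ## and no foreign exclusive term leaks in
    foreign <- unlist(gt$go_exclusive[setdiff(LAYERS, layer)])
    expect_false(any(foreign %in% seen))
  }
})
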