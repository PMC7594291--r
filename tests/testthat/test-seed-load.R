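cfg_default <- dispersal_config()

test_that("volume converts to dry mass at 0.13 g/ml", {
  expect_equal(volume_to_dry_mass(1, cfg_default), 0.13)
  expect_equal(volume_to_dry_mass(172.3, cfg_default), 22.399)
  expect_error(volume_to_dry_mass(0, cfg_default), "> 0")
  expect_error(volume_to_dry_mass(-5, cfg_default), "> 0")
})

test_that("contamination filter excludes species in >= 3 distinct control trays", {
  seedl <- data.frame(sample_id = c("s1", "s1", "s2"),
                      species = c("weed", "herb", "weed"),
                      count = c(4L, 2L, 1L))
  ctrl <- data.frame(tray_id = c("t1", "t2", "t3", "t1", "t2", "t1", "t1"),
                     species = c("weed", "weed", "weed", "herb", "herb",
                                 "other", "other"))
  out <- exclude_contaminants(seedl, ctrl, cfg_default)
  expect_identical(out$excluded, "weed")          # 3 distinct trays
  expect_false("weed" %in% out$seedlings$species) # removed everywhere
  expect_true("herb" %in% out$seedlings$species)  # only 2 trays: retained

  # duplicate rows within one tray do not count twice
  ctrl2 <- data.frame(tray_id = c("t1", "t1", "t1"), species = "dup")
  expect_length(exclude_contaminants(seedl, ctrl2, cfg_default)$excluded, 0)

  # no control rows: no exclusions
  none <- exclude_contaminants(seedl, ctrl[0, ], cfg_default)
  expect_identical(none$seedlings, seedl)
  expect_length(none$excluded, 0)
})

test_that("seed load Q follows count / (volume * 0.13) and cell means", {
  dung <- data.frame(sample_id = c("s1", "s2", "s3"),
                     animal_id = c("a1", "a1", "a2"),
                     collection_date = as.Date(c("2018-06-05", "2018-06-20",
                                                 "2018-07-02")),
                     volume_ml = c(100, 100, 200))
  seedl <- data.frame(sample_id = c("s1", "s2", "s3"),
                      species = c("spA", "spA", "spA"),
                      count = c(13L, 39L, 0L))
  tab <- build_seed_load_table(dung, seedl, cfg_default)
  # 13 seedlings in 100 ml at 0.13 g/ml = 1.0 seedlings per gram
  expect_equal(tab$samples$q_total[tab$samples$sample_id == "s1"], 1.0)
  # cell (a1, Jun) holds two samples with q = 1 and 3: mean 2
  cell <- tab$cells[tab$cells$animal_id == "a1" &
                      tab$cells$month == "Jun", ]
  expect_equal(cell$q, 2.0)
  # zero seedlings give q = 0
  expect_equal(tab$totals$total_q[tab$totals$animal_id == "a2"], 0)

  # cell totals equal species sums exactly
  multi <- rbind(seedl,
                 data.frame(sample_id = "s1", species = "spB", count = 26L))
  tab2 <- build_seed_load_table(dung, multi, cfg_default)
  t_a1 <- tab2$totals$total_q[tab2$totals$animal_id == "a1"]
  s_a1 <- sum(tab2$cells$q[tab2$cells$animal_id == "a1"])
  expect_equal(t_a1, s_a1)

  # the literal count/volume*ratio variant differs by the mass factor
  cfg_lit <- dispersal_config(q_formula = "literal")
  tab_lit <- build_seed_load_table(dung, seedl, cfg_lit)
  expect_equal(tab_lit$samples$q_total[1], 13 / 100 * 0.13)

  expect_error(build_seed_load_table(dung, transform(seedl,
                                                     sample_id = "nope"),
                                     cfg_default),
               "unknown sample_id")
})

test_that("Q is invariant to proportional sample splitting", {
  dung1 <- data.frame(sample_id = "s1", animal_id = "a1",
                      collection_date = as.Date("2018-08-10"),
                      volume_ml = 200)
  seedl1 <- data.frame(sample_id = "s1", species = "spA", count = 26L)
  # split into two half-volume samples with half the counts each
  dung2 <- data.frame(sample_id = c("s1a", "s1b"), animal_id = "a1",
                      collection_date = as.Date("2018-08-10"),
                      volume_ml = c(100, 100))
  seedl2 <- data.frame(sample_id = c("s1a", "s1b"), species = "spA",
                       count = c(13L, 13L))
  q1 <- build_seed_load_table(dung1, seedl1, cfg_default)$cells$q
  q2 <- build_seed_load_table(dung2, seedl2, cfg_default)$cells$q
  expect_equal(q1, q2)
})

test_that("pooled and sum aggregation modes behave as documented", {
  dung <- data.frame(sample_id = c("s1", "s2"), animal_id = "a1",
                     collection_date = as.Date("2018-06-05"),
                     volume_ml = c(100, 300))
  seedl <- data.frame(sample_id = c("s1", "s2"), species = "spA",
                      count = c(13L, 13L))
  pooled <- build_seed_load_table(dung, seedl,
                                  dispersal_config(cell_aggregation = "pooled"))
  expect_equal(pooled$cells$q, 26 / (400 * 0.13))
  summed <- build_seed_load_table(dung, seedl,
                                  dispersal_config(cell_aggregation = "sum"))
  expect_equal(summed$cells$q, 13 / 13 + 13 / 39)
})

test_that("species filter requires a minimum number of dispersing individuals", {
  dung <- data.frame(sample_id = sprintf("s%d", 1:6),
                     animal_id = sprintf("a%d", 1:6),
                     collection_date = as.Date("2018-09-15"),
                     volume_ml = 100)
  seedl <- rbind(
    data.frame(sample_id = sprintf("s%d", 1:5), species = "common",
               count = 3L),
    data.frame(sample_id = sprintf("s%d", 1:4), species = "scarce",
               count = 2L))
  tab <- build_seed_load_table(dung, seedl, cfg_default)
  counts <- species_individual_counts(tab, cfg_default)
  expect_equal(unname(counts$counts[c("common", "scarce")]), c(5L, 4L))
  # 5 individuals meets the threshold, 4 does not
  expect_identical(counts$filtered, "common")

  empty <- build_seed_load_table(dung, seedl[0, ], cfg_default)
  expect_length(species_individual_counts(empty, cfg_default)$counts, 0)
})

test_that("species_load_vector zero-fills unsampled species cells", {
  dung <- data.frame(sample_id = c("s1", "s2"), animal_id = c("a1", "a2"),
                     collection_date = as.Date(c("2018-05-02",
                                                 "2018-06-02")),
                     volume_ml = 100)
  seedl <- data.frame(sample_id = "s1", species = "spA", count = 13L)
  tab <- build_seed_load_table(dung, seedl, cfg_default)
  lv <- species_load_vector(tab, "spA")
  expect_equal(nrow(lv), 2) # every sampled cell appears
  expect_equal(sort(lv$q), c(0, 1))
})
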