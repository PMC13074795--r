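test_that("TAA and EAA sums skip missing constituents and exclude taurine", {
  expect_equal(compute_taa(full_profile(100)), 1800)
  p <- full_profile(100)
  p <- p[names(p) != "TRP"]
  expect_equal(compute_taa(p), 1700)
  expect_equal(compute_taa(c(TAU = 50)), 0)
  expect_equal(compute_eaa(c(full_profile(100), TAU = 999)), 1000)
  expect_equal(compute_eaa(numeric(0)), 0)
})

test_that("sums agree with an independent brute-force re-implementation", {
  taa18 <- c("ILE", "LEU", "LYS", "MET", "PHE", "THR", "TRP", "VAL", "HIS",
             "ARG", "TYR", "CYS", "ALA", "ASP", "GLU", "GLY", "PRO", "SER")
  set.seed(3)
  for (i in 1:30) {
    keys <- sample(aa_keys(), sample(1:19, 1))
    p <- stats::setNames(runif(length(keys), 0, 3000), keys)
    brute <- 0
    for (k in taa18) if (k %in% names(p)) brute <- brute + p[[k]]
    expect_equal(compute_taa(p), brute)
    expect_lte(compute_eaa(p), compute_taa(p))
  }
})

test_that("build_database is total, deterministic and empty-safe", {
  empty <- build_database(NULL, mk_ref("r", "x", profile = full_profile()),
                          NULL)
  expect_identical(nrow(empty$entries), 0L)
  expect_length(empty$ledger, 0)

  w <- generate_reference_set(fixture_spec(seed = 2, n_items = 50))
  db <- build_database(w$items, w$refs, w$simmap)
  expect_identical(db$entries$category,
                   unname(w$expected[db$entries$item_id]))
  expect_false(any(db$entries$category == "DEFERRED"))
  # materialized sums match recomputation from the stored profiles
  for (i in c(1, 25, 50)) {
    expect_equal(db$entries$taa_mg[i],
                 compute_taa(db$entries[i, aa_keys()]))
    expect_equal(db$entries$eaa_mg[i],
                 compute_eaa(db$entries[i, aa_keys()]))
    expect_lte(db$entries$eaa_mg[i], db$entries$taa_mg[i])
  }
})

test_that("coverage percentages and the overall cell ratio are consistent", {
  w <- generate_reference_set(
    fixture_spec(seed = 8, n_items = 40,
                 missing_counts = c(TRP = 4, TAU = 10)))
  db <- build_database(w$items, w$refs, w$simmap)
  cr <- coverage_report(db)
  per <- cr$per_variable
  expect_equal(per$percent[per$variable == "TRP"], 36 / 40 * 100)
  expect_equal(per$percent[per$variable == "TAU"], 30 / 40 * 100)
  expect_equal(per$percent[per$variable == "TAA"], 100)
  expect_true(all(per$percent >= 0 & per$percent <= 100))
  # overall = equal-weight mean of per-variable percentages
  expect_equal(cr$overall_percent, mean(per$percent))
  # fully populated database reports 100 everywhere
  w2 <- generate_reference_set(fixture_spec(seed = 8, n_items = 20,
                                            missing_rates = numeric(0)))
  cr2 <- coverage_report(build_database(w2$items, w2$refs, w2$simmap))
  expect_true(all(cr2$per_variable$percent == 100))
  expect_equal(cr2$overall_percent, 100)
})

test_that("source composition counts are conserved and percents sum to 100", {
  w <- generate_reference_set(fixture_spec(seed = 13, n_items = 60))
  db <- build_database(w$items, w$refs, w$simmap)
  sr <- source_composition_report(db$ledger, w$refs)
  expect_equal(sum(sr$by_source$n), 60)
  expect_equal(sum(sr$by_category$n), 60)
  expect_equal(sum(sr$by_source$percent), 100)
  # per-source counts within a category add up to the category subtotal
  for (cat in sr$by_category$category) {
    expect_equal(sum(sr$by_source$n[sr$by_source$category == cat]),
                 sr$by_category$n[sr$by_category$category == cat])
  }
  # single-category ledger
  one <- source_composition_report(db$ledger[
    vapply(db$ledger, function(r) r$category, "") == "CALCULATED"])
  expect_equal(one$by_category$percent, 100)
})

test_that("a second-pass reference set resolves deferrals and coverage never drops", {
  spec <- fixture_spec(seed = 17, n_items = 40,
                       path_mix = c(ANALYTICAL = 0.5, CALCULATED = 0.25,
                                    SUBSTITUTED = 0, DEFERRED = 0.25))
  w <- generate_reference_set(spec)
  db <- build_database(w$items, w$refs, w$simmap)
  n_def <- sum(db$entries$category == "DEFERRED")
  expect_gt(n_def, 0)
  cov1 <- coverage_report(db)

  # second source: an analytical, within-tolerance twin for each deferral
  def_ids <- db$entries$item_id[db$entries$category == "DEFERRED"]
  refs2 <- do.call(rbind, lapply(def_ids, function(id) {
    it <- w$items[w$items$item_id == id, ]
    mk_ref(paste0("P2", id), it$name, prep = it$preparation,
           group = it$food_group, profile = full_profile(), base = it,
           source = "second pass")
  }))
  simmap2 <- data.frame(item_id = def_ids, ref_id = paste0("P2", def_ids),
                        rank = 1L, rationale = "TAXONOMIC")
  db2 <- resolve_deferred(db, w$items, refs2, simmap2)
  expect_false(any(db2$entries$category == "DEFERRED"))
  # previously resolved entries untouched
  keep <- db$entries$category != "DEFERRED"
  expect_identical(db2$entries[keep, ], db$entries[keep, ])
  cov2 <- coverage_report(db2)
  expect_true(all(cov2$per_variable$n_nonmissing >=
                    cov1$per_variable$n_nonmissing))
  expect_gte(cov2$overall_percent, cov1$overall_percent)
})
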