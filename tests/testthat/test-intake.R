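# small two-item world shared by the intake tests
intake_world <- function() {
  items <- rbind(mk_item("f1", "rice", protein = 6),
                 mk_item("f2", "tofu", protein = 12))
  refs <- rbind(mk_ref("r1", "rice", profile = c(full_profile(300),
                                                 TAU = 10), base = items[1, ]),
                mk_ref("r2", "tofu", profile = full_profile(800),
                       base = items[2, ]))
  simmap <- data.frame(item_id = c("f1", "f2"), ref_id = c("r1", "r2"),
                       rank = 1L, rationale = "TAXONOMIC")
  db <- build_database(items, refs, simmap)
  list(items = items, db = db, protein_db = protein_lookup(items))
}

test_that("item contributions follow frequency x portion/100 x content", {
  got <- item_contribution(2, 50, c(LYS = 300))
  expect_equal(got[["LYS"]], 300)
  expect_equal(got[["GLU"]], 0)  # missing contributes nothing
  expect_equal(unname(item_contribution(0, 50, full_profile())),
               rep(0, 19))
  base <- item_contribution(1.5, 80, full_profile(120))
  expect_equal(item_contribution(3, 80, full_profile(120)), 2 * base)
})

test_that("participant intakes match a brute-force double loop", {
  w <- intake_world()
  resp <- data.frame(item_id = c("f1", "f2"),
                     freq_per_day = c(2, 0.5), portion_g = c(150, 80))
  p <- data.frame(participant_id = "P1")
  got <- participant_intakes(p, resp, w$db, w$protein_db)
  # oracle: explicit loop over items x keys
  exp_aa <- stats::setNames(rep(0, 19), aa_keys())
  for (i in seq_len(nrow(resp))) {
    prof <- as_profile(w$db$entries[w$db$entries$item_id ==
                                      resp$item_id[i], ])
    for (k in aa_keys()) {
      v <- prof[[k]]
      if (!is.na(v)) {
        exp_aa[k] <- exp_aa[k] +
          resp$freq_per_day[i] * resp$portion_g[i] / 100 * v
      }
    }
  }
  expect_equal(unlist(got[aa_keys()]), exp_aa[aa_keys()],
               ignore_attr = TRUE)
  expect_equal(got$protein_g, 2 * 1.5 * 6 + 0.5 * 0.8 * 12)
  expect_equal(got$taa_mg, sum(exp_aa[taa_keys()]))
  expect_equal(got$eaa_mg, sum(exp_aa[eaa_keys()]))
})

test_that("the TAA-to-protein ratio and empty responses behave as specified", {
  w <- intake_world()
  # one response engineered to 60 g protein and 52,020 mg TAA per day
  items <- mk_item("f9", "stew", protein = 60)
  refs <- mk_ref("r9", "stew", profile = full_profile(52020 / 18),
                 base = items)
  simmap <- data.frame(item_id = "f9", ref_id = "r9", rank = 1L,
                       rationale = "FOOD_TYPE")
  db <- build_database(items, refs, simmap)
  got <- participant_intakes(data.frame(participant_id = "P1"),
                             data.frame(item_id = "f9", freq_per_day = 1,
                                        portion_g = 100),
                             db, protein_lookup(items))
  expect_equal(got$taa_protein_percent, 86.7)
  # no responses: zero intakes, missing ratio
  none <- participant_intakes(data.frame(participant_id = "P2"),
                              data.frame(item_id = character(),
                                         freq_per_day = numeric(),
                                         portion_g = numeric()),
                              w$db, w$protein_db)
  expect_equal(none$protein_g, 0)
  expect_equal(none$taa_mg, 0)
  expect_true(is.na(none$taa_protein_percent))
})

test_that("unknown response items error in strict mode and skip in lenient", {
  w <- intake_world()
  resp <- data.frame(item_id = c("f1", "ghost"), freq_per_day = 1,
                     portion_g = 100)
  p <- data.frame(participant_id = "P1")
  expect_error(participant_intakes(p, resp, w$db, w$protein_db),
               class = "ffqaa_validation_error")
  expect_message(
    got <- participant_intakes(p, resp, w$db, w$protein_db,
                               mode = "lenient"),
    "skipping")
  expect_equal(got$protein_g, 6)
})

test_that("protein EAR is (0.66/0.9) x body weight", {
  expect_equal(protein_ear(60), 44.0)
  expect_equal(protein_ear(90), 66.0)
  s <- runif(1, 0.5, 2)
  expect_equal(protein_ear(s * 70), s * protein_ear(70))
  expect_error(protein_ear(0), class = "ffqaa_validation_error")
})

test_that("below-EAR proportions use strict comparison and partition strata", {
  participants <- data.frame(participant_id = paste0("P", 1:4),
                             sex = c("M", "M", "F", "F"),
                             age = c(35, 55, 70, 40), weight_kg = 60)
  intakes <- data.frame(participant_id = paste0("P", 1:4),
                        protein_g = c(30, 50, 50, 50))
  for (k in aa_keys()) intakes[[k]] <- 1e6  # amino acids all adequate
  ear <- default_ear_table()
  rep <- below_ear_proportions(intakes, participants, ear)
  tot <- subset(rep, sex == "Total" & age_bin == "All" & key == "PROTEIN")
  expect_equal(tot$percent_below, 25)  # exactly one of four below 44 g
  # an intake exactly at the EAR is adequate
  at <- intakes
  at$protein_g <- protein_ear(60)
  rep_at <- below_ear_proportions(at, participants, ear)
  at_prot <- subset(rep_at, key == "PROTEIN" & n > 0)
  expect_true(all(at_prot$percent_below == 0))
  # strata partition: age-bin counts sum to the stratum total
  for (sx in c("Total", "M", "F")) {
    sub <- subset(rep, sex == sx & key == "PROTEIN")
    expect_equal(sum(sub$n[sub$age_bin != "All"]),
                 sub$n[sub$age_bin == "All"])
  }
  # all intakes above all EARs -> 0 everywhere
  rich <- intakes
  rich$protein_g <- 500
  rep_rich <- below_ear_proportions(rich, participants, ear)
  expect_true(all(rep_rich$percent_below[rep_rich$n > 0] == 0))
})

test_that("combined requirements sum constituent intakes", {
  participants <- data.frame(participant_id = "P1", sex = "F", age = 45,
                             weight_kg = 60)
  intakes <- data.frame(participant_id = "P1", protein_g = 100)
  for (k in aa_keys()) intakes[[k]] <- 0
  # PHE + TYR requirement at 60 kg is 1500 mg/day; 800 + 800 = 1600 passes
  intakes$PHE <- 800
  intakes$TYR <- 800
  ear <- default_ear_table()
  ear$aa_requirements <- c(`PHE+TYR` = 25)
  rep <- below_ear_proportions(intakes, participants, ear)
  expect_equal(subset(rep, key == "PHE+TYR" &
                        age_bin == "All" & sex == "Total")$percent_below, 0)
  intakes$TYR <- 600  # 1400 < 1500
  rep <- below_ear_proportions(intakes, participants, ear)
  expect_equal(subset(rep, key == "PHE+TYR" &
                        age_bin == "All" & sex == "Total")$percent_below, 100)
})

test_that("raising every requirement weakly increases every proportion", {
  spec <- fixture_spec(seed = 31, n_items = 30, cohort_size = 150)
  w <- generate_reference_set(spec)
  db <- build_database(w$items, w$refs, w$simmap)
  coh <- generate_cohort(spec, w$items)
  ii <- cohort_intakes(coh, db, protein_lookup(w$items))
  ear_lo <- default_ear_table()
  ear_hi <- ear_lo
  ear_hi$protein_coefficient <- ear_lo$protein_coefficient * 1.5
  ear_hi$aa_requirements <- ear_lo$aa_requirements * 1.5
  lo <- below_ear_proportions(ii, coh$participants, ear_lo)
  hi <- below_ear_proportions(ii, coh$participants, ear_hi)
  expect_true(all(hi$percent_below >= lo$percent_below, na.rm = TRUE))
  # additivity: stratified counts sum to the population count
  expect_equal(sum(subset(lo, sex != "Total" & age_bin == "All" &
                            key == "PROTEIN")$n),
               subset(lo, sex == "Total" & age_bin == "All" &
                        key == "PROTEIN")$n)
})
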