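# Builders for micro-fixtures used across the matching and database tests.

mk_item <- function(id = "it1", name = "apple pie", prep = "raw",
                    group = "general", energy = 200, carb = 30,
                    protein = 10, fat = 5, moisture = 55) {
  data.frame(item_id = id, name = name, preparation = prep,
             food_group = group, similarity_key = "s1",
             energy_kcal = energy, carb_g = carb, protein_g = protein,
             fat_g = fat, moisture_g = moisture, stringsAsFactors = FALSE)
}

mk_ref <- function(id, name, prep = "raw", group = "general",
                   nut_scale = 1, profile = NULL,
                   analytical = !is.null(profile), source = "tbl",
                   base = mk_item()) {
  r <- base[, c("item_id", "name", "preparation", "food_group",
                "similarity_key", "energy_kcal", "carb_g", "protein_g",
                "fat_g", "moisture_g")]
  r$item_id <- id
  r$name <- name
  r$preparation <- prep
  r$food_group <- group
  for (col in c("energy_kcal", "carb_g", "protein_g", "fat_g",
                "moisture_g")) {
    r[[col]] <- r[[col]] * nut_scale
  }
  aa <- stats::setNames(rep(NA_real_, length(aa_keys())), aa_keys())
  if (!is.null(profile)) aa[names(profile)] <- profile
  r <- cbind(r, as.data.frame(as.list(aa)))
  r$source <- source
  r$is_analytical <- analytical
  rownames(r) <- NULL
  r
}

full_profile <- function(value = 100) {
  stats::setNames(rep(value, length(taa_keys())), taa_keys())
}

test_factors <- list(default = 6.25)

# One micro-fixture per predicate combination of the decision tree:
#   N: a name-matched reference exists
#   F: among name matches, one shares the item's preparation form
#   T: the relevant candidate's macronutrients are within tolerance
#   S: an analytical similar food is available in the similarity map
# The name-matched candidate is analytical only when it shares the form
# (so the similarity-route predicate S is carried by r_sim alone).
make_scenario <- function(N, F, T, S) {
  item <- mk_item()
  scale <- if (T) 1.1 else 1.5
  refs <- list()
  sim <- list()
  rank <- 0L
  add_sim <- function(id) {
    rank <<- rank + 1L
    sim[[length(sim) + 1L]] <<- data.frame(item_id = "it1", ref_id = id,
                                           rank = rank,
                                           rationale = "FOOD_TYPE",
                                           stringsAsFactors = FALSE)
  }
  if (N) {
    refs[[length(refs) + 1L]] <- mk_ref(
      "r_nm", "Apple  Pie", prep = if (F) "raw" else "boiled",
      nut_scale = scale, profile = if (F) full_profile() else NULL)
    add_sim("r_nm")
  }
  refs[[length(refs) + 1L]] <- mk_ref(
    "r_sim", "pear tart", prep = "boiled", nut_scale = scale,
    profile = if (S) full_profile() else NULL)
  add_sim("r_sim")
  list(item = item, refs = do.call(rbind, refs),
       simmap = do.call(rbind, sim))
}

# hand-written expected-category table for the decision tree
expected_category <- function(N, F, T, S) {
  if (N && F) {
    if (T) "ANALYTICAL" else if (S) "CALCULATED" else "DEFERRED"
  } else {
    if (!S) "DEFERRED" else if (T) "SUBSTITUTED" else "CALCULATED"
  }
}
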