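# The sequential decision algorithm that assigns each FFQ food item an
# amino acid profile with provenance.  The tree, in order:
#
#   (A)  exact name concordance (post-normalization) with the reference set?
#   (A1)   among name matches, identical preparation form?
#   (A1a)    best such candidate analytical AND macronutrients within
#            tolerance            -> ANALYTICAL (profile copied verbatim)
#   (A1b)    else: any similar food (similarity map) with a DIFFERENT
#            preparation form analytical? -> CALCULATED (nitrogen-corrected)
#   (A1c)    else                          -> DEFERRED
#   (A2)   name matches but no shared preparation form -> fall through to (B)
#   (B)  scan similarity-map candidates in rank order for an analytical one
#   (B1)   found, within tolerance  -> SUBSTITUTED (profile copied verbatim)
#   (B2)   found, outside tolerance -> CALCULATED (nitrogen-corrected)
#   (B3)   none analytical          -> DEFERRED
#
# Every node visited is recorded in the assignment trace, so the category of
# each item is auditable after the fact.

#' Macronutrient tolerance screen
#'
#' Compares the five matching nutrients (energy, carbohydrate, protein,
#' fat, moisture) of a candidate reference food against the target item.
#' The relative difference base is the TARGET item's value (the fixed
#' object of assignment): `|candidate - target| / target`.  When the target
#' value is exactly 0 the relative difference is undefined; the candidate
#' passes that nutrient iff it lies within an absolute band (default 0.5
#' units).  Boundary equality counts as within: a candidate exactly 20%
#' away passes the default screen.
#'
#' @param target,candidate nutrient vectors (named numeric over
#'   `energy_kcal, carb_g, protein_g, fat_g, moisture_g`, or one-row
#'   data.frames carrying those columns).
#' @param tol relative tolerance as a fraction (default 0.20).
#' @param zero_band absolute band used when a target nutrient is 0.
#' @return list with `diff` (named per-nutrient relative differences) and
#'   `within` (single logical: conjunction over all five nutrients).
#' @export
nutrient_tolerance <- function(target, candidate, tol = 0.20,
                               zero_band = 0.5) {
  if (!is.numeric(tol) || tol <= 0) stop_config("tolerance must be > 0")
  t <- as_nutrients(target)
  c_ <- as_nutrients(candidate)
  if (any(t < 0) || any(c_ < 0)) {
    stop_validation("negative nutrient values")
  }
  d <- ifelse(t > 0, abs(c_ - t) / t, ifelse(c_ <= zero_band, 0, Inf))
  names(d) <- NUTRIENT_COLS
  list(diff = d, within = all(d <= tol))
}

# ordered similarity-map candidate ids for one item
simmap_candidates <- function(item_id, simmap) {
  if (is.null(simmap) || nrow(simmap) == 0) return(character())
  rows <- simmap[simmap$item_id == item_id, , drop = FALSE]
  rows$ref_id[order(rows$rank)]
}

#' Classify one FFQ food item
#'
#' Runs the sequential matching/substitution decision tree for a single
#' item against a validated reference set and returns an assignment record:
#' the category (`ANALYTICAL`, `CALCULATED`, `SUBSTITUTED` or `DEFERRED`),
#' the assigned profile (absent iff deferred), the id of the reference food
#' used, and the full decision trace.
#'
#' `ANALYTICAL` and `SUBSTITUTED` profiles are verbatim copies of the
#' reference profile; `CALCULATED` profiles are the reference profile
#' rescaled by the target/similar nitrogen ratio, each food's nitrogen
#' derived from its protein via its own food-group conversion factor.
#'
#' Candidate ordering: the similarity map's rank order is authoritative;
#' name-matched candidates absent from the map are ordered by id.
#'
#' @param item one-row data.frame in the item schema.
#' @param refs data.frame in the reference schema.
#' @param simmap data.frame with columns `item_id`, `ref_id`, `rank`
#'   (and optionally `rationale`).
#' @param factors named list of nitrogen-to-protein factors by food group,
#'   with a `default` entry.
#' @param tol relative macronutrient tolerance (default 0.20).
#' @param zero_band absolute band for zero-valued target nutrients.
#' @return an object of class `assignment_record`: list with `item_id`,
#'   `category`, `profile` (named numeric or `NULL`), `source_ref`, `trace`
#'   (list of `(node, outcome)` pairs).
#' @export
classify_assignment <- function(item, refs, simmap, factors,
                                tol = 0.20, zero_band = 0.5) {
  trace <- list()
  note <- function(node, outcome) {
    trace[[length(trace) + 1L]] <<- list(node = node,
                                         outcome = isTRUE(outcome))
  }
  finish <- function(category, profile = NULL, source_ref = NA_character_) {
    structure(list(item_id = item$item_id, category = category,
                   profile = profile, source_ref = source_ref,
                   trace = trace),
              class = "assignment_record")
  }
  ref_row <- function(id) {
    i <- match(id, refs$item_id)
    if (is.na(i)) {
      stop_config(paste0("similarity map references unknown food '", id, "'"))
    }
    refs[i, , drop = FALSE]
  }
  ref_has_analytical <- function(row) {
    isTRUE(as.logical(row$is_analytical)) && has_profile(as_profile(row))
  }
  calc_from <- function(row) {
    n_t <- nitrogen_from_protein(item$protein_g,
                                 np_factor(item$food_group, factors))
    n_s <- nitrogen_from_protein(row$protein_g,
                                 np_factor(row$food_group, factors))
    nitrogen_corrected_profile(as_profile(row), n_t, n_s)
  }
  item_name <- normalize_name(item$name)
  item_prep <- normalize_name(item$preparation)
  cand_ids <- simmap_candidates(item$item_id, simmap)
  ref_names <- normalize_name(refs$name)
  ref_preps <- normalize_name(refs$preparation)

  # (A) exact name concordance
  name_idx <- which(ref_names == item_name)
  note("name_match", length(name_idx) > 0)
  fell_through <- FALSE
  if (length(name_idx) > 0) {
    form_idx <- name_idx[ref_preps[name_idx] == item_prep]
    note("form_match", length(form_idx) > 0)
    if (length(form_idx) > 0) {
      # best candidate: similarity-map order first, else id order
      ids <- refs$item_id[form_idx]
      ranked <- ids[match(cand_ids, ids)]
      ranked <- ranked[!is.na(ranked)]
      best_id <- if (length(ranked)) ranked[[1]] else sort(ids)[[1]]
      best <- ref_row(best_id)
      direct <- ref_has_analytical(best)
      note("analytical_direct", direct)
      if (direct) {
        tr <- nutrient_tolerance(item, best, tol, zero_band)
        note("tolerance_direct", tr$within)
        if (tr$within) {
          return(finish("ANALYTICAL", as_profile(best), best_id))
        }
      }
      # (A1b): analytical similar food with a different preparation form
      alt_id <- NULL
      for (id in cand_ids) {
        row <- ref_row(id)
        if (normalize_name(row$preparation) != item_prep &&
            ref_has_analytical(row)) {
          alt_id <- id
          break
        }
      }
      note("analytical_similar_other_form", !is.null(alt_id))
      if (!is.null(alt_id)) {
        row <- ref_row(alt_id)
        return(finish("CALCULATED", calc_from(row), alt_id))
      }
      return(finish("DEFERRED"))
    }
    fell_through <- TRUE   # (A2)
  }
  if (fell_through) note("fall_through_to_similarity", TRUE)

  # (B) similarity-map scan for the first analytical candidate
  sim_id <- NULL
  for (id in cand_ids) {
    if (ref_has_analytical(ref_row(id))) {
      sim_id <- id
      break
    }
  }
  note("analytical_similar", !is.null(sim_id))
  if (!is.null(sim_id)) {
    row <- ref_row(sim_id)
    tr <- nutrient_tolerance(item, row, tol, zero_band)
    note("tolerance_similar", tr$within)
    if (tr$within) {
      return(finish("SUBSTITUTED", as_profile(row), sim_id))
    }
    return(finish("CALCULATED", calc_from(row), sim_id))
  }
  finish("DEFERRED")
}

#' @export
print.assignment_record <- function(x, ...) {
  cat(sprintf("<assignment_record> %s: %s (source: %s)\n",
              x$item_id, x$category,
              ifelse(is.na(x$source_ref), "-", x$source_ref)))
  for (step in x$trace) {
    cat(sprintf("  %-32s %s\n", step$node, step$outcome))
  }
  invisible(x)
}
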