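# Assembly of per-item assignment records into an amino acid database,
# plus the two standard reports: provenance composition (categories and
# sources) and coverage (populated cells per report variable).

#' Sum of total amino acids
#'
#' TAA is the sum of the 18 protein amino acids (taurine excluded) over the
#' values present in the profile: missing constituents are skipped, not
#' treated as zero, so TAA is computable for every non-deferred food even
#' when individual amino acids are unavailable.
#'
#' @param profile amino acid profile (mg/100 g); anything accepted by
#'   [as_profile()].
#' @param keys key set to sum over (default [taa_keys()]).
#' @return mg per 100 g; 0 when no constituent is present.
#' @export
compute_taa <- function(profile, keys = taa_keys()) {
  p <- as_profile(profile)[keys]
  sum(p, na.rm = TRUE)
}

#' Sum of essential amino acids
#'
#' As [compute_taa()] over the 10-key essential set (including histidine
#' and arginine).
#'
#' @inheritParams compute_taa
#' @export
compute_eaa <- function(profile, keys = eaa_keys()) {
  compute_taa(profile, keys = keys)
}

#' Build an amino acid database from items and references
#'
#' Runs [classify_assignment()] for every item and assembles the result
#' into an `aa_database`: one entry per item carrying the assigned profile,
#' the materialized TAA and EAA sums, the provenance category and the
#' source reference, plus the full assignment ledger.  Deterministic given
#' identical inputs; no item is ever dropped (deferred items get an entry
#' with an absent profile).
#'
#' @param items data.frame of FFQ food items.
#' @param refs data.frame of reference foods (one or more composition
#'   tables row-bound together; validate with [validate_reference_set()]).
#' @param simmap similarity map data.frame (`item_id`, `ref_id`, `rank`).
#' @param config run configuration, see [default_config()].
#' @return object of class `aa_database`: list with `entries` (data.frame:
#'   `item_id`, one column per amino acid, `taa_mg`, `eaa_mg`, `category`,
#'   `source_ref`), `ledger` (list of `assignment_record`s) and
#'   `variable_set` (coverage report variables).
#' @export
build_database <- function(items, refs, simmap, config = default_config()) {
  n <- if (is.null(items)) 0L else nrow(items)
  ledger <- vector("list", n)
  prof_mat <- matrix(NA_real_, nrow = n, ncol = length(AA_KEYS),
                     dimnames = list(NULL, AA_KEYS))
  taa <- eaa <- rep(NA_real_, n)
  category <- source_ref <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rec <- classify_assignment(items[i, , drop = FALSE], refs, simmap,
                               config$nitrogen_factors,
                               tol = config$tolerance,
                               zero_band = config$absolute_zero_band)
    ledger[[i]] <- rec
    category[i] <- rec$category
    source_ref[i] <- rec$source_ref
    if (!is.null(rec$profile)) {
      prof_mat[i, ] <- rec$profile
      taa[i] <- compute_taa(rec$profile, config$taa_keys)
      eaa[i] <- compute_eaa(rec$profile, config$eaa_keys)
    }
  }
  entries <- data.frame(item_id = if (n) items$item_id else character(),
                        stringsAsFactors = FALSE)
  entries <- cbind(entries, as.data.frame(prof_mat))
  entries$taa_mg <- taa
  entries$eaa_mg <- eaa
  entries$category <- category
  entries$source_ref <- source_ref
  structure(list(entries = entries, ledger = ledger,
                 variable_set = config$coverage_variables),
            class = "aa_database")
}

#' Re-classify deferred items against an additional reference set
#'
#' Database construction is multi-pass in practice: items deferred for lack
#' of analytical data are resolved later when further composition tables or
#' literature values become available.  Only `DEFERRED` entries are
#' re-classified; resolved categories and profiles are never revisited, so
#' coverage can only grow.
#'
#' @param db an `aa_database`.
#' @param items the original item list.
#' @param refs2,simmap2 the additional reference set and its similarity map.
#' @inheritParams build_database
#' @return the updated `aa_database`.
#' @export
resolve_deferred <- function(db, items, refs2, simmap2,
                             config = default_config()) {
  idx <- which(db$entries$category == "DEFERRED")
  for (i in idx) {
    item <- items[items$item_id == db$entries$item_id[i], , drop = FALSE]
    rec <- classify_assignment(item, refs2, simmap2,
                               config$nitrogen_factors,
                               tol = config$tolerance,
                               zero_band = config$absolute_zero_band)
    if (rec$category == "DEFERRED") next
    db$ledger[[i]] <- rec
    db$entries[i, AA_KEYS] <- as.list(rec$profile)
    db$entries$taa_mg[i] <- compute_taa(rec$profile, config$taa_keys)
    db$entries$eaa_mg[i] <- compute_eaa(rec$profile, config$eaa_keys)
    db$entries$category[i] <- rec$category
    db$entries$source_ref[i] <- rec$source_ref
  }
  db
}

#' Coverage report
#'
#' Per-variable coverage is the number of items with a non-missing value
#' divided by the number of items.  TAA and EAA count as populated for
#' every non-deferred item (they are computable from partial profiles).
#' Overall coverage is populated cells over total possible cells across the
#' configured variable set — algebraically, the equal-weight mean of the
#' per-variable percentages.  Values are kept at full precision; rounding
#' (half-up, one decimal) happens at serialization/printing only.
#'
#' @param db an `aa_database` with at least one entry.
#' @return object of class `coverage_report`: list with `per_variable`
#'   (data.frame `variable`, `n_nonmissing`, `percent`), `overall_percent`
#'   and `n_items`.
#' @export
coverage_report <- function(db) {
  entries <- db$entries
  if (nrow(entries) == 0) stop_validation("empty database: nothing to report")
  n <- nrow(entries)
  vars <- db$variable_set
  count_var <- function(v) {
    col <- switch(v, TAA = "taa_mg", EAA = "eaa_mg", v)
    sum(!is.na(entries[[col]]))
  }
  n_non <- vapply(vars, count_var, integer(1))
  per <- data.frame(variable = vars, n_nonmissing = unname(n_non),
                    percent = unname(n_non) / n * 100,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_variable = per,
                 overall_percent = sum(n_non) / (n * length(vars)) * 100,
                 n_items = n),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d items, %d variables\n",
              x$n_items, nrow(x$per_variable)))
  df <- x$per_variable
  df$percent <- round_half_up(df$percent, 1)
  print(df, row.names = FALSE)
  cat(sprintf("overall coverage: %.1f%%\n",
              round_half_up(x$overall_percent, 1)))
  invisible(x)
}

#' Provenance composition report
#'
#' Tabulates how the database was put together: counts and percentages of
#' items per (category, source) pair with category subtotals.  Sources for
#' the report come from the reference table's `source` column via each
#' record's `source_ref`; deferred items are reported under source `none`.
#'
#' @param ledger list of `assignment_record`s (from [build_database()]),
#'   non-empty.
#' @param refs optional reference table used to resolve `source_ref` ids to
#'   source labels; when absent the reference ids themselves are reported.
#' @return object of class `source_composition_report`: list with
#'   `by_source` (data.frame `category`, `source`, `n`, `percent`),
#'   `by_category` (subtotals) and `n_items`.
#' @export
source_composition_report <- function(ledger, refs = NULL) {
  if (length(ledger) == 0) stop_validation("empty ledger: nothing to report")
  category <- vapply(ledger, function(r) r$category, character(1))
  src_ref <- vapply(ledger, function(r) as.character(r$source_ref),
                    character(1))
  source <- src_ref
  if (!is.null(refs)) {
    m <- match(src_ref, refs$item_id)
    source <- ifelse(is.na(m), src_ref, refs$source[m])
  }
  source[is.na(source)] <- "none"
  n_items <- length(ledger)
  tab <- as.data.frame(table(category = category, source = source),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  by_source <- data.frame(category = tab$category, source = tab$source,
                          n = tab$Freq, percent = tab$Freq / n_items * 100,
                          stringsAsFactors = FALSE, row.names = NULL)
  by_source <- by_source[order(by_source$category, -by_source$n), ,
                         drop = FALSE]
  ctab <- as.data.frame(table(category = category), stringsAsFactors = FALSE)
  by_category <- data.frame(category = ctab$category, n = ctab$Freq,
                            percent = ctab$Freq / n_items * 100,
                            stringsAsFactors = FALSE, row.names = NULL)
  structure(list(by_source = by_source, by_category = by_category,
                 n_items = n_items),
            class = "source_composition_report")
}

#' @export
print.source_composition_report <- function(x, ...) {
  cat(sprintf("<source_composition_report> %d items\n", x$n_items))
  df <- x$by_category
  df$percent <- round_half_up(df$percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
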