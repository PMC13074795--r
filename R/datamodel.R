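# Controlled vocabularies, validation and configuration shared by all stages.

#' Amino acid vocabulary
#'
#' The package tracks 19 amino acids per 100 g edible portion, following the
#' unit and variable conventions of national food composition tables.  The
#' total amino acid (TAA) sum covers 18 of them; taurine (TAU) is stored in
#' profiles and reported on its own but never enters TAA, because taurine
#' data are far sparser than the protein amino acids and would otherwise make
#' the TAA sum incomparable across foods.  The essential amino acid (EAA) set
#' keeps histidine and arginine, consistent with composition-table practice
#' that classifies both as essential during growth.
#'
#' @return `aa_keys()` returns all 19 amino acid identifiers; `taa_keys()`
#'   the 18 identifiers entering the TAA sum; `eaa_keys()` the 10 essential
#'   identifiers.
#' @examples
#' length(aa_keys())  # 19
#' setdiff(aa_keys(), taa_keys())  # "TAU"
#' @export
aa_keys <- function() AA_KEYS

#' @rdname aa_keys
#' @export
taa_keys <- function() setdiff(AA_KEYS, "TAU")

#' @rdname aa_keys
#' @export
eaa_keys <- function() AA_KEYS[1:10]

AA_KEYS <- c("ILE", "LEU", "LYS", "MET", "PHE", "THR", "TRP", "VAL", "HIS",
             "ARG", "TYR", "CYS", "ALA", "ASP", "GLU", "GLY", "PRO", "SER",
             "TAU")

NUTRIENT_COLS <- c("energy_kcal", "carb_g", "protein_g", "fat_g", "moisture_g")

ITEM_COLS <- c("item_id", "name", "preparation", "food_group",
               "similarity_key", NUTRIENT_COLS)

REF_COLS <- c("item_id", "name", "preparation", "food_group",
              "similarity_key", NUTRIENT_COLS, AA_KEYS, "source",
              "is_analytical")

# condition helpers: exit-code contract maps validation errors to 1 and
# configuration errors to 2
stop_validation <- function(msg) {
  stop(structure(class = c("ffqaa_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_config <- function(msg) {
  stop(structure(class = c("ffqaa_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Normalize a food name
#'
#' Case-folds, strips leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces.  Name concordance in the matching
#' engine is exact equality after this normalization; synonyms are the
#' similarity map's job, not string matching's.
#'
#' @param raw character vector of food names.
#' @return canonical character vector; idempotent under re-application.
#' @examples
#' normalize_name("  Boiled  RICE ")  # "boiled rice"
#' @export
normalize_name <- function(raw) {
  gsub("[[:space:]]+", " ", trimws(tolower(as.character(raw))))
}

#' Coerce to a complete amino acid profile
#'
#' A profile is a named numeric vector over the 19-key vocabulary, in mg per
#' 100 g edible portion.  Absent amino acids are `NA`, which is distinct
#' from a measured 0: sums and coverage counts skip `NA` only.
#'
#' @param x named numeric vector (a subset of the vocabulary) or a one-row
#'   data.frame carrying amino acid columns.
#' @return named numeric vector of length 19 in vocabulary order.
#' @export
as_profile <- function(x) {
  if (is.data.frame(x)) {
    present <- intersect(AA_KEYS, names(x))
    x <- unlist(x[1, present, drop = FALSE])
    names(x) <- present
  }
  bad <- setdiff(names(x), AA_KEYS)
  if (length(bad)) {
    stop_validation(paste0("unknown amino acid key(s): ",
                           paste(bad, collapse = ", ")))
  }
  out <- stats::setNames(rep(NA_real_, length(AA_KEYS)), AA_KEYS)
  out[names(x)] <- as.numeric(x)
  if (any(out < 0, na.rm = TRUE)) {
    stop_validation("amino acid values must be >= 0")
  }
  out
}

has_profile <- function(profile) any(!is.na(profile))

as_nutrients <- function(x) {
  if (is.data.frame(x)) {
    x <- unlist(x[1, intersect(NUTRIENT_COLS, names(x)), drop = FALSE])
  }
  miss <- setdiff(NUTRIENT_COLS, names(x))
  if (length(miss)) {
    stop_validation(paste0("missing nutrient field(s): ",
                           paste(miss, collapse = ", ")))
  }
  out <- as.numeric(x[NUTRIENT_COLS])
  names(out) <- NUTRIENT_COLS
  if (anyNA(out)) stop_validation("macronutrients must be complete")
  out
}

#' Validate a reference food composition table
#'
#' Reports (rather than raises) per-record violations: duplicate ids,
#' negative nutrient or amino acid values, missing macronutrients, and the
#' analytical flag set without any amino acid value present.
#'
#' @param refs data.frame in the reference schema (see [read_refs()]).
#' @return data.frame with columns `row`, `id`, `problem`; zero rows when
#'   the table is valid.
#' @export
validate_reference_set <- function(refs) {
  report <- data.frame(row = integer(), id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  if (is.null(refs) || nrow(refs) == 0) return(report)
  add <- function(row, id, problem) {
    rbind(report, data.frame(row = row, id = id, problem = problem,
                             stringsAsFactors = FALSE))
  }
  dup <- duplicated(refs$item_id)
  for (i in which(dup)) {
    report <- add(i, refs$item_id[i], "duplicate id")
  }
  for (i in seq_len(nrow(refs))) {
    nut <- suppressWarnings(as.numeric(refs[i, NUTRIENT_COLS]))
    if (anyNA(nut)) {
      report <- add(i, refs$item_id[i], "incomplete macronutrients")
    } else if (any(nut < 0)) {
      report <- add(i, refs$item_id[i], "negative nutrient value")
    }
    prof <- suppressWarnings(as.numeric(refs[i, intersect(AA_KEYS, names(refs))]))
    if (any(prof < 0, na.rm = TRUE)) {
      report <- add(i, refs$item_id[i], "negative amino acid value")
    }
    if (isTRUE(refs$is_analytical[i]) && !any(!is.na(prof))) {
      report <- add(i, refs$item_id[i], "analytical flag without profile")
    }
  }
  report
}

#' Validate an FFQ food-item list
#'
#' @param items data.frame in the item schema (see [read_items()]).
#' @return data.frame with columns `row`, `id`, `problem`.
#' @export
validate_items <- function(items) {
  report <- data.frame(row = integer(), id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  if (is.null(items) || nrow(items) == 0) return(report)
  dup <- which(duplicated(items$item_id))
  for (i in dup) {
    report <- rbind(report, data.frame(row = i, id = items$item_id[i],
                                       problem = "duplicate id"))
  }
  for (i in seq_len(nrow(items))) {
    nut <- suppressWarnings(as.numeric(items[i, NUTRIENT_COLS]))
    prob <- if (anyNA(nut)) "incomplete macronutrients"
            else if (any(nut < 0)) "negative nutrient value"
            else if (!nzchar(normalize_name(items$name[i]))) "empty name"
            else NA_character_
    if (!is.na(prob)) {
      report <- rbind(report, data.frame(row = i, id = items$item_id[i],
                                         problem = prob))
    }
  }
  report
}

#' Default run configuration
#'
#' Collects every tunable the pipeline reads: the macronutrient tolerance
#' (0.20, i.e. the +/-20% screen), the absolute band used when a target
#' nutrient is exactly zero, the TAA/EAA key sets, the coverage variable
#' set (TAA, EAA, the 18 TAA amino acids and taurine: 21 report variables),
#' nitrogen-to-protein conversion factors by food group, the EAR table and
#' age bins, and the linkage mode.
#'
#' The shipped nitrogen factors are the traditional food-group factors
#' (6.25 general, 5.83 cereals, 5.71 soy/legumes, 6.38 dairy); national
#' composition tables publish their own revisions, so treat these as
#' placeholders and supply the table-specific values as data.
#'
#' @return a named list; see sections in the package vignette.
#' @export
default_config <- function() {
  list(
    tolerance = 0.20,
    absolute_zero_band = 0.5,
    taa_keys = taa_keys(),
    eaa_keys = eaa_keys(),
    coverage_variables = c("TAA", "EAA", taa_keys(), "TAU"),
    nitrogen_factors = list(default = 6.25, cereals = 5.83, legumes = 5.71,
                            dairy = 6.38, meat = 6.25, fish = 6.25,
                            vegetables = 6.25, fruits = 6.25),
    ear_table = default_ear_table(),
    linkage = "strict"
  )
}

#' Default EAR table (illustrative)
#'
#' Estimated Average Requirements used for adequacy screening.  The protein
#' EAR is body-weight based: (0.66 g/kg/day) / 0.9 digestibility correction,
#' multiplied by body weight.  The per-amino-acid values (mg/kg/day) are the
#' FAO/WHO/UNU (2007) adult requirement estimates and are shipped as an
#' illustrative default: national reference-intake tables should be supplied
#' by the user where available.  Combined requirements are declared with a
#' `+` in the key (aromatic pair PHE+TYR; sulfur pair MET+CYS) and compare
#' the summed intake to the combined requirement.
#'
#' @return list with `protein_coefficient` (g/kg/day), `aa_requirements`
#'   (named numeric, mg/kg/day) and `age_bins` (list of `c(low, high)` year
#'   ranges, closed intervals).
#' @export
default_ear_table <- function() {
  list(
    protein_coefficient = 0.66 / 0.9,
    aa_requirements = c(ILE = 20, LEU = 39, LYS = 30, `MET+CYS` = 15,
                        `PHE+TYR` = 25, THR = 15, TRP = 4, VAL = 26,
                        HIS = 10),
    age_bins = list(c(30, 49), c(50, 64), c(65, 74))
  )
}

# food-group nitrogen factor lookup with configured default fallback
np_factor <- function(food_group, factors) {
  f <- factors[[food_group]]
  if (is.null(f)) f <- factors[["default"]]
  if (is.null(f)) {
    stop_config(paste0("no nitrogen-to-protein factor for food group '",
                       food_group, "' and no default configured"))
  }
  f <- as.numeric(f)
  if (!is.finite(f) || f <= 0) stop_config("conversion factors must be > 0")
  f
}

#' Round half-up
#'
#' Report serialization uses half-up rounding to one decimal (the convention
#' of printed composition tables), unlike base R's round-half-to-even.
#' Internal computation is never rounded.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
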