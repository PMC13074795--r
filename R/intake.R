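# Application of the database to cohort records: per-participant amino
# acid and protein intakes, TAA-to-protein ratio, and EAR-based inadequacy
# prevalence stratified by sex and age group.

#' Amino acid contribution of one FFQ response
#'
#' Standard FFQ arithmetic: daily intake of amino acid k from one item is
#' frequency (events/day) x portion (g/event) / 100 x content (mg/100 g).
#' Missing amino acids contribute nothing (zero), they do not propagate NA
#' into intake totals.
#'
#' @param frequency consumption events per day (>= 0).
#' @param portion grams consumed per event (>= 0).
#' @param profile amino acid profile of the item (mg/100 g).
#' @return named numeric vector over the 19-key vocabulary, mg/day.
#' @examples
#' item_contribution(2, 50, c(LYS = 300))[["LYS"]]  # 300
#' @export
item_contribution <- function(frequency, portion, profile) {
  if (frequency < 0 || portion < 0) {
    stop_validation("frequency and portion must be >= 0")
  }
  p <- as_profile(profile)
  p[is.na(p)] <- 0
  frequency * (portion / 100) * p
}

#' Per-participant intakes
#'
#' Sums item contributions over a participant's responses: per-amino-acid
#' mg/day, protein g/day, the TAA and EAA sums, and the TAA-to-protein
#' ratio (TAA mg / protein mg x 100).  With no responses all intakes are 0
#' and the ratio is reported as missing.
#'
#' @param participant one-row data.frame with at least `participant_id`.
#' @param responses data.frame with columns `item_id`, `freq_per_day`,
#'   `portion_g` for this participant.
#' @param db an `aa_database`.
#' @param protein_db named numeric vector, item_id -> protein g/100 g
#'   (build with [protein_lookup()]).
#' @param mode `"strict"` errors on a response item absent from the
#'   database; `"lenient"` skips it with a message.
#' @return one-row data.frame: `participant_id`, one column per amino acid
#'   (mg/day), `protein_g`, `taa_mg`, `eaa_mg`, `taa_protein_percent`.
#' @export
participant_intakes <- function(participant, responses, db, protein_db,
                                mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  entries <- db$entries
  idx <- match(responses$item_id, entries$item_id)
  if (anyNA(idx)) {
    bad <- responses$item_id[is.na(idx)]
    if (mode == "strict") {
      stop_validation(paste0("response item(s) not in database: ",
                             paste(unique(bad), collapse = ", ")))
    }
    message("skipping ", length(bad), " response(s) with unknown item ids")
    responses <- responses[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  amount <- responses$freq_per_day * responses$portion_g / 100
  prof <- as.matrix(entries[idx, AA_KEYS, drop = FALSE])
  prof[is.na(prof)] <- 0
  aa <- if (length(amount)) as.numeric(crossprod(prof, amount))
        else numeric(length(AA_KEYS))
  names(aa) <- AA_KEYS
  pidx <- match(responses$item_id, names(protein_db))
  protein <- sum(amount * protein_db[pidx], na.rm = TRUE)
  taa <- sum(aa[taa_keys()])
  eaa <- sum(aa[eaa_keys()])
  ratio <- if (protein > 0) taa / (protein * 1000) * 100 else NA_real_
  out <- data.frame(participant_id = participant$participant_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(aa)))
  out$protein_g <- protein
  out$taa_mg <- taa
  out$eaa_mg <- eaa
  out$taa_protein_percent <- ratio
  out
}

#' Intakes for a whole cohort
#'
#' @param cohort list with `participants` (data.frame `participant_id`,
#'   `sex`, `age`, `weight_kg`) and `responses` (long data.frame
#'   `participant_id`, `item_id`, `freq_per_day`, `portion_g`).
#' @inheritParams participant_intakes
#' @return data.frame, one row per participant (see
#'   [participant_intakes()]).
#' @export
cohort_intakes <- function(cohort, db, protein_db,
                           mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  parts <- cohort$participants
  resp_split <- split(cohort$responses,
                      factor(cohort$responses$participant_id,
                             levels = parts$participant_id))
  rows <- lapply(seq_len(nrow(parts)), function(i) {
    r <- resp_split[[as.character(parts$participant_id[i])]]
    if (is.null(r)) {
      r <- data.frame(item_id = character(), freq_per_day = numeric(),
                      portion_g = numeric())
    }
    participant_intakes(parts[i, , drop = FALSE], r, db, protein_db, mode)
  })
  do.call(rbind, rows)
}

#' Protein lookup table from an item list
#'
#' @param items data.frame in the item schema.
#' @return named numeric vector item_id -> protein g/100 g.
#' @export
protein_lookup <- function(items) {
  stats::setNames(items$protein_g, items$item_id)
}

#' Body-weight-based protein EAR
#'
#' g/day = (0.66 g/kg/day) / 0.9 x body weight: the nitrogen-balance
#' requirement corrected for protein quality/digestibility, scaled by body
#' weight.
#'
#' @param body_weight kg (> 0).
#' @param coefficient g/kg/day after correction (default 0.66/0.9).
#' @return g protein per day.
#' @examples
#' protein_ear(60)  # 44
#' @export
protein_ear <- function(body_weight, coefficient = 0.66 / 0.9) {
  if (any(body_weight <= 0)) stop_validation("body weight must be > 0")
  coefficient * body_weight
}

age_bin_label <- function(bin) paste0(bin[1], "-", bin[2])

assign_age_bin <- function(age, age_bins, strict = TRUE) {
  labels <- vapply(age_bins, age_bin_label, character(1))
  out <- rep(NA_character_, length(age))
  for (i in seq_along(age_bins)) {
    b <- age_bins[[i]]
    out[age >= b[1] & age <= b[2]] <- labels[i]
  }
  if (anyNA(out)) {
    if (strict) {
      stop_validation("participant age outside all configured age bins")
    }
    message("excluding ", sum(is.na(out)),
            " participant(s) outside all age bins")
  }
  out
}

#' Prevalence of intakes below the EAR
#'
#' For each stratum (Total / men / women crossed with the configured age
#' bins) and each requirement key, the percentage of participants whose
#' intake is strictly below their individual EAR.  An intake exactly at the
#' EAR counts as adequate.  Amino acid EARs are requirement (mg/kg/day)
#' x body weight; the protein EAR comes from [protein_ear()].  Combined
#' requirement keys (`PHE+TYR`, `MET+CYS`, ...) compare the summed intake
#' of the constituent amino acids to the combined requirement.
#'
#' @param intakes data.frame from [cohort_intakes()].
#' @param participants data.frame `participant_id`, `sex`, `age`,
#'   `weight_kg`.
#' @param ear EAR table, see [default_ear_table()].
#' @param strict_age error on participants outside all age bins (default);
#'   otherwise they are excluded with a message.
#' @return object of class `adequacy_report`: data.frame with columns
#'   `sex` (`Total`, `M`, `F`), `age_bin`, `key`, `n`, `percent_below`.
#' @export
below_ear_proportions <- function(intakes, participants,
                                  ear = default_ear_table(),
                                  strict_age = TRUE) {
  d <- merge(intakes, participants, by = "participant_id")
  d$age_bin <- assign_age_bin(d$age, ear$age_bins, strict = strict_age)
  d <- d[!is.na(d$age_bin), , drop = FALSE]
  keys <- c("PROTEIN", names(ear$aa_requirements))
  intake_of <- function(key) {
    if (key == "PROTEIN") return(d$protein_g)
    parts <- strsplit(key, "+", fixed = TRUE)[[1]]
    bad <- setdiff(parts, AA_KEYS)
    if (length(bad)) {
      stop_config(paste0("unknown amino acid in EAR key: ", key))
    }
    rowSums(d[, parts, drop = FALSE])
  }
  ear_of <- function(key) {
    if (key == "PROTEIN") return(protein_ear(d$weight_kg,
                                             ear$protein_coefficient))
    ear$aa_requirements[[key]] * d$weight_kg
  }
  bins <- vapply(ear$age_bins, age_bin_label, character(1))
  rows <- list()
  for (key in keys) {
    below <- intake_of(key) < ear_of(key)
    for (sex in c("Total", "M", "F")) {
      sel_sex <- if (sex == "Total") rep(TRUE, nrow(d)) else d$sex == sex
      for (bin in c("All", bins)) {
        sel <- sel_sex & (bin == "All" | d$age_bin == bin)
        n <- sum(sel)
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sex, age_bin = bin, key = key, n = n,
          percent_below = if (n > 0) mean(below[sel]) * 100 else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("adequacy_report", "data.frame"))
}
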