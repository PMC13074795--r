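# Readers/writers for the CSV schemas, the JSON run configuration and the
# JSONL assignment ledger.  Empty cells in amino acid columns map to NA
# (missing), never 0; reading back a written table reproduces the records.

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop_validation(paste0(label, " file not found: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = c("", "NA"))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_validation(paste0(label, " file ", path, " lacks column(s): ",
                           paste(miss, collapse = ", ")))
  }
  df
}

check_numeric_cols <- function(df, cols, label) {
  for (col in intersect(cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad)) {
        stop_validation(sprintf("%s: malformed numeric in column '%s', row %d",
                                label, col, bad[1]))
      }
      df[[col]] <- conv
    }
  }
  df
}

#' Read an FFQ item list
#' @param path CSV with columns `item_id, name, preparation, food_group,
#'   similarity_key, energy_kcal, carb_g, protein_g, fat_g, moisture_g`.
#' @return data.frame in the item schema.
#' @export
read_items <- function(path) {
  df <- read_csv_checked(path, ITEM_COLS, "items")
  check_numeric_cols(df, NUTRIENT_COLS, "items")
}

#' Read a reference food composition table
#' @param path CSV in the item schema plus one column per amino acid key
#'   (mg/100 g, empty cell = missing), `source` and `is_analytical`.
#' @return data.frame in the reference schema.
#' @export
read_refs <- function(path) {
  df <- read_csv_checked(path, REF_COLS, "reference")
  df <- check_numeric_cols(df, c(NUTRIENT_COLS, AA_KEYS), "reference")
  df$is_analytical <- as.logical(df$is_analytical)
  df
}

#' Read a similarity map
#' @param path CSV with columns `item_id, ref_id, rank` (and optionally
#'   `rationale`).
#' @export
read_simmap <- function(path) {
  df <- read_csv_checked(path, c("item_id", "ref_id", "rank"), "simmap")
  check_numeric_cols(df, "rank", "simmap")
}

#' Read cohort files
#' @param participants_path CSV `participant_id, sex, age, weight_kg`.
#' @param responses_path CSV `participant_id, item_id, freq_per_day,
#'   portion_g`.
#' @return list with `participants` and `responses`.
#' @export
read_cohort <- function(participants_path, responses_path) {
  parts <- read_csv_checked(participants_path,
                            c("participant_id", "sex", "age", "weight_kg"),
                            "participants")
  parts <- check_numeric_cols(parts, c("age", "weight_kg"), "participants")
  resp <- read_csv_checked(responses_path,
                           c("participant_id", "item_id", "freq_per_day",
                             "portion_g"), "responses")
  resp <- check_numeric_cols(resp, c("freq_per_day", "portion_g"),
                             "responses")
  list(participants = parts, responses = resp)
}

#' Write / read a table (round-trip safe)
#' @param df data.frame.
#' @param path output CSV path; missing values become empty cells.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write database entries to CSV
#' @param db an `aa_database`.
#' @param path output path.
#' @export
write_database <- function(db, path) {
  write_table(db$entries, path)
}

#' Read database entries from CSV
#' @param path CSV written by [write_database()].
#' @param config run configuration (supplies the coverage variable set).
#' @return an `aa_database` (with an empty ledger).
#' @export
read_database <- function(path, config = default_config()) {
  df <- read_csv_checked(path, c("item_id", AA_KEYS, "taa_mg", "eaa_mg",
                                 "category", "source_ref"), "database")
  df <- check_numeric_cols(df, c(AA_KEYS, "taa_mg", "eaa_mg"), "database")
  structure(list(entries = df, ledger = list(),
                 variable_set = config$coverage_variables),
            class = "aa_database")
}

#' Write the assignment ledger as JSONL
#'
#' One JSON object per item: id, category, source, profile (missing amino
#' acids as null) and the full decision trace.
#'
#' @param ledger list of `assignment_record`s.
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in ledger) {
    obj <- list(item_id = rec$item_id, category = rec$category,
                source_ref = rec$source_ref,
                profile = if (is.null(rec$profile)) NULL
                          else as.list(rec$profile),
                trace = rec$trace)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null"), con)
  }
  invisible(path)
}

#' Read a JSONL assignment ledger
#' @param path file written by [write_ledger()].
#' @return list of `assignment_record`s.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    profile <- if (is.null(obj$profile)) NULL else {
      as_profile(unlist(lapply(obj$profile,
                               function(v) if (is.null(v)) NA_real_
                                           else as.numeric(v))))
    }
    structure(list(item_id = obj$item_id, category = obj$category,
                   source_ref = if (is.null(obj$source_ref)) NA_character_
                                else obj$source_ref,
                   profile = profile,
                   trace = lapply(obj$trace, function(s)
                     list(node = s$node, outcome = isTRUE(s$outcome)))),
              class = "assignment_record")
  })
}

#' Read a JSON run configuration
#'
#' Any field absent from the file keeps its [default_config()] value.
#'
#' @param path JSON document.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(paste0("config file not found: ", path))
  }
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.numeric(cfg$tolerance) || cfg$tolerance <= 0) {
    stop_config("tolerance must be > 0")
  }
  bad <- setdiff(c(cfg$taa_keys, cfg$eaa_keys,
                   setdiff(cfg$coverage_variables, c("TAA", "EAA"))),
                 AA_KEYS)
  if (length(bad)) {
    stop_config(paste0("config references unknown amino acid key(s): ",
                       paste(bad, collapse = ", ")))
  }
  if (is.list(cfg$ear_table$aa_requirements)) {
    cfg$ear_table$aa_requirements <- unlist(cfg$ear_table$aa_requirements)
  }
  if (is.data.frame(cfg$ear_table$age_bins) ||
      is.matrix(cfg$ear_table$age_bins)) {
    m <- as.matrix(cfg$ear_table$age_bins)
    cfg$ear_table$age_bins <- lapply(seq_len(nrow(m)),
                                     function(i) as.numeric(m[i, ]))
  }
  cfg
}

#' Write a run configuration as JSON
#' @param config configuration list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors lose their names in JSON arrays; store the EAR
  # requirement map as an object
  if (!is.null(config$ear_table$aa_requirements)) {
    config$ear_table$aa_requirements <-
      as.list(config$ear_table$aa_requirements)
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
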