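Package: ffqaa
Title: Rule-Based Amino Acid Composition Databases for FFQ Intake Estimation
Version: 0.1.0
Authors@R: person("ffqaa", "developers", email = "ffqaa@example.org",
    role = c("aut", "cre"))
Description: Constructs food-item amino acid composition databases from
    reference food composition tables using a sequential rule-based
    matching and substitution algorithm (exact name concordance,
    preparation-form agreement, a +/-20% macronutrient tolerance screen,
    and nitrogen-ratio correction of similar-food profiles), with full
    provenance tracking of every assignment decision.  Applies the
    constructed database to food-frequency-questionnaire cohort records
    to estimate per-participant amino acid intakes, total and essential
    amino acid sums, the amino-acid-to-protein ratio, and the prevalence
    of intakes below the Estimated Average Requirement stratified by sex
    and age group.  Includes a deterministic synthetic-fixture generator
    with embedded ground truth so every stage is testable without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
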