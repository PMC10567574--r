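## Rule model of PUCH substrate specificity.
##
## PUCH — the trimer of TOFU-1, TOFU-2 and SLFL-3 or SLFL-4 — cleaves a
## capped piRNA precursor between nucleotides 2 and 3, leaving a
## 5'-monophosphate on the downstream product. Cleavage requires, jointly:
## an intact trimer with catalytically active TOFU-2 (the E216A active-site
## mutation abolishes activity), a 7-methyl-G cap (TMG caps and uncapped 5'
## ends are rejected), a uridine at position 3, and a divalent cation
## (Mg2+ or Mn2+; Ca2+ only at high concentration; Zn2+ never; EDTA
## chelation blocks the reaction). A C at position 1 slows but does not
## abolish cleavage; sequence beyond position 3 is irrelevant.

#' Describe a capped RNA substrate
#'
#' @param sequence RNA sequence (A/C/G/U), position 1 = 5'-most templated
#'   base; at least 3 nt.
#' @param cap 5' chemistry: `"m7G"`, `"TMG"`, `"monophosphate_5p"` or
#'   `"hydroxyl_5p"`.
#' @param label free-text name.
#' @return a `substrate` list.
#' @export
substrate <- function(sequence, cap = c("m7G", "TMG", "monophosphate_5p",
                                        "hydroxyl_5p"), label = sequence) {
  cap <- match.arg(cap)
  sequence <- toupper(sequence)
  if (grepl("[^ACGU]", sequence)) {
    stop("substrate sequence must be RNA (A/C/G/U): ", sequence,
         call. = FALSE)
  }
  structure(list(sequence = sequence, cap = cap, label = label),
            class = "substrate")
}

#' Describe the enzyme state
#'
#' @param variant `"wild_type"` or `"E216A"` (TOFU-2 active-site mutant).
#' @param subunits_present subunit names present in the assembly; activity
#'   requires TOFU-1 and TOFU-2 plus SLFL-3 or SLFL-4.
#' @return an `enzyme_state` list.
#' @export
enzyme_state <- function(variant = c("wild_type", "E216A"),
                         subunits_present = c("TOFU-1", "TOFU-2", "SLFL-3")) {
  variant <- match.arg(variant)
  allowed <- c("TOFU-1", "TOFU-2", "SLFL-3", "SLFL-4")
  stopifnot(all(subunits_present %in% allowed))
  structure(list(variant = variant,
                 subunits_present = unique(subunits_present)),
            class = "enzyme_state")
}

#' Describe reaction conditions
#'
#' @param metal divalent cation: `"Mg"`, `"Mn"`, `"Ca"`, `"Zn"` or `"none"`.
#' @param metal_concentration concentration in mM (>= 0).
#' @param edta_present is the chelator EDTA present?
#' @return a `reaction_conditions` list.
#' @export
reaction_conditions <- function(metal = c("Mg", "Mn", "Ca", "Zn", "none"),
                                metal_concentration = 5,
                                edta_present = FALSE) {
  metal <- match.arg(metal)
  stopifnot(is.numeric(metal_concentration), metal_concentration >= 0)
  structure(list(metal = metal,
                 metal_concentration = metal_concentration,
                 edta_present = isTRUE(edta_present)),
            class = "reaction_conditions")
}

subunit_rule_satisfied <- function(e) {
  all(c("TOFU-1", "TOFU-2") %in% e$subunits_present) &&
    any(c("SLFL-3", "SLFL-4") %in% e$subunits_present)
}

metal_supports_cleavage <- function(c, high_ca_mM, min_metal_mM) {
  switch(c$metal,
         Mg = , Mn = c$metal_concentration >= min_metal_mM,
         Ca = c$metal_concentration >= high_ca_mM,
         FALSE)
}

#' Assess one substrate
#'
#' Applies the full rule set and returns the predicted outcome. Position-1
#' identity does not gate cleavage but sets the rate class: C is slow, A/G
#' fast; U at position 1 was not assayed and is mapped to fast with a
#' `position1_untested` flag.
#'
#' @param s a [substrate()].
#' @param e an [enzyme_state()].
#' @param c a [reaction_conditions()].
#' @param high_ca_mM Ca2+ threshold in mM above which it supports cleavage
#'   (default 11, the top of the tested series).
#' @param min_metal_mM minimum Mg2+/Mn2+ concentration in mM (default 1).
#' @return a `cleavage_outcome` list: `cleaved`, `site` (scissile bond after
#'   position 2, or NA), `product_5prime` (`"monophosphate"` or NA),
#'   `product_sequence` (sequence from position 3 on, or NA), `rate_class`
#'   (`"fast"`, `"slow"` or `"none"`), `position1_untested`.
#' @export
assess_substrate <- function(s, e, c, high_ca_mM = 11, min_metal_mM = 1) {
  stopifnot(inherits(s, "substrate"), inherits(e, "enzyme_state"),
            inherits(c, "reaction_conditions"))
  if (nchar(s$sequence) < 3L) {
    stop("substrate must be at least 3 nt long", call. = FALSE)
  }
  cleaved <- e$variant == "wild_type" &&
    subunit_rule_satisfied(e) &&
    s$cap == "m7G" &&
    substr(s$sequence, 3L, 3L) == "U" &&
    !c$edta_present &&
    metal_supports_cleavage(c, high_ca_mM, min_metal_mM)
  p1 <- substr(s$sequence, 1L, 1L)
  structure(list(
    cleaved = cleaved,
    site = if (cleaved) 2L else NA_integer_,
    product_5prime = if (cleaved) "monophosphate" else NA_character_,
    product_sequence = if (cleaved) substring(s$sequence, 3L) else
      NA_character_,
    rate_class = if (!cleaved) "none" else if (p1 == "C") "slow" else "fast",
    position1_untested = cleaved && p1 == "U",
    label = s$label), class = "cleavage_outcome")
}

#' Assess a substrate mixture
#'
#' Cleavage-incompetent substrates do not inhibit processing of competent
#' ones, so each substrate's outcome equals its solo outcome regardless of
#' the other species or their multiplicities.
#'
#' @param substrates list of [substrate()]s (>= 1), optionally with
#'   multiplicities via repetition.
#' @param e an [enzyme_state()].
#' @param c a [reaction_conditions()].
#' @param ... passed to [assess_substrate()].
#' @return list of `cleavage_outcome`s, one per substrate, in input order.
#' @export
assess_mixture <- function(substrates, e, c, ...) {
  stopifnot(length(substrates) >= 1L)
  lapply(substrates, assess_substrate, e = e, c = c, ...)
}

#' Tabulate outcomes over a panel
#'
#' Cartesian evaluation of substrates x enzyme states x conditions.
#'
#' @param substrates list of [substrate()]s.
#' @param enzymes list of [enzyme_state()]s.
#' @param conditions list of [reaction_conditions()]s.
#' @param ... passed to [assess_substrate()].
#' @return data.frame with one row per combination: `label`, `cap`,
#'   `variant`, `metal`, `edta`, `cleaved`, `rate_class`, `product_sequence`.
#' @export
truth_table <- function(substrates, enzymes, conditions, ...) {
  grid <- expand.grid(s = seq_along(substrates), e = seq_along(enzymes),
                      c = seq_along(conditions))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- substrates[[grid$s[i]]]
    e <- enzymes[[grid$e[i]]]
    cc <- conditions[[grid$c[i]]]
    o <- assess_substrate(s, e, cc, ...)
    data.frame(label = s$label, cap = s$cap, variant = e$variant,
               metal = cc$metal, edta = cc$edta_present,
               cleaved = o$cleaved, rate_class = o$rate_class,
               product_sequence = if (is.na(o$product_sequence)) "" else
                 o$product_sequence,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a truth table as TSV
#' @param table data.frame from [truth_table()].
#' @param path output file.
#' @export
write_truth_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The reference assay panel
#'
#' The eight-case panel used throughout: canonical m7G/AAU substrate under
#' permissive conditions, then one perturbation at a time (position-3 C,
#' position-1 C, TMG cap, 5'-monophosphate, E216A enzyme, Zn2+, EDTA).
#'
#' @param tail RNA appended after the first three bases (default a 25-nt
#'   run emulating the remainder of a ~28-nt precursor).
#' @return data.frame of panel inputs with the expected qualitative verdict
#'   columns left to the caller to compute via [truth_table()].
#' @export
reference_panel <- function(tail = strrep("A", 25L)) {
  list(
    AAU_m7G = list(s = substrate(paste0("AAU", tail), "m7G", "AAU"),
                   e = enzyme_state(), c = reaction_conditions("Mg", 5)),
    AAC_m7G = list(s = substrate(paste0("AAC", tail), "m7G", "AAC"),
                   e = enzyme_state(), c = reaction_conditions("Mg", 5)),
    CAU_m7G = list(s = substrate(paste0("CAU", tail), "m7G", "CAU"),
                   e = enzyme_state(), c = reaction_conditions("Mg", 5)),
    AAU_TMG = list(s = substrate(paste0("AAU", tail), "TMG", "AAU-TMG"),
                   e = enzyme_state(), c = reaction_conditions("Mg", 5)),
    AAU_5P = list(s = substrate(paste0("AAU", tail), "monophosphate_5p",
                                "AAU-5P"),
                  e = enzyme_state(), c = reaction_conditions("Mg", 5)),
    AAU_E216A = list(s = substrate(paste0("AAU", tail), "m7G", "AAU"),
                     e = enzyme_state("E216A"),
                     c = reaction_conditions("Mg", 5)),
    AAU_Zn = list(s = substrate(paste0("AAU", tail), "m7G", "AAU"),
                  e = enzyme_state(), c = reaction_conditions("Zn", 5)),
    AAU_EDTA = list(s = substrate(paste0("AAU", tail), "m7G", "AAU"),
                    e = enzyme_state(),
                    c = reaction_conditions("Mg", 5, edta_present = TRUE)))
}
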