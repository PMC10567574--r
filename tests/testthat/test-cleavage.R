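wt <- enzyme_state()
mg <- reaction_conditions("Mg", 5)

test_that("the eight-case reference panel reproduces the assay outcomes", {
  panel <- reference_panel()
  verdicts <- vapply(panel, function(p)
    assess_substrate(p$s, p$e, p$c)$cleaved, logical(1))
  expect_equal(verdicts, c(AAU_m7G = TRUE, AAC_m7G = FALSE, CAU_m7G = TRUE,
                           AAU_TMG = FALSE, AAU_5P = FALSE,
                           AAU_E216A = FALSE, AAU_Zn = FALSE,
                           AAU_EDTA = FALSE))
  rates <- vapply(panel, function(p)
    assess_substrate(p$s, p$e, p$c)$rate_class, character(1))
  expect_equal(rates[["AAU_m7G"]], "fast")
  expect_equal(rates[["CAU_m7G"]], "slow")
  expect_equal(rates[["AAC_m7G"]], "none")
})

test_that("cleavage yields a 5'-monophosphate product from position 3 on", {
  s <- substrate("AAUGGCCAAUU", "m7G")
  o <- assess_substrate(s, wt, mg)
  expect_true(o$cleaved)
  expect_equal(o$site, 2L)
  expect_equal(o$product_5prime, "monophosphate")
  expect_equal(o$product_sequence, "UGGCCAAUU")
  expect_equal(nchar(o$product_sequence), nchar(s$sequence) - 2L)
})

test_that("the verdict is invariant under any 3' tail", {
  set.seed(17)
  for (i in 1:50) {
    tail <- paste(sample(c("A", "C", "G", "U"), sample(0:30, 1),
                         replace = TRUE), collapse = "")
    o <- assess_substrate(substrate(paste0("AAU", tail), "m7G"), wt, mg)
    expect_true(o$cleaved)
    expect_equal(o$rate_class, "fast")
    o2 <- assess_substrate(substrate(paste0("AAC", tail), "m7G"), wt, mg)
    expect_false(o2$cleaved)
  }
  ## minimal 3-nt substrate behaves like full length; shorter is an error
  expect_true(assess_substrate(substrate("AAU", "m7G"), wt, mg)$cleaved)
  expect_error(assess_substrate(substrate("AU", "m7G"), wt, mg),
               "at least 3 nt")
})

test_that("no cap or position-3 combination other than m7G/U ever cleaves", {
  caps <- c("m7G", "TMG", "monophosphate_5p", "hydroxyl_5p")
  bases <- c("A", "C", "G", "U")
  for (cap in caps) {
    for (p1 in bases) {
      for (p3 in bases) {
        o <- assess_substrate(substrate(paste0(p1, "A", p3, "GG"), cap),
                              wt, mg)
        expect_equal(o$cleaved, cap == "m7G" && p3 == "U",
                     info = paste(cap, p1, p3))
      }
    }
  }
})

test_that("subunit requirements: TOFU-1 and TOFU-2 plus either SLFL", {
  s <- substrate("AAUGG", "m7G")
  combos <- list(
    list(sub = c("TOFU-1", "TOFU-2", "SLFL-3"), ok = TRUE),
    list(sub = c("TOFU-1", "TOFU-2", "SLFL-4"), ok = TRUE),
    list(sub = c("TOFU-1", "TOFU-2", "SLFL-3", "SLFL-4"), ok = TRUE),
    list(sub = c("TOFU-1", "TOFU-2"), ok = FALSE),
    list(sub = c("TOFU-1", "SLFL-3"), ok = FALSE),
    list(sub = c("TOFU-2", "SLFL-3", "SLFL-4"), ok = FALSE))
  for (cc in combos) {
    e <- enzyme_state("wild_type", cc$sub)
    expect_equal(assess_substrate(s, e, mg)$cleaved, cc$ok,
                 info = paste(cc$sub, collapse = "+"))
  }
  expect_false(assess_substrate(
    s, enzyme_state("E216A", c("TOFU-1", "TOFU-2", "SLFL-3")), mg)$cleaved)
})

test_that("metal rules: Mg/Mn at >=1 mM, Ca only high, Zn/none/EDTA never", {
  s <- substrate("AAUGG", "m7G")
  go <- function(metal, conc, edta = FALSE)
    assess_substrate(s, wt, reaction_conditions(metal, conc,
                                                edta_present = edta))$cleaved
  expect_true(go("Mg", 1))
  expect_true(go("Mn", 2))
  expect_false(go("Mg", 0.5))
  expect_false(go("Ca", 4))
  expect_true(go("Ca", 11))
  expect_false(go("Zn", 50))
  expect_false(go("none", 0))
  expect_false(go("Mg", 5, edta = TRUE))
  ## threshold is configurable
  low_ca <- reaction_conditions("Ca", 4)
  expect_true(assess_substrate(s, wt, low_ca, high_ca_mM = 4)$cleaved)
})

test_that("position-1 U is flagged as untested, A/G/U map to fast", {
  for (p1 in c("A", "G", "U")) {
    o <- assess_substrate(substrate(paste0(p1, "AUGG"), "m7G"), wt, mg)
    expect_equal(o$rate_class, "fast")
    expect_equal(o$position1_untested, p1 == "U")
  }
})

test_that("mixtures show no competitive inhibition and order invariance", {
  aau <- substrate("AAUGG", "m7G", label = "AAU")
  aac <- substrate("AACGG", "m7G", label = "AAC")
  mix <- assess_mixture(list(aau, aac, aac), wt, mg)
  expect_equal(vapply(mix, `[[`, logical(1), "cleaved"),
               c(TRUE, FALSE, FALSE))
  solo <- assess_substrate(aau, wt, mg)
  expect_equal(mix[[1]], solo)
  perm <- assess_mixture(list(aac, aac, aau), wt, mg)
  expect_equal(vapply(perm, `[[`, character(1), "label"),
               c("AAC", "AAC", "AAU"))
  expect_equal(perm[[3]], mix[[1]])
  expect_equal(assess_mixture(list(aau), wt, mg)[[1]], solo)
})

test_that("truth_table evaluates the cartesian grid", {
  tab <- truth_table(
    substrates = list(substrate("AAUGG", "m7G", "aau"),
                      substrate("AACGG", "m7G", "aac")),
    enzymes = list(wt, enzyme_state("E216A")),
    conditions = list(mg, reaction_conditions("Zn", 5)))
  expect_equal(nrow(tab), 8L)
  expect_equal(sum(tab$cleaved), 1L)
  hit <- tab[tab$cleaved, ]
  expect_equal(hit$label, "aau")
  expect_equal(hit$variant, "wild_type")
  expect_equal(hit$metal, "Mg")
  ## all-E216A panel: zero cleavage events
  dead <- truth_table(list(substrate("AAUGG", "m7G")),
                      list(enzyme_state("E216A")), list(mg))
  expect_false(any(dead$cleaved))
  ## relabeling leaves verdicts unchanged
  tab2 <- truth_table(
    substrates = list(substrate("AAUGG", "m7G", "x"),
                      substrate("AACGG", "m7G", "y")),
    enzymes = list(wt, enzyme_state("E216A")),
    conditions = list(mg, reaction_conditions("Zn", 5)))
  expect_equal(tab$cleaved, tab2$cleaved)
})

test_that("substrate validation", {
  expect_error(substrate("AATGG", "m7G"), "RNA")
  expect_error(substrate("AAUGG", "capX"))
})
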