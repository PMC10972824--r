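test_that("location x oncogenicity gives the four record classes", {
  dom <- kinase_domain()  # 688-875
  expect_identical(classify_mutation("L858R", TRUE, dom), "V")
  expect_identical(classify_mutation("A300T", FALSE, dom), "II")
  expect_identical(classify_mutation("G719S", FALSE, dom), "IV")
  expect_identical(classify_mutation("E200K", TRUE, dom), "III")
  # the canonical activating variants are all class V
  for (pc in c("L858R", "S768I", "L861Q", "G719S")) {
    expect_identical(classify_mutation(pc, TRUE, dom), "V")
  }
  expect_error(classify_mutation("splice_site", TRUE, dom), "unparseable")
})

test_that("every parseable record gets exactly one of II-V; unparsed are flagged", {
  set.seed(13)
  tab <- data.frame(cell_line = "L1", gene = "EGFR",
                    protein_change = c(paste0("A", sample(1:1200, 50), "V"),
                                       "indel?"),
                    oncogenic = sample(c(TRUE, FALSE), 51, TRUE))
  expect_warning(out <- classify_mutations(tab), "unparseable")
  expect_true(all(out$class[!out$unparsed] %in% c("II", "III", "IV", "V")))
  expect_true(out$unparsed[51] && is.na(out$class[51]))
  expect_identical(nrow(out), 51L)  # nothing dropped
})

test_that("widening the domain only promotes II to IV and III to V", {
  set.seed(14)
  tab <- data.frame(cell_line = "L1", gene = "EGFR",
                    protein_change = paste0("A", sample(1:1200, 200, TRUE), "V"),
                    oncogenic = sample(c(TRUE, FALSE), 200, TRUE))
  narrow <- classify_mutations(tab, kinase_domain(700, 800))$class
  wide <- classify_mutations(tab, kinase_domain(600, 900))$class
  moved <- narrow != wide
  expect_true(all(paste(narrow[moved], wide[moved]) %in% c("II IV", "III V")))
})

test_that("cell-line label is the precedence maximum; empty is none", {
  expect_identical(classify_cell_line(character(0)), "none")
  expect_identical(classify_cell_line(c("II", "V")), "V")
  # enumeration of all pairs agrees with the ordinal mapping
  mp <- default_class_mapping()
  labs <- c("II", "III", "IV", "V")
  for (a in labs) for (b in labs) {
    expect_identical(mutation_score(classify_cell_line(c(a, b))),
                     max(mutation_score(a), mutation_score(b)))
  }
})

test_that("ordinal score follows the configured mapping", {
  expect_identical(mutation_score("none"), 0)
  expect_identical(mutation_score("V"), max(default_class_mapping()))
  expect_true(mutation_score("V") > mutation_score("III") &&
                mutation_score("III") > mutation_score("II"))
  expect_error(mutation_score("VI"), "unknown")
  custom <- c(none = 0, II = 1, IV = 3, III = 2, V = 9)
  expect_identical(mutation_score("IV", custom), 3)
})

test_that("class-V/AUC association is recovered when planted and only then", {
  p <- generate_panel(panel_recipe(n_lines = 200, mut_ppv = 1, seed = 17))
  cls <- cell_line_classes(p$bundle$mutations, p$bundle$lines)
  expect_identical(unname(cls[p$truth$mutation_class == "V"][1]), "V")
  assoc <- quiet(class_auc_association(p$bundle$responses[, 1], cls))
  expect_lt(assoc$p[assoc$class == "V"], 0.05)

  p0 <- generate_panel(panel_recipe(n_lines = 200, mut_ppv = 0, seed = 18))
  cls0 <- cell_line_classes(p0$bundle$mutations, p0$bundle$lines)
  assoc0 <- quiet(class_auc_association(p0$bundle$responses[, 1], cls0))
  expect_gt(assoc0$p[assoc0$class == "V"], 0.05)
})

test_that("under-sized classes are skipped with a reason, not tested", {
  auc <- setNames(rnorm(20), paste0("L", 1:20))
  cls <- setNames(rep("none", 20), names(auc))
  cls[1] <- "V"
  expect_message(out <- class_auc_association(auc, cls), "skipped")
  expect_true(out$skipped[out$class == "V"])
  expect_true(is.na(out$p[out$class == "V"]))
})

test_that("null mutation placement keeps class-V false-positive rate in check", {
  ps <- vapply(1:100, function(i) {
    p <- generate_panel(panel_recipe(n_lines = 120, n_genes = 30, set_size = 5,
                                     mut_ppv = 0, seed = 400 + i))
    cls <- cell_line_classes(p$bundle$mutations, p$bundle$lines)
    a <- quiet(class_auc_association(p$bundle$responses[, 1], cls))
    pv <- a$p[a$class == "V"]
    if (length(pv) == 0) NA_real_ else pv
  }, 0)
  expect_lte(mean(ps < 0.05, na.rm = TRUE), 0.1)
})
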