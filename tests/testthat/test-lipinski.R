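test_that("rule boundaries follow the literal wording", {
  cases <- list(
    list(over = list(),                    pass = TRUE,  rules = ""),
    list(over = list(mw = 500),            pass = FALSE, rules = "R1"),
    list(over = list(mw = 499.99),         pass = TRUE,  rules = ""),
    list(over = list(hbd = 6L),            pass = FALSE, rules = "R2"),
    list(over = list(hbd = 5L),            pass = TRUE,  rules = ""),
    list(over = list(hba = 10L),           pass = FALSE, rules = "R3"),
    list(over = list(hba = 9L),            pass = TRUE,  rules = ""),
    list(over = list(clogp = 5),           pass = TRUE,  rules = ""),
    list(over = list(clogp = -2),          pass = TRUE,  rules = ""),
    list(over = list(clogp = 5.01),        pass = FALSE, rules = "R4"),
    list(over = list(clogp = -2.01),       pass = FALSE, rules = "R4"),
    list(over = list(rotatable_bonds = 10L), pass = TRUE, rules = ""),
    list(over = list(rotatable_bonds = 11L), pass = FALSE, rules = "R5"),
    list(over = list(mw = 600, hbd = 7L),  pass = FALSE, rules = "R1;R2")
  )
  for (cs in cases) {
    v <- lipinski_verdict(do.call(comp_row, cs$over))
    expect_equal(v$passed, cs$pass, info = paste(names(cs$over), collapse = ","))
    expect_equal(v$failed_rules, cs$rules)
  }
})

test_that("a KGEC-table compound with in-range fixture properties passes", {
  v <- lipinski_verdict(comp_row("WLP232", mw = 444.65, hbd = 2L, hba = 4L,
                                 clogp = 4.1, rotatable_bonds = 6L))
  expect_true(v$passed)
})

test_that("every published key-component molecular weight satisfies R1", {
  kgec <- readr::read_csv(
    system.file("extdata", "wlp_kgec_components.csv", package = "netpharm"),
    show_col_types = FALSE
  )
  expect_equal(nrow(kgec), 29)
  expect_true(all(kgec$mw < 500))
  expect_equal(kgec$mw[kgec$name == "alisol B"], 444.65)
})

test_that("unknown properties block strict mode but not lenient mode", {
  c1 <- comp_row("C1", clogp = NA)
  strict <- lipinski_verdict(c1, strict = TRUE)
  expect_false(strict$passed)
  expect_equal(strict$unknown_properties, "clogp")
  expect_equal(strict$failed_rules, "")
  lenient <- lipinski_verdict(c1, strict = FALSE)
  expect_true(lenient$passed)
})

test_that("lenient-mode active set contains the strict-mode active set", {
  comps <- gen_components(80, rule_fail_prob = 0.3, seed = 11)
  comps$clogp[c(3, 9)] <- NA
  strict <- screen_components(comps, strict = TRUE)
  lenient <- screen_components(comps, strict = FALSE)
  expect_true(all(strict$active$component_id %in%
                    lenient$active$component_id))
})

test_that("screening is per-component: screen(A union B) = union of screens", {
  a <- gen_components(15, seed = 1, id_prefix = "A")
  b <- gen_components(15, seed = 2, id_prefix = "B")
  both <- screen_components(dplyr::bind_rows(a, b))
  expect_setequal(
    both$active$component_id,
    c(screen_components(a)$active$component_id,
      screen_components(b)$active$component_id)
  )
})

test_that("hand-built fixture screens to the expected active count", {
  comps <- dplyr::bind_rows(
    lapply(sprintf("P%02d", 1:7), comp_row),  # 7 clean
    comp_row("F1", mw = 700),
    comp_row("F2", hbd = 8L),
    comp_row("F3", rotatable_bonds = 15L)
  )
  res <- screen_components(comps)
  expect_equal(nrow(res$active), 7)
  expect_equal(sum(!res$report$passed), 3)
  expect_equal(nrow(screen_components(comps[0, ])$active), 0)
})

test_that("per-herb tallies count multi-herb components in each herb", {
  comps <- dplyr::bind_rows(
    comp_row("C1", herbs = "GZ;BZ"),
    comp_row("C2", herbs = "GZ"),
    comp_row("C3", herbs = "BZ", mw = 900)
  )
  res <- screen_components(comps)
  gz <- res$by_herb[res$by_herb$herb == "GZ", ]
  bz <- res$by_herb[res$by_herb$herb == "BZ", ]
  expect_equal(gz$components, 2)
  expect_equal(gz$active, 2)
  expect_equal(bz$components, 2)
  expect_equal(bz$active, 1)
  tot <- res$by_herb[res$by_herb$herb == "Total", ]
  expect_equal(tot$components, 4)  # herb-wise counting, as printed tables do
})
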