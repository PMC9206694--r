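test_that("case selection matches event PTs case-insensitively and once per case", {
  db <- tiny_db()
  ev <- hyperammonaemia_event()
  expect_setequal(select_cases(db, ev), c("c1", "c2"))

  # a case with several event PTs is still selected once
  rx <- dplyr::bind_rows(db$reactions,
                         tibble::tibble(case_id = "c1",
                                        pt = "hyperammonaemic ENCEPHALOPATHY"))
  db2 <- icsr_db(db$reports, db$drugs, rx)
  expect_equal(sum(select_cases(db2, ev) == "c1"), 1L)
  # background-only case stays excluded; unknown event yields empty set
  expect_false("c3" %in% select_cases(db, ev))
  expect_length(select_cases(db, event_definition("x", "Unheard of term")), 0)
  # monotone: adding a case never removes selected ones
  extra <- icsr_db(
    dplyr::bind_rows(db$reports, tibble::tibble(
      case_id = "c9", country = "US", report_year = 2020L, age_years = 1,
      sex = "male", outcomes = list(character(0)))),
    dplyr::bind_rows(db$drugs, tibble::tibble(
      case_id = "c9", drug_id = "dA", drug_name = "alphadrug",
      role = "suspect", time_to_onset_days = 1L, action_taken = "unknown")),
    dplyr::bind_rows(db$reactions, tibble::tibble(case_id = "c9",
                                                  pt = "Hyperammonaemia")))
  expect_true(all(select_cases(db, ev) %in% select_cases(extra, ev)))
})

test_that("only suspect and interacting drug mentions are eligible", {
  db <- tiny_db()
  el <- eligible_drugs(db$drugs)
  expect_setequal(paste(el$case_id, el$drug_id),
                  c("c1 dA", "c2 dA", "c3 dC"))  # c1's concomitant dB absent
  # an all-concomitant case contributes nothing
  expect_equal(nrow(eligible_drugs(
    tibble::tibble(case_id = "z", drug_id = c("d1", "d2"),
                   role = "concomitant"))), 0L)
  # duplicate suspect mentions collapse to one pair
  expect_equal(nrow(eligible_drugs(
    tibble::tibble(case_id = "z", drug_id = "d1",
                   role = c("suspect", "suspect")))), 1L)
})

test_that("drugs_with_event maps eligible drugs to their event cases", {
  db <- tiny_db()
  ev <- hyperammonaemia_event()
  dwe <- drugs_with_event(db, ev)
  expect_equal(dwe$drug_id, "dA")
  expect_setequal(dwe$case_ids[[1]], c("c1", "c2"))
  # the concomitant-only dB never appears even though co-reported
  expect_false("dB" %in% dwe$drug_id)
  # values are subsets of the selected cases
  expect_true(all(unlist(dwe$case_ids) %in% select_cases(db, ev)))
})

test_that("contingency counts are case-level and respect roles", {
  db <- tiny_db()
  ev <- hyperammonaemia_event()
  cc <- contingency_for(db, ev, "dA")
  expect_equal(unlist(cc[c("n_observed", "n_drug", "n_effect", "n_total")]),
               c(n_observed = 2, n_drug = 2, n_effect = 2, n_total = 3))
  # concomitant-only drug: zero observed despite co-reporting
  cb <- contingency_for(db, ev, "dB")
  expect_equal(cb$n_observed, 0L)
  expect_equal(cb$n_drug, 0L)
  # absent drug yields zero counts, not an error
  cz <- contingency_for(db, ev, "not_a_drug")
  expect_equal(cz$n_observed, 0L)
  # single-case database where drug is suspect and event present
  one <- icsr_db(
    tibble::tibble(case_id = "only", country = "FR", report_year = 2000L,
                   age_years = 30, sex = "male",
                   outcomes = list(character(0))),
    tibble::tibble(case_id = "only", drug_id = "d", drug_name = "d",
                   role = "suspect", time_to_onset_days = NA_integer_,
                   action_taken = "unknown"),
    tibble::tibble(case_id = "only", pt = "Hyperammonaemia"))
  expect_equal(unlist(contingency_for(one, ev, "d")[
    c("n_observed", "n_drug", "n_effect", "n_total")]),
    c(n_observed = 1, n_drug = 1, n_effect = 1, n_total = 1))
})

test_that("screening returns one deterministic row per event-associated drug", {
  g <- generate_database(small_config(n_cases = 800, seed = 21L))
  ev <- hyperammonaemia_event()
  sc <- screen_drugs(g$db, ev)
  expect_equal(nrow(sc), nrow(drugs_with_event(g$db, ev)))
  expect_true(all(sc$n_observed <= pmin(sc$n_drug, sc$n_effect)))
  # deterministic ordering: descending n_observed, ties by drug_id
  expect_equal(order(-sc$n_observed, sc$drug_id), seq_len(nrow(sc)))
  # identical on recomputation
  expect_identical(tidy(sc), tidy(screen_drugs(g$db, ev)))
})

test_that("exclusions tag the first applicable reason in stage order", {
  db <- tiny_db()
  ev <- hyperammonaemia_event()

  mk_screen <- function(drug_name, significant, case_ids) {
    s <- tibble::tibble(
      drug_id = "d1", drug_name = drug_name, n_observed = 4L, n_drug = 4L,
      n_effect = 10L, n_total = 100L, expected = 0.4, ic = 1,
      ic025 = if (significant) 0.5 else -0.3, ic975 = 2,
      significant = significant, case_ids = list(case_ids))
    class(s) <- c("ic_screen", class(s))
    s
  }
  countries <- icsr_db(
    tibble::tibble(case_id = sprintf("k%d", 1:4),
                   country = c("JP", "JP", "JP", "JP"),
                   report_year = 2000L, age_years = 1, sex = "male",
                   outcomes = list(character(0), character(0),
                                   character(0), character(0))),
    tibble::tibble(case_id = sprintf("k%d", 1:4), drug_id = "d1",
                   drug_name = "x", role = "suspect",
                   time_to_onset_days = NA_integer_,
                   action_taken = "unknown"),
    tibble::tibble(case_id = sprintf("k%d", 1:4), pt = "Hyperammonaemia"))

  # non-significant wins even for a single-country protopathic drug
  r1 <- apply_exclusions(mk_screen("lactulose", FALSE, sprintf("k%d", 1:4)),
                         countries)
  expect_equal(as.character(r1$exclusion_reason), "not_significant")
  # significant single-country wins over protopathic
  r2 <- apply_exclusions(mk_screen("lactulose", TRUE, sprintf("k%d", 1:4)),
                         countries)
  expect_equal(as.character(r2$exclusion_reason), "single_country")
  # significant multi-country protopathic name -> protopathic
  multi <- countries
  multi$reports$country <- c("JP", "FR", "JP", "FR")
  r3 <- apply_exclusions(mk_screen("Lactulose  ", TRUE, sprintf("k%d", 1:4)),
                         multi)
  expect_equal(as.character(r3$exclusion_reason), "protopathic")
  # significant, multi-country, unlisted name -> retained
  r4 <- apply_exclusions(mk_screen("somedrug", TRUE, sprintf("k%d", 1:4)),
                         multi)
  expect_true(r4$retained)
  expect_true(is.na(r4$exclusion_reason))
  # a single event case is single-country by construction
  r5 <- apply_exclusions(mk_screen("somedrug", TRUE, "k1"), multi)
  expect_equal(as.character(r5$exclusion_reason), "single_country")
})

test_that("exclusions partition the screen with single-valued reasons", {
  g <- generate_database(small_config(n_cases = 2000, seed = 31L))
  sc <- screen_drugs(g$db, hyperammonaemia_event())
  ex <- apply_exclusions(sc, g$db)
  expect_equal(nrow(ex), nrow(sc))
  expect_equal(sum(ex$retained) + sum(!is.na(ex$exclusion_reason)), nrow(sc))
  tal <- exclusion_tally(ex)
  expect_equal(tal$screened,
               tal$not_significant + tal$single_country + tal$protopathic +
                 tal$retained)
})
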