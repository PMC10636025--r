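test_that("the default rule table is total and stages match the system", {
  rules <- default_tls_rules()
  expect_silent(lymphspect:::validate_tls_rules(rules))
  expect_equal(nrow(rules), 64)

  # every findings combination yields exactly one stage
  for (dbf in c("none", "proximal", "distal", "entire"))
    for (pln in c(TRUE, FALSE))
      for (iln in c(TRUE, FALSE))
        for (duct in c(TRUE, FALSE)) {
          f <- findings_record(dbf, pln, iln, duct)
          s <- tls_stage(f)
          expect_length(s$label, 1)
          expect_true(s$label %in% tls_labels())
        }

  # descriptor anchors
  expect_equal(tls_stage(findings_record("none", TRUE, FALSE, TRUE))$label,
               "P-1")
  expect_equal(tls_stage(findings_record("distal", TRUE, FALSE, TRUE))$label,
               "P-2")
  expect_equal(tls_stage(findings_record("entire", TRUE, TRUE, TRUE))$label,
               "P-3")
  expect_equal(tls_stage(findings_record("entire", FALSE, FALSE,
                                         FALSE))$label, "T-4")
  expect_equal(tls_stage(findings_record("proximal", FALSE, FALSE,
                                         FALSE))$label, "T-5")
  expect_equal(tls_stage(findings_record("none", FALSE, FALSE,
                                         FALSE))$label, "T-6")
  # L-0 needs the normal-drainage call on top of nodes + ducts + no DBF
  expect_equal(tls_stage(findings_record("none", TRUE, FALSE, TRUE,
                                         normal_drainage = TRUE))$label,
               "L-0")
  expect_equal(tls_group("L-0"), "normal")
  expect_equal(tls_group("P-3"), "partial")
  expect_equal(tls_group("T-4"), "total")

  # an incomplete rule table is a configuration error
  expect_error(tls_stage(findings_record("none", TRUE), rules[-1, ]),
               "not total")
  dup <- rbind(rules, rules[1, ])
  expect_error(tls_stage(findings_record("none", TRUE), dup), "more than once")
})

test_that("staging comparison conserves subjects and handles artifacts", {
  # all concordant
  same <- data.frame(id = 1:5, stage_planar = c("P-1", "P-2", "T-4", "T-5",
                                                "T-6"),
                     stage_combined = c("P-1", "P-2", "T-4", "T-5", "T-6"))
  r <- compare_stagings(same)
  expect_equal(r$n_modified, 0)
  expect_equal(r$modification_rate_percent, 0)
  expect_equal(sum(diag(r$table)), 5)

  # 8 modifications of which 2 are contamination artifacts
  calls <- data.frame(
    id = sprintf("S%02d", 1:12),
    stage_planar = c(rep("P-2", 4), "P-1", "P-1", "T-6", "T-4", "T-4",
                     "T-5", "P-3", "P-3"),
    stage_combined = c(rep("P-2", 4), "P-2", "P-2", "P-2", "P-3", "P-3",
                       "P-3", "T-4", "T-4"),
    contamination_flag = c(rep(FALSE, 10), TRUE, TRUE))
  r2 <- compare_stagings(calls)
  expect_equal(r2$n_total, 12)
  expect_equal(r2$n_excluded_contamination, 2)
  expect_equal(r2$evaluable_n, 10)
  expect_equal(r2$n_modified, 6)
  expect_equal(unname(r2$decomposition["partial_to_total"]), 0)
  expect_equal(unname(r2$decomposition["within_partial"]), 2)
  expect_equal(unname(r2$decomposition["total_to_partial"]), 4)
  # conservation: diagonal + off-diagonal + excluded = input count
  expect_equal(sum(diag(r2$table)) + r2$n_modified +
                 r2$n_excluded_contamination, nrow(calls))

  miss <- same
  miss$stage_combined[2] <- NA
  expect_error(compare_stagings(miss), "missing a reading: 2")
})

test_that("region patterns are the exact product of the two flags", {
  combos <- expand.grid(dbf = c(FALSE, TRUE), hp = c(FALSE, TRUE))
  pats <- mapply(function(d, h) region_pattern(d, h)$pattern,
                 combos$dbf, combos$hp)
  expect_setequal(pats, c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+", "DBF-/HP+"))
  expect_equal(length(unique(pats)), 4) # bijection
  expect_equal(region_pattern(TRUE, TRUE)$pattern, "DBF+/HP+")
  expect_equal(region_pattern(FALSE, FALSE)$pattern, "DBF-/HP-")
})

test_that("hybrid classes match a hand-derived decision table", {
  # Independent oracle: the 16 ordered pairs and their classes, written out
  # by hand from the class definitions (NA = covered by no class).
  oracle <- rbind(
    data.frame(p = "DBF-/HP-", q = c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+",
                                     "DBF-/HP+"), class = c(1, 2, 3, NA)),
    data.frame(p = "DBF+/HP-", q = c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+",
                                     "DBF-/HP+"), class = c(2, 2, 3, NA)),
    data.frame(p = "DBF+/HP+", q = c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+",
                                     "DBF-/HP+"), class = c(3, 3, 3, 4)),
    data.frame(p = "DBF-/HP+", q = c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+",
                                     "DBF-/HP+"), class = c(NA, NA, 4, 5)))
  tab <- hybrid_decision_table("strict")
  m <- merge(tab, oracle, by.x = c("proximal", "distal"),
             by.y = c("p", "q"))
  expect_equal(nrow(m), 16)
  expect_identical(m$class.x, as.integer(m$class.y))
  expect_identical(m$unclassifiable, is.na(m$class.y))
  expect_equal(sum(tab$unclassifiable), 4)

  # representative case-series anchors
  expect_equal(hybrid_classify("DBF-/HP-", "DBF-/HP-")$class, 1L)
  expect_equal(hybrid_classify("DBF-/HP-", "DBF+/HP-")$class, 2L)
  expect_equal(hybrid_classify("DBF+/HP+", "DBF+/HP+")$class, 3L)
  expect_equal(hybrid_classify("DBF-/HP+", "DBF+/HP+")$class, 4L)
  expect_equal(hybrid_classify("DBF-/HP+", "DBF-/HP+")$class, 5L)

  # region_pattern objects are accepted directly
  expect_equal(hybrid_classify(region_pattern(FALSE, TRUE),
                               region_pattern(TRUE, TRUE))$class, 4L)
})

test_that("uncovered pairs error under strict and impute under nearest", {
  expect_error(hybrid_classify("DBF+/HP-", "DBF-/HP+"),
               "matches no hybrid class")
  r <- hybrid_classify("DBF+/HP-", "DBF-/HP+", policy = "nearest")
  expect_true(r$imputed)
  expect_true(r$class %in% 1:5)
  covered <- hybrid_classify("DBF-/HP-", "DBF-/HP-", policy = "nearest")
  expect_false(covered$imputed)
})

test_that("covered classifications are symmetric in region order", {
  tab <- hybrid_decision_table("strict")
  for (i in seq_len(nrow(tab))) {
    j <- which(tab$proximal == tab$distal[i] & tab$distal == tab$proximal[i])
    expect_identical(tab$class[i], tab$class[j])
    expect_identical(tab$unclassifiable[i], tab$unclassifiable[j])
  }
})
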