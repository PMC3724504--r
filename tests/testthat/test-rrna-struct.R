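test_that("substitution calling skips gaps and ambiguity", {
  rec <- call_substitutions("ACGT", "ACGA")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$position, 4)
  expect_equal(rec$ref_base, "U")  # RNA alphabet
  expect_equal(rec$obs_base, "A")

  expect_equal(nrow(call_substitutions("AC-T", "ACGT")), 0)
  expect_equal(nrow(call_substitutions("ACNT", "ACGT")), 0)
  expect_equal(nrow(call_substitutions("ACGT", "ACGT")), 0)
  expect_error(call_substitutions("ACGT", "ACG"), "equal aligned lengths")
})

test_that("dot-bracket parsing yields an involution", {
  st <- parse_dotbracket("(((....)))")
  expect_equal(st[1:3], c(10L, 9L, 8L))
  expect_true(all(is.na(st[4:7])))
  paired <- which(!is.na(st))
  expect_identical(st[st[paired]], paired)  # partner of partner = self
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "only")
})

test_that("pairing-preserving changes are conservative, pairing-breaking disruptive", {
  # hairpin: positions 1-3 pair with 10-8; reference AAU....AUU
  #   pos1 A - pos10 U   pos2 A - pos9 U   pos3 U - pos8 A
  st <- parse_dotbracket("(((....)))")
  ref <- "AATCCCCATT"

  # G opposite U is a wobble pair: conservative
  q1 <- "GATCCCCATT"
  r1 <- classify_substitutions(call_substitutions(ref, q1), st, q1)
  expect_equal(r1$class, "conservative")

  # C opposite U cannot pair: disruptive
  q2 <- "CATCCCCATT"
  r2 <- classify_substitutions(call_substitutions(ref, q2), st, q2)
  expect_equal(r2$class, "disruptive")

  # loop substitution: conservative
  q3 <- "AATGCCCATT"
  r3 <- classify_substitutions(call_substitutions(ref, q3), st, q3)
  expect_equal(r3$class, "conservative")

  # compensatory double substitution restoring pairing: both conservative
  q4 <- "GATCCCCATC"  # pos1 A->G with pos10 U->C: G-C pair
  r4 <- classify_substitutions(call_substitutions(ref, q4), st, q4)
  expect_equal(r4$class, c("conservative", "conservative"))

  # every record gets exactly one class
  expect_true(all(r4$class %in% c("conservative", "disruptive")))
  expect_error(classify_substitutions(
    data.frame(position = 99, ref_base = "A", obs_base = "G"), st, ref),
    "lacks structure")
})

test_that("variability scoring counts low- and high-variability hits", {
  rec <- data.frame(position = c(1, 2, 5, 7, 9),
                    ref_base = "A", obs_base = "G",
                    class = NA_character_, variability = "unscored")
  all_low <- setNames(rep("low", 10), 1:10)
  s <- score_variability(rec, all_low)
  expect_equal(s$low_variability, 5)
  expect_equal(s$high_variability, 0)

  mixed <- c(`1` = "high", `2` = "low")
  s2 <- score_variability(rec[1:2, ], mixed)
  expect_equal(c(s2$high_variability, s2$low_variability), c(1, 1))

  s3 <- score_variability(rec[0, ], mixed)
  expect_equal(s3$n_substitutions, 0)
  expect_equal(s3$low_variability + s3$high_variability, 0)

  # positions without map coverage stay unscored
  s4 <- score_variability(rec, mixed)
  expect_equal(s4$unscored, 3)
})

test_that("classification summary counts are complete and consistent", {
  fx <- make_structure_fixture(120, 3, seed = 2)
  ref <- make_progenitor(120, 0.5, seed = 2)
  qry <- mutate_sequence(ref, 15, seed = 5)
  rec <- classify_substitutions(call_substitutions(ref, qry), fx$structure, qry)
  summ <- score_variability(rec, fx$varmap)
  expect_equal(summ$disruptive + summ$conservative, summ$n_substitutions)
  expect_equal(summ$low_variability + summ$high_variability +
                 summ$unscored, summ$n_substitutions)
  expect_equal(summ$unscored, 0)  # fixture map covers every position
})

test_that("Fisher's exact test matches enumeration and stats::fisher.test", {
  # printed-table contrast: strong disruptive excess
  expect_lt(fisher_exact_2x2(85, 95, 9, 60), 1e-3)

  # full hypergeometric enumeration: P(X=3) = P(X=0) = 1/20
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1)
  # the observed table is the mode: p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)

  # brute-force oracle over random tables with margins <= 30
  set.seed(77)
  for (i in 1:40) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0) next
    p <- fisher_exact_2x2(a, b, c, d)
    expect_equal(p, fisher_brute(a, b, c, d), tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-7)
    expect_true(p > 0 && p <= 1)
  }

  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "row sums")
})

test_that("growing the disruptive excess never weakens the evidence", {
  ps <- vapply(0:20, function(k) fisher_exact_2x2(10 + k, 20, 5, 20), 0)
  expect_true(all(diff(ps) <= 1e-12))
})
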