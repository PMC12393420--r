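minimal_model_text <- c(
  "#species",
  "id\tname\trole\ty_init\ty_max\ttau",
  "A\tA\tinput\t\t\t",
  "B\tB\toutput\t\t\t",
  "#rules",
  "rule\tw\tn\tec50",
  "=> A\t\t\t",
  "A => B\t\t\t"
)

test_that("a two-species model parses with all defaults filled in", {
  m <- parse_model(minimal_model_text)
  expect_s3_class(m, "network_model")
  expect_equal(nrow(m$species), 2)
  expect_equal(length(m$rules), 2)
  expect_equal(m$species$y_init, c(0, 0))
  expect_equal(m$species$y_max, c(1, 1))
  expect_equal(m$species$tau, c(1, 1))
  for (r in m$rules) {
    expect_equal(r$w, 1)
    expect_equal(r$n, 1.4)
    expect_equal(r$ec50, 0.5)
  }
  expect_identical(m$rules[[1]]$regulators$id, character(0))
  expect_identical(m$rules[[2]]$regulators$id, "A")
})

test_that("comments, blank lines and inline comments are ignored", {
  txt <- c("# a file comment", "", minimal_model_text[1:3],
           "B\tB node\toutput\t0\t1\t2\t# trailing comment", "",
           minimal_model_text[5:8])
  m <- parse_model(txt)
  expect_equal(m$species$name[2], "B node")
  expect_equal(m$species$tau[2], 2)
})

test_that("malformed inputs yield diagnostics naming the id and line", {
  bad <- c(minimal_model_text, "A => C\t\t\t")
  expect_error(parse_model(bad), "C")
  expect_error(parse_model(bad), "line 9")
  dup <- c(minimal_model_text[1:3], "A\tA again\tinput\t\t\t",
           minimal_model_text[4:8])
  expect_error(parse_model(dup), "duplicate species id")
  expect_error(parse_model(c("A\tA\tinput", minimal_model_text)),
               "before the first section")
  expect_error(parse_model(sub("rule\tw\tn\tec50", "w\trule", minimal_model_text)),
               "expected header")
  # ec50 outside (0, 0.5^(1/n))
  bad_ec <- minimal_model_text
  bad_ec[8] <- "A => B\t1\t1.4\t0.7"
  expect_error(parse_model(bad_ec), "ec50")
  # non-input species with only source rules
  src_only <- minimal_model_text
  src_only[8] <- "=> B\t\t\t"
  expect_error(parse_model(src_only), "at least one rule with a regulator")
  # input with a regulator rule
  not_src <- minimal_model_text
  not_src[7] <- "B => A\t\t\t"
  expect_error(parse_model(not_src), "exactly one source rule")
  expect_error(parse_model(c(minimal_model_text, "A B\t\t\t")), "malformed rule")
})

test_that("parse/write round-trips are exact on generated models", {
  kinds <- c("random_acyclic", "random", "cascade", "fan_in", "feedback")
  for (seed in 1:10) {
    kind <- kinds[(seed %% length(kinds)) + 1]
    m <- generate_random_network(5, 7, seed = seed, kind = kind)
    m2 <- parse_model(write_model(m))
    expect_equal(m2$species, m$species)
    expect_equal(length(m2$rules), length(m$rules))
    for (i in seq_along(m$rules)) {
      expect_equal(m2$rules[[i]]$regulators, m$rules[[i]]$regulators)
      expect_identical(m2$rules[[i]]$product, m$rules[[i]]$product)
      expect_identical(m2$rules[[i]]$w, m$rules[[i]]$w)
      expect_identical(m2$rules[[i]]$n, m$rules[[i]]$n)
      expect_identical(m2$rules[[i]]$ec50, m$rules[[i]]$ec50)
    }
  }
})

test_that("write_model output is deterministic and semantically stable", {
  m <- build_dyrk1a_model()
  l1 <- write_model(m)
  l2 <- write_model(m)
  expect_identical(l1, l2)
  # write(parse(t)) re-parses to the same model even though comments drop
  m2 <- parse_model(write_model(parse_model(minimal_model_text)))
  expect_equal(m2, parse_model(minimal_model_text))
})

test_that("validation suites parse, including defaults and empty files", {
  txt <- c("id\tperturbation\treadout\texpected_direction\tcontext\tsource",
           "v1\tKO:DYRK1A\tDNA_replication\tincrease\tcardiomyocyte\tref11",
           "v5\tOE:CDK2\tDNA_replication\tincrease\tcardiomyocyte\tref24",
           "vx\tKO:DYRK1A:0.3;OE:CDK2\tCycD\tno_change\tcancer\trefX")
  suite <- parse_validation_suite(txt)
  expect_s3_class(suite, "validation_suite")
  expect_equal(nrow(suite), 3)
  p1 <- suite$perturbations[[1]][[1]]
  expect_equal(p1$kind, "knockdown")
  expect_equal(p1$fraction, 1)  # 100% knockdown default
  expect_equal(suite$perturbations[[2]][[1]]$kind, "overexpression")
  expect_equal(length(suite$perturbations[[3]]), 2)
  expect_equal(suite$perturbations[[3]][[1]]$fraction, 0.3)

  expect_equal(nrow(parse_validation_suite(character())), 0)
  expect_equal(nrow(parse_validation_suite(txt[1])), 0)

  expect_error(parse_validation_suite(c(txt[1], "v\tKO:X\tY\tup\tc\ts")),
               "unknown direction")
  expect_error(parse_validation_suite(c(txt[1], "v\tXX:X\tY\tincrease\tc\ts")),
               "malformed perturbation")
  expect_error(parse_validation_suite(c(txt[1], "v\tKO:X:2\tY\tincrease\tc\ts")),
               "fraction")
})

test_that("validation suites round-trip through write_validation_suite", {
  suite <- cardiomyocyte_suite()
  lines <- write_validation_suite(suite)
  suite2 <- parse_validation_suite(lines)
  expect_equal(suite2$id, suite$id)
  expect_equal(suite2$expected_direction, suite$expected_direction)
  for (i in seq_len(nrow(suite))) {
    expect_equal(suite2$perturbations[[i]], suite$perturbations[[i]])
  }
})
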