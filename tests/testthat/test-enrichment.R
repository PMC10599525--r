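test_that("count_codons tallies sense codons and rejects stops in windows", {
  code <- genetic_code_partition()
  z <- count_codons(list(), code)
  expect_equal(sum(z), 0)
  expect_equal(attr(z, "total"), 0)

  cc <- count_codons(list(c("AAA", "AAA", "AAG")), code)
  expect_equal(unname(cc["AAA"]), 2)
  expect_equal(unname(cc["AAG"]), 1)
  expect_equal(attr(cc, "total"), 3)

  # additivity under concatenation
  dbl <- count_codons(list(c("AAA", "AAA", "AAG"), c("AAA", "AAA", "AAG")), code)
  expect_equal(as.integer(dbl), 2L * as.integer(cc))

  expect_error(count_codons(list(c("AAA", "TAA")), code), "stop codon")
  # ambiguous codons silently excluded
  amb <- count_codons(list(c("AAN", "AAA")), code)
  expect_equal(attr(amb, "total"), 1)
})

test_that("log_odds_cell matches the closed form and handles zeros", {
  eq <- log_odds_cell(10, 20, 10, 20)
  expect_equal(eq$log_odds, 0)
  expect_equal(eq$se, sqrt(1 / 10 + 1 / 10 + 1 / 20 + 1 / 20))
  expect_false(eq$corrected)

  lc <- log_odds_cell(8, 2, 2, 8)
  expect_equal(lc$log_odds, log(16))
  expect_equal(lc$se, sqrt(1.25))

  z <- log_odds_cell(0, 10, 5, 5)
  expect_true(z$corrected)
  expect_equal(z$log_odds, log((0.5 / 10.5) / (5.5 / 5.5)))
  expect_equal(z$se, sqrt(1 / 0.5 + 1 / 10.5 + 2 / 5.5))

  expect_true(is.na(log_odds_cell(0, 10, 5, 5, correction = "drop")$log_odds))
  expect_true(is.na(log_odds_cell(0, 0, 5, 5)$log_odds))
})

test_that("log_odds_vector agrees with an independent 2x2 oracle", {
  # oracle: blocks rebuilt from the Biostrings genetic code, plain
  # arithmetic per codon
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  oracle_vector <- function(t_counts, c_counts) {
    out <- c()
    for (cdn in sense) {
      syn <- setdiff(sense[gc[sense] == gc[[cdn]]], cdn)
      if (!length(syn)) next
      n1 <- t_counts[cdn]; s1 <- sum(t_counts[syn])
      n2 <- c_counts[cdn]; s2 <- sum(c_counts[syn])
      out[cdn] <- if (all(c(n1, s1, n2, s2) > 0))
        log((n1 / s1) / (n2 / s2)) else NA_real_
    }
    out[order(names(out))]
  }

  code <- genetic_code_partition()
  set.seed(42)
  for (i in 1:5) {
    t_raw <- stats::setNames(rpois(61, 30) + 1L, code$sense_codons)
    c_raw <- stats::setNames(rpois(61, 30) + 1L, code$sense_codons)
    tc <- structure(t_raw, total = sum(t_raw), class = "codon_counts")
    cc <- structure(c_raw, total = sum(c_raw), class = "codon_counts")
    v <- log_odds_vector(tc, cc, code)
    o <- oracle_vector(t_raw, c_raw)
    expect_equal(stats::setNames(v$log_odds, v$codon), o, tolerance = 1e-12)
  }
})

test_that("vector symmetries: swap, 2-fold negation, count scaling, block locality", {
  code <- genetic_code_partition()
  set.seed(7)
  t_raw <- stats::setNames(rpois(61, 40) + 1L, code$sense_codons)
  c_raw <- stats::setNames(rpois(61, 40) + 1L, code$sense_codons)
  as_cc <- function(x) structure(x, total = sum(x), class = "codon_counts")
  ab <- log_odds_vector(as_cc(t_raw), as_cc(c_raw), code)
  ba <- log_odds_vector(as_cc(c_raw), as_cc(t_raw), code)
  expect_equal(ab$log_odds, -ba$log_odds)
  expect_equal(ab$se, ba$se)

  # 2-fold block antisymmetry within one vector
  expect_equal(ab$log_odds[ab$codon == "AAA"], -ab$log_odds[ab$codon == "AAG"])
  expect_equal(ab$se[ab$codon == "AAA"], ab$se[ab$codon == "AAG"])

  # doubling all counts: log odds unchanged, SE shrinks by 1/sqrt(2)
  dbl <- log_odds_vector(as_cc(2L * t_raw), as_cc(2L * c_raw), code)
  expect_equal(dbl$log_odds, ab$log_odds)
  expect_equal(dbl$se, ab$se / sqrt(2))

  # block locality: changing Lys counts leaves other blocks untouched
  t2 <- t_raw; t2["AAA"] <- t2["AAA"] + 100L
  mod <- log_odds_vector(as_cc(t2), as_cc(c_raw), code)
  keep <- !mod$codon %in% c("AAA", "AAG")
  expect_equal(mod$log_odds[keep], ab$log_odds[keep])

  # target == comparator -> exact zeros
  self <- log_odds_vector(as_cc(t_raw), as_cc(t_raw), code)
  expect_equal(self$log_odds, rep(0, 59))
})

test_that("repartitioned blocks compute against the reduced synonym set", {
  # Lys-style example on a two-fold block
  code <- genetic_code_partition()
  as_cc <- function(x) {
    v <- stats::setNames(rep(1L, 61), code$sense_codons)
    v[names(x)] <- as.integer(x)
    structure(v, total = sum(v), class = "codon_counts")
  }
  v <- log_odds_vector(as_cc(c(AAA = 8, AAG = 2)), as_cc(c(AAA = 2, AAG = 8)), code)
  expect_equal(v$log_odds[v$codon == "AAA"], log(16))
  expect_equal(v$log_odds[v$codon == "AAG"], -log(16))

  # splitting Arg: AGG is now scored only against AGA
  split_code <- genetic_code_partition(repartition = list(
    R_AG = c("AGA", "AGG"), R_CG = c("CGT", "CGC", "CGA", "CGG")
  ))
  t_cnt <- as_cc(c(AGA = 10, AGG = 30, CGT = 5))
  c_cnt <- as_cc(c(AGA = 20, AGG = 20, CGT = 5))
  v2 <- log_odds_vector(t_cnt, c_cnt, split_code)
  expect_equal(v2$log_odds[v2$codon == "AGG"], log((30 / 10) / (20 / 20)))
})

test_that("positional log odds isolates a position-specific enrichment", {
  code <- genetic_code_partition()
  # target: AAA at position 2 only; elsewhere balanced Lys usage
  base <- c("GCA", "AAA", "AAG", "GCC", "AAA", "AAG")
  tgt <- c(list(), replicate(60, replace(base, 2, "AAA"), simplify = FALSE))
  cmp <- replicate(60, base, simplify = FALSE)
  # make comparator position 2 an even Lys split
  cmp[seq(1, 60, 2)] <- lapply(cmp[seq(1, 60, 2)], replace, 2, "AAA")
  cmp[seq(2, 60, 2)] <- lapply(cmp[seq(2, 60, 2)], replace, 2, "AAG")
  pm <- positional_log_odds(tgt, cmp, positions = c(2, 5), code = code)
  expect_length(pm, 2)
  aaa2 <- pm[["2"]]$log_odds[pm[["2"]]$codon == "AAA"]
  aaa5 <- pm[["5"]]$log_odds[pm[["5"]]$codon == "AAA"]
  expect_gt(aaa2, 1)
  expect_equal(aaa5, 0)
  # identical sets give zero vectors everywhere
  pm0 <- positional_log_odds(cmp, cmp, positions = 1:3, code = code)
  expect_true(all(vapply(pm0, function(v)
    all(is.na(v$log_odds) | v$log_odds == 0), TRUE)))
  # matrix assembly aligns codons x positions
  m <- positional_matrix_values(pm)
  expect_equal(dim(m), c(59, 2))
  # ragged input errors
  expect_error(positional_log_odds(list(c("AAA")), cmp, positions = 2),
               "too short")
})

test_that("vector CSV round trip preserves entries", {
  code <- genetic_code_partition()
  set.seed(3)
  t_raw <- stats::setNames(rpois(61, 25) + 1L, code$sense_codons)
  c_raw <- stats::setNames(rpois(61, 25) + 1L, code$sense_codons)
  as_cc <- function(x) structure(x, total = sum(x), class = "codon_counts")
  v <- log_odds_vector(as_cc(t_raw), as_cc(c_raw), code, label = "V_test")
  f <- withr::local_tempfile(fileext = ".csv")
  write_logodds_vector(v, f)
  v2 <- read_logodds_vector(f, label = "V_test")
  expect_equal(v2$log_odds, v$log_odds)
  expect_equal(v2$se, v$se)
  expect_equal(v2$codon, v$codon)
  # header-mapped read of a foreign table layout with extra columns
  df <- data.frame(codon = v$codon, foo = 1, V_x = v$log_odds)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  v3 <- read_logodds_vector(f2, value_col = "V_x")
  expect_equal(v3$log_odds, v$log_odds)
})
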