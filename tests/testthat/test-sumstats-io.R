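test_that("well-formed tables parse and row-level invariants are enforced", {
  tab <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                    effect_allele = c("a", "G", "C"),
                    other_allele = c("g", "T", "A"),
                    eaf = c(0.2, 0.5, 0.9),
                    beta = c(0.1, -0.05, 0.2),
                    se = c(0.01, 0.02, 0.03),
                    pvalue = c(1e-10, 0.5, 1e-8))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_summary_stats(f)
  expect_equal(nrow(got), 3)
  expect_equal(got$effect_allele, c("A", "G", "C"))  # upper-cased
  expect_equal(got$beta, tab$beta)

  # a zero-se row is rejected with a report, others still load
  tab$se[2] <- 0
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(got <- read_summary_stats(f), "rejected")
  expect_equal(got$rsid, c("rs1", "rs3"))
  rej <- attr(got, "rejected")
  expect_equal(rej$rsid, "rs2")
  expect_match(rej$reason, "standard error")

  # structural problems are hard errors
  write.table(tab[, setdiff(names(tab), "se")], f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(f), "mandatory column.*se")
  tab$se[2] <- 0.02
  tab$rsid[3] <- "rs1"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(f), "duplicated rsid.*rs1")
})

test_that("column mapping and delimiter selection work", {
  tab <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.3,
                    Effect = 0.1, StdErr = 0.01, P = 1e-9)
  f <- tempfile(fileext = ".csv")
  write.table(tab, f, sep = ",", quote = FALSE, row.names = FALSE)
  got <- read_summary_stats(f, column_map = c(
    rsid = "SNP", effect_allele = "A1", other_allele = "A2", eaf = "freq",
    beta = "Effect", se = "StdErr", pvalue = "P"), delimiter = ",")
  expect_equal(got$rsid, "rs1")
  expect_equal(got$beta, 0.1)
  expect_true(is.na(got$n))
})

test_that("a generated table survives a write/read round trip unchanged", {
  sim <- simulate_instruments(J = 25, theta = 0.1, seed = 11)
  f <- tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, f)
  back <- read_summary_stats(f)
  expect_equal(back, sim$exposure, ignore_attr = TRUE)
})

test_that("palindrome detection matches enumeration of all allele pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a = bases, b = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]      # 12 ordered pairs
  got <- is_palindromic(pairs$a, pairs$b)
  expect_equal(sum(got), 4)                 # A/T, T/A, C/G, G/C
  expect_true(all(got == (paste(pmin(pairs$a, pairs$b),
                                pmax(pairs$a, pairs$b)) %in%
                          c("A T", "C G"))))
  expect_true(is_palindromic("A", "T"))
  expect_false(is_palindromic("A", "G"))
  expect_warning(res <- is_palindromic("AT", "A"), "multi-base")
  expect_false(res)
})

test_that("orientation flips negative effects and is idempotent", {
  x <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                  eaf = 0.30, beta = -0.10, se = 0.02, pvalue = 1e-6,
                  n = NA_real_)
  y <- orient_to_increasing_allele(x)
  expect_equal(y$effect_allele, "G")
  expect_equal(y$other_allele, "A")
  expect_equal(y$beta, 0.10)
  expect_equal(y$eaf, 0.70)
  expect_equal(y$se, x$se)
  expect_equal(y$pvalue, x$pvalue)

  x$beta <- 0.10
  expect_identical(orient_to_increasing_allele(x), x)

  # property: orient twice == orient once, over random records
  for (s in 1:20) {
    set.seed(s)
    tab <- make_assoc(10, seed = s)
    once <- orient_to_increasing_allele(tab)
    expect_identical(orient_to_increasing_allele(once), once)
    expect_true(all(once$beta >= 0))
  }
})

test_that("harmonization aligns, flags and conserves variants", {
  expo <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                     effect_allele = c("A", "A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "G", "C"),
                     eaf = c(0.3, 0.3, 0.5, 0.3, 0.3),
                     beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                     se = rep(0.01, 5), pvalue = rep(1e-9, 5),
                     n = NA_real_)
  outc <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs5"),
                     effect_allele = c("A", "G", "A", "A"),
                     other_allele = c("G", "A", "T", "G"),
                     eaf = c(0.32, 0.69, 0.5, 0.31),
                     beta = c(0.05, -0.05, 0.02, 0.01),
                     se = rep(0.02, 4), pvalue = rep(0.01, 4),
                     n = NA_real_)
  h <- harmonize(expo, outc)
  expect_s3_class(h, "harmonized_instruments")
  flags <- setNames(h$exclusion_flag, h$rsid)
  expect_equal(unname(flags["rs1"]), "none")
  # swapped alleles: beta negated, eaf complemented, retained
  expect_equal(unname(flags["rs2"]), "none")
  expect_equal(h$beta_outcome[h$rsid == "rs2"], 0.05)
  expect_equal(h$eaf_outcome[h$rsid == "rs2"], 0.31)
  # palindromic A/T at eaf 0.5 in both studies: maximally ambiguous
  expect_equal(unname(flags["rs3"]), "palindromic_ambiguous")
  # absent from outcome, no proxy search: excluded and logged
  expect_equal(unname(flags["rs4"]), "missing_in_outcome")
  # allele pair matching neither directly nor by swap
  expect_equal(unname(flags["rs5"]), "multiallelic_conflict")

  log <- attr(h, "log")
  expect_equal(log$n_input, 5)
  expect_equal(log$n_retained + log$n_excluded, log$n_input)
  expect_equal(nrow(retained_instruments(h)), 2)
  expect_error(harmonize(expo, transform(outc, rsid = paste0("x", rsid))),
               "no overlapping")
})

test_that("cross-study frequency inconsistency is flagged", {
  expo <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                     eaf = 0.10, beta = 0.1, se = 0.01, pvalue = 1e-9,
                     n = NA_real_)
  outc <- transform(expo, eaf = 0.45, beta = 0.05, se = 0.02, pvalue = 0.01)
  expect_equal(harmonize(expo, outc)$exclusion_flag, "allele_mismatch")
  expect_equal(harmonize(expo, outc, freq_tolerance = 0.5)$exclusion_flag,
               "none")
})

test_that("palindromic variants with clear same-side frequencies survive", {
  expo <- data.frame(rsid = c("rs1", "rs2"),
                     effect_allele = "A", other_allele = "T",
                     eaf = c(0.30, 0.30), beta = 0.1, se = 0.01,
                     pvalue = 1e-9, n = NA_real_)
  outc <- transform(expo, eaf = c(0.33, 0.65), beta = 0.05, se = 0.02,
                    pvalue = 0.01)
  h <- harmonize(expo, outc)
  expect_equal(h$exclusion_flag, c("none", "palindromic_ambiguous"))
  # near 0.5 in one study (MAF above the ambiguity limit): excluded
  outc$eaf <- c(0.45, 0.33)
  h <- harmonize(expo, outc)
  expect_equal(h$exclusion_flag[1], "palindromic_ambiguous")
})

test_that("harmonization is symmetric under re-encoding of both tables", {
  sim <- simulate_instruments(J = 15, theta = 0.1, seed = 21)
  base <- retained_instruments(harmonize(sim$exposure, sim$outcome))
  flip_encoding <- function(tab, idx) {
    ea <- tab$effect_allele[idx]
    tab$effect_allele[idx] <- tab$other_allele[idx]
    tab$other_allele[idx] <- ea
    tab$beta[idx] <- -tab$beta[idx]
    tab$eaf[idx] <- 1 - tab$eaf[idx]
    tab
  }
  idx <- c(2, 5, 9)
  flipped <- retained_instruments(
    harmonize(flip_encoding(sim$exposure, idx),
              flip_encoding(sim$outcome, idx)))
  expect_equal(flipped$beta_exposure, base$beta_exposure)
  expect_equal(flipped$beta_outcome, base$beta_outcome)
})

test_that("consistent non-palindromic synthetic data is fully retained", {
  for (s in c(3, 17, 91)) {
    sim <- simulate_instruments(J = 40, theta = 0.05, seed = s)
    h <- harmonize(sim$exposure, sim$outcome)
    expect_true(all(h$exclusion_flag == "none"))
    expect_true(all(h$beta_exposure >= 0))
  }
})

test_that("harmonized tables and logs serialize to TSV and JSON", {
  sim <- simulate_instruments(J = 8, theta = 0.1, seed = 31)
  h <- harmonize(sim$exposure, sim$outcome)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_harmonized(h, tsv)
  got <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(names(got)[1:2], c("rsid", "effect_allele"))
  expect_equal(nrow(got), 8)
  write_harmonization_log(h, js)
  log <- jsonlite::read_json(js)
  expect_equal(log$n_input, 8)
})
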