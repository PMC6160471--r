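# Reading, validation and harmonization of GWAS summary-statistic tables.

#' Standard column names for a summary-statistic table
#'
#' Mandatory: rsid, effect_allele, other_allele, beta, se, pvalue.
#' Optional: eaf, n.
#' @keywords internal
.SUMSTAT_COLS <- c("rsid", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pvalue", "n")
.SUMSTAT_MANDATORY <- c("rsid", "effect_allele", "other_allele",
                        "beta", "se", "pvalue")

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (optionally gzipped) of per-variant
#' associations into a validated data frame with the package's standard
#' columns: \code{rsid}, \code{effect_allele}, \code{other_allele},
#' \code{eaf}, \code{beta}, \code{se}, \code{pvalue} and optionally
#' \code{n}.  Exposure effect sizes are expected in per-SD units and
#' outcome effect sizes on the log-odds scale, but the reader itself is
#' scale-agnostic.
#'
#' Rows violating per-row invariants (non-positive standard error,
#' allele frequency outside [0, 1], p-value outside (0, 1], identical
#' effect and other allele) are dropped and reported in the
#' \code{"rejected"} attribute of the result.  Structural problems
#' (missing mandatory column, duplicated rsid) are hard errors.
#'
#' @param path Path to a delimited text file with one header row.
#' @param column_map Optional named character vector mapping standard
#'   names to the file's column names, e.g.
#'   \code{c(rsid = "SNP", beta = "Effect")}.  Unmapped standard names
#'   are looked up verbatim.
#' @param delimiter Field separator, default tab.
#' @return A data frame of validated variant associations, with
#'   attribute \code{"rejected"} holding a data frame of dropped rows
#'   and the reason each was dropped.
#' @export
read_summary_stats <- function(path, column_map = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  nm <- stats::setNames(.SUMSTAT_COLS, .SUMSTAT_COLS)
  if (!is.null(column_map)) nm[names(column_map)] <- column_map
  for (col in .SUMSTAT_MANDATORY) {
    if (!nm[[col]] %in% names(raw))
      stop("mandatory column missing: '", nm[[col]], "' (", col, ")")
  }
  out <- data.frame(rsid = as.character(raw[[nm["rsid"]]]),
                    effect_allele = toupper(as.character(raw[[nm["effect_allele"]]])),
                    other_allele = toupper(as.character(raw[[nm["other_allele"]]])),
                    eaf = if (nm["eaf"] %in% names(raw)) as.numeric(raw[[nm["eaf"]]]) else NA_real_,
                    beta = as.numeric(raw[[nm["beta"]]]),
                    se = as.numeric(raw[[nm["se"]]]),
                    pvalue = as.numeric(raw[[nm["pvalue"]]]),
                    n = if (nm["n"] %in% names(raw)) as.numeric(raw[[nm["n"]]]) else NA_real_,
                    stringsAsFactors = FALSE)
  validate_associations(out)
}

#' Validate a table of variant associations
#'
#' Enforces the row-level invariants of a summary-statistic table and
#' drops offending rows with a per-row report; duplicated rsids are a
#' hard error.
#'
#' @param x Data frame with the standard summary-statistic columns.
#' @return The validated data frame with attribute \code{"rejected"}.
#' @export
validate_associations <- function(x) {
  dup <- unique(x$rsid[duplicated(x$rsid)])
  if (length(dup) > 0)
    stop("duplicated rsid(s): ", paste(dup, collapse = ", "))
  reason <- rep(NA_character_, nrow(x))
  bad_se <- !is.finite(x$se) | x$se <= 0
  bad_eaf <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  bad_p <- !is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1
  bad_allele <- x$effect_allele == x$other_allele
  reason[bad_allele] <- "effect and other allele identical"
  reason[bad_p] <- "p-value outside (0, 1]"
  reason[bad_eaf] <- "eaf outside [0, 1]"
  reason[bad_se] <- "non-positive or missing standard error"
  keep <- is.na(reason)
  rejected <- data.frame(rsid = x$rsid[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    message(nrow(rejected), " row(s) rejected during validation")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are complementary
#' (A/T or C/G), so strand orientation cannot be resolved from the
#' alleles alone.  Vectorized.
#'
#' @param effect_allele,other_allele Character vectors of alleles.
#' @return Logical vector; multi-base alleles give \code{FALSE} with a
#'   warning (indels cannot be palindromic in this sense).
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  multi <- nchar(a) != 1L | nchar(b) != 1L
  if (any(multi))
    warning("multi-base allele(s) treated as non-palindromic")
  pal <- (a == "A" & b == "T") | (a == "T" & b == "A") |
         (a == "C" & b == "G") | (a == "G" & b == "C")
  pal & !multi
}

#' Orient associations to the trait-increasing allele
#'
#' Flips each record with a negative effect size so that the effect
#' allele is the trait-increasing allele: effect and other alleles are
#' swapped, the beta is negated and the effect-allele frequency is
#' complemented.  Standard error and p-value are unchanged.  Idempotent.
#'
#' @param assoc Data frame of variant associations.
#' @return The oriented data frame.
#' @export
orient_to_increasing_allele <- function(assoc) {
  flip <- !is.na(assoc$beta) & assoc$beta < 0
  if (any(flip)) {
    ea <- assoc$effect_allele[flip]
    assoc$effect_allele[flip] <- assoc$other_allele[flip]
    assoc$other_allele[flip] <- ea
    assoc$beta[flip] <- -assoc$beta[flip]
    assoc$eaf[flip] <- 1 - assoc$eaf[flip]
  }
  assoc
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins exposure and outcome association tables on rsid and places both
#' effects on the exposure-increasing allele.  Outcome records whose
#' alleles match the exposure's after a swap have their beta negated and
#' frequency complemented.  Palindromic variants are retained only when
#' both studies report an effect-allele frequency on the same side of
#' 0.5 and each frequency is far enough from 0.5 to make the assignment
#' unambiguous (minor allele frequency at most \code{maf_ambiguity_limit}).
#' Variants absent from the outcome, allele pairs matching neither
#' directly nor by swap, and variants with inconsistent cross-study
#' frequencies are flagged and excluded from estimation.
#'
#' @param exposure Exposure association table (validated); orientation to
#'   the increasing allele is applied internally.
#' @param outcome Outcome association table (validated).
#' @param maf_ambiguity_limit Palindromic variants with minor-allele
#'   frequency above this value in either study are deemed unalignable.
#'   Default 0.42.
#' @param freq_tolerance Maximum tolerated cross-study difference in
#'   effect-allele frequency. Default 0.20.
#' @return A data frame of harmonized instruments with columns
#'   \code{rsid}, \code{effect_allele}, \code{other_allele},
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}, \code{eaf_exposure}, \code{eaf_outcome},
#'   \code{exclusion_flag}; rows with flag \code{"none"} enter
#'   estimation.  The \code{"log"} attribute holds the harmonization
#'   log (per-variant records and counts by reason).
#' @export
harmonize <- function(exposure, outcome,
                      maf_ambiguity_limit = 0.42, freq_tolerance = 0.20) {
  exposure_flip <- !is.na(exposure$beta) & exposure$beta < 0
  exposure <- orient_to_increasing_allele(exposure)
  if (!any(exposure$rsid %in% outcome$rsid))
    stop("no overlapping variants between exposure and outcome tables")
  om <- match(exposure$rsid, outcome$rsid)
  J <- nrow(exposure)
  flag <- rep("none", J)
  flipped <- rep(FALSE, J)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, J)

  for (j in seq_len(J)) {
    if (is.na(om[j])) { flag[j] <- "missing_in_outcome"; next }
    o <- outcome[om[j], ]
    direct <- o$effect_allele == exposure$effect_allele[j] &&
              o$other_allele == exposure$other_allele[j]
    swapped <- o$effect_allele == exposure$other_allele[j] &&
               o$other_allele == exposure$effect_allele[j]
    if (!direct && !swapped) { flag[j] <- "multiallelic_conflict"; next }
    beta_out[j] <- if (direct) o$beta else -o$beta
    se_out[j] <- o$se
    eaf_out[j] <- if (direct) o$eaf else 1 - o$eaf
    flipped[j] <- swapped
  }

  single <- nchar(exposure$effect_allele) == 1L & nchar(exposure$other_allele) == 1L
  pal <- rep(FALSE, J)
  pal[single] <- suppressWarnings(
    is_palindromic(exposure$effect_allele[single], exposure$other_allele[single]))
  margin <- 0.5 - maf_ambiguity_limit
  for (j in which(pal & flag == "none")) {
    fe <- exposure$eaf[j]; fo <- eaf_out[j]
    ok <- !is.na(fe) && !is.na(fo) &&
      sign(fe - 0.5) == sign(fo - 0.5) &&
      abs(fe - 0.5) >= margin && abs(fo - 0.5) >= margin
    if (!ok) flag[j] <- "palindromic_ambiguous"
  }

  freq_diff <- abs(exposure$eaf - eaf_out)
  mism <- flag == "none" & !is.na(freq_diff) & freq_diff > freq_tolerance
  flag[mism] <- "allele_mismatch"

  res <- data.frame(rsid = exposure$rsid,
                    effect_allele = exposure$effect_allele,
                    other_allele = exposure$other_allele,
                    beta_exposure = exposure$beta,
                    se_exposure = exposure$se,
                    beta_outcome = beta_out,
                    se_outcome = se_out,
                    eaf_exposure = exposure$eaf,
                    eaf_outcome = eaf_out,
                    exclusion_flag = flag,
                    stringsAsFactors = FALSE)
  log <- list(
    n_input = J,
    n_retained = sum(flag == "none"),
    n_excluded = sum(flag != "none"),
    counts_by_reason = as.list(table(flag[flag != "none"])),
    records = data.frame(rsid = res$rsid, exposure_flip = exposure_flip,
                         outcome_allele_swap = flipped,
                         eaf_difference = freq_diff, exclusion_flag = flag,
                         stringsAsFactors = FALSE))
  attr(res, "log") <- log
  class(res) <- c("harmonized_instruments", "data.frame")
  res
}

#' Retained (estimation-ready) rows of a harmonized table
#' @param h Result of [harmonize()].
#' @return The rows with \code{exclusion_flag == "none"}.
#' @export
retained_instruments <- function(h) {
  out <- h[h$exclusion_flag == "none", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a harmonized table as TSV
#'
#' Columns are written in a fixed order so downstream consumers can rely
#' on it.
#' @param h Result of [harmonize()].
#' @param path Output path.
#' @export
write_harmonized <- function(h, path) {
  cols <- c("rsid", "effect_allele", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome", "eaf_exposure", "eaf_outcome",
            "exclusion_flag")
  utils::write.table(as.data.frame(h)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the harmonization log as JSON
#' @param h Result of [harmonize()].
#' @param path Output path.
#' @export
write_harmonization_log <- function(h, path) {
  jsonlite::write_json(attr(h, "log"), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
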