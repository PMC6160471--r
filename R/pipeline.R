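# Study orchestration: lipid analyses (comprehensive -> restrictive ->
# MR-PRESSO-adjusted) and cis drug-target analyses, with reporting.

.DEFAULT_THRESHOLDS <- list(p_gws = 5e-8, p_secondary = 1e-3, r2_max = 0.4,
                            alpha_global = 0.05, alpha_outlier = 0.05,
                            maf_ambiguity_limit = 0.42, freq_tolerance = 0.20)

#' Build or load an analysis configuration
#'
#' Accepts either a path to a YAML file or a list.  Required fields:
#' \code{seed}, plus \code{panel} and \code{outcomes} for the lipid
#' analysis and/or \code{genes} for the drug-target analysis.  Tables
#' may be given as file paths (read lazily at run time) or as data
#' frames.  Threshold defaults: genome-wide significance 5e-8, secondary
#' lipid association 1e-3, LD pruning ceiling r2 < 0.4, MR-PRESSO
#' global/outlier alpha 0.05.
#'
#' @param x Path to a YAML config or a list.
#' @return A validated \code{mr_config} list.
#' @export
mr_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("config must set a seed")
  th <- .DEFAULT_THRESHOLDS
  th[names(cfg$thresholds)] <- cfg$thresholds
  cfg$thresholds <- th
  if (is.null(cfg$n_sim)) cfg$n_sim <- 1000
  if (is.null(cfg$n_boot)) cfg$n_boot <- 1000
  if (is.null(cfg$effects_model)) cfg$effects_model <- "multiplicative_random"
  if (is.null(cfg$presso_on_comprehensive)) cfg$presso_on_comprehensive <- TRUE
  refs <- c(list(cfg$panel), unname(as.list(cfg$outcomes)),
            unlist(lapply(cfg$genes,
                          function(g) list(g$exposure, g$ld)),
                   recursive = FALSE))
  for (p in refs)
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("configured file does not exist: ", p)
  class(cfg) <- c("mr_config", "list")
  cfg
}

.load_sumstats <- function(x) {
  if (is.character(x)) read_summary_stats(x) else x
}

.load_panel <- function(x) {
  if (is.character(x))
    utils::read.table(x, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else x
}

.load_ld <- function(x) {
  if (is.character(x)) load_ld_matrix(x) else validate_ld_matrix(x)
}

# exposure-format view of one lipid's statistics from a multi-lipid panel
panel_to_exposure <- function(panel, lipid) {
  cols <- .panel_cols(lipid)
  data.frame(rsid = panel$rsid,
             effect_allele = toupper(panel$effect_allele),
             other_allele = toupper(panel$other_allele),
             eaf = if ("eaf" %in% names(panel)) panel$eaf else NA_real_,
             beta = panel[[cols["beta"]]],
             se = panel[[cols["se"]]],
             pvalue = panel[[cols["p"]]],
             n = NA_real_, stringsAsFactors = FALSE)
}

.empty_result_row <- function() {
  data.frame(exposure = NA_character_, outcome = NA_character_,
             selection = NA_character_, method = NA_character_,
             n_variants = NA_integer_, beta = NA_real_, se = NA_real_,
             or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
             pvalue = NA_real_, intercept = NA_real_,
             intercept_p = NA_real_, phi = NA_real_,
             q_prime = NA_real_, q_prime_p = NA_real_,
             presso_global_p = NA_real_, n_outliers = NA_integer_,
             outliers = NA_character_, error = NA_character_,
             stringsAsFactors = FALSE)
}

.estimate_row <- function(exposure, outcome, selection, est, qp = NULL,
                          presso_p = NA_real_, n_outliers = NA_integer_,
                          outliers = NA_character_) {
  row <- .empty_result_row()
  row$exposure <- exposure; row$outcome <- outcome
  row$selection <- selection; row$method <- est$method
  row$n_variants <- est$n_variants
  row$beta <- est$beta; row$se <- est$se
  or <- to_odds_ratio(est)
  row$or <- or$or; row$or_ci_low <- or$ci_low; row$or_ci_high <- or$ci_high
  row$pvalue <- est$pvalue
  if (!is.null(est$intercept)) {
    row$intercept <- est$intercept; row$intercept_p <- est$intercept_p
  }
  row$phi <- est$phi
  if (!is.null(qp)) { row$q_prime <- qp$q_prime; row$q_prime_p <- qp$pvalue }
  row$presso_global_p <- presso_p
  row$n_outliers <- n_outliers
  row$outliers <- outliers
  row
}

.error_row <- function(exposure, outcome, selection, method, e) {
  row <- .empty_result_row()
  row$exposure <- exposure; row$outcome <- outcome
  row$selection <- selection; row$method <- method
  row$error <- conditionMessage(e)
  row
}

#' Run the full lipid-level MR analysis
#'
#' For every lipid in the panel crossed with every configured outcome:
#' comprehensive and restrictive instrument selection, harmonization,
#' IVW / MR-Egger / weighted-median estimation with the modified
#' second-order-weight heterogeneity statistic, and the MR-PRESSO
#' remove-and-retest workflow on the restrictive set (and, by default,
#' also on the comprehensive set).  Failures are isolated per cell: an
#' error in one lipid-outcome combination is recorded in the
#' \code{error} column and the run continues.
#'
#' @param config An [mr_config()].
#' @return Data frame of results, one row per
#'   (exposure, outcome, selection, method), with OR-scale columns and
#'   a \code{decision} flag (see [apply_decision_rule()]).
#' @export
run_lipid_analysis <- function(config) {
  config <- mr_config(config)
  panel <- .load_panel(config$panel)
  .check_panel(panel)
  outcomes <- lapply(config$outcomes, .load_sumstats)
  th <- config$thresholds
  rows <- list()
  cell <- 0L
  for (lipid in .LIPIDS) {
    expo <- panel_to_exposure(panel, lipid)
    for (oname in names(outcomes)) {
      cell <- cell + 1L
      seed_cell <- .substream(config$seed, 100L + cell)
      sets <- tryCatch(
        list(comprehensive = select_comprehensive(panel, lipid, th$p_gws),
             restrictive = select_restrictive(panel, lipid, th$p_gws,
                                              th$p_secondary)),
        error = function(e) e)
      if (inherits(sets, "error")) {
        rows[[length(rows) + 1L]] <-
          .error_row(lipid, oname, "selection", "all", sets)
        next
      }
      harm <- tryCatch(
        retained_instruments(harmonize(expo, outcomes[[oname]],
                                       th$maf_ambiguity_limit,
                                       th$freq_tolerance)),
        error = function(e) e)
      if (inherits(harm, "error")) {
        rows[[length(rows) + 1L]] <-
          .error_row(lipid, oname, "harmonization", "all", harm)
        next
      }
      for (sel in names(sets)) {
        dat <- harm[harm$rsid %in% sets[[sel]], , drop = FALSE]
        qp <- tryCatch(q_prime(dat), error = function(e) NULL)
        fits <- list(
          ivw = function() mr_ivw(dat, config$effects_model),
          egger = function() mr_egger(dat),
          weighted_median = function()
            mr_weighted_median(dat, config$n_boot, seed_cell))
        for (m in names(fits)) {
          rows[[length(rows) + 1L]] <- tryCatch(
            .estimate_row(lipid, oname, sel, fits[[m]](), qp),
            error = function(e) .error_row(lipid, oname, sel, m, e))
        }
        run_presso <- sel == "restrictive" ||
          (sel == "comprehensive" && isTRUE(config$presso_on_comprehensive))
        if (run_presso) {
          rows[[length(rows) + 1L]] <- tryCatch({
            pw <- presso_workflow(dat, config$n_sim, seed_cell,
                                  th$alpha_outlier, th$alpha_global,
                                  config$effects_model)
            .estimate_row(lipid, oname, paste0(sel, "_presso"),
                          pw$adjusted_estimate, pw$q_prime_after,
                          presso_p = pw$global_p,
                          n_outliers = length(pw$outliers),
                          outliers = paste(pw$outliers, collapse = ","))
          }, error = function(e)
            .error_row(lipid, oname, paste0(sel, "_presso"), "ivw", e))
        }
      }
    }
  }
  apply_decision_rule(do.call(rbind, rows))
}

#' Run the cis drug-target MR analysis
#'
#' For every configured gene region crossed with every outcome: greedy
#' LD-pruned instrument selection, harmonization, and correlated-
#' instrument IVW and Egger estimation with the signed LD matrix
#' re-signed to the post-orientation allele coding.  Per-cell error
#' isolation as in [run_lipid_analysis()].
#'
#' @param config An [mr_config()] with a \code{genes} list (each entry:
#'   \code{gene}, \code{lipid}, \code{exposure} summary statistics for
#'   the candidate variants, \code{ld} matrix).
#' @return Data frame of results with a \code{decision} flag.
#' @export
run_drug_target_analysis <- function(config) {
  config <- mr_config(config)
  outcomes <- lapply(config$outcomes, .load_sumstats)
  th <- config$thresholds
  rows <- list()
  for (g in config$genes) {
    expo <- .load_sumstats(g$exposure)
    ld <- .load_ld(g$ld)
    for (oname in names(outcomes)) {
      res <- tryCatch({
        region <- gene_region_spec(g$gene, g$lipid,
                                   data.frame(rsid = expo$rsid,
                                              pvalue = expo$pvalue,
                                              stringsAsFactors = FALSE))
        sel <- select_gene_region(region, ld, th$p_gws, th$r2_max)
        h <- harmonize(expo[expo$rsid %in% sel, , drop = FALSE],
                       outcomes[[oname]],
                       th$maf_ambiguity_limit, th$freq_tolerance)
        dat <- retained_instruments(h)
        # re-sign LD to the allele coding after orientation flips
        recs <- attr(h, "log")$records
        flip <- recs$exposure_flip[match(dat$rsid, recs$rsid)]
        s <- ifelse(flip, -1, 1)
        ld_sub <- ld[dat$rsid, dat$rsid, drop = FALSE] * outer(s, s)
        dimnames(ld_sub) <- list(dat$rsid, dat$rsid)
        qp <- tryCatch(q_prime(dat), error = function(e) NULL)
        list(
          .estimate_row(g$gene, oname, "gene_region",
                        mr_ivw_correlated(dat, ld_sub), qp),
          .estimate_row(g$gene, oname, "gene_region",
                        mr_egger_correlated(dat, ld_sub), qp))
      }, error = function(e)
        list(.error_row(g$gene, oname, "gene_region", "correlated", e)))
      rows <- c(rows, res)
    }
  }
  apply_decision_rule(do.call(rbind, rows))
}

#' Flag results meeting the study's decision rule
#'
#' A result cell (one exposure-outcome-selection group) is marked when
#' its estimates agree in direction across methods, the IVW-type
#' estimate passes nominal significance, the Egger confidence interval
#' overlaps the IVW interval (magnitude agreement), and there is no
#' evidence of pleiotropic bias (Egger intercept p > 0.05 and, when
#' available, heterogeneity p > 0.05).  The flag annotates; it never
#' filters rows.
#'
#' @param results Result data frame from the run functions.
#' @return The data frame with a logical \code{decision} column.
#' @export
apply_decision_rule <- function(results) {
  results$decision <- NA
  if (nrow(results) == 0) return(results)
  key <- paste(results$exposure, results$outcome, results$selection)
  for (k in unique(key)) {
    idx <- which(key == k & is.na(results$error))
    if (length(idx) == 0) next
    grp <- results[idx, ]
    ivw_row <- grp[grp$method %in% c("ivw", "ivw_correlated"), ][1, ]
    egger_row <- grp[grp$method %in% c("egger", "egger_correlated"), ][1, ]
    if (is.na(ivw_row$method)) next
    ok <- length(unique(sign(grp$beta))) == 1 &&
      ivw_row$pvalue < 0.05
    if (ok && !is.na(egger_row$method)) {
      overlap <- egger_row$or_ci_low <= ivw_row$or_ci_high &&
                 egger_row$or_ci_high >= ivw_row$or_ci_low
      ok <- overlap && (is.na(egger_row$intercept_p) ||
                        egger_row$intercept_p > 0.05)
    }
    if (ok && !is.na(ivw_row$q_prime_p))
      ok <- ivw_row$q_prime_p > 0.05
    results$decision[idx] <- ok
  }
  results
}

#' Write an analysis report as TSV and JSON
#'
#' @param results Result data frame.
#' @param dir Output directory (created if absent).
#' @param prefix File name stem, default \code{"mr_results"}.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, prefix = "mr_results") {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  json <- file.path(dir, paste0(prefix, ".json"))
  utils::write.table(results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(results, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
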